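#' Soft-thresholded coexpression adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta` (unsigned, Pearson), or
#' `((1 + cor)/2)^beta` for the signed variant.  Constant genes are dropped
#' with a warning; the diagonal is set to 1.
#'
#' @param expr genes x samples matrix (>= 4 samples).
#' @param beta soft power, >= 1.
#' @param signed use the signed transformation instead of `|cor|`.
#' @return symmetric adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(expr, beta = 6, signed = FALSE) {
  .stop_if(beta < 1, "beta must be >= 1")
  expr <- as.matrix(expr)
  .stop_if(ncol(expr) < 4, "need at least 4 samples")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant genes")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  cc <- cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology scan over soft powers
#'
#' For each candidate power, computes the connectivity distribution
#' `k_i = sum_(u != i) a_iu`, bins it (default 10 bins), regresses
#' `log10(frequency)` on `log10(mean bin k)` and reports the signed fit
#' index `-sign(slope) * R^2` together with mean/median/max connectivity.
#' The smallest power whose index reaches `rsq_target` is recommended.
#'
#' @param expr genes x samples matrix.
#' @param powers candidate powers, within \[1, 30\].
#' @param n_bins histogram bins for the connectivity distribution.
#' @param rsq_target fit-index target for the recommendation (default 0.8).
#' @return object of class `soft_threshold_scan`: data frame (`power`,
#'   `fit_index`, `mean_k`, `median_k`, `max_k`) with attribute
#'   `recommended` (NA when no power reaches the target).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, n_bins = 10,
                                rsq_target = 0.8) {
  .stop_if(any(powers < 1 | powers > 30), "powers must lie in [1, 30]")
  powers <- sort(unique(powers))
  expr <- as.matrix(expr)
  cc <- abs(cor(t(expr)))
  diag(cc) <- 0
  rows <- lapply(powers, function(b) {
    a <- cc^b
    k <- rowSums(a)
    .stop_if(all(k == 0), "all-zero connectivity at power ", b)
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    mk <- tapply(k, bin, mean)
    keep <- !is.na(freq) & freq > 0 & mk > 0
    fit_index <- NA_real_
    if (sum(keep) >= 3) {
      lf <- log10(freq[keep]); lk <- log10(mk[keep])
      fit <- stats::lm.fit(cbind(1, lk), lf)
      r2 <- 1 - sum(fit$residuals^2) / sum((lf - mean(lf))^2)
      fit_index <- unname(-sign(fit$coefficients[2]) * r2)
    }
    data.frame(power = b, fit_index = fit_index, mean_k = mean(k),
               median_k = median(k), max_k = max(k))
  })
  out <- do.call(rbind, rows)
  rec <- out$power[!is.na(out$fit_index) & out$fit_index >= rsq_target]
  attr(out, "recommended") <- if (length(rec)) min(rec) else NA_integer_
  class(out) <- c("soft_threshold_scan", "data.frame")
  out
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (scale-free fit index)\n")
  print(as.data.frame(round(as.data.frame(x), 3)))
  rec <- attr(x, "recommended")
  cat("recommended power:", if (is.na(rec)) "none reaches target" else rec, "\n")
  invisible(x)
}

#' @export
plot.soft_threshold_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$power, x$fit_index, type = "b", xlab = "soft power",
       ylab = "scale-free fit index", ...)
  graphics::abline(h = 0.8, lty = 2)
  plot(x$power, x$mean_k, type = "b", log = "y", xlab = "soft power",
       ylab = "mean connectivity", ...)
  invisible(x)
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.  The adjacency
#' diagonal is excluded from both `k` and `l`.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return symmetric TOM in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  .stop_if(!isSymmetric(unname(a), tol = 1e-12), "adjacency must be symmetric")
  diag(a) <- 1
  k <- rowSums(a) - 1
  l <- a %*% a - 2 * a          # removes the two diagonal contributions
  tom <- (l + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

# consolidate fragments of one module found in different sequential
# rounds: iteratively merge the pair of modules with the largest absolute
# eigengene correlation while it exceeds min_cor (independent factors
# rarely exceed |cor| ~0.5 at bulk-study sample sizes, fragments of one
# factor do)
.consolidate_fragments <- function(expr, labels, min_cor = 0.55) {
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2) break
    egs <- eigengenes(expr, labels)
    cc <- abs(cor(t(egs)))
    diag(cc) <- 0
    if (max(cc) < min_cor) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    labels[labels == mods[ij[2]]] <- mods[ij[1]]
  }
  labels
}

# deep adaptive cut of the average-linkage TOM dendrogram: clusters at
# height mean - core_sd * SD of the off-diagonal dissimilarity (fallback:
# median merge height when no merge lies below)
.tom_cores <- function(tom, core_min, core_sd = 2) {
  d <- 1 - tom
  hc <- hclust(as.dist(d), method = "average")
  offd <- d[upper.tri(d)]
  h0 <- mean(offd) - core_sd * sd(offd)
  if (h0 <= min(hc$height)) {
    # strongly separated geometry: cut in the largest gap of merge heights
    hs <- sort(hc$height)
    if (length(hs) > 1) {
      i <- which.max(diff(hs))
      h0 <- (hs[i] + hs[i + 1]) / 2
    } else {
      h0 <- hs[1] / 2
    }
  }
  cl <- cutree(hc, h = h0)
  tab <- table(cl)
  list(cores = lapply(names(tab[tab >= core_min]),
                      function(b) which(cl == as.integer(b))),
       tree = hc)
}

#' Detect coexpression modules from a TOM
#'
#' Tree-based module detection in three stages: (1) a deep adaptive cut of
#' the average-linkage dendrogram of `1 - TOM` proposes tight cores;
#' (2) cores belonging to the same module are consolidated by linking pairs
#' whose mean inter-core TOM reaches `link_frac` of the looser core's
#' internal TOM; (3) genes are iteratively assigned to the core with the
#' highest mean TOM relative to that core's internal level (threshold
#' `assign_frac`, self-similarity excluded).  Modules smaller than
#' `min_size` are dissolved into label 0 (unassigned); labels are numbered
#' by decreasing size (1 = largest).
#'
#' @param tom topological overlap matrix (see [tom_similarity()]).
#' @param min_size minimum module size (>= 2).
#' @param core_min minimum size of a core proposal.
#' @param core_sd depth of the core cut, in SDs of the off-diagonal
#'   dissimilarity below its mean.
#' @param link_frac consolidation threshold (fraction of core tightness).
#' @param assign_frac membership threshold (fraction of module tightness).
#' @param n_iter assignment iterations.
#' @return integer labels, one per gene (named from `tom` rownames);
#'   0 = unassigned.
#' @export
detect_modules <- function(tom, min_size = 20, core_min = 3, core_sd = 2,
                           link_frac = 0.6, assign_frac = 0.5, n_iter = 3) {
  .stop_if(min_size < 2, "min_size must be >= 2")
  tom <- as.matrix(tom)
  G <- nrow(tom)
  empty <- setNames(integer(G), rownames(tom))
  if (G < 2 * min_size) return(empty)
  cores <- .tom_cores(tom, core_min, core_sd)$cores
  if (!length(cores)) return(empty)

  # consolidate fragments of the same module
  M <- length(cores)
  ref <- vapply(cores, function(g) {
    tg <- tom[g, g]; mean(tg[upper.tri(tg)])
  }, numeric(1))
  if (M > 1) {
    link <- matrix(FALSE, M, M)
    for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
      bt <- mean(tom[cores[[i]], cores[[j]]])
      link[i, j] <- link[j, i] <- bt >= link_frac * min(ref[i], ref[j])
    }
    comp <- seq_len(M)
    repeat {
      changed <- FALSE
      for (i in seq_len(M)) for (j in seq_len(M)) {
        if (link[i, j] && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    cores <- lapply(unique(comp),
                    function(cc) sort(unique(unlist(cores[comp == cc]))))
  }
  cores <- cores[lengths(cores) >= min_size]
  if (!length(cores)) return(empty)

  # iterative relative mean-TOM assignment
  for (it in seq_len(n_iter)) {
    S <- vapply(cores, function(g) {
      s <- rowSums(tom[, g, drop = FALSE])
      s[g] <- s[g] - 1                      # exclude self (diag TOM = 1)
      den <- rep(length(g), G); den[g] <- length(g) - 1
      s / pmax(den, 1)
    }, numeric(G))
    S <- matrix(S, nrow = G)
    refs <- vapply(seq_along(cores),
                   function(m) median(S[cores[[m]], m]), numeric(1))
    R <- sweep(S, 2, pmax(refs, .Machine$double.eps), `/`)
    best <- max.col(R, ties.method = "first")
    bv <- R[cbind(seq_len(G), best)]
    lab <- ifelse(bv >= assign_frac, best, 0L)
    cores <- lapply(seq_along(cores), function(m) which(lab == m))
    cores <- cores[lengths(cores) >= min_size]
    if (!length(cores)) return(empty)
  }
  lab <- integer(G)
  for (m in seq_along(cores)) lab[cores[[m]]] <- m
  names(lab) <- rownames(tom)
  .renumber_labels(lab)
}

#' Module eigengene
#'
#' First principal component (sample scores, unit norm) of the standardized
#' expression of the module's member genes, sign-oriented so that the mean
#' correlation with the members is positive.  A one-gene module returns the
#' standardized gene itself (unit norm).
#'
#' @param expr genes x samples matrix.
#' @param labels integer module labels (named by gene) or a logical/index
#'   selector of member rows.
#' @param module module label to extract (ignored when `labels` selects
#'   rows directly).
#' @return numeric vector of per-sample scores (unit norm), named by
#'   sample.
#' @export
module_eigengene <- function(expr, labels, module = NULL) {
  expr <- as.matrix(expr)
  rows <- if (is.null(module)) {
    if (is.logical(labels)) which(labels) else labels
  } else {
    which(labels == module)
  }
  .stop_if(length(rows) == 0, "module is empty")
  x <- expr[rows, , drop = FALSE]
  xs <- t(scale(t(x)))
  xs[!is.finite(xs)] <- 0
  if (nrow(xs) == 1L) {
    v <- drop(xs)
    v <- v / sqrt(sum(v^2))
  } else {
    v <- svd(xs, nu = 0, nv = 1)$v[, 1]
  }
  mm <- suppressWarnings(cor(t(x), v))
  if (mean(mm, na.rm = TRUE) < 0) v <- -v
  setNames(v, colnames(expr))
}

#' Eigengenes of all modules
#'
#' @param expr genes x samples matrix.
#' @param labels integer module labels, 0 = unassigned.
#' @return matrix modules x samples, rows named `ME<label>`.
#' @export
eigengenes <- function(expr, labels) {
  mods <- setdiff(sort(unique(labels)), 0L)
  .stop_if(!length(mods), "no modules in labels")
  out <- t(vapply(mods, function(m) module_eigengene(expr, labels, m),
                  numeric(ncol(expr))))
  rownames(out) <- paste0("ME", mods)
  colnames(out) <- colnames(expr)
  out
}

#' Merge modules with correlated eigengenes
#'
#' Average-linkage clustering of module eigengenes on `1 - cor`; groups
#' joining below `cut_height` (eigengene correlation above
#' `1 - cut_height`) are unified, and the procedure iterates until stable.
#'
#' @param expr genes x samples matrix.
#' @param labels integer module labels.
#' @param cut_height merge height on the `1 - cor` scale (default 0.25,
#'   i.e. correlation > 0.75 merges).
#' @return relabeled integer vector (renumbered by size).
#' @export
merge_modules <- function(expr, labels, cut_height = 0.25) {
  repeat {
    mods <- setdiff(sort(unique(labels)), 0L)
    if (length(mods) < 2) break
    egs <- t(eigengenes(expr, labels))          # samples x modules
    d <- 1 - cor(egs)
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = cut_height)
    if (max(table(grp)) == 1L) break
    for (gidx in unique(grp)) {
      members <- mods[grp == gidx]
      if (length(members) > 1)
        labels[labels %in% members] <- members[1]
    }
  }
  .renumber_labels(labels)
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module
#' eigengene.  A gene's own-module column is its module membership (MM).
#'
#' @param expr genes x samples matrix.
#' @param egs eigengene matrix from [eigengenes()] (modules x samples).
#' @return genes x modules correlation matrix in \[-1, 1\]; constant genes
#'   give `NA` with a warning.
#' @export
module_membership <- function(expr, egs) {
  expr <- as.matrix(expr)
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) warning(sum(sds == 0), " constant genes give NA MM")
  mm <- suppressWarnings(cor(t(expr), t(egs)))
  dimnames(mm) <- list(rownames(expr), rownames(egs))
  mm
}

#' Hubgenes of a module
#'
#' The `top_n` member genes with the highest absolute module membership,
#' in decreasing |MM| order (ties broken by gene ID).  If the module has
#' fewer than `top_n` members, the whole module is returned.
#'
#' @param mm module-membership matrix from [module_membership()].
#' @param labels integer module labels named by gene.
#' @param module module label.
#' @param top_n number of hubgenes (default 30).
#' @param expr optional expression matrix; when given, the pairwise
#'   correlation sub-matrix of the hubgenes is attached as attribute
#'   `"cor"` (for circle-plot-style display).
#' @return named numeric vector of MM values, ordered by decreasing |MM|.
#' @export
hubgenes <- function(mm, labels, module, top_n = 30, expr = NULL) {
  members <- names(labels)[labels == module]
  .stop_if(!length(members), "module ", module, " does not exist")
  col <- paste0("ME", module)
  v <- mm[members, col]
  ord <- order(-abs(v), members)
  sel <- ord[seq_len(min(top_n, length(members)))]
  out <- setNames(v[sel], members[sel])
  if (!is.null(expr)) attr(out, "cor") <- cor(t(expr[names(out), , drop = FALSE]))
  out
}

#' Fit a weighted gene-coexpression network
#'
#' The full network pipeline: soft-thresholded adjacency ([adjacency_matrix()]),
#' topological overlap ([tom_similarity()]), tree-based module detection
#' ([detect_modules()]) applied sequentially — after each round the TOM is
#' recomputed on the unassigned genes so weaker modules surface once
#' stronger ones are removed — followed by eigengene merging
#' ([merge_modules()]), eigengenes and module membership.
#'
#' @param expr genes x samples expression matrix (transformed/adjusted).
#' @param beta soft power (default 6).
#' @param min_size minimum module size.
#' @param merge_height eigengene merge height (see [merge_modules()]).
#' @param max_rounds sequential detection rounds (default 3).
#' @param cross_round_cor absolute eigengene-correlation threshold above
#'   which modules found in different rounds are treated as fragments of
#'   one module and consolidated (default 0.55).
#' @param signed signed adjacency variant.
#' @param keep_matrices retain adjacency and TOM in the result (memory
#'   permitting).
#' @param ... further arguments passed to [detect_modules()].
#' @return object of class `coex_net`: list with `beta`, `labels`,
#'   `eigengenes`, `mm`, `connectivity`, `dendrogram` (full-TOM
#'   average-linkage tree), `n_modules`, and optionally `adjacency`, `tom`.
#' @export
coexpression_network <- function(expr, beta = 6, min_size = 20,
                                 merge_height = 0.25, max_rounds = 3,
                                 cross_round_cor = 0.55,
                                 signed = FALSE, keep_matrices = NULL, ...) {
  expr <- as.matrix(expr)
  .stop_if(is.null(rownames(expr)), "expression matrix needs gene rownames")
  a <- adjacency_matrix(expr, beta = beta, signed = signed)
  expr <- expr[rownames(a), , drop = FALSE]  # constant genes dropped
  G <- nrow(a)
  if (is.null(keep_matrices)) keep_matrices <- G <= 5000
  tom_full <- tom_similarity(a)
  dend <- hclust(as.dist(1 - tom_full), method = "average")

  labels <- setNames(integer(G), rownames(a))
  remain <- seq_len(G)
  next_lab <- 1L
  for (round in seq_len(max_rounds)) {
    if (length(remain) < 2 * min_size) break
    tom_r <- if (length(remain) == G) tom_full else
      tom_similarity(a[remain, remain, drop = FALSE])
    sub <- detect_modules(tom_r, min_size = min_size, ...)
    mods <- setdiff(unique(sub), 0L)
    if (!length(mods)) break
    for (m in mods) {
      labels[remain[sub == m]] <- next_lab
      next_lab <- next_lab + 1L
    }
    remain <- which(labels == 0L)
  }
  if (any(labels > 0)) labels <- .consolidate_fragments(expr, labels,
                                                       cross_round_cor)
  labels <- .renumber_labels(labels)
  if (any(labels > 0)) labels <- merge_modules(expr, labels, merge_height)

  egs <- if (any(labels > 0)) eigengenes(expr, labels) else NULL
  mm <- if (!is.null(egs)) module_membership(expr, egs) else NULL
  structure(list(beta = beta, labels = labels, eigengenes = egs, mm = mm,
                 connectivity = rowSums(a) - 1, dendrogram = dend,
                 n_modules = length(setdiff(unique(labels), 0L)),
                 adjacency = if (keep_matrices) a else NULL,
                 tom = if (keep_matrices) tom_full else NULL,
                 params = list(min_size = min_size,
                               merge_height = merge_height,
                               max_rounds = max_rounds, signed = signed,
                               detect = list(...))),
            class = "coex_net")
}

#' @export
print.coex_net <- function(x, ...) {
  cat("coex_net: beta =", x$beta, "|", length(x$labels), "genes |",
      x$n_modules, "modules |", sum(x$labels == 0), "unassigned\n")
  if (x$n_modules > 0) {
    sz <- table(x$labels[x$labels > 0])
    cat("  module sizes:", paste(sz, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.coex_net <- function(object, ...) {
  print(object)
  if (object$n_modules > 0) {
    mods <- setdiff(sort(unique(object$labels)), 0L)
    mean_mm <- vapply(mods, function(m) {
      mean(abs(object$mm[object$labels == m, paste0("ME", m)]), na.rm = TRUE)
    }, numeric(1))
    cat("  mean |MM| per module:", paste(round(mean_mm, 2), collapse = ", "),
        "\n")
  }
  invisible(object)
}

#' @export
plot.coex_net <- function(x, ...) {
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "TOM dendrogram", xlab = "", sub = "", ...)
  invisible(x)
}
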