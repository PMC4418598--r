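#' Within-module correlation matrices in two conditions
#'
#' Pairwise Pearson correlations among a module's member genes, computed
#' separately in a reference and a test condition, with rows and columns in
#' the identical order (descending reference module membership) so the two
#' matrices can be compared side by side.
#'
#' @param expr_ref,expr_test genes x samples matrices for the two
#'   conditions (the same gene identifiers must be present in both).
#' @param labels integer module labels named by gene (from the reference
#'   condition).
#' @param module module label to extract.
#' @return list with `ref` and `test` correlation matrices and `order`
#'   (the gene order used).
#' @export
condition_matrices <- function(expr_ref, expr_test, labels, module) {
  members <- names(labels)[labels == module]
  .stop_if(!length(members), "module ", module, " is empty")
  missing <- setdiff(members, rownames(expr_test))
  .stop_if(length(missing) > 0,
           "genes missing in test condition: ",
           paste(missing, collapse = ", "))
  eg <- module_eigengene(expr_ref, labels, module)
  mm <- drop(cor(t(expr_ref[members, , drop = FALSE]), eg))
  ord <- members[order(-mm, members)]
  list(ref = cor(t(expr_ref[ord, , drop = FALSE])),
       test = cor(t(expr_test[ord, , drop = FALSE])),
       order = ord)
}

#' Module-membership shift between conditions
#'
#' For every module (taken from the reference condition), the eigengene is
#' recomputed in each condition on the identical member-gene set, oriented
#' so its mean correlation with the members is positive, and each member's
#' module membership is measured in both conditions.  The drop
#' `delta_mm = mm_ref - mm_test` quantifies disconnection; genes with
#' `mm_ref >= high_cut` and `mm_test <= low_cut` are flagged disconnected.
#'
#' @param expr_ref,expr_test genes x samples matrices for the two
#'   conditions.
#' @param labels integer module labels named by gene.
#' @param high_cut,low_cut disconnection decision thresholds (defaults 0.5
#'   and 0.2); the rule is a configurable formalization, not a universal
#'   constant.
#' @param min_module smallest analyzable module (default 3); smaller
#'   modules are skipped with a warning.
#' @return data frame of class `rewiring_report`: `gene`, `module`,
#'   `mm_ref`, `mm_test`, `delta_mm`, `disconnected`.
#' @export
membership_shift <- function(expr_ref, expr_test, labels,
                             high_cut = 0.5, low_cut = 0.2, min_module = 3) {
  mods <- setdiff(sort(unique(labels)), 0L)
  .stop_if(!length(mods), "no modules in labels")
  rows <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    present_ref <- intersect(members, rownames(expr_ref))
    present_test <- intersect(members, rownames(expr_test))
    if (length(present_ref) < min_module || length(present_test) < min_module) {
      warning("module ", m, " smaller than ", min_module,
              " in one condition; skipped")
      next
    }
    shared <- intersect(present_ref, present_test)
    eg_ref <- module_eigengene(expr_ref[shared, , drop = FALSE],
                               rep(TRUE, length(shared)))
    eg_test <- module_eigengene(expr_test[shared, , drop = FALSE],
                                rep(TRUE, length(shared)))
    mm_ref <- drop(cor(t(expr_ref[shared, , drop = FALSE]), eg_ref))
    mm_test <- drop(cor(t(expr_test[shared, , drop = FALSE]), eg_test))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = shared, module = m, mm_ref = mm_ref, mm_test = mm_test,
      delta_mm = mm_ref - mm_test,
      disconnected = mm_ref >= high_cut & mm_test <= low_cut,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), module = integer(), mm_ref = numeric(),
               mm_test = numeric(), delta_mm = numeric(),
               disconnected = logical(), stringsAsFactors = FALSE)
  structure(out, high_cut = high_cut, low_cut = low_cut,
            class = c("rewiring_report", "data.frame"))
}

#' @export
print.rewiring_report <- function(x, ...) {
  cat("rewiring_report:", nrow(x), "genes in",
      length(unique(x$module)), "modules;",
      sum(x$disconnected), "flagged disconnected",
      sprintf("(mm_ref >= %g & mm_test <= %g)\n",
              attr(x, "high_cut"), attr(x, "low_cut")))
  if (nrow(x)) {
    top <- x[order(-x$delta_mm), , drop = FALSE]
    print(head(as.data.frame(top), 6))
  }
  invisible(x)
}

#' Thresholded correlation edge network
#'
#' Keeps the edge (i, j) when the two-sided correlation-test p-value is
#' below `p_cut` and `|cor|` exceeds `cor_cut`; edge weights are the
#' correlations (both signs retained).
#'
#' @param expr genes x samples matrix (>= 5 samples).
#' @param p_cut p-value threshold (default 0.05).
#' @param cor_cut absolute-correlation threshold (default 0.4).
#' @return data frame `gene_i`, `gene_j`, `cor`, `p` (each unordered pair
#'   once, `i < j` by row order).
#' @export
edge_network <- function(expr, p_cut = 0.05, cor_cut = 0.4) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  .stop_if(n < 5, "need at least 5 samples")
  cc <- cor(t(expr))
  r <- cc[upper.tri(cc)]
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  keep <- p < p_cut & abs(r) > cor_cut
  data.frame(gene_i = rownames(cc)[idx[keep, 1]],
             gene_j = rownames(cc)[idx[keep, 2]],
             cor = r[keep], p = p[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Module preservation across studies
#'
#' Treats study A as reference and study B as test: maps genes by shared
#' identifiers (unmapped genes are dropped with a report), skips modules
#' with less than `min_mapped` of their members mappable, and applies
#' [membership_shift()] to the mapped expression.  The result carries a
#' per-gene connection-loss ranking (descending `delta_mm`).
#'
#' @param labels_ref module labels from the reference study (named by
#'   gene).
#' @param expr_ref,expr_test expression matrices of the two studies, gene
#'   identifiers in a shared namespace.
#' @param min_mapped minimum fraction of a module's genes that must map
#'   (default 0.5).
#' @param ... passed to [membership_shift()].
#' @return a `rewiring_report` (possibly empty), with attribute `ranking`
#'   (genes by decreasing connection loss) and `n_unmapped`.
#' @export
preserve_across_studies <- function(labels_ref, expr_ref, expr_test,
                                    min_mapped = 0.5, ...) {
  shared <- intersect(intersect(names(labels_ref), rownames(expr_ref)),
                      rownames(expr_test))
  n_unmapped <- length(names(labels_ref)) - length(shared)
  if (n_unmapped > 0)
    message(n_unmapped, " genes not mappable between studies; dropped")
  empty_report <- function() {
    structure(data.frame(gene = character(), module = integer(),
                         mm_ref = numeric(), mm_test = numeric(),
                         delta_mm = numeric(), disconnected = logical(),
                         stringsAsFactors = FALSE),
              high_cut = 0.5, low_cut = 0.2, ranking = character(),
              n_unmapped = n_unmapped,
              class = c("rewiring_report", "data.frame"))
  }
  if (!length(shared)) {
    warning("no genes mappable between studies; empty report")
    return(empty_report())
  }
  labels <- labels_ref[shared]
  for (m in setdiff(sort(unique(labels_ref)), 0L)) {
    full <- sum(labels_ref == m)
    got <- sum(labels == m)
    if (got < min_mapped * full) {
      warning("module ", m, ": only ", got, "/", full,
              " genes mappable; skipped")
      labels[labels == m] <- 0L
    }
  }
  if (!any(labels > 0)) {
    warning("no module retained after mapping; empty report")
    return(empty_report())
  }
  out <- membership_shift(expr_ref[shared, , drop = FALSE],
                          expr_test[shared, , drop = FALSE], labels, ...)
  attr(out, "ranking") <- out$gene[order(-out$delta_mm)]
  attr(out, "n_unmapped") <- n_unmapped
  out
}
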