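#' Jaccard index of two sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Best-matching module between two partitions
#'
#' For every reference module, finds the test module maximizing either the
#' Jaccard index of the member sets or the absolute correlation between the
#' module eigengenes (the sign of a principal component being arbitrary).
#' Matching is independent per reference module (not one-to-one); ties are
#' broken by larger test module, then lower test label.  Label 0 is
#' excluded on both sides.
#'
#' @param ref_labels,test_labels integer labels named by gene (same gene
#'   universe).
#' @param criterion `"jaccard"` or `"eigengene_cor"`.
#' @param expr expression matrix (genes x samples) on which eigengenes are
#'   computed; required for `criterion = "eigengene_cor"`.
#' @return data frame: `ref`, `test` (NA when the test partition has no
#'   modules), `score`.
#' @export
best_match <- function(ref_labels, test_labels,
                       criterion = c("jaccard", "eigengene_cor"),
                       expr = NULL) {
  criterion <- match.arg(criterion)
  ref_mods <- setdiff(sort(unique(ref_labels)), 0L)
  test_mods <- setdiff(sort(unique(test_labels)), 0L)
  .stop_if(!length(ref_mods), "no reference modules")
  if (criterion == "eigengene_cor")
    .stop_if(is.null(expr), "expr required for eigengene matching")
  test_sizes <- vapply(test_mods, function(m) sum(test_labels == m), integer(1))

  rows <- lapply(ref_mods, function(rm) {
    ref_set <- names(ref_labels)[ref_labels == rm]
    if (!length(test_mods))
      return(data.frame(ref = rm, test = NA_integer_, score = 0))
    score <- if (criterion == "jaccard") {
      vapply(test_mods, function(tm)
        jaccard(ref_set, names(test_labels)[test_labels == tm]), numeric(1))
    } else {
      er <- module_eigengene(expr, match(ref_set, rownames(expr)))
      vapply(test_mods, function(tm) {
        et <- module_eigengene(expr, test_labels, tm)
        abs(cor(er, et))
      }, numeric(1))
    }
    ord <- order(-score, -test_sizes, test_mods)
    data.frame(ref = rm, test = test_mods[ord[1]], score = score[ord[1]])
  })
  do.call(rbind, rows)
}

#' Jackknife stability of coexpression modules
#'
#' Reruns the full module-detection pipeline on every leave-one-out subset
#' of the samples (or subjects, when `subjects` is given: all of a
#' subject's columns are removed together) with parameters identical to the
#' reference run.  For each subset, every reference module is matched to
#' the test module with the maximum Jaccard index; a gene's counter
#' \eqn{k_i} is incremented when it lands in its own module's best match.
#' A gene is "correctly classified" when
#' \eqn{k_i \ge \lceil r \cdot n_{subsets} \rceil} (default `r = 18/22`).
#' The eigengene-correlation matching criterion is reported alongside.
#'
#' @param expr genes x samples matrix (single-condition, e.g. baseline).
#' @param subjects optional per-column subject ids; default one subset per
#'   column.
#' @param threshold_frac stability fraction `r` (default 18/22).
#' @param beta,min_size,merge_height,max_rounds,... network parameters,
#'   passed to [coexpression_network()] for the reference and every subset
#'   (identical by construction).
#' @param reference optional pre-fitted reference `coex_net`; its recorded
#'   parameters must equal the ones given, otherwise an error is raised.
#' @return object of class `stability_report`: list with `module_summary`
#'   (module, size, mean_jaccard, sd_jaccard, mean_eigengene_cor,
#'   prop_correct), `gene_table` (gene, module, k, stable), `n_subsets`,
#'   `threshold`, `reference`.
#' @export
jackknife_stability <- function(expr, subjects = NULL,
                                threshold_frac = 18 / 22,
                                beta = 6, min_size = 20, merge_height = 0.25,
                                max_rounds = 3, reference = NULL, ...) {
  expr <- as.matrix(expr)
  .stop_if(ncol(expr) < 5, "need at least 5 samples")
  params <- list(beta = beta, min_size = min_size,
                 merge_height = merge_height, max_rounds = max_rounds)
  if (is.null(reference)) {
    reference <- coexpression_network(expr, beta = beta, min_size = min_size,
                                      merge_height = merge_height,
                                      max_rounds = max_rounds, ...)
  } else {
    stopifnot(inherits(reference, "coex_net"))
    got <- c(list(beta = reference$beta), reference$params[
      c("min_size", "merge_height", "max_rounds")])
    .stop_if(!identical(unname(unlist(got)), unname(unlist(params))),
             "reference network parameters differ from the requested ones")
  }
  ref_labels <- reference$labels
  ref_mods <- setdiff(sort(unique(ref_labels)), 0L)
  .stop_if(!length(ref_mods), "reference run found no modules")

  units <- if (is.null(subjects)) as.list(seq_len(ncol(expr))) else
    split(seq_len(ncol(expr)), subjects)
  n_subsets <- length(units)
  threshold <- ceiling(threshold_frac * n_subsets)

  k <- setNames(integer(length(ref_labels)), names(ref_labels))
  jac <- matrix(NA_real_, length(ref_mods), n_subsets)
  egc <- matrix(NA_real_, length(ref_mods), n_subsets)
  for (s in seq_len(n_subsets)) {
    sub_expr <- expr[, -units[[s]], drop = FALSE]
    net_s <- coexpression_network(sub_expr, beta = beta, min_size = min_size,
                                  merge_height = merge_height,
                                  max_rounds = max_rounds, ...)
    test_labels <- net_s$labels[names(ref_labels)]
    names(test_labels) <- names(ref_labels)
    bm <- best_match(ref_labels, test_labels, "jaccard")
    jac[, s] <- bm$score
    has_mods <- any(test_labels > 0, na.rm = TRUE)
    if (has_mods) {
      bme <- best_match(ref_labels, test_labels, "eigengene_cor",
                        expr = sub_expr)
      egc[, s] <- bme$score
    } else {
      egc[, s] <- 0
    }
    for (i in seq_along(ref_mods)) {
      if (is.na(bm$test[i])) next
      members <- names(ref_labels)[ref_labels == ref_mods[i]]
      in_match <- members[test_labels[members] == bm$test[i] &
                            !is.na(test_labels[members])]
      k[in_match] <- k[in_match] + 1L
    }
  }
  stable <- k >= threshold
  module_summary <- data.frame(
    module = ref_mods,
    size = vapply(ref_mods, function(m) sum(ref_labels == m), integer(1)),
    mean_jaccard = rowMeans(jac),
    sd_jaccard = apply(jac, 1, sd),
    mean_eigengene_cor = rowMeans(egc),
    prop_correct = vapply(ref_mods, function(m)
      mean(stable[ref_labels == m]), numeric(1)))
  gene_table <- data.frame(gene = names(ref_labels),
                           module = as.integer(ref_labels),
                           k = as.integer(k), stable = stable,
                           row.names = NULL, stringsAsFactors = FALSE)
  gene_table <- gene_table[gene_table$module > 0, , drop = FALSE]
  structure(list(module_summary = module_summary, gene_table = gene_table,
                 n_subsets = n_subsets, threshold = threshold,
                 reference = reference),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Jackknife stability over", x$n_subsets, "leave-one-out subsets",
      "(stable: k >=", paste0(x$threshold, ")"), "\n")
  print(cbind(x$module_summary[1:2],
              round(x$module_summary[-(1:2)], 3)))
  invisible(x)
}
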