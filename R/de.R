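#' Benjamini-Hochberg step-up false discovery rates
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the `m` non-missing p-values;
#' `NA` entries propagate.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values in the input order.
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
#' @export
bh_fdr <- function(p) {
  .stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0L) return(out)
  ps <- p[ok]
  ord <- order(ps)
  q <- ps[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out[ok][ord] <- q
  out
}

#' Paired differential-expression table
#'
#' Per-gene two-stage fit: NB dispersion by method of moments on a Poisson
#' fit with subject indicators (absorbing the pairing), then the NB mixed
#' model of [fit_nb_mixed()] with a subject random intercept, log size
#' factors as offset, and the requested fixed covariates.  The time
#' coefficient (T3 vs T0, natural-log scale) is tested by a Wald t-test and
#' adjusted by Benjamini-Hochberg.  Genes whose fit does not converge get
#' `NA` p-values and are excluded from the FDR (their number is reported).
#'
#' @param study a filtered [count_study()] with size factors.
#' @param covariates character vector of metadata columns to include as
#'   fixed effects in addition to time (e.g.
#'   `c("age", "ethnicity", "run", "rin", "concentration")`); default none.
#' @param interaction_procedure if `TRUE`, adds procedure and
#'   time-by-procedure fixed effects and reports the interaction test.
#' @param fdr_threshold significance threshold used by `summary()`.
#' @return data frame of class `de_table`, one row per gene in input order:
#'   `gene`, `time_coef`, `se`, `t_stat`, `p_value`, `fdr`,
#'   `mean_counts_T0`, `mean_counts_T3`, `dispersion`, `subject_variance`,
#'   `converged` (+ interaction columns when requested).
#' @export
de_table <- function(study, covariates = NULL, interaction_procedure = FALSE,
                     fdr_threshold = 0.05) {
  stopifnot(inherits(study, "count_study"))
  .stop_if(is.null(study$size_factors),
           "size factors missing; run size_factors() first")
  meta <- study$samples
  .stop_if(is.null(meta$time) || is.null(meta$subject),
           "metadata must carry 'time' and 'subject'")
  offset <- log(study$size_factors)

  fml <- "~ time"
  if (!is.null(covariates)) {
    .stop_if(!all(covariates %in% names(meta)),
             "unknown covariates: ",
             paste(setdiff(covariates, names(meta)), collapse = ", "))
    fml <- paste(fml, "+", paste(covariates, collapse = " + "))
  }
  if (interaction_procedure) fml <- paste(fml, "+ procedure + time:procedure")
  X <- model.matrix(stats::as.formula(fml), data = meta)
  tname <- grep("^time", colnames(X), value = TRUE)[1]
  iname <- if (interaction_procedure)
    grep(":", colnames(X), value = TRUE)[1] else NULL
  # moment fit absorbs between-subject variation via subject indicators
  Xd <- model.matrix(~ subject + time, data = meta)

  G <- nrow(study$counts)
  res <- matrix(NA_real_, G, 6,
                dimnames = list(NULL, c("time_coef", "se", "t_stat", "p_value",
                                        "dispersion", "subject_variance")))
  inter <- matrix(NA_real_, G, 3,
                  dimnames = list(NULL, c("interaction_coef", "interaction_t",
                                          "interaction_p")))
  conv <- logical(G)
  for (g in seq_len(G)) {
    y <- study$counts[g, ]
    phi <- tryCatch(estimate_dispersion(y, Xd, offset),
                    error = function(e) NA_real_)
    if (is.na(phi)) next
    fit <- tryCatch(fit_nb_mixed(y, X, meta$subject, offset, phi),
                    error = function(e) NULL)
    if (is.null(fit)) next
    conv[g] <- fit$converged
    i <- match(tname, fit$coefficients$term)
    res[g, ] <- c(fit$coefficients$estimate[i], fit$coefficients$se[i],
                  fit$coefficients$t[i], fit$coefficients$p[i],
                  phi, fit$sigma2)
    if (!is.null(iname)) {
      j <- match(iname, fit$coefficients$term)
      inter[g, ] <- c(fit$coefficients$estimate[j], fit$coefficients$t[j],
                      fit$coefficients$p[j])
    }
  }
  time <- meta$time
  out <- data.frame(gene = rownames(study$counts), res,
                    mean_counts_T0 = rowMeans(study$counts[, time == "T0", drop = FALSE]),
                    mean_counts_T3 = rowMeans(study$counts[, time == "T3", drop = FALSE]),
                    converged = conv, stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_value)
  if (interaction_procedure) {
    out <- cbind(out, inter)
    out$interaction_fdr <- bh_fdr(out$interaction_p)
  }
  n_bad <- sum(!conv)
  if (n_bad > 0)
    message(n_bad, " genes did not converge and are excluded from the FDR")
  rownames(out) <- NULL
  structure(out, n_nonconverged = n_bad, fdr_threshold = fdr_threshold,
            class = c("de_table", "data.frame"))
}

#' @export
summary.de_table <- function(object, threshold = attr(object, "fdr_threshold"),
                             ...) {
  n <- nrow(object)
  n_de <- sum(object$fdr < threshold, na.rm = TRUE)
  cat("Differential expression over", n, "genes\n")
  cat(sprintf("  %d genes (%s%%) differentially expressed at FDR < %g\n",
              n_de, format(de_fraction(n_de, n)), threshold))
  if (attr(object, "n_nonconverged") > 0)
    cat("  non-converged fits excluded from FDR:",
        attr(object, "n_nonconverged"), "\n")
  invisible(list(n = n, n_de = n_de,
                 percent_de = de_fraction(n_de, n)))
}

#' @export
print.de_table <- function(x, ...) {
  cat("de_table:", nrow(x), "genes;",
      sum(x$fdr < attr(x, "fdr_threshold"), na.rm = TRUE),
      "significant at FDR <", attr(x, "fdr_threshold"), "\n")
  print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Percentage of differentially expressed genes
#'
#' Reporting utility: `100 * n_de / n_total`, rounded to `digits` decimals
#' (e.g. 1214 of 15972 genes gives 7.6).
#'
#' @param n_de number of significant genes.
#' @param n_total number of genes analyzed.
#' @param digits decimals to keep (default 1).
#' @return numeric percentage.
#' @export
de_fraction <- function(n_de, n_total, digits = 1) {
  .stop_if(n_total <= 0, "n_total must be positive")
  round(100 * n_de / n_total, digits)
}

#' Export a ranked gene list for enrichment tools
#'
#' Genes ranked by their signed or absolute Wald t statistics, descending
#' (RNK-style two-column output).  Genes with missing t are dropped with a
#' message.
#'
#' @param de a [de_table()].
#' @param mode `"signed"` or `"absolute"`.
#' @return data frame with columns `gene`, `score`, sorted descending.
#' @export
export_ranked <- function(de, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  ok <- !is.na(de$t_stat)
  if (any(!ok)) message(sum(!ok), " genes with missing t excluded")
  score <- if (mode == "signed") de$t_stat[ok] else abs(de$t_stat[ok])
  out <- data.frame(gene = de$gene[ok], score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' @rdname export_ranked
#' @param ranked output of `export_ranked()`.
#' @param path output file (tab-separated, no header).
#' @export
write_rnk <- function(ranked, path) {
  write.table(ranked, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the actual overlap between
#' each gene set and a selection (e.g. a module or the DE genes), relative
#' to a gene universe; Benjamini-Hochberg adjusted across sets.
#'
#' @param gene_sets named list of character vectors (or a single vector).
#' @param selection character vector of selected genes.
#' @param universe character vector of all analyzed genes.
#' @return data frame: `set`, `set_size`, `selection_size`, `overlap`, `p`,
#'   `fdr`.
#' @export
hypergeom_enrich <- function(gene_sets, selection, universe) {
  .stop_if(length(universe) == 0, "empty universe")
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  universe <- unique(universe)
  selection <- intersect(unique(selection), universe)
  n_sel <- length(selection)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(s, selection))
    p <- phyper(k - 1, length(s), length(universe) - length(s), n_sel,
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), selection_size = n_sel,
               overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out
}
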