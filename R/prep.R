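#' Construct a paired count study
#'
#' Bundles a gene-by-sample integer count matrix with per-sample metadata.
#' Metadata rows are matched to count columns by the `sample` column; the
#' usual covariates are `subject`, `time` (`"T0"`/`"T3"`), `run`, `rin`,
#' `concentration`, `age`, `ethnicity` and `procedure`.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames
#'   required, unique), samples in columns.
#' @param samples data frame with one row per sample and a `sample` column
#'   matching `colnames(counts)`.
#' @param size_factors optional positive per-sample normalization factors.
#' @return object of class `count_study`: list with elements `counts`,
#'   `samples`, `size_factors`.
#' @export
count_study <- function(counts, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  .stop_if(is.null(rownames(counts)), "counts must have gene rownames")
  .stop_if(anyDuplicated(rownames(counts)) > 0,
           "duplicated gene IDs: ",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                 collapse = ", "))
  .stop_if(any(counts < 0) || any(counts != round(counts)),
           "counts must be non-negative integers")
  storage.mode(counts) <- "integer"

  .stop_if(!is.data.frame(samples) || is.null(samples$sample),
           "samples must be a data frame with a 'sample' column")
  .stop_if(is.null(colnames(counts)), "counts must have sample colnames")
  missing <- setdiff(colnames(counts), samples$sample)
  .stop_if(length(missing) > 0,
           "samples missing from metadata: ", paste(missing, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (!is.null(size_factors)) {
    .stop_if(length(size_factors) != ncol(counts) || any(size_factors <= 0),
             "size_factors must be positive, one per sample")
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors),
            class = "count_study")
}

#' @export
print.count_study <- function(x, ...) {
  cat("count_study:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  if (!is.null(x$samples$time))
    cat("  time points:",
        paste(names(table(x$samples$time)), table(x$samples$time),
              sep = "=", collapse = ", "), "\n")
  cat("  size factors:",
      if (is.null(x$size_factors)) "not computed" else "computed", "\n")
  invisible(x)
}

#' Read a count study from TSV files
#'
#' `counts_path` must be a TSV with gene IDs in the first column and one
#' numeric column per sample; `meta_path` a TSV keyed by a `sample` column.
#' `write_counts()` is the inverse; `read_counts(write_counts(x))` restores
#' the study.
#'
#' @param counts_path path to the counts TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a [count_study()].
#' @export
read_counts <- function(counts_path, meta_path) {
  tab <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  .stop_if(!is.numeric(mat), "non-numeric count entries in ", counts_path)
  rownames(mat) <- genes
  meta <- read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  count_study(mat, meta)
}

#' @rdname read_counts
#' @param study a [count_study()].
#' @export
write_counts <- function(study, counts_path, meta_path) {
  stopifnot(inherits(study, "count_study"))
  tab <- data.frame(gene = rownames(study$counts), study$counts,
                    check.names = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(study)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of the ratio
#' of the sample's count to the gene's geometric mean across samples.
#' Genes with a zero count in any sample are excluded from the median.
#'
#' @param counts count matrix or [count_study()].
#' @return positive numeric vector, one per sample (named).  When given a
#'   `count_study`, the study is returned with `size_factors` filled in.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_study")) {
    counts$size_factors <- size_factors(counts$counts)
    return(counts)
  }
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  .stop_if(!any(ok),
           "no gene has nonzero counts in all samples; ",
           "consider adding a pseudo-count before normalization")
  lg <- log(counts[ok, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(counts[ok, , drop = FALSE] / geo, 2, median)
  setNames(sf, colnames(counts))
}

#' Filter weakly expressed genes from a paired study
#'
#' Removes genes whose mean raw count is below `min_mean` at both time
#' points (a gene is kept as soon as one time point reaches the threshold;
#' the rule is strict `<` at both).
#'
#' @param study a [count_study()] with a `time` column in its metadata.
#' @param min_mean threshold on the per-time mean count (default 10).
#' @return the filtered `count_study`; the number of removed genes is
#'   reported via `attr(, "n_removed")` and a message.
#' @export
filter_low_expression <- function(study, min_mean = 10) {
  stopifnot(inherits(study, "count_study"))
  time <- study$samples$time
  .stop_if(is.null(time) || length(unique(time)) != 2,
           "paired study with two time points required")
  tps <- sort(unique(time))
  m1 <- rowMeans(study$counts[, time == tps[1], drop = FALSE])
  m2 <- rowMeans(study$counts[, time == tps[2], drop = FALSE])
  keep <- !(m1 < min_mean & m2 < min_mean)
  removed <- sum(!keep)
  message(removed, " genes removed with mean counts < ", min_mean,
          " at both time points")
  out <- count_study(study$counts[keep, , drop = FALSE], study$samples,
                     study$size_factors)
  attr(out, "n_removed") <- removed
  out
}

#' Variance-stabilizing transform of normalized counts
#'
#' `log2(count / size_factor + 1)`, the simple stabilizer appropriate when
#' downstream analyses use only correlations.  Monotone in counts within
#' each sample.
#'
#' @param study a [count_study()] with size factors computed (see
#'   [size_factors()]).
#' @return numeric matrix (genes x samples) with a `"transform"` attribute.
#' @export
vst_transform <- function(study) {
  stopifnot(inherits(study, "count_study"))
  .stop_if(is.null(study$size_factors),
           "size factors missing; run size_factors() first")
  out <- log2(sweep(study$counts, 2, study$size_factors, `/`) + 1)
  attr(out, "transform") <- "log2(count/sf + 1)"
  out
}

#' Regress technical covariates out of an expression matrix
#'
#' Per gene, replaces expression by the residuals of an ordinary
#' least-squares regression on the covariates, with the gene's mean added
#' back.  Categorical covariates are expanded to indicators; constant or
#' collinear columns are dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @param covariates data frame of per-sample covariates (e.g. run, RIN,
#'   RNA concentration), rows aligned with `colnames(expr)`.
#' @return adjusted matrix of the same shape; residuals are numerically
#'   uncorrelated with every retained covariate column.
#' @export
adjust_covariates <- function(expr, covariates) {
  expr <- as.matrix(expr)
  stopifnot(is.data.frame(covariates) || is.matrix(covariates))
  covariates <- as.data.frame(covariates)
  .stop_if(nrow(covariates) != ncol(expr),
           "covariate rows must align with expression columns")
  X <- model.matrix(~ ., data = covariates)
  # drop constant (beyond intercept) and collinear columns
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, sd) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[seq(qx$rank + 1, ncol(X))]
    warning("dropping collinear covariate columns: ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, -drop_cols, drop = FALSE]
    qx <- qr(X)
  }
  fitted <- t(qr.fitted(qx, t(expr)))
  res <- expr - fitted + rowMeans(expr)
  dimnames(res) <- dimnames(expr)
  attr(res, "transform") <- attr(expr, "transform")
  attr(res, "adjusted_for") <- colnames(X)[-1]
  res
}

#' Select the most variable genes
#'
#' Ranks genes by variance over the given columns (typically the baseline
#' samples) and keeps the top `k`.  Ties at the cutoff are broken by
#' lexicographic gene ID.
#'
#' @param expr genes x samples matrix with rownames.
#' @param k number of genes to keep (`k <= nrow(expr)`).
#' @param columns columns over which to compute the variance (names or
#'   indices); default all.
#' @return the row-subset matrix, in decreasing-variance order.
#' @export
select_most_variable <- function(expr, k, columns = colnames(expr)) {
  expr <- as.matrix(expr)
  .stop_if(k <= 0, "k must be positive")
  .stop_if(k > nrow(expr), "k exceeds the number of genes")
  v <- apply(expr[, columns, drop = FALSE], 1, var)
  ord <- order(-v, rownames(expr))
  out <- expr[ord[seq_len(k)], , drop = FALSE]
  attr(out, "transform") <- attr(expr, "transform")
  out
}
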