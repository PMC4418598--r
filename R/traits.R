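#' Eigengene-trait association (Spearman)
#'
#' Spearman rank correlation (mid-rank ties) between every module eigengene
#' and every phenotypic trait, with two-sided p-values from the
#' t-approximation, pairwise-complete handling of missing values, and
#' Benjamini-Hochberg adjustment across the full trait-by-module grid.
#'
#' @param egs eigengene matrix, modules x samples (see [eigengenes()]).
#' @param traits data frame of numeric traits, one row per sample (aligned
#'   with the eigengene columns); non-numeric columns are ignored.
#' @param min_n minimum paired observations per cell (default 5); cells
#'   below it give `NA` with a warning.
#' @return object of class `trait_association`: list of trait x module
#'   matrices `rho`, `p`, `q`, `n`.
#' @export
eigengene_trait_cor <- function(egs, traits, min_n = 5) {
  egs <- as.matrix(egs)
  stopifnot(is.data.frame(traits))
  .stop_if(nrow(traits) != ncol(egs),
           "trait rows must align with eigengene samples")
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[, num, drop = FALSE]
  .stop_if(ncol(traits) == 0, "no numeric traits")

  tn <- colnames(traits); mn <- rownames(egs)
  rho <- p <- n <- matrix(NA_real_, length(tn), length(mn),
                          dimnames = list(tn, mn))
  warned_const <- warned_n <- FALSE
  for (i in seq_along(tn)) for (j in seq_along(mn)) {
    x <- traits[[i]]; y <- egs[j, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n) { warned_n <- TRUE; next }
    if (sd(x[ok]) == 0) { warned_const <- TRUE; next }
    s <- .spearman(x, y)
    rho[i, j] <- s["rho"]; p[i, j] <- s["p"]; n[i, j] <- s["n"]
  }
  if (warned_const) warning("constant trait(s): NA cells")
  if (warned_n) warning("cells with fewer than ", min_n,
                        " paired observations: NA")
  q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(rho = rho, p = p, q = q, n = n),
            class = "trait_association")
}

#' @export
print.trait_association <- function(x, ...) {
  cat("Eigengene-trait Spearman correlations",
      sprintf("(%d traits x %d modules)\n", nrow(x$rho), ncol(x$rho)))
  print(round(x$rho, 2))
  invisible(x)
}

#' @export
plot.trait_association <- function(x, ...) {
  r <- x$rho
  graphics::image(seq_len(ncol(r)), seq_len(nrow(r)), t(r),
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(21, "Blue-Red 2"),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(r)), colnames(r), las = 2)
  graphics::axis(2, seq_len(nrow(r)), rownames(r), las = 1)
  invisible(x)
}

#' Export a trait association as heatmap-ready tables
#'
#' Writes `rho`, `p` and `q` matrices (traits in rows, modules in columns)
#' as TSV files with a common prefix.
#'
#' @param assoc a [eigengene_trait_cor()] result.
#' @param prefix path prefix; files `<prefix>_rho.tsv` etc. are written.
#' @return the file paths, invisibly.
#' @export
write_trait_association <- function(assoc, prefix) {
  paths <- character()
  for (what in c("rho", "p", "q")) {
    f <- paste0(prefix, "_", what, ".tsv")
    write.table(data.frame(trait = rownames(assoc[[what]]), assoc[[what]],
                           check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
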