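# internal helpers shared across modules

# renumber positive integer labels by decreasing group size; ties keep the
# smaller incoming label first; 0 stays 0
.renumber_labels <- function(labels) {
  mods <- setdiff(sort(unique(labels)), 0L)
  if (!length(mods)) return(labels)
  sz <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sz, mods)]
  out <- integer(length(labels))
  for (m in seq_along(ord)) out[labels == ord[m]] <- m
  names(out) <- names(labels)
  out
}

# area under the ROC curve for scores (higher = more positive-like);
# rank statistic, ties get mid-ranks
.auroc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  ok <- !is.na(scores)
  scores <- scores[ok]; is_positive <- as.logical(is_positive[ok])
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Spearman rho with mid-rank ties + two-sided t-approximation p-value,
# pairwise complete
.spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
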