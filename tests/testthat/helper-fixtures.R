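# shared fixtures and independent oracles, built in code at test time

# two perfectly separated blocks driven by independent factors
make_blocks <- function(block_sizes = c(50, 50), n_samples = 22, noise = 0,
                        seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(block_sizes), function(b) {
    f <- rnorm(n_samples)
    matrix(rep(f, each = block_sizes[b]), block_sizes[b]) +
      noise * matrix(rnorm(block_sizes[b] * n_samples), block_sizes[b])
  }))
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

# factor-loaded module expression: gene i = load[i] * f + sqrt(1-load^2) * e
make_module_expr <- function(loadings, n_samples = 22, seed = 1) {
  set.seed(seed)
  f <- rnorm(n_samples)
  x <- sapply(seq_len(n_samples), function(j)
    loadings * f[j] + sqrt(1 - loadings^2) * rnorm(length(loadings)))
  rownames(x) <- sprintf("g%03d", seq_along(loadings))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  x
}

# standard preprocessing to the baseline (T0) expression matrix
t0_expression <- function(sim, adjust = TRUE) {
  st <- size_factors(sim$study)
  x <- vst_transform(st)
  if (adjust)
    x <- adjust_covariates(x, st$samples[, c("run", "rin", "concentration")])
  x[, st$samples$time == "T0"]
}

# best-match Jaccard of a detected partition against one true module
jaccard_vs_truth <- function(labels, truth, m) {
  gm <- names(truth)[truth == m]
  labs <- setdiff(unique(labels), 0L)
  if (!length(labs)) return(0)
  max(vapply(labs, function(b)
    jaccard(gm, names(labels)[labels == b]), numeric(1)))
}

# brute-force BH step-up: literal definition q_(i) = min_{j>=i} p_(j) m / j
bh_brute <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  ps <- p[ok]; m <- length(ps)
  if (m == 0) return(out)
  ord <- order(ps)
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(ps[ord][i:m] * m / (i:m)))
  out[ok][ord] <- q
  out
}

# brute-force TOM by triple loop
tom_brute <- function(a) {
  G <- nrow(a)
  out <- matrix(0, G, G)
  for (i in seq_len(G)) for (j in seq_len(G)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(G)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

# two columns with exact sample correlation r
make_exact_cor <- function(r, n = 22, seed = 1) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  a <- a - mean(a)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a^2)
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  cbind(a, r * a + sqrt(1 - r^2) * b)
}
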