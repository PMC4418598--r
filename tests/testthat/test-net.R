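test_that("adjacency is |cor|^beta with unit diagonal", {
  x <- t(make_exact_cor(-0.5, n = 22, seed = 2))
  rownames(x) <- c("g1", "g2")
  a6 <- adjacency_matrix(x, beta = 6)
  expect_equal(a6["g1", "g2"], 0.015625, tolerance = 1e-12)  # | -0.5 |^6
  expect_equal(diag(a6), c(g1 = 1, g2 = 1))
  # perfectly correlated pair: a = 1 for any beta
  y <- rbind(g1 = 1:22 + 0, g2 = 2 * (1:22) + 5)
  expect_equal(adjacency_matrix(y, beta = 9)["g1", "g2"], 1)
  # orthogonal pair: a = 0
  z <- t(make_exact_cor(0, n = 22, seed = 3)); rownames(z) <- c("g1", "g2")
  expect_lt(adjacency_matrix(z, beta = 6)["g1", "g2"], 1e-15)
  expect_error(adjacency_matrix(x, beta = 0.5), "beta")
  expect_error(adjacency_matrix(x[, 1:3]), "4 samples")
  expect_warning(adjacency_matrix(rbind(x, g3 = rep(1, 22))), "constant")
})

test_that("TOM matches the hand example and the triple-loop oracle", {
  a1 <- matrix(1, 3, 3)
  t1 <- tom_similarity(a1)
  expect_equal(t1[1, 2], 1)                      # (1+1)/(2+1-1)
  a0 <- diag(3)
  expect_equal(unname(tom_similarity(a0)), diag(3))  # no shared neighbors
  set.seed(4)
  for (i in 1:10) {
    r <- matrix(runif(400), 20, 20)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    expect_lt(max(abs(tom_similarity(a) - tom_brute(a))), 1e-10)
  }
  bad <- matrix(runif(16), 4, 4)
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("soft-threshold scan: connectivity decreases, modular data low power", {
  sim <- generate_study(synth_config(n_genes = 800, n_modules = 3,
                                     module_sizes = c(150, 100, 60), seed = 4))
  x0 <- t0_expression(sim, adjust = FALSE)
  scan <- pick_soft_threshold(x0, powers = 1:10)
  expect_true(all(diff(scan$mean_k) < 0))
  expect_lte(attr(scan, "recommended"), 10)
  # i.i.d. noise: scan still returned, low fit index at small powers
  xn <- matrix(rnorm(300 * 22), 300, 22,
               dimnames = list(sprintf("g%03d", 1:300), NULL))
  scn <- pick_soft_threshold(xn, powers = 1:4)
  expect_s3_class(scn, "soft_threshold_scan")
  expect_true(all(scn$fit_index[1:2] < 0.8, na.rm = TRUE))
  expect_error(pick_soft_threshold(x0, powers = c(1, 40)), "1, 30")
})

test_that("idealized blocks give exactly two fully assigned modules", {
  x <- make_blocks(c(50, 50), noise = 0.01, seed = 2)
  tom <- tom_similarity(adjacency_matrix(x))
  lab <- detect_modules(tom)
  expect_identical(sort(as.integer(table(lab[lab > 0]))), c(50L, 50L))
  expect_equal(sum(lab == 0), 0L)
  # both blocks pure
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_error(detect_modules(tom, min_size = 1), "min_size")
})

test_that("pure-noise expression leaves the majority unassigned", {
  set.seed(6)
  xn <- matrix(rnorm(600 * 22), 600, 22,
               dimnames = list(sprintf("g%03d", 1:600), NULL))
  lab <- detect_modules(tom_similarity(adjacency_matrix(xn)))
  expect_gt(mean(lab == 0), 0.5)
})

test_that("labels are numbered by decreasing size and stable under gene order", {
  x <- make_blocks(c(60, 30), noise = 0.05, seed = 3)
  tom <- tom_similarity(adjacency_matrix(x))
  lab <- detect_modules(tom)
  expect_equal(sum(lab == 1), 60L)   # 1 = largest
  expect_equal(sum(lab == 2), 30L)
  perm <- sample(nrow(x))
  lab2 <- detect_modules(tom_similarity(adjacency_matrix(x[perm, ])))
  expect_identical(unname(lab2[names(lab)]), unname(lab))
})

test_that("eigengene is the oriented unit-norm PC1", {
  # identical genes: eigengene equals the standardized common profile
  f <- rnorm(22)
  x <- matrix(rep(f, each = 5), 5, dimnames = list(paste0("g", 1:5), NULL))
  eg <- module_eigengene(x, rep(1L, 5), 1L)
  expect_equal(sum(eg^2), 1)
  expect_equal(abs(cor(eg, f)), 1, tolerance = 1e-12)
  expect_gt(cor(eg, f), 0)                 # oriented towards members
  mm <- cor(t(x), eg)
  expect_equal(unname(mm[, 1]), rep(1, 5), tolerance = 1e-12)
  # flipping every member's sign flips nothing after re-orientation
  eg2 <- module_eigengene(-x, rep(1L, 5), 1L)
  expect_equal(unname(cor(t(-x), eg2)[1, 1]), 1, tolerance = 1e-12)
  # single-gene module returns the standardized gene
  eg1 <- module_eigengene(x[1, , drop = FALSE], 1L)
  expect_equal(abs(cor(eg1, f)), 1, tolerance = 1e-12)
  expect_error(module_eigengene(x, rep(1L, 5), 2L), "empty")
})

test_that("eigengene explains at least as much variance as any member", {
  set.seed(11)
  x <- make_module_expr(runif(30, 0.4, 0.9), seed = 11)
  eg <- module_eigengene(x, rep(1L, 30), 1L)
  xs <- t(scale(t(x)))
  ev_eig <- sum(cor(t(xs), eg)^2)
  ev_member <- max(vapply(seq_len(30), function(i)
    sum(cor(t(xs), xs[i, ])^2), numeric(1)))
  expect_gte(ev_eig, ev_member - 1e-10)
})

test_that("module merging joins only correlated eigengenes and is idempotent", {
  set.seed(12)
  f1 <- rnorm(40); f2 <- rnorm(40)
  mk <- function(f, n, noise) t(sapply(seq_len(n), function(i)
    f + noise * rnorm(length(f))))
  # modules 1 and 2 share a factor (eigengene cor ~0.95), module 3 is apart
  x <- rbind(mk(f1, 30, 0.2), mk(f1, 25, 0.2), mk(f2, 25, 0.2))
  rownames(x) <- sprintf("g%03d", 1:80)
  lab <- setNames(rep(c(1L, 2L, 3L), c(30, 25, 25)), rownames(x))
  merged <- merge_modules(x, lab)
  expect_equal(length(setdiff(unique(merged), 0L)), 2L)
  expect_equal(length(unique(merged[1:55])), 1L)       # 1 and 2 unified
  expect_false(merged[1] == merged[60])                # 3 kept apart
  expect_identical(merge_modules(x, merged), merged)   # idempotent
})

test_that("module membership is a bounded correlation with NA for constants", {
  x <- make_blocks(c(20, 20), noise = 0.3, seed = 5)
  lab <- setNames(rep(c(1L, 2L), each = 20), rownames(x))
  egs <- eigengenes(x, lab)
  mm <- module_membership(x, egs)
  expect_true(all(abs(mm) <= 1 + 1e-12))
  expect_identical(colnames(mm), c("ME1", "ME2"))
  xc <- rbind(x, gconst = rep(2, ncol(x)))
  expect_warning(mmc <- module_membership(xc, egs), "constant")
  expect_true(all(is.na(mmc["gconst", ])))
  # genes orthogonal to a module factor have small MM on average
  set.seed(13)
  mm_null <- replicate(30, {
    g <- rnorm(ncol(x))
    cor(g, egs[1, ])
  })
  expect_lt(abs(mean(mm_null)), 2 / sqrt(ncol(x)))
})

test_that("hubgenes rank members by absolute MM with planted hub on top", {
  x <- make_blocks(10, n_samples = 22, noise = 0.2, seed = 6)
  lab <- setNames(rep(1L, 10), rownames(x))
  mm <- module_membership(x, eigengenes(x, lab))
  hub <- hubgenes(mm, lab, 1, top_n = 30)
  expect_length(hub, 10)                      # whole module when top_n > size
  expect_true(all(diff(abs(hub)) <= 1e-12))
  # |MM| ordering: -0.98 ranks below 0.99
  mm2 <- matrix(c(0.99, -0.98, 0.5), dimnames = list(c("a", "b", "c"), "ME1"))
  lab2 <- setNames(rep(1L, 3), c("a", "b", "c"))
  expect_identical(names(hubgenes(mm2, lab2, 1, top_n = 2)), c("a", "b"))
  # planted hub (loading 0.95 vs 0.6) ranks first in >= 90% of seeds
  hits <- vapply(1:20, function(s) {
    xm <- make_module_expr(c(0.95, rep(0.6, 19)), seed = 100 + s)
    labm <- setNames(rep(1L, 20), rownames(xm))
    mmm <- module_membership(xm, eigengenes(xm, labm))
    names(hubgenes(mmm, labm, 1, top_n = 1)) == "g001"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the full network fit recovers planted structure end to end", {
  sim <- generate_study(synth_config(n_genes = 600, n_modules = 2,
                                     module_sizes = c(120, 80),
                                     module_loading = 0.8, seed = 14))
  x0 <- t0_expression(sim)
  net <- coexpression_network(x0)
  expect_s3_class(net, "coex_net")
  truth <- sim$truth$module_of_gene
  expect_gte(jaccard_vs_truth(net$labels, truth, 1), 0.7)
  expect_gte(jaccard_vs_truth(net$labels, truth, 2), 0.7)
  expect_identical(rownames(net$mm), names(net$labels))
  expect_equal(nrow(net$eigengenes), net$n_modules)
  # eigengene sign convention: mean own-module MM positive
  for (m in seq_len(net$n_modules)) {
    own <- net$mm[net$labels == m, paste0("ME", m)]
    expect_gt(mean(own), 0)
  }
})
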