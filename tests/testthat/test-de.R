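paired_design <- function(S = 22) {
  list(X = cbind(`(Intercept)` = 1, timeT3 = rep(c(0, 1), each = S)),
       subject = rep(sprintf("s%02d", seq_len(S)), 2))
}

test_that("BH step-up matches the hand example and the brute force", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(1.0), 1.0)
  set.seed(1)
  for (i in 1:200) {
    m <- sample(1:100, 1)
    p <- runif(m)
    p[sample(m, rbinom(1, 2, 0.5))] <- NA
    expect_equal(bh_fdr(p), bh_brute(p))
  }
  # order equivariance
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.2, 1.2)), "0, 1")
})

test_that("dispersion estimator recovers phi by method of moments", {
  d <- paired_design(22)
  set.seed(5)
  phis0 <- replicate(200, {
    y <- rpois(44, exp(4 + 0.2 * d$X[, 2]))
    estimate_dispersion(y, d$X)
  })
  expect_lt(median(phis0), 0.05)             # Poisson-simulated: phi ~ 0
  phis5 <- replicate(200, {
    y <- rnbinom(44, mu = exp(5), size = 2)  # phi = 0.5
    estimate_dispersion(y, d$X)
  })
  expect_gte(median(phis5), 0.3)
  expect_lte(median(phis5), 0.7)
  expect_equal(estimate_dispersion(rep(50L, 44), d$X), 0)  # underdispersed
  expect_error(estimate_dispersion(1:4, cbind(1, c(1, 1, 1, 1))),
               "degenerate")
})

test_that("NB mixed fit reduces to the Poisson GLM at the boundary", {
  d <- paired_design(10)
  set.seed(2)
  y <- rpois(20, exp(3 + 0.4 * d$X[, 2]))
  f <- fit_nb_mixed(y, d$X, subject = NULL, phi = 0, sigma2 = 0)
  g <- glm(y ~ d$X[, 2], family = poisson())
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$coefficients$se, unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-6)
})

test_that("NB mixed fit with fixed phi matches an independent NB GLM", {
  skip_if_not_installed("MASS")
  d <- paired_design(15)
  set.seed(9)
  y <- rnbinom(30, mu = exp(4 + 0.5 * d$X[, 2]), size = 5)
  f <- fit_nb_mixed(y, d$X, subject = NULL, phi = 1 / 5, sigma2 = 0)
  g <- glm(y ~ d$X[, 2], family = MASS::negative.binomial(theta = 5))
  expect_equal(f$coefficients$estimate, unname(coef(g)), tolerance = 1e-6)
})

test_that("exact pairing null gives a time coefficient of zero", {
  d <- paired_design(22)
  set.seed(3)
  y0 <- rnbinom(22, mu = 200, size = 5)
  y <- c(y0, y0)                             # T3 identical to T0
  f <- fit_nb_mixed(y, d$X, d$subject, offset = 0, phi = 0.2)
  expect_lt(abs(f$coefficients$estimate[2]), 1e-6)
  expect_lt(abs(f$coefficients$t[2]), 0.2)
})

test_that("rescaling every size factor only shifts the intercept", {
  d <- paired_design(12)
  set.seed(7)
  sf <- exp(rnorm(24, 0, 0.2))
  y <- rpois(24, sf * exp(4 + 0.3 * d$X[, 2]))
  f1 <- fit_nb_mixed(y, d$X, d$subject, log(sf), phi = 0.1)
  f2 <- fit_nb_mixed(y, d$X, d$subject, log(10 * sf), phi = 0.1)
  expect_equal(f1$coefficients$estimate[2], f2$coefficients$estimate[2],
               tolerance = 1e-6)
  expect_equal(f1$coefficients$estimate[1] - log(10),
               f2$coefficients$estimate[1], tolerance = 1e-6)
})

test_that("de_table has Table-2 shape and sane single-gene degenerate case", {
  sim <- generate_study(synth_config(n_genes = 60, n_modules = 1,
                                     module_sizes = 20L, seed = 8))
  st <- size_factors(sim$study)
  de <- de_table(st)
  expect_s3_class(de, "de_table")
  expect_identical(de$gene, rownames(st$counts))
  expect_true(all(c("time_coef", "se", "t_stat", "p_value", "fdr",
                    "mean_counts_T0", "mean_counts_T3", "dispersion",
                    "subject_variance") %in% names(de)))
  expect_true(all(de$mean_counts_T0 >= 0 & de$mean_counts_T3 >= 0))
  expect_true(all(de$fdr >= de$p_value - 1e-12, na.rm = TRUE))
  # single-gene study: fdr equals p
  st1 <- count_study(st$counts[1, , drop = FALSE], st$samples,
                     st$size_factors)
  de1 <- de_table(st1)
  expect_equal(de1$fdr, de1$p_value)
})

test_that("the procedure interaction model reports its test columns", {
  sim <- generate_study(synth_config(n_genes = 40, n_modules = 1,
                                     module_sizes = 20L, seed = 12))
  st <- size_factors(sim$study)
  de <- de_table(st, interaction_procedure = TRUE)
  expect_true(all(c("interaction_coef", "interaction_t", "interaction_p",
                    "interaction_fdr") %in% names(de)))
  expect_true(any(is.finite(de$interaction_p)))
  # with no planted procedure effect the interaction is mostly null
  expect_gt(mean(de$interaction_p > 0.05, na.rm = TRUE), 0.7)
})

test_that("null p-values are near-uniform (KS)", {
  cfg <- synth_config(n_genes = 1000, frac_de = 0, module_loading = 0,
                      n_modules = 0, module_sizes = integer(),
                      frac_disconnected = 0, seed = 21)
  de <- de_table(size_factors(generate_study(cfg)$study))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
})

test_that("ranked export sorts by signed or absolute t", {
  de <- structure(data.frame(gene = c("g1", "g2", "g3"),
                             t_stat = c(2, -3, 1)),
                  class = c("de_table", "data.frame"))
  expect_identical(export_ranked(de, "signed")$gene, c("g1", "g3", "g2"))
  ab <- export_ranked(de, "absolute")
  expect_identical(ab$gene, c("g2", "g1", "g3"))
  expect_true(all(ab$score >= 0))
  f <- tempfile()
  write_rnk(export_ranked(de, "signed"), f)
  rk <- read.delim(f, header = FALSE)
  expect_identical(rk[[1]], c("g1", "g3", "g2"))
  unlink(f)
})

test_that("hypergeometric enrichment matches closed-form counting", {
  universe <- paste0("g", 1:10)
  r <- hypergeom_enrich(list(s = paste0("g", 1:5)),
                        selection = paste0("g", c(1:3, 5)),
                        universe = universe)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)   # C(5,4)C(5,0)/C(10,4)
  expect_equal(r$overlap, 4L)
  # zero overlap: upper tail at 0 is 1
  r0 <- hypergeom_enrich(list(s = paste0("g", 1:3)),
                         selection = paste0("g", 8:9), universe = universe)
  expect_equal(r0$p, 1)
  # selection = universe: overlap is certain
  r1 <- hypergeom_enrich(list(s = paste0("g", 1:4)),
                         selection = universe, universe = universe)
  expect_equal(r1$p, 1)
  expect_error(hypergeom_enrich(list(s = "g1"), "g1", character()), "universe")
})

test_that("GMT reading returns named gene sets", {
  f <- tempfile()
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_identical(names(gs), c("setA", "setB"))
  expect_identical(gs$setB, c("g2", "g4"))
  unlink(f)
})

test_that("de_fraction reports the printed-percentage convention", {
  expect_identical(de_fraction(1214, 15972), 7.6)
  expect_identical(de_fraction(1, 3, digits = 2), 33.33)
  expect_error(de_fraction(1, 0), "positive")
})
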