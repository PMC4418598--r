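#' Configuration for the synthetic paired count generator
#'
#' Defines the generative model for a paired (T0/T3) RNA-seq study with
#' planted structure: negative-binomial counts with per-sample size factors,
#' a subject random intercept shared by the two time points, a time effect
#' for a fraction of genes, latent per-sample module factors that induce
#' coexpression modules, and "disconnected" genes whose module loading is
#' zeroed at T3 (loss of coexpression without loss of expression).
#'
#' The log-mean of gene g in sample j is
#' \deqn{\mu_g + u_{s(j)} + \delta_g 1[t(j)=T3] + c_g \lambda_{gm} f_m(j)}
#' and counts are NB with variance \eqn{\mu + \phi \mu^2}.  `module_loading`
#' is on the correlation scale: \eqn{c_g} is chosen so that the correlation
#' between a member gene's log-expression and its module factor is
#' approximately `module_loading` (hence within-module gene-gene correlation
#' about `module_loading^2`).
#'
#' @param n_subjects number of subjects; each contributes one T0 and one T3
#'   sample.
#' @param n_genes total number of genes.
#' @param n_modules number of planted coexpression modules.
#' @param module_sizes integer vector of length `n_modules`; must sum to at
#'   most `n_genes`.
#' @param module_loading correlation-scale factor loading in \[0, 1\].
#' @param frac_de fraction of genes given a nonzero time effect.
#' @param de_log_fc magnitude of the time effect on the natural-log scale
#'   (signs are randomized per gene).
#' @param frac_disconnected fraction of module genes whose loading is zeroed
#'   at T3.
#' @param dispersion NB dispersion phi >= 0 (phi = 0 gives Poisson counts).
#' @param subject_sd SD of the per-subject random intercept (log scale).
#' @param libsize_sd SD of the log size factors.
#' @param base_log_mean_range interval (natural log) for gene baseline
#'   log-means.
#' @param seed RNG seed; the same config and seed give bit-identical output.
#' @return an object of class `synth_config`.
#' @seealso [generate_study()], [generate_traits()]
#' @export
synth_config <- function(n_subjects = 22L, n_genes = 2000L, n_modules = 5L,
                         module_sizes = c(300L, 200L, 150L, 100L, 50L),
                         module_loading = 0.7, frac_de = 0.1,
                         de_log_fc = log(2), frac_disconnected = 0.1,
                         dispersion = 0.2, subject_sd = 0.2, libsize_sd = 0.2,
                         base_log_mean_range = c(log(50), log(2000)),
                         seed = 1L) {
  .stop_if(n_subjects < 2, "need at least 2 subjects")
  .stop_if(length(module_sizes) != n_modules,
           "module_sizes must have length n_modules")
  .stop_if(sum(module_sizes) > n_genes,
           "module_sizes exceed n_genes (", sum(module_sizes), " > ", n_genes, ")")
  for (f in c(module_loading, frac_de, frac_disconnected))
    .stop_if(f < 0 || f > 1, "fractions and loadings must lie in [0, 1]")
  .stop_if(dispersion < 0, "dispersion must be >= 0")
  .stop_if(subject_sd < 0 || libsize_sd < 0, "SDs must be >= 0")
  .stop_if(length(base_log_mean_range) != 2 || diff(base_log_mean_range) < 0,
           "base_log_mean_range must be an increasing interval")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_genes = as.integer(n_genes),
                 n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 module_loading = module_loading, frac_de = frac_de,
                 de_log_fc = de_log_fc, frac_disconnected = frac_disconnected,
                 dispersion = dispersion, subject_sd = subject_sd,
                 libsize_sd = libsize_sd,
                 base_log_mean_range = base_log_mean_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic paired count study with known ground truth
#'
#' Draws a paired T0/T3 negative-binomial count study from the generative
#' model described in [synth_config()], together with a baseline trait table
#' (see [generate_traits()]) and the ground truth needed to score recovery:
#' module membership, true differentially expressed genes, disconnected
#' genes, size factors and subject effects.
#'
#' Sample metadata carries subject, time, sequencing run (two levels), RIN,
#' RNA concentration, age, ethnicity and surgical procedure.  Run and RIN
#' have small planted per-gene effects so that covariate adjustment is
#' testable.
#'
#' @param config a [synth_config()] object.
#' @return a list with components `study` (a [count_study()]), `traits`
#'   (data frame of per-subject baseline traits), and `truth` (list:
#'   `module_of_gene`, `de_genes`, `de_log_fc`, `disconnected_genes`,
#'   `true_size_factors`, `true_subject_effects`, `factors` - the per-sample
#'   module factor matrix).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  S <- config$n_subjects; G <- config$n_genes; M <- config$n_modules
  ns <- 2L * S
  genes <- sprintf("g%04d", seq_len(G))
  subjects <- sprintf("s%02d", seq_len(S))
  time <- rep(c("T0", "T3"), each = S)
  sample_ids <- paste0(rep(subjects, 2L), "_", time)

  # gene-level parameters
  mu <- runif(G, config$base_log_mean_range[1], config$base_log_mean_range[2])
  labels <- integer(G)
  idx <- 1L
  for (m in seq_len(M)) {
    labels[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  names(labels) <- genes

  # sample-level parameters
  u <- rnorm(S, 0, config$subject_sd)                  # subject intercepts
  sf <- exp(rnorm(ns, 0, config$libsize_sd))           # true size factors
  run <- factor(sample(c("R1", "R2"), ns, replace = TRUE))
  rin <- pmin(10, pmax(6, rnorm(ns, 8, 0.5)))
  conc <- rlnorm(ns, log(100), 0.3)
  age <- round(runif(S, 28, 55))
  ethnicity <- factor(ifelse(rbinom(S, 1, 0.8) == 1, "european", "other"))
  n_rygb <- round(15 / 22 * S)
  procedure <- factor(rep(c("RYGB", "AGB"), c(n_rygb, S - n_rygb)))

  # latent module factors, independent per sample
  fac <- matrix(rnorm(ns * max(M, 1L)), ns, max(M, 1L),
                dimnames = list(sample_ids, paste0("M", seq_len(max(M, 1L)))))

  # planted DE genes and disconnected module genes
  n_de <- round(config$frac_de * G)
  de_idx <- if (n_de > 0) sort(sample.int(G, n_de)) else integer()
  delta <- numeric(G)
  if (n_de > 0) delta[de_idx] <- config$de_log_fc * sample(c(-1, 1), n_de, TRUE)
  mod_idx <- which(labels > 0)
  n_dis <- round(config$frac_disconnected * length(mod_idx))
  dis_idx <- if (n_dis > 0) sort(sample(mod_idx, n_dis)) else integer()

  # small planted covariate effects (run, RIN) per gene
  g_run <- rnorm(G, 0, 0.1)
  g_rin <- rnorm(G, 0, 0.05)

  # loading -> log-scale coefficient: noise variance of log counts is about
  # trigamma(1/phi) + 1/mean (NB log-scale variance); the shared subject
  # intercept is absorbed by size factors and not counted
  vnoise <- (if (config$dispersion > 0) trigamma(1 / config$dispersion) else 0) +
    1 / exp(mu)
  lam <- config$module_loading
  cg <- ifelse(labels > 0 & lam > 0 & lam < 1,
               lam * sqrt(vnoise) / sqrt(1 - lam^2),
               ifelse(labels > 0 & lam >= 1, 10 * sqrt(vnoise), 0))

  eta <- matrix(mu, G, ns)
  eta <- eta + matrix(u[rep(seq_len(S), 2L)], G, ns, byrow = TRUE)
  eta <- eta + outer(delta, as.numeric(time == "T3"))
  eta <- eta + outer(g_run, as.numeric(run == "R2"))
  eta <- eta + outer(g_rin, rin - mean(rin))
  for (m in seq_len(M)) {
    gm <- which(labels == m)
    if (!length(gm)) next
    load_vec <- matrix(cg[gm], length(gm), ns)
    if (length(dis_idx)) {
      off <- intersect(gm, dis_idx)
      if (length(off)) load_vec[match(off, gm), time == "T3"] <- 0
    }
    eta[gm, ] <- eta[gm, ] + load_vec * matrix(fac[, m], length(gm), ns, byrow = TRUE)
  }
  mu_lin <- sweep(exp(eta), 2, sf, `*`)
  counts <- if (config$dispersion > 0) {
    matrix(rnbinom(G * ns, mu = mu_lin, size = 1 / config$dispersion), G, ns)
  } else {
    matrix(rpois(G * ns, lambda = mu_lin), G, ns)
  }
  dimnames(counts) <- list(genes, sample_ids)

  samples <- data.frame(sample = sample_ids,
                        subject = rep(subjects, 2L),
                        time = time, run = run, rin = rin,
                        concentration = conc,
                        age = rep(age, 2L),
                        ethnicity = rep(as.character(ethnicity), 2L),
                        procedure = rep(as.character(procedure), 2L),
                        stringsAsFactors = FALSE)
  study <- count_study(counts, samples)

  truth <- list(module_of_gene = labels,
                de_genes = genes[de_idx],
                de_log_fc = setNames(delta, genes),
                disconnected_genes = genes[dis_idx],
                true_size_factors = setNames(sf, sample_ids),
                true_subject_effects = setNames(u, subjects),
                factors = fac)

  traits <- generate_traits(fac[time == "T0", , drop = FALSE],
                            seed = config$seed + 1L)
  traits$subject <- subjects
  traits <- traits[, c("subject", setdiff(names(traits), "subject"))]

  list(study = study, traits = traits, truth = truth)
}

#' Default trait specification for the synthetic trait table
#'
#' Maps each simulated clinical trait to a module factor, a target Spearman
#' correlation and a realistic unit scale (means/SDs typical of a severely
#' obese bariatric-surgery cohort at baseline).  Insulin and glucose are
#' always included so that HOMA-IR is computable.
#'
#' @param n_modules number of modules available; trait-module indices are
#'   folded into `1..n_modules`.
#' @return data frame with columns `trait`, `module`, `rho`, `mean`, `sd`.
#' @export
default_trait_spec <- function(n_modules = 5L) {
  spec <- data.frame(
    trait = c("bmi", "fat_mass", "lean_mass", "adipocyte_volume", "leptin",
              "crp", "il6", "adiponectin",
              "glucose", "insulin",
              "triglycerides", "hdl",
              "sbp", "dbp"),
    module = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L),
    rho = c(0.6, 0.55, 0.4, 0.5, 0.6, 0.5, 0.4, -0.4,
            0.4, 0.5, 0.4, -0.4, 0.3, 0.3),
    mean = c(46.5, 61.9, 59.4, 936.7, 85.4, 9.36, 5.40, 4.59,
             5.12, 21.6, 1.30, 1.11, 130, 80),
    sd = c(5.6, 10.5, 6.4, 188.4, 35.5, 4.34, 3.11, 1.94,
           0.65, 10.9, 0.59, 0.32, 15, 10),
    stringsAsFactors = FALSE)
  spec$module <- ((spec$module - 1L) %% max(as.integer(n_modules), 1L)) + 1L
  spec
}

#' Generate traits correlated with module factors
#'
#' Each trait is a noisy linear function of its designated module factor:
#' `z = rho * scale(f) + sqrt(1 - rho^2) * e`, mapped to trait units via
#' `mean + sd * z` and truncated at a small positive floor for
#' concentration-like traits.  The population correlation with the factor is
#' `rho`.
#'
#' @param factors numeric matrix, rows = samples/subjects, columns = module
#'   factors.
#' @param spec data frame with columns `trait`, `module`, `rho` and
#'   optionally `mean`, `sd` (defaults 0/1); see [default_trait_spec()].
#' @param seed RNG seed.
#' @return data frame of traits, one row per row of `factors`.
#' @export
generate_traits <- function(factors, spec = default_trait_spec(ncol(factors)),
                            seed = 1L) {
  factors <- as.matrix(factors)
  .stop_if(any(!spec$module %in% seq_len(ncol(factors))),
           "trait spec refers to unknown module label")
  .stop_if(any(abs(spec$rho) >= 1), "target_rho entries must lie in (-1, 1)")
  if (is.null(spec$mean)) spec$mean <- 0
  if (is.null(spec$sd)) spec$sd <- 1
  set.seed(seed)
  n <- nrow(factors)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    f <- as.numeric(scale(factors[, spec$module[i]]))
    z <- spec$rho[i] * f + sqrt(1 - spec$rho[i]^2) * rnorm(n)
    v <- spec$mean[i] + spec$sd[i] * z
    if (spec$mean[i] > 0) v <- pmax(v, 0.01 * spec$mean[i])
    v
  })
  names(out) <- spec$trait
  as.data.frame(out)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `counts.tsv`, `samples.tsv`, `traits.tsv` and `truth.json` under
#' `dir` so a study can be inspected or re-loaded with [read_counts()].
#'
#' @param sim result of [generate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$study, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  write.table(sim$traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$factors <- NULL  # matrix ground truth kept in-memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
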