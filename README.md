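# pairnet

Analysis toolkit for **paired (before/after) bulk RNA-seq studies** of the
kind produced by bariatric-surgery and other intervention cohorts: the
same subjects are profiled at baseline (T0) and after the intervention
(T3), and the questions are

1. which genes change expression with time, and
2. how the baseline **coexpression network** is organized — its modules,
   their stability, their clinical-trait associations — and which genes
   become **disconnected** from their module after the intervention
   (network rewiring without necessarily a change in mean expression).

The package is aimed at statisticians and computational biologists who
want every stage of such an analysis as tested, composable R functions,
plus a synthetic-data generator that plants known structure so the whole
pipeline can be validated against ground truth.

## The models at the core

**Differential expression.** Per gene, a negative-binomial mixed model
with log link,

    y_gj ~ NB(mu_gj, phi_g),   log mu_gj = log s_j + x_j' beta_g + u_{g,s(j)},
    u_{g,s} ~ N(0, sigma_g^2),

with median-of-ratios size factors `s_j` as offset, fixed effects for
time and technical/clinical covariates, and a per-subject random
intercept for the pairing. Dispersion is estimated first by method of
moments on Pearson residuals; the mixed model is then maximized by
penalized IRLS with the subject variance profiled out on the
Laplace-approximate likelihood. Wald t-tests
(df = n_obs − n_fixed − 1) are BH-adjusted across genes.

**Coexpression network.** Unsigned weighted adjacency
`a_ij = |cor(x_i, x_j)|^beta` (default `beta = 6`), topological-overlap
similarity, and tree-based module detection (deep adaptive cut for
cores, TOM-based consolidation and iterative relative-tightness
assignment, sequential extraction rounds, eigengene merging at r > 0.75).
Modules are summarized by eigengenes (oriented unit-norm PC1), module
membership `MM = cor(gene, eigengene)` and hubgenes; stability is
assessed by leave-one-out jackknife with maximum-Jaccard matching and
the k_i >= ceil(18/22 · n) classification rule; traits are associated by
Spearman correlation; and cross-condition rewiring is quantified by the
membership drop `delta_MM = MM_ref − MM_test` on a fixed gene set, plus
thresholded edge networks (|cor| > 0.4 and p < 0.05).

Clinical utilities include HOMA-IR (`insulin × glucose / 22.5`),
metabolic-syndrome factor counting and a diabetes rule.

## Worked example

```r
library(pairnet)

# a paired study with known truth: 22 subjects, 800 genes,
# 3 planted modules (150/100/60 genes, loading 0.8), 10% DE genes
cfg <- synth_config(n_subjects = 22, n_genes = 800, n_modules = 3,
                    module_sizes = c(150, 100, 60), module_loading = 0.8,
                    seed = 42)
sim   <- generate_study(cfg)
study <- size_factors(filter_low_expression(sim$study))

## 1. differential expression -------------------------------------------
de <- de_table(study)
summary(de)
#> Differential expression over 800 genes
#>   84 genes (10.5%) differentially expressed at FDR < 0.05

## 2. baseline coexpression network -------------------------------------
x  <- vst_transform(study)
x  <- adjust_covariates(x, study$samples[, c("run", "rin", "concentration")])
x0 <- x[, study$samples$time == "T0"]
net <- coexpression_network(x0)
net
#> coex_net: beta = 6 | 800 genes | 3 modules | 477 unassigned
#>   module sizes: 167, 102, 54

## 3. jackknife stability ------------------------------------------------
jackknife_stability(x0)
#> Jackknife stability over 22 leave-one-out subsets (stable: k >= 18)
#>   module size mean_jaccard sd_jaccard mean_eigengene_cor prop_correct
#> 1      1  167        0.960      0.026              1.000        0.958
#> 2      2  102        0.987      0.012              1.000        1.000
#> 3      3   54        0.868      0.085              0.998        0.907

## 4. eigengene-trait associations (Spearman) ----------------------------
assoc <- eigengene_trait_cor(net$eigengenes, sim$traits[-1])
round(assoc$rho[1:3, ], 2)
#>            ME1   ME2  ME3
#> bmi       0.45 -0.38 0.13
#> fat_mass  0.26  0.15 -0.16
#> lean_mass 0.61  0.04 -0.04

## 5. rewiring after the intervention ------------------------------------
x3 <- x[, study$samples$time == "T3"]
shift <- membership_shift(x0, x3, net$labels)
shift
#> rewiring_report: 323 genes in 3 modules; 32 flagged disconnected
#>   (mm_ref >= 0.5 & mm_test <= 0.2)
#>      gene module    mm_ref    mm_test delta_mm disconnected
#> 253 g0237      2 0.8108113 -0.4727961 1.283607         TRUE
#> ...
```

The detected modules recover the planted ones (sizes 167/102/54 against
150/100/60), the jackknife marks them stable, and 18 of the top 20 genes
by `delta_mm` are genes whose module loading was truly zeroed at T3 in
the generator.

## Package layout

| file | contents |
|---|---|
| `R/synth.R` | synthetic paired-study and trait generator |
| `R/pheno.R` | HOMA-IR, MetS, diabetes classification |
| `R/prep.R` | count I/O, filtering, size factors, VST, covariate adjustment, gene selection |
| `R/nbglmm.R`, `R/de.R` | NB mixed model, dispersion, BH FDR, DE table, ranked export, hypergeometric enrichment |
| `R/net.R` | adjacency, soft-threshold scan, TOM, module detection, eigengenes, MM, hubgenes, `coexpression_network()` |
| `R/stab.R` | Jaccard, best-match, jackknife stability |
| `R/traits.R` | eigengene-trait Spearman associations |
| `R/rewire.R` | condition matrices, membership shift, edge networks, cross-study preservation |

The methods vignette (`vignettes/paired-coexpression-rewiring.Rmd`)
documents the models, the numerical choices and the design decisions in
detail.
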