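test_that("f_statistic reproduces the closed form and its limits", {
  expect_equal(f_statistic(0.01, 1001, 1), 999 * (0.01 / 0.99),
               tolerance = 1e-12)
  expect_equal(f_statistic(0.5, 12, 1), 10)
  expect_identical(f_statistic(0, 100, 1), 0)
  expect_error(f_statistic(1, 100, 1), "0, 1")
  expect_error(f_statistic(-0.1, 100, 1), "0, 1")
  expect_error(f_statistic(0.1, 2, 1), "n > k")
})

test_that("f_statistic is strictly increasing in r2 and n", {
  r2s <- seq(0.01, 0.9, by = 0.05)
  expect_true(all(diff(f_statistic(r2s, 100, 1)) > 0))
  ns <- seq(10, 500, by = 10)
  expect_true(all(diff(vapply(ns, function(n) f_statistic(0.1, n, 1),
                              numeric(1))) > 0))
})

test_that("max-rescaled r2 matches an independent likelihood computation", {
  withr::with_seed(41, {
    d <- rbinom(400, 2, 0.3)
    y <- rbinom(400, 1, plogis(-0.3 + 0.5 * d))
  })
  fit1 <- glm(y ~ d, family = binomial())
  fit0 <- glm(y ~ 1, family = binomial())
  n <- length(y)
  r2_cs <- 1 - exp((2 / n) * (as.numeric(logLik(fit0)) -
                                as.numeric(logLik(fit1))))
  upper <- 1 - exp((2 / n) * as.numeric(logLik(fit0)))
  expect_equal(r2_for_unrelated(d, y), r2_cs / upper, tolerance = 1e-8)
})

test_that("r2_for_unrelated spans its limits", {
  withr::with_seed(42, {
    y <- rbinom(50000, 1, 0.5)
    d_null <- rbinom(50000, 2, 0.3)
  })
  expect_lt(r2_for_unrelated(d_null, y), 0.001)
  expect_gt(r2_for_unrelated(2L * y, y), 0.95)  # perfect prediction
})

test_that("related-sample r2 is symmetric and null-calibrated", {
  withr::with_seed(43, {
    n <- 2000
    fam <- rep(sprintf("f%03d", 1:400), each = 5)
    d <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, 0.5)
  })
  r2 <- r2_for_related(d, y, covariates = NULL, family_ids = fam)
  expect_lt(r2, 0.002)
  # direction symmetry of the simple-regression R-squared
  fitA <- lm(d ~ residuals(glm(y ~ 1, family = binomial()),
                           type = "response"))
  fitB <- lm(residuals(glm(y ~ 1, family = binomial()),
                       type = "response") ~ d)
  expect_equal(summary(fitA)$r.squared, summary(fitB)$r.squared,
               tolerance = 1e-12)
})

test_that("modelling the family intercept sharpens the planted-SNP r2", {
  # family-driven exposure variation is removed by the mixed model, so the
  # SNP's share of the residual variation exceeds its share of the raw
  # variation
  withr::with_seed(44, {
    n <- 4000
    fam <- rep(sprintf("f%03d", 1:400), each = 10)
    u <- rep(rnorm(400, 0, 2), each = 10)
    d <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(0.35 * d + u))
  })
  r2_rel <- r2_for_related(d, y, covariates = NULL, family_ids = fam)
  r2_naive <- r2_for_unrelated(d, y)
  expect_gt(r2_rel, r2_naive)
})

test_that("ld_prune keeps the more exposure-associated duplicate", {
  withr::with_seed(45, {
    d <- rbinom(500, 2, 0.3)
  })
  dmat <- cbind(a = d, b = d)
  expect_identical(ld_prune(dmat, c(a = 0.2, b = 0.001), 0.3), "b")
  expect_identical(ld_prune(dmat, c(a = 0.001, b = 0.2), 0.3), "a")
  # p tie: lexicographically later id removed
  expect_identical(ld_prune(dmat, c(a = 0.05, b = 0.05), 0.3), "a")
})

test_that("independent variants all survive pruning", {
  withr::with_seed(46, {
    dmat <- matrix(rbinom(10000 * 6, 2, 0.3), ncol = 6)
  })
  colnames(dmat) <- sprintf("v%d", 1:6)
  ps <- setNames(runif(6), colnames(dmat))
  expect_identical(ld_prune(dmat, ps, 0.3), colnames(dmat))
})

test_that("pruning a planted correlated triple matches brute force", {
  withr::with_seed(47, {
    n <- 300
    base <- rbinom(n, 2, 0.4)
    flip <- function(x, rate) {
      sel <- runif(n) < rate
      x[sel] <- rbinom(sum(sel), 2, 0.4)
      x
    }
    dmat <- cbind(
      v1 = base, v2 = flip(base, 0.15), v3 = flip(base, 0.2),
      v4 = rbinom(n, 2, 0.3), v5 = rbinom(n, 2, 0.3)
    )
    ps <- setNames(c(0.01, 0.02, 0.03, 0.2, 0.5), colnames(dmat))
  })
  kept <- ld_prune(dmat, ps, 0.3)
  # postcondition recertified by direct recomputation
  cm <- cor(dmat[, kept])^2
  expect_true(all(cm[upper.tri(cm)] < 0.3))
  # exhaustive search over all 2^5 subsets for the largest feasible set
  best <- 0L
  for (mask in 0:31) {
    ids <- colnames(dmat)[bitwAnd(mask, 2^(0:4)) > 0]
    if (length(ids) < 2L) { best <- max(best, length(ids)); next }
    cc <- cor(dmat[, ids])^2
    if (all(cc[upper.tri(cc)] < 0.3)) best <- max(best, length(ids))
  }
  expect_identical(length(kept), best)
})

test_that("planted confounders are identified and nulls are not", {
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_cohort(sim_config(
      n_individuals = 10000, n_snps_per_gene = 1,
      confounder_effects = list(smoking = list(bmi = 1, outcome = -0.4)),
      seed = 400 + s
    ))
    co <- derive_variables(sim$cohort)
    conf <- identify_confounders(co, c("smoking", "pc1"), alpha = 0.05)
    if ("smoking" %in% conf$covariate) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  expect_identical(
    nrow(identify_confounders(co, character(0))), 0L)
})

test_that("null covariates are selected at about the nominal rate", {
  false_pos <- 0L
  n_reps <- 100L
  for (s in seq_len(n_reps)) {
    sim <- simulate_cohort(sim_config(
      n_individuals = 1500, n_snps_per_gene = 1, seed = 500 + s
    ))
    co <- derive_variables(sim$cohort)
    conf <- identify_confounders(co, "pc1", alpha = 0.05)
    if (nrow(conf) > 0L) false_pos <- false_pos + 1L
  }
  expect_gt(false_pos / n_reps, 0.005)
  expect_lt(false_pos / n_reps, 0.125)
})

test_that("assumption tests pass planted-valid and fail planted-invalid", {
  ok_valid <- 0L; caught_pleio <- 0L; caught_null <- 0L
  for (s in 1:3) {
    sim <- simulate_cohort(sim_config(
      n_individuals = 8000, genes = c("FTO", "LEP", "MC4R"),
      n_snps_per_gene = 1, maf_range = c(0.3, 0.3),
      beta_main = c(1.2, 1.2, 0),          # SNP3 has no BMI effect
      pleiotropy_effects = c(0, 0.5, 0),   # SNP2 hits the outcome directly
      seed = 600 + s
    ))
    co <- derive_variables(sim$cohort)
    conf <- identify_confounders(co, c("sex", "pc1"))
    res <- purrr::map_dfr(1:3, function(j) {
      test_assumptions(sim$genotypes$dosages[, j], co, conf,
                       id = sprintf("snp%d", j))
    })
    if (res$passed[1]) ok_valid <- ok_valid + 1L
    if (grepl("exclusion", res$reasons[2])) caught_pleio <- caught_pleio + 1L
    if (!res$passed[3] &&
        grepl("relevance|weak_instrument", res$reasons[3])) {
      caught_null <- caught_null + 1L
    }
  }
  expect_gte(ok_valid, 2L)
  expect_identical(caught_pleio, 3L)
  expect_identical(caught_null, 3L)
})

test_that("monomorphic variants fail fast with a reason", {
  sim <- simulate_cohort(sim_config(n_individuals = 500,
                                    n_snps_per_gene = 1, seed = 49))
  co <- derive_variables(sim$cohort)
  res <- test_assumptions(rep(0L, 500), co, character(0))
  expect_false(res$passed)
  expect_match(res$reasons, "monomorphic")
})

test_that("select_ivs audit stages partition the candidates", {
  sim <- simulate_cohort(sim_config(
    n_individuals = 3000, n_snps_per_gene = 2, beta_main = 0.6, seed = 50
  ))
  co <- derive_variables(sim$cohort)
  audit <- select_ivs(sim$genotypes, co, f_min = 2)
  expect_identical(nrow(audit), 16L)
  expect_identical(sum(audit$stage == "qualified") +
                     sum(startsWith(audit$stage, "failed_")) +
                     sum(audit$stage == "monomorphic"),
                   nrow(audit))
  # LD-pruned retained set is re-certified below the cutoff
  qual <- audit$id[audit$stage == "qualified"]
  if (length(qual) >= 2L) {
    cm <- cor(sim$genotypes$dosages[, qual])^2
    expect_true(all(cm[upper.tri(cm)] < 0.3))
  }
  # an unattainable strength threshold leaves the qualified set empty
  audit_inf <- suppressWarnings(select_ivs(sim$genotypes, co, f_min = Inf))
  expect_identical(sum(audit_inf$stage == "qualified"), 0L)
  expect_true(any(audit_inf$stage == "failed_F"))
})

test_that("gwas mode screens on the adjusted exposure scan first", {
  sim <- simulate_cohort(sim_config(
    n_individuals = 3000, genes = c("FTO", "LEP"), n_snps_per_gene = 1,
    beta_main = c(1.0, 0), seed = 51
  ))
  co <- derive_variables(sim$cohort)
  audit <- select_ivs(sim$genotypes, co, mode = "gwas", f_min = 2)
  expect_identical(audit$stage[2], "failed_gwas_scan")
  expect_identical(audit$stage[1], "qualified")
})

test_that("relevance screening is calibrated under the null", {
  # null SNPs: no planted effects anywhere
  sim <- simulate_cohort(sim_config(
    n_individuals = 5000, genes = sprintf("G%02d", 1:25),
    n_snps_per_gene = 20, beta_main = 0, seed = 52
  ))
  co <- derive_variables(sim$cohort)
  dat <- co[!co$excluded, ]
  idx <- match(dat$id, sim$genotypes$ids)
  p_rel <- vapply(seq_len(500), function(j) {
    compositemr:::fast_logit(sim$genotypes$dosages[idx, j],
                             dat$exposure)[["p"]]
  }, numeric(1))
  rate <- mean(p_rel < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
})
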