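#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. Defaults
#' emulate a candidate-gene cohort of older adults: SNPs in eight
#' obesity/BMI genes drive mean BMI over ages 75-85, BMI dichotomized into
#' overweight (25 <= BMI < 30) versus normal weight (18.5 <= BMI < 25) acts
#' on the log-odds of surviving past age 85, and categorical covariates are
#' drawn with frequencies typical of such cohorts.
#'
#' @param n_individuals cohort size.
#' @param n_snps_per_gene SNPs simulated per candidate gene.
#' @param genes gene labels; one block of SNPs per gene.
#' @param maf_range minor-allele frequencies drawn uniformly from this
#'   interval, within (0, 0.5].
#' @param beta_main additive effect of each minor allele on mean BMI
#'   (kg/m^2); scalar or per-SNP vector.
#' @param beta_interaction effect on mean BMI of the recoded dosage (see
#'   [recode_pair()]) of each interacting SNP pair; scalar or per-pair.
#' @param interaction_pairs 2-column matrix of SNP indices forming
#'   interacting pairs; `NULL` pairs consecutive SNPs (1,2), (3,4), ... when
#'   `beta_interaction` is non-zero.
#' @param theta_true log-odds effect of overweight (vs normal weight) on
#'   surviving to age 85.
#' @param outcome_intercept baseline log-odds of surviving to 85.
#' @param confounder_effects named list of `list(bmi =, outcome =)` effects
#'   per covariate (acting on both BMI mean and survival log-odds — that
#'   dual action is what makes a covariate a confounder). Covariate names
#'   must be among the generated covariates.
#' @param pleiotropy_effects per-SNP direct log-odds effects on the outcome
#'   (scalar recycled or vector); a non-zero value plants an
#'   exclusion-assumption violation.
#' @param covariate_freqs named list of category probabilities for
#'   `sex` (codes 1,2), `race` (1,2,3), `education` (0,1,2), `smoking`
#'   (0,1), `comorbidity` (0,1), `field_center` (1,2).
#' @param n_families number of families (0 = unrelated); individuals are
#'   assigned round-robin.
#' @param family_effect_sd sd of the family-level random intercept on BMI.
#' @param bmi_noise_sd residual sd of individual mean BMI (kg/m^2).
#' @param bmi_measure_sd measurement noise sd around the individual mean
#'   for each repeated BMI measure (default 0: measures equal the mean).
#' @param n_bmi_measures repeated BMI measures per individual, at ages
#'   uniform in [75, 85].
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 5000,
                       n_snps_per_gene = 3,
                       genes = OBESITY_GENES,
                       maf_range = c(0.1, 0.4),
                       beta_main = 0.25,
                       beta_interaction = 0,
                       interaction_pairs = NULL,
                       theta_true = 0.2,
                       outcome_intercept = 1.1,
                       confounder_effects = list(),
                       pleiotropy_effects = 0,
                       covariate_freqs = list(),
                       n_families = 0,
                       family_effect_sd = 0,
                       bmi_noise_sd = 2.5,
                       bmi_measure_sd = 0,
                       n_bmi_measures = 3,
                       seed = 1L) {
  assert_number(n_individuals, "n_individuals", lo = 1)
  assert_number(n_snps_per_gene, "n_snps_per_gene", lo = 0)
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5]")
  }
  for (nm in c("family_effect_sd", "bmi_noise_sd", "bmi_measure_sd")) {
    assert_number(get(nm), nm, lo = 0)
  }
  assert_number(n_families, "n_families", lo = 0)
  assert_number(n_bmi_measures, "n_bmi_measures", lo = 1)
  assert_number(theta_true, "theta_true")
  assert_number(outcome_intercept, "outcome_intercept")
  assert_number(seed, "seed")
  defaults_freq <- list(
    sex = c(`1` = 0.45, `2` = 0.55),
    race = c(`1` = 0.80, `2` = 0.15, `3` = 0.05),
    education = c(`0` = 0.20, `1` = 0.40, `2` = 0.40),
    smoking = c(`0` = 0.44, `1` = 0.56),
    comorbidity = c(`0` = 0.39, `1` = 0.61),
    field_center = c(`1` = 0.80, `2` = 0.20)
  )
  unknown <- setdiff(names(covariate_freqs), names(defaults_freq))
  if (length(unknown)) {
    abort(paste0("unknown covariate_freqs entries: ",
                 paste(unknown, collapse = ", ")))
  }
  covariate_freqs <- modifyList(defaults_freq, covariate_freqs)
  for (nm in names(covariate_freqs)) {
    pr <- covariate_freqs[[nm]]
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8) {
      abort(sprintf("covariate_freqs$%s must be non-negative and sum to 1", nm))
    }
  }
  valid_cov <- c(names(defaults_freq), "pc1", "pc2")
  unknown <- setdiff(names(confounder_effects), valid_cov)
  if (length(unknown)) {
    abort(paste0("confounder_effects for unknown covariates: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- length(genes) * n_snps_per_gene
  if (!length(beta_main) %in% c(1L, m)) {
    abort("`beta_main` must be scalar or one value per SNP")
  }
  if (!is.null(interaction_pairs)) {
    interaction_pairs <- as.matrix(interaction_pairs)
    if (ncol(interaction_pairs) != 2L ||
        any(interaction_pairs < 1) || any(interaction_pairs > m)) {
      abort("`interaction_pairs` must be a 2-column matrix of SNP indices")
    }
  }
  if (!length(pleiotropy_effects) %in% c(1L, m)) {
    abort("`pleiotropy_effects` must be scalar or one value per SNP")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_snps_per_gene = as.integer(n_snps_per_gene),
      genes = genes,
      maf_range = maf_range,
      beta_main = beta_main,
      beta_interaction = beta_interaction,
      interaction_pairs = interaction_pairs,
      theta_true = theta_true,
      outcome_intercept = outcome_intercept,
      confounder_effects = confounder_effects,
      pleiotropy_effects = pleiotropy_effects,
      covariate_freqs = covariate_freqs,
      n_families = as.integer(n_families),
      family_effect_sd = family_effect_sd,
      bmi_noise_sd = bmi_noise_sd,
      bmi_measure_sd = bmi_measure_sd,
      n_bmi_measures = as.integer(n_bmi_measures),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sample_cat <- function(n, probs) {
  as.integer(names(probs))[
    sample.int(length(probs), n, replace = TRUE, prob = probs)
  ]
}

#' Simulate a candidate-gene cohort with known ground truth
#'
#' Draws genotypes per SNP as binomial(2, maf) (Hardy-Weinberg), builds
#' individual mean BMI from baseline 21.75 kg/m^2 plus SNP main effects,
#' SNP x SNP interaction effects on recoded pair dosages, confounder terms,
#' a family random intercept and Gaussian noise; emits repeated BMI
#' measures at ages uniform in [75, 85]; and draws survival past 85 from a
#' logistic model in overweight status, confounders and any planted direct
#' (pleiotropic) SNP effects. Survivors are censored at an age >= 85,
#' deaths occur uniformly in [76, 85). Individuals whose mean BMI falls
#' outside [18.5, 30) are still emitted: filtering is the job of
#' [derive_variables()].
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [geno_matrix()]) and `cohort` (a tibble
#'   of raw phenotypes: covariates, ages, death indicator, family id and a
#'   `bmi_measures` list-column).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be built with sim_config()")
  }
  withr::local_seed(config$seed)
  n <- config$n_individuals
  m <- length(config$genes) * config$n_snps_per_gene

  mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  G <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
  gene_of <- rep(config$genes, each = config$n_snps_per_gene)
  ids <- sprintf("ind%05d", seq_len(n))
  snp_ids <- if (m > 0L) {
    paste0("rs_", gene_of, "_",
           rep(seq_len(max(config$n_snps_per_gene, 1L)),
               times = length(config$genes)))
  } else character()
  variants <- tibble::tibble(
    id = snp_ids,
    gene = gene_of,
    chrom = as.character(rep(seq_along(config$genes),
                             each = config$n_snps_per_gene)),
    pos = 1000L * seq_len(m),
    a1 = rep("A", m),
    a2 = rep("G", m),
    maf = if (m > 0L) unname(colMeans(G) / 2) else numeric()
  )

  covs <- tibble::tibble(
    sex = sample_cat(n, config$covariate_freqs$sex),
    race = sample_cat(n, config$covariate_freqs$race),
    education = sample_cat(n, config$covariate_freqs$education),
    smoking = sample_cat(n, config$covariate_freqs$smoking),
    comorbidity = sample_cat(n, config$covariate_freqs$comorbidity),
    field_center = sample_cat(n, config$covariate_freqs$field_center),
    pc1 = rnorm(n),
    pc2 = rnorm(n)
  )

  family_id <- if (config$n_families > 0L) {
    sprintf("fam%04d", rep_len(seq_len(config$n_families), n))
  } else ids
  fam_int <- if (config$n_families > 0L && config$family_effect_sd > 0) {
    u <- rnorm(config$n_families, 0, config$family_effect_sd)
    u[rep_len(seq_len(config$n_families), n)]
  } else rep(0, n)

  conf_bmi <- rep(0, n)
  conf_out <- rep(0, n)
  for (nm in names(config$confounder_effects)) {
    eff <- config$confounder_effects[[nm]]
    v <- as.numeric(covs[[nm]])
    conf_bmi <- conf_bmi + (eff$bmi %||% 0) * v
    conf_out <- conf_out + (eff$outcome %||% 0) * v
  }

  beta_main <- rep_len(config$beta_main, m)
  mean_bmi <- 21.75 + as.vector(G %*% beta_main) + conf_bmi + fam_int +
    rnorm(n, 0, config$bmi_noise_sd)

  pairs <- config$interaction_pairs
  if (is.null(pairs) && any(config$beta_interaction != 0) && m >= 2L) {
    idx <- seq_len(m - m %% 2L)
    pairs <- matrix(idx, ncol = 2L, byrow = TRUE)
  }
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    b_int <- rep_len(config$beta_interaction, nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      rc <- recode_pair(G[, pairs[p, 1L]], G[, pairs[p, 2L]])
      mean_bmi <- mean_bmi + b_int[p] * rc
    }
  }

  overweight_gen <- as.numeric(mean_bmi >= 25)  # generation-time exposure
  pleio <- rep_len(config$pleiotropy_effects, m)
  lp <- config$outcome_intercept + config$theta_true * overweight_gen +
    conf_out + if (m > 0L) as.vector(G %*% pleio) else 0
  survived <- rbinom(n, 1L, plogis(lp))

  enrollment_age <- pmin(pmax(rnorm(n, 67, 7), 50), 75.5)
  event_age <- ifelse(survived == 1L, runif(n, 85, 95), runif(n, 76, 85))
  death <- ifelse(survived == 1L, 0L, 1L)

  k <- config$n_bmi_measures
  meas_age <- matrix(runif(n * k, 75, 85), n, k)
  meas_bmi <- mean_bmi + matrix(rnorm(n * k, 0, config$bmi_measure_sd), n, k)
  bmi_measures <- lapply(seq_len(n), function(i) {
    ord <- order(meas_age[i, ])
    bmi_frame(meas_age[i, ord], meas_bmi[i, ord])
  })

  cohort <- tibble::tibble(
    id = ids,
    family_id = family_id,
    covs,
    enrollment_age = enrollment_age,
    event_age = event_age,
    death = death,
    bmi_measures = bmi_measures,
    true_mean_bmi = mean_bmi
  )
  list(
    genotypes = geno_matrix(G, variants, ids = ids),
    cohort = cohort
  )
}

#' Write a simulated cohort to disk
#'
#' Writes the genotypes as a PLINK bed/bim/fam triplet and the phenotypes
#' as a TSV (see [write_phenotypes()] for the `bmi_measures` encoding).
#' The files round-trip losslessly through [read_plink()] /
#' [read_phenotypes()].
#'
#' @param genotypes a [geno_matrix()].
#' @param cohort the phenotype tibble from [simulate_cohort()].
#' @param prefix output path prefix; writes `<prefix>.bed/.bim/.fam` and
#'   `<prefix>.pheno.tsv`.
#' @export
write_cohort <- function(genotypes, cohort, prefix) {
  if (!identical(genotypes$ids, cohort$id)) {
    abort("genotypes and cohort must cover the same individuals, in order")
  }
  write_plink(genotypes, prefix,
              family_ids = cohort$family_id,
              sex = cohort$sex)
  write_phenotypes(dplyr::select(cohort, -dplyr::any_of("true_mean_bmi")),
                   paste0(prefix, ".pheno.tsv"))
  # gene labels are not representable in bim; sidecar keeps them readable
  readr::write_tsv(genotypes$variants[, c("id", "gene")],
                   paste0(prefix, ".genes.tsv"))
  invisible(prefix)
}
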