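#' Identify confounders among candidate covariates
#'
#' Fits one logistic regression of the outcome on the exposure plus all
#' candidate covariates and returns the covariates with a significant
#' coefficient. A categorical covariate counts as significant if any of its
#' level coefficients is. Only covariates that act on the outcome this way
#' are carried into the instrument assumption tests as confounders.
#'
#' @param cohort derived cohort (see [derive_variables()]); only retained
#'   individuals are used.
#' @param covariates covariate column names to screen; `sex`, `race`,
#'   `education`, `smoking`, `comorbidity` and `field_center` are treated
#'   as categorical, anything else as continuous.
#' @param alpha significance level (default 0.05).
#' @return tibble with one row per identified confounder: `covariate`,
#'   `estimate` (coefficient of the most significant level), `p`. The full
#'   screen (all covariates) is attached as attribute `screen`.
#' @export
identify_confounders <- function(cohort, covariates, alpha = 0.05) {
  assert_number(alpha, "alpha", lo = 0, hi = 1)
  dat <- retained(cohort)
  if (length(covariates) == 0L) {
    return(tibble::tibble(covariate = character(), estimate = numeric(),
                          p = numeric()))
  }
  missing_cols <- setdiff(covariates, names(dat))
  if (length(missing_cols)) {
    abort(paste0("covariates not in cohort: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dat2 <- dat[, c("outcome", "exposure", covariates)]
  for (cv in intersect(covariates, .categorical_covariates)) {
    dat2[[cv]] <- factor(dat2[[cv]])
  }
  # drop constant covariates (single level) up front
  const <- covariates[vapply(dat2[covariates],
                             function(x) length(unique(na.omit(x))) < 2L,
                             logical(1))]
  use <- setdiff(covariates, const)
  screen <- tibble::tibble(covariate = character(), estimate = numeric(),
                           p = numeric(), note = character())
  if (length(use)) {
    f <- as.formula(paste("outcome ~ exposure +",
                          paste(use, collapse = " + ")))
    fit <- suppressWarnings(glm(f, family = binomial(), data = dat2))
    sm <- summary(fit)$coefficients
    terms_of <- function(cv) {
      rn <- rownames(sm)
      if (is.factor(dat2[[cv]])) rn[startsWith(rn, cv)] else intersect(rn, cv)
    }
    screen <- purrr::map_dfr(use, function(cv) {
      tm <- terms_of(cv)
      if (!length(tm)) {
        return(tibble::tibble(covariate = cv, estimate = NA_real_,
                              p = NA_real_, note = "dropped (aliased)"))
      }
      j <- tm[which.min(sm[tm, 4L])]
      tibble::tibble(covariate = cv, estimate = sm[j, 1L], p = sm[j, 4L],
                     note = if (fit$converged) "" else "non-convergence")
    })
  }
  if (length(const)) {
    screen <- dplyr::bind_rows(
      screen,
      tibble::tibble(covariate = const, estimate = NA_real_, p = NA_real_,
                     note = "constant")
    )
  }
  out <- screen |>
    dplyr::filter(!is.na(.data$p), .data$p < alpha) |>
    dplyr::select("covariate", "estimate", "p")
  attr(out, "screen") <- screen
  out
}

.categorical_covariates <- c("sex", "race", "education", "smoking",
                             "comorbidity", "field_center")

#' Test the three instrumental-variable assumptions for one variant
#'
#' Relevance: the dosage must be significantly associated with the exposure
#' under both codings — logistic on the binary overweight indicator and
#' linear on continuous mean BMI. Independence: the dosage must not be
#' associated with any identified confounder (linear test for continuous
#' covariates, logistic for binary, chi-square for multi-level
#' categorical). Exclusion: the dosage must not be associated with the
#' outcome given the exposure and confounders, again under both exposure
#' codings. Instrument strength: the F statistic from the max-rescaled
#' R-squared (or the residual-based R-squared for related samples) must
#' exceed `f_min`.
#'
#' @param dosage per-individual dosage vector aligned with `cohort`.
#' @param cohort derived cohort.
#' @param confounders tibble from [identify_confounders()] (or a character
#'   vector of covariate names).
#' @param alpha significance level for all assumption tests.
#' @param f_min instrument-strength threshold (F > f_min required).
#' @param family_ids optional family ids (aligned with `cohort` rows);
#'   switches instrument strength to the residual-based related-samples
#'   R-squared.
#' @param id variant id used in the result row.
#' @return one-row tibble: association estimates and p-values for each
#'   assumption, `r2`, `f_value`, `passed`, and a comma-separated
#'   `reasons` string for failures.
#' @export
test_assumptions <- function(dosage, cohort, confounders, alpha = 0.05,
                             f_min = 10, family_ids = NULL, id = "variant") {
  assert_number(alpha, "alpha", lo = 0, hi = 1)
  dat <- retained(cohort)
  if (!is.null(family_ids)) {
    stopifnot(length(family_ids) == nrow(cohort))
    fam_dat <- family_ids[!cohort$excluded]
  } else fam_dat <- NULL
  d <- dosage[match(dat$id, cohort$id)]
  ok <- !is.na(d)
  dat <- dat[ok, , drop = FALSE]
  d <- d[ok]
  if (!is.null(fam_dat)) fam_dat <- fam_dat[ok]
  conf_names <- if (is.data.frame(confounders)) confounders$covariate
                else as.character(confounders)

  row <- tibble::tibble(
    id = id, n_used = length(d),
    beta1 = NA_real_, se1 = NA_real_, p1 = NA_real_,
    beta1_cont = NA_real_, p1_cont = NA_real_,
    p_confounder_min = NA_real_,
    beta31 = NA_real_, p31 = NA_real_, p31_cont = NA_real_,
    r2 = NA_real_, f_value = NA_real_,
    passed = FALSE, reasons = ""
  )
  if (length(unique(d)) < 2L) {
    row$reasons <- "monomorphic"
    return(row)
  }

  reasons <- character()

  rel_bin <- fast_logit(d, dat$exposure)
  rel_cont <- fast_lm(d, dat$mean_bmi_75_85)
  row$beta1 <- rel_bin[["beta"]]; row$se1 <- rel_bin[["se"]]
  row$p1 <- rel_bin[["p"]]
  row$beta1_cont <- rel_cont[["beta"]]; row$p1_cont <- rel_cont[["p"]]
  if (!isTRUE(rel_bin[["p"]] < alpha) || !isTRUE(rel_cont[["p"]] < alpha)) {
    reasons <- c(reasons, "relevance")
  }

  if (length(conf_names)) {
    p_conf <- vapply(conf_names, function(cv) {
      v <- dat[[cv]]
      nlev <- length(unique(na.omit(v)))
      if (cv %in% .categorical_covariates && nlev > 2L) {
        suppressWarnings(chisq.test(table(v, d))$p.value)
      } else if (cv %in% .categorical_covariates && nlev == 2L) {
        y01 <- as.integer(factor(v)) - 1L
        fast_logit(d, y01)[["p"]]
      } else {
        fast_lm(d, as.numeric(v))[["p"]]
      }
    }, numeric(1))
    row$p_confounder_min <- suppressWarnings(min(p_conf, na.rm = TRUE))
    if (isTRUE(any(p_conf < alpha))) reasons <- c(reasons, "confounder")
  }

  excl <- exclusion_test(d, dat, conf_names)
  row$beta31 <- excl["beta_bin"]
  row$p31 <- excl["p_bin"]
  row$p31_cont <- excl["p_cont"]
  if (isTRUE(excl["p_bin"] < alpha) || isTRUE(excl["p_cont"] < alpha)) {
    reasons <- c(reasons, "exclusion")
  }

  r2 <- if (!is.null(fam_dat) && length(unique(fam_dat)) < length(fam_dat)) {
    covs <- dat[, intersect(conf_names, names(dat)), drop = FALSE]
    r2_for_related(d, dat$exposure, covariates = covs, family_ids = fam_dat)
  } else {
    r2_for_unrelated(d, dat$exposure)
  }
  row$r2 <- r2
  row$f_value <- f_statistic(r2, n = length(d), k = 1L)
  if (!isTRUE(row$f_value > f_min)) reasons <- c(reasons, "weak_instrument")

  row$passed <- length(reasons) == 0L
  row$reasons <- paste(reasons, collapse = ",")
  row
}

# Exclusion-assumption fits: outcome ~ dosage + exposure + confounders,
# with exposure entered binary and, separately, as continuous mean BMI.
exclusion_test <- function(d, dat, conf_names) {
  conf_names <- intersect(conf_names, names(dat))
  df <- data.frame(outcome = dat$outcome, d = d,
                   exposure = dat$exposure,
                   mean_bmi = dat$mean_bmi_75_85)
  for (cv in conf_names) {
    v <- dat[[cv]]
    df[[cv]] <- if (cv %in% .categorical_covariates) factor(v) else v
  }
  rhs <- if (length(conf_names)) paste("+", paste(conf_names, collapse = " + "))
         else ""
  fit_b <- suppressWarnings(
    glm(as.formula(paste("outcome ~ d + exposure", rhs)),
        family = binomial(), data = df)
  )
  fit_c <- suppressWarnings(
    glm(as.formula(paste("outcome ~ d + mean_bmi", rhs)),
        family = binomial(), data = df)
  )
  get_d <- function(fit) {
    sm <- summary(fit)$coefficients
    if (!"d" %in% rownames(sm)) return(c(NA_real_, NA_real_))
    c(sm["d", 1L], sm["d", 4L])
  }
  b <- get_d(fit_b); cc <- get_d(fit_c)
  c(beta_bin = b[1L], p_bin = b[2L], p_cont = cc[2L])
}

#' Instrument-strength F statistic
#'
#' `F = ((n - k - 1) / k) * (r2 / (1 - r2))`, with `k = 1` when instruments
#' are assessed one at a time. F > 10 is the conventional weak-instrument
#' threshold.
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @param n sample size (`n > k + 1`).
#' @param k number of instruments in the model.
#' @return the F value.
#' @examples
#' f_statistic(0.01, 1001, 1)  # ~ 10.09
#' @export
f_statistic <- function(r2, n, k = 1L) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    abort("`r2` must lie in [0, 1)")
  }
  if (any(n <= k + 1)) abort("need n > k + 1")
  if (any(k < 1)) abort("need k >= 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Max-rescaled R-squared for a binary exposure (unrelated samples)
#'
#' Fits a logistic regression of the binary exposure on the dosage,
#' computes the Cox-Snell generalized R-squared
#' `1 - exp((dev - dev0) / n)` and divides it by its attainable upper
#' bound `1 - exp(-dev0 / n)` (the max-rescaled, or Nagelkerke,
#' correction), giving the R-squared fed to [f_statistic()].
#'
#' @param dosage dosage vector.
#' @param exposure binary exposure vector.
#' @return rescaled R-squared in `[0, 1]`.
#' @export
r2_for_unrelated <- function(dosage, exposure) {
  ok <- !is.na(dosage) & !is.na(exposure)
  d <- dosage[ok]; y <- exposure[ok]
  n <- length(y)
  if (n < 3L || length(unique(y)) < 2L) return(NA_real_)
  fit <- suppressWarnings(glm.fit(cbind(1, d), y, family = binomial()))
  dev0 <- fit$null.deviance
  dev1 <- fit$deviance
  r2_cs <- 1 - exp((dev1 - dev0) / n)
  upper <- 1 - exp(-dev0 / n)
  min(max(r2_cs / upper, 0), 1)
}

#' Residual-based R-squared for related samples
#'
#' For family data the exposure is first modelled with a logistic mixed
#' model (fixed covariates plus a family-level random intercept); the
#' response residuals then stand in for the exposure, and the R-squared is
#' the squared Pearson correlation between residuals and dosage —
#' identical whichever of the two is treated as the regression response.
#' If the mixed model fails to converge the fit falls back to a plain
#' fixed-effects logistic regression, with a warning.
#'
#' @param dosage dosage vector.
#' @param exposure binary exposure vector.
#' @param covariates data frame of covariates for the exposure model (may
#'   be empty).
#' @param family_ids family identifiers.
#' @return R-squared in `[0, 1]`.
#' @export
r2_for_related <- function(dosage, exposure, covariates = NULL,
                           family_ids = NULL) {
  if (is.null(family_ids)) abort("family_ids required")
  ok <- !is.na(dosage) & !is.na(exposure)
  df <- data.frame(exposure = exposure[ok], fam = factor(family_ids[ok]))
  cv_names <- character()
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    for (cv in names(covariates)) {
      v <- covariates[[cv]]
      df[[cv]] <- if (cv %in% .categorical_covariates) factor(v) else v
    }
    cv_names <- names(covariates)
  }
  rhs <- if (length(cv_names)) paste(cv_names, collapse = " + ") else "1"
  f <- as.formula(paste("exposure ~", rhs, "+ (1 | fam)"))
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::glmer(f, data = df, family = binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  res <- if (!is.null(fit)) {
    stats::residuals(fit, type = "response")
  } else {
    warn("mixed model did not converge; falling back to fixed-effects fit")
    f2 <- as.formula(paste("exposure ~", rhs))
    stats::residuals(glm(f2, data = df, family = binomial()),
                     type = "response")
  }
  r <- suppressWarnings(cor(res, dosage[ok]))
  if (is.na(r)) return(NA_real_)
  r^2
}

#' Greedy linkage-disequilibrium pruning
#'
#' While any pair of retained variants has squared Pearson dosage
#' correlation at or above `r2_max`, the pair with the largest r-squared is
#' processed (ties broken by variant id order) and its member with the
#' larger exposure-association p-value is removed (p ties broken by
#' removing the lexicographically later id). The default cutoff is 0.3.
#'
#' @param dosages individuals x variants dosage matrix with variant ids as
#'   column names.
#' @param p_values named exposure-association p-values (smaller = more
#'   strongly associated, so kept preferentially).
#' @param r2_max squared-correlation cutoff.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(dosages, p_values, r2_max = 0.3) {
  assert_number(r2_max, "r2_max", lo = 0, hi = 1)
  ids <- colnames(dosages)
  if (is.null(ids)) abort("dosage matrix needs variant ids as column names")
  if (length(ids) <= 1L) return(ids)
  if (is.null(names(p_values))) names(p_values) <- ids
  cm <- suppressWarnings(cor(dosages, use = "pairwise.complete.obs"))^2
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  alive <- setNames(rep(TRUE, length(ids)), ids)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx < r2_max || nrow(sub) < 2L) break
    hits <- which(sub == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    pair_ids <- cbind(rownames(sub)[hits[, 1L]], colnames(sub)[hits[, 2L]])
    ord <- order(pair_ids[, 1L], pair_ids[, 2L])
    a <- pair_ids[ord[1L], 1L]; b <- pair_ids[ord[1L], 2L]
    pa <- p_values[[a]]; pb <- p_values[[b]]
    drop_id <- if (is.na(pa) && is.na(pb)) max(a, b)
      else if (is.na(pa)) a
      else if (is.na(pb)) b
      else if (pa > pb) a
      else if (pb > pa) b
      else max(a, b)
    alive[drop_id] <- FALSE
  }
  ids[alive[ids]]
}

#' Screen candidate instruments into a qualified IV set
#'
#' Runs the full screening pipeline: (gwas mode only) an
#' exposure-association scan with covariates keeping candidates with
#' p below `alpha`; confounder identification; the three assumption tests
#' plus instrument strength per candidate; and finally greedy LD pruning of
#' the passers. Every candidate's fate is recorded in the returned audit
#' trail.
#'
#' @param g a [geno_matrix()] of candidate variants (single SNPs,
#'   composites, or both), aligned with `cohort` individuals.
#' @param cohort derived cohort.
#' @param mode `"candidate_gene"` (default) screens every supplied variant;
#'   `"gwas"` first keeps only variants whose covariate-adjusted exposure
#'   association has p < `alpha`.
#' @param covariates covariates screened for confounding (and adjusted for
#'   in the gwas-mode scan).
#' @param alpha significance level for all screening tests.
#' @param f_min instrument-strength threshold.
#' @param r2_max LD-pruning cutoff.
#' @param family_ids optional family ids aligned with `cohort`.
#' @param bonferroni apply a Bonferroni correction to the relevance alpha
#'   across candidates (off by default).
#' @return tibble audit trail with one row per candidate: the
#'   [test_assumptions()] columns plus `stage` (`"qualified"`,
#'   `"failed_relevance"`, `"failed_confounder"`, `"failed_exclusion"`,
#'   `"failed_F"`, `"failed_LD"`, `"failed_gwas_scan"` or
#'   `"monomorphic"`). Identified confounders are attached as attribute
#'   `confounders`.
#' @export
select_ivs <- function(g, cohort, mode = c("candidate_gene", "gwas"),
                       covariates = c("sex", "race", "education", "smoking",
                                      "comorbidity", "field_center",
                                      "pc1", "pc2"),
                       alpha = 0.05, f_min = 10, r2_max = 0.3,
                       family_ids = NULL, bonferroni = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "geno_matrix"))
  dat <- retained(cohort)
  idx <- match(dat$id, g$ids)
  if (anyNA(idx)) abort("cohort contains individuals absent from genotypes")
  m <- nrow(g$variants)
  if (m == 0L) {
    warn("no candidate variants supplied")
    out <- tibble::tibble(id = character(), stage = character())
    attr(out, "confounders") <-
      identify_confounders(cohort, covariates, alpha)
    return(out)
  }

  conf <- identify_confounders(cohort, intersect(covariates, names(cohort)),
                               alpha)

  gwas_keep <- rep(TRUE, m)
  gwas_p <- rep(NA_real_, m)
  if (mode == "gwas") {
    covs_use <- intersect(covariates, names(dat))
    df <- dat[, c("exposure", covs_use)]
    for (cv in intersect(covs_use, .categorical_covariates)) {
      df[[cv]] <- factor(df[[cv]])
    }
    for (j in seq_len(m)) {
      df$d <- g$dosages[idx, j]
      if (length(unique(na.omit(df$d))) < 2L) { gwas_keep[j] <- FALSE; next }
      rhs <- if (length(covs_use)) paste("+", paste(covs_use, collapse = " + "))
             else ""
      fit <- suppressWarnings(
        glm(as.formula(paste("exposure ~ d", rhs)),
            family = binomial(), data = df)
      )
      sm <- summary(fit)$coefficients
      gwas_p[j] <- if ("d" %in% rownames(sm)) sm["d", 4L] else NA_real_
      gwas_keep[j] <- isTRUE(gwas_p[j] < alpha)
    }
  }

  alpha_rel <- if (bonferroni) alpha / m else alpha
  audit <- purrr::map_dfr(seq_len(m), function(j) {
    if (!gwas_keep[j]) {
      return(tibble::tibble(id = g$variants$id[j], n_used = NA_integer_,
                            beta1 = NA_real_, se1 = NA_real_, p1 = gwas_p[j],
                            beta1_cont = NA_real_, p1_cont = NA_real_,
                            p_confounder_min = NA_real_, beta31 = NA_real_,
                            p31 = NA_real_, p31_cont = NA_real_,
                            r2 = NA_real_, f_value = NA_real_,
                            passed = FALSE, reasons = "gwas_scan"))
    }
    test_assumptions(g$dosages[, j][match(cohort$id, g$ids)], cohort, conf,
                     alpha = alpha_rel, f_min = f_min,
                     family_ids = family_ids, id = g$variants$id[j])
  })

  stage_of <- function(reasons, passed) {
    dplyr::case_when(
      passed ~ "qualified",
      reasons == "gwas_scan" ~ "failed_gwas_scan",
      grepl("monomorphic", reasons) ~ "monomorphic",
      grepl("relevance", reasons) ~ "failed_relevance",
      grepl("confounder", reasons) ~ "failed_confounder",
      grepl("exclusion", reasons) ~ "failed_exclusion",
      grepl("weak_instrument", reasons) ~ "failed_F",
      TRUE ~ "failed_other"
    )
  }
  audit$stage <- stage_of(audit$reasons, audit$passed)

  qual <- audit$id[audit$stage == "qualified"]
  if (length(qual) >= 2L) {
    dmat <- g$dosages[idx, match(qual, g$variants$id), drop = FALSE]
    colnames(dmat) <- qual
    keep <- ld_prune(dmat, setNames(audit$p1[match(qual, audit$id)], qual),
                     r2_max = r2_max)
    pruned <- setdiff(qual, keep)
    audit$stage[audit$id %in% pruned] <- "failed_LD"
    audit$passed[audit$id %in% pruned] <- FALSE
    audit$reasons[audit$id %in% pruned] <- "ld_prune"
  }
  if (!any(audit$stage == "qualified")) {
    warn("no qualified instruments after screening")
  }
  attr(audit, "confounders") <- conf
  audit
}
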