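#' Per-instrument association statistics
#'
#' For each qualified instrument, fits the two covariate-free univariate
#' logistic regressions used by the summary-statistic estimators:
#' exposure ~ dosage (giving `beta_x`, `se_x`) and outcome ~ dosage
#' (giving `beta_y`, `se_y`), with Wald standard errors. Individuals with
#' a missing dosage for a given instrument are dropped pairwise for that
#' instrument only. Instruments with a separated or non-converged fit are
#' flagged and excluded by the estimators.
#'
#' @param g a [geno_matrix()] of qualified instruments (or a plain dosage
#'   matrix with variant ids as column names, aligned with the retained
#'   cohort).
#' @param cohort derived cohort; only retained individuals are used.
#' @return tibble with one row per instrument: `id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `n_used`, `ok` (FALSE where a fit failed).
#' @export
association_stats <- function(g, cohort) {
  dat <- retained(cohort)
  if (inherits(g, "geno_matrix")) {
    idx <- match(dat$id, g$ids)
    if (anyNA(idx)) abort("cohort contains individuals absent from genotypes")
    dmat <- g$dosages[idx, , drop = FALSE]
    ids <- g$variants$id
  } else {
    dmat <- as.matrix(g)
    if (nrow(dmat) == nrow(cohort)) {
      dmat <- dmat[!cohort$excluded, , drop = FALSE]
    }
    if (nrow(dmat) != nrow(dat)) {
      abort("dosage matrix rows must match the cohort (raw or retained)")
    }
    ids <- colnames(dmat) %||% sprintf("iv%03d", seq_len(ncol(dmat)))
  }
  purrr::map_dfr(seq_along(ids), function(j) {
    d <- dmat[, j]
    fx <- fast_logit(d, dat$exposure)
    fy <- fast_logit(d, dat$outcome)
    ok <- all(is.finite(c(fx[["beta"]], fx[["se"]],
                          fy[["beta"]], fy[["se"]])))
    if (!ok) {
      warn(sprintf("instrument %s: unstable fit (dropped from estimators)",
                   ids[j]))
    }
    tibble::tibble(
      id = ids[j],
      beta_x = fx[["beta"]], se_x = fx[["se"]],
      beta_y = fy[["beta"]], se_y = fy[["se"]],
      n_used = as.integer(min(fx[["n"]], fy[["n"]])),
      ok = ok
    )
  })
}

# Ratio estimates and weights shared by the estimators.
# First-order (delta-method) se: se(theta_j) = se_y / |beta_x|;
# second-order adds the beta_y^2 * se_x^2 / beta_x^4 term.
ratio_stats <- function(stats, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  st <- if ("ok" %in% names(stats)) dplyr::filter(stats, .data$ok) else stats
  zero <- !is.na(st$beta_x) & st$beta_x == 0
  if (any(zero)) {
    warn(sprintf("%d instrument(s) with beta_x = 0 excluded", sum(zero)))
    st <- st[!zero, , drop = FALSE]
  }
  theta <- st$beta_y / st$beta_x
  se <- if (se_order == "first") {
    st$se_y / abs(st$beta_x)
  } else {
    sqrt(st$se_y^2 / st$beta_x^2 +
           st$beta_y^2 * st$se_x^2 / st$beta_x^4)
  }
  dplyr::mutate(st, theta = theta, se_theta = se, w = 1 / se^2)
}

mr_row <- function(method, estimate, se, n_iv, extra = list()) {
  z <- estimate / se
  out <- tibble::tibble(
    method = method,
    estimate = estimate,
    se = se,
    ci_lo = estimate - qnorm(0.975) * se,
    ci_hi = estimate + qnorm(0.975) * se,
    p = 2 * pnorm(-abs(z)),
    n_iv = as.integer(n_iv)
  )
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Inverse-variance weighted estimator
#'
#' The causal log-odds estimate is the inverse-variance weighted average of
#' the per-instrument ratio estimates `theta_j = beta_y_j / beta_x_j`, with
#' first-order standard errors `se_y_j / |beta_x_j|`; algebraically
#' identical to weighted least squares of `beta_y` on `beta_x` through the
#' origin with weights `1 / se_y^2`.
#'
#' @param stats tibble from [association_stats()].
#' @param se_order `"first"` (default) or `"second"`-order ratio standard
#'   errors.
#' @return one-row tibble: `method`, `estimate`, `se`, `ci_lo`, `ci_hi`,
#'   `p` (normal-theory, two-sided), `n_iv`.
#' @export
ivw <- function(stats, se_order = "first") {
  rs <- ratio_stats(stats, se_order)
  if (nrow(rs) < 1L) abort("ivw needs at least 1 usable instrument")
  wsum <- sum(rs$w)
  # single instrument: the weight cancels algebraically, so return the
  # plain Wald ratio rather than its floating-point reweighting
  est <- if (nrow(rs) == 1L) rs$theta else sum(rs$w * rs$theta) / wsum
  mr_row("ivw", est, 1 / sqrt(wsum), nrow(rs))
}

#' Penalized inverse-variance weighted estimator
#'
#' Down-weights instruments contributing excess heterogeneity: with
#' `Q_j = w_j (theta_j - theta_IVW)^2` and `q_j` its upper-tail chi-square
#' (1 df) probability, the penalized weight is
#' `w_j * min(1, penalty_factor * q_j)`; the IVW average is then recomputed
#' with the penalized weights. Used when standard IVW is inconclusive under
#' relatively weak instruments.
#'
#' @param stats tibble from [association_stats()].
#' @param penalty_factor multiplier on `q_j` (default 20).
#' @param se_order ratio standard-error order.
#' @return one-row tibble as [ivw()], with `method = "penalized_ivw"`.
#' @export
penalized_ivw <- function(stats, penalty_factor = 20, se_order = "first") {
  assert_number(penalty_factor, "penalty_factor", lo = 0)
  rs <- ratio_stats(stats, se_order)
  if (nrow(rs) < 3L) abort("penalized_ivw needs at least 3 instruments")
  est0 <- sum(rs$w * rs$theta) / sum(rs$w)
  Q <- rs$w * (rs$theta - est0)^2
  q <- pchisq(Q, df = 1L, lower.tail = FALSE)
  w2 <- rs$w * pmin(1, penalty_factor * q)
  if (sum(w2) <= 0 || !is.finite(sum(w2))) {
    abort("all weights penalized to zero; estimates are mutually inconsistent")
  }
  mr_row("penalized_ivw", sum(w2 * rs$theta) / sum(w2), 1 / sqrt(sum(w2)),
         nrow(rs))
}

# Interpolated weighted median of ordered ratio estimates.
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1L]) return(theta[1L])
  if (0.5 > s[length(s)]) return(theta[length(theta)])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1L] - theta[k]) * (0.5 - s[k]) / (s[k + 1L] - s[k])
}

#' Weighted-median estimator
#'
#' Orders the per-instrument ratio estimates and takes the value at 50% of
#' cumulative inverse-variance weight (with linear interpolation between
#' adjacent estimates); consistent when at least half the total weight
#' comes from valid instruments. The standard error is a seeded parametric
#' bootstrap: `beta_x` and `beta_y` are resampled from normal distributions
#' with their estimated standard errors and the median recomputed.
#'
#' @param stats tibble from [association_stats()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param se_order ratio standard-error order.
#' @return one-row tibble as [ivw()], with `method = "weighted_median"`.
#' @export
weighted_median <- function(stats, n_boot = 1000, seed = 1L,
                            se_order = "first") {
  assert_number(n_boot, "n_boot", lo = 10)
  rs <- ratio_stats(stats, se_order)
  if (nrow(rs) < 3L) abort("weighted_median needs at least 3 instruments")
  if (any(!is.finite(rs$w)) || all(rs$w == 0)) {
    abort("degenerate weights")
  }
  est <- weighted_median_point(rs$theta, rs$w)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(rs), rs$beta_x, rs$se_x)
      by <- rnorm(nrow(rs), rs$beta_y, rs$se_y)
      th <- by / bx
      se <- rs$se_y / abs(bx)
      weighted_median_point(th, 1 / se^2)
    }, numeric(1))
  })
  mr_row("weighted_median", est, sd(boot), nrow(rs))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an unconstrained intercept, each instrument oriented
#' so `beta_x >= 0` and weighted by `1 / se_y^2`. The slope is the causal
#' estimate; an intercept distinct from the origin indicates directional
#' pleiotropy, so an intercept confidence interval containing 0 supports
#' the exclusion assumption.
#'
#' @param stats tibble from [association_stats()].
#' @return two-row tibble (`method` = `"egger"` and `"egger_intercept"`)
#'   with estimates, normal-theory CIs and p-values.
#' @export
mr_egger <- function(stats) {
  st <- if ("ok" %in% names(stats)) dplyr::filter(stats, .data$ok) else stats
  if (nrow(st) < 3L) abort("mr_egger needs at least 3 instruments")
  flip <- st$beta_x < 0
  bx <- ifelse(flip, -st$beta_x, st$beta_x)
  by <- ifelse(flip, -st$beta_y, st$beta_y)
  if (sd(bx) < 1e-12) {
    warn("near-zero spread in beta_x; MR-Egger fit is unstable")
  }
  fit <- lm(by ~ bx, weights = 1 / st$se_y^2)
  sm <- summary(fit)$coefficients
  dplyr::bind_rows(
    mr_row("egger", sm["bx", 1L], sm["bx", 2L], nrow(st)),
    mr_row("egger_intercept", sm["(Intercept)", 1L], sm["(Intercept)", 2L],
           nrow(st))
  )
}

#' E-value for an observed risk ratio
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to
#' fully explain away the observed association:
#' `E = RR + sqrt(RR * (RR - 1))`. Risk ratios below 1 are first inverted.
#'
#' @param rr risk ratio(s), > 0.
#' @return E-value(s), always >= 1.
#' @examples
#' evalue(4)  # 4 + sqrt(12)
#' @export
evalue <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) abort("`rr` must be positive")
  rr <- ifelse(rr < 1, 1 / rr, rr)
  rr + sqrt(rr * (rr - 1))
}

#' E-value summary over instruments
#'
#' Converts each instrument's ratio estimate to an odds ratio
#' `exp(theta_j)`, maps it to a risk ratio (default `sqrt(OR)`, the
#' square-root approximation appropriate for a common outcome such as
#' survival past 85; `"rare_outcome"` uses the OR directly), applies
#' [evalue()], and summarizes over instruments.
#'
#' @param stats tibble from [association_stats()].
#' @param conversion `"common_outcome_sqrt"` (default) or `"rare_outcome"`.
#' @param se_order ratio standard-error order.
#' @return one-row tibble: `average`, `min`, `max`, `n_iv`.
#' @export
evalue_summary <- function(stats,
                           conversion = c("common_outcome_sqrt",
                                          "rare_outcome"),
                           se_order = "first") {
  conversion <- match.arg(conversion)
  rs <- ratio_stats(stats, se_order)
  if (nrow(rs) < 1L) abort("evalue_summary needs at least 1 instrument")
  or <- exp(rs$theta)
  rr <- if (conversion == "common_outcome_sqrt") sqrt(or) else or
  ev <- evalue(rr)
  tibble::tibble(average = mean(ev), min = min(ev), max = max(ev),
                 n_iv = nrow(rs))
}

run_mr_one <- function(stats, n_boot, seed, penalty_factor,
                       evalue_conversion, se_order) {
  usable <- if ("ok" %in% names(stats)) sum(stats$ok) else nrow(stats)
  if (usable < 1L) abort("no usable instruments; refusing to run")
  res <- ivw(stats, se_order)
  if (usable >= 3L) {
    if (res$p[res$method == "ivw"] >= 0.05) {
      res <- dplyr::bind_rows(
        res, penalized_ivw(stats, penalty_factor, se_order))
    }
    res <- dplyr::bind_rows(
      res,
      weighted_median(stats, n_boot = n_boot, seed = seed,
                      se_order = se_order),
      mr_egger(stats)
    )
  } else {
    warn("fewer than 3 instruments: weighted median and MR-Egger skipped")
  }
  ev <- evalue_summary(stats, evalue_conversion, se_order)
  list(results = res, evalues = ev)
}

#' Run the full MR estimator suite
#'
#' Computes per-instrument association statistics, then the estimator
#' suite: IVW always; penalized IVW when standard IVW has p >= 0.05;
#' weighted median and MR-Egger when at least 3 instruments are usable;
#' and the E-value summary. The significance verdict follows the rule
#' "statistically significant IVW and MR-Egger intercept non-distinct from
#' the origin" (IVW p < 0.05 and intercept CI containing 0). Optionally
#' stratifies the cohort (e.g. by sex and race) and reports each stratum
#' alongside the combined sample.
#'
#' @param g qualified instruments: a [geno_matrix()] or dosage matrix (see
#'   [association_stats()]).
#' @param cohort derived cohort.
#' @param strata optional character vector of cohort columns to stratify
#'   by; the unstratified analysis is always reported as stratum `"all"`.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param penalty_factor penalized-IVW penalty multiplier.
#' @param evalue_conversion odds-ratio to risk-ratio conversion for
#'   E-values.
#' @param se_order ratio standard-error order (`"first"` or `"second"`).
#' @return An object of class `mr_result`: list with `results` (tibble of
#'   per-stratum, per-method estimates), `stats` (per-IV statistics),
#'   `evalues`, `verdict` (per-stratum significance call) and `options`.
#'   Methods: [tidy()], [glance()], `print()`, [autoplot()].
#' @export
run_mr <- function(g, cohort, strata = NULL, n_boot = 1000, seed = 1L,
                   penalty_factor = 20,
                   evalue_conversion = c("common_outcome_sqrt",
                                         "rare_outcome"),
                   se_order = c("first", "second")) {
  evalue_conversion <- match.arg(evalue_conversion)
  se_order <- match.arg(se_order)
  n_iv_in <- if (inherits(g, "geno_matrix")) nrow(g$variants) else ncol(g)
  if (is.null(n_iv_in) || n_iv_in < 1L) {
    abort("no qualified instruments supplied; refusing to run")
  }
  if (!inherits(g, "geno_matrix")) {
    # wrap plain dosage matrices so strata can subset by individual id
    dmat <- as.matrix(g)
    row_ids <- if (nrow(dmat) == nrow(cohort)) cohort$id
               else retained(cohort)$id
    if (nrow(dmat) != length(row_ids)) {
      abort("dosage matrix rows must match the cohort (raw or retained)")
    }
    ids_v <- colnames(dmat) %||% sprintf("iv%03d", seq_len(ncol(dmat)))
    g <- geno_matrix(dmat, tibble::tibble(
      id = ids_v, gene = NA_character_, chrom = "0",
      pos = seq_len(ncol(dmat)), a1 = "A", a2 = "G"
    ), ids = row_ids)
  }
  groups <- list(all = cohort)
  if (!is.null(strata)) {
    missing_cols <- setdiff(strata, names(cohort))
    if (length(missing_cols)) {
      abort(paste0("strata columns not in cohort: ",
                   paste(missing_cols, collapse = ", ")))
    }
    dat <- retained(cohort)
    labs <- do.call(paste, c(dat[strata], sep = "/"))
    for (lv in sort(unique(labs))) {
      groups[[lv]] <- cohort[cohort$id %in% dat$id[labs == lv], ,
                             drop = FALSE]
    }
  }
  all_res <- list(); all_stats <- list(); all_ev <- list(); verd <- list()
  for (nm in names(groups)) {
    co <- groups[[nm]]
    st <- association_stats(g, co)
    one <- run_mr_one(st, n_boot, seed, penalty_factor, evalue_conversion,
                      se_order)
    n_ind <- nrow(retained(co))
    all_res[[nm]] <- dplyr::mutate(one$results, stratum = nm,
                                   n_individuals = n_ind,
                                   .before = 1L)
    all_stats[[nm]] <- dplyr::mutate(st, stratum = nm, .before = 1L)
    all_ev[[nm]] <- dplyr::mutate(one$evalues, stratum = nm, .before = 1L)
    r <- one$results
    ivw_p <- r$p[r$method == "ivw"]
    icpt <- r[r$method == "egger_intercept", , drop = FALSE]
    egger_ok <- if (nrow(icpt)) icpt$ci_lo <= 0 && icpt$ci_hi >= 0 else NA
    verd[[nm]] <- tibble::tibble(
      stratum = nm, n_individuals = n_ind,
      n_iv = r$n_iv[r$method == "ivw"],
      ivw_p = ivw_p,
      egger_intercept_covers_zero = egger_ok,
      significant = isTRUE(ivw_p < 0.05) && isTRUE(egger_ok)
    )
  }
  structure(
    list(
      results = dplyr::bind_rows(all_res),
      stats = dplyr::bind_rows(all_stats),
      evalues = dplyr::bind_rows(all_ev),
      verdict = dplyr::bind_rows(verd),
      options = list(n_boot = n_boot, seed = seed,
                     penalty_factor = penalty_factor,
                     evalue_conversion = evalue_conversion,
                     se_order = se_order, strata = strata)
    ),
    class = "mr_result"
  )
}

#' @method print mr_result
#' @export
print.mr_result <- function(x, ...) {
  cat("<mr_result>\n")
  print(x$verdict)
  cat("\nEstimates:\n")
  print(x$results)
  invisible(x)
}

#' @rdname run_mr
#' @param x,object an `mr_result`.
#' @param ... unused.
#' @export
tidy.mr_result <- function(x, ...) x$results

#' @rdname run_mr
#' @export
glance.mr_result <- function(x, ...) {
  dplyr::left_join(
    x$verdict,
    dplyr::select(x$evalues, "stratum", evalue_average = "average",
                  evalue_min = "min", evalue_max = "max"),
    by = "stratum"
  )
}

#' Forest-style plot of MR estimates
#'
#' @param object an `mr_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mr_result <- function(object, ...) {
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(x = .data$estimate, y = .data$method)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi)
    ) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(
      x = "causal log-odds estimate (95% CI)", y = NULL,
      title = "Mendelian randomization estimates"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of instrument associations
#'
#' Plots per-instrument outcome associations against exposure associations
#' (oriented so `beta_x >= 0`) with the IVW line through the origin and,
#' when estimable, the MR-Egger line.
#'
#' @param x an `mr_result`.
#' @param stratum stratum to plot (default `"all"`).
#' @return a ggplot.
#' @export
plot_mr_scatter <- function(x, stratum = "all") {
  st <- dplyr::filter(x$stats, .data$stratum == !!stratum, .data$ok)
  flip <- st$beta_x < 0
  st$beta_x[flip] <- -st$beta_x[flip]
  st$beta_y[flip] <- -st$beta_y[flip]
  res <- dplyr::filter(x$results, .data$stratum == !!stratum)
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = 0,
      slope = res$estimate[res$method == "ivw"],
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "instrument-exposure log-odds (beta_x)",
      y = "instrument-outcome log-odds (beta_y)",
      title = paste0("Instrument associations (", stratum, ")")
    ) +
    ggplot2::theme_minimal()
  if (any(res$method == "egger")) {
    p <- p + ggplot2::geom_abline(
      intercept = res$estimate[res$method == "egger_intercept"],
      slope = res$estimate[res$method == "egger"],
      colour = "firebrick", linetype = 2
    )
  }
  p
}
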