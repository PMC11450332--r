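#' Cohort characteristics table
#'
#' Summarizes the analysis sample per sex-by-race stratum and overall:
#' mean (sd) of enrollment age and of age at death or last follow-up, and
#' n (%) for education at high-school level or above, ever smoked,
#' comorbidity, overweight and survival past 85, plus per-variable missing
#' counts among retained individuals.
#'
#' @param cohort derived cohort (see [derive_variables()]).
#' @return tidy tibble with columns `stratum`, `variable`, `n`, `mean`,
#'   `sd`, `count`, `pct`, `n_missing`; strata with no individuals are
#'   emitted with `n = 0`.
#' @export
descriptive_table <- function(cohort) {
  dat <- retained(cohort)
  sex_lab <- c(`1` = "male", `2` = "female")
  race_lab <- c(`1` = "white", `2` = "black", `3` = "other")
  strat_of <- function(d) {
    paste(race_lab[as.character(d$race)], sex_lab[as.character(d$sex)])
  }
  levels_all <- c(as.vector(outer(race_lab, sex_lab, paste)), "total")
  dat$stratum <- strat_of(dat)

  summarize_block <- function(d, label) {
    cont <- function(var, x) tibble::tibble(
      stratum = label, variable = var, n = sum(!is.na(x)),
      mean = if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(x)) > 1L) sd(x, na.rm = TRUE) else NA_real_,
      count = NA_integer_, pct = NA_real_,
      n_missing = sum(is.na(x))
    )
    bin <- function(var, x) tibble::tibble(
      stratum = label, variable = var, n = sum(!is.na(x)),
      mean = NA_real_, sd = NA_real_,
      count = sum(x == 1L, na.rm = TRUE),
      pct = if (any(!is.na(x))) 100 * mean(x == 1L, na.rm = TRUE)
            else NA_real_,
      n_missing = sum(is.na(x))
    )
    dplyr::bind_rows(
      tibble::tibble(stratum = label, variable = "n_individuals",
                     n = nrow(d), mean = NA_real_, sd = NA_real_,
                     count = nrow(d), pct = NA_real_, n_missing = 0L),
      cont("enrollment_age", d$enrollment_age),
      cont("event_age", d$event_age),
      bin("education_hs_plus", as.integer(d$education >= 1L)),
      bin("ever_smoked", d$smoking),
      bin("comorbidity", d$comorbidity),
      bin("overweight", d$exposure),
      bin("survive_85", d$outcome)
    )
  }
  purrr::map_dfr(levels_all, function(lv) {
    d <- if (lv == "total") dat else dat[dat$stratum == lv, , drop = FALSE]
    summarize_block(d, lv)
  })
}

#' Left-truncated Kaplan-Meier survival curves by exposure group
#'
#' Product-limit estimates of survival past age 75 with delayed entry at
#' `max(enrollment age, 75)`: an individual joins the risk set only at
#' their entry age, so early deaths among late entrants cannot bias the
#' curve. Individuals whose event or censoring age does not exceed their
#' entry age are never at risk and are excluded (count reported).
#' Confidence bands are log-log (exponential Greenwood).
#'
#' @param cohort derived cohort; needs `enrollment_age`, `event_age`,
#'   `death` and the grouping column.
#' @param group_by cohort column defining the groups (default
#'   `"exposure"`).
#' @param conf_level confidence level for the bands.
#' @return tibble of class `km_curves`: `group`, `age`, `n_risk`,
#'   `n_event`, `survival`, `lower`, `upper`; the number of
#'   never-at-risk exclusions is attached as attribute `n_never_at_risk`.
#' @export
kaplan_meier <- function(cohort, group_by = "exposure",
                         conf_level = 0.95) {
  dat <- retained(cohort)
  if (!group_by %in% names(dat)) {
    abort(paste0("grouping column not in cohort: ", group_by))
  }
  entry <- pmax(dat$enrollment_age, 75)
  keep <- dat$event_age > entry
  n_never <- sum(!keep)
  d <- dat[keep, , drop = FALSE]
  entry <- entry[keep]
  grp <- d[[group_by]]
  if (group_by == "exposure") {
    grp <- ifelse(grp == 1L, "overweight", "normal weight")
  }
  # entry treated as just before any event at the same age, so an
  # individual entering exactly at an event age is in that risk set
  fit <- survival::survfit(
    survival::Surv(entry - 1e-9, d$event_age, d$death) ~ grp,
    conf.type = "log-log", conf.int = conf_level
  )
  strata_names <- if (is.null(fit$strata)) {
    rep(unique(grp), length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(
    group = strata_names,
    age = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv,
    lower = fit$lower,
    upper = fit$upper
  )
  attr(out, "n_never_at_risk") <- n_never
  class(out) <- c("km_curves", class(out))
  out
}

#' Plot Kaplan-Meier curves
#'
#' @param object a `km_curves` tibble from [kaplan_meier()].
#' @param ... unused.
#' @return a ggplot step plot with confidence bands.
#' @export
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$age, y = .data$survival,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "age (years)", y = "survival probability",
                  colour = NULL, fill = NULL,
                  title = "Survival past 75 by BMI group (left-truncated)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_curves
#' @param x a `km_curves` tibble.
#' @export
plot_km <- function(x, ...) autoplot.km_curves(x, ...)

#' Assemble a run report directory
#'
#' Writes the supplied stage outputs into `out_dir` as plain-text files
#' (config echo, seed, QC report, composite manifest, IV audit trail, MR
#' results as TSV and JSON, per-IV statistics, Kaplan-Meier curve data,
#' descriptive table, and a human-readable Markdown summary). A manifest
#' records which pieces are present; runs missing any core piece are
#' flagged incomplete. Re-running with the same config and seed reproduces
#' identical numeric content.
#'
#' @param out_dir output directory (created if needed).
#' @param config run configuration (list; echoed as YAML).
#' @param seed master seed.
#' @param qc_report,composite_manifest,iv_audit,mr,km,descriptives stage
#'   outputs; `mr` is an `mr_result`, the rest tibbles. `NULL` pieces are
#'   skipped and flagged.
#' @return tibble manifest (file, present); attribute `complete` is TRUE
#'   when all core pieces were written.
#' @export
build_report <- function(out_dir, config, seed, qc_report = NULL,
                         composite_manifest = NULL, iv_audit = NULL,
                         mr = NULL, km = NULL, descriptives = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  yaml::write_yaml(config, p("config.yaml"))
  writeLines(as.character(seed), p("seed.txt"))
  pieces <- list(
    qc_report = list(qc_report, "qc_report.tsv"),
    composite_manifest = list(composite_manifest, "composite_manifest.tsv"),
    iv_audit = list(iv_audit, "iv_audit.tsv"),
    km = list(km, "km_curves.tsv"),
    descriptives = list(descriptives, "descriptive_table.tsv")
  )
  present <- c(config = TRUE, seed = TRUE)
  for (nm in names(pieces)) {
    obj <- pieces[[nm]][[1L]]
    if (!is.null(obj)) {
      readr::write_tsv(tibble::as_tibble(obj), p(pieces[[nm]][[2L]]))
      present[nm] <- TRUE
    } else present[nm] <- FALSE
  }
  if (!is.null(mr)) {
    readr::write_tsv(mr$results, p("mr_results.tsv"))
    readr::write_tsv(mr$stats, p("mr_iv_stats.tsv"))
    jsonlite::write_json(
      list(results = mr$results, evalues = mr$evalues,
           verdict = mr$verdict),
      p("mr_results.json"), digits = NA, dataframe = "rows"
    )
    present["mr"] <- TRUE
  } else present["mr"] <- FALSE

  core <- c("qc_report", "iv_audit", "mr", "km", "descriptives")
  complete <- all(present[core])
  lines <- c(
    "# Composite-SNP MR run summary", "",
    paste0("- seed: ", seed),
    paste0("- complete: ", complete),
    paste0("- pieces: ", paste(names(present)[present], collapse = ", "))
  )
  if (!is.null(mr)) {
    v <- mr$verdict
    lines <- c(lines, "", "## Verdicts", "",
               sprintf("- %s: n=%d, IVs=%d, IVW p=%.3g, significant=%s",
                       v$stratum, v$n_individuals, v$n_iv, v$ivw_p,
                       v$significant))
  }
  writeLines(lines, p("summary.md"))
  manifest <- tibble::tibble(piece = names(present),
                             present = unname(present))
  readr::write_tsv(manifest, p("manifest.tsv"))
  if (!complete) warn("report incomplete: missing core stage outputs")
  attr(manifest, "complete") <- complete
  manifest
}
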