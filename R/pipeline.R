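#' Run configuration for the end-to-end pipeline
#'
#' Validates a run configuration supplied as a nested list or a YAML file.
#' Exactly one of `input` (paths to existing PLINK + phenotype files) or
#' `simulation` (arguments for [sim_config()]) must be present. Remaining
#' blocks hold stage options with the conventional defaults: QC thresholds,
#' composite pairing scope, screening alpha 0.05, F threshold 10, LD
#' r-squared cutoff 0.3, estimator options and optional strata.
#'
#' @param config list or path to a YAML file.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    abort("exactly one of `input` and `simulation` must be present")
  }
  defaults <- list(
    qc = list(snp_call_rate = 0.95, ind_call_rate = 0.95,
              maf_min = 0.01, hwe_p_min = 1e-6),
    composite = list(pairing_scope = "all_pairs"),
    iv = list(mode = "candidate_gene", alpha = 0.05, f_min = 10,
              r2_max = 0.3,
              candidates = "composite"),   # composite | single | both
    estimators = list(n_boot = 1000, penalty_factor = 20,
                      evalue_conversion = "common_outcome_sqrt",
                      se_order = "first"),
    strata = NULL,
    seed = 1L
  )
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      config[[nm]] <- modifyList(defaults[[nm]], config[[nm]] %||% list())
    } else if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  with(config$qc, {
    for (v in c(snp_call_rate, ind_call_rate, maf_min, hwe_p_min)) {
      if (v < 0 || v > 1) abort("QC thresholds must lie in [0, 1]")
    }
  })
  if (!config$iv$mode %in% c("candidate_gene", "gwas")) {
    abort("iv$mode must be 'candidate_gene' or 'gwas'")
  }
  if (!config$iv$candidates %in% c("composite", "single", "both")) {
    abort("iv$candidates must be 'composite', 'single' or 'both'")
  }
  assert_number(config$iv$alpha, "iv$alpha", 0, 1)
  assert_number(config$iv$r2_max, "iv$r2_max", 0, 1)
  structure(config, class = c("run_config", "list"))
}

log_stage <- function(log_path, ...) {
  msg <- sprintf(...)
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", msg)
  inform(line)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(msg)
}

#' Run the full composite-SNP MR pipeline
#'
#' Orchestrates the stages: simulate (or read) genotypes and phenotypes;
#' quality control; derivation of exposure/outcome variables; composite
#' SNP construction; instrument screening; MR estimation (optionally per
#' stratum); Kaplan-Meier and descriptive output; and the run report. One
#' master seed drives per-stage substreams so stages are independently
#' reproducible; every stage logs its input/output counts.
#'
#' @param config a [run_config()], a list, or a YAML path.
#' @param out_dir report directory (default `tempfile("cmr_run")`).
#' @return list with all stage outputs (`genotypes`, `cohort`,
#'   `composites`, `iv_audit`, `mr`, `km`, `descriptives`, `report_dir`,
#'   `manifest`), invisibly classed `cmr_run`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cmr_run")) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  seed <- as.integer(cfg$seed)

  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- sim_args$seed %||% stage_seed(seed, "simulate")
    sc <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(sc)
    g <- sim$genotypes
    pheno <- sim$cohort
    log_stage(log_path, "simulate: %d individuals, %d variants",
              length(g$ids), nrow(g$variants))
  } else {
    g <- read_plink(cfg$input$plink_prefix)
    pheno <- read_phenotypes(cfg$input$phenotype_file)
    log_stage(log_path, "read: %d individuals, %d variants",
              length(g$ids), nrow(g$variants))
  }

  fam_ids <- if (!is.null(pheno$family_id) &&
                 dplyr::n_distinct(pheno$family_id) < nrow(pheno)) {
    pheno$family_id
  } else NULL

  g_qc <- qc_filter(
    g,
    snp_call_rate = cfg$qc$snp_call_rate,
    ind_call_rate = cfg$qc$ind_call_rate,
    maf_min = cfg$qc$maf_min,
    hwe_p_min = cfg$qc$hwe_p_min,
    family_ids = fam_ids
  )
  qc_rep <- attr(g_qc, "qc_report")
  log_stage(log_path, "qc: %d -> %d variants, %d -> %d individuals",
            nrow(g$variants), nrow(g_qc$variants),
            length(g$ids), length(g_qc$ids))

  pheno_qc <- pheno[pheno$id %in% g_qc$ids, , drop = FALSE]
  cohort <- derive_variables(pheno_qc)
  log_stage(log_path, "derive: %d retained of %d",
            nrow(retained(cohort)), nrow(cohort))

  composites <- NULL
  candidates <- g_qc
  if (cfg$iv$candidates %in% c("composite", "both") &&
      cfg$iv$mode == "candidate_gene") {
    composites <- build_composites(g_qc, cfg$composite$pairing_scope)
    log_stage(log_path, "composite: %d pairs (%s)",
              nrow(composites$variants), cfg$composite$pairing_scope)
    candidates <- if (cfg$iv$candidates == "composite") composites
      else bind_geno(g_qc, composites)
  } else if (cfg$iv$mode == "gwas") {
    log_stage(log_path,
              "gwas mode: exposure scan restricted to supplied variants")
  }

  fam_for_iv <- if (!is.null(fam_ids)) {
    cohort$family_id
  } else NULL
  iv_audit <- select_ivs(
    candidates, cohort,
    mode = cfg$iv$mode, alpha = cfg$iv$alpha, f_min = cfg$iv$f_min,
    r2_max = cfg$iv$r2_max, family_ids = fam_for_iv
  )
  qual_ids <- iv_audit$id[iv_audit$stage == "qualified"]
  log_stage(log_path, "select-iv: %d qualified of %d candidates",
            length(qual_ids), nrow(iv_audit))
  if (!length(qual_ids)) {
    abort("pipeline stage select-iv: zero qualified instruments; MR refused")
  }

  keep <- match(qual_ids, candidates$variants$id)
  g_iv <- geno_matrix(candidates$dosages[, keep, drop = FALSE],
                      candidates$variants[keep, , drop = FALSE],
                      ids = candidates$ids)
  mr <- run_mr(
    g_iv, cohort,
    strata = cfg$strata,
    n_boot = cfg$estimators$n_boot,
    seed = stage_seed(seed, "mr"),
    penalty_factor = cfg$estimators$penalty_factor,
    evalue_conversion = cfg$estimators$evalue_conversion,
    se_order = cfg$estimators$se_order
  )
  log_stage(log_path, "mr: IVW estimate %.4f (p=%.3g) on %d IVs",
            mr$results$estimate[mr$results$method == "ivw" &
                                  mr$results$stratum == "all"],
            mr$results$p[mr$results$method == "ivw" &
                           mr$results$stratum == "all"],
            length(qual_ids))

  km <- kaplan_meier(cohort)
  desc <- descriptive_table(cohort)
  manifest <- build_report(
    out_dir, config = unclass(cfg), seed = seed,
    qc_report = qc_rep,
    composite_manifest = if (!is.null(composites)) composites$variants,
    iv_audit = iv_audit, mr = mr, km = km, descriptives = desc
  )
  log_stage(log_path, "report: written to %s (complete=%s)",
            out_dir, attr(manifest, "complete"))

  invisible(structure(
    list(genotypes = g_qc, cohort = cohort, composites = composites,
         iv_audit = iv_audit, mr = mr, km = km, descriptives = desc,
         report_dir = out_dir, manifest = manifest),
    class = "cmr_run"
  ))
}

# Column-bind two geno_matrix objects over the same individuals.
bind_geno <- function(a, b) {
  stopifnot(identical(a$ids, b$ids))
  geno_matrix(
    cbind(a$dosages, b$dosages),
    dplyr::bind_rows(a$variants, b$variants),
    ids = a$ids
  )
}
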