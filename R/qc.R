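# Hardy-Weinberg exact test (two-sided, conditional on allele counts).
# n_het: observed heterozygotes; n_hom_rare: rare-allele homozygotes;
# n_hom_common: common-allele homozygotes. Returns the exact p-value as the
# summed probability of all heterozygote counts no more probable than the
# observed one.
hwe_exact_p <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  if (n == 0L) return(1)
  n_rare <- 2L * n_hom_rare + n_het
  if (n_rare > n) {  # orient to the rarer allele
    n_rare <- 2L * n - n_rare
  }
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log unnormalized probabilities of each possible het count
  lp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs + 1e-12])
}

hwe_p_for_variant <- function(d) {
  d <- d[!is.na(d)]
  hwe_exact_p(sum(d == 1L), sum(d == 2L), sum(d == 0L))
}

#' Quality-control filter for a genotype matrix
#'
#' Removes variants and individuals failing call-rate, minor-allele
#' frequency and Hardy-Weinberg thresholds. The three passes (variant call
#' rate, individual call rate, then MAF and an exact Hardy-Weinberg test on
#' the post-filter sample) iterate to a fixed point so the filter is
#' idempotent. When family ids are supplied the Hardy-Weinberg test uses
#' one individual per family (founders) to avoid relatedness inflation.
#'
#' @param g a [geno_matrix()].
#' @param snp_call_rate minimum per-variant genotyping rate.
#' @param ind_call_rate minimum per-individual genotyping rate.
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p (0 disables).
#' @param family_ids optional per-individual family ids aligned with
#'   `g$ids`.
#' @return The filtered [geno_matrix()], with a `qc_report` attribute: a
#'   tibble of removal counts per criterion.
#' @export
qc_filter <- function(g, snp_call_rate = 0.95, ind_call_rate = 0.95,
                      maf_min = 0.01, hwe_p_min = 1e-6,
                      family_ids = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  for (nm in c("snp_call_rate", "ind_call_rate", "maf_min", "hwe_p_min")) {
    assert_number(get(nm), nm, lo = 0, hi = 1)
  }
  if (!is.null(family_ids)) {
    stopifnot(length(family_ids) == length(g$ids))
    names(family_ids) <- g$ids
  }
  dos <- g$dosages
  removed <- c(snp_call_rate = 0L, ind_call_rate = 0L,
               maf = 0L, hwe = 0L)
  repeat {
    changed <- FALSE
    if (ncol(dos) > 0L) {
      cr <- colMeans(!is.na(dos))
      drop_v <- cr < snp_call_rate
      if (any(drop_v)) {
        removed["snp_call_rate"] <- removed["snp_call_rate"] + sum(drop_v)
        dos <- dos[, !drop_v, drop = FALSE]
        changed <- TRUE
      }
    }
    if (nrow(dos) > 0L && ncol(dos) > 0L) {
      ir <- rowMeans(!is.na(dos))
      drop_i <- ir < ind_call_rate
      if (any(drop_i)) {
        removed["ind_call_rate"] <- removed["ind_call_rate"] + sum(drop_i)
        dos <- dos[!drop_i, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (ncol(dos) > 0L) {
      maf <- colMeans(dos, na.rm = TRUE) / 2
      maf <- pmin(maf, 1 - maf)
      drop_v <- is.na(maf) | maf < maf_min
      if (hwe_p_min > 0 && nrow(dos) > 0L) {
        hdos <- dos
        if (!is.null(family_ids)) {
          fid <- family_ids[rownames(dos)]
          hdos <- dos[!duplicated(fid), , drop = FALSE]
        }
        hwe_p <- apply(hdos, 2L, hwe_p_for_variant)
        drop_hwe <- !drop_v & hwe_p < hwe_p_min
        removed["hwe"] <- removed["hwe"] + sum(drop_hwe)
        drop_v2 <- drop_v | drop_hwe
      } else {
        drop_v2 <- drop_v
      }
      removed["maf"] <- removed["maf"] + sum(drop_v)
      if (any(drop_v2)) {
        dos <- dos[, !drop_v2, drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (ncol(dos) == 0L && ncol(g$dosages) > 0L) {
    warn("qc_filter removed all variants")
  }
  keep_v <- match(colnames(dos), g$variants$id)
  out <- geno_matrix(
    dos,
    dplyr::mutate(g$variants[keep_v, , drop = FALSE],
                  maf = pmin(colMeans(dos, na.rm = TRUE) / 2,
                             1 - colMeans(dos, na.rm = TRUE) / 2)),
    ids = rownames(dos)
  )
  report <- tibble::tibble(
    criterion = names(removed),
    removed = as.integer(removed),
    kind = c("variant", "individual", "variant", "variant")
  )
  attr(out, "qc_report") <- report
  out
}
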