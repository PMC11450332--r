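# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the package's own code paths.

# Weighted median by interpolating the cumulative-weight curve with approx().
wm_oracle <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(x = s, y = theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

# IVW as weighted least squares of beta_y on beta_x through the origin,
# weights 1/se_y^2 (fixed-effect scale for the se).
wls_origin_oracle <- function(bx, by, sey) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sey^2)
  sm <- summary(fit)
  c(estimate = unname(coef(fit)[1L]),
    se = unname(sm$coefficients[1L, 2L] / sm$sigma))
}

# Hand-rolled iteratively-reweighted-least-squares logistic solver.
irls_logit_oracle <- function(x, y, tol = 1e-12, maxit = 50L) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    XtW <- t(X * W)
    b_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  V <- solve(t(X * (1 / (1 + exp(-as.vector(X %*% b)))) *
                 (1 - 1 / (1 + exp(-as.vector(X %*% b)))) ) %*% X)
  list(beta = as.vector(b), se = sqrt(diag(V)))
}

# Exact Hardy-Weinberg p-value by direct enumeration with choose().
hwe_oracle <- function(n_het, n_hom_rare, n_hom_common) {
  n <- n_het + n_hom_rare + n_hom_common
  n_rare <- 2L * n_hom_rare + n_het
  if (n_rare > n) n_rare <- 2L * n - n_rare
  if (n_rare == 0L || n == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  prob_of <- function(h) {
    hr <- (n_rare - h) / 2
    # multinomial count of genotype configurations x 2^het phasings,
    # conditional on the allele count (common denominator drops out)
    choose(n, h) * choose(n - h, hr) * 2^h
  }
  pr <- vapply(hets, prob_of, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs + 1e-12])
}

# Decode a PLINK bed file byte by byte with plain integer arithmetic.
bed_decode_oracle <- function(bed_path, n, m) {
  raw <- readBin(bed_path, "raw", file.size(bed_path))
  stopifnot(as.integer(raw[1:3]) == c(0x6c, 0x1b, 0x01))
  payload <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  out <- matrix(NA_integer_, n, m)
  map <- c(2L, NA_integer_, 1L, 0L)  # 2-bit value 0,1,2,3 -> dosage
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      byte <- payload[(j - 1L) * bpv + (i - 1L) %/% 4L + 1L]
      k <- (i - 1L) %% 4L
      bits <- (byte %/% 4L^k) %% 4L
      out[i, j] <- map[bits + 1L]
    }
  }
  out
}

# Expected composite dosage-class frequencies for two independent SNPs
# with the given minor-allele frequencies: convolution of two binomial(2, p)
# dosage distributions pushed through the 0/1-,2-,3/4- recoding.
composite_freq_oracle <- function(p, q) {
  pa <- stats::dbinom(0:2, 2, p)
  pb <- stats::dbinom(0:2, 2, q)
  psum <- rep(0, 5)
  for (a in 0:2) for (b in 0:2) {
    psum[a + b + 1L] <- psum[a + b + 1L] + pa[a + 1L] * pb[b + 1L]
  }
  c(`0` = psum[1] + psum[2], `1` = psum[3], `2` = psum[4] + psum[5])
}

# Build a minimal derived-cohort tibble directly from vectors, bypassing
# the simulator, for estimator-level tests.
make_cohort <- function(exposure, outcome, mean_bmi = NULL, ...) {
  n <- length(exposure)
  tibble::tibble(
    id = sprintf("p%05d", seq_len(n)),
    exposure = as.integer(exposure),
    outcome = as.integer(outcome),
    mean_bmi_75_85 = mean_bmi %||% (18.6 + 11 * exposure),
    excluded = FALSE,
    exclusion_reason = NA_character_,
    ...
  )
}

# Random per-IV summary-statistic sets for estimator tests. Directional
# pleiotropy is planted relative to the exposure-increasing orientation,
# so `positive_bx = TRUE` keeps all instruments in that orientation.
make_stats <- function(m, seed, theta = 0.2, pleiotropy = 0,
                       positive_bx = pleiotropy != 0) {
  withr::with_seed(seed, {
    signs <- if (positive_bx) rep(1, m) else sample(c(-1, 1), m, TRUE)
    bx <- runif(m, 0.2, 0.8) * signs
    sex <- runif(m, 0.02, 0.1)
    sey <- runif(m, 0.02, 0.1)
    by <- theta * bx + pleiotropy + rnorm(m, 0, sey)
    tibble::tibble(
      id = sprintf("iv%03d", seq_len(m)),
      beta_x = bx, se_x = sex, beta_y = by, se_y = sey,
      n_used = 5000L, ok = TRUE
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runif_seeded <- function(max, seed) {
  withr::with_seed(seed, runif(1, -max, max))
}

# Derive analysis variables and keep the retained subset.
retained_cohort <- function(raw) {
  co <- derive_variables(raw)
  co[!co$excluded, , drop = FALSE]
}
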