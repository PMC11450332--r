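# Internal helpers shared across modules.

# Fast univariate logistic fit y ~ 1 + x via glm.fit.
# Returns c(beta, se, p) for the slope, or NA triple on failure/separation.
fast_logit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = length(y)))
  }
  X <- cbind(1, x)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  p <- fit$rank
  if (p < 2L || !fit$converged) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = length(y)))
  }
  covm <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  beta <- unname(coef(fit)[2L])
  se <- sqrt(covm[2L, 2L])
  # crude separation guard: absurd slope or exploding se
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 100) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = length(y)))
  }
  z <- beta / se
  c(beta = unname(beta), se = se, p = 2 * pnorm(-abs(z)), n = length(y))
}

# Fast univariate OLS fit y ~ 1 + x; returns c(beta, se, p).
fast_lm <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3L || length(unique(x)) < 2L) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = n))
  }
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  beta <- sum((x - mx) * (y - my)) / sxx
  res <- (y - my) - beta * (x - mx)
  s2 <- sum(res^2) / (n - 2L)
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  c(beta = beta, se = se, p = 2 * stats::pt(-abs(tval), df = n - 2L), n = n)
}

# Cheap tibble constructor for the per-individual BMI measurement frames:
# building tens of thousands of them through tibble() dominates simulation
# time otherwise.
bmi_frame <- function(age, bmi) {
  structure(
    list(age = as.numeric(age), bmi = as.numeric(bmi)),
    class = c("tbl_df", "tbl", "data.frame"),
    row.names = .set_row_names(length(age))
  )
}

# Deterministic per-stage seed derivation from one master seed.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, qc = 2L, derive = 3L, composite = 4L,
    select_iv = 5L, mr = 6L, report = 7L
  )
  i <- offsets[[stage]]
  as.integer((as.double(seed) + 1000003 * i) %% 2147483647)
}

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}
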