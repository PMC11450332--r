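test_that("a single instrument reduces IVW to the plain Wald ratio", {
  st <- tibble::tibble(id = "iv1", beta_x = 0.4, se_x = 0.05,
                       beta_y = 0.12, se_y = 0.06, n_used = 1000L,
                       ok = TRUE)
  out <- ivw(st)
  expect_identical(out$estimate, 0.12 / 0.4)
  expect_identical(out$n_iv, 1L)
})

test_that("equal-precision instruments average their ratios", {
  st <- tibble::tibble(
    id = c("a", "b"), beta_x = c(1, 1), se_x = 0.01,
    beta_y = c(0.1, 0.3), se_y = c(0.05, 0.05), n_used = 1000L, ok = TRUE
  )
  expect_equal(ivw(st)$estimate, 0.2, tolerance = 1e-12)
})

test_that("IVW equals weighted least squares through the origin", {
  for (s in 1:10) {
    st <- make_stats(20, seed = 700 + s)
    got <- ivw(st)
    oracle <- wls_origin_oracle(st$beta_x, st$beta_y, st$se_y)
    expect_equal(got$estimate, unname(oracle["estimate"]),
                 tolerance = 1e-10)
    expect_equal(got$se, unname(oracle["se"]), tolerance = 1e-10)
  }
})

test_that("instruments with beta_x = 0 are excluded with a warning", {
  st <- make_stats(5, seed = 71)
  st$beta_x[2] <- 0
  expect_warning(out <- ivw(st), "beta_x = 0")
  expect_identical(out$n_iv, 4L)
})

test_that("penalization leaves homogeneous instruments untouched", {
  st <- tibble::tibble(
    id = sprintf("iv%d", 1:5), beta_x = 0.5, se_x = 0.02,
    beta_y = 0.1, se_y = 0.04, n_used = 1000L, ok = TRUE
  )
  expect_equal(penalized_ivw(st)$estimate, ivw(st)$estimate,
               tolerance = 1e-12)
})

test_that("penalization shrinks the influence of a gross outlier", {
  st <- make_stats(19, seed = 72, theta = 0.2)
  outlier <- tibble::tibble(id = "bad", beta_x = 0.5, se_x = 0.01,
                            beta_y = 2.5, se_y = 0.01, n_used = 1000L,
                            ok = TRUE)
  st2 <- dplyr::bind_rows(st, outlier)
  est_ivw <- ivw(st2)$estimate
  est_pen <- penalized_ivw(st2)$estimate
  expect_lt(abs(est_pen - 0.2), abs(est_ivw - 0.2))
})

test_that("an infinite penalty factor recovers plain IVW", {
  st <- make_stats(12, seed = 73)
  expect_equal(penalized_ivw(st, penalty_factor = Inf)$estimate,
               ivw(st)$estimate, tolerance = 1e-10)
})

test_that("weighted median interpolates the cumulative-weight curve", {
  st <- tibble::tibble(
    id = c("a", "b", "c"), beta_x = 1, se_x = 0.01,
    beta_y = c(0.1, 0.2, 0.9), se_y = 0.05, n_used = 1000L, ok = TRUE
  )
  expect_equal(weighted_median(st, n_boot = 50, seed = 1)$estimate, 0.2,
               tolerance = 1e-12)
  st$beta_y <- rep(0.37, 3)
  expect_equal(weighted_median(st, n_boot = 50, seed = 1)$estimate, 0.37,
               tolerance = 1e-12)
})

test_that("weighted median matches the independent interpolation oracle", {
  for (s in 1:20) {
    st <- make_stats(5 + s %% 7, seed = 800 + s)
    got <- weighted_median(st, n_boot = 50, seed = 1)$estimate
    theta <- st$beta_y / st$beta_x
    w <- (abs(st$beta_x) / st$se_y)^2
    expect_equal(got, wm_oracle(theta, w), tolerance = 1e-12)
  }
})

test_that("equal weights with odd counts give the plain median", {
  for (m in c(3L, 5L, 9L)) {
    st <- tibble::tibble(
      id = sprintf("iv%d", seq_len(m)), beta_x = 1, se_x = 0.01,
      beta_y = withr::with_seed(m, rnorm(m)), se_y = 0.05,
      n_used = 1000L, ok = TRUE
    )
    expect_equal(weighted_median(st, n_boot = 50, seed = 1)$estimate,
                 median(st$beta_y), tolerance = 1e-12)
  }
})

test_that("duplicating an instrument at half weight changes nothing", {
  st <- make_stats(7, seed = 74)
  theta <- st$beta_y / st$beta_x
  w <- (abs(st$beta_x) / st$se_y)^2
  # split the extreme ratio: cumulative weights below the median crossing
  # are untouched, so the interpolated estimate is exactly preserved
  k <- which.max(theta)
  w2 <- c(w[k] / 2, w[k] / 2, w[-k])
  theta2 <- c(theta[k], theta[k], theta[-k])
  expect_equal(compositemr:::weighted_median_point(theta2, w2),
               compositemr:::weighted_median_point(theta, w),
               tolerance = 1e-12)
  # splitting an interior ratio moves the estimate only within the
  # resolution of its own weight share
  w3 <- c(w[1] / 2, w[1] / 2, w[-1])
  theta3 <- c(theta[1], theta[1], theta[-1])
  expect_equal(compositemr:::weighted_median_point(theta3, w3),
               compositemr:::weighted_median_point(theta, w),
               tolerance = 1e-3)
})

test_that("the weighted-median bootstrap is seed-reproducible", {
  st <- make_stats(8, seed = 75)
  a <- weighted_median(st, n_boot = 200, seed = 42)
  b <- weighted_median(st, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c2 <- weighted_median(st, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c2$se))
})

test_that("collinear instruments reproduce their line in MR-Egger", {
  st <- tibble::tibble(
    id = c("a", "b", "c"), beta_x = c(0.2, 0.5, 0.8), se_x = 0.02,
    beta_y = 0.05 + 0.3 * c(0.2, 0.5, 0.8), se_y = c(0.03, 0.05, 0.04),
    n_used = 1000L, ok = TRUE
  )
  # exact fit: lm warns about a perfect (zero-residual) regression
  out <- suppressWarnings(mr_egger(st))
  expect_equal(out$estimate[out$method == "egger"], 0.3, tolerance = 1e-12)
  expect_equal(out$estimate[out$method == "egger_intercept"], 0.05,
               tolerance = 1e-12)
})

test_that("estimators are equivariant under joint sign flips", {
  st <- make_stats(9, seed = 76)
  flipped <- st
  flipped$beta_x[c(2, 5)] <- -flipped$beta_x[c(2, 5)]
  flipped$beta_y[c(2, 5)] <- -flipped$beta_y[c(2, 5)]
  expect_equal(ivw(flipped)$estimate, ivw(st)$estimate, tolerance = 1e-12)
  expect_equal(weighted_median(flipped, n_boot = 50, seed = 1)$estimate,
               weighted_median(st, n_boot = 50, seed = 1)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$estimate, mr_egger(st)$estimate,
               tolerance = 1e-12)
})

test_that("the E-value closed form and its symmetries hold", {
  expect_identical(evalue(1), 1)
  expect_equal(evalue(4), 4 + sqrt(12), tolerance = 1e-12)
  expect_equal(evalue(0.25), evalue(4), tolerance = 1e-12)
  expect_error(evalue(0), "positive")
  expect_error(evalue(-2), "positive")
  expect_true(all(evalue(c(1.1, 2, 8)) >= 1))
})

test_that("E-value summaries chain OR -> RR -> E correctly", {
  st <- tibble::tibble(
    id = c("a", "b", "c"), beta_x = 1, se_x = 0.01,
    beta_y = log(c(1.2, 1.8, 0.7)), se_y = 0.05, n_used = 1000L, ok = TRUE
  )
  ev <- evalue_summary(st)  # theta_j = log OR directly since beta_x = 1
  hand <- evalue(sqrt(c(1.2, 1.8, 0.7)))
  expect_equal(ev$average, mean(hand), tolerance = 1e-12)
  expect_equal(ev$min, min(hand), tolerance = 1e-12)
  expect_equal(ev$max, max(hand), tolerance = 1e-12)
  ev_rare <- evalue_summary(st, conversion = "rare_outcome")
  expect_equal(ev_rare$max, evalue(1.8), tolerance = 1e-12)
  # null ratios give the null E-value triple
  st$beta_y <- 0
  expect_equal(unlist(evalue_summary(st)[, 1:3]),
               c(average = 1, min = 1, max = 1))
  expect_equal(unlist(evalue_summary(st[1, ])[, 1:3]),
               c(average = 1, min = 1, max = 1))
})

test_that("association_stats matches a hand-rolled IRLS solver", {
  withr::with_seed(77, {
    n <- 800
    d <- rbinom(n, 2, 0.3)
    x <- rbinom(n, 1, plogis(-0.2 + 0.4 * d))
    y <- rbinom(n, 1, plogis(0.8 + 0.25 * x))
  })
  co <- make_cohort(x, y)
  dmat <- matrix(d, ncol = 1, dimnames = list(NULL, "iv1"))
  st <- association_stats(dmat, co)
  ox <- irls_logit_oracle(d, x)
  oy <- irls_logit_oracle(d, y)
  expect_equal(st$beta_x, unname(ox$beta[2]), tolerance = 1e-6)
  expect_equal(st$beta_y, unname(oy$beta[2]), tolerance = 1e-6)
  # glm.fit stops on a deviance criterion; allow its solver resolution
  expect_equal(st$se_x, unname(ox$se[2]), tolerance = 1e-4)
  expect_equal(st$se_y, unname(oy$se[2]), tolerance = 1e-4)
})

test_that("association_stats recovers a planted exposure log-odds effect", {
  withr::with_seed(78, {
    n <- 50000
    d <- rbinom(n, 2, 0.3)
    x <- rbinom(n, 1, plogis(-0.5 + 0.3 * d))
    y <- rbinom(n, 1, 0.7)
  })
  st <- association_stats(matrix(d, ncol = 1, dimnames = list(NULL, "v")),
                          make_cohort(x, y))
  expect_lt(abs(st$beta_x - 0.3), 0.05)
  expect_lt(abs(st$beta_y), 3 * st$se_y)  # no outcome path planted
})

test_that("run_mr assembles the suite and its significance verdict", {
  withr::with_seed(79, {
    n <- 3000; m <- 6
    G <- matrix(rbinom(n * m, 2, 0.3), n, m,
                dimnames = list(NULL, sprintf("iv%d", 1:m)))
    x <- rbinom(n, 1, plogis(-0.4 + 0.4 * rowSums(G) / m * 3))
    y <- rbinom(n, 1, plogis(0.6 + 0.6 * x))
    sex <- sample(1:2, n, TRUE)
  })
  co <- make_cohort(x, y, sex = sex)
  res <- run_mr(G, co, strata = "sex", n_boot = 100, seed = 5)
  expect_s3_class(res, "mr_result")
  expect_setequal(unique(res$results$stratum), c("all", "1", "2"))
  expect_true(all(c("ivw", "weighted_median", "egger", "egger_intercept")
                  %in% res$results$method[res$results$stratum == "all"]))
  # broom-style accessors agree with the underlying tables
  expect_identical(tidy(res), res$results)
  expect_identical(glance(res)$stratum, res$verdict$stratum)
  expect_true(all(res$results$ci_lo <= res$results$estimate &
                    res$results$estimate <= res$results$ci_hi))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_mr_scatter(res), "ggplot")
})

test_that("run_mr refuses empty input and degrades below 3 instruments", {
  co <- make_cohort(rbinom(200, 1, 0.5), rbinom(200, 1, 0.5))
  expect_error(run_mr(matrix(numeric(), 200, 0), co), "no qualified")
  withr::with_seed(80, {
    G <- matrix(rbinom(400, 2, 0.4), 200, 2,
                dimnames = list(NULL, c("a", "b")))
  })
  expect_warning(res <- run_mr(G, co, n_boot = 50), "fewer than 3")
  expect_identical(res$results$method, "ivw")
})

test_that("penalized IVW is reported exactly when IVW is inconclusive", {
  st_null <- make_stats(10, seed = 81, theta = 0)
  out <- compositemr:::run_mr_one(st_null, n_boot = 50, seed = 1,
                                  penalty_factor = 20,
                                  evalue_conversion = "common_outcome_sqrt",
                                  se_order = "first")
  has_pen <- "penalized_ivw" %in% out$results$method
  ivw_p <- out$results$p[out$results$method == "ivw"]
  expect_identical(has_pen, ivw_p >= 0.05)
})
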