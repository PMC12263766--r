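instr <- function(gx, gy, sy, sx = 0.01) {
  tibble::tibble(
    exposure_beta = gx, exposure_se = sx,
    outcome_beta = gy, outcome_se = sy
  )
}

test_that("ratio estimate follows the delta-method formula", {
  e <- mr_ratio(instr(0.1, 0.2, 0.05))
  expect_equal(e$beta, 2.0)
  expect_equal(e$se, 0.5)
  expect_equal(e$method, "ratio")
  # Null outcome: estimate 0, p of 1.
  e0 <- mr_ratio(instr(0.1, 0, 0.05))
  expect_equal(e0$beta, 0)
  expect_equal(e0$se, 0.5)
  expect_equal(e0$pval, 1)
  # Negative exposure association flips the sign, not the SE.
  en <- mr_ratio(instr(-0.1, 0.2, 0.05))
  expect_equal(en$beta, -2.0)
  expect_equal(en$se, 0.5)
  expect_error(mr_ratio(instr(0, 0.2, 0.05)), class = "ketomr_domain_error")
})

test_that("IVW matches its closed form and reduces to the ratio at J = 1", {
  e <- mr_ivw(instr(c(0.1, 0.2), c(0.05, 0.10), c(0.05, 0.05)))
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 1 / sqrt(20), tolerance = 1e-12)
  expect_equal(e$q_stat, 0, tolerance = 1e-20)
  expect_equal(e$ci_low, e$beta - qnorm(0.975) * e$se)

  single <- instr(0.1, 0.2, 0.05)
  expect_equal(glance(mr_ivw(single))[, c("method", "estimate", "std.error")],
               glance(mr_ratio(single))[, c("method", "estimate", "std.error")])

  # All-null outcomes give a zero estimate.
  expect_equal(mr_ivw(instr(c(0.1, 0.2, 0.3), c(0, 0, 0), 0.05))$beta, 0)
  expect_error(mr_ivw(instr(numeric(0), numeric(0), numeric(0))),
               class = "ketomr_usage_error")
})

test_that("IVW equals weighted least squares through the origin (oracle)", {
  set.seed(501)
  for (rep in 1:200) {
    j <- sample(2:30, 1)
    x <- random_instruments(j)
    est <- mr_ivw(x, model = "fe")
    orc <- oracle_wls_origin(x$exposure_beta, x$outcome_beta, x$outcome_se)
    expect_equal(est$beta, orc$beta, tolerance = 1e-10)
    expect_equal(est$se, orc$se_fixed, tolerance = 1e-10)
    expect_equal(est$q_stat, orc$q, tolerance = 1e-8)
  }
})

test_that("IVW scale behaviour: invariant beta, linear fixed SE, floored MRE", {
  set.seed(502)
  x <- random_instruments(8)
  base_fe <- mr_ivw(x, model = "fe")
  for (k in c(0.5, 2, 10)) {
    xs <- dplyr::mutate(x, outcome_se = outcome_se * k)
    scaled <- mr_ivw(xs, model = "fe")
    expect_equal(scaled$beta, base_fe$beta, tolerance = 1e-12)
    expect_equal(scaled$se, k * base_fe$se, tolerance = 1e-12)
  }
  # The MRE standard error never undercuts the fixed-effect one.
  for (rep in 1:50) {
    y <- random_instruments(sample(2:15, 1))
    expect_gte(mr_ivw(y, model = "mre")$se, mr_ivw(y, model = "fe")$se)
  }
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  gx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  sy <- c(0.02, 0.05, 0.01, 0.03, 0.02)
  # Gamma = 0.01 + 0.3 * gamma_x exactly: zero residual fit.
  e <- mr_egger(instr(gx, 0.01 + 0.3 * gx, sy))
  expect_equal(e$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.01, tolerance = 1e-10)
  expect_equal(e$q_stat, 0, tolerance = 1e-16)
  # Proportional data: intercept exactly zero, slope equals IVW.
  e2 <- mr_egger(instr(gx, 0.3 * gx, sy))
  expect_equal(e2$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(e2$beta, 0.3, tolerance = 1e-12)
  expect_equal(e2$beta, mr_ivw(instr(gx, 0.3 * gx, sy))$beta,
               tolerance = 1e-10)

  set.seed(503)
  for (rep in 1:100) {
    j <- sample(3:20, 1)
    x <- random_instruments(j)
    # Orient like the implementation so the oracle fits the same data.
    o <- ifelse(x$exposure_beta < 0, -1, 1)
    coefs <- oracle_wls_intercept(x$exposure_beta * o, x$outcome_beta * o,
                                  x$outcome_se)
    e <- mr_egger(x)
    expect_equal(e$egger_intercept, unname(coefs[1]), tolerance = 1e-10)
    expect_equal(e$beta, unname(coefs[2]), tolerance = 1e-10)
  }
  expect_error(mr_egger(instr(c(0.1, 0.2), c(0.1, 0.2), 0.05)),
               class = "ketomr_usage_error")
})

test_that("weighted median interpolates across standardized weights", {
  # theta = (1, 2, 3): equal weights give the plain median.
  x_eq <- instr(c(1, 1, 1), c(1, 2, 3), 1)
  e <- mr_weighted_median(x_eq, n_boot = 50, seed = 1)
  expect_equal(e$beta, 2)
  # Weights (1, 1, 2): interpolation between s2 = 0.375 and s3 = 0.75.
  x_w <- instr(c(1, 1, sqrt(2)), c(1, 2, 3 * sqrt(2)), 1)
  e2 <- mr_weighted_median(x_w, n_boot = 50, seed = 1)
  expect_equal(e2$beta, 2 + (0.5 - 0.375) / (0.75 - 0.375), tolerance = 1e-12)
  # Identical ratios: the estimate is that constant and the bootstrap SE is
  # small.
  x_c <- instr(c(0.2, 0.25, 0.3), 0.4 * c(0.2, 0.25, 0.3), 0.001,
               sx = 0.001)
  e3 <- mr_weighted_median(x_c, n_boot = 200, seed = 2)
  expect_equal(e3$beta, 0.4, tolerance = 1e-12)
  expect_lt(e3$se, 0.05)
  # Equal weights and odd J reduce to the ordinary median.
  set.seed(504)
  for (rep in 1:20) {
    j <- sample(c(3, 5, 7, 9), 1)
    theta <- rnorm(j)
    e4 <- mr_weighted_median(instr(rep(1, j), theta, 1), n_boot = 10,
                             seed = 3)
    expect_equal(e4$beta, median(theta), tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap is reproducible and leaves the RNG alone", {
  set.seed(99)
  x <- random_instruments(6)
  before <- .Random.seed
  a <- mr_weighted_median(x, n_boot = 100, seed = 7)
  expect_identical(.Random.seed, before)
  b <- mr_weighted_median(x, n_boot = 100, seed = 7)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(x, n_boot = 100, seed = 8)
  expect_false(identical(a$se, c$se))
  expect_error(mr_weighted_median(x, n_boot = 10),
               class = "ketomr_usage_error")
})

test_that("Cochran's Q measures weighted dispersion around beta", {
  # Identical ratios: no heterogeneity.
  x_c <- instr(c(0.1, 0.2, 0.4), 0.5 * c(0.1, 0.2, 0.4), 0.05)
  q <- cochran_q(x_c, 0.5)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$pval, 1)
  # Two pairs with unit weights: Q = w1 (0 - 0.5)^2 + w2 (1 - 0.5)^2 = 0.5.
  x2 <- instr(c(1, 1), c(0, 1), 1)
  q2 <- cochran_q(x2, 0.5)
  expect_equal(q2$q_stat, 0.5)
  expect_equal(q2$q_df, 1)
  # Q grows as one ratio moves away from beta.
  qs <- sapply(c(1, 2, 4), function(d) {
    cochran_q(instr(c(1, 1), c(0, d), 1), 0)$q_stat
  })
  expect_true(all(diff(qs) > 0))
  expect_error(cochran_q(instr(1, 1, 1), 1), class = "ketomr_usage_error")
})

test_that("tidy and glance return broom-shaped tibbles", {
  set.seed(505)
  x <- random_instruments(5)
  e <- mr_egger(x)
  td <- tidy(e)
  expect_equal(td$term, c("slope", "intercept"))
  expect_named(td, c("method", "term", "estimate", "std.error", "statistic",
                     "p.value", "conf.low", "conf.high"))
  gl <- glance(mr_ivw(x))
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_variants, 5L)
  all_est <- mr_estimate_all(x, seed = 1)
  expect_setequal(all_est$method, c("ivw_mre", "weighted_median", "egger"))
  expect_true(all(all_est$term == "slope"))
  # Dispatch honours instrument-count preconditions.
  expect_equal(mr_estimate_all(x[1, ], seed = 1)$method, "ratio")
  expect_equal(mr_estimate_all(x[1:2, ], seed = 1)$method, "ivw_mre")
})
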