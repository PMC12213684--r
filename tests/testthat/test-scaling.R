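test_that("empirical CCDF counts tail mass correctly", {
  f <- empirical_ccdf(c(1, 1, 2))
  expect_equal(f(1), 1)
  expect_equal(f(2), 1 / 3)
  expect_equal(empirical_ccdf(5)(5), 1)
  expect_error(empirical_ccdf(numeric(0)), class = "socnet_spec_error")
  # geometric closed form: P(X >= 2) = 1 - p
  withr::with_seed(5, {
    p <- 0.5
    x <- rgeom(1e4, p) + 1
    se <- sqrt(p * (1 - p) / 1e4)
    expect_lt(abs(empirical_ccdf(x)(2) - (1 - p)), 3 * se)
  })
  # monotone nonincreasing, right support positive
  withr::with_seed(6, {
    x <- sample(1:50, 500, replace = TRUE)
    tab <- attr(empirical_ccdf(x), "table")
    expect_true(all(diff(tab$ccdf) < 0))
    expect_true(all(tab$ccdf > 0))
  })
})

test_that("truncated power-law fit recovers self-generated parameters", {
  s <- rtpl(3e4, alpha = 1.5, lambda = 500, seed = 11)
  fit <- fit_truncated_power_law(s)
  expect_lt(abs(fit$alpha - 1.5), 0.1)
  expect_lt(abs(log(fit$lambda / 500)), log(1.5))
  # fitted CCDF is a proper tail function
  expect_equal(fit$ccdf(1), 1)
  xs <- c(1, 2, 5, 10, 50, 100, 500)
  expect_true(all(diff(fit$ccdf(xs)) <= 0))
  # tidiers
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "lambda"))
  expect_equal(glance(fit)$nobs, 3e4)
})

test_that("pure power-law samples are fit with a cutoff beyond the data", {
  s <- rtpl(3e4, alpha = 2.5, lambda = Inf, seed = 12)
  fit <- fit_truncated_power_law(s)
  expect_lt(abs(fit$alpha - 2.5), 0.1)
  expect_gte(fit$lambda, max(s))
})

test_that("degenerate or tiny catalogs are rejected", {
  expect_error(fit_truncated_power_law(rep(3, 1000)),
               class = "socnet_fit_error")
  expect_error(fit_truncated_power_law(1:10), class = "socnet_fit_error")
  expect_error(fit_truncated_power_law(c(rep(1, 100), 0.5)),
               class = "socnet_fit_error")
})

test_that("fitted and empirical CCDFs agree on self-generated catalogs", {
  s <- rtpl(1e5, alpha = 1.6, lambda = 800, seed = 13)
  fit <- fit_truncated_power_law(s)
  emp <- empirical_ccdf(s)
  pts <- sort(unique(s))
  pts <- pts[emp(pts) >= 1e-3]  # where the empirical tail is resolved
  ratio <- emp(pts) / fit$ccdf(pts)
  expect_true(all(ratio < 2 & ratio > 0.5))
})

test_that("fits are stable across halves of a stationary catalog", {
  s <- rtpl(4e4, alpha = 1.5, lambda = 1000, seed = 14)
  a <- fit_truncated_power_law(s[1:2e4])$alpha
  b <- fit_truncated_power_law(s[2e4 + 1:2e4])$alpha
  expect_lt(abs(a - b), 0.1)
})

test_that("regime cascade maps the four constructed catalogs correctly", {
  # supercritical: five or fewer avalanches in the run
  expect_equal(classify_regime(c(10, 500, 2000))$label, "supercritical")
  expect_equal(classify_regime(rep(1e4, 5))$label, "supercritical")
  # subcritical: bounded maximum after the first-five drop
  sub <- pmin(rtpl(1e4, 1.5, 100, seed = 4), 316L)
  r_sub <- classify_regime(sub)
  expect_equal(r_sub$label, "subcritical")
  expect_lte(r_sub$evidence$max_size, 10^2.5)
  # dragon king: injected tail bump; critical: same catalog without the bump
  clean <- rtpl(1e5, alpha = 1.9, lambda = 300, seed = 3)
  contaminated <- c(clean, rep(2000L, 500))
  r_dk <- classify_regime(contaminated)
  r_cr <- classify_regime(clean)
  expect_equal(r_dk$label, "dragon_king")
  expect_equal(r_cr$label, "critical")
  # both threshold conditions hold for the positive case
  expect_lt(r_dk$evidence$ccdf_at_tail, 1e-2)
  expect_gt(r_dk$evidence$max_deviation_ratio, 1.1)
  expect_lt(r_cr$evidence$max_deviation_ratio, 1.1)
})

test_that("the supercritical gate precedes the first-five drop", {
  # six entries: not supercritical even though the five dropped leave one
  r <- classify_regime(c(1, 1, 1, 1, 1, 7))
  expect_equal(r$label, "subcritical")
  # permuting the catalog never changes the supercritical count test
  withr::with_seed(8, {
    s <- rtpl(2000, 1.5, 50, seed = 9)
    l1 <- classify_regime(s)$label
    l2 <- classify_regime(c(s[6:2000], s[1:5]))$label
    expect_equal(l1, l2)
  })
})

test_that("dk_factor variants are a pure configuration change", {
  contaminated <- c(rtpl(1e5, alpha = 1.9, lambda = 300, seed = 3),
                    rep(2000L, 500))
  for (f in c(1.1, 1.3, 1.5)) {
    r <- classify_regime(contaminated, dk_factor = f)
    expect_equal(r$label, "dragon_king")
    expect_equal(r$evidence$dk_factor, f)
  }
})

test_that("size-duration scaling recovers exact and branching-process slopes", {
  # deterministic quadratic relation
  withr::with_seed(15, {
    d <- sample(1:60, 400, replace = TRUE)
    av <- tibble::tibble(start_t = seq_along(d), size = d^2, duration = d)
    sc <- size_duration_scaling(av)
    expect_equal(sc$gamma_fit, 2, tolerance = 1e-8)
  })
  # constant durations: no span
  av2 <- tibble::tibble(start_t = 1:200, size = 1:200,
                        duration = rep(4L, 200))
  expect_error(size_duration_scaling(av2), class = "socnet_spec_error")
  # critical Galton-Watson: observed slope near the crackling-noise prediction
  gw <- galton_watson_avalanches(15000, seed = 5, size_cap = 1e5)
  sc_gw <- size_duration_scaling(gw)
  expect_lt(abs(sc_gw$gamma_fit - sc_gw$gamma_pred), 0.3)
  expect_lt(abs(sc_gw$alpha - 1.5), 0.15)
})
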