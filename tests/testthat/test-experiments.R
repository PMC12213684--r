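test_that("phase sweep covers the grid with the requested replicates", {
  wc <- c(random = 2)
  sw <- run_phase_sweep("random", tau_grid = c(100, 200),
                        u_grid = c(0.2, 0.8), replicates = 2,
                        n = 200, t_max = 500, w_c = wc,
                        window = c(50, 500), seed = 1)
  expect_equal(nrow(sw), 8)
  counts <- dplyr::count(sw, tau, u)
  expect_true(all(counts$n == 2))
  expect_true(all(sw$w_c_used == 2))
  expect_true(all(is.na(sw$error)))
})

test_that("the reference grid yields 90 cells per network kind", {
  grid <- tidyr::expand_grid(tau = seq(100, 1000, by = 100),
                             u = seq(0.1, 0.9, by = 0.1))
  expect_equal(nrow(grid), 90)
})

test_that("sweeps are reproducible bit-for-bit and resumable", {
  wc <- c(random = 2, regular = 3)
  args <- list(kinds = c("random", "regular"), tau_grid = 150,
               u_grid = c(0.3, 0.6), n = 200, t_max = 400,
               w_c = wc, window = c(50, 400), seed = 7)
  a <- do.call(run_phase_sweep, args)
  b <- do.call(run_phase_sweep, args)
  expect_identical(a, b)
  # resume: previously computed rows are carried over unchanged
  c <- do.call(run_phase_sweep, c(args, list(done = a[1:2, ])))
  expect_identical(c, a)
})

test_that("per-cell seeds differ across cells and replicates", {
  s1 <- derive_seed(1, "random", 100, 0.5, 1)
  s2 <- derive_seed(1, "random", 100, 0.5, 2)
  s3 <- derive_seed(1, "regular", 100, 0.5, 1)
  expect_true(length(unique(c(s1, s2, s3))) == 3)
  expect_true(all(c(s1, s2, s3) > 0))
  expect_identical(s1, derive_seed(1, "random", 100, 0.5, 1))
})

test_that("ME replicates produce one deterministic row per run", {
  r <- run_me_replicates("random", tau = 150, u = 0.4, n_runs = 3,
                         n = 200, t_max = 400, w_c = 2,
                         window = c(50, 400), seed = 3)
  expect_equal(nrow(r), 3)
  expect_equal(r$run, 1:3)
  expect_equal(length(unique(r$seed)), 3)
  r2 <- run_me_replicates("random", tau = 150, u = 0.4, n_runs = 3,
                          n = 200, t_max = 400, w_c = 2,
                          window = c(50, 400), seed = 3)
  expect_identical(r, r2)
})

test_that("single characterization validates its window and returns the bundle", {
  expect_error(
    run_single_characterization("random", n = 100, t_max = 100,
                                w_c = 2, window = c(50, 500), seed = 1),
    class = "socnet_spec_error")
  ch <- run_single_characterization("random", tau = 200, u = 0.3, n = 300,
                                    t_max = 2000, w_c = 2, seed = 2)
  expect_s3_class(ch$trace, "soc_trace")
  expect_s3_class(ch$avalanches, "soc_avalanches")
  expect_s3_class(ch$regime, "soc_regime")
  expect_equal(ch$deviation$t_a, 200)
  expect_equal(ch$deviation$t_b, 2000)
  # no spontaneous seeding: no avalanches, subcritical/supercritical side
  ch0 <- run_single_characterization("random", n = 300, t_max = 2000,
                                     w_c = 2, lif = lif_params(p_spont = 0),
                                     seed = 3)
  expect_equal(nrow(ch0$avalanches), 0)
  expect_equal(ch0$regime$label, "supercritical")
})

test_that("sweep records per-cell failures without aborting", {
  # u inside (0,1) but t_max too small for the default window is caught
  expect_error(run_phase_sweep("random", 100, 0.5, n = 100, t_max = 10,
                               w_c = c(random = 2), window = c(50, 400),
                               seed = 1),
               class = "socnet_spec_error")
  expect_error(run_phase_sweep("random", 100, 1.5, n = 100, t_max = 400,
                               w_c = c(random = 2), seed = 1),
               class = "socnet_spec_error")
  # a genuinely failing cell (impossible initial strength) is recorded,
  # not propagated
  sw <- run_phase_sweep("random", 100, 0.5, n = 100, t_max = 400,
                        w_c = c(random = -1), window = c(50, 400), seed = 1)
  expect_equal(nrow(sw), 1)
  expect_false(is.na(sw$error))
  expect_true(is.na(sw$regime))
})

test_that("autoplot methods return ggplot objects", {
  net <- build_network("random", 300, 8, seed = 1)
  tr <- run_simulation(net, lif_params(p_spont = 1e-3),
                       plasticity_params(tau = 100, u = 0.5),
                       t_max = 2000, w_init = 2, seed = 1)
  av <- extract_avalanches(tr)
  expect_s3_class(autoplot(av), "ggplot")
  expect_s3_class(autoplot(tr, w_c = 2), "ggplot")
  wc <- estimate_critical_point(net, w_min = 1, w_max = 3, w_step = 0.5,
                                steps_per_w = 500, seed = 1)
  expect_s3_class(autoplot(wc), "ggplot")
  expect_s3_class(glance(wc), "tbl_df")
  sw <- run_phase_sweep("random", c(100, 200), c(0.3, 0.6), n = 200,
                        t_max = 400, w_c = c(random = 2),
                        window = c(50, 400), seed = 2)
  expect_s3_class(plot_phase_diagram(sw), "ggplot")
})
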