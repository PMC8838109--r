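test_that("gen_decay produces exact mono-exponentials at zero noise", {
  expect_equal(gen_decay(1, 1)$intensity, exp(-1), tolerance = 1e-12)
  expect_equal(gen_decay(1, 0)$intensity, 1.0, tolerance = 1e-12)
  crv <- gen_decay(2.5, c(0, 1, 2, 4, 8))
  expect_equal(crv$intensity, exp(-c(0, 1, 2, 4, 8) / 2.5), tolerance = 1e-12)
  expect_error(gen_decay(-1, 1), "positive")
  expect_error(gen_decay(1, numeric()), "non-empty")
})

test_that("noisy decay curves round-trip through fit_decay near the truth", {
  crv <- gen_decay(0.4, log_delays(), noise_sd = 0.02, seed = 7)
  est <- fit_decay(crv)$T1
  expect_equal(est, 0.4, tolerance = 0.02 / 0.4)  # 0.4 +/- 0.02 s
})

test_that("rate series follow the Arrhenius law exactly on both branches", {
  Rg <- spindyn_constants$R_gas
  slow <- gen_rate_series(ground_truth(30, A = 1), 250, "slow")
  expect_equal(log(slow$rate_s1), 30000 / (Rg * 250), tolerance = 1e-10)
  expect_equal(log(slow$rate_s1), 14.43, tolerance = 1e-3)
  fast <- gen_rate_series(ground_truth(30, A = 1), 250, "fast")
  expect_equal(log(fast$rate_s1), -30000 / (Rg * 250), tolerance = 1e-10)
  # E* = 0: rate = A at all temperatures
  flat <- gen_rate_series(ground_truth(0, A = 3.7), seq(220, 330, 10), "slow")
  expect_equal(flat$rate_s1, rep(3.7, 12), tolerance = 1e-12)
  # ln R vs 1/T exactly linear at zero noise
  rs <- gen_rate_series(ground_truth(12, A = 0.2), seq(230, 320, 5), "slow")
  fit <- lm(log(rate_s1) ~ I(1 / T_K), data = rs)
  expect_lt(suppressWarnings(summary(fit))$sigma, 1e-12)  # perfect fit by design
  expect_error(gen_rate_series(ground_truth(10), numeric()), "non-empty")
})

test_that("generators are bit-identical under a fixed seed and leave the RNG alone", {
  a <- gen_decay(1, log_delays(), 0.05, seed = 11)
  b <- gen_decay(1, log_delays(), 0.05, seed = 11)
  expect_identical(a$intensity, b$intensity)
  r1 <- gen_rate_series(ground_truth(20, 1, 0.02, seed = 5), seq(240, 300, 10), "slow")
  r2 <- gen_rate_series(ground_truth(20, 1, 0.02, seed = 5), seq(240, 300, 10), "slow")
  expect_identical(r1$rate_s1, r2$rate_s1)
  set.seed(99); before <- .Random.seed
  invisible(gen_decay(1, log_delays(), 0.05, seed = 11))
  expect_identical(.Random.seed, before)
})

test_that("estimator scatter grows with the generator noise level", {
  scatter <- sapply(c(0.01, 0.05, 0.15), function(ns) {
    est <- sapply(1:40, function(s) fit_decay(gen_decay(1, log_delays(), ns, seed = s))$T1)
    sd(est)
  })
  expect_true(all(diff(scatter) > 0))
})

test_that("Pake patterns obey the splitting convention and coverage check", {
  # convention-defining case: scale 1 -> splitting = D
  p <- gen_pake(13.5, scale = 1, lb = 0.05)
  expect_equal(extract_splitting(p)$splitting, 13.5, tolerance = 0.05 / 13.5)
  # Lee-Goldburg scaled: splitting = D / sqrt(3)
  p2 <- gen_pake(23.5, scale = lg_scale(), lb = 0.05)
  expect_equal(extract_splitting(p2)$splitting, 23.5 / sqrt(3), tolerance = 0.05 / 13.5)
  # linear scaling of the coupling: S2 = 1/3 motional averaging pre-scaling
  p3 <- gen_pake(13.5 / 3, scale = 1, lb = 0.05)
  expect_equal(extract_splitting(p3)$splitting, 4.5, tolerance = 0.05 / 4.5)
  expect_error(gen_pake(23.5, scale = 1, grid = seq(-10, 10, 0.05)), "cover")
  # 2:1 horn-to-shoulder structure of the eta = 0 powder average
  pp <- gen_pake(10, scale = 1, lb = 0.1)
  horn <- max(pp$intensity)
  foot <- pp$intensity[which.min(abs(pp$freq_kHz - 9.8))]
  expect_lt(foot, horn / 2)
})

test_that("two-site exchange lineshape has the correct slow and fast limits", {
  g <- seq(-200, 200, by = 0.25)
  slow <- gen_exchange_spectrum(exchange_pair(-50, 50, k = 0, T2 = 1), g)
  pk <- order(slow$intensity, decreasing = TRUE)[1:2]
  expect_setequal(round(sort(slow$freq_Hz[pk])), c(-50, 50))
  fast <- gen_exchange_spectrum(exchange_pair(-50, 50, k = 1e6, T2 = 1), g)
  expect_equal(fast$freq_Hz[which.max(fast$intensity)], 0, tolerance = 0.3)
  # unequal populations: fast limit collapses to the weighted mean
  fastw <- gen_exchange_spectrum(exchange_pair(-50, 50, k = 1e6, T2 = 1,
                                               populations = c(0.25, 0.75)), g)
  expect_equal(fastw$freq_Hz[which.max(fastw$intensity)], 25, tolerance = 0.5)
})

test_that("exchange doublet collapses at the classical coalescence rate", {
  # numeric sweep: the central local minimum disappears at k = pi*dnu/sqrt(2)
  g <- seq(-200, 200, by = 0.25)
  ks <- seq(180, 260, by = 2)
  has_min <- sapply(ks, function(k) {
    sp <- gen_exchange_spectrum(exchange_pair(-50, 50, k, T2 = 1), g)
    y0 <- sp$intensity[which.min(abs(sp$freq_Hz))]
    y0 < max(sp$intensity) * 0.999
  })
  k_coal <- ks[max(which(has_min))]
  expect_equal(k_coal, pi * 100 / sqrt(2), tolerance = 0.05)
})

test_that("DSC generator integrals and baseline steps match the requested truth", {
  flat <- gen_dsc(baseline_cp = 1.2, transitions = NULL)
  expect_equal(flat$signal, rep(1.2 * 10 / 60, nrow(flat)), tolerance = 1e-12)
  tr <- gen_dsc(transitions = data.frame(T_K = 272, dH_kJmol = 1.13, width_K = 1.5))
  expect_equal(integrate_peak(tr, c(262, 282)), 1.13, tolerance = 0.01 / 1.13)
  step <- data.frame(T_K = c(200, 271.999, 272.001, 320), cp = c(1.2, 1.2, 1.098, 1.098))
  trc <- gen_dsc(baseline_cp = step, mode = "cp")
  expect_equal(cp_step(trc, 272), 0.102, tolerance = 0.005 / 0.102)
  expect_warning(
    gen_dsc(transitions = data.frame(T_K = c(250, 251), dH_kJmol = c(1, 1), width_K = c(2, 2))),
    "overlap")
})

test_that("toy cells validate elements and produce consumable geometry", {
  empty <- gen_toy_cell(c(10, 10, 10))
  expect_equal(cell_volume(empty), 1000)
  one <- gen_toy_cell(c(10, 10, 10), data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_equal(nrow(one$sites), 1)
  pair <- gen_toy_cell(c(10, 10, 10),
                       data.frame(element = "O", x = c(0, 0.28), y = 0, z = 0))
  cl <- contacts(pair, "O", "O", 3.2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$dist_A, 2.80, tolerance = 1e-10)
  expect_error(gen_toy_cell(c(10, 10, 10), data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unknown element")
})

test_that("zero-noise generator outputs round-trip their parameters to 0.1%", {
  # decay -> T1
  est <- fit_decay(gen_decay(6.1, log_delays(12, 0.5, 30)))$T1
  expect_equal(est, 6.1, tolerance = 1e-3)
  # rate series -> E*
  fit <- arrhenius_fit(gen_rate_series(ground_truth(17.3, A = 0.01), seq(240, 300, 6), "slow"))
  expect_equal(fit$E_star, 17.3, tolerance = 1e-3)
  # Pake -> D (within one bin; sub-0.1% is not defined below the bin width)
  ex <- extract_splitting(gen_pake(18, scale = lg_scale(), lb = 0.05))
  expect_equal(ex$D_eff, 18, tolerance = 0.05 / (18 * lg_scale()))
  # DSC -> dH
  tr <- gen_dsc(transitions = data.frame(T_K = 260, dH_kJmol = 2.4, width_K = 2))
  expect_equal(integrate_peak(tr, c(248, 270)), 2.4, tolerance = 1e-3)
  # cell -> volume and distances
  cell <- gen_toy_cell(c(8, 9, 10, 90, 104, 90))
  expect_equal(cell_volume(cell), 8 * 9 * 10 * sin(104 * pi / 180), tolerance = 1e-10)
})
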