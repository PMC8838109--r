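test_that("fit_decay recovers T1 exactly on clean data and flags bad input", {
  # noiseless long-T1 curve (slow ester dynamics at low temperature)
  crv <- gen_decay(6.1, log_delays(12, 0.5, 30))
  expect_equal(fit_decay(crv)$T1, 6.1, tolerance = 1e-6)
  # an exact exponential through few points is still exact
  crv2 <- decay_curve(c(0, 0.5, 1, 2), exp(-c(0, 0.5, 1, 2)))
  expect_equal(fit_decay(crv2)$T1, 1, tolerance = 1e-8)
  expect_error(fit_decay(decay_curve(c(0, 1, 2), c(1, 0.5, 0.2))), "at least 4")
  expect_error(fit_decay(decay_curve(0:4, rep(1, 5))), "all equal")
})

test_that("fit_decay standard errors are calibrated against Monte-Carlo scatter", {
  est <- t(sapply(1:100, function(s) {
    f <- fit_decay(gen_decay(1, log_delays(), noise_sd = 0.05, seed = s))
    c(f$T1, f$stderr)
  }))
  expect_equal(mean(est[, 1]), 1, tolerance = 0.01)
  # reported stderr should match the empirical spread within ~30%
  expect_equal(mean(est[, 2]), sd(est[, 1]), tolerance = 0.3)
})

test_that("stretched-exponential option reduces to beta = 1 on pure exponentials", {
  crv <- gen_decay(0.8, log_delays())
  f <- fit_decay(crv, stretched = TRUE)
  expect_equal(f$beta, 1, tolerance = 1e-3)
  expect_equal(f$T1, 0.8, tolerance = 1e-3)
})

test_that("arrhenius_fit reproduces printed activation energies on both branches", {
  slow <- gen_rate_series(ground_truth(30.0, A = 1e-4), seq(240, 270, length.out = 8), "slow")
  fs <- arrhenius_fit(slow)
  expect_equal(fs$E_star, 30.0, tolerance = 1e-6)
  expect_identical(fs$branch, "slow")
  fast <- gen_rate_series(ground_truth(4.1, A = 2), seq(280, 330, length.out = 8), "fast")
  ff <- arrhenius_fit(fast)
  expect_equal(ff$E_star, 4.1, tolerance = 1e-6)
  expect_identical(ff$branch, "fast")
  # constant rates: zero activation energy, flagged
  const <- rate_series(seq(240, 300, 10), rep(0.5, 7))
  fc <- arrhenius_fit(const)
  expect_equal(fc$E_star, 0)
  expect_equal(fc$r_squared, 0)
  expect_true(fc$flat)
})

test_that("arrhenius_fit warns on windows spanning a rate maximum", {
  # cap-shaped series: fast branch at high T joined to slow branch at low T
  Tg <- seq(230, 310, 5)
  p <- sd_params(nu_C = 125, nu_H = 500)
  tau0 <- 8e-10 * exp(20000 / spindyn_constants$R_gas * (1 / Tg - 1 / 270))
  rates <- sapply(tau0, function(tc) { p$tau_c <- tc; bpp_rate(p) })
  expect_warning(arrhenius_fit(rate_series(Tg, rates)), "interior maximum|split")
})

test_that("zero-noise Arrhenius recovery is exact across random parameter draws", {
  set.seed(42)
  for (i in 1:20) {
    E <- runif(1, 2, 60); A <- 10^runif(1, -5, 2)
    br <- sample(c("slow", "fast"), 1)
    rs <- gen_rate_series(ground_truth(E, A), seq(230, 320, length.out = 9), br)
    fit <- arrhenius_fit(rs)
    expect_equal(fit$E_star, E, tolerance = 1e-3)
    expect_identical(fit$branch, br)
    expect_equal(fit$lnA, log(A), tolerance = 1e-6)
  }
})

test_that("noisy Arrhenius recovery stays within three standard errors", {
  hits <- sapply(1:200, function(s) {
    rs <- gen_rate_series(ground_truth(30, A = 1e-4, noise_sd = 0.02, seed = s),
                          seq(240, 270, length.out = 8), "slow")
    fit <- arrhenius_fit(rs)
    abs(fit$E_star - 30) <= 3 * fit$stderr_E
  })
  expect_gte(mean(hits), 0.95)
})

test_that("bpp_rate vanishes in extreme narrowing and peaks near omegaC tau = 0.79", {
  p <- sd_params(nu_C = 125, nu_H = 500)
  p$tau_c <- 1e-15
  expect_lt(bpp_rate(p), 1e-4)
  # dense-scan oracle for the lab-frame maximum
  taus <- 10^seq(-11, -7, length.out = 4000)
  pp <- sd_params(nu_C = 125, nu_H = 500); pp$tau_c <- taus
  rates <- bpp_rate(pp)
  tau_max <- taus[which.max(rates)]
  expect_equal(2 * pi * 125e6 * tau_max, 0.79, tolerance = 0.05)
  # unimodal and positive over the scan
  expect_true(all(rates > 0))
  d <- diff(rates)
  expect_equal(sum(diff(sign(d)) != 0), 1)  # one sign change of the derivative
})

test_that("methyl jump convention maps the observed T1 range onto the expected tau band", {
  mp <- methyl_jump_params(nu_C = 125, nu_H = 500)
  tau_hi <- invert_rate_to_tau(1 / 1.1, mp, branch = "fast")  # longest T1
  tau_lo <- invert_rate_to_tau(1 / 0.4, mp, branch = "fast")  # shortest T1
  expect_equal(tau_hi, 4.8e-11, tolerance = 0.25)
  expect_equal(tau_lo, 1.1e-10, tolerance = 0.25)
  expect_lt(tau_hi, tau_lo)
})

test_that("invert_rate_to_tau is the two-branch inverse of bpp_rate", {
  p <- sd_params(nu_C = 125, nu_H = 500)
  # round trip on the fast branch
  p$tau_c <- 1e-10
  r <- bpp_rate(p)
  expect_equal(invert_rate_to_tau(r, p, branch = "fast"), 1e-10, tolerance = 1e-6)
  # half-maximum rate: two distinct roots, both reproducing the input rate
  taus <- 10^seq(-12, -6, length.out = 2000)
  pp <- p; pp$tau_c <- taus
  rmax <- max(bpp_rate(pp))
  for (br in c("fast", "slow")) {
    tau <- invert_rate_to_tau(rmax / 2, p, branch = br)
    p2 <- p; p2$tau_c <- tau
    expect_equal(bpp_rate(p2), rmax / 2, tolerance = 1e-6)
  }
  t_f <- invert_rate_to_tau(rmax / 2, p, branch = "fast")
  t_s <- invert_rate_to_tau(rmax / 2, p, branch = "slow")
  expect_gt(t_s / t_f, 2)
  # at the maximum both branches coincide
  tm_f <- invert_rate_to_tau(rmax, p, branch = "fast")
  tm_s <- invert_rate_to_tau(rmax, p, branch = "slow")
  expect_equal(tm_f, tm_s, tolerance = 1e-4)
  # unreachable rate names the maximum
  expect_error(invert_rate_to_tau(rmax * 1.1, p), "maximum")
})

test_that("inversion round-trips hold across random correlation times on each branch", {
  set.seed(7)
  p <- sd_params(nu_C = 125, nu_H = 500)
  tmax <- spindyn:::.bpp_tau_max(p)
  for (i in 1:10) {
    tau <- 10^runif(1, -12, log10(tmax) - 0.05)
    p$tau_c <- tau
    expect_equal(invert_rate_to_tau(bpp_rate(p), p, branch = "fast"), tau, tolerance = 1e-6)
    tau_s <- 10^runif(1, log10(tmax) + 0.05, -6)
    p$tau_c <- tau_s
    expect_equal(invert_rate_to_tau(bpp_rate(p), p, branch = "slow"), tau_s, tolerance = 1e-6)
  }
})

test_that("rotating-frame matching rule returns the reciprocal spin-lock frequency", {
  expect_equal(r1rho_max_tau(62.5), 1.6e-5, tolerance = 1e-12)
  expect_equal(r1rho_max_tau(100), 1.0e-5, tolerance = 1e-12)
  expect_equal(r1rho_max_tau(50), 2.0e-5, tolerance = 1e-12)
  expect_error(r1rho_max_tau(0), "positive")
})

test_that("rotating-frame rates add a low-frequency term and shift the maximum", {
  p <- sd_params(nu_C = 125, nu_H = 500)
  p$tau_c <- 1e-5
  expect_gt(bpp_rate(p, frame = "rotating", spin_lock_nu = 62.5), bpp_rate(p))
  t_rot <- spindyn:::.bpp_tau_max(p, "rotating", 62.5)
  t_lab <- spindyn:::.bpp_tau_max(p, "lab")
  expect_gt(t_rot, t_lab)  # kHz probe is matched by much slower motion
})

test_that("correlation times classify onto the expected T1 branch", {
  p <- sd_params(nu_C = 125, nu_H = 500)
  expect_identical(classify_tau_branch(1e-10, p), "fast")
  expect_identical(classify_tau_branch(8e-9, p), "slow")
})
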