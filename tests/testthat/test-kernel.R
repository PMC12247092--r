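# Forward model: hyperfine spectrum, spectral-diffusion kernel (exact and
# approximate), transverse factor, and signal composition.

test_that("hyperfine spectrum is a normalized Gaussian with the stated scaling", {
  expect_equal(hyperfine_spectrum(0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  for (sg in c(0.3, 1, 2.5)) {
    om <- seq(-8 * sg, 8 * sg, length.out = 2001)
    expect_lt(abs(ihridme:::trapz(om, hyperfine_spectrum(om, sg)) - 1), 1e-6)
  }
  # scaling identity: rho_sigma(omega) = rho_1(omega/sigma) / sigma
  expect_equal(hyperfine_spectrum(2, 2), hyperfine_spectrum(1, 1) / 2,
               tolerance = 1e-12)
  expect_error(hyperfine_spectrum(0.5, -1), "positive")
  expect_warning(hyperfine_spectrum(seq(-2, 2, 0.1), 1.5), "narrower")
})

test_that("mixing-time law and transverse factor evaluate as stated", {
  kp <- kernel_params(kappa = 0.016, beta = 0.13)
  # deuterated water-glycerol value at the longest mixing time
  expect_equal(alpha_mixing(480, kp), 1 - exp(-0.245 * 0.016 * 480),
               tolerance = 1e-12)
  expect_equal(alpha_mixing(480, kp), 0.8477, tolerance = 1e-4)
  expect_equal(alpha_mixing(0, kp), 0)
  # monotone increasing, saturating at 1
  a <- alpha_mixing(seq(0, 5000, by = 100), kp)
  expect_true(all(diff(a) > 0))
  expect_lt(abs(a[length(a)] - 1), 1e-5)

  expect_equal(transverse_factor(2, 0.5, 0.13), exp(-0.13), tolerance = 1e-12)
  expect_equal(transverse_factor(1, 1, 0.13), exp(-0.13), tolerance = 1e-12)
  expect_true(all(transverse_factor(t_std, 0.7, 0) == 1))
  # sigma*t congruence
  expect_equal(transverse_factor(2 * 1.3, 0.4, 0.2),
               transverse_factor(1.3, 0.8, 0.2), tolerance = 1e-12)
})

test_that("approximate kernel limits: Tmix = 0 and full mixing", {
  kp <- kernel_params(kappa = 0.02)
  t <- t_std
  expect_true(all(ridme_kernel(t, 0, 0.5, kp) == 1))
  kp_fast <- kernel_params(kappa = 1e6)
  expect_equal(ridme_kernel(t, 1e6, 0.5, kp_fast), exp(-0.25 * t^2),
               tolerance = 1e-9)
})

test_that("magnetization spectrum: initial condition, stationarity, conservation", {
  # Tmix = 0 returns exp(i omega t) rho(omega)
  ev <- evolve_spectrum(t = 1.7, Tmix = 0, sigma = 0.8, kappa = 0.02)
  mu0 <- exp(1i * ev$omega * 1.7) * hyperfine_spectrum(ev$omega, 0.8)
  expect_lt(max(Mod(ev$mu - mu0)), 1e-12)
  # t = 0: mu = rho is stationary for any Tmix
  ev2 <- evolve_spectrum(t = 0, Tmix = 300, sigma = 0.8, kappa = 0.02)
  expect_lt(max(Mod(ev2$mu - hyperfine_spectrum(ev2$omega, 0.8))), 1e-8)
  expect_equal(ev2$R, 1, tolerance = 1e-8)
  # integral of mu conserved along the mixing block (tau = kappa Tmix = 1)
  ev3 <- evolve_spectrum(t = 1, Tmix = 50, sigma = 1, kappa = 0.02)
  expect_lt(ev3$conservation, 1e-6)
})

test_that("exact kernel: boundary values, monotonicity, master-curve congruence", {
  kp <- kernel_params(kappa = 0.02)
  expect_equal(ridme_kernel(0, 200, 0.6, kp, mode = "exact"), 1,
               tolerance = 1e-6)
  expect_true(all(ridme_kernel(t_std, 0, 0.6, kp, mode = "exact") == 1))
  R <- ridme_kernel(seq(0, 4, 0.1), 200, 0.6, kp, mode = "exact")
  expect_true(all(R >= -1 - 1e-9 & R <= 1 + 1e-9))
  expect_true(all(diff(R) <= 1e-9))
  # congruence: value depends on (sigma t, kappa Tmix) only
  combos <- list(c(0.5, 2.2, 0.02, 500), c(1.1, 1.0, 0.01, 1000),
                 c(0.8, 1.375, 0.05, 200))
  vals <- vapply(combos, function(cb)
    ridme_kernel(cb[2], cb[4], cb[1], kernel_params(cb[3]), mode = "exact"),
    numeric(1))
  expect_lt(max(abs(vals - vals[1])), 1e-3)
})

test_that("exact and approximate kernels agree within the documented band", {
  # achieved bound over sigma*t in [0, 3], kappa*Tmix in [0.1, 50]: 0.03
  sg <- seq(0, 3, by = 0.25)
  tg <- c(0.1, 0.5, 1, 2, 5, 10, 20, 50)
  R <- ihridme:::sd_master_solve(sg, tg)$R
  Ra <- exp(-outer(sg^2, 1 - exp(-0.245 * tg)))
  expect_lt(max(abs(R - Ra)), 0.03)
  # spot value (sigma t = 1, kappa Tmix = 10)
  r1 <- ihridme:::sd_master_solve(1, 10)$R[1, 1]
  expect_lt(abs(r1 - exp(-(1 - exp(-2.45)))), 0.03)
  # solver self-consistency: doubling the grid changes the kernel < 1e-4
  r_fine <- ihridme:::sd_master_solve(1, 10, nx = 1601, dtau0 = 0.005)$R[1, 1]
  expect_lt(abs(r1 - r_fine), 1e-4)
})

test_that("signal composition: V = R * F, closed form, heterogeneous limits", {
  kp <- kernel_params(kappa = 0.016, beta = 0.13)
  t <- t_std
  # beta = 0, Tmix = 0 -> V identically 1
  expect_true(all(ridme_signal(t, 0, 0.5, kernel_params(0.016)) == 1))
  # approx mode equals the closed form exp(-(alpha + beta) sigma^2 t^2)
  V <- ridme_signal(t, 120, 0.5, kp)
  expect_equal(V, exp(-(alpha_mixing(120, kp) + 0.13) * 0.25 * t^2),
               tolerance = 1e-14)
  # exact mode composes kernel and transverse factor
  Vx <- ridme_signal(t, 120, 0.5, kp, mode = "exact")
  expect_equal(Vx, ridme_kernel(t, 120, 0.5, kp, mode = "exact") *
                     transverse_factor(t, 0.5, 0.13), tolerance = 1e-12)

  # delta distribution reproduces the homogeneous signal
  d <- dist_delta(0.5, grid = seq(0, 1.5, length.out = 81))
  s_at <- d$sigma[which.max(d$p)]
  expect_equal(ridme_signal(t, 120, d, kp), ridme_signal(t, 120, s_at, kp),
               tolerance = 1e-10)
  # two-spike mixture is the arithmetic mean of the homogeneous signals
  g <- seq(0, 1.5, length.out = 81)
  w <- numeric(81); w[21] <- 1; w[41] <- 1
  mix <- density_distribution(g, w)
  Vmix <- ridme_signal(t, 120, mix, kp)
  expect_equal(Vmix, (ridme_signal(t, 120, g[21], kp) +
                      ridme_signal(t, 120, g[41], kp)) / 2, tolerance = 1e-10)
  # broad Gaussian: V(0) = 1 and monotone decreasing
  pg <- dist_gaussian(0.5, 0.18)
  Vg <- ridme_signal(t, 240, pg, kp)
  expect_equal(Vg[1], 1, tolerance = 1e-9)
  expect_true(all(diff(Vg) < 0))
})

test_that("multinuclear composition is a pointwise product on a common grid", {
  t <- t_std
  a <- exp(-0.3 * t^2); b <- exp(-0.1 * t^2)
  expect_equal(signal_product(a, b), exp(-0.4 * t^2), tolerance = 1e-14)
  expect_identical(signal_product(a), a)
  expect_equal(signal_product(a, rep(1, length(t))), a)
  expect_error(signal_product(a, b[-1]), "mismatched")
})
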