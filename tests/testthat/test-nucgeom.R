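# Structure-based sigma: point-dipole couplings, shell model, powder
# averaging, cloud model, ensembles and cutoff scanning.

test_that("point-dipole coupling: magic angle, axial value, angular average", {
  ma <- acos(1 / sqrt(3))
  r <- c(sin(ma), 0, cos(ma))
  expect_lt(abs(point_dipole(r, "1H")), 1e-12)
  # proton on the field axis at 1 nm: |A| = 2 * prefactor ~ 0.994 angular MHz
  expect_equal(abs(point_dipole(c(0, 0, 1), "1H")), 2 * hyperfine_prefactor("1H"),
               tolerance = 1e-12)
  expect_equal(abs(point_dipole(c(0, 0, 1), "1H")), 0.994, tolerance = 1e-3)
  # <(1 - 3 cos^2)^2> over uniform field directions = 4/5; by symmetry this
  # equals the average over uniformly oriented unit vectors at fixed field
  U <- ihridme:::fibonacci_sphere(4000)
  A2 <- mean(point_dipole(U, "1H", field = c(0, 0, 1))^2)
  expect_equal(A2, 4 / 5 * hyperfine_prefactor("1H")^2, tolerance = 1e-3)
  expect_error(point_dipole(c(0, 0, 0), "1H"), "zero-length")
})

test_that("sigma of a configuration follows the variance identity", {
  # single nucleus at the magic angle
  ma <- acos(1 / sqrt(3))
  cfg <- nuclear_config(matrix(c(sin(ma), 0, cos(ma)), 1))
  expect_lt(sigma_config(cfg), 1e-12)
  # closed form for A = (1, 2), I = 1/2: sigma^2 = 1.25
  sg <- sqrt(0.5 * 1.5 / 3 * sum(c(1, 2)^2))
  expect_equal(sg^2, 1.25, tolerance = 1e-12)
  # exact agreement with state enumeration for random configurations
  for (n in c(3, 6, 10)) {
    cfg <- nuclear_config(random_cluster(n, seed = n))
    A <- point_dipole(cfg$coords, cfg$iso, cfg$field)
    expect_equal(sigma_config(cfg)^2, hyperfine_states(A)$var,
                 tolerance = 1e-12)
  }
})

test_that("shell constant and analytic shell formula", {
  expect_equal(shell_constant("1H"), 0.222, tolerance = 0.005 / 0.222)
  # sigma scales as sqrt(CH)
  expect_equal(sigma_shell(1.2, 2 * 10), sqrt(2) * sigma_shell(1.2, 10),
               tolerance = 1e-12)
  expect_error(sigma_shell(-1, 10), "R must be")
  # Monte-Carlo cross-check: uniform protons in [R, 10 R], orientation
  # averaged, against the closed form truncated at the outer radius
  set.seed(11)
  R_in <- 1; R_out <- 10; dens <- 5   # nm^-3
  n <- round(dens * 4 / 3 * pi * (R_out^3 - R_in^3))
  pts <- matrix(stats::rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) *
    (stats::runif(n, R_in^3 / R_out^3, 1) * R_out^3)^(1 / 3)
  s2 <- mean(ihridme:::sigma_orientations(pts, ihridme:::fibonacci_sphere(100))^2)
  s2_formula <- sigma_shell(R_in, dens)^2 - sigma_shell(R_out, dens)^2
  expect_equal(sqrt(s2), sqrt(s2_formula), tolerance = 0.03)
})

test_that("orientation averaging: isotropy, Pake limit, rotation invariance", {
  # thick isotropic shell: near-delta histogram
  set.seed(5)
  n <- 3000
  pts <- matrix(stats::rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * (1 + 2 * stats::runif(n)^(1 / 3))
  oa <- orientation_average(nuclear_config(pts), n = 200)
  expect_lt(stats::sd(oa$sigma) / mean(oa$sigma), 0.05)

  # single nucleus: sigma spans zero (magic angle) to the axial maximum
  cfg1 <- nuclear_config(matrix(c(0, 0, 1), 1))
  oa1 <- orientation_average(cfg1, n = 2000)
  A_max <- abs(point_dipole(c(0, 0, 1), "1H"))
  expect_lt(min(oa1$sigma) / max(oa1$sigma), 0.05)
  expect_equal(max(oa1$sigma), sqrt(0.25 * A_max^2), tolerance = 5e-3)

  # global rotation leaves the sigma samples' distribution unchanged
  cfg <- nuclear_config(random_cluster(20, seed = 9))
  th <- 0.7
  Rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cfg_rot <- nuclear_config(cfg$coords %*% t(Rot))
  m1 <- orientation_average(cfg, n = 1500)$sigma
  m2 <- orientation_average(cfg_rot, n = 1500)$sigma
  expect_equal(mean(m1), mean(m2), tolerance = 1e-3)
  expect_equal(stats::sd(m1), stats::sd(m2), tolerance = 1e-2)
  expect_error(orientation_average(cfg, n = 10), ">= 50")
})

test_that("cloud model: proton count, Pake-like far limit, point-dipole limit", {
  cm <- cloud_model(d = 6, R = 1.5, CH = 20, n_theta = 181, seed = 4)
  expect_equal(cm$n_protons, 170)
  # the magic-angle dip: sigma drops far below its axial maximum; the
  # residual floor is set by the angular spread of the cloud (~ R/(d sqrt(5)))
  # and vanishes in the point-cloud limit d >> R
  expect_lt(min(cm$sigma), 0.2 * max(cm$sigma))
  cm_far <- cloud_model(d = 30, R = 1.5, CH = 20, n_theta = 181, seed = 4)
  expect_lt(min(cm_far$sigma), 0.05 * max(cm_far$sigma))
  expect_lt(min(cm_far$sigma) / max(cm_far$sigma),
            min(cm$sigma) / max(cm$sigma))
  # d >> R: sigma(theta) proportional to |1 - 3 cos^2 theta| of the centre
  cm2 <- cloud_model(d = 30, R = 1.5, CH = 20, n_theta = 41, seed = 4)
  shape <- abs(1 - 3 * cos(cm2$theta)^2)
  ratio <- cm2$sigma / (shape * max(cm2$sigma) / max(shape))
  ok <- shape > 0.3   # away from the magic-angle zero
  expect_lt(max(abs(ratio[ok] - 1)), 0.1)
})

test_that("ensemble p(sigma): cutoff monotonicity and broadening by close protons", {
  ens <- toy_ensemble(15, n_chains = 4, beads_per_chain = 8, seed = 21)
  pr_all <- ensemble_sigma(ens, r_cut = 0, n_orientations = 100)
  # a cutoff beyond every proton zeroes sigma
  pr_far <- ensemble_sigma(ens, r_cut = 50, n_orientations = 100)
  expect_true(all(pr_far$sigma == 0))
  # mean sigma is non-increasing in r_cut
  rc <- c(0, 0.5, 1.0, 1.5, 2.0)
  mns <- vapply(rc, function(r)
    mean(ensemble_sigma(ens, r, n_orientations = 100)$sigma), numeric(1))
  expect_true(all(diff(mns) <= 1e-12))
  # including close protons shifts p(sigma) up and broadens it
  st_close <- distribution_stats(ensemble_sigma(ens, 0.5, 100)$distribution)
  st_far <- distribution_stats(ensemble_sigma(ens, 2.0, 100)$distribution)
  expect_gt(st_close[["mean"]], st_far[["mean"]])
  expect_gt(st_close[["sd"]], st_far[["sd"]])
})

test_that("cutoff scan recovers a planted cutoff and is smooth", {
  ens <- toy_ensemble(12, n_chains = 5, beads_per_chain = 8, seed = 33)
  target <- ensemble_sigma(ens, r_cut = 1.2, n_orientations = 80)$distribution
  sc <- cutoff_scan(ens, target, n_orientations = 80)
  expect_equal(sc$r_cut, seq(0.5, 2.0, by = 0.05))   # default grid
  expect_lte(abs(sc$r_cut_opt - 1.2), 0.05)
  # smoothness: adjacent RMSD changes below half the curve range
  expect_lt(max(abs(diff(sc$rmsd))), 0.5 * diff(range(sc$rmsd)) + 1e-12)
})

test_that("nuclear moment ratios and isotope scaling of sigma", {
  expect_equal(moment_ratio("1H", "19F"), 1.06, tolerance = 0.01)
  expect_equal(moment_ratio("1H", "13C"), 3.98, tolerance = 0.01 * 3.98)
  expect_equal(moment_ratio("1H", "31P"), 2.47, tolerance = 0.01 * 2.47)
  expect_equal(sigma_isotope_scaling("1H", "1H"), 1)
  expect_equal(sigma_isotope_scaling("1H", "13C"),
               (1 / moment_ratio("1H", "13C"))^(11 / 8), tolerance = 1e-12)
  expect_equal(sigma_isotope_scaling("1H", "13C"), 0.150, tolerance = 0.01)
  expect_equal(sigma_isotope_scaling("1H", "19F", density_ratio = 2),
               2 * sigma_isotope_scaling("1H", "19F"), tolerance = 1e-12)
})
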