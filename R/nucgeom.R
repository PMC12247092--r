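# Structure-based prediction of the hyperfine spectrum width sigma and its
# distribution p(sigma): point-dipole couplings, the variance identity
# sigma^2 = I(I+1)/3 sum A_j^2, the analytic uniform-shell formula,
# powder (orientation) averaging, the anisotropic proton-cloud model, and
# cutoff-radius scanning for coordinate ensembles.

#' Electron-relative nuclear configuration
#'
#' @param coords Matrix (n x 3) of nuclear coordinates relative to the
#'   electron spin, nm.
#' @param iso Isotope label or object shared by all nuclei (default `"1H"`).
#' @param field Magnetic-field direction (default +z); normalized
#'   internally.
#' @return Object of class `"nuclear_config"`.
#' @export
nuclear_config <- function(coords, iso = "1H", field = c(0, 0, 1)) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  r <- sqrt(rowSums(coords^2))
  if (any(r == 0)) stop("no nucleus may sit at the electron position")
  field <- field / sqrt(sum(field^2))
  structure(list(coords = coords, iso = isotope(iso), field = field),
            class = "nuclear_config")
}

#' Secular point-dipole hyperfine coupling
#'
#' `A = (hbar mu0 gamma_e gamma_n / 4 pi) (1 - 3 cos^2 theta) / r^3` in
#' angular MHz, with `theta` the angle between the electron-nucleus vector
#' and the field direction. Vanishes at the magic angle
#' `arccos(1/sqrt(3))`.
#'
#' @param r_vec Electron-nucleus vector(s): length-3 vector or n x 3
#'   matrix, nm.
#' @param iso Isotope label or object.
#' @param field Field direction (normalized internally).
#' @return Coupling(s) in angular MHz (signed).
#' @export
point_dipole <- function(r_vec, iso = "1H", field = c(0, 0, 1)) {
  r_vec <- matrix(as.numeric(r_vec), ncol = 3)
  r <- sqrt(rowSums(r_vec^2))
  if (any(r == 0)) stop("zero-length electron-nucleus vector")
  field <- field / sqrt(sum(field^2))
  cth <- drop(r_vec %*% field) / r
  hyperfine_prefactor(iso) * (1 - 3 * cth^2) / r^3
}

#' Hyperfine spectrum width of a nuclear configuration
#'
#' `sigma = sqrt( I(I+1)/3 * sum_j A_j^2 )` for a fixed field direction;
#' exact under the ergodicity assumption (all nuclear spin states equally
#' weighted), as can be verified against explicit enumeration with
#' [hyperfine_states()].
#'
#' @param config A [nuclear_config()].
#' @param field Optional field direction overriding the one in `config`.
#' @return sigma in angular MHz.
#' @export
sigma_config <- function(config, field = NULL) {
  stopifnot(inherits(config, "nuclear_config"))
  if (is.null(field)) field <- config$field
  A <- point_dipole(config$coords, config$iso, field)
  I <- config$iso$I
  sqrt(I * (I + 1) / 3 * sum(A^2))
}

#' Analytic uniform-shell width
#'
#' Closed-form width for nuclei uniformly distributed from radius `R` to
#' infinity at number density `CH`:
#' `sigma^2 = (4 pi / 3) B^2 CH / R^3` with `B` from [shell_constant()].
#'
#' @param R Inner radius, nm (> 0).
#' @param CH Number density, nm^-3 (use
#'   `sigma_concentration(x, "molar", "density")` for molar input).
#' @param iso Isotope (default protons).
#' @return sigma in angular MHz.
#' @export
sigma_shell <- function(R, CH, iso = "1H") {
  if (any(R <= 0)) stop("R must be > 0")
  if (any(CH < 0)) stop("CH must be >= 0")
  B <- shell_constant(iso)
  sqrt(4 * pi / 3 * B^2 * CH / R^3)
}

# quasi-uniform deterministic point set on the unit sphere (Fibonacci
# lattice) -- reproducible powder grids without seeds
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# sigma for every row of a direction matrix U (n x 3); vectorized core
sigma_orientations <- function(coords, U, iso = "1H") {
  iso <- isotope(iso)
  r <- sqrt(rowSums(coords^2))
  rhat <- coords / r
  pref <- hyperfine_prefactor(iso)
  C2 <- (U %*% t(rhat))^2                       # cos^2 theta, n_dir x N
  term <- (1 - 3 * C2)^2 %*% (1 / r^6)          # sum_j (1-3c^2)^2 / r^6
  sqrt(iso$I * (iso$I + 1) / 3 * pref^2 * drop(term))
}

#' Powder average of the hyperfine spectrum width
#'
#' Evaluates sigma of a configuration over a quasi-uniform spherical grid
#' of field directions (deterministic Fibonacci lattice) and returns the
#' samples together with a normalized histogram p(sigma).
#'
#' @param config A [nuclear_config()].
#' @param n Number of field directions (>= 50).
#' @param breaks Histogram breaks (passed to [hist()]; default 40 bins).
#' @return List with `sigma` (samples, one per direction), `directions`,
#'   and `distribution` (a [density_distribution()]).
#' @export
orientation_average <- function(config, n = 400, breaks = 40) {
  stopifnot(inherits(config, "nuclear_config"))
  if (n < 50) stop("n must be >= 50 for a meaningful powder average")
  U <- fibonacci_sphere(n)
  s <- sigma_orientations(config$coords, U, config$iso)
  list(sigma = s, directions = U,
       distribution = sigma_histogram(s, breaks = breaks))
}

# histogram of sigma samples (optionally weighted) as a density_distribution
sigma_histogram <- function(s, weights = NULL, breaks = 40) {
  if (is.null(weights)) weights <- rep(1, length(s))
  rng <- range(s)
  if (diff(rng) == 0) rng <- rng + c(-1, 1) * max(1e-6, abs(rng[1]) * 1e-3)
  br <- if (length(breaks) == 1L) seq(rng[1], rng[2], length.out = breaks + 1L) else breaks
  idx <- findInterval(s, br, rightmost.closed = TRUE, all.inside = TRUE)
  w <- vapply(seq_len(length(br) - 1L), function(k) sum(weights[idx == k]),
              numeric(1))
  mid <- (br[-1] + br[-length(br)]) / 2
  density_distribution(mid, w / diff(br))
}

#' Anisotropic proton-cloud model
#'
#' A spherical cloud of protons of radius `R` and local concentration `CH`
#' with its centre at distance `d` from the electron spin. The number of
#' protons is the deterministic rounding of `CH * V_sphere`; positions are
#' drawn uniformly inside the sphere. The cloud orientation angle `theta`
#' (between the field and the electron-centre vector; the azimuth is
#' irrelevant by cylindrical symmetry) is swept over `[0, pi]` and sigma is
#' computed at each angle; the histogram is weighted by `sin(theta)` so it
#' represents isotropic powder statistics (disable with
#' `sin_weight = FALSE`). For `d` much larger than `R` the distribution
#' approaches half of a Pake pattern and touches zero near the magic angle.
#'
#' @param d Electron-centre distance, nm.
#' @param R Cloud radius, nm.
#' @param CH Local proton concentration, mol L^-1.
#' @param n_theta Number of theta samples (default 181).
#' @param seed Optional RNG seed for the proton placement.
#' @param sin_weight Weight the histogram by sin(theta) (default TRUE).
#' @param breaks Histogram breaks.
#' @return List with `theta`, `sigma` (per angle), `n_protons`, and
#'   `distribution`.
#' @export
cloud_model <- function(d, R, CH, n_theta = 181, seed = NULL,
                        sin_weight = TRUE, breaks = 40) {
  if (d < 0 || R <= 0 || CH < 0) stop("invalid cloud geometry")
  if (!is.null(seed)) set.seed(seed)
  dens <- sigma_concentration(CH, "molar", "density")   # nm^-3
  n_p <- round(dens * 4 / 3 * pi * R^3)
  # uniform points in the sphere
  pts <- matrix(stats::rnorm(3 * n_p), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R * stats::runif(n_p)^(1 / 3)
  theta <- seq(0, pi, length.out = n_theta)
  # equivalent view: field fixed along +z, cloud centre rotated in the xz
  # plane by theta
  s <- vapply(theta, function(th) {
    centre <- d * c(sin(th), 0, cos(th))
    coords <- sweep(pts, 2, centre, `+`)
    sigma_orientations(coords, matrix(c(0, 0, 1), 1), "1H")
  }, numeric(1))
  w <- if (sin_weight) sin(theta) else rep(1, n_theta)
  list(theta = theta, sigma = s, n_protons = n_p,
       distribution = sigma_histogram(s, weights = w, breaks = breaks))
}

#' Ensemble prediction of p(sigma)
#'
#' Converts a coordinate ensemble into a distribution of hyperfine spectrum
#' widths: per conformer, protons closer to the electron than the cutoff
#' radius (the spin-diffusion-blocked zone) are excluded, sigma is
#' evaluated over a spherical grid of field directions, and all
#' (conformer, orientation) samples are pooled into a histogram.
#'
#' @param ensemble A `ridme_ensemble` (see [toy_ensemble()],
#'   [read_ensemble()]).
#' @param r_cut Cutoff radius, nm: protons with `|r| < r_cut` are dropped.
#'   A conformer losing all protons contributes sigma = 0.
#' @param n_orientations Field directions per conformer (default 200).
#' @param breaks Histogram breaks for the pooled samples.
#' @return List of class `"ensemble_prediction"` with `sigma` (matrix
#'   conformers x orientations), `r_cut`, and `distribution`.
#' @export
ensemble_sigma <- function(ensemble, r_cut = 0, n_orientations = 200,
                           breaks = 40) {
  U <- fibonacci_sphere(n_orientations)
  S <- t(vapply(ensemble, function(cf) {
    coords <- sweep(cf$protons, 2, cf$electron, `-`)
    r <- sqrt(rowSums(coords^2))
    coords <- coords[r >= r_cut, , drop = FALSE]
    if (nrow(coords) == 0) return(rep(0, n_orientations))
    sigma_orientations(coords, U, "1H")
  }, numeric(n_orientations)))
  structure(list(sigma = S, r_cut = r_cut,
                 distribution = sigma_histogram(as.numeric(S), breaks = breaks)),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  st <- distribution_stats(x$distribution)
  cat(sprintf(
    "Ensemble p(sigma) at r_cut = %g nm: mean %.4f, sd %.4f angular MHz\n",
    x$r_cut, st["mean"], st["sd"]))
  invisible(x)
}

#' Cutoff-radius scan against a target distribution
#'
#' Recomputes the ensemble p(sigma) for each candidate cutoff radius and
#' compares it to a target distribution (e.g. the fitted experimental one)
#' by RMSD on the target's sigma grid. Ties are broken towards the smaller
#' cutoff.
#'
#' @param ensemble A `ridme_ensemble`.
#' @param target A [density_distribution()].
#' @param r_cut Candidate cutoffs, nm (default 0.5 to 2.0 in 0.05 steps).
#' @param n_orientations Field directions per conformer.
#' @return List of class `"cutoff_scan"` with `r_cut`, `rmsd`,
#'   `r_cut_opt`, and the optimal prediction.
#' @export
cutoff_scan <- function(ensemble, target, r_cut = seq(0.5, 2.0, by = 0.05),
                        n_orientations = 200) {
  stopifnot(inherits(target, "density_distribution"))
  if (length(r_cut) < 1L) stop("empty cutoff grid")
  grid <- target$sigma
  br <- c(grid[1] - diff(grid[1:2]) / 2,
          grid + c(diff(grid) / 2, diff(grid)[length(grid) - 1] / 2))
  preds <- lapply(r_cut, function(rc) {
    pr <- ensemble_sigma(ensemble, r_cut = rc, n_orientations = n_orientations)
    s <- pmin(pmax(as.numeric(pr$sigma), br[1]), br[length(br)])
    pr$distribution <- sigma_histogram(s, breaks = br)
    pr
  })
  rmsd <- vapply(preds, function(pr)
    sqrt(mean((pr$distribution$p - target$p)^2)), numeric(1))
  best <- which(rmsd <= min(rmsd) + 1e-15)[1]
  structure(list(r_cut = r_cut, rmsd = rmsd, r_cut_opt = r_cut[best],
                 prediction = preds[[best]], target = target),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("Cutoff-radius scan over [%g, %g] nm: optimum r_cut = %g nm (RMSD %.3e)\n",
              min(x$r_cut), max(x$r_cut), x$r_cut_opt, min(x$rmsd)))
  invisible(x)
}

#' @export
plot.cutoff_scan <- function(x, ...) {
  graphics::plot(x$r_cut, x$rmsd, type = "b", xlab = "r_cut (nm)",
                 ylab = "RMSD", ...)
  graphics::abline(v = x$r_cut_opt, lty = 2)
  invisible(x)
}
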