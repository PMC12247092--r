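# Physical constants (CODATA 2018) used throughout the package.
# Internal unit convention: angular frequencies in 10^6 rad s^-1 (written
# "angular MHz"), times in microseconds, distances in nm. Phases are then
# simply A * t without 2*pi factors.

.const <- list(
  hbar    = 1.054571817e-34,   # J s
  mu0     = 1.25663706212e-6,  # N A^-2
  gamma_e = 1.76085963023e11,  # rad s^-1 T^-1, electron gyromagnetic ratio (magnitude)
  NA_mol  = 6.02214076e23      # mol^-1
)

# Gyromagnetic ratios, rad s^-1 T^-1 (CODATA / standard NMR tables).
.isotopes <- list(
  "1H"  = list(symbol = "1H",  I = 0.5, gamma = 2.6752218744e8),
  "2H"  = list(symbol = "2H",  I = 1.0, gamma = 4.10662791e7),
  "13C" = list(symbol = "13C", I = 0.5, gamma = 6.728284e7),
  "19F" = list(symbol = "19F", I = 0.5, gamma = 2.518148e8),
  "31P" = list(symbol = "31P", I = 0.5, gamma = 1.08394e8)
)

#' Isotope properties
#'
#' Returns spin quantum number, gyromagnetic ratio, and derived magnetic
#' moment scale for the magnetic isotopes known to the package.
#'
#' @param symbol Isotope label, e.g. `"1H"`, `"13C"`, `"19F"`, `"31P"`.
#' @return A list of class `"isotope"` with elements `symbol`, `I` (spin
#'   quantum number), `gamma` (rad s^-1 T^-1) and `mu` (magnetic moment
#'   scale `gamma * hbar * sqrt(I (I + 1))`, J T^-1).
#' @examples
#' isotope("1H")$gamma / isotope("13C")$gamma
#' @export
isotope <- function(symbol) {
  if (inherits(symbol, "isotope")) return(symbol)
  iso <- .isotopes[[match.arg(symbol, names(.isotopes))]]
  if (iso$I <= 0) stop("isotope has no magnetic moment: ", symbol)
  iso$mu <- iso$gamma * .const$hbar * sqrt(iso$I * (iso$I + 1))
  class(iso) <- "isotope"
  iso
}

#' Point-dipole hyperfine prefactor
#'
#' The electron-nuclear point-dipole prefactor `hbar mu0 gamma_e gamma_n / 4 pi`
#' in angular MHz nm^3. For protons this is approximately 0.497: a proton at
#' 1 nm on the field axis has |A| = 2 * 0.497 angular MHz.
#'
#' @param iso An isotope label or object (default `"1H"`).
#' @return Prefactor in 10^6 rad s^-1 nm^3.
#' @export
hyperfine_prefactor <- function(iso = "1H") {
  iso <- isotope(iso)
  pref <- .const$hbar * .const$mu0 * .const$gamma_e * iso$gamma / (4 * pi)
  pref / (1e6 * 1e-27)  # rad s^-1 m^3 -> 1e6 rad s^-1 nm^3
}

# Internuclear (homonuclear) dipolar prefactor, angular MHz nm^3.
dipolar_prefactor <- function(iso = "1H") {
  iso <- isotope(iso)
  pref <- .const$hbar * .const$mu0 * iso$gamma^2 / (4 * pi)
  pref / (1e6 * 1e-27)
}

#' Shell-model constant B
#'
#' Constant of the analytic uniform-shell variance formula
#' `sigma^2(R, Inf) = (4 pi / 3) B^2 C R^-3`:
#' `B = |hbar mu0 gamma_e gamma_n / 4 pi| * sqrt(4 I (I + 1) / 15)`,
#' about 0.222 angular MHz nm^3 for protons.
#'
#' @inheritParams hyperfine_prefactor
#' @return B in 10^6 rad s^-1 nm^3.
#' @export
shell_constant <- function(iso = "1H") {
  iso <- isotope(iso)
  hyperfine_prefactor(iso) * sqrt(4 * iso$I * (iso$I + 1) / 15)
}

#' Nuclear magnetic moment ratio
#'
#' Ratio `mu_a / mu_b` of the magnetic moment scales of two isotopes; for
#' equal spin quantum numbers this equals the ratio of gyromagnetic ratios.
#'
#' @param a,b Isotope labels or objects.
#' @export
moment_ratio <- function(a, b) {
  isotope(a)$mu / isotope(b)$mu
}

# Empirical calibration sigma / C_H for water-glycerol glass, in MHz per
# mol L^-1 (treated as an opaque calibration constant).
.sigma_per_molar <- 0.0215
# 1 mol L^-1 = 0.60221 nm^-3
.nm3_per_molar <- .const$NA_mol * 1e-24

#' Convert between hyperfine spectrum width and proton concentration
#'
#' Linear calibration between the hyperfine spectrum width sigma and the
#' local proton concentration, `sigma = f * C`, with
#' f = 0.0215 MHz L mol^-1 when the concentration is molar, or
#' f = 0.0215 / 0.60221 = 0.0357 MHz nm^3 when the number density
#' (nm^-3) is used.
#'
#' @param x Numeric values to convert (non-negative).
#' @param from,to One of `"sigma"` (MHz), `"molar"` (mol L^-1),
#'   `"density"` (nm^-3).
#' @return Converted values.
#' @examples
#' sigma_concentration(1, from = "molar", to = "sigma")   # 0.0215 MHz
#' sigma_concentration(16.1, from = "molar", to = "sigma")
#' @export
sigma_concentration <- function(x, from = c("sigma", "molar", "density"),
                                to = c("molar", "sigma", "density")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (any(x < 0)) stop("negative values cannot be converted")
  # express in sigma (MHz) first
  s <- switch(from,
    sigma = x,
    molar = x * .sigma_per_molar,
    density = x / .nm3_per_molar * .sigma_per_molar
  )
  switch(to,
    sigma = s,
    molar = s / .sigma_per_molar,
    density = s / .sigma_per_molar * .nm3_per_molar
  )
}

#' Isotope scaling of the hyperfine spectrum width
#'
#' For a uniform nuclear bath the width scales as
#' `sigma proportional to |mu_nuc|^(11/8) * C_n`; the ratio
#' `sigma_b / sigma_a` for two isotopes at a density ratio `C_b / C_a`
#' follows directly.
#'
#' @param a,b Isotope labels or objects (reference and target).
#' @param density_ratio `C_b / C_a` (default 1).
#' @return The width ratio `sigma_b / sigma_a`.
#' @examples
#' sigma_isotope_scaling("1H", "13C")  # about 0.150
#' @export
sigma_isotope_scaling <- function(a, b, density_ratio = 1) {
  ma <- isotope(a)$mu
  mb <- isotope(b)$mu
  if (ma == 0 || mb == 0) stop("zero magnetic moment")
  (mb / ma)^(11 / 8) * density_ratio
}

# trapezoid rule (used throughout; grids need not be uniform)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# trapezoid quadrature weights on a grid
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}
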