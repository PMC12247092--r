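# Synthetic trace sets and toy conformational ensembles: the numerical
# test bed for the forward model and the inversion.

#' Simulate an ih-RIDME trace set
#'
#' Generates forward-model traces
#' `V(t; Tmix) = integral K(sigma t; Tmix) p(sigma) dsigma * F(t)` for a
#' series of mixing times and adds centred Gaussian white noise at the
#' requested per-trace signal-to-noise ratio `SNR = V(0) / rms(noise)`.
#' Noise is added to the raw (pre-division) traces, so the noise doubling of
#' reference-divided data emerges naturally. Optionally a zero-time
#' echo-crossing-like spike growing with the mixing time is injected for
#' normalization-window tests.
#'
#' @param sigma Scalar width (angular MHz) or a [density_distribution()].
#' @param t Time grid (default 201 points on 0-4 us).
#' @param Tmix Mixing times in microseconds (default 30, 60, 120, 240,
#'   480; the smallest is the reference).
#' @param params [kernel_params()] (default kappa = 0.016 /us,
#'   beta = 0.13: water-glycerol-like spectral diffusion).
#' @param snr Signal-to-noise ratio (`Inf` for noise-free).
#' @param seed Optional RNG seed for reproducible noise.
#' @param mode Kernel mode (`"approx"` default).
#' @param artifact Optional zero-time artifact spec:
#'   `list(width, amplitude)` adds
#'   `amplitude * (Tmix / max(Tmix)) * exp(-(t / width)^2)` to each trace.
#' @param d1,d2 Static delays stored as metadata (default 0.4 and 4.2 us).
#' @return A normalized [trace_set()].
#' @export
simulate_traceset <- function(sigma, t = seq(0, 4, length.out = 201),
                              Tmix = c(30, 60, 120, 240, 480),
                              params = kernel_params(kappa = 0.016, beta = 0.13),
                              snr = Inf, seed = NULL,
                              mode = c("approx", "exact"),
                              artifact = NULL, d1 = 0.4, d2 = 4.2) {
  mode <- match.arg(mode)
  if (!is.infinite(snr) && snr <= 0) stop("snr must be > 0 or Inf")
  if (!is.null(seed)) set.seed(seed)
  V <- vapply(Tmix, function(Tm)
    ridme_signal(t, Tm, sigma, params, mode = mode), numeric(length(t)))
  if (!is.null(artifact)) {
    spike <- exp(-(t / artifact$width)^2)
    for (j in seq_along(Tmix))
      V[, j] <- V[, j] + artifact$amplitude * (Tmix[j] / max(Tmix)) * spike
  }
  if (is.finite(snr)) {
    V <- V + matrix(stats::rnorm(length(V), sd = 1 / snr), nrow = nrow(V))
  }
  trace_set(t, V, Tmix, d1 = d1, d2 = d2,
            normalized = is.infinite(snr) && is.null(artifact))
}

#' Toy conformational ensemble of pseudo-proton chains
#'
#' Generates an anisotropic stand-in for a flexible spin-labelled molecule:
#' free random-walk chains of pseudo-protons anchored on one side of a fixed
#' electron position. Chains are anchored on a hemisphere of radius
#' `anchor_radius` around +z, so the proton cloud is one-sided by
#' construction, which makes the orientation-averaged p(sigma) broad.
#'
#' @param n_conformers Number of conformers.
#' @param n_chains Chains per conformer.
#' @param beads_per_chain Pseudo-protons per chain.
#' @param bond_length Step length of the random walk (nm, default 0.15).
#' @param anchor_radius Distance of chain anchors from the electron (nm).
#' @param seed Optional RNG seed.
#' @return List of class `"ridme_ensemble"`: one element per conformer,
#'   each with `electron` (position, origin) and `protons`
#'   (matrix n x 3, nm).
#' @export
toy_ensemble <- function(n_conformers, n_chains = 4, beads_per_chain = 10,
                         bond_length = 0.15, anchor_radius = 0.8,
                         seed = NULL) {
  if (n_conformers < 1 || n_chains < 1 || beads_per_chain < 1)
    stop("counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  conf <- lapply(seq_len(n_conformers), function(ic) {
    pts <- matrix(NA_real_, n_chains * beads_per_chain, 3)
    row <- 1L
    for (ch in seq_len(n_chains)) {
      # anchor on the +z hemisphere
      u <- stats::rnorm(3)
      u[3] <- abs(u[3])
      pos <- anchor_radius * u / sqrt(sum(u^2))
      for (b in seq_len(beads_per_chain)) {
        step <- stats::rnorm(3)
        pos <- pos + bond_length * step / sqrt(sum(step^2))
        pts[row, ] <- pos
        row <- row + 1L
      }
    }
    list(electron = c(0, 0, 0), protons = pts)
  })
  structure(conf, class = "ridme_ensemble")
}

#' @export
print.ridme_ensemble <- function(x, ...) {
  np <- vapply(x, function(cf) nrow(cf$protons), integer(1))
  cat("Coordinate ensemble:", length(x), "conformers,",
      paste(range(np), collapse = "-"), "protons each\n")
  invisible(x)
}
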