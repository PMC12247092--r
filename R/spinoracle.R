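# Exact density-matrix simulation of the ih-RIDME sequence for small
# electron-nuclear spin systems, and exact enumeration of the hyperfine
# spectrum. Dense complex algebra on the 2^(N+1)-dimensional product space;
# this is a desk-scale validation oracle for the statistical model, not a
# production simulator.

.pauli <- list(
  x = matrix(c(0, 1, 1, 0), 2) / 2,
  y = matrix(c(0, 1i, -1i, 0), 2) / 2,
  z = matrix(c(1, 0, 0, -1), 2) / 2,
  plus = matrix(c(0, 0, 1, 0), 2),
  minus = matrix(c(0, 1, 0, 0), 2),
  id = diag(2)
)

# operator op acting on spin `pos` out of `n` spin-1/2 particles
# (position 1 = electron)
single_spin_op <- function(op, pos, n) {
  m <- matrix(1 + 0i, 1, 1)
  for (k in seq_len(n)) {
    m <- kronecker(m, if (k == pos) op else .pauli$id)
  }
  m
}

#' Electron-nuclear spin system
#'
#' Builds the explicit Hamiltonians of one electron spin 1/2 coupled to N
#' nuclear spins 1/2: the secular hyperfine term
#' `H_hf = sum_j A_j Sz Iz_j` and the homonuclear dipolar flip-flop term
#' `H_dd = sum_{j != k} w_jk (1/2 Iz_j Iz_k - 1/4 I+_j I-_k)`.
#' Couplings can be given explicitly or derived from a
#' [nuclear_config()] via the point-dipole formula (electron-nuclear for
#' `A_j`, internuclear for `w_jk`, same angular-frequency convention).
#'
#' @param A Hyperfine couplings, angular MHz (or omit and pass `config`).
#' @param omega_dd Symmetric matrix of nuclear dipolar couplings, angular
#'   MHz (default all 0).
#' @param config Optional [nuclear_config()] from which `A` and
#'   `omega_dd` are computed.
#' @return Object of class `"spin_system"` with fields `A`, `omega_dd`,
#'   `N`, `dim`, and the Hamiltonian matrices `H_hf`, `H_dd`.
#' @export
spin_system <- function(A = NULL, omega_dd = NULL, config = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "nuclear_config"))
    A <- point_dipole(config$coords, config$iso, config$field)
    n <- length(A)
    omega_dd <- matrix(0, n, n)
    pref <- dipolar_prefactor(config$iso)
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      rv <- config$coords[j, ] - config$coords[k, ]
      r <- sqrt(sum(rv^2))
      cth <- sum(rv * config$field) / r
      omega_dd[j, k] <- omega_dd[k, j] <- pref * (1 - 3 * cth^2) / r^3
    }
  }
  N <- length(A)
  if (N < 1) stop("at least one nucleus required")
  if (N > 12) stop("N = ", N, " nuclei exceed the dense-matrix limit (dimension 2^13)")
  if (is.null(omega_dd)) omega_dd <- matrix(0, N, N)
  omega_dd <- (omega_dd + t(omega_dd)) / 2
  diag(omega_dd) <- 0

  n_sp <- N + 1L
  dim <- 2L^n_sp
  Sz <- single_spin_op(.pauli$z, 1, n_sp)
  H_hf <- matrix(0i, dim, dim)
  for (j in seq_len(N)) {
    H_hf <- H_hf + A[j] * (Sz %*% single_spin_op(.pauli$z, j + 1, n_sp))
  }
  H_dd <- matrix(0i, dim, dim)
  if (any(omega_dd != 0)) {
    for (j in seq_len(N)) for (k in seq_len(N)) {
      if (j == k || omega_dd[j, k] == 0) next
      Izj <- single_spin_op(.pauli$z, j + 1, n_sp)
      Izk <- single_spin_op(.pauli$z, k + 1, n_sp)
      Ipj <- single_spin_op(.pauli$plus, j + 1, n_sp)
      Imk <- single_spin_op(.pauli$minus, k + 1, n_sp)
      H_dd <- H_dd + omega_dd[j, k] * (0.5 * (Izj %*% Izk) - 0.25 * (Ipj %*% Imk))
    }
  }
  structure(list(A = A, omega_dd = omega_dd, N = N, dim = dim,
                 H_hf = H_hf, H_dd = H_dd),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("Spin system: electron + ", x$N, " nuclei (dimension ", x$dim, ")\n",
      sep = "")
  cat("  A (angular MHz):", paste(signif(x$A, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Exact hyperfine spectrum by enumeration
#'
#' Enumerates the hyperfine field `omega_hf = sum_j A_j m_j` over all 2^N
#' nuclear Zeeman product states (`m_j = +/- 1/2`) with equal weights. Its
#' variance equals `(1/4) sum A_j^2`, the spin-1/2 case of the closed-form
#' variance identity used by [sigma_config()].
#'
#' @param A Hyperfine couplings (angular MHz), or a `spin_system`.
#' @return List with `omega` (2^N offsets), `mean`, `var`, `sd`.
#' @export
hyperfine_states <- function(A) {
  if (inherits(A, "spin_system")) A <- A$A
  N <- length(A)
  if (N > 20) stop("enumeration limited to N <= 20")
  omega <- 0
  for (j in seq_len(N)) omega <- as.numeric(outer(omega, c(-0.5, 0.5) * A[j], `+`))
  m <- mean(omega)
  v <- mean((omega - m)^2)
  list(omega = omega, mean = m, var = v, sd = sqrt(v))
}

# matrix exponential exp(-i H t) for Hermitian H via eigendecomposition;
# returns a function of t
propagator_factory <- function(H) {
  if (all(H == 0)) {
    d <- nrow(H)
    return(function(t) diag(d) + 0i)
  }
  e <- eigen(H, symmetric = TRUE)
  V <- e$vectors
  lam <- e$values
  function(t) V %*% (exp(-1i * lam * t) * Conj(t(V)))
}

#' Exact ih-RIDME simulation
#'
#' Propagates the electron coherence through the five-pulse sequence
#' (preparation echo, pi/2 - Tmix - pi/2 mixing block, detection echo) with
#' ideal instantaneous pulses and the full Hamiltonian `H_hf + H_dd`, or
#' hyperfine-only evolution in the transverse blocks
#' (`transverse = "hf"`), which realizes the stationary-bath approximation
#' of the statistical model. The initial state is electron coherence with
#' unpolarized nuclei (high-temperature limit); the detected quantity is
#' `tr(Sx sigma3)`, normalized to its `t = 0` value.
#'
#' Electron coherence present during the mixing block is discarded and the
#' two storage quadratures (mixing pulses about x and about y) are summed:
#' this is the coherence-pathway selection that phase cycling performs in
#' the experiment, and it makes the simulated observable the polarization-
#' storage signal `< cos((omega - omega') t) >` that the magnetization-
#' spectrum model describes.
#'
#' @param sys A [spin_system()].
#' @param t Incremented delay grid, microseconds.
#' @param Tmix Mixing time, microseconds.
#' @param d1,d2 Static delays, microseconds (d2 must exceed `max(t)`).
#' @param transverse `"full"` (default) or `"hf"`: Hamiltonian during the
#'   preparation and detection blocks.
#' @param mixing `"full"` (default) or `"hf"`: Hamiltonian during the
#'   mixing block (with `"hf"` there is no spectral diffusion and the
#'   decay is flat).
#' @param normalize Normalize to V(0) (default TRUE).
#' @return Numeric vector V(t).
#' @export
simulate_ridme <- function(sys, t, Tmix, d1 = 0.4, d2 = 4.2,
                           transverse = c("full", "hf"),
                           mixing = c("full", "hf"), normalize = TRUE) {
  stopifnot(inherits(sys, "spin_system"))
  transverse <- match.arg(transverse)
  mixing <- match.arg(mixing)
  if (any(t < 0) || Tmix < 0 || d1 < 0 || d2 <= 0) stop("delays must be >= 0")
  if (max(t) > d2) stop("t may not exceed d2 (echo runs out of the detection window)")

  n_sp <- sys$N + 1L
  half <- 2L^sys$N
  H_full <- sys$H_hf + sys$H_dd
  H_trans <- if (transverse == "full") H_full else sys$H_hf
  H_mix <- if (mixing == "full") H_full else sys$H_hf
  U_t <- propagator_factory(H_trans)
  U_mix <- propagator_factory(H_mix)(Tmix)

  Sx <- single_spin_op(.pauli$x, 1, n_sp)
  pulse <- function(op, theta) {
    single_spin_op(cos(theta / 2) * .pauli$id - 2i * sin(theta / 2) * op,
                   1, n_sp)
  }
  P180 <- pulse(.pauli$x, pi)
  P90 <- list(x = pulse(.pauli$x, pi / 2), y = pulse(.pauli$y, pi / 2))

  rho0 <- Sx / 2^sys$N   # electron coherence, unpolarized nuclei
  Ud1 <- U_t(d1)
  Ud2 <- U_t(d2)
  sandwich <- function(U, rho) U %*% rho %*% Conj(t(U))
  # drop electron coherence (off-diagonal electron blocks) during mixing
  zstore <- function(rho) {
    rho[seq_len(half), half + seq_len(half)] <- 0
    rho[half + seq_len(half), seq_len(half)] <- 0
    rho
  }
  echo <- function(tt) {
    s1 <- sandwich(U_t(d1 + tt) %*% P180 %*% Ud1, rho0)
    v <- 0
    for (ph in c("y", "x")) {
      s2 <- zstore(sandwich(P90[[ph]], s1))
      s2 <- sandwich(P90[[ph]], sandwich(U_mix, s2))
      s3 <- sandwich(Ud2 %*% P180 %*% U_t(d2 - tt), s2)
      v <- v + Re(sum(diag(Sx %*% s3)))
    }
    v
  }
  V <- vapply(t, echo, numeric(1))
  if (normalize) V <- V / echo(0)
  V
}
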