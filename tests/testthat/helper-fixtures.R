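# Shared fixtures: water-glycerol-like kernel parameters and the standard
# mixing-time series used by the numerical experiments.
kp_std <- kernel_params(kappa = 0.016, beta = 0.13)
Tmix_std <- c(30, 60, 120, 240, 480)
t_std <- seq(0, 4, length.out = 201)

# a small reproducible nuclear cluster at a given centre distance (nm)
random_cluster <- function(n, centre = c(1, 0, 0.3), spread = 0.12, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = spread), ncol = 3) +
    matrix(rep(centre, each = n), ncol = 3)
}
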