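# shared fixtures: an SDS-like conductivity setup (the well-characterized
# anionic-surfactant case) and generating parameter sets for every property
# kind, used by round-trip and recovery tests

sds_params <- function() {
  c(cmc = 8.099, r = 0.112, a = 66.74, b = 26.43, kappa_s = 0)
}

sds_curve <- function(n = 50, noise = NULL) {
  simulate_curve("conductivity", sds_params(),
                 grid = list(type = "linear", min = 0.1, max = 16.2, n = n),
                 noise = noise)
}

# one generating parameter set per property kind, with a sensible grid
kind_setups <- function() {
  list(
    conductivity = list(
      params = sds_params(),
      grid = list(type = "linear", min = 0.1, max = 16.2, n = 60)),
    molar_conductivity = list(
      params = c(cmc = 8.099, r = 0.112, a = 66.74, b = 26.43),
      grid = list(type = "linear", min = 0.4, max = 24, n = 60)),
    surface_tension = list(
      params = c(cmc = 1, r = 0.1, gamma0 = 72, st_coeff = 10, k_ad = 50),
      grid = list(type = "linear", min = 0.05, max = 3, n = 60)),
    nmr = list(
      params = c(cmc = 8.1, r = 0.11, delta_free = 1.2, delta_mic = 0.8),
      grid = list(type = "linear", min = 0.4, max = 24, n = 60)),
    fluorescence = list(
      params = c(cmc = 0.27, r = 0.15, k = 37, f_free = 0.1, f_bound = 1),
      grid = list(type = "log", min = 0.0135, max = 0.81, n = 60)),
    pyrene_ratio = list(
      params = c(cmc = 0.27, r = 0.16, c = 148, sr_free = 0.45,
                 sr_bound = 0.98),
      grid = list(type = "log", min = 0.0135, max = 0.81, n = 60)),
    absorbance = list(
      params = c(cmc = 0.27, r = 0.108, eps_free = 1.1, eps_mic = 1.6,
                 path = 1),
      grid = list(type = "linear", min = 0.0135, max = 0.81, n = 60)),
    absorbance_ratio = list(
      params = c(cmc = 0.27, r = 0.108, q1 = 0.8, qm = 1.3, qa = 1.2),
      grid = list(type = "linear", min = 0.0135, max = 0.81, n = 60)),
    fcs_diffusion = list(
      params = c(cmc = 0.27, r = 0.15, k = 37, d_free = 400, d_bound = 60),
      grid = list(type = "log", min = 0.0135, max = 0.81, n = 60)),
    aggregation = list(
      params = c(cac = 90, r = 0.36),
      grid = list(type = "log", min = 4.5, max = 270, n = 60))
  )
}

# double numerical integration of the Gaussian curvature: builds [S1] from
# the Gaussian second derivative alone, anchored at the plateau [S1] -> cmc,
# by cumulative trapezoids on a fine grid. Independent of the closed form.
s1_by_double_integration <- function(s0_max, cmc, r, amp, n = 6e5) {
  sig <- r * cmc
  L <- max(s0_max, cmc + 13 * sig)
  u <- seq(0, L, length.out = n)
  g <- -amp * exp(-(u - cmc)^2 / (2 * sig^2)) / (sqrt(2 * pi) * sig)
  G <- pracma::cumtrapz(u, g)       # int_0^t g
  s1p <- G - G[n]                   # slope, zero at the top of the grid
  H <- pracma::cumtrapz(u, s1p)
  s1 <- cmc - (H[n] - H)            # plateau anchored at cmc
  list(u = u, s1 = as.numeric(s1))
}
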