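# Property forward models: limiting values, conservation identities,
# monotonicity between the two plateaus, and the conductivity-width
# relations between the Gaussian and Boltzmann transition models.

mic_sds <- function(r = 0.112, n = NULL) micellization_params(8.099, r, n = n)

test_that("conductivity reduces to the two limiting straight lines", {
  p <- conductivity_params(a = 66.74, b = 26.43, kappa_s = 1.5, mic = mic_sds())
  expect_equal(conductivity(0, p), 1.5)
  # Table-2-like parameters: slope well above the cmc approaches b
  slope <- (conductivity(16, p) - conductivity(15, p)) / 1
  expect_equal(slope, 26.43, tolerance = 0.005)
  # piecewise-linear limit below the break
  p0 <- conductivity_params(66.74, 26.43, 1.5, mic = micellization_params(8.099, 1e-9))
  s0 <- seq(0, 0.9 * 8.099, length.out = 20)
  expect_identical(conductivity(s0, p0), 66.74 * s0 + 1.5)
  # r = 1e-3: two straight lines within 1e-6 of dynamic range away from break
  p1 <- conductivity_params(66.74, 26.43, 1.5, mic = mic_sds(r = 1e-3))
  s0 <- seq(0, 16.2, length.out = 400)
  away <- abs(s0 - 8.099) > 0.1
  k1 <- 66.74 * s0 + 1.5
  k2 <- 66.74 * 8.099 + 26.43 * (s0 - 8.099) + 1.5
  expected <- ifelse(s0 < 8.099, k1, k2)
  rng <- diff(range(conductivity(s0, p1)))
  expect_lt(max(abs(conductivity(s0, p1) - expected)[away]) / rng, 1e-6)
})

test_that("molar conductivity falls monotonically from a to b", {
  p <- conductivity_params(66.74, 26.43, 0, mic = mic_sds(r = 0.01))
  expect_equal(molar_conductivity(0.05, p), 66.74, tolerance = 1e-6)
  expect_equal(molar_conductivity(1e5, p), 26.43, tolerance = 1e-3)
  lam <- molar_conductivity(seq(0.5, 40, length.out = 200),
                            conductivity_params(66.74, 26.43, 0, mic = mic_sds()))
  expect_true(all(diff(lam) <= 1e-12))
  expect_error(molar_conductivity(0, p), "> 0")
})

test_that("Boltzmann conductivity model: limits, midpoint slope, overflow", {
  p <- carpena_params(a = 66.74, b = 26.43, kappa_s = 2, cmc = 8.099,
                      delta = 0.52)
  expect_equal(carpena_conductivity(0, p), 2)
  # asymptotic slope above the cmc is b
  sl <- (carpena_conductivity(100, p) - carpena_conductivity(99, p))
  expect_equal(sl, 26.43, tolerance = 1e-8)
  # differential conductivity at the cmc is the sigmoid midpoint (a+b)/2
  h <- 1e-5
  dmid <- (carpena_conductivity(8.099 + h, p) -
             carpena_conductivity(8.099 - h, p)) / (2 * h)
  expect_equal(dmid, (66.74 + 26.43) / 2, tolerance = 1e-6)
  # log-sum-exp keeps sharp transitions finite far above the cmc
  psharp <- carpena_params(66.74, 26.43, 0, cmc = 8.099, delta = 1e-3)
  expect_true(is.finite(carpena_conductivity(1e4, psharp)))
  expect_error(carpena_params(66.74, 26.43, 0, cmc = 8.099, delta = 0),
               "delta")
})

test_that("equal-slope width ratio is 4/sqrt(2*pi), confirmed numerically", {
  expect_identical(equal_slope_width_ratio(), 4 / sqrt(2 * pi))
  expect_equal(round(equal_slope_width_ratio(), 2), 1.60)
  # Boltzmann-side curvature at the cmc is (b - a)/(4*delta)
  p <- carpena_params(a = 60, b = 30, kappa_s = 0, cmc = 5, delta = 0.4)
  h <- 1e-3
  d2 <- (carpena_conductivity(5 + h, p) - 2 * carpena_conductivity(5, p) +
           carpena_conductivity(5 - h, p)) / h^2
  expect_equal(d2, (30 - 60) / (4 * 0.4), tolerance = 1e-4)
})

test_that("best-fit width ratio is ~1.75 and scale invariant", {
  grid <- seq(0, 16.2, length.out = 200)
  ratio <- best_fit_width_ratio(8.099, 0.112, grid)
  expect_equal(ratio, 1.75, tolerance = 0.05 / 1.75)
  # dimensionless: rescaling all concentrations by 10 changes nothing
  ratio10 <- best_fit_width_ratio(80.99, 0.112, grid * 10)
  expect_equal(ratio10, ratio, tolerance = 1e-6)
  # across widths the ratio stays within the reported 1.5-1.8 band
  for (r in c(0.05, 0.1, 0.2, 0.3)) {
    rr <- best_fit_width_ratio(8.099, r, seq(0, 16.2, length.out = 200))
    expect_gt(rr, 1.5)
    expect_lt(rr, 1.8)
  }
})

test_that("matched conductivity and Boltzmann curves nearly coincide", {
  # with sigma/delta = 1.75 the two models differ by < 0.3% of dynamic range
  s0 <- seq(0, 2 * 8.099, length.out = 400)
  pm <- conductivity_params(66.74, 26.43, 0, mic = mic_sds())
  pc <- carpena_params(66.74, 26.43, 0, cmc = 8.099,
                       delta = 0.112 * 8.099 / 1.75)
  km <- conductivity(s0, pm)
  kc <- carpena_conductivity(s0, pc)
  expect_lt(max(abs(km - kc)) / diff(range(km)), 0.003)
})

test_that("surface tension: solvent limit and monomer plateau", {
  mic <- micellization_params(1, 0.01)
  p <- surface_tension_params(gamma0 = 72, st_coeff = 8, k_ad = 100, mic = mic)
  expect_equal(surface_tension(0, p), 72)
  p0 <- surface_tension_params(72, 8, k_ad = 0, mic = mic)
  expect_identical(surface_tension(c(0, 0.5, 2, 5), p0), rep(72, 4))
  # micelles are not surface active: gamma flat above the cmc
  expect_lt(abs(surface_tension(2, p) - surface_tension(5, p)), 1e-6)
  expect_error(surface_tension_params(-1, 8, 1, mic), "gamma0")
})

test_that("NMR shift interpolates between monomer and micelle shifts", {
  mic <- micellization_params(8, 0.05)
  p <- nmr_params(delta_free = 1.2, delta_mic = 0.8, mic = mic)
  expect_equal(nmr_shift(0.1, p), 1.2, tolerance = 1e-9)
  expect_equal(nmr_shift(1e5, p), 0.8, tolerance = 1e-3)
  # equal species populations give the arithmetic mean of the shifts
  s_eq <- uniroot(function(s) monomer_concentration(s, mic) - s / 2,
                  c(8, 30))$root
  expect_equal(nmr_shift(s_eq, p), 1.0, tolerance = 1e-6)
  expect_error(nmr_shift(0, p), "> 0")
})

test_that("dye fractions partition exactly", {
  expect_equal(dye_fractions(0, 5), list(x_free = 1, x_bound = 0))
  expect_equal(dye_fractions(1, 1), list(x_free = 0.5, x_bound = 0.5))
  expect_equal(dye_fractions(3, 1), list(x_free = 0.25, x_bound = 0.75))
  m <- seq(0, 10, length.out = 50)
  fr <- dye_fractions(m, 2.3)
  expect_identical(fr$x_free + fr$x_bound, rep(1, 50))
  expect_error(dye_fractions(-1, 1), ">= 0")
})

test_that("fluorescence: plateaus and composite/per-micelle equivalence", {
  mic <- micellization_params(0.27, 0.01, n = 100)
  p <- dye_binding_params(f_free = 0.1, f_bound = 1, k_bind = 3000, mic = mic)
  expect_equal(fluorescence_intensity(0.1, p), 0.1, tolerance = 1e-9)
  expect_equal(fluorescence_intensity(1e5, p), 1, tolerance = 1e-3)
  pc <- dye_binding_params(0.1, 1, k_bind_per_surfactant = 3000 / 100,
                           mic = mic)
  s0 <- seq(0.01, 1, length.out = 40)
  expect_equal(fluorescence_intensity(s0, pc), fluorescence_intensity(s0, p),
               tolerance = 1e-12)
  expect_error(
    dye_binding_params(0.1, 1, k_bind = 10,
                       mic = micellization_params(0.27, 0.1)),
    "aggregation number")
})

test_that("pyrene spectral ratio spans its two limits", {
  mic <- micellization_params(0.27, 0.16, n = 100)
  p <- pyrene_ratio_params(sr_free = 0.45, sr_bound = 0.98, c_bind = 3000,
                           mic = mic)
  expect_equal(pyrene_spectral_ratio(0.001, p), 0.45, tolerance = 1e-4)
  expect_equal(pyrene_spectral_ratio(1e5, p), 0.98, tolerance = 1e-3)
  # midpoint identity at c*[M] = 1 with the TX100 band-ratio values
  m_mid <- 1 / 3000
  s_mid <- uniroot(function(s)
    (s - monomer_concentration(s, mic)) / 100 - m_mid, c(0.27, 10),
    tol = 1e-12)$root
  expect_equal(pyrene_spectral_ratio(s_mid, p), (0.45 + 0.98) / 2,
               tolerance = 1e-6)
  expect_equal((0.45 + 0.98) / 2, 0.715)
})

test_that("absorbance is linear in the species concentrations", {
  mic <- micellization_params(0.27, 0.108)
  p <- absorbance_params(eps_free = c(1.1, 0.9), eps_mic = c(1.6, 0.8),
                         path = 2, mic = mic)
  expect_equal(absorbance(0, p, 1), 0)
  s0 <- seq(0.05, 1, length.out = 30)
  s1 <- monomer_concentration(s0, mic)
  expect_equal(absorbance(s0, p, 2),
               (s1 * 0.9 + (s0 - s1) * 0.8) * 2, tolerance = 1e-14)
  # equal coefficients degenerate to a straight line
  pe <- absorbance_params(c(1.3), c(1.3), path = 2, mic = mic)
  expect_equal(absorbance(s0, pe, 1), 1.3 * 2 * s0, tolerance = 1e-12)
  expect_error(absorbance(s0, p, 3), "wavelength")
})

test_that("absorbance ratio interpolates between q1 and qm", {
  mic <- micellization_params(0.27, 0.05)
  p <- absorbance_params(1, 1, q1 = 0.8, qm = 1.3, qa = 1.2, mic = mic)
  expect_equal(absorbance_ratio(0.01, p), 0.8, tolerance = 1e-8)
  expect_equal(absorbance_ratio(1e4, p), 1.3, tolerance = 1e-3)
  pq <- absorbance_params(1, 1, q1 = 1.05, qm = 1.05, qa = 0.7, mic = mic)
  s0 <- seq(0.05, 2, length.out = 25)
  expect_equal(absorbance_ratio(s0, pq), rep(1.05, 25), tolerance = 1e-12)
})

test_that("mean diffusion falls from the free to the bound coefficient", {
  mic <- micellization_params(0.27, 0.15, n = 100)
  p <- diffusion_params(d_free = 400, d_bound = 60, k_bind = 3000, mic = mic)
  expect_equal(mean_diffusion(0.01, p), 400, tolerance = 0.5)
  expect_equal(mean_diffusion(1e5, p), 60, tolerance = 0.5)
  m_mid <- 1 / 3000
  s_mid <- uniroot(function(s)
    (s - monomer_concentration(s, mic)) / 100 - m_mid, c(0.27, 10),
    tol = 1e-12)$root
  expect_equal(mean_diffusion(s_mid, p), (400 + 60) / 2, tolerance = 1e-4)
  expect_error(diffusion_params(60, 400, k_bind = 1, mic = mic), "d_free")
})

test_that("aggregated fraction rises from 0 to 1 through ~0.14 at the cac", {
  p <- aggregation_params(cac = 90, r = 0.36)
  expect_lt(aggregated_fraction(1, p), 0.01)
  expect_equal(aggregated_fraction(1e6, p), 1, tolerance = 1e-3)
  # closed form (A/2)*sqrt(2/pi)*r at the critical point, frozen: 0.1435768
  expect_equal(aggregated_fraction(90, p), 0.1435768, tolerance = 1e-6)
  expect_error(aggregated_fraction(0, p), "> 0")
})

test_that("sigmoidal properties are bounded and monotone in the micelle load", {
  setups <- kind_setups()
  for (kind in c("fluorescence", "pyrene_ratio", "absorbance_ratio",
                 "fcs_diffusion")) {
    su <- setups[[kind]]
    x <- seq(su$params[["cmc"]] * 0.05, su$params[["cmc"]] * 20,
             length.out = 300)
    y <- forward_model(kind, x, su$params)
    lims <- switch(kind,
      fluorescence = su$params[c("f_free", "f_bound")],
      pyrene_ratio = su$params[c("sr_free", "sr_bound")],
      absorbance_ratio = su$params[c("q1", "qm")],
      fcs_diffusion = su$params[c("d_free", "d_bound")])
    expect_true(all(y >= min(lims) - 1e-9 & y <= max(lims) + 1e-9),
                label = paste(kind, "bounded"))
    expect_true(all(diff(y) * sign(lims[2] - lims[1]) >= -1e-12),
                label = paste(kind, "monotone"))
  }
})
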