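# Concentration model: amplitude normalization, monomer/micelle closed forms,
# derivatives, degrees of micellization, and equivalence with the
# double-integration construction the closed form is derived from.

test_that("amplitude matches its limits and the double-integration oracle", {
  # near 1 for narrow transitions; exp underflow is silent for tiny r
  expect_equal(round(amplitude(0.4), 2), 1.00)
  expect_lt(abs(amplitude(0.01) - 1), 1e-15)
  expect_identical(amplitude(1e-4), 1)
  # frozen from bisection on the normalization constant that makes the
  # double-integrated Gaussian model give zero monomer at zero concentration
  # (helper s1_by_double_integration; oracle value 0.9230921436)
  expect_equal(amplitude(1.0), 0.9230921, tolerance = 1e-7)
  expect_error(amplitude(0), "> 0")
  expect_error(amplitude(-0.1), "> 0")
})

test_that("monomer concentration obeys normalization, plateau and 4% anchors", {
  p <- micellization_params(cmc = 1, r = 0.1)
  expect_lt(abs(monomer_concentration(0, p)), 1e-12)
  expect_lt(abs(monomer_concentration(100, p) - 1), 1e-12)
  # at the cmc only ~4% of the surfactant is micellized (r = 0.1)
  expect_equal(monomer_concentration(1, p), 0.960, tolerance = 1e-3)
  expect_error(monomer_concentration(-1, p), ">= 0")
  # scale invariance in (cmc, sigma)
  p2 <- micellization_params(cmc = 8.099, r = 0.1)
  s0 <- c(0.3, 0.9, 1, 1.4, 3)
  expect_equal(monomer_concentration(s0 * 8.099, p2) / 8.099,
               monomer_concentration(s0, p), tolerance = 1e-12)
})

test_that("normalization identity holds across a 50-point r grid", {
  for (r in seq(0.01, 1, length.out = 50)) {
    p <- micellization_params(cmc = 2.5, r = r)
    expect_lt(abs(monomer_concentration(0, p)), 1e-12 * 2.5)
  }
})

test_that("species profile conserves mass and forms micelle concentrations", {
  p <- micellization_params(cmc = 1, r = 0.1, n = 100)
  grid <- seq(0, 3, length.out = 301)
  sp <- species_profile(grid, p)
  expect_identical(sp$s1 + sp$sm, sp$s0)   # exact conservation
  expect_true(all(diff(sp$s1) >= 0))
  expect_true(all(diff(sp$sm) >= -1e-15))
  expect_true(all(sp$s1 >= 0 & sp$s1 <= sp$s0 + 1e-12))
  expect_equal(sp$m, sp$sm / 100)
  # micelle concentration at the cmc: closed form (A/2)*sqrt(2/pi)*r*cmc/n,
  # frozen from the double-integration oracle: 3.989422804e-4
  expect_equal(sp$m[sp$s0 == 1], 3.989422804e-4, tolerance = 1e-9)
  expect_error(species_profile(c(1, 0.5, 2), p), "ascending")
})

test_that("wider transitions produce more premicellar aggregation", {
  s0 <- 0.8
  sm_wide <- s0 - monomer_concentration(s0, micellization_params(1, 0.5))
  sm_narrow <- s0 - monomer_concentration(s0, micellization_params(1, 0.1))
  expect_gt(sm_wide, sm_narrow)
})

test_that("first derivative is the erf sigmoid and matches finite differences", {
  p <- micellization_params(cmc = 1, r = 0.1)
  A <- amplitude(0.1)
  expect_equal(first_derivative(1, p), A / 2, tolerance = 1e-14)
  expect_equal(first_derivative(1e-9, p), A, tolerance = 1e-12)
  # strictly positive through the transition; underflows to exact zero only
  # far above it, where erf saturates in double precision
  expect_true(all(first_derivative(seq(0, 1.5, 0.05), p) > 0))
  expect_true(all(first_derivative(seq(0, 5, 0.05), p) >= 0))
  grid <- seq(0.01, 3, length.out = 200)
  h <- 1e-6
  fd <- (monomer_concentration(grid + h, p) -
           monomer_concentration(grid - h, p)) / (2 * h)
  expect_lt(max(abs(fd - first_derivative(grid, p))), 1e-6)
})

test_that("second derivative is the negative Gaussian centred at the cmc", {
  p <- micellization_params(cmc = 2, r = 0.15)
  sig <- 0.3
  A <- amplitude(0.15)
  expect_equal(second_derivative(2, p), -A / (sqrt(2 * pi) * sig),
               tolerance = 1e-14)
  for (d in c(0.05, 0.2, 0.5)) {
    expect_equal(second_derivative(2 - d, p), second_derivative(2 + d, p),
                 tolerance = 1e-12)
  }
  grid <- seq(0.2, 5, length.out = 150)
  expect_true(all(second_derivative(grid, p) <= 0))
  h <- 1e-4
  fd2 <- (monomer_concentration(grid + h, p) - 2 * monomer_concentration(grid, p) +
            monomer_concentration(grid - h, p)) / h^2
  ref <- second_derivative(grid, p)
  expect_lt(max(abs(fd2 - ref)) / max(abs(ref)), 1e-5)
  dp <- derivative_profile(grid, p)
  expect_equal(dp$first + dp$gamma, rep(1, length(grid)))
  expect_equal(grid[which.min(dp$second)], 2, tolerance = 0.02)
})

test_that("degree of micellization: differential and fractional forms", {
  p <- micellization_params(cmc = 1, r = 0.1)
  # ~4% micellized at the cmc for r = 0.1
  expect_equal(signif(degree_of_micellization(1, p, "fractional"), 2), 0.040)
  expect_equal(degree_of_micellization(1, p, "differential"),
               1 - amplitude(0.1) / 2, tolerance = 1e-14)
  expect_equal(degree_of_micellization(1e4, p, "fractional"),
               1 - 1 / 1e4, tolerance = 1e-10)
  expect_error(degree_of_micellization(0, p, "fractional"), "s0 > 0")
})

test_that("closed form equals the double integration of the Gaussian", {
  for (r in c(0.05, 0.1, 0.3, 0.5)) {
    num <- s1_by_double_integration(3, cmc = 1, r = r, amp = amplitude(r),
                                    n = 2e5)
    cf <- monomer_concentration(num$u, micellization_params(1, r))
    expect_lt(max(abs(num$s1 - cf)), 1e-8)
  }
})

test_that("r -> 0 approaches the piecewise-linear limit", {
  p <- micellization_params(cmc = 1, r = 1e-3)
  s0 <- seq(0, 3, length.out = 400)
  keep <- abs(s0 - 1) > 0.01
  expect_lt(max(abs(monomer_concentration(s0, p) - pmin(s0, 1))[keep]), 1e-6)
  # explicit analytic branch below the threshold
  p0 <- micellization_params(cmc = 1, r = 1e-9)
  expect_identical(monomer_concentration(s0, p0), pmin(s0, 1))
})

test_that("monotonicity and amplitude bound of the first derivative", {
  s0 <- seq(0, 4, length.out = 300)
  for (r in c(0.02, 0.1, 0.3, 0.6, 1)) {
    p <- micellization_params(cmc = 1, r = r)
    d <- first_derivative(s0, p)
    A <- amplitude(r)
    expect_true(all(d >= 0 & d <= A + 1e-15))
    expect_true(all(d[s0 < 1 + 5 * r] > 0))
    expect_lte(A, 1)
    expect_true(all(diff(monomer_concentration(s0, p)) >= -1e-15))
  }
})

test_that("parameter containers validate their domains", {
  expect_error(micellization_params(-1, 0.1), "cmc")
  expect_error(micellization_params(1, 0), "r")
  expect_error(micellization_params(1, 0.1, n = 0.5), "n")
  p <- micellization_params(1, 0.25)
  expect_equal(sigma_from_relative_width(p$cmc, p$r), 0.25)
  expect_equal(sigma_from_relative_width(90, 0.36), 32.4)
  # roundtrip r = sigma/cmc
  expect_equal(sigma_from_relative_width(2, 0.3) / 2, 0.3)
})
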