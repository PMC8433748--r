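# Forward models mapping total surfactant concentration to measurable
# properties. Each model combines the concentration model (monomer and
# micellized concentrations) with the standard equation for the property.
# The distinct gammas of the field are kept apart: gamma_st (surface
# tension), gamma_diff (differential degree of micellization) and gamma_agg
# (aggregated fraction) never share an identifier.

#' Conductivity model parameters
#'
#' Specific conductance of an ionic surfactant solution is linear in the
#' species concentrations: `kappa = a*[S1] + b*[Sm] + kappa_s`, where `a` and
#' `b` are the slopes of the limiting straight lines below and above the cmc
#' (molar conductivity units, e.g. uS/cm/mM) and `kappa_s` the residual
#' solvent conductivity.
#'
#' @param a slope below the cmc, > 0.
#' @param b slope above the cmc (typically b < a for ionic surfactants).
#' @param kappa_s residual solvent conductivity.
#' @param mic a [micellization_params] object.
#' @return Object of class `conductivity_params`.
#' @export
conductivity_params <- function(a, b, kappa_s = 0, mic) {
  stopifnot(inherits(mic, "micellization_params"), is.finite(a), is.finite(b),
            is.finite(kappa_s))
  if (a <= 0) stop("'a' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, kappa_s = kappa_s, mic = mic),
            class = "conductivity_params")
}

#' Conductivity of an ionic surfactant solution
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [conductivity_params] object.
#' @return Conductivity values `a*[S1] + b*([S]0 - [S1]) + kappa_s`.
#' @export
conductivity <- function(s0, p) {
  stopifnot(inherits(p, "conductivity_params"))
  s1 <- monomer_concentration(s0, p$mic)
  p$a * s1 + p$b * (s0 - s1) + p$kappa_s
}

#' Molar conductivity
#'
#' `Lambda_m = (kappa - kappa_s)/[S]0 = a*[S1]/[S]0 + b*[Sm]/[S]0`; falls
#' sigmoidally from `a` to `b` as micelles take up the added surfactant.
#'
#' @param s0 total concentration(s), strictly > 0.
#' @param p a [conductivity_params] object.
#' @return Molar conductivity values.
#' @export
molar_conductivity <- function(s0, p) {
  stopifnot(inherits(p, "conductivity_params"))
  if (any(s0 <= 0)) stop("molar conductivity requires s0 > 0", call. = FALSE)
  s1 <- monomer_concentration(s0, p$mic)
  p$a * s1 / s0 + p$b * (s0 - s1) / s0
}

#' Boltzmann-sigmoid conductivity model parameters
#'
#' Alternative conductivity model in which the differential conductivity
#' dkappa/d\[S\]0 is a Boltzmann sigmoid centred at the cmc with width
#' `delta`; its integral is fitted to conductivity data. The width `delta`
#' is not the Gaussian width sigma of the concentration model; see
#' [equal_slope_width_ratio()] and [best_fit_width_ratio()].
#'
#' @param a,b limiting slopes as in [conductivity_params].
#' @param kappa_s residual solvent conductivity.
#' @param cmc critical micelle concentration, > 0.
#' @param delta transition width, > 0 (concentration units).
#' @return Object of class `carpena_params`.
#' @export
carpena_params <- function(a, b, kappa_s = 0, cmc, delta) {
  stopifnot(is.finite(a), is.finite(b), is.finite(kappa_s), is.finite(cmc),
            is.finite(delta))
  if (cmc <= 0) stop("'cmc' must be > 0", call. = FALSE)
  if (delta <= 0) stop("'delta' must be > 0", call. = FALSE)
  structure(list(a = a, b = b, kappa_s = kappa_s, cmc = cmc, delta = delta),
            class = "carpena_params")
}

# log(1 + exp(z)) without overflow
.log1pexp <- function(z) ifelse(z > 33, z + log1p(exp(-z)), log1p(exp(z)))

#' Boltzmann-sigmoid (Carpena) conductivity
#'
#' Integrated Boltzmann model,
#' `kappa = kappa_s + a*s0 + delta*(b - a) * ln[(1 + e^((s0-cmc)/delta)) /
#' (1 + e^(-cmc/delta))]`, evaluated with an overflow-safe log-sum-exp.
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [carpena_params] object.
#' @return Conductivity values.
#' @export
carpena_conductivity <- function(s0, p) {
  stopifnot(inherits(p, "carpena_params"))
  p$kappa_s + p$a * s0 + p$delta * (p$b - p$a) *
    (.log1pexp((s0 - p$cmc) / p$delta) - .log1pexp(-p$cmc / p$delta))
}

#' Width ratio giving equal sigmoid slopes at the cmc
#'
#' The Gaussian width sigma of the concentration model and the Boltzmann
#' width delta produce differential-conductivity sigmoids with the same slope
#' at the cmc when `sigma/delta = 4/sqrt(2*pi)` (about 1.60): the Boltzmann
#' curvature there is `(b - a)/(4*delta)` and the Gaussian one
#' `(b - a)/(sqrt(2*pi)*sigma)` (for r < 0.4 where A ~ 1).
#'
#' @return The dimensionless ratio `4/sqrt(2*pi)`.
#' @export
equal_slope_width_ratio <- function() 4 / sqrt(2 * pi)

#' Width ratio from the best fit of the Boltzmann model
#'
#' Generates a noiseless conductivity curve from the concentration model and
#' least-squares fits the integrated Boltzmann expression (free: cmc, delta,
#' a, b, kappa_s); returns the ratio of the generating sigma = r*cmc to the
#' fitted delta. For typical conductivity setups the ratio is about 1.7-1.8,
#' close to but distinct from the equal-slope value 1.60. The ratio is
#' computed on the full integrated curves, not on their derivative sigmoids.
#'
#' @param cmc generating critical micelle concentration.
#' @param r generating relative transition width.
#' @param grid concentration grid spanning at least \[0, 2*cmc\].
#' @param a,b,kappa_s conductivity slopes and offset of the generating curve.
#' @return The dimensionless ratio sigma/delta.
#' @examples
#' best_fit_width_ratio(8.099, 0.112, seq(0, 16.2, length.out = 200))
#' @export
best_fit_width_ratio <- function(cmc, r, grid, a = 66.74, b = 26.43,
                                 kappa_s = 0) {
  if (max(grid) < 2 * cmc) {
    stop("'grid' must span at least [0, 2*cmc]", call. = FALSE)
  }
  p <- conductivity_params(a, b, kappa_s,
                           mic = micellization_params(cmc, r))
  curve <- titration_curve(grid, conductivity(grid, p), kind = "conductivity")
  fit <- fit_curve(curve, model_kind = "carpena")
  if (!fit$converged) stop("Boltzmann-model fit did not converge: ",
                           fit$message, call. = FALSE)
  (r * cmc) / fit$estimates[["delta"]]
}

#' Surface tension (Szyszkowski) parameters
#'
#' `gamma_st = gamma0 - st_coeff * ln(1 + k_ad*[S1])`: surface tension
#' depends only on the monomer concentration because micelles are not surface
#' active. `st_coeff = R*T/omega` with omega the molar cross-sectional area
#' at the surface; `k_ad` is the adsorption equilibrium constant.
#'
#' @param gamma0 solvent surface tension (e.g. mN/m), > 0.
#' @param st_coeff Szyszkowski coefficient R*T/omega (same unit as gamma0).
#' @param k_ad adsorption equilibrium constant (1/concentration), >= 0.
#' @param mic a [micellization_params] object.
#' @return Object of class `surface_tension_params`.
#' @export
surface_tension_params <- function(gamma0, st_coeff, k_ad, mic) {
  stopifnot(inherits(mic, "micellization_params"))
  if (gamma0 <= 0) stop("'gamma0' must be > 0", call. = FALSE)
  if (k_ad < 0) stop("'k_ad' must be >= 0", call. = FALSE)
  structure(list(gamma0 = gamma0, st_coeff = st_coeff, k_ad = k_ad, mic = mic),
            class = "surface_tension_params")
}

#' Surface tension of a surfactant solution
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [surface_tension_params] object.
#' @return Surface tension values.
#' @export
surface_tension <- function(s0, p) {
  stopifnot(inherits(p, "surface_tension_params"))
  s1 <- monomer_concentration(s0, p$mic)
  p$gamma0 - p$st_coeff * log(1 + p$k_ad * s1)
}

#' NMR chemical shift parameters
#'
#' The observed shift is the population-weighted mean of the monomer and
#' micelle shifts: `delta_obs = (delta_free - delta_mic)*[S1]/[S]0 +
#' delta_mic`.
#'
#' @param delta_free chemical shift of the monomeric surfactant (ppm).
#' @param delta_mic chemical shift of the micellized surfactant (ppm).
#' @param mic a [micellization_params] object.
#' @return Object of class `nmr_params`.
#' @export
nmr_params <- function(delta_free, delta_mic, mic) {
  stopifnot(inherits(mic, "micellization_params"),
            is.finite(delta_free), is.finite(delta_mic))
  structure(list(delta_free = delta_free, delta_mic = delta_mic, mic = mic),
            class = "nmr_params")
}

#' Observed NMR chemical shift
#'
#' @param s0 total concentration(s), strictly > 0.
#' @param p an [nmr_params] object.
#' @return Chemical shift values (ppm).
#' @export
nmr_shift <- function(s0, p) {
  stopifnot(inherits(p, "nmr_params"))
  if (any(s0 <= 0)) stop("NMR shift requires s0 > 0", call. = FALSE)
  s1 <- monomer_concentration(s0, p$mic)
  (p$delta_free - p$delta_mic) * s1 / s0 + p$delta_mic
}

#' Molar fractions of free and micelle-bound dye
#'
#' For the exchange equilibrium `D_f + M <-> D_b` with binding constant K,
#' `X_f = 1/(1 + K*[M])` and `X_b = K*[M]/(1 + K*[M])`; they sum to one
#' exactly.
#'
#' @param m micelle concentration(s), >= 0.
#' @param k_bind binding equilibrium constant (1/concentration), >= 0.
#' @return List with components `x_free` and `x_bound`.
#' @examples
#' dye_fractions(1, 3) # 25% free, 75% bound
#' @export
dye_fractions <- function(m, k_bind) {
  if (any(m < 0) || any(k_bind < 0)) {
    stop("'m' and 'k_bind' must be >= 0", call. = FALSE)
  }
  km <- k_bind * m
  x_b <- km / (1 + km)
  list(x_free = 1 - x_b, x_bound = x_b)
}

#' Dye-binding fluorescence parameters
#'
#' Emission of a dye exchanging between water and micelles:
#' `F = F_f*X_f + F_b*X_b` with the fractions of [dye_fractions()]. K and the
#' aggregation number n are jointly unidentifiable from a single curve
#' (\[M\] = \[Sm\]/n), so the default parameterization is the composite
#' per-surfactant constant `k_bind_per_surfactant = K/n` applied to \[Sm\];
#' supply `k_bind` plus `n` in `mic` for the per-micelle form.
#'
#' @param f_free,f_bound limiting intensities of free and bound dye, >= 0.
#' @param k_bind per-micelle binding constant (requires `mic$n`).
#' @param k_bind_per_surfactant composite constant K/n (1/concentration of
#'   micellized surfactant). Exactly one of the two constants must be given.
#' @param mic a [micellization_params] object.
#' @return Object of class `dye_binding_params`.
#' @export
dye_binding_params <- function(f_free, f_bound, k_bind = NULL,
                               k_bind_per_surfactant = NULL, mic) {
  stopifnot(inherits(mic, "micellization_params"))
  if (f_free < 0 || f_bound < 0) {
    stop("limiting intensities must be >= 0", call. = FALSE)
  }
  if (is.null(k_bind) == is.null(k_bind_per_surfactant)) {
    stop("give exactly one of 'k_bind' or 'k_bind_per_surfactant'",
         call. = FALSE)
  }
  if (!is.null(k_bind) && is.null(mic$n)) {
    stop("per-micelle 'k_bind' requires the aggregation number 'n' in 'mic'",
         call. = FALSE)
  }
  structure(list(f_free = f_free, f_bound = f_bound, k_bind = k_bind,
                 k_bind_per_surfactant = k_bind_per_surfactant, mic = mic),
            class = "dye_binding_params")
}

# K*[M] for either parameterization of a binding constant
.km_term <- function(s0, mic, k_bind, k_per_s) {
  sm <- s0 - monomer_concentration(s0, mic)
  if (!is.null(k_per_s)) k_per_s * sm else k_bind * sm / mic$n
}

#' Fluorescence intensity of an exchanging dye
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [dye_binding_params] object.
#' @return Intensity values (arbitrary units).
#' @export
fluorescence_intensity <- function(s0, p) {
  stopifnot(inherits(p, "dye_binding_params"))
  km <- .km_term(s0, p$mic, p$k_bind, p$k_bind_per_surfactant)
  (p$f_free + p$f_bound * km) / (1 + km)
}

#' Pyrene spectral-ratio parameters
#'
#' The pyrene monomer band ratio (e.g. I_I/I_III at 372/384 nm) follows
#' `SR = (SR_f + SR_b*c*[M]) / (1 + c*[M])` for r < 0.4. The constant `c`
#' lumps the binding constant, the pyrene-surfactant quenching constant, the
#' brightness ratio of free and bound monomer and the cmc; its printed
#' decomposition in the source literature is typographically corrupted, so
#' `c` is treated as a single free parameter and never decomposed here. As
#' for dyes, the per-surfactant composite `c_per_surfactant` (applied to
#' \[Sm\]) is the default; the per-micelle form needs `mic$n`.
#'
#' @param sr_free spectral ratio of free (aqueous) pyrene.
#' @param sr_bound spectral ratio of micelle-bound pyrene.
#' @param c_bind per-micelle composite constant (requires `mic$n`), >= 0.
#' @param c_per_surfactant composite constant per micellized surfactant.
#' @param mic a [micellization_params] object.
#' @return Object of class `pyrene_ratio_params`.
#' @export
pyrene_ratio_params <- function(sr_free, sr_bound, c_bind = NULL,
                                c_per_surfactant = NULL, mic) {
  stopifnot(inherits(mic, "micellization_params"))
  if (is.null(c_bind) == is.null(c_per_surfactant)) {
    stop("give exactly one of 'c_bind' or 'c_per_surfactant'", call. = FALSE)
  }
  cc <- if (!is.null(c_bind)) c_bind else c_per_surfactant
  if (cc < 0) stop("composite constant must be >= 0", call. = FALSE)
  if (!is.null(c_bind) && is.null(mic$n)) {
    stop("per-micelle 'c_bind' requires 'n' in 'mic'", call. = FALSE)
  }
  structure(list(sr_free = sr_free, sr_bound = sr_bound, c_bind = c_bind,
                 c_per_surfactant = c_per_surfactant, mic = mic),
            class = "pyrene_ratio_params")
}

#' Pyrene spectral ratio
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [pyrene_ratio_params] object.
#' @return Dimensionless spectral ratio values.
#' @export
pyrene_spectral_ratio <- function(s0, p) {
  stopifnot(inherits(p, "pyrene_ratio_params"))
  cm <- .km_term(s0, p$mic, p$c_bind, p$c_per_surfactant)
  (p$sr_free + p$sr_bound * cm) / (1 + cm)
}

#' Absorbance parameters
#'
#' Direct UV-Vis absorbance of the surfactant as the sum of the species
#' contributions, `A(lambda) = [S1]*eps_free(lambda)*path +
#' [Sm]*eps_mic(lambda)*path`, and the two-wavelength absorbance ratio
#' `q_A = ([S1]*q1 + [Sm]*qm*qa) / ([S1] + [Sm]*qa)` with `q1`, `qm` the
#' per-species wavelength ratios and `qa` the species ratio at the reference
#' wavelength.
#'
#' @param eps_free,eps_mic molar absorption coefficients per wavelength
#'   (equal-length vectors), >= 0.
#' @param path optical path length, > 0.
#' @param q1,qm,qa absorbance ratios (needed only for [absorbance_ratio()]).
#' @param mic a [micellization_params] object.
#' @return Object of class `absorbance_params`.
#' @export
absorbance_params <- function(eps_free, eps_mic, path = 1,
                              q1 = NULL, qm = NULL, qa = NULL, mic) {
  stopifnot(inherits(mic, "micellization_params"),
            length(eps_free) == length(eps_mic))
  if (any(eps_free < 0) || any(eps_mic < 0)) {
    stop("absorption coefficients must be >= 0", call. = FALSE)
  }
  if (path <= 0) stop("'path' must be > 0", call. = FALSE)
  structure(list(eps_free = eps_free, eps_mic = eps_mic, path = path,
                 q1 = q1, qm = qm, qa = qa, mic = mic),
            class = "absorbance_params")
}

#' Absorbance at one wavelength
#'
#' @param s0 total concentration(s), >= 0.
#' @param p an [absorbance_params] object.
#' @param wavelength index into the coefficient vectors of `p`.
#' @return Absorbance values.
#' @export
absorbance <- function(s0, p, wavelength = 1L) {
  stopifnot(inherits(p, "absorbance_params"))
  if (wavelength < 1L || wavelength > length(p$eps_free)) {
    stop("unknown wavelength index ", wavelength, call. = FALSE)
  }
  s1 <- monomer_concentration(s0, p$mic)
  (s1 * p$eps_free[wavelength] + (s0 - s1) * p$eps_mic[wavelength]) * p$path
}

#' Absorbance ratio at two wavelengths
#'
#' @param s0 total concentration(s), strictly > 0.
#' @param p an [absorbance_params] object with `q1`, `qm`, `qa` set.
#' @return Dimensionless absorbance ratio values.
#' @export
absorbance_ratio <- function(s0, p) {
  stopifnot(inherits(p, "absorbance_params"))
  if (is.null(p$q1) || is.null(p$qm) || is.null(p$qa)) {
    stop("'q1', 'qm' and 'qa' must be set for the absorbance ratio",
         call. = FALSE)
  }
  if (any(s0 <= 0)) stop("absorbance ratio requires s0 > 0", call. = FALSE)
  s1 <- monomer_concentration(s0, p$mic)
  sm <- s0 - s1
  den <- s1 + sm * p$qa
  if (any(den == 0)) stop("zero denominator in absorbance ratio", call. = FALSE)
  (s1 * p$q1 + sm * p$qm * p$qa) / den
}

#' Tracer diffusion parameters
#'
#' Mean translational diffusion coefficient of a dye exchanging between water
#' and micelles (as measured by FCS): `D = D_f*X_f + D_b*X_b` with the
#' fractions of [dye_fractions()]. Free dye must diffuse faster than bound
#' dye.
#'
#' @param d_free diffusion coefficient of the free dye (e.g. um^2/s), > 0.
#' @param d_bound diffusion coefficient of the micelle-bound dye,
#'   0 < d_bound < d_free.
#' @param k_bind per-micelle binding constant (requires `mic$n`).
#' @param k_bind_per_surfactant composite constant K/n.
#' @param mic a [micellization_params] object.
#' @return Object of class `diffusion_params`.
#' @export
diffusion_params <- function(d_free, d_bound, k_bind = NULL,
                             k_bind_per_surfactant = NULL, mic) {
  stopifnot(inherits(mic, "micellization_params"))
  if (!(d_free > d_bound && d_bound > 0)) {
    stop("require d_free > d_bound > 0", call. = FALSE)
  }
  if (is.null(k_bind) == is.null(k_bind_per_surfactant)) {
    stop("give exactly one of 'k_bind' or 'k_bind_per_surfactant'",
         call. = FALSE)
  }
  if (!is.null(k_bind) && is.null(mic$n)) {
    stop("per-micelle 'k_bind' requires 'n' in 'mic'", call. = FALSE)
  }
  structure(list(d_free = d_free, d_bound = d_bound, k_bind = k_bind,
                 k_bind_per_surfactant = k_bind_per_surfactant, mic = mic),
            class = "diffusion_params")
}

#' Mean diffusion coefficient of an exchanging dye
#'
#' @param s0 total concentration(s), >= 0.
#' @param p a [diffusion_params] object.
#' @return Mean diffusion coefficient values.
#' @export
mean_diffusion <- function(s0, p) {
  stopifnot(inherits(p, "diffusion_params"))
  km <- .km_term(s0, p$mic, p$k_bind, p$k_bind_per_surfactant)
  (p$d_free + p$d_bound * km) / (1 + km)
}

#' Aggregation parameters
#'
#' The concentration model applied to a non-surfactant aggregating species
#' (e.g. an amyloid peptide): the critical aggregation concentration (cac)
#' plays the role of the cmc.
#'
#' @param cac critical aggregation concentration, > 0.
#' @param r relative transition width, > 0.
#' @return Object of class `aggregation_params`.
#' @export
aggregation_params <- function(cac, r) {
  structure(list(mic = micellization_params(cmc = cac, r = r)),
            class = "aggregation_params")
}

#' Aggregated fraction of a self-assembling species
#'
#' `gamma_agg = [A_g]/[A] = 1 - [S1]/[S]0` with the concentration model
#' evaluated at cmc := cac.
#'
#' @param a_total total species concentration(s), strictly > 0.
#' @param p an [aggregation_params] object.
#' @return Aggregated fraction values in \[0, 1).
#' @export
aggregated_fraction <- function(a_total, p) {
  stopifnot(inherits(p, "aggregation_params"))
  if (any(a_total <= 0)) {
    stop("aggregated fraction requires total concentration > 0", call. = FALSE)
  }
  1 - monomer_concentration(a_total, p$mic) / a_total
}
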