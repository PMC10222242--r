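# Formulations, particle populations and the diffusion-layer dissolution
# rate law.

#' Dosage-form specification
#'
#' @param form One of `"tablet"`, `"suspension"`, `"solution"`.
#' @param dose Dose (mg).
#' @param median_particle_diameter_d50 Median API particle diameter (um).
#'   Ignored for solutions.
#' @param fraction_dose_dissolved_initial Fraction of the dose already in
#'   solution when dosing (1 for solutions).
#' @param vehicle_concentration Drug concentration of the suspension vehicle
#'   (mg/mL); `NA` for other forms.
#' @param vehicle_viscosity Viscosity of the suspension vehicle (cps);
#'   `NA` for other forms.
#' @param dlm_scalar Empirical diffusion-layer-model rate multiplier. The
#'   single place where hydrodynamics and (for tablets) disintegration are
#'   absorbed; applied identically in vitro and in vivo.
#'
#' @return An object of class `formulation_spec`.
#' @export
formulation_spec <- function(form = c("tablet", "suspension", "solution"),
                             dose,
                             median_particle_diameter_d50 = NA_real_,
                             fraction_dose_dissolved_initial = 0,
                             vehicle_concentration = NA_real_,
                             vehicle_viscosity = NA_real_,
                             dlm_scalar = 1) {
  form <- match.arg(form)
  stopifnot(
    is.numeric(dose), dose > 0,
    fraction_dose_dissolved_initial >= 0, fraction_dose_dissolved_initial <= 1,
    dlm_scalar > 0
  )
  if (form == "solution") {
    fraction_dose_dissolved_initial <- 1
  } else {
    if (!is.finite(median_particle_diameter_d50) ||
        median_particle_diameter_d50 <= 0) {
      stop("solid forms need a positive `median_particle_diameter_d50`")
    }
  }
  if (form == "suspension" &&
      (!is.finite(vehicle_viscosity) || vehicle_viscosity <= 0)) {
    stop("suspensions need a positive `vehicle_viscosity`")
  }
  structure(
    list(form = form, dose = dose,
         median_particle_diameter_d50 = median_particle_diameter_d50,
         fraction_dose_dissolved_initial = fraction_dose_dissolved_initial,
         vehicle_concentration = vehicle_concentration,
         vehicle_viscosity = vehicle_viscosity,
         dlm_scalar = dlm_scalar),
    class = "formulation_spec"
  )
}

#' @export
print.formulation_spec <- function(x, ...) {
  cat(sprintf("<formulation_spec> %s, %g mg\n", x$form, x$dose))
  if (x$form != "solution") {
    cat(sprintf("  D50 %g um, fraction pre-dissolved %g, DLM scalar %g\n",
                x$median_particle_diameter_d50,
                x$fraction_dose_dissolved_initial, x$dlm_scalar))
  }
  if (x$form == "suspension") {
    cat(sprintf("  vehicle %g mg/mL, %g cps\n",
                x$vehicle_concentration, x$vehicle_viscosity))
  }
  invisible(x)
}

#' Initialise a particle population for the solid fraction of a dose
#'
#' Monodisperse by default: all particles at radius D50/2; particle count is
#' the solid dose mass divided by the single-particle mass
#' `(4/3) * pi * r^3 * density`.
#'
#' @param formulation A [formulation_spec()].
#' @param physchem A [drug_physchem()] (supplies particle density).
#'
#' @return An object of class `particle_population` with fields `bins`
#'   (data frame of `radius_um`, `particle_count`) and `undissolved_mass`
#'   (mg).
#' @export
init_particle_population <- function(formulation, physchem) {
  stopifnot(inherits(formulation, "formulation_spec"),
            inherits(physchem, "drug_physchem"))
  solid_mass <- formulation$dose *
    (1 - formulation$fraction_dose_dissolved_initial)
  if (formulation$form == "solution" || solid_mass <= 0) {
    return(structure(
      list(bins = data.frame(radius_um = numeric(), particle_count = numeric()),
           undissolved_mass = 0),
      class = "particle_population"
    ))
  }
  r_um <- formulation$median_particle_diameter_d50 / 2
  m_particle <- single_particle_mass_mg(r_um, physchem$particle_density)
  structure(
    list(bins = data.frame(radius_um = r_um,
                           particle_count = solid_mass / m_particle),
         undissolved_mass = solid_mass),
    class = "particle_population"
  )
}

# Mass of one spherical particle (mg) at radius r (um); density in g/cm^3
# (1 g/cm^3 = 1e-9 mg/um^3).
single_particle_mass_mg <- function(radius_um, density_g_cm3) {
  (4 / 3) * pi * radius_um^3 * density_g_cm3 * 1e-9
}

#' Diffusion-layer model dissolution rate per particle bin
#'
#' Per-bin mass transfer rate into solution:
#' `rate = scalar * count * 4 * pi * D * (Cs - Cb) * (r / h_eff)` expressed
#' in g/s with D in cm^2/s and concentrations in g/cm^3, where
#' `h_eff = min(r, 30 um)` is the particle-size-dependent effective
#' diffusion-layer thickness. A reference length of 1 cm is folded into the
#' DLM scalar convention so the rate is linear in the driving force
#' `Cs - Cb` and independent of radius once `r < 30 um`. The driving force
#' is clamped at zero when the bulk is at (or numerically above) the surface
#' solubility: no precipitation in this rate law.
#'
#' @param particles A [init_particle_population()] result.
#' @param medium A [medium_state()] (supplies pH, volume, viscosity,
#'   temperature, dissolved mass).
#' @param physchem A [drug_physchem()].
#' @param dlm_scalar Empirical rate multiplier.
#'
#' @return Numeric vector, one dissolution rate (mg/s) per bin.
#' @export
dlm_rate <- function(particles, medium, physchem, dlm_scalar = 1) {
  stopifnot(inherits(particles, "particle_population"),
            inherits(medium, "medium_state"))
  if (nrow(particles$bins) == 0) return(numeric())
  cs <- solubility_at_ph(physchem, medium$ph)           # mg/mL
  cb <- medium$dissolved_mass / medium$volume           # mg/mL
  dC <- max(cs - cb, 0)                                 # clamp: no precipitation
  d_coef <- diffusion_coefficient(physchem, medium)     # cm^2/s
  r <- particles$bins$radius_um
  h_eff <- pmin(r, 30)
  ratio <- ifelse(r > 0, r / h_eff, 0)
  # mg/s: 4*pi*D[cm^2/s] * dC[mg/mL = 1e-3 g/cm^3] * ratio, g/s -> mg/s (x1e3)
  dlm_scalar * particles$bins$particle_count * 4 * pi * d_coef *
    (dC * 1e-3) * ratio * 1e3
}

#' Simulate closed-vessel USP II dissolution
#'
#' Integrates the diffusion-layer rate law in a fixed-pH, fixed-volume
#' stirred vessel. Suspension runs use the vehicle viscosity as the medium
#' viscosity (the in vitro medium is thickened to match the dosed vehicle);
#' tablets and solutions use the aqueous reference. The dissolved
#' concentration is bounded by the solubility cap, so the profile plateaus
#' at `min(1, Cs * V / dose)`.
#'
#' @param formulation A [formulation_spec()].
#' @param medium A [medium_state()]; its viscosity is overridden for
#'   suspensions as described.
#' @param timepoints Sampling times (min), sorted, positive.
#' @param physchem A [drug_physchem()].
#' @param rtol,atol Integration tolerances.
#'
#' @return A `dissolution_profile`: data frame with columns `time_min`,
#'   `fraction_dissolved`, `ph`, `formulation`, plus attribute `medium`.
#' @export
simulate_usp2 <- function(formulation, medium, timepoints, physchem,
                          rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(formulation, "formulation_spec"),
            inherits(medium, "medium_state"))
  if (is.unsorted(timepoints, strictly = TRUE) || any(timepoints <= 0)) {
    stop("`timepoints` must be sorted, strictly increasing and positive")
  }
  if (formulation$form == "suspension") {
    medium <- medium_state(medium$ph, medium$volume,
                           viscosity = formulation$vehicle_viscosity,
                           temperature = medium$temperature,
                           dissolved_mass = medium$dissolved_mass)
  }
  dose <- formulation$dose
  pp <- init_particle_population(formulation, physchem)
  dissolved0 <- dose * formulation$fraction_dose_dissolved_initial +
    medium$dissolved_mass

  if (nrow(pp$bins) == 0) {
    out <- data.frame(time_min = timepoints,
                      fraction_dissolved = rep(min(1, dissolved0 / dose),
                                               length(timepoints)),
                      ph = medium$ph, formulation = formulation$form)
    return(new_dissolution_profile(out, medium))
  }

  n_count <- pp$bins$particle_count
  rho <- physchem$particle_density
  cs <- solubility_at_ph(physchem, medium$ph)
  d_coef <- diffusion_coefficient(physchem, medium)
  vol <- medium$volume
  scalar <- formulation$dlm_scalar

  deriv <- function(t, y, parms) {
    m_solid <- y[1]
    diss <- y[2]
    rate <- usp2_rate_mg_min(m_solid, diss, n_count, rho, cs, d_coef, vol,
                             scalar)
    list(c(-rate, rate))
  }
  times <- c(0, timepoints)
  sol <- deSolve::lsoda(c(solid = pp$undissolved_mass, dissolved = dissolved0),
                        times, deriv, parms = NULL, rtol = rtol, atol = atol)
  frac <- pmin(pmax(sol[-1, "dissolved"] / dose, 0), 1)
  out <- data.frame(time_min = timepoints, fraction_dissolved = frac,
                    ph = medium$ph, formulation = formulation$form)
  new_dissolution_profile(out, medium)
}

# Shared rate kernel (mg/min) for the vessel integrators. The raw
# diffusion-layer rate is combined harmonically with a first-order ceiling
# (1000/h on the solid) that bounds the stiffness of near-instant
# dissolution and tapers the rate smoothly to zero with the remaining
# solid; the same regularisation is used by the gut integrator.
usp2_rate_mg_min <- function(m_solid, dissolved, n_count, rho, cs, d_coef,
                             vol, scalar) {
  if (m_solid <= 0) return(0)
  r_um <- (3 * m_solid / (4 * pi * n_count * rho * 1e-9))^(1 / 3)
  dC <- max(cs - dissolved / vol, 0)
  if (dC <= 0) return(0)
  ratio <- r_um / min(r_um, 30)
  raw <- scalar * n_count * 4 * pi * d_coef * (dC * 1e-3) * ratio * 1e3 * 60
  cap <- (1000 / 60) * m_solid
  raw * cap / (raw + cap)
}

new_dissolution_profile <- function(df, medium) {
  structure(df, medium = medium, class = c("dissolution_profile", "data.frame"))
}

#' Fixed-step reference integrator for vessel dissolution
#'
#' Forward-Euler integration of the same rate law at a fixed small step,
#' used as an independent numerical cross-check of [simulate_usp2()] on
#' small instances.
#'
#' @inheritParams simulate_usp2
#' @param dt Step size (s).
#' @return A data frame with `time_min` and `fraction_dissolved`.
#' @export
simulate_usp2_fixed_step <- function(formulation, medium, timepoints,
                                     physchem, dt = 0.01) {
  stopifnot(inherits(formulation, "formulation_spec"))
  if (formulation$form == "suspension") {
    medium <- medium_state(medium$ph, medium$volume,
                           viscosity = formulation$vehicle_viscosity,
                           temperature = medium$temperature,
                           dissolved_mass = medium$dissolved_mass)
  }
  pp <- init_particle_population(formulation, physchem)
  dose <- formulation$dose
  m_solid <- pp$undissolved_mass
  dissolved <- dose * formulation$fraction_dose_dissolved_initial +
    medium$dissolved_mass
  n_count <- if (nrow(pp$bins)) pp$bins$particle_count else 0
  cs <- solubility_at_ph(physchem, medium$ph)
  d_coef <- diffusion_coefficient(physchem, medium)
  out <- numeric(length(timepoints))
  t_s <- 0
  targets_s <- timepoints * 60
  i <- 1
  while (i <= length(targets_s)) {
    while (t_s < targets_s[i]) {
      step <- min(dt, targets_s[i] - t_s)
      rate <- usp2_rate_mg_min(m_solid, dissolved, n_count,
                               physchem$particle_density, cs, d_coef,
                               medium$volume, formulation$dlm_scalar) / 60
      dm <- min(rate * step, m_solid)
      m_solid <- m_solid - dm
      dissolved <- dissolved + dm
      t_s <- t_s + step
    }
    out[i] <- dissolved / dose
    i <- i + 1
  }
  data.frame(time_min = timepoints, fraction_dissolved = pmin(out, 1))
}

#' Read or write dissolution profiles as CSV
#'
#' Tidy interchange format: columns `time_min`, `fraction_dissolved`, `ph`,
#' `formulation`.
#'
#' @param profiles A data frame (one or more stacked profiles).
#' @param path File path.
#' @return `read_dissolution_csv()` returns a data frame.
#' @export
write_dissolution_csv <- function(profiles, path) {
  req <- c("time_min", "fraction_dissolved", "ph", "formulation")
  stopifnot(all(req %in% names(profiles)))
  utils::write.csv(as.data.frame(profiles)[req], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissolution_csv
#' @export
read_dissolution_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("time_min", "fraction_dissolved", "ph", "formulation")
  if (!all(req %in% names(df))) stop("not a dissolution profile CSV")
  df
}
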