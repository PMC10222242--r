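# Catenary gastrointestinal transit-and-absorption model.

GUT_SEGMENT_NAMES <- c("stomach", "duodenum", "jejunum_1", "jejunum_2",
                       "ileum_1", "ileum_2", "ileum_3", "ileum_4", "colon")

#' Default fasted-adult gastrointestinal physiology
#'
#' Nine luminal segments (stomach, duodenum, jejunum I-II, ileum I-IV,
#' colon) with fasted-adult defaults: stomach pH 1.5 and mean residence
#' time (MRT) 0.4 h; total small-intestine transit 3.34 h split across the
#' six small-intestine segments in proportion to typical segment lengths;
#' colon MRT 12 h; luminal pH rising 6.4 to 7.4 along the small intestine
#' and 6.8 in the colon. All values are configurable; these are published
#' fasted-adult conventions, not study-specific measurements.
#'
#' @param gastric_mrt_h Stomach mean residence time (h).
#' @param si_transit_h Total small-intestine transit time (h).
#' @param colon_mrt_h Colon mean residence time (h).
#' @param stomach_ph Fasted stomach pH.
#' @param stomach_viscosity Viscosity of gastric fluid (cps). For suspension
#'   dosing the vehicle viscosity should be used here (see
#'   [apply_formulation_to_physiology()]).
#'
#' @return An object of class `gut_physiology`: a data frame of segments
#'   (`name`, `ph`, `mean_residence_time_h`, `fluid_volume_ml`, `radius_cm`,
#'   `viscosity_cps`) with transit-time attributes.
#' @export
default_fasted_physiology <- function(gastric_mrt_h = 0.4,
                                      si_transit_h = 3.34,
                                      colon_mrt_h = 12,
                                      stomach_ph = 1.5,
                                      stomach_viscosity = water_viscosity_cps()) {
  stopifnot(gastric_mrt_h > 0, si_transit_h > 0, colon_mrt_h > 0)
  si_split <- c(0.08, 0.22, 0.22, 0.12, 0.12, 0.12, 0.12)  # duo, jej x2, ileum x4
  si_split <- si_split / sum(si_split)
  seg <- data.frame(
    name = GUT_SEGMENT_NAMES,
    ph = c(stomach_ph, 6.4, 6.5, 6.6, 6.8, 7.0, 7.2, 7.4, 6.8),
    mean_residence_time_h = c(gastric_mrt_h, si_split * si_transit_h,
                              colon_mrt_h),
    fluid_volume_ml = c(50, 15, 25, 25, 10, 10, 10, 10, 13),
    radius_cm = c(10, rep(1.175, 7), 2.4),
    viscosity_cps = c(stomach_viscosity, rep(water_viscosity_cps(), 8)),
    stringsAsFactors = FALSE
  )
  new_gut_physiology(seg)
}

new_gut_physiology <- function(segments) {
  stopifnot(nrow(segments) == 9L,
            identical(segments$name, GUT_SEGMENT_NAMES),
            all(segments$mean_residence_time_h > 0),
            all(segments$fluid_volume_ml >= 0),
            all(segments$radius_cm > 0))
  structure(
    segments,
    gastric_transit_time = segments$mean_residence_time_h[1],
    small_intestine_transit_time = sum(segments$mean_residence_time_h[2:8]),
    colon_transit_time = segments$mean_residence_time_h[9],
    stomach_ph_fasted = segments$ph[1],
    class = c("gut_physiology", "data.frame")
  )
}

#' @export
print.gut_physiology <- function(x, ...) {
  cat("<gut_physiology> 9 segments\n")
  cat(sprintf("  gastric MRT %.2f h | SI transit %.2f h | colon MRT %.1f h | stomach pH %.1f\n",
              attr(x, "gastric_transit_time"),
              attr(x, "small_intestine_transit_time"),
              attr(x, "colon_transit_time"),
              attr(x, "stomach_ph_fasted")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Adjust physiology for the dosed formulation
#'
#' Suspensions are swallowed with their viscous vehicle: gastric fluid
#' viscosity is set to the vehicle viscosity so the diffusion-layer model
#' sees the thickened stomach contents. Intestinal segments keep the
#' aqueous reference (gastric emptying dilutes the vehicle). Other forms
#' leave the physiology untouched.
#'
#' @param physiology A [default_fasted_physiology()]-style object.
#' @param formulation A [formulation_spec()].
#' @return A `gut_physiology`.
#' @export
apply_formulation_to_physiology <- function(physiology, formulation) {
  stopifnot(inherits(physiology, "gut_physiology"),
            inherits(formulation, "formulation_spec"))
  if (formulation$form == "suspension") {
    physiology$viscosity_cps[1] <- formulation$vehicle_viscosity
  } else {
    physiology$viscosity_cps[1] <- water_viscosity_cps()
  }
  new_gut_physiology(as.data.frame(physiology))
}

#' Absorption rate constant from effective permeability
#'
#' Cylindrical-tube convention: `ka = 2 * Peff / R`, converted to 1/h.
#'
#' @param peff Effective permeability (cm/s).
#' @param segment_radius Luminal radius (cm).
#' @return First-order absorption rate constant (1/h).
#' @examples
#' ka_from_peff(3e-4, 1.175)  # ~1.84 1/h
#' @export
ka_from_peff <- function(peff, segment_radius) {
  stopifnot(peff >= 0, segment_radius > 0)
  2 * peff / segment_radius * 3600
}

# Per-segment first-order absorption rate constants (1/h). Stomach
# absorption is zero (ionisation-limited at acidic pH); intestinal and
# colonic segments absorb dissolved drug at 2*Peff/R.
segment_ka <- function(physiology, peff) {
  ka <- vapply(seq_len(nrow(physiology)), function(i) {
    ka_from_peff(peff, physiology$radius_cm[i])
  }, numeric(1))
  ka[1] <- 0
  ka
}

#' Simulate gastrointestinal transit, dissolution and absorption
#'
#' Solves the catenary luminal ODE system: first-order transit between
#' segments at rate 1/MRT (solids, particle count and dissolved drug all
#' move with the fluid), diffusion-layer dissolution inside each segment at
#' that segment's pH with the dissolved concentration capped at the local
#' solubility, and first-order absorption of dissolved drug only
#' (`ka = 2*Peff/R`; none in the stomach). Drug leaving the colon is
#' tracked as exited-unabsorbed. No luminal degradation.
#'
#' @param formulation A [formulation_spec()].
#' @param physiology A `gut_physiology` (vehicle viscosity is applied
#'   automatically).
#' @param physchem A [drug_physchem()].
#' @param peff Effective permeability (cm/s).
#' @param duration Simulation horizon (h); must cover at least five total
#'   transit times.
#' @param times Optional explicit output grid (h).
#'
#' @return A list of class `gut_simulation`:
#'   `luminal` (data frame time course: `time_h`, `segment`, `compartment`,
#'   `mass_mg`), `portal_flux` (data frame `time_h`, `flux_mg_h`),
#'   `fraction_absorbed_fa`, `segment_fa` (named per-segment absorbed
#'   fractions), `mass_balance_error` (max relative), and the raw solver
#'   matrix in `$ode`.
#' @export
simulate_gut <- function(formulation, physiology, physchem, peff,
                         duration = 96, times = NULL) {
  stopifnot(inherits(physiology, "gut_physiology"))
  total_transit <- attr(physiology, "gastric_transit_time") +
    attr(physiology, "small_intestine_transit_time") +
    attr(physiology, "colon_transit_time")
  if (duration < 5 * total_transit) {
    stop("`duration` must cover at least 5x the total transit time")
  }
  physiology <- apply_formulation_to_physiology(physiology, formulation)
  if (is.null(times)) times <- default_output_times(duration)
  sol <- solve_gut_system(formulation, physiology, physchem, peff, times)
  summarise_gut_solution(sol, formulation, physiology, physchem, peff)
}

default_output_times <- function(duration) {
  t <- c(seq(0, 1, by = 0.02), seq(1.05, 6, by = 0.05),
         seq(6.25, 24, by = 0.25), seq(25, duration, by = 1))
  unique(t[t <= duration])
}

# Solves the combined luminal + systemic ODE in compiled code. The systemic
# parameters default to zero-clearance placeholders when only gut outputs
# are needed; simulate_subject_profile() supplies real disposition.
solve_gut_system <- function(formulation, physiology, physchem, peff, times,
                             disposition = NULL, subject = NULL,
                             rtol = 1e-9, atol = 1e-10) {
  parms <- build_ode_parms(formulation, physiology, physchem, peff,
                           disposition, subject)
  y0 <- build_ode_state(formulation, physchem)
  out <- deSolve::lsoda(y0, times, func = "pbpkbe_derivs",
                        parms = parms, dllname = "pbpkbe",
                        initfunc = "pbpkbe_init",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  attr(out, "parms") <- parms
  out
}

# Parameter vector layout shared with src/pbpk_ode.c (keep in sync):
# [0:8]   1/MRT per segment
# [9:17]  solubility Cs (mg/mL) per segment
# [18:26] fluid volume (mL) per segment
# [27:35] ka (1/h) per segment
# [36:44] diffusion coefficient (cm^2/s) per segment
# [45] particle density (mg/um^3), [46] dlm scalar,
# [47] Qpv, [48] Qha, [49] Qh (L/h), [50] fu_b*CLuint (L/h),
# [51] CLrenal blood (L/h), [52] CLin, [53] CLout (L/h),
# [54] Vpv, [55] Vliver, [56] Vcentral, [57] Vsac (L)
build_ode_parms <- function(formulation, physiology, physchem, peff,
                            disposition = NULL, subject = NULL) {
  cs <- solubility_at_ph(physchem, physiology$ph)
  dcoef <- vapply(seq_len(nrow(physiology)), function(i) {
    diffusion_coefficient(
      physchem, medium_state(physiology$ph[i],
                             max(physiology$fluid_volume_ml[i], 1),
                             viscosity = physiology$viscosity_cps[i])
    )
  }, numeric(1))
  ka <- segment_ka(physiology, peff)
  if (is.null(disposition)) {
    sys <- c(0.75 * 90, 0.25 * 90, 90, 0, 0, 0, 1e-6, 0.07, 1.69, 9.8, 7)
  } else {
    stopifnot(inherits(disposition, "disposition_params"))
    bw <- if (is.null(subject)) 70 else subject$body_weight
    qh <- if (is.null(subject)) disposition$q_h else subject$hepatic_blood_flow
    cluint <- disposition$cl_u_int_h *
      (if (is.null(subject)) 1 else subject$cl_u_int_multiplier)
    fub <- disposition$fu_blood *
      (if (is.null(subject)) 1 else subject$fu_plasma_multiplier)
    clr_b <- disposition$cl_renal / disposition$blood_plasma_ratio_bp *
      (if (is.null(subject)) 1 else subject$cl_renal_multiplier)
    sys <- c(0.75 * qh, 0.25 * qh, qh, fub * cluint, clr_b,
             disposition$cl_in, disposition$cl_out,
             0.001 * bw, 0.0241 * bw, disposition$vss * bw,
             disposition$v_sac * bw)
  }
  c(1 / physiology$mean_residence_time_h, cs, physiology$fluid_volume_ml,
    ka, dcoef, physchem$particle_density * 1e-9, formulation$dlm_scalar,
    sys)
}

# State layout (keep in sync with src/pbpk_ode.c):
# [1:9] solid mass per segment, [10:18] particle count per segment,
# [19:27] dissolved mass per segment, [28:36] cumulative absorbed per
# segment, [37] exited unabsorbed, [38] portal vein, [39] liver,
# [40] systemic blood, [41] SAC  (amounts in mg)
build_ode_state <- function(formulation, physchem) {
  pp <- init_particle_population(formulation, physchem)
  solid <- numeric(9); count <- numeric(9); dis <- numeric(9)
  solid[1] <- pp$undissolved_mass
  count[1] <- if (nrow(pp$bins)) pp$bins$particle_count else 0
  dis[1] <- formulation$dose * formulation$fraction_dose_dissolved_initial
  y <- c(solid, count, dis, numeric(9), 0, 0, 0, 0, 0)
  names(y) <- c(paste0("solid_", GUT_SEGMENT_NAMES),
                paste0("count_", GUT_SEGMENT_NAMES),
                paste0("dis_", GUT_SEGMENT_NAMES),
                paste0("abs_", GUT_SEGMENT_NAMES),
                "exited", "portal", "liver", "systemic", "sac")
  y
}

summarise_gut_solution <- function(sol, formulation, physiology, physchem,
                                   peff) {
  times <- sol[, "time"]
  dose <- formulation$dose
  ka <- segment_ka(physiology, peff)
  dis_cols <- paste0("dis_", GUT_SEGMENT_NAMES)
  abs_cols <- paste0("abs_", GUT_SEGMENT_NAMES)
  solid_cols <- paste0("solid_", GUT_SEGMENT_NAMES)
  flux <- pmax(as.matrix(sol[, dis_cols, drop = FALSE]) %*% ka, 0)  # mg/h
  absorbed <- sol[, abs_cols, drop = FALSE]
  total_absorbed <- rowSums(absorbed)
  luminal_total <- rowSums(sol[, c(solid_cols, dis_cols), drop = FALSE])
  balance <- luminal_total + total_absorbed + sol[, "exited"]
  mass_balance_error <- max(abs(balance - dose)) / dose
  if (mass_balance_error > 1e-6) {
    stop(sprintf("luminal mass balance violated (%.2e relative)",
                 mass_balance_error))
  }

  seg_fa <- absorbed[nrow(absorbed), ] / dose
  names(seg_fa) <- GUT_SEGMENT_NAMES

  luminal <- do.call(rbind, lapply(c("solid", "dis", "abs"), function(cmp) {
    cols <- paste0(cmp, "_", GUT_SEGMENT_NAMES)
    data.frame(
      time_h = rep(times, times = 9),
      segment = rep(GUT_SEGMENT_NAMES, each = length(times)),
      compartment = c(solid = "undissolved", dis = "dissolved",
                      abs = "absorbed")[[cmp]],
      mass_mg = as.vector(as.matrix(sol[, cols, drop = FALSE]))
    )
  }))

  structure(
    list(
      luminal = luminal,
      portal_flux = data.frame(time_h = times, flux_mg_h = as.vector(flux)),
      fraction_absorbed_fa = unname(total_absorbed[length(total_absorbed)] / dose),
      segment_fa = seg_fa,
      mass_balance_error = mass_balance_error,
      ode = sol
    ),
    class = "gut_simulation"
  )
}

#' @export
print.gut_simulation <- function(x, ...) {
  cat("<gut_simulation>\n")
  cat(sprintf("  fa = %.4f | max mass-balance error %.2e\n",
              x$fraction_absorbed_fa, x$mass_balance_error))
  invisible(x)
}

#' Realised gastric residence time of drug mass
#'
#' Mean residence time of drug (all luminal forms) in the stomach computed
#' from the simulated time course: `MRT = integral(stomach mass) / dose`.
#' For a solute emptied first order this equals the configured gastric MRT.
#'
#' @param gut_sim A [simulate_gut()] result.
#' @return List with `realized_mrt_h` (NA for a zero-dose input, flagged by
#'   `empty = TRUE`).
#' @export
gastric_emptying_observer <- function(gut_sim) {
  stopifnot(inherits(gut_sim, "gut_simulation"))
  sol <- gut_sim$ode
  stomach <- sol[, "solid_stomach"] + sol[, "dis_stomach"]
  dose <- stomach[1] + sol[1, "exited"] +
    sum(sol[1, paste0("solid_", GUT_SEGMENT_NAMES[-1])]) +
    sum(sol[1, paste0("dis_", GUT_SEGMENT_NAMES[-1])])
  if (dose <= 0) {
    return(list(realized_mrt_h = NA_real_, empty = TRUE))
  }
  t <- sol[, "time"]
  auc <- sum(diff(t) * (utils::head(stomach, -1) + utils::tail(stomach, -1)) / 2)
  list(realized_mrt_h = unname(auc / dose), empty = FALSE)
}

#' Closed-form absorbed fraction for a catenary gut with no dissolution limit
#'
#' For a fully dissolved dose transiting a catenary chain with first-order
#' transit `1/tau_i` and absorption `ka_i`, the fraction escaping each
#' segment is `1/(1 + ka_i * tau_i)`, so
#' `fa = 1 - prod_i 1/(1 + ka_i * tau_i)`. Used as the analytic oracle for
#' the ODE integrator in the solubility-unlimited limit.
#'
#' @param physiology A `gut_physiology`.
#' @param peff Effective permeability (cm/s).
#' @return Fraction absorbed.
#' @export
catenary_fa_closed_form <- function(physiology, peff) {
  ka <- segment_ka(physiology, peff)
  tau <- physiology$mean_residence_time_h
  1 - prod(1 / (1 + ka * tau))
}

#' Export a luminal time course as tidy CSV
#' @param gut_sim A [simulate_gut()] result.
#' @param path File path.
#' @export
write_luminal_csv <- function(gut_sim, path) {
  stopifnot(inherits(gut_sim, "gut_simulation"))
  utils::write.csv(gut_sim$luminal, path, row.names = FALSE)
  invisible(path)
}
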