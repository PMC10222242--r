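# Configuration: the full drug/formulation/trial parameterisation as one
# nested list, YAML round trip, strict validation.

#' Default drug model configuration (bempedoic acid 180 mg)
#'
#' The complete shipped parameterisation: physicochemistry (MW 344.5,
#' diprotic acid pKa 4.88/5.60, logP 4.328, intrinsic solubility
#' 0.0051 mg/mL), permeability (3e-4 cm/s effective), formulations
#' (commercial IR tablet, D50 36.4 um, DLM scalar 0.07; pilot oral
#' suspension, D50 50 um, 20 mg/mL vehicle at 118.8 cps, 0.01% of dose in
#' solution, DLM scalar 0.3; 240 mg oral solution), disposition (CLoral
#' 0.81 L/h, CLrenal 0.03 L/h, B:P 0.55, fu 0.026, fa 0.97, fg 1, Q_H
#' 90 L/h, Kp scalar 2, Vss 0.14 L/kg, Vsac 0.1 L/kg, CLin/CLout
#' 3.16/1.32 L/h), fasted gut physiology defaults, the 59-subject
#' population spec and the crossover/parallel trial design.
#'
#' @return A nested list of class `drug_model_config`.
#' @export
default_drug_config <- function() {
  cfg <- list(
    drug = list(
      name = "bempedoic acid",
      molecular_weight = 344.5,
      log_p = 4.328,
      pka1 = 4.88,
      pka2 = 5.60,
      intrinsic_solubility_mg_ml = 0.0051,
      particle_density_g_cm3 = 1.2
    ),
    permeability = list(
      caco2_1e6_cm_s = 11.5,
      peff_cm_s = 3e-4
    ),
    dose_mg = 180,
    formulations = list(
      tablet = list(
        form = "tablet", dose_mg = 180,
        median_particle_diameter_d50_um = 36.4,
        fraction_dose_dissolved_initial = 0,
        dlm_scalar = 0.07
      ),
      suspension = list(
        form = "suspension", dose_mg = 180,
        median_particle_diameter_d50_um = 50,
        fraction_dose_dissolved_initial = 1e-4,
        vehicle_concentration_mg_ml = 20,
        vehicle_viscosity_cps = 118.8,
        dlm_scalar = 0.3
      ),
      solution = list(
        form = "solution", dose_mg = 240,
        fraction_dose_dissolved_initial = 1,
        dlm_scalar = 1
      )
    ),
    disposition = list(
      cl_oral_l_h = 0.81,
      cl_renal_l_h = 0.03,
      blood_plasma_ratio = 0.55,
      fu_plasma = 0.026,
      fa = 0.97,
      fg = 1,
      uptake = 1,
      q_h_l_h = 90,
      kp_scalar = 2,
      vss_l_kg = 0.14,
      v_sac_l_kg = 0.1,
      cl_in_l_h = 3.16,
      cl_out_l_h = 1.32
    ),
    physiology = list(
      gastric_mrt_h = 0.4,
      si_transit_h = 3.34,
      colon_mrt_h = 12,
      stomach_ph = 1.5
    ),
    population = list(
      n_subjects = 59,
      age_min = 20, age_max = 60,
      proportion_female = 0.5,
      occasion_cv = 0.05,
      variability = default_variability()
    ),
    trial = list(
      schedule_study = "004",
      washout_days = 14,
      n_trials = 10
    ),
    seed = 1L
  )
  validate_drug_config(cfg)
}

#' Validate a configuration list
#'
#' Enforces the schema of [default_drug_config()]: unknown keys anywhere in
#' the tree are rejected, required keys must be present, and module-level
#' invariants (pKa ordering, positive dose, fractions in range, Vss >
#' Vsac, ...) are checked. All offending fields are reported together.
#'
#' @param cfg A nested configuration list.
#' @return The validated config, classed `drug_model_config`.
#' @export
validate_drug_config <- function(cfg) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  check_keys <- function(x, allowed, required = allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown)) {
      note(sprintf("%s: unknown key(s) %s", where,
                   paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      note(sprintf("%s: missing key(s) %s", where,
                   paste(missing, collapse = ", ")))
    }
  }

  check_keys(cfg, c("drug", "permeability", "dose_mg", "formulations",
                    "disposition", "physiology", "population", "trial",
                    "seed"), where = "config")
  d <- cfg$drug
  check_keys(d, c("name", "molecular_weight", "log_p", "pka1", "pka2",
                  "intrinsic_solubility_mg_ml", "particle_density_g_cm3"),
             where = "drug")
  if (!is.null(d$pka1) && !is.null(d$pka2) && !(d$pka1 < d$pka2)) {
    note("drug: pka1 must be < pka2")
  }
  if (!is.null(d$molecular_weight) && d$molecular_weight <= 0) {
    note("drug: molecular_weight must be positive")
  }
  if (!is.null(d$intrinsic_solubility_mg_ml) &&
      d$intrinsic_solubility_mg_ml <= 0) {
    note("drug: intrinsic_solubility_mg_ml must be positive")
  }
  check_keys(cfg$permeability, c("caco2_1e6_cm_s", "peff_cm_s"),
             required = "peff_cm_s", where = "permeability")
  if (!is.null(cfg$dose_mg) && cfg$dose_mg <= 0) note("dose_mg must be positive")

  for (fname in names(cfg$formulations)) {
    f <- cfg$formulations[[fname]]
    check_keys(f, c("form", "dose_mg", "median_particle_diameter_d50_um",
                    "fraction_dose_dissolved_initial",
                    "vehicle_concentration_mg_ml", "vehicle_viscosity_cps",
                    "dlm_scalar"),
               required = c("form", "dose_mg", "dlm_scalar"),
               where = paste0("formulations$", fname))
    if (!is.null(f$form) && !f$form %in% c("tablet", "suspension", "solution")) {
      note(sprintf("formulations$%s: unknown form '%s'", fname, f$form))
    }
    fr <- f$fraction_dose_dissolved_initial
    if (!is.null(fr) && (fr < 0 || fr > 1)) {
      note(sprintf("formulations$%s: fraction_dose_dissolved_initial not in [0,1]",
                   fname))
    }
  }

  dp <- cfg$disposition
  check_keys(dp, c("cl_oral_l_h", "cl_renal_l_h", "blood_plasma_ratio",
                   "fu_plasma", "fa", "fg", "uptake", "q_h_l_h", "kp_scalar",
                   "vss_l_kg", "v_sac_l_kg", "cl_in_l_h", "cl_out_l_h"),
             where = "disposition")
  if (!is.null(dp$fu_plasma) && (dp$fu_plasma <= 0 || dp$fu_plasma > 1)) {
    note("disposition: fu_plasma must be in (0,1]")
  }
  if (!is.null(dp$fa) && (dp$fa <= 0 || dp$fa > 1)) {
    note("disposition: fa must be in (0,1]")
  }
  if (!is.null(dp$vss_l_kg) && !is.null(dp$v_sac_l_kg) &&
      !(dp$vss_l_kg > dp$v_sac_l_kg)) {
    note("disposition: vss_l_kg must exceed v_sac_l_kg")
  }
  check_keys(cfg$physiology, c("gastric_mrt_h", "si_transit_h",
                               "colon_mrt_h", "stomach_ph"),
             where = "physiology")
  pp <- cfg$population
  check_keys(pp, c("n_subjects", "age_min", "age_max", "proportion_female",
                   "occasion_cv", "variability"), where = "population")
  if (!is.null(pp$variability)) {
    check_keys(pp$variability, names(default_variability()),
               required = character(), where = "population$variability")
  }
  check_keys(cfg$trial, c("schedule_study", "washout_days", "n_trials"),
             where = "trial")

  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "drug_model_config")
}

#' Load / save a configuration as YAML
#'
#' `load_config()` reads, validates and returns the configuration;
#' `save_config()` writes it. The round trip is the identity.
#'
#' @param path File path.
#' @return `load_config()`: a validated `drug_model_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_drug_config(cfg)
}

#' @rdname load_config
#' @param cfg A `drug_model_config`.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_drug_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.drug_model_config <- function(x, ...) {
  cat(sprintf("<drug_model_config> %s, dose %g mg\n", x$drug$name, x$dose_mg))
  cat("  formulations:", paste(names(x$formulations), collapse = ", "), "\n")
  cat(sprintf("  population n = %d, trial schedule study %s\n",
              x$population$n_subjects, x$trial$schedule_study))
  invisible(x)
}

# ---- accessors: build module objects from a config ----

#' Build module objects from a configuration
#'
#' `config_physchem()`, `config_formulation()`, `config_disposition()`,
#' `config_physiology()`, `config_population_spec()` and
#' `config_trial_design()` construct the validated module objects from a
#' `drug_model_config`.
#'
#' @param cfg A `drug_model_config`.
#' @param name Formulation name (for `config_formulation()`).
#' @param kind Trial kind (for `config_trial_design()`).
#' @name config-accessors
NULL

#' @rdname config-accessors
#' @export
config_physchem <- function(cfg) {
  d <- cfg$drug
  drug_physchem(d$molecular_weight, d$log_p, d$pka1, d$pka2,
                d$intrinsic_solubility_mg_ml, d$particle_density_g_cm3)
}

#' @rdname config-accessors
#' @export
config_formulation <- function(cfg, name) {
  f <- cfg$formulations[[name]]
  if (is.null(f)) stop("no formulation named '", name, "' in config")
  formulation_spec(
    form = f$form, dose = f$dose_mg,
    median_particle_diameter_d50 = f$median_particle_diameter_d50_um %||% NA_real_,
    fraction_dose_dissolved_initial = f$fraction_dose_dissolved_initial %||% 0,
    vehicle_concentration = f$vehicle_concentration_mg_ml %||% NA_real_,
    vehicle_viscosity = f$vehicle_viscosity_cps %||% NA_real_,
    dlm_scalar = f$dlm_scalar
  )
}

#' @rdname config-accessors
#' @export
config_disposition <- function(cfg) {
  d <- cfg$disposition
  disposition_params(
    cl_oral = d$cl_oral_l_h, cl_renal = d$cl_renal_l_h,
    blood_plasma_ratio_bp = d$blood_plasma_ratio, fu_plasma = d$fu_plasma,
    fa = d$fa, fg = d$fg, uptake = d$uptake, q_h = d$q_h_l_h,
    vss = d$vss_l_kg, v_sac = d$v_sac_l_kg,
    cl_in = d$cl_in_l_h, cl_out = d$cl_out_l_h, kp_scalar = d$kp_scalar
  )
}

#' @rdname config-accessors
#' @export
config_physiology <- function(cfg) {
  p <- cfg$physiology
  default_fasted_physiology(gastric_mrt_h = p$gastric_mrt_h,
                            si_transit_h = p$si_transit_h,
                            colon_mrt_h = p$colon_mrt_h,
                            stomach_ph = p$stomach_ph)
}

#' @rdname config-accessors
#' @export
config_population_spec <- function(cfg) {
  p <- cfg$population
  population_spec(n_subjects = p$n_subjects,
                  age_range = c(p$age_min, p$age_max),
                  proportion_female = p$proportion_female,
                  variability = p$variability,
                  occasion_cv = p$occasion_cv,
                  seed = cfg$seed)
}

#' @rdname config-accessors
#' @export
config_trial_design <- function(cfg, kind = "crossover") {
  trial_design(kind = kind, washout = cfg$trial$washout_days,
               sampling_schedule = study_schedule(cfg$trial$schedule_study),
               n_trials = cfg$trial$n_trials)
}

#' Replace fields of a population spec
#' @param spec A [population_spec()].
#' @param ... Fields to replace (e.g. `seed`, `n_subjects`).
#' @return A new `population_spec`.
#' @export
modify_population_spec <- function(spec, ...) {
  stopifnot(inherits(spec, "population_spec"))
  repl <- list(...)
  for (nm in names(repl)) spec[[nm]] <- repl[[nm]]
  population_spec(n_subjects = spec$n_subjects, age_range = spec$age_range,
                  proportion_female = spec$proportion_female,
                  variability = spec$variability,
                  occasion_cv = spec$occasion_cv, seed = spec$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the configuration hash (MD5 of its YAML serialisation), seed,
#' package version and timestamp next to a set of CSV outputs, so a run
#' can be reproduced exactly.
#'
#' @param cfg A `drug_model_config`.
#' @param seed Integer seed of the run.
#' @param outputs Character vector of files written.
#' @param path Manifest path (JSON).
#' @export
write_run_manifest <- function(cfg, seed, outputs, path) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("pbpkbe")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
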