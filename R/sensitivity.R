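# Physiology-exposure sensitivity and the biopharmaceutical safe space.

#' Correlate gastrointestinal physiology with PK outputs
#'
#' Pearson correlations between each subject-level physiology value and
#' each subject-level PK output, pooled across all trials of a trial set
#' (or any subject-level data frame with the physiology and PK columns).
#' Zero-variance inputs are flagged as undefined, not silently zero.
#'
#' @param subject_data A `trial_set`, `be_trial`, or data frame holding the
#'   physiology columns and PK outputs.
#' @param parameters Physiology columns; defaults to gastric, small
#'   intestine and colon transit times and fasted stomach pH.
#' @param outputs PK columns.
#' @param arm For trial data, which arm's outputs to use (physiology is
#'   identical across arms).
#'
#' @return A `sensitivity_report`: data frame `parameter`, `output`, `r`,
#'   `n`, `undefined`.
#' @export
correlate_physiology <- function(subject_data,
                                 parameters = c("gastric_tt", "stomach_ph",
                                                "si_tt", "colon_tt"),
                                 outputs = c("cmax", "tmax", "auc_inf"),
                                 arm = "ref") {
  df <- subject_level_data(subject_data)
  if ("arm" %in% names(df)) df <- df[df$arm == arm, ]
  if (nrow(df) < 3) stop("need at least 3 pooled subjects")
  missing_cols <- setdiff(c(parameters, outputs), names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  grid <- expand.grid(parameter = parameters, output = outputs,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- df[[grid$parameter[i]]]; y <- df[[grid$output[i]]]
    ok <- is.finite(x) & is.finite(y)
    undef <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0 || sum(ok) < 3
    data.frame(parameter = grid$parameter[i], output = grid$output[i],
               r = if (undef) NA_real_ else stats::cor(x[ok], y[ok]),
               n = sum(ok), undefined = undef)
  })
  structure(do.call(rbind, res), class = c("sensitivity_report", "data.frame"))
}

subject_level_data <- function(x) {
  if (inherits(x, "trial_set")) return(x$subject_pk)
  if (inherits(x, "be_trial")) return(x$subject_pk)
  as.data.frame(x)
}

#' Worst-case suspension: nearly all drug pre-dissolved
#'
#' Re-runs the crossover bioequivalence assessment with the test
#' suspension's fraction of dose in solution raised to the boundary value
#' (default 0.99), everything else unchanged, using the same seed as the
#' base run so the difference reflects the changed input only. Reports the
#' worst-case GMRs/CIs and the geometric-mean tmax shift versus base.
#'
#' @param config Drug model configuration.
#' @param fraction Boundary fraction of dose in solution.
#' @param seed Trial seed (population + occasion noise).
#' @param design A [trial_design()].
#'
#' @return List with `base` and `worst` (`be_trial`s), `tmax_ratio`
#'   (geometric-mean worst/base tmax of the test arm) and
#'   `tmax_shift_pct`.
#' @export
worst_case_fraction_dissolved <- function(config, fraction = 0.99, seed = 1L,
                                          design = trial_design("crossover")) {
  stopifnot(fraction >= 0, fraction <= 1)
  test <- config_formulation(config, "suspension")
  ref <- config_formulation(config, "tablet")
  worst_test <- test
  worst_test$fraction_dose_dissolved_initial <- fraction
  pop <- generate_population(
    modify_population_spec(config_population_spec(config), seed = seed)
  )
  base <- run_be_trial(design, test, ref, pop, config, seed = seed)
  worst <- run_be_trial(design, worst_test, ref, pop, config, seed = seed)
  gm <- function(x) exp(mean(log(x)))
  tb <- base$subject_pk$tmax[base$subject_pk$arm == "test"]
  tw <- worst$subject_pk$tmax[worst$subject_pk$arm == "test"]
  ratio <- gm(tw) / gm(tb)
  list(base = base, worst = worst, tmax_ratio = ratio,
       tmax_shift_pct = 100 * (ratio - 1))
}

#' Scan the particle-size x fraction-dissolved safe space
#'
#' One crossover bioequivalence evaluation per grid cell, with the test
#' suspension's median particle diameter and initial fraction dissolved
#' set to the cell values. The identical seed is used in every cell, so
#' differences between cells reflect the varied formulation attributes
#' only.
#'
#' @param d50_grid Median particle diameters (um).
#' @param fraction_grid Initial fractions of dose in solution.
#' @param config Drug model configuration.
#' @param seed Trial seed shared by all cells.
#' @param design A [trial_design()].
#'
#' @return A `safe_space_map`: data frame `d50_um`,
#'   `fraction_dissolved`, `cmax_gmr`, `auc_gmr`, `pass_be`.
#' @export
safe_space_scan <- function(d50_grid = c(10, 25, 50, 100, 200),
                            fraction_grid = c(1e-4, 0.01, 0.5, 0.99),
                            config = default_drug_config(), seed = 1L,
                            design = trial_design("crossover")) {
  stopifnot(length(d50_grid) >= 1, length(fraction_grid) >= 1)
  ref <- config_formulation(config, "tablet")
  base_test <- config_formulation(config, "suspension")
  pop <- generate_population(
    modify_population_spec(config_population_spec(config), seed = seed)
  )
  grid <- expand.grid(d50_um = d50_grid, fraction_dissolved = fraction_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    test <- base_test
    test$median_particle_diameter_d50 <- grid$d50_um[i]
    test$fraction_dose_dissolved_initial <- grid$fraction_dissolved[i]
    tr <- run_be_trial(design, test, ref, pop, config, seed = seed)
    data.frame(
      d50_um = grid$d50_um[i],
      fraction_dissolved = grid$fraction_dissolved[i],
      cmax_gmr = tr$results$cmax$gmr,
      auc_gmr = tr$results$auc_last$gmr,
      pass_be = tr$results$cmax$pass_be && tr$results$auc_last$pass_be &&
        tr$results$auc_inf$pass_be
    )
  })
  structure(do.call(rbind, rows),
            seed = seed, class = c("safe_space_map", "data.frame"))
}

#' @export
print.safe_space_map <- function(x, ...) {
  cat(sprintf("<safe_space_map> %d cells, %d pass BE\n", nrow(x),
              sum(x$pass_be)))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity report or safe-space map as CSV
#' @param x A `sensitivity_report` or `safe_space_map`.
#' @param path File path.
#' @export
write_sensitivity_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
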