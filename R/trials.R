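# Virtual bioequivalence trials: designs, GMR statistics, trial sets.

#' Bioequivalence trial design
#'
#' @param kind `"crossover"` (identical subjects in both periods, paired
#'   analysis) or `"parallel"` (population split 1:1, Welch analysis).
#' @param washout Washout between crossover periods (days); the simulation
#'   resets all state between periods, so this is bookkeeping only.
#' @param sampling_schedule PK sampling times (h).
#' @param n_trials Number of replicate trials for [trial_set_summary()].
#'
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(kind = c("crossover", "parallel"), washout = 14,
                         sampling_schedule = study_schedule("004"),
                         n_trials = 10) {
  kind <- match.arg(kind)
  stopifnot(washout >= 0, n_trials >= 1, all(sampling_schedule >= 0))
  structure(
    list(kind = kind, washout = washout,
         sampling_schedule = sort(unique(sampling_schedule)),
         n_trials = as.integer(n_trials)),
    class = "trial_design"
  )
}

#' Clinical-style PK sampling schedules
#'
#' Named schedules of the studies emulated by the synthetic-data module:
#' `"001"` (single oral solution, to 168 h), `"002"` and `"004"` (single
#' tablet dose, to 120 h).
#'
#' @param study One of `"001"`, `"002"`, `"004"`.
#' @return Numeric vector of sampling times (h), including pre-dose 0.
#' @export
study_schedule <- function(study = c("004", "002", "001")) {
  study <- match.arg(study)
  switch(study,
    "001" = c(0, 2, 4, 6, 12, 24, 48, 96, 144, 168),
    "002" = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24, 48, 72, 96, 120),
    "004" = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 24, 48, 72, 96, 120)
  )
}

#' Geometric mean ratio with 90% confidence interval
#'
#' Log-scale analysis of test/reference exposure. Crossover: the mean
#' within-subject log difference with a t(n-1) interval. Parallel: the
#' difference of arm log-means with a Welch t interval. The GMR and bounds
#' are returned in percent; `pass_be` is `TRUE` when the whole CI lies in
#' [80, 125].
#'
#' @param test,ref Positive exposure values. Crossover: equal-length paired
#'   vectors (same subject order). Parallel: the two independent arms.
#' @param design `"crossover"` or `"parallel"` (or a [trial_design()]).
#' @param parameter Label carried in the result.
#' @param conf Confidence level of the two-sided interval (0.90 for the
#'   standard two-one-sided-tests assessment).
#'
#' @return An object of class `be_result`.
#' @export
gmr_ci <- function(test, ref, design = "crossover", parameter = "exposure",
                   conf = 0.90) {
  if (inherits(design, "trial_design")) design <- design$kind
  design <- match.arg(design, c("crossover", "parallel"))
  test <- test[is.finite(test)]; ref <- ref[is.finite(ref)]
  if (any(c(test, ref) <= 0)) stop("exposure values must be positive")
  alpha <- (1 - conf) / 2
  if (design == "crossover") {
    if (length(test) != length(ref)) stop("crossover requires paired values")
    n <- length(test)
    if (n < 2) stop("need at least 2 subjects per arm")
    d <- log(test) - log(ref)
    est <- mean(d)
    se <- stats::sd(d) / sqrt(n)
    if (!is.finite(se) || se == 0) {
      lo <- hi <- est
    } else {
      tq <- stats::qt(1 - alpha, df = n - 1)
      lo <- est - tq * se; hi <- est + tq * se
    }
  } else {
    n1 <- length(test); n2 <- length(ref)
    if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per arm")
    lt <- log(test); lr <- log(ref)
    est <- mean(lt) - mean(lr)
    v1 <- stats::var(lt) / n1; v2 <- stats::var(lr) / n2
    se <- sqrt(v1 + v2)
    if (se == 0) {
      lo <- hi <- est
    } else {
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
      tq <- stats::qt(1 - alpha, df = df)
      lo <- est - tq * se; hi <- est + tq * se
    }
  }
  gcv <- function(x) {
    if (length(x) < 2) return(NA_real_)
    100 * sqrt(exp(stats::var(log(x))) - 1)
  }
  new_be_result(parameter, design, 100 * exp(est), 100 * exp(lo),
                100 * exp(hi), gcv(test), gcv(ref),
                n_test = length(test), n_ref = length(ref))
}

new_be_result <- function(parameter, design, gmr, lo, hi, cv_test, cv_ref,
                          n_test, n_ref) {
  stopifnot(lo <= gmr + 1e-9, gmr <= hi + 1e-9)
  structure(
    list(parameter = parameter, design = design, gmr = gmr,
         ci90_low = lo, ci90_high = hi,
         percent_cv_test = cv_test, percent_cv_ref = cv_ref,
         pass_be = (lo >= 80 && hi <= 125),
         n_test = n_test, n_ref = n_ref),
    class = "be_result"
  )
}

#' @export
print.be_result <- function(x, ...) {
  cat(sprintf("<be_result> %s (%s): GMR %.1f%% (90%% CI %.1f-%.1f) %s\n",
              x$parameter, x$design, x$gmr, x$ci90_low, x$ci90_high,
              if (x$pass_be) "PASS" else "FAIL"))
  invisible(x)
}

# Simulate all subjects of a population for one formulation; returns
# subject-level NCA and (optionally) the sampled profiles.
simulate_pk_population <- function(population, formulation, config,
                                   schedule = study_schedule("004"),
                                   occasion_multipliers = NULL,
                                   keep_profiles = FALSE) {
  physchem <- config_physchem(config)
  params <- config_disposition(config)
  base_phys <- config_physiology(config)
  peff <- config$permeability$peff_cm_s
  n <- length(population)
  if (is.null(occasion_multipliers)) occasion_multipliers <- rep(1, n)
  rows <- vector("list", n)
  profs <- if (keep_profiles) vector("list", n) else NULL
  for (i in seq_len(n)) {
    subj <- population[[i]]
    prof <- simulate_subject_profile(subj, params, formulation, physchem,
                                     base_phys, peff,
                                     duration = max(schedule, 120))
    prof$conc_ug_ml <- prof$conc_ug_ml * occasion_multipliers[i]
    pk <- nca(prof, schedule)
    rows[[i]] <- data.frame(
      subject_id = subj$id,
      cmax = pk$cmax, tmax = pk$tmax,
      auc_last = pk$auc_last, auc_inf = pk$auc_inf,
      gastric_tt = subj$gastric_mrt_multiplier *
        attr(base_phys, "gastric_transit_time"),
      stomach_ph = subj$stomach_ph,
      si_tt = subj$si_transit_multiplier *
        attr(base_phys, "small_intestine_transit_time"),
      colon_tt = subj$colon_mrt_multiplier *
        attr(base_phys, "colon_transit_time"),
      undefined = pk$undefined
    )
    if (keep_profiles) {
      profs[[i]] <- data.frame(subject_id = subj$id, time_h = pk$schedule,
                               conc_ug_ml = pk$sampled)
    }
  }
  out <- list(pk = do.call(rbind, rows))
  if (keep_profiles) out$profiles <- do.call(rbind, profs)
  out
}

#' Run one virtual bioequivalence trial
#'
#' Simulates every subject under test and reference formulations and
#' analyses Cmax, AUC_last and AUC_inf with [gmr_ci()]. Crossover:
#' identical physiology in both periods, with an independent lognormal
#' occasion multiplier (CV from the population spec) per period; the
#' washout resets all state. Parallel: the population is split 1:1 at
#' random under the trial seed, one arm per formulation. Subjects whose
#' NCA fails are excluded with a warning and counted in `excluded`.
#'
#' @param design A [trial_design()].
#' @param test,ref [formulation_spec()]s for test and reference.
#' @param population A `virtual_population`.
#' @param config A drug model configuration ([default_drug_config()]).
#' @param seed Integer seed for the occasion noise and the parallel split.
#'
#' @return An object of class `be_trial`: list of `be_result` per
#'   parameter (`cmax`, `auc_last`, `auc_inf`), subject-level data
#'   (`subject_pk`), `excluded` count.
#' @export
run_be_trial <- function(design, test, ref, population, config, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  n <- length(population)
  occ_cv <- config$population$occasion_cv
  schedule <- design$sampling_schedule
  with_seed(seed, {
    if (design$kind == "crossover") {
      occ_t <- rlnorm_cv(n, occ_cv)
      occ_r <- rlnorm_cv(n, occ_cv)
      sim_t <- simulate_pk_population(population, test, config, schedule,
                                      occasion_multipliers = occ_t)
      sim_r <- simulate_pk_population(population, ref, config, schedule,
                                      occasion_multipliers = occ_r)
      pk_t <- sim_t$pk; pk_r <- sim_r$pk
      ok <- !(pk_t$undefined | pk_r$undefined) &
        is.finite(pk_t$auc_inf) & is.finite(pk_r$auc_inf)
      excluded <- sum(!ok)
      if (excluded > 0) {
        warning(sprintf("%d subject(s) excluded for failed NCA", excluded))
      }
      results <- lapply(c("cmax", "auc_last", "auc_inf"), function(p) {
        gmr_ci(pk_t[[p]][ok], pk_r[[p]][ok], "crossover", parameter = p)
      })
      subject_pk <- rbind(
        cbind(pk_r[ok, ], arm = "ref", period = 1L),
        cbind(pk_t[ok, ], arm = "test", period = 2L)
      )
    } else {
      idx <- sample(n)
      test_idx <- sort(idx[seq_len(ceiling(n / 2))])
      ref_idx <- sort(setdiff(seq_len(n), test_idx))
      occ <- rlnorm_cv(n, occ_cv)
      sim_t <- simulate_pk_population(population[test_idx], test, config,
                                      schedule,
                                      occasion_multipliers = occ[test_idx])
      sim_r <- simulate_pk_population(population[ref_idx], ref, config,
                                      schedule,
                                      occasion_multipliers = occ[ref_idx])
      pk_t <- sim_t$pk[!sim_t$pk$undefined & is.finite(sim_t$pk$auc_inf), ]
      pk_r <- sim_r$pk[!sim_r$pk$undefined & is.finite(sim_r$pk$auc_inf), ]
      excluded <- (nrow(sim_t$pk) - nrow(pk_t)) +
        (nrow(sim_r$pk) - nrow(pk_r))
      if (excluded > 0) {
        warning(sprintf("%d subject(s) excluded for failed NCA", excluded))
      }
      results <- lapply(c("cmax", "auc_last", "auc_inf"), function(p) {
        gmr_ci(pk_t[[p]], pk_r[[p]], "parallel", parameter = p)
      })
      subject_pk <- rbind(cbind(pk_r, arm = "ref", period = 1L),
                          cbind(pk_t, arm = "test", period = 1L))
    }
    names(results) <- c("cmax", "auc_last", "auc_inf")
    structure(
      list(results = results, subject_pk = subject_pk,
           excluded = excluded, design = design, seed = seed),
      class = "be_trial"
    )
  })
}

#' @export
print.be_trial <- function(x, ...) {
  cat(sprintf("<be_trial> %s, n = %d%s\n", x$design$kind,
              length(unique(x$subject_pk$subject_id)),
              if (x$excluded) sprintf(" (%d excluded)", x$excluded) else ""))
  for (r in x$results) print(r)
  invisible(x)
}

#' Summarise a trial as a tidy data frame
#' @param trial A `be_trial`.
#' @param trial_id Optional id column value.
#' @return Data frame, one row per PK parameter.
#' @export
be_trial_table <- function(trial, trial_id = NA_integer_) {
  do.call(rbind, lapply(trial$results, function(r) {
    data.frame(trial_id = trial_id, parameter = r$parameter,
               gmr_pct = r$gmr, ci_low_pct = r$ci90_low,
               ci_high_pct = r$ci90_high, cv_test = r$percent_cv_test,
               cv_ref = r$percent_cv_ref, pass_be = r$pass_be)
  }))
}

#' Run a set of replicate virtual trials
#'
#' Runs `n_trials` independent trials; each trial regenerates its
#' population and occasion noise under a seed derived deterministically
#' from `base_seed` (`base_seed + trial index`). Returns a forest-plot
#' style table of per-trial GMRs and CIs and flags trials whose CI exits
#' the 80-125% window.
#'
#' @param design A [trial_design()] (its `n_trials` is used unless
#'   `n_trials` is given).
#' @param test,ref Formulations.
#' @param config Drug model configuration.
#' @param base_seed Integer base seed.
#' @param n_trials Number of trials.
#'
#' @return An object of class `trial_set`: `table` (per-trial per-parameter
#'   rows), `trials` (list of `be_trial`), `subject_pk` (pooled
#'   subject-level data with `trial_id`), `seeds`.
#' @export
trial_set_summary <- function(design, test, ref, config, base_seed = 1L,
                              n_trials = design$n_trials) {
  stopifnot(n_trials >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_trials)
  trials <- vector("list", n_trials)
  tabs <- vector("list", n_trials)
  subj <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    pop <- generate_population(
      modify_population_spec(config_population_spec(config), seed = seeds[i])
    )
    trials[[i]] <- run_be_trial(design, test, ref, pop, config,
                                seed = seeds[i])
    tabs[[i]] <- be_trial_table(trials[[i]], trial_id = i)
    subj[[i]] <- cbind(trials[[i]]$subject_pk, trial_id = i)
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  structure(
    list(table = table, trials = trials,
         subject_pk = do.call(rbind, subj), seeds = seeds,
         flagged = unique(table$trial_id[!table$pass_be])),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trial(s)\n", length(x$trials)))
  print(x$table, row.names = FALSE)
  if (length(x$flagged)) {
    cat("trials with CI outside 80-125%:", paste(x$flagged, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Geometric mean of per-trial GMRs for one parameter
#' @param trial_set A `trial_set`.
#' @param parameter `"cmax"`, `"auc_last"` or `"auc_inf"`.
#' @return Percent GMR.
#' @export
pooled_gmr <- function(trial_set, parameter) {
  g <- trial_set$table$gmr_pct[trial_set$table$parameter == parameter]
  exp(mean(log(g)))
}

#' Write a trial-set table as CSV
#' @param trial_set A `trial_set`.
#' @param path File path.
#' @export
write_trials_csv <- function(trial_set, path) {
  utils::write.csv(trial_set$table, path, row.names = FALSE)
  invisible(path)
}
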