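# Shared fixtures: the shipped bempedoic-acid parameterisation and small
# variants used to keep simulation-heavy tests fast.

bpa_config <- function() default_drug_config()

bpa_physchem <- function() config_physchem(bpa_config())

# a reduced-population copy of the shipped config for trial mechanics tests
small_config <- function(n = 8, occasion_cv = 0.05, variability = NULL) {
  cfg <- default_drug_config()
  cfg$population$n_subjects <- n
  cfg$population$occasion_cv <- occasion_cv
  if (!is.null(variability)) cfg$population$variability <- variability
  validate_drug_config(cfg)
}

zero_variability <- function() {
  v <- default_variability()
  v[names(v)] <- 0
  v
}

usp2_media <- function() {
  list(medium_state(1.2, 900), medium_state(4.5, 900),
       medium_state(6.6, 900), medium_state(6.8, 900))
}

usp2_timepoints <- function() c(5, 10, 15, 20, 30, 45, 60, 75)
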