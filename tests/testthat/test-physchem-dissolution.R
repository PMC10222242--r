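# pH-dependent solubility, diffusivity, particle populations and the
# closed-vessel USP II dissolution simulation.

test_that("diprotic-acid solubility follows the Henderson-Hasselbalch form", {
  pc <- bpa_physchem()
  # far below pKa1 the neutral species dominates: S -> S0
  expect_equal(solubility_at_ph(pc, 1.2), 0.0051, tolerance = 1e-3)
  # hand evaluation of S0*(1 + 10^1.92 + 10^3.12)
  expect_equal(solubility_at_ph(pc, 6.8),
               0.0051 * (1 + 10^1.92 + 10^3.12), tolerance = 1e-12)
  expect_equal(solubility_at_ph(pc, 6.8), 7.15, tolerance = 1e-3)
  # hand evaluation at the suspension vehicle pH
  expect_equal(solubility_at_ph(pc, 4.53),
               0.0051 * (1 + 10^-0.35 + 10^-1.42), tolerance = 1e-12)
  expect_equal(solubility_at_ph(pc, 4.53), 0.00757, tolerance = 1e-3)
  # strictly increasing in pH, never below S0
  ph <- seq(0, 14, by = 0.25)
  s <- solubility_at_ph(pc, ph)
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= pc$intrinsic_solubility_s0))
  expect_error(solubility_at_ph(pc, NaN), "finite")
  expect_error(solubility_at_ph(pc, -1), "within")
})

test_that("equilibrium fraction dissolved is the solubility-cap law", {
  pc <- bpa_physchem()
  expect_equal(equilibrium_fraction_dissolved(180, medium_state(4.5, 900), pc),
               solubility_at_ph(pc, 4.5) * 900 / 180, tolerance = 1e-12)
  expect_equal(equilibrium_fraction_dissolved(180, medium_state(4.5, 900), pc),
               0.037, tolerance = 0.01)
  # high pH: solubility x volume >> dose, capped at 1
  expect_identical(equilibrium_fraction_dissolved(180, medium_state(6.8, 900), pc), 1)
  # suspension vehicle: 9 mL at pH 4.53 -> ~0.038% in solution
  expect_equal(equilibrium_fraction_dissolved(180, medium_state(4.53, 9), pc),
               3.8e-4, tolerance = 0.01)
  expect_error(equilibrium_fraction_dissolved(0, medium_state(4.5, 900), pc),
               "positive")
})

test_that("Stokes-Einstein diffusivity scales as 1/viscosity", {
  pc <- bpa_physchem()
  m1 <- medium_state(6.8, 900, viscosity = water_viscosity_cps())
  m2 <- medium_state(6.8, 900, viscosity = 2 * water_viscosity_cps())
  m3 <- medium_state(6.8, 900, viscosity = 118.8)
  d1 <- diffusion_coefficient(pc, m1)
  expect_equal(diffusion_coefficient(pc, m2), d1 / 2, tolerance = 1e-12)
  expect_equal(diffusion_coefficient(pc, m3) / d1, 0.6915 / 118.8,
               tolerance = 1e-12)
  # order of magnitude for a small molecule in water at 310 K
  expect_gt(d1, 2e-6)
  expect_lt(d1, 2e-5)
})

test_that("particle populations conserve mass and handle solutions", {
  pc <- bpa_physchem()
  susp <- formulation_spec("suspension", dose = 180,
                           median_particle_diameter_d50 = 50,
                           vehicle_concentration = 20,
                           vehicle_viscosity = 118.8, dlm_scalar = 0.3)
  pp <- init_particle_population(susp, pc)
  # N = solid mass / ((4/3) pi r^3 rho), r = 25 um
  n_expect <- 0.18 / ((4 / 3) * pi * (2.5e-3)^3 * 1.2)
  expect_equal(pp$bins$particle_count, n_expect, tolerance = 1e-6)
  expect_equal(pp$bins$particle_count, 2.29e6, tolerance = 0.005)
  # mass reconstruction identity within 0.1%
  recon <- pp$bins$particle_count *
    (4 / 3) * pi * pp$bins$radius_um^3 * pc$particle_density * 1e-9
  expect_equal(recon, pp$undissolved_mass, tolerance = 1e-3)
  # solutions carry no particles
  sol <- formulation_spec("solution", dose = 240)
  pps <- init_particle_population(sol, pc)
  expect_identical(nrow(pps$bins), 0L)
  expect_identical(pps$undissolved_mass, 0)
  expect_error(formulation_spec("tablet", dose = 180,
                                median_particle_diameter_d50 = 0),
               "positive")
})

test_that("diffusion-layer rate law matches its stated form", {
  pc <- bpa_physchem()
  m_sink <- medium_state(6.8, 900, dissolved_mass = 0)
  one <- structure(list(bins = data.frame(radius_um = 25, particle_count = 1),
                        undissolved_mass = 1e-4),
                   class = "particle_population")
  # independent evaluation: 4*pi*D*Cs*(r/h_eff) in mg/s, h_eff = r at 25 um
  d <- diffusion_coefficient(pc, m_sink)
  cs <- solubility_at_ph(pc, 6.8)
  expect_equal(dlm_rate(one, m_sink, pc, 1), 4 * pi * d * cs,
               tolerance = 1e-12)
  # ~0.5-0.6 ug/s for a single particle under sink at pH 6.8
  expect_equal(dlm_rate(one, m_sink, pc, 1) * 1e3, 0.6, tolerance = 0.15)
  # zero driving force -> zero rate for every bin
  m_sat <- medium_state(6.8, 900, dissolved_mass = cs * 900)
  expect_identical(dlm_rate(one, m_sat, pc, 1), 0)
  # above saturation the rate clamps at zero (no precipitation)
  m_super <- medium_state(6.8, 900, dissolved_mass = 2 * cs * 900)
  expect_identical(dlm_rate(one, m_super, pc, 1), 0)
  # linear in the DLM scalar
  expect_equal(dlm_rate(one, m_sink, pc, 0.6), 2 * dlm_rate(one, m_sink, pc, 0.3),
               tolerance = 1e-12)
})

test_that("USP II simulation reproduces the plateau law in all four media", {
  cfg <- bpa_config()
  pc <- bpa_physchem()
  tab <- config_formulation(cfg, "tablet")
  susp <- config_formulation(cfg, "suspension")
  for (form in list(tab, susp)) {
    for (m in usp2_media()) {
      prof <- simulate_usp2(form, m, c(usp2_timepoints(), 600), pc)
      expect_true(all(diff(prof$fraction_dissolved) >= -1e-9))
      expect_true(all(prof$fraction_dissolved >= 0 &
                        prof$fraction_dissolved <= 1))
      cap <- equilibrium_fraction_dissolved(form$dose, m, pc)
      # terminal fraction equals min(1, Cs V / dose) within 1%
      expect_equal(prof$fraction_dissolved[length(prof$fraction_dissolved)],
                   cap, tolerance = 0.01)
      expect_true(all(prof$fraction_dissolved <= cap + 1e-6))
    }
  }
  # near-complete dissolution by 75 min at intestinal pH for both solids
  for (form in list(tab, susp)) {
    for (ph in c(6.6, 6.8)) {
      prof <- simulate_usp2(form, medium_state(ph, 900), usp2_timepoints(), pc)
      expect_gte(prof$fraction_dissolved[8], 0.90)
    }
  }
  # a fully pre-dissolved dose stays at 1
  sol <- formulation_spec("solution", dose = 180)
  prof <- simulate_usp2(sol, medium_state(6.8, 900), usp2_timepoints(), pc)
  expect_equal(prof$fraction_dissolved, rep(1, 8), tolerance = 1e-12)
})

test_that("dissolution kinetics respect D50, DLM-scalar and viscosity monotonicity", {
  pc <- bpa_physchem()
  m <- medium_state(6.8, 900)
  tp <- c(0.5, 1, 2)
  mk <- function(d50, scalar, visc = NULL) {
    f <- formulation_spec("tablet", dose = 180,
                          median_particle_diameter_d50 = d50,
                          dlm_scalar = scalar)
    med <- if (is.null(visc)) m else medium_state(6.8, 900, viscosity = visc)
    simulate_usp2(f, med, tp, pc)$fraction_dissolved
  }
  # slower kinetics regime so the ceiling does not mask ordering
  f_small <- mk(40, 1e-3); f_mid <- mk(80, 1e-3); f_large <- mk(160, 1e-3)
  expect_true(all(f_small >= f_mid - 1e-9))
  expect_true(all(f_mid >= f_large - 1e-9))
  expect_true(all(mk(80, 2e-3) >= f_mid - 1e-9))
  expect_true(all(mk(80, 1e-3, visc = 10) <= f_mid + 1e-9))
})

test_that("adaptive integration matches a fixed-step reference on a small instance", {
  pc <- bpa_physchem()
  dose_toy <- 10 * (4 / 3) * pi * (25e-4)^3 * 1.2 * 1e3  # 10 particles, mg
  toy <- formulation_spec("tablet", dose = dose_toy,
                          median_particle_diameter_d50 = 50,
                          dlm_scalar = 1e-4)
  m <- medium_state(6.8, 10)
  tp <- c(0.5, 1, 2, 5, 10)
  a <- simulate_usp2(toy, m, tp, pc)
  b <- simulate_usp2_fixed_step(toy, m, tp, pc, dt = 0.01)
  expect_equal(a$fraction_dissolved, b$fraction_dissolved, tolerance = 5e-3)
})

test_that("dissolution profiles round-trip through CSV", {
  cfg <- bpa_config()
  pc <- bpa_physchem()
  prof <- simulate_usp2(config_formulation(cfg, "tablet"),
                        medium_state(6.8, 900), usp2_timepoints(), pc)
  path <- tempfile(fileext = ".csv")
  write_dissolution_csv(prof, path)
  back <- read_dissolution_csv(path)
  expect_equal(back$fraction_dissolved, prof$fraction_dissolved,
               tolerance = 1e-9)
  expect_equal(back$ph, prof$ph)
})
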