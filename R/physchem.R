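# Physicochemical primitives: diprotic-acid solubility, molecular diffusivity,
# dissolution media.

#' Drug physicochemical parameter set
#'
#' Bundles the physicochemical constants of a diprotic acid needed by the
#' dissolution and disposition models.
#'
#' @param molecular_weight Molecular weight (g/mol).
#' @param log_p Octanol:water log partition coefficient of the neutral
#'   species.
#' @param pka1,pka2 First and second acid dissociation constants
#'   (`pka1 < pka2`).
#' @param intrinsic_solubility_s0 Intrinsic (neutral species) aqueous
#'   solubility (mg/mL).
#' @param particle_density True density of the solid (g/cm^3). Not measured
#'   for most drug products; 1.2 g/cm^3 is a typical small-molecule crystal
#'   density.
#'
#' @return An object of class `drug_physchem`.
#' @examples
#' bpa <- drug_physchem(344.5, 4.328, 4.88, 5.60, 0.0051)
#' solubility_at_ph(bpa, 6.8)
#' @export
drug_physchem <- function(molecular_weight, log_p, pka1, pka2,
                          intrinsic_solubility_s0, particle_density = 1.2) {
  stopifnot(
    is.numeric(molecular_weight), molecular_weight > 0,
    is.numeric(pka1), is.numeric(pka2), pka1 < pka2,
    is.numeric(intrinsic_solubility_s0), intrinsic_solubility_s0 > 0,
    is.numeric(particle_density), particle_density > 0
  )
  structure(
    list(
      molecular_weight = molecular_weight,
      log_p = log_p,
      pka1 = pka1,
      pka2 = pka2,
      intrinsic_solubility_s0 = intrinsic_solubility_s0,
      particle_density = particle_density
    ),
    class = "drug_physchem"
  )
}

#' @export
print.drug_physchem <- function(x, ...) {
  cat("<drug_physchem>\n")
  cat(sprintf("  MW %.1f g/mol, logP %.3f, pKa %.2f/%.2f (diprotic acid)\n",
              x$molecular_weight, x$log_p, x$pka1, x$pka2))
  cat(sprintf("  S0 %.4g mg/mL, solid density %.2f g/cm^3\n",
              x$intrinsic_solubility_s0, x$particle_density))
  invisible(x)
}

#' Dissolution medium state
#'
#' @param ph Bulk pH of the medium.
#' @param volume Fluid volume (mL).
#' @param viscosity Dynamic viscosity (cps). Defaults to water at 37 C.
#' @param temperature Temperature (K).
#' @param dissolved_mass Drug mass already in solution (mg).
#'
#' @return An object of class `medium_state`.
#' @export
medium_state <- function(ph, volume, viscosity = water_viscosity_cps(),
                         temperature = 310, dissolved_mass = 0) {
  stopifnot(
    is.finite(ph), ph >= 0, ph <= 14,
    volume > 0, viscosity > 0, temperature > 0, dissolved_mass >= 0
  )
  structure(
    list(ph = ph, volume = volume, viscosity = viscosity,
         temperature = temperature, dissolved_mass = dissolved_mass),
    class = "medium_state"
  )
}

#' Reference viscosity of aqueous media
#'
#' Dynamic viscosity of water at 310 K, used as the default for all aqueous
#' dissolution media and intestinal luminal fluid.
#'
#' @return Viscosity in cps.
#' @export
water_viscosity_cps <- function() 0.6915

#' Total solubility of a diprotic acid at a given pH
#'
#' Henderson-Hasselbalch total (neutral + mono- + di-anion) solubility:
#' `S(pH) = S0 * (1 + 10^(pH - pKa1) + 10^(2*pH - pKa1 - pKa2))`.
#' The neutral-species solubility is pH independent; each ionised species
#' adds capacity in proportion to its equilibrium ratio with the neutral
#' form.
#'
#' @param physchem A [drug_physchem()] object.
#' @param ph pH (scalar or vector), in `[0, 14]`.
#'
#' @return Total solubility (mg/mL), strictly increasing in pH and never
#'   below `intrinsic_solubility_s0`.
#' @export
solubility_at_ph <- function(physchem, ph) {
  stopifnot(inherits(physchem, "drug_physchem"))
  if (!all(is.finite(ph))) stop("`ph` must be finite")
  if (any(ph < 0 | ph > 14)) stop("`ph` must be within [0, 14]")
  s0 <- physchem$intrinsic_solubility_s0
  s0 * (1 + 10^(ph - physchem$pka1) +
          10^(2 * ph - physchem$pka1 - physchem$pka2))
}

#' Equilibrium fraction of a dose dissolved in a finite medium
#'
#' Solubility-cap law: the terminal fraction dissolved in a closed vessel is
#' `min(1, S(pH) * V / dose)`.
#'
#' @param dose Dose (mg).
#' @param medium A [medium_state()].
#' @param physchem A [drug_physchem()].
#'
#' @return Fraction in `[0, 1]`.
#' @export
equilibrium_fraction_dissolved <- function(dose, medium, physchem) {
  stopifnot(inherits(medium, "medium_state"))
  if (!is.numeric(dose) || dose <= 0) stop("`dose` must be positive")
  min(1, solubility_at_ph(physchem, medium$ph) * medium$volume / dose)
}

#' Molecular diffusion coefficient by Stokes-Einstein
#'
#' `D = kB * T / (6 * pi * eta * r_mol)`, with the molecular radius derived
#' from the molar volume assuming a molecular density of 1.2 g/cm^3:
#' `r_mol = (3 * MW / (4 * pi * rho * N_A))^(1/3)`. The fixed
#' molecular-density convention makes D reproducible bit-for-bit; D scales
#' exactly as `1/eta`.
#'
#' @param physchem A [drug_physchem()].
#' @param medium A [medium_state()] supplying viscosity (cps) and
#'   temperature (K).
#'
#' @return Diffusion coefficient (cm^2/s).
#' @export
diffusion_coefficient <- function(physchem, medium) {
  stopifnot(inherits(physchem, "drug_physchem"), inherits(medium, "medium_state"))
  kb <- 1.380649e-16             # erg/K
  na <- 6.02214076e23            # 1/mol
  rho_mol <- 1.2                 # g/cm^3, documented convention
  v_molecule <- physchem$molecular_weight / (rho_mol * na)  # cm^3
  r_mol <- (3 * v_molecule / (4 * pi))^(1 / 3)              # cm
  eta_poise <- medium$viscosity / 100                       # cps -> poise
  kb * medium$temperature / (6 * pi * eta_poise * r_mol)
}
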