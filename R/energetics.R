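# H2-sensitive / H2-tolerant boundary (Pa). Pathways whose maximum tolerable
# H2 partial pressure falls below this are H2-sensitive; exactly at the
# boundary is classified H2-tolerant.
HS_HT_BOUNDARY_PA <- 100

#' Electron-carrier ledger for a catabolic pathway
#'
#' Per-turnover counts of ATP and reduced electron carriers produced and
#' consumed by a pathway, plus the ATP synthase ATP:H+ ratio `x`. The
#' ferredoxin slot (`fdh2_*`) is counted per *single electron* transferred
#' (one reduced 2-electron ferredoxin = 2 units); NADH, ETF and quinol are
#' counted per 2-electron carrier. Each carrier slot is weighted by the
#' number of proton-translocation equivalents its re-oxidation to H2 or
#' formate costs (NADH: x, reverse electron transport) or recovers
#' (ferredoxin: x per electron via ion-pumping oxidation), with ETF and
#' quinol charged two equivalents (2x) each.
#'
#' @param atp_gen,atp_cons Substrate-level ATP formed / invested.
#' @param nadh_gen,nadh_cons NADH formed / consumed.
#' @param fdh2_gen,fdh2_cons Reduced ferredoxin, single-electron units.
#' @param etfh2_gen,etfh2_cons Reduced electron transfer flavoprotein.
#' @param quinol_gen,quinol_cons Reduced quinone.
#' @param ion_ratio_x ATP synthesised per translocated ion (in (0, 1]);
#'   1/3 for organotrophy, 1/5 for methanogenesis by default usage.
#' @return An object of class `carrier_ledger`.
#' @export
#' @examples
#' # glucose -> 2 acetate: 4 ATP, 2 NADH, 2 reduced ferredoxin (4 electrons)
#' atp_yield(carrier_ledger(atp_gen = 4, nadh_gen = 2, fdh2_gen = 4,
#'                          ion_ratio_x = 1/3))
carrier_ledger <- function(atp_gen = 0, atp_cons = 0, nadh_gen = 0,
                           nadh_cons = 0, fdh2_gen = 0, fdh2_cons = 0,
                           etfh2_gen = 0, etfh2_cons = 0, quinol_gen = 0,
                           quinol_cons = 0, ion_ratio_x = 1/3) {
  counts <- c(atp_gen = atp_gen, atp_cons = atp_cons, nadh_gen = nadh_gen,
              nadh_cons = nadh_cons, fdh2_gen = fdh2_gen,
              fdh2_cons = fdh2_cons, etfh2_gen = etfh2_gen,
              etfh2_cons = etfh2_cons, quinol_gen = quinol_gen,
              quinol_cons = quinol_cons)
  if (any(counts < 0)) stop("ledger counts must be non-negative")
  if (!(ion_ratio_x > 0 && ion_ratio_x <= 1)) {
    stop("ion_ratio_x must lie in (0, 1]")
  }
  structure(c(as.list(counts), list(ion_ratio_x = ion_ratio_x)),
            class = "carrier_ledger")
}

#' ATP yield of a pathway from its carrier ledger
#'
#' Net ATP per reaction turnover:
#' `(ATPgen - ATPcons) - x*dNADH + x*dFdH2 - 2x*dETFH2 - 2x*dquinol`,
#' with `d` the generated-minus-consumed difference and `x` the ATP:H+
#' ratio. Fractional yields are expected (e.g. 0.33 for syntrophic
#' butyrate oxidation, 4.67 for glucose fermentation to acetate).
#'
#' @param ledger A [carrier_ledger()].
#' @return Net ATP per reaction (fractional).
#' @export
atp_yield <- function(ledger) {
  stopifnot(inherits(ledger, "carrier_ledger"))
  x <- ledger$ion_ratio_x
  with(ledger,
       (atp_gen - atp_cons) -
         x * (nadh_gen - nadh_cons) +
         x * (fdh2_gen - fdh2_cons) -
         2 * x * (etfh2_gen - etfh2_cons) -
         2 * x * (quinol_gen - quinol_cons))
}

#' Net Gibbs energy including the ATP synthesis charge
#'
#' `delta_g_in_situ(rxn, cond) + atp * dg_atp_synthesis`: the energy left
#' after charging the pathway's ATP yield at the assumed cost of ATP
#' synthesis (60 kJ/mol by default). A pathway is operable where this is
#' negative.
#'
#' @param rxn A [reaction()].
#' @param cond A [conditions()] object (supplies `dg_atp_synthesis`).
#' @param atp ATP yield per reaction (see [atp_yield()]).
#' @param constants Constants table.
#' @return Energy in kJ/mol.
#' @export
net_delta_g <- function(rxn, cond, atp, constants = formation_energies()) {
  delta_g_in_situ(rxn, cond, constants) + atp * cond$dg_atp_synthesis
}

#' Threshold H2 partial pressure of a pathway
#'
#' Solves `net_delta_g = 0` for the H2 partial pressure in closed form
#' (Delta G is affine in ln p_H2). For H2-producing reactions this is the
#' maximum tolerable H2 pressure; for H2-consuming reactions the minimum
#' usable pressure.
#'
#' @inheritParams net_delta_g
#' @return Pressure in Pa.
#' @export
#' @examples
#' but <- reaction("butyrate_ox",
#'                 c(butyrate = -1, h2o = -2, acetate = 2, hplus = 1, h2 = 2))
#' h2_max(but, digester_conditions(), atp = 1/3)  # about 2.6 Pa
h2_max <- function(rxn, cond, atp, constants = formation_energies()) {
  nu <- rxn$stoich
  if (!("h2" %in% names(nu)) || nu[["h2"]] == 0) {
    stop("reaction '", rxn$id, "' has no H2 term; threshold not applicable")
  }
  cond0 <- cond
  cond0$activities["h2"] <- P_ATM_PA  # reference point: 1 atm
  c0 <- net_delta_g(rxn, cond0, atp, constants)
  P_ATM_PA * exp(-c0 / (nu[["h2"]] * RGAS * cond$temperature))
}

#' Classify a threshold pressure as H2-sensitive or H2-tolerant
#'
#' @param h2max_pa Threshold pressure in Pa.
#' @param boundary_pa Class boundary (default 100 Pa; the boundary value
#'   itself is classified HT).
#' @return `"HS"` or `"HT"`.
#' @export
classify_hs_ht <- function(h2max_pa, boundary_pa = HS_HT_BOUNDARY_PA) {
  stopifnot(is.finite(h2max_pa), h2max_pa > 0)
  ifelse(h2max_pa < boundary_pa, "HS", "HT")
}

#' Redirect a fraction of electrons to O2 respiration
#'
#' Builds the modified balanced reaction in which a fraction of the
#' H2-equivalent electron pairs reduce O2 to water (cytochrome bd oxidase
#' style, no additional ion translocation credited) instead of protons to
#' H2, then recomputes the H2 threshold and the in-situ Gibbs energy.
#' Dissolved O2 must be present in the conditions as an effective partial
#' pressure (see [digester_conditions()]).
#'
#' @param rxn An H2-producing [reaction()].
#' @param cond A [conditions()] with O2 and H2 activities set.
#' @param atp ATP yield per reaction.
#' @param fraction Fraction of electron pairs redirected, in [0, 1).
#' @param constants Constants table.
#' @return List with elements `reaction` (the modified reaction),
#'   `h2_max_pa` and `delta_g` (in-situ, at the H2 pressure in `cond`).
#' @export
o2_redirect <- function(rxn, cond, atp, fraction,
                        constants = formation_energies()) {
  if (!(fraction >= 0 && fraction < 1)) stop("fraction must lie in [0, 1)")
  nu <- rxn$stoich
  if (!("h2" %in% names(nu)) || nu[["h2"]] <= 0) {
    stop("O2 redirection requires an H2-producing reaction")
  }
  nh2 <- nu[["h2"]]
  st <- nu
  st[["h2"]] <- nh2 * (1 - fraction)
  # each redirected H2-equivalent pair reduces 1/2 O2 to one H2O
  st[["o2"]] <- (if ("o2" %in% names(st)) st[["o2"]] else 0) - nh2 * fraction / 2
  st[["h2o"]] <- (if ("h2o" %in% names(st)) st[["h2o"]] else 0) + nh2 * fraction
  mod <- reaction(sprintf("%s_o2redirect_%g", rxn$id, fraction), st,
                  constants = constants)
  list(reaction = mod,
       h2_max_pa = h2_max(mod, cond, atp, constants),
       delta_g = delta_g_in_situ(mod, cond, constants))
}

#' H2 partial pressure thermodynamically equivalent to a formate level
#'
#' The H2 pressure at which `formate- + H2O -> HCO3- + H2` is at
#' equilibrium for the given formate and bicarbonate activities: formate
#' below this equivalence behaves as the softer electron carrier. Linear
#' in the formate concentration.
#'
#' @param formate_conc Formate concentration (M).
#' @param cond A [conditions()] (HCO3-, temperature, pH).
#' @param constants Constants table.
#' @return Equivalent H2 partial pressure in Pa.
#' @export
#' @examples
#' formate_h2_equivalence(2.5e-6, digester_conditions())  # about 4 Pa
formate_h2_equivalence <- function(formate_conc, cond = digester_conditions(),
                                   constants = formation_energies()) {
  stopifnot(formate_conc > 0)
  rxn <- reaction("formate_to_h2",
                  c(formate = -1, h2o = -1, hco3 = 1, h2 = 1),
                  constants = constants)
  cond$activities["formate"] <- formate_conc
  h2_max(rxn, cond, atp = 0, constants)
}

#' Pathway energetics summary
#'
#' Convenience wrapper computing, for one pathway from the catalog, the
#' standard transformed energy, ATP yield, threshold H2 pressure and HS/HT
#' class under a condition set.
#'
#' @param pathway A pathway definition (see [pathway_catalog()]).
#' @param cond A [conditions()] object.
#' @param constants Constants table.
#' @return A one-row data.frame: `pathway`, `dg0_prime`, `atp_yield`,
#'   `h2_max_pa`, `class` (NA where the reaction has no H2 term),
#'   `ambiguous`.
#' @export
pathway_energetics <- function(pathway, cond = digester_conditions(),
                               constants = formation_energies()) {
  atp <- atp_yield(pathway$ledger)
  has_h2 <- "h2" %in% names(pathway$reaction$stoich) &&
    pathway$reaction$stoich[["h2"]] != 0
  h2 <- if (has_h2) h2_max(pathway$reaction, cond, atp, constants) else NA_real_
  cls <- if (has_h2) classify_hs_ht(h2) else NA_character_
  data.frame(pathway = pathway$id,
             dg0_prime = delta_g_standard(pathway$reaction, T_REF, constants),
             atp_yield = atp,
             h2_max_pa = h2,
             class = cls,
             ambiguous = identical(pathway$directionality, "ambiguous"),
             stringsAsFactors = FALSE)
}
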