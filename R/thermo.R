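# Physical constants used throughout. R in kJ/mol/K, standard state 1 atm.
RGAS <- 8.31446e-3
T_REF <- 298.15
P_ATM_PA <- 101325

#' Load the bundled formation-energy table
#'
#' Reads the table of standard transformed Gibbs energies of formation
#' (kJ/mol, 298.15 K, pH 7; Thauer-convention values) and, where available,
#' enthalpies of formation used for temperature correction. The table also
#' records each compound's elemental formula, charge and phase, which drive
#' activity conventions (1 M for aqueous species, 1 atm for gases, unit
#' activity for liquid water) and reaction balance checking.
#'
#' @param path Path to a delimited constants file. Defaults to the bundled
#'   table shipped with the package.
#' @return A data.frame with one row per compound and columns `id`,
#'   `formula`, `charge`, `phase`, `dgf0_prime_kj_mol`, `dhf0_prime_kj_mol`
#'   (NA where no reliable enthalpy exists) and `source`.
#' @export
#' @examples
#' head(formation_energies())
formation_energies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "formation_energies.tsv", package = "ecothermo")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, strip.white = TRUE)
  needed <- c("id", "formula", "charge", "phase", "dgf0_prime_kj_mol")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("constants table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("duplicate compound ids in constants table")
  if (any(!is.finite(tab$dgf0_prime_kj_mol))) {
    stop("non-finite formation energy in constants table")
  }
  if (!all(tab$phase %in% c("aqueous", "gas", "liquid_water"))) {
    stop("unknown phase in constants table")
  }
  tab
}

# Parse an elemental formula string like "C4H7O2" into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "") return(numeric(0))
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Za-z]+", "", parts)
  n <- ifelse(n == "", 1, as.numeric(n))
  tapply(n, el, sum)
}

#' Define a chemical reaction
#'
#' A reaction is a named, signed stoichiometry over compound ids from the
#' constants table: negative coefficients are consumed, positive produced.
#' Rational coefficients (e.g. 1/2 O2) are supported exactly as numerics.
#'
#' @param id Reaction name.
#' @param stoich Named numeric vector of signed stoichiometric coefficients.
#' @param constants Constants table (see [formation_energies()]); used to
#'   validate compound ids and element/charge balance.
#' @param check Verify element and charge balance (default TRUE).
#' @param tol Balance tolerance per element.
#' @return An object of class `reaction`.
#' @export
#' @examples
#' reaction("butyrate_ox", c(butyrate = -1, h2o = -2, acetate = 2, hplus = 1, h2 = 2))
reaction <- function(id, stoich, constants = formation_energies(), check = TRUE,
                     tol = 1e-9) {
  stopifnot(is.numeric(stoich), !is.null(names(stoich)))
  stoich <- stoich[stoich != 0]
  unknown <- setdiff(names(stoich), constants$id)
  if (length(unknown) > 0) {
    stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(stoich) > 0 && (all(stoich > 0) || all(stoich < 0))) {
    stop("reaction must have at least one compound on each side")
  }
  if (check && length(stoich) > 0) {
    bal <- new.env()
    charge <- 0
    for (i in seq_along(stoich)) {
      row <- constants[constants$id == names(stoich)[i], ]
      f <- parse_formula(row$formula)
      for (el in names(f)) {
        prev <- mget(el, envir = bal, ifnotfound = 0)[[1]]
        assign(el, prev + stoich[[i]] * f[[el]], envir = bal)
      }
      charge <- charge + stoich[[i]] * row$charge
    }
    resid <- unlist(as.list(bal))
    bad <- resid[abs(resid) > tol]
    if (length(bad) > 0) {
      stop(sprintf("reaction '%s' not element-balanced: %s", id,
                   paste(sprintf("%s %+0.4g", names(bad), bad), collapse = ", ")))
    }
    if (abs(charge) > tol) {
      stop(sprintf("reaction '%s' not charge-balanced (residual %+0.4g)", id, charge))
    }
  }
  structure(list(id = id, stoich = stoich), class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  fmt <- function(v) paste(sprintf("%s %s", ifelse(abs(v) == 1, "", format(abs(v))),
                                   names(v)), collapse = " + ")
  cat(sprintf("<reaction> %s: %s -> %s\n", x$id, fmt(lhs), fmt(rhs)))
  invisible(x)
}

# Reverse a reaction (negate all coefficients).
reverse_reaction <- function(rxn) {
  reaction(paste0(rxn$id, "_rev"), -rxn$stoich, check = FALSE)
}

#' In-situ condition set
#'
#' Bundles temperature, pH, compound activities and the free energy of ATP
#' synthesis. Aqueous activities are molar concentrations; gas activities are
#' partial pressures in Pa (converted internally to the 1 atm standard
#' state); liquid water has unit activity; H+ enters only through pH.
#' Aqueous compounds without an explicit activity default to 0.1 uM.
#'
#' @param temperature Temperature in K (default 310.15, i.e. 37 C).
#' @param pH pH (default 7).
#' @param activities Named numeric vector: molar for aqueous compounds,
#'   Pa for gases. Overrides the defaults.
#' @param dg_atp_synthesis Free energy charged per ATP synthesised
#'   (kJ/mol, default 60).
#' @param default_aqueous Default activity for unspecified aqueous
#'   compounds (M, default 1e-7).
#' @return An object of class `conditions`.
#' @export
conditions <- function(temperature = 310.15, pH = 7, activities = numeric(0),
                       dg_atp_synthesis = 60, default_aqueous = 1e-7) {
  stopifnot(temperature > 0)
  if (length(activities) > 0) {
    stopifnot(!is.null(names(activities)))
    if (any(activities <= 0)) stop("activities must be strictly positive")
  }
  structure(list(temperature = temperature, pH = pH,
                 activities = activities,
                 dg_atp_synthesis = dg_atp_synthesis,
                 default_aqueous = default_aqueous),
            class = "conditions")
}

#' Standard anaerobic digester conditions
#'
#' The default in-situ condition set used throughout the package: 37 C,
#' pH 7, 300 uM acetate, 10 uM other fatty acids, 1 mM NH4+, 50 mM HCO3-,
#' 50 kPa CH4, 3.9e-4 atm H2S, and 0.1 uM for all other aqueous compounds.
#' Dissolved O2 (50 nM unless overridden) is expressed as an effective
#' partial pressure through a fixed Henry constant of 1.3e-3 M/atm.
#'
#' @param ... Named activity overrides (molar for aqueous, Pa for gas),
#'   passed on top of the defaults.
#' @param temperature Temperature in K.
#' @param o2_nM Dissolved O2 concentration in nM, converted to an effective
#'   partial pressure.
#' @return A `conditions` object.
#' @export
#' @examples
#' digester_conditions(butyrate = 1e-2)  # raise butyrate to 10 mM
digester_conditions <- function(..., temperature = 310.15, o2_nM = 50) {
  act <- c(
    acetate = 3e-4,
    butyrate = 1e-5, propionate = 1e-5, isobutyrate = 1e-5,
    isovalerate = 1e-5, methylbutyrate2 = 1e-5,
    nh4 = 1e-3, hco3 = 5e-2,
    formate = 2.5e-6,                    # in-situ digester estimate
    ch4 = 50000,                         # Pa
    h2s = 3.9e-4 * P_ATM_PA,             # Pa
    o2 = (o2_nM * 1e-9 / HENRY_O2_M_PER_ATM) * P_ATM_PA  # Pa
  )
  over <- c(...)
  if (length(over) > 0) act[names(over)] <- over
  conditions(temperature = temperature, activities = act)
}

# Henry constant for O2 at the reference temperature, M per atm.
HENRY_O2_M_PER_ATM <- 1.3e-3

# Per-reaction temperature correction of the standard transformed Gibbs
# energy. Applied via Gibbs-Helmholtz only when every compound in the
# reaction carries an enthalpy of formation; otherwise the 298.15 K free
# energies are used unchanged. Mixing corrected and uncorrected compounds
# within one reaction is deliberately avoided (see the methods vignette).
.dgf_at_temperature <- function(ids, temperature, constants) {
  idx <- match(ids, constants$id)
  if (anyNA(idx)) {
    stop("missing constant for compound(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  g <- constants$dgf0_prime_kj_mol[idx]
  h <- constants$dhf0_prime_kj_mol[idx]
  if (abs(temperature - T_REF) > 1e-12 && all(!is.na(h))) {
    g <- h - (temperature / T_REF) * (h - g)
  }
  g
}

#' Standard transformed Gibbs energy of reaction
#'
#' Computes the standard transformed Gibbs energy change (kJ/mol, pH 7,
#' standard states: 1 M aqueous, 1 atm gas, unit-activity water) at a given
#' temperature. H+ contributes its pH 7 activity term so that the value is
#' the conventional transformed standard energy. The 25 C table values are
#' extrapolated with the Gibbs-Helmholtz relation when enthalpies are
#' available for every compound in the reaction; at 298.15 K the correction
#' vanishes.
#'
#' @param rxn A [reaction()].
#' @param temperature Temperature in K.
#' @param constants Constants table.
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' r <- reaction("knallgas", c(h2 = -1, o2 = -0.5, h2o = 1))
#' delta_g_standard(r)  # about -237 kJ/mol
delta_g_standard <- function(rxn, temperature = T_REF,
                             constants = formation_energies()) {
  stopifnot(inherits(rxn, "reaction"))
  st <- rxn$stoich
  if (length(st) == 0) return(0)
  g <- .dgf_at_temperature(names(st), temperature, constants)
  dg <- sum(st * g)
  # pH 7 contribution of H+ (transformed convention)
  nu_h <- if ("hplus" %in% names(st)) st[["hplus"]] else 0
  dg + nu_h * RGAS * temperature * log(1e-7)
}

#' In-situ Gibbs energy of reaction
#'
#' Evaluates Delta G = Delta G0'(T) + RT * sum(nu * ln a) under a condition
#' set. Gas activities are partial pressure / 101325 Pa, water activity is
#' 1, and H+ enters only through the pH (the term vanishes at pH 7 relative
#' to the transformed standard energy).
#'
#' @param rxn A [reaction()].
#' @param cond A [conditions()] object.
#' @param constants Constants table.
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' r <- reaction("butyrate_ox",
#'               c(butyrate = -1, h2o = -2, acetate = 2, hplus = 1, h2 = 2))
#' delta_g_in_situ(r, digester_conditions(h2 = 10))  # 10 Pa H2
delta_g_in_situ <- function(rxn, cond, constants = formation_energies()) {
  stopifnot(inherits(rxn, "reaction"), inherits(cond, "conditions"))
  st <- rxn$stoich
  if (length(st) == 0) return(0)
  temperature <- cond$temperature
  g <- .dgf_at_temperature(names(st), temperature, constants)
  dg <- sum(st * g)
  idx <- match(names(st), constants$id)
  phase <- constants$phase[idx]
  lna <- numeric(length(st))
  for (i in seq_along(st)) {
    id <- names(st)[i]
    if (id == "hplus") {
      lna[i] <- log(10^(-cond$pH))
    } else if (phase[i] == "liquid_water") {
      lna[i] <- 0
    } else {
      a <- if (id %in% names(cond$activities)) cond$activities[[id]] else {
        if (phase[i] == "gas") {
          stop("no partial pressure supplied for gas compound '", id, "'")
        }
        cond$default_aqueous
      }
      if (a <= 0) stop("non-positive activity for compound '", id, "'")
      if (phase[i] == "gas") a <- a / P_ATM_PA
      lna[i] <- log(a)
    }
  }
  dg + RGAS * temperature * sum(st * lna)
}
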