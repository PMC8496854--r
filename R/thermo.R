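# Gas constant, kJ mol^-1 K^-1
RGAS <- 8.31446e-3
# extended Debye-Hueckel prefactor at 298 K, kJ mol^-1 M^-1/2 (Alberty convention)
DH_A <- 2.91482
DH_B <- 1.6

#' Aqueous conditions for transformed Gibbs energies
#'
#' @param pH pH of the medium (warned outside [0, 14]).
#' @param ionic_strength Ionic strength in mol/L (must be >= 0).
#' @param temperature Temperature in kelvin (must be > 0). Default 298.15 K.
#' @return A \code{conditions} list with fields \code{pH},
#'   \code{ionic_strength}, \code{temperature} and the gas constant \code{R}
#'   in kJ/mol/K.
#' @export
conditions <- function(pH = 7.0, ionic_strength = 0.25, temperature = 298.15) {
  stopifnot(temperature > 0, ionic_strength >= 0)
  if (pH < 0 || pH > 14) warning("pH ", pH, " outside [0, 14]")
  structure(list(pH = pH, ionic_strength = ionic_strength,
                 temperature = temperature, R = RGAS),
            class = "conditions")
}

#' Protonation-state (pseudoisomer) specification for one compound
#'
#' A compound in solution is a Boltzmann mixture of protonation states
#' (pseudoisomers). The spec records the dissociation constants and which
#' state is the reference: \code{pKa[i]} is the pKa of the dissociation of
#' the i-th proton (the state with i protons losing one), \code{m} is the
#' proton count of the reference pseudoisomer (the most abundant at pH 7,
#' I = 0.25 M), and \code{z_ref} its formal charge. State \code{n} carries
#' charge \code{z_ref + (n - m)}. \code{N_H}, the number of dissociable
#' protons, equals \code{length(pKa)}.
#'
#' @param compound_id Compound identifier.
#' @param pKa Numeric vector of pKa values, indexed by proton count
#'   (may be empty for compounds with no dissociable protons).
#' @param m Proton index of the reference pseudoisomer, \code{0 <= m <= length(pKa)}.
#' @param z_ref Formal charge of the reference pseudoisomer.
#' @return A \code{pseudoisomer_spec}.
#' @export
pseudoisomer_spec <- function(compound_id, pKa = numeric(0), m = 0L, z_ref = 0L) {
  pKa <- as.numeric(pKa)
  m <- as.integer(m)
  if (m > length(pKa) || m < 0) {
    mt_error(sprintf("spec '%s': reference proton count m=%d outside [0, N_H=%d]",
                     compound_id, m, length(pKa)), "mt_input_error")
  }
  structure(list(compound_id = compound_id, pKa = pKa,
                 N_H = length(pKa), m = m, z_ref = as.integer(z_ref)),
            class = "pseudoisomer_spec")
}

# log-sum-exp
lse <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# extended Debye-Hueckel exponent term for pseudoisomer with charge z and n
# protons; dimensionless (energy divided by RT)
dh_term <- function(z, n, I, RT) {
  if (I <= 0) return(rep(0, length(z)))
  DH_A * (z^2 - n) * sqrt(I) / (RT * (1 + DH_B * sqrt(I)))
}

#' Transform offset of one compound: ddG = DfG'o - DfGo
#'
#' Difference between the transformed standard formation energy of the
#' pseudoisomer mixture at the given conditions and the (untransformed)
#' formation energy of the reference pseudoisomer:
#' \deqn{\Delta\Delta G = RT\ln 10\, m\, \mathrm{pH} - RT \ln \sum_{n=0}^{N_H}
#'   \exp\Big[\ln 10 \sum_{i=m+1}^{n}(pK_a(i)-\mathrm{pH}) +
#'   \frac{A (z_n^2-n)\sqrt I}{RT(1+1.6\sqrt I)}\Big]}
#' with \eqn{A = 2.91482} kJ/mol/M\eqn{^{1/2}}; the inner sum is empty for
#' \eqn{n = m} and runs downward with negated sign for \eqn{n < m}. The
#' Boltzmann sum is evaluated with log-sum-exp so extreme pKa values cannot
#' overflow.
#'
#' @param spec A \code{\link{pseudoisomer_spec}}.
#' @param cond A \code{\link{conditions}} object.
#' @return The offset in kJ/mol (0 for a spec with no dissociable protons at
#'   \code{m = 0}).
#' @export
pseudoisomer_ddG <- function(spec, cond = conditions()) {
  stopifnot(inherits(spec, "pseudoisomer_spec"), inherits(cond, "conditions"))
  RT <- cond$R * cond$temperature
  n <- 0:spec$N_H
  # signed partial sums of (pKa(i) - pH) from the reference index m
  delta <- spec$pKa - cond$pH
  csum <- c(0, cumsum(delta))            # csum[k+1] = sum_{i<=k} delta_i
  pka_part <- csum[n + 1] - csum[spec$m + 1]
  z_n <- spec$z_ref + (n - spec$m)
  expo <- log(10) * pka_part + dh_term(z_n, n, cond$ionic_strength, RT)
  RT * log(10) * spec$m * cond$pH - RT * lse(expo)
}

#' Apparent equilibrium constant to transformed reaction Gibbs energy
#'
#' \eqn{\Delta_r G'^\circ = -RT \ln K'}.
#'
#' @param K_prime Apparent equilibrium constant (must be > 0); measured over
#'   total (all-pseudoisomer) concentrations.
#' @param temperature Temperature in kelvin.
#' @return Gibbs energy in kJ/mol.
#' @export
kprime_to_drgo <- function(K_prime, temperature = 298.15) {
  if (any(K_prime <= 0)) mt_error("K' must be positive", "mt_input_error")
  -RGAS * temperature * log(K_prime)
}

mt_rxn_ddG <- function(rxn, specs, cond) {
  ids <- names(rxn)
  ddG <- vapply(ids, function(id) {
    sp <- specs[[id]]
    if (is.null(sp)) {
      warning("no pseudoisomer spec for compound '", id, "'; using ddG = 0")
      0
    } else pseudoisomer_ddG(sp, cond)
  }, numeric(1))
  sum(as.numeric(rxn) * ddG)
}

#' Standardize an observed transformed reaction energy to the reference
#' pseudoisomers (inverse Legendre transform at reaction level)
#'
#' \eqn{\Delta_r G^\circ = \Delta_r G'^\circ_{obs} - \sum_i S_{ij}\,
#' \Delta\Delta G_i} at the observation's conditions. Compounds without a
#' spec contribute 0 with a warning.
#'
#' @param drg_prime_obs Observed \eqn{\Delta_r G'^\circ} in kJ/mol.
#' @param rxn Named signed stoichiometry vector (see
#'   \code{\link{parse_reaction}}).
#' @param specs Named list of \code{\link{pseudoisomer_spec}} objects keyed
#'   by compound ID.
#' @param cond \code{\link{conditions}} of the measurement.
#' @return \eqn{\Delta_r G^\circ} in kJ/mol.
#' @export
untransform_reaction <- function(drg_prime_obs, rxn, specs, cond = conditions()) {
  drg_prime_obs - mt_rxn_ddG(rxn, specs, cond)
}

#' Transform a predicted reference-pseudoisomer reaction energy to given
#' conditions
#'
#' Exact inverse of \code{\link{untransform_reaction}} at identical
#' conditions: \eqn{\Delta_r G'^\circ = \Delta_r G^\circ + \sum_i S_{ij}
#' \Delta\Delta G_i}.
#'
#' @param drg_standard \eqn{\Delta_r G^\circ} in kJ/mol (reference
#'   pseudoisomers).
#' @inheritParams untransform_reaction
#' @return \eqn{\Delta_r G'^\circ} in kJ/mol.
#' @export
transform_prediction <- function(drg_standard, rxn, specs, cond = conditions()) {
  drg_standard + mt_rxn_ddG(rxn, specs, cond)
}

#' Adjust a standard transformed reaction energy for actual concentrations
#'
#' \eqn{\Delta_r G' = \Delta_r G'^\circ + RT \sum_i S_{ij} \ln c_i} with
#' concentrations in mol/L.
#'
#' @param drg_prime_standard \eqn{\Delta_r G'^\circ} in kJ/mol.
#' @param concentrations Named numeric vector of concentrations (mol/L) for
#'   every compound in the reaction; all must be positive.
#' @param rxn Named signed stoichiometry vector.
#' @param temperature Temperature in kelvin.
#' @return \eqn{\Delta_r G'} in kJ/mol.
#' @export
concentration_adjust <- function(drg_prime_standard, concentrations, rxn,
                                 temperature = 298.15) {
  ids <- names(rxn)
  conc <- concentrations[ids]
  if (any(is.na(conc)) || any(conc <= 0)) {
    mt_error("every compound needs a positive concentration", "mt_input_error")
  }
  drg_prime_standard + RGAS * temperature * sum(as.numeric(rxn) * log(conc))
}

#' Load pseudoisomer specifications from a TSV file
#'
#' Expected columns: \code{compound_id}, \code{pKa_list} (semicolon-separated
#' pKa values, possibly empty), \code{m} (reference proton count), and
#' \code{z_ref} (reference charge).
#'
#' @param path Path to the TSV file.
#' @return Named list of \code{\link{pseudoisomer_spec}}s keyed by compound
#'   ID.
#' @export
load_pseudoisomer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "pKa_list", "m", "z_ref")
  if (!all(need %in% names(tab))) {
    mt_error(paste0("pseudoisomer table needs columns: ",
                    paste(need, collapse = ", ")), "mt_input_error")
  }
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    pka <- tab$pKa_list[[i]]
    pka <- if (is.na(pka) || !nzchar(pka)) numeric(0)
           else as.numeric(strsplit(pka, ";")[[1]])
    pseudoisomer_spec(tab$compound_id[[i]], pka, tab$m[[i]], tab$z_ref[[i]])
  })
  stats::setNames(specs, tab$compound_id)
}
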