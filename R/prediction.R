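#' Parse a reaction string into signed stoichiometry
#'
#' Grammar: \code{[coef] ID (+ [coef] ID)* <=> [coef] ID (+ [coef] ID)*}
#' with a default coefficient of 1. Reactant coefficients are negative,
#' product coefficients positive; repeated IDs are merged by summation. A
#' reaction whose net stoichiometry cancels completely (e.g.
#' \code{"2 A <=> A + A"}) is flagged as a null reaction with a warning.
#'
#' @param text Reaction string, e.g. \code{"C00096 <=> C02280"} or
#'   \code{"1 C00031 + 1 C00002 <=> 1 C00092 + 1 C00008"}.
#' @param novel_structures Optional named character vector/list mapping IDs
#'   absent from the compound table (conventionally \code{N#####}) to their
#'   InChI or SMILES; attached to the result for downstream decomposition.
#' @return A \code{reaction_stoich}: named numeric vector of signed
#'   coefficients with the source string and any novel structures as
#'   attributes.
#' @export
parse_reaction <- function(text, novel_structures = NULL) {
  sides <- strsplit(text, "<=>", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    mt_error(sprintf("reaction '%s' must contain exactly one '<=>'", text),
             "mt_parse_error")
  }
  parse_side <- function(side, sign) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    if (!length(terms)) {
      mt_error(sprintf("reaction '%s' has an empty side", text), "mt_parse_error")
    }
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^(?:([0-9]+(?:\\.[0-9]+)?|[0-9]+/[0-9]+)\\s+)?(\\S+)$", tm))[[1]]
      if (!length(m)) {
        mt_error(sprintf("cannot parse reaction term '%s'", tm), "mt_parse_error")
      }
      coef <- if (nzchar(m[2])) {
        if (grepl("/", m[2])) {
          parts <- as.numeric(strsplit(m[2], "/")[[1]])
          parts[1] / parts[2]
        } else as.numeric(m[2])
      } else 1
      out[m[3]] <- (if (is.na(out[m[3]])) 0 else out[m[3]]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- lhs
  for (id in names(rhs)) {
    stoich[id] <- (if (is.na(stoich[id])) 0 else stoich[id]) + rhs[id]
  }
  null_reaction <- FALSE
  stoich <- stoich[stoich != 0]
  if (!length(stoich)) {
    warning("reaction '", text, "' has zero net stoichiometry (null reaction)")
    null_reaction <- TRUE
  }
  if (!is.null(novel_structures)) novel_structures <- unlist(novel_structures)
  structure(stoich, class = "reaction_stoich", source = text,
            novel_structures = novel_structures, null_reaction = null_reaction)
}

#' @export
print.reaction_stoich <- function(x, ...) {
  cat("<reaction>", attr(x, "source"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# reverse a reaction (negate all coefficients); used in tests and rules
reverse_reaction <- function(rxn) {
  out <- -as.numeric(rxn)
  names(out) <- names(rxn)
  attributes(out) <- attributes(rxn)
  out
}

# element balance: signed element totals over the reaction, hydrogens
# excluded (protonation is handled by the Legendre transform)
element_imbalance <- function(rxn, compounds) {
  ids <- names(rxn)
  el <- compounds$elements[match(ids, compounds$compound_id)]
  all_el <- setdiff(unique(unlist(lapply(el, names))), "H")
  vapply(all_el, function(e) {
    sum(vapply(seq_along(ids), function(i) {
      cnt <- el[[i]][e]
      as.numeric(rxn[i]) * (if (is.na(cnt)) 0 else cnt)
    }, numeric(1)))
  }, numeric(1))
}

#' End-to-end reaction Gibbs energy prediction
#'
#' Builds the net moiety-change vector of the reaction from the compound
#' structures, applies the fitted contribution model to get the mean and
#' predictive standard deviation of \eqn{\Delta_r G^\circ} (reference
#' pseudoisomers), and adds the pseudoisomer/pH/ionic-strength offsets to
#' report \eqn{\Delta_r G'^\circ} at the requested conditions. The standard
#' deviation passes through the (deterministic) transform unchanged.
#' Compounds not present in \code{compounds} must have structures supplied
#' via the reaction's \code{novel_structures} attribute or the
#' \code{novel_structures} argument. An element imbalance (hydrogens
#' excluded) sets a flag but does not block the prediction, since rule-like
#' transformations often track cofactors externally.
#'
#' @param rxn A \code{\link{parse_reaction}} result or reaction string.
#' @param model A \code{ridge_model} from \code{\link{fit_bayesian_ridge}}.
#' @param compounds A \code{\link{compound_table}} with the known compounds.
#' @param specs Optional named list of \code{\link{pseudoisomer_spec}}s;
#'   compounds without one contribute no transform offset (with a warning).
#' @param cond \code{\link{conditions}} for the transformed energy.
#' @param novel_structures Named character vector of structures for IDs
#'   absent from \code{compounds}.
#' @param radii,stereo Decomposition mode; defaults to the mode the model
#'   was trained with (combined radii, stereo on, when the model does not
#'   record one).
#' @return A \code{prediction_report}: list with \code{drg_standard}
#'   (mean/sd, reference pseudoisomers), \code{drg_prime} (at \code{cond}),
#'   \code{sd}, the nonzero \code{moiety_change} entries, the
#'   \code{unseen_moieties}, and \code{flags} (unbalanced / missing specs /
#'   null reaction).
#' @export
predict_reaction <- function(rxn, model, compounds, specs = NULL,
                             cond = conditions(), novel_structures = NULL,
                             radii = NULL, stereo = NULL) {
  radii <- radii %||% model$radii %||% c(1, 2)
  stereo <- stereo %||% model$stereo %||% TRUE
  if (is.character(rxn)) rxn <- parse_reaction(rxn, novel_structures)
  stopifnot(inherits(rxn, "reaction_stoich"), inherits(model, "ridge_model"))
  if (length(rxn) == 0) {
    # fully cancelled stoichiometry: nothing to decompose, zero change vector
    return(structure(list(
      reaction = attr(rxn, "source"), stoichiometry = numeric(0),
      drg_standard = 0, drg_prime = 0, sd = 1 / sqrt(model$beta),
      conditions = cond, moiety_change = numeric(0),
      unseen_moieties = character(0),
      flags = list(unbalanced = FALSE, element_imbalance = numeric(0),
                   missing_pseudoisomer_specs = character(0),
                   null_reaction = TRUE)
    ), class = "prediction_report"))
  }
  novel <- c(attr(rxn, "novel_structures"), novel_structures)
  ids <- names(rxn)
  known <- ids %in% compounds$compound_id
  if (any(!known)) {
    need <- ids[!known]
    have <- need %in% names(novel)
    if (any(!have)) {
      mt_error(paste0("compound(s) not in table and no structure supplied: ",
                      paste(need[!have], collapse = ", ")), "mt_input_error")
    }
    extra <- compound_table(need, unname(unlist(novel[need])))
    extra$elements <- lapply(seq_len(nrow(extra)), function(i) extra$elements[[i]])
    compounds <- rbind_compound_tables(compounds, extra)
  }
  G <- build_incidence(compounds[compounds$compound_id %in% ids, , drop = FALSE],
                       radii = radii, stereo = stereo)
  x <- moiety_change(rxn, G)
  pred <- predict_mean_std(model, x)
  missing_specs <- if (is.null(specs)) ids else setdiff(ids, names(specs))
  drg_prime <- withCallingHandlers(
    transform_prediction(pred$mean, rxn, specs %||% list(), cond),
    warning = function(w) invokeRestart("muffleWarning"))
  imb <- element_imbalance(rxn, compounds)
  x_nz <- x[x != 0]
  structure(list(
    reaction = attr(rxn, "source"),
    stoichiometry = stats::setNames(as.numeric(rxn), names(rxn)),
    drg_standard = pred$mean,
    drg_prime = drg_prime,
    sd = pred$sd,
    conditions = cond,
    moiety_change = x_nz,
    unseen_moieties = pred$unseen_moieties,
    flags = list(
      unbalanced = any(abs(imb) > 1e-9),
      element_imbalance = imb[abs(imb) > 1e-9],
      missing_pseudoisomer_specs = missing_specs,
      null_reaction = isTRUE(attr(rxn, "null_reaction"))
    )
  ), class = "prediction_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_compound_tables <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  structure(out, class = c("compound_table", "data.frame"),
            toolkit = attr(a, "toolkit"),
            toolkit_version = attr(a, "toolkit_version"))
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction>", x$reaction, "\n")
  cat(sprintf("  drG'o = %.2f +/- %.2f kJ/mol  (pH %.2f, I %.2f M, T %.2f K)\n",
              x$drg_prime, x$sd, x$conditions$pH, x$conditions$ionic_strength,
              x$conditions$temperature))
  cat(sprintf("  drGo (reference pseudoisomers) = %.2f kJ/mol\n", x$drg_standard))
  if (length(x$unseen_moieties)) {
    cat("  unseen moieties:", paste(x$unseen_moieties, collapse = ", "), "\n")
  }
  if (isTRUE(x$flags$unbalanced)) cat("  warning: element-unbalanced reaction\n")
  invisible(x)
}
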