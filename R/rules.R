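#' Classify the thermodynamic directionality of a reaction rule
#'
#' A rule is treated as irreversible only when two conditions hold
#' simultaneously: the credible interval \eqn{mean \pm k\,sd} excludes zero,
#' and \eqn{|mean|} exceeds the conservative cutoff (metabolite
#' concentrations, rarely known at pathway-design time, can tilt smaller
#' driving forces). An all-negative interval means the rule can run only as
#' written (\code{forward_only}); an all-positive interval only in reverse
#' (\code{reverse_only}); anything else is \code{reversible}.
#'
#' @param mean Predicted \eqn{\Delta_r G'^\circ} in kJ/mol (vectorized).
#' @param sd Predictive standard deviation in kJ/mol (recycled).
#' @param k Credible-interval multiplier (default 3, i.e. ~99.7\%).
#' @param cutoff Driving-force cutoff in kJ/mol (default 20).
#' @return Character vector in \code{{"reversible", "forward_only",
#'   "reverse_only"}}.
#' @export
classify_rule <- function(mean, sd, k = 3, cutoff = 20) {
  stopifnot(all(sd >= 0))
  lo <- mean - k * sd
  hi <- mean + k * sd
  ifelse(hi < 0 & abs(mean) > cutoff, "forward_only",
         ifelse(lo > 0 & abs(mean) > cutoff, "reverse_only", "reversible"))
}

# canonical orientation: first nonzero entry (in the lexicographic moiety
# order of G's columns) is made positive; returns list(x, flipped)
canonical_orientation <- function(x) {
  nz <- which(x != 0)
  if (!length(nz)) return(list(x = x, flipped = FALSE))
  if (x[nz[1]] < 0) list(x = -x, flipped = TRUE) else list(x = x, flipped = FALSE)
}

#' Deduplicate reactions into moiety-change rules and classify them
#'
#' Reactions performing the same substrate-to-product transformation share
#' the same net moiety-change vector; such reactions are collapsed into one
#' rule. A rule and its exact negation are unified by orienting each vector
#' so its first nonzero entry (lexicographic moiety order) is positive; the
#' original direction of each member is recorded. If a model is supplied,
#' each rule gets a predicted mean, standard deviation, \eqn{\pm k\,sd}
#' credible interval and a directionality label (relative to the canonical
#' orientation).
#'
#' @param reactions Named list of reaction stoichiometries (outputs of
#'   \code{\link{parse_reaction}} or named coefficient vectors).
#' @param G Moiety incidence matrix covering all compounds involved.
#' @param model Optional \code{ridge_model} for energetic annotation.
#' @param specs,cond Optional pseudoisomer specs and conditions applied to
#'   the rule prediction (means are transformed; the sd is unchanged).
#' @param k,cutoff See \code{\link{classify_rule}}.
#' @return A \code{rule_table}: data frame with one row per rule
#'   (\code{rule_id}, \code{n_members}, \code{members},
#'   \code{member_direction}, and when a model is given \code{mean},
#'   \code{sd}, \code{ci_lo}, \code{ci_hi}, \code{label}); change vectors in
#'   the \code{"change_vectors"} attribute.
#' @export
build_rule_table <- function(reactions, G, model = NULL, specs = NULL,
                             cond = conditions(), k = 3, cutoff = 20) {
  if (is.null(names(reactions))) {
    names(reactions) <- paste0("rxn", seq_along(reactions))
  }
  changes <- lapply(reactions, moiety_change, G = G)
  oriented <- lapply(changes, canonical_orientation)
  sig <- vapply(oriented, function(o) paste(signif(o$x, 12), collapse = ","),
                character(1))
  groups <- split(seq_along(reactions), sig)
  # deterministic rule order: by first appearance
  groups <- groups[order(vapply(groups, min, integer(1)))]
  rows <- lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    data.frame(
      rule_id = sprintf("MR%04d", i),
      n_members = length(idx),
      members = paste(names(reactions)[idx], collapse = ";"),
      member_direction = paste(ifelse(
        vapply(oriented[idx], `[[`, logical(1), "flipped"), "-", "+"),
        collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  vecs <- lapply(groups, function(idx) oriented[[idx[1]]]$x)
  names(vecs) <- tab$rule_id
  if (!is.null(model)) {
    preds <- lapply(seq_along(groups), function(i) {
      idx <- groups[[i]][1]
      p <- predict_mean_std(model, vecs[[i]])
      rep_rxn <- reactions[[idx]]
      flip <- oriented[[idx]]$flipped
      mu <- p$mean
      if (!is.null(specs)) {
        # transform offset computed on the representative reaction, oriented
        sgn <- if (flip) -1 else 1
        mu <- transform_prediction(mu, stats::setNames(
          sgn * as.numeric(rep_rxn), names(rep_rxn)), specs, cond)
      }
      list(mean = mu, sd = p$sd, n_unseen = length(p$unseen_moieties))
    })
    tab$mean <- vapply(preds, `[[`, numeric(1), "mean")
    tab$sd <- vapply(preds, `[[`, numeric(1), "sd")
    tab$ci_lo <- tab$mean - k * tab$sd
    tab$ci_hi <- tab$mean + k * tab$sd
    tab$n_unseen_moieties <- vapply(preds, `[[`, numeric(1), "n_unseen")
    tab$label <- classify_rule(tab$mean, tab$sd, k = k, cutoff = cutoff)
  }
  structure(tab, class = c("rule_table", "data.frame"),
            change_vectors = vecs, k = k, cutoff = cutoff)
}
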