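# Synthetic corpora with known ground truth. Molecules come from a fixed
# template grammar (carbon chains of length 2-8 decorated with OH/NH2/SH/
# CH3/Cl substituents, optionally at stereocentres), which guarantees
# chemically valid structures without random graph generation. Observations
# are exactly additive in the moiety contributions plus Gaussian noise, so
# every downstream module can be tested against a known answer.

SUBSTITUENTS <- c("O", "N", "S", "C", "Cl")  # -OH -NH2 -SH -CH3 -Cl

# one random template molecule as a SMILES string
template_molecule <- function() {
  len <- sample(2:8, 1)
  n_sub <- sample(0:2, 1)
  backbone <- rep("C", len)
  # substitutable interior positions (interior carbons can be stereocentres)
  interior <- setdiff(seq_len(len), c(1, len))
  if (n_sub > 0 && length(interior)) {
    pos <- sample(interior, min(n_sub, length(interior)))
    for (p in pos) {
      sub <- sample(SUBSTITUENTS, 1)
      stereo <- sample(c(TRUE, FALSE), 1)
      backbone[p] <- if (stereo) {
        sprintf("[C@%sH](%s)", if (sample(c(TRUE, FALSE), 1)) "@" else "", sub)
      } else {
        sprintf("C(%s)", sub)
      }
    }
  }
  paste(backbone, collapse = "")
}

#' Generate a self-contained synthetic corpus with known energetics
#'
#' Builds a small molecule library from the template grammar, decomposes it
#' into moieties, draws ground-truth moiety contributions from
#' \eqn{N(0, \code{contribution_sd}^2)}, assembles sparse random reactions,
#' and simulates observations \eqn{y = S^T G \cdot \Delta_g G^\circ_{true} +
#' N(0, \code{noise_sd}^2)}. The library always contains one enantiomer pair
#' (2-butanol R/S) and the reaction interconverting them, whose change
#' vector is zero without stereochemistry but nonzero with it -- the
#' epimerase/isomerase scenario.
#'
#' Moiety incidence matrices carry exact counting identities (for example,
#' the environment count of a hydroxyl oxygen always equals the summed
#' counts of the carbon environments it is attached to), so the design
#' matrix can never reach full column rank; instead the reaction set is
#' required to preserve the library's full information content
#' (\code{rank(S^T G) = rank(G)}, redrawn otherwise) and per-column
#' identifiability can be queried with \code{\link{identifiable_moieties}}.
#'
#' @param n_molecules Number of template molecules (>= 5; default 40).
#' @param n_reactions Number of simulated reactions (default 1000).
#' @param noise_sd Observation noise, kJ/mol (default 1).
#' @param seed Integer seed; the corpus is a deterministic function of it.
#' @param radii Decomposition radii (default 1: the generating model is
#'   additive in radius-1 moieties).
#' @param stereo Stereo-aware decomposition (default TRUE).
#' @param contribution_sd Spread of the true moiety contributions, kJ/mol
#'   (default 30, the scale of fitted moiety contributions on experimental
#'   corpora).
#' @param max_retries Redraws allowed for the rank check (default 20).
#' @return A \code{synthetic_corpus} list: \code{compounds}, \code{G},
#'   \code{S}, \code{reactions} (named coefficient vectors), \code{X},
#'   \code{y}, \code{dgG_true}, \code{noise_sd}, \code{seed}, plus the
#'   decomposition mode.
#' @export
generate_corpus <- function(n_molecules = 40, n_reactions = 1000, noise_sd = 1,
                            seed = 1, radii = 1, stereo = TRUE,
                            contribution_sd = 30, max_retries = 20) {
  stopifnot(n_molecules >= 5, n_reactions >= 2)
  withr::with_seed(as.integer(seed), {
    # enantiomer pair first: guarantees the stereo refinement scenario
    smiles <- c("C[C@H](O)CC", "C[C@@H](O)CC")
    tries <- 0
    while (length(smiles) < n_molecules && tries < 500 * n_molecules) {
      cand <- template_molecule()
      tries <- tries + 1
      if (!cand %in% smiles) smiles <- c(smiles, cand)
    }
    ids <- sprintf("M%03d", seq_along(smiles))
    compounds <- compound_table(ids, smiles)
    G <- build_incidence(compounds, radii = radii, stereo = stereo)
    p <- ncol(G)
    dgG_true <- stats::setNames(stats::rnorm(p, 0, contribution_sd), colnames(G))

    draw_reactions <- function() {
      rxns <- vector("list", n_reactions)
      # reaction 1: the enantiomer interconversion (isomerase scenario)
      rxns[[1]] <- stats::setNames(c(-1, 1), ids[1:2])
      for (j in seq(2, n_reactions)) {
        k <- sample(2:4, 1)
        cpds <- sample(ids, k)
        n_react <- sample(seq_len(k - 1), 1)
        coefs <- sample(1:2, k, replace = TRUE)
        coefs[seq_len(n_react)] <- -coefs[seq_len(n_react)]
        rxns[[j]] <- stats::setNames(as.numeric(coefs), cpds)
      }
      names(rxns) <- sprintf("R%04d", seq_len(n_reactions))
      rxns
    }
    build_S <- function(rxns) {
      S <- matrix(0, nrow = length(ids), ncol = length(rxns),
                  dimnames = list(ids, names(rxns)))
      for (j in seq_along(rxns)) S[names(rxns[[j]]), j] <- rxns[[j]]
      S
    }

    rank_G <- qr(unclass(G))$rank
    check_rank <- n_reactions >= 2 * p
    for (attempt in seq_len(max_retries)) {
      reactions <- draw_reactions()
      S <- build_S(reactions)
      X <- t(S) %*% unclass(G)
      if (!check_rank || qr(X)$rank == rank_G) break
      if (attempt == max_retries) {
        mt_error(sprintf(
          "design matrix lost rank after %d redraws (%d reactions, rank %d < %d)",
          max_retries, n_reactions, qr(X)$rank, rank_G), "mt_generator_error")
      }
    }
    y <- drop(X %*% dgG_true) + stats::rnorm(n_reactions, 0, noise_sd)
    structure(list(
      compounds = compounds, G = G, S = S, reactions = reactions,
      X = X, y = y, dgG_true = dgG_true, noise_sd = noise_sd,
      seed = as.integer(seed), radii = radii, stereo = stereo,
      contribution_sd = contribution_sd
    ), class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic corpus: %d molecules, %d moieties, %d reactions; noise %.2g kJ/mol; seed %d>\n",
    nrow(x$G), ncol(x$G), length(x$y), x$noise_sd, x$seed))
  invisible(x)
}

#' Hand-written pseudoisomer fixtures with closed-form limits
#'
#' Three specifications used throughout the tests: \code{P0} (no dissociable
#' protons: the transform offset is identically zero), \code{P1} (one pKa at
#' 7.5, reference fully protonated) and \code{P2} (two pKas, reference in the
#' middle at m = 1, charge -1).
#'
#' @return Named list of \code{\link{pseudoisomer_spec}}s.
#' @export
fixture_pseudoisomer_specs <- function() {
  list(
    P0 = pseudoisomer_spec("P0", numeric(0), m = 0, z_ref = 0),
    P1 = pseudoisomer_spec("P1", pKa = 7.5, m = 1, z_ref = 0),
    P2 = pseudoisomer_spec("P2", pKa = c(4.2, 9.1), m = 1, z_ref = -1)
  )
}

#' Write the standard fixture TSV bundle for a synthetic corpus
#'
#' Writes \code{compounds.tsv} (compound_id, smiles), \code{training.tsv}
#' (reaction string, observed energy, pH/I/T columns at reference
#' conditions) and \code{pseudoisomers.tsv} (the three fixture specs) into
#' \code{dir}.
#'
#' @param corpus A \code{\link{generate_corpus}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_corpus_fixtures <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(compound_id = corpus$compounds$compound_id,
               smiles = corpus$compounds$canonical_smiles),
    file.path(dir, "compounds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  rxn_string <- vapply(corpus$reactions, function(r) {
    side <- function(sgn) paste(sprintf("%g %s", abs(r[sgn(r) ]), names(r)[sgn(r)]),
                                collapse = " + ")
    paste(side(function(v) v < 0), "<=>", side(function(v) v > 0))
  }, character(1))
  utils::write.table(
    data.frame(reaction = rxn_string, drg_obs = corpus$y,
               pH = 7.0, ionic_strength = 0.25, temperature = 298.15),
    file.path(dir, "training.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  specs <- fixture_pseudoisomer_specs()
  utils::write.table(
    data.frame(compound_id = names(specs),
               pKa_list = vapply(specs, function(s) paste(s$pKa, collapse = ";"),
                                 character(1)),
               m = vapply(specs, `[[`, integer(1), "m"),
               z_ref = vapply(specs, `[[`, integer(1), "z_ref")),
    file.path(dir, "pseudoisomers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load the public experimental thermodynamics corpus (user-downloaded)
#'
#' Points the training pipeline at a local checkout of the
#' component-contribution repository's TECRDB-derived data. The data are
#' never downloaded automatically; obtain them from
#' \url{https://github.com/eladnoor/component-contribution/} first. The
#' loader reads the TECRDB table (reaction strings with apparent equilibrium
#' constants and measurement conditions) and reports how the counts compare
#' with the expected ~4,001 reactions over 673 metabolites.
#'
#' @param dir Directory containing the downloaded corpus (a file matching
#'   \code{TECRDB*.tsv} is searched recursively).
#' @return List with \code{observations} (data frame: reaction string,
#'   K_prime and/or observed energy, pH, I, T) and \code{n_reactions},
#'   \code{n_metabolites}.
#' @export
load_thermo_corpus <- function(dir) {
  if (!dir.exists(dir)) {
    mt_error(paste0(
      "corpus directory '", dir, "' not found. Download the training corpus from ",
      "https://github.com/eladnoor/component-contribution/ and pass its path."),
      "mt_input_error")
  }
  hits <- list.files(dir, pattern = "^TECRDB.*\\.tsv$", recursive = TRUE,
                     full.names = TRUE, ignore.case = TRUE)
  if (!length(hits)) {
    mt_error(paste0("no TECRDB*.tsv found under '", dir, "'; expected the ",
                    "component-contribution data layout"), "mt_input_error")
  }
  tab <- utils::read.delim(hits[[1]], stringsAsFactors = FALSE, comment.char = "")
  names(tab) <- sub("^X\\.+", "", names(tab))  # tolerate '!'-prefixed headers
  rxn_col <- grep("reaction", names(tab), ignore.case = TRUE, value = TRUE)[1]
  if (is.na(rxn_col)) {
    mt_error("TECRDB table has no reaction column", "mt_input_error")
  }
  rxns <- tab[[rxn_col]]
  mets <- unique(unlist(strsplit(gsub("[0-9.]+ | ?[+=<>]+ ?", " ", rxns), "\\s+")))
  mets <- mets[grepl("^[CN][0-9]{5}$", mets)]
  message(sprintf(
    "loaded %d observations over %d metabolites (expected ~4001 reactions / 673 metabolites)",
    nrow(tab), length(mets)))
  list(observations = tab, n_reactions = nrow(tab), n_metabolites = length(mets))
}
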