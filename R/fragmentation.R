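# Moiety columns are namespaced as "r<radius>:<canonical fragment SMILES>" so
# radius-1 and radius-2 keys never collide when both are used in one matrix.
moiety_colname <- function(radius, key) paste0("r", radius, ":", key)

#' Split a moiety column label into radius and fragment key
#'
#' @param label Character vector of labels of the form \code{"r1:CCO"}.
#' @return Data frame with columns \code{radius} (integer) and \code{key}.
#' @export
moiety_label_parts <- function(label) {
  m <- regmatches(label, regexec("^r([0-9]+):(.*)$", label))
  data.frame(radius = vapply(m, function(x) as.integer(x[2]), integer(1)),
             key = vapply(m, function(x) x[3], character(1)),
             stringsAsFactors = FALSE)
}

mt_structure_of <- function(x) {
  if (inherits(x, "compound_record")) x$canonical_smiles
  else if (is.character(x) && length(x) == 1) x
  else mt_error("expected a compound_record or a single structure string",
                "mt_input_error")
}

check_radii <- function(radii) {
  radii <- as.integer(radii)
  if (any(radii < 1)) {
    mt_error("radius 0 is excluded by construction (each atom alone carries no bonding information)",
             "mt_input_error")
  }
  if (any(radii > 2)) {
    mt_error("radii above 2 are rejected: larger environments multiply the moiety alphabet and overfit the available training data",
             "mt_input_error")
  }
  sort(unique(radii))
}

#' Bonding environment of one atom as a canonical SMILES fragment
#'
#' Extracts the induced subgraph on all atoms within \code{radius} bonds of
#' the chosen atom (keeping every bond among them, including ring closures
#' between peripheral atoms) and returns its canonical SMILES. At the edge of
#' a small molecule the environment is simply the truncated reachable
#' subgraph. With \code{stereo = FALSE} all chirality annotations are
#' stripped before canonicalization.
#'
#' @param x A \code{compound_record} or a structure string.
#' @param atom_index 1-based atom index in the toolkit's atom ordering of the
#'   parsed structure (hydrogens are implicit and carry no index).
#' @param radius Bonding distance, 1 or 2.
#' @param stereo Keep stereochemistry annotations? Default \code{TRUE}.
#' @return A single fragment SMILES string.
#' @export
atom_environment <- function(x, atom_index, radius, stereo = TRUE) {
  radius <- check_radii(radius)
  stopifnot(length(radius) == 1, length(atom_index) == 1)
  structure_ <- mt_structure_of(x)
  envs <- mt_environments(structure_, radius, stereo)[[1]][[as.character(radius)]]
  if (atom_index < 1 || atom_index > length(envs)) {
    mt_error(sprintf("atom_index %d out of range [1, %d]",
                     as.integer(atom_index), length(envs)), "mt_input_error")
  }
  envs[[atom_index]]
}

#' Decompose a molecule into its moiety count vector
#'
#' Every non-hydrogen atom contributes exactly one bonding environment, so
#' the counts always sum to the heavy-atom count per radius.
#'
#' @inheritParams atom_environment
#' @param radius Bonding distance(s): 1, 2 or \code{c(1, 2)}.
#' @return A \code{moiety_vector}: data frame with columns \code{moiety}
#'   (namespaced label), \code{radius}, \code{key} (fragment SMILES) and
#'   \code{count}, with the heavy-atom count and decomposition mode as
#'   attributes.
#' @examples
#' \dontrun{
#' decompose("NO", radius = 1)          # hydroxylamine: 2 environments
#' decompose("C[C@@H](O)CC", radius = 1, stereo = FALSE)
#' }
#' @export
decompose <- function(x, radius = c(1, 2), stereo = TRUE) {
  radii <- check_radii(radius)
  structure_ <- mt_structure_of(x)
  envs <- mt_environments(structure_, radii, stereo)[[1]]
  rows <- do.call(rbind, lapply(radii, function(r) {
    keys <- envs[[as.character(r)]]
    cnt <- table(keys)
    data.frame(moiety = moiety_colname(r, names(cnt)),
               radius = r, key = names(cnt),
               count = as.integer(cnt), stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$radius, rows$key, method = "radix"), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("moiety_vector", "data.frame"),
            heavy_atom_count = length(envs[[1]]),
            stereo = stereo, radii = radii)
}

#' Moiety incidence matrix over a compound table
#'
#' Builds the compounds-by-moieties count matrix \eqn{G_{i,g}}: entry
#' \eqn{(i, g)} counts how often moiety \eqn{g} occurs in compound \eqn{i}.
#' With \code{radii = c(1, 2)} the matrix is the horizontal concatenation of
#' the per-radius matrices (the combined-radius description). Columns are
#' ordered lexicographically by (radius, key) so the matrix is reproducible
#' across runs.
#'
#' @param compounds A \code{\link{compound_table}}.
#' @param radii Bonding distances to include (subset of \code{c(1, 2)}).
#' @param stereo Keep stereochemistry annotations? Default \code{TRUE}.
#' @return An integer matrix of class \code{moiety_incidence} with compound
#'   IDs as row names, namespaced moiety labels as column names, and
#'   \code{radii}, \code{stereo}, \code{toolkit}, \code{toolkit_version}
#'   attributes.
#' @export
build_incidence <- function(compounds, radii = c(1, 2), stereo = TRUE) {
  radii <- check_radii(radii)
  stopifnot(inherits(compounds, "compound_table"))
  smiles <- compounds$canonical_smiles
  envs <- tryCatch(
    mt_environments(smiles, radii, stereo),
    moietherm_error = function(e) {
      # identify all failing compounds before aborting
      bad <- character(0)
      for (i in seq_along(smiles)) {
        ok <- tryCatch({mt_environments(smiles[[i]], radii, stereo); TRUE},
                       moietherm_error = function(e2) FALSE)
        if (!ok) bad <- c(bad, compounds$compound_id[[i]])
      }
      mt_error(paste0("decomposition failed for compound(s): ",
                      paste(bad, collapse = ", ")), "mt_decompose_error")
    })
  per_cpd <- lapply(envs, function(e) {
    counts <- unlist(lapply(radii, function(r) {
      cnt <- table(e[[as.character(r)]])
      stats::setNames(as.integer(cnt), moiety_colname(r, names(cnt)))
    }))
  })
  cols <- sort(unique(unlist(lapply(per_cpd, names))) %||% character(0),
               method = "radix")
  G <- matrix(0L, nrow = length(per_cpd), ncol = length(cols),
              dimnames = list(compounds$compound_id, cols))
  for (i in seq_along(per_cpd)) G[i, names(per_cpd[[i]])] <- per_cpd[[i]]
  tk <- mt_toolkit()
  structure(G, class = c("moiety_incidence", "matrix", "array"),
            radii = radii, stereo = stereo,
            toolkit = tk$name, toolkit_version = tk$version)
}

#' @export
print.moiety_incidence <- function(x, ...) {
  cat(sprintf("<moiety incidence: %d compounds x %d moieties; radii {%s}; stereo %s; %s %s>\n",
              nrow(x), ncol(x), paste(attr(x, "radii"), collapse = ","),
              if (isTRUE(attr(x, "stereo"))) "on" else "off",
              attr(x, "toolkit"), attr(x, "toolkit_version")))
  invisible(x)
}

#' Net moiety-change vector of a reaction
#'
#' Computes the reaction feature vector \eqn{x_j = S^T G} restricted to one
#' reaction: the signed sum of the reactants' and products' moiety count
#' rows, weighted by stoichiometry. Antisymmetric under reaction reversal.
#'
#' @param reaction A \code{\link{parse_reaction}} result (named signed
#'   coefficient vector) or any named numeric vector over compound IDs.
#' @param G A \code{\link{build_incidence}} matrix whose rows cover every
#'   compound in the reaction.
#' @return Named numeric vector over the moiety columns of \code{G}.
#' @export
moiety_change <- function(reaction, G) {
  ids <- names(reaction)
  missing_ids <- setdiff(ids, rownames(G))
  if (length(missing_ids)) {
    mt_error(paste0("compound(s) not in incidence matrix: ",
                    paste(missing_ids, collapse = ", ")), "mt_input_error")
  }
  drop(as.numeric(reaction) %*% G[ids, , drop = FALSE])
}

#' Serialize an incidence matrix to TSV plus a JSON metadata sidecar
#'
#' @param G A \code{moiety_incidence} matrix.
#' @param path Output TSV path; metadata goes to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_incidence <- function(G, path) {
  df <- data.frame(compound_id = rownames(G), as.data.frame(unclass(G)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(radii = attr(G, "radii"), stereo = attr(G, "stereo"),
               toolkit = attr(G, "toolkit"),
               toolkit_version = attr(G, "toolkit_version"),
               n_compounds = nrow(G), n_moieties = ncol(G))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
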