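#' Parse and canonicalize a compound structure
#'
#' Accepts an InChI (detected by the \code{InChI=} prefix) or a SMILES string,
#' canonicalizes it to isomeric canonical SMILES with implicit hydrogens, and
#' records the bookkeeping needed downstream: heavy-atom count, formal charge
#' and the number of hydrogens in the encoded protonation state. Stereo
#' annotations present in the input are preserved. Structures containing
#' metal atoms or repeat-unit wildcards (polymers) are rejected: no training
#' data exists for them and their energetics are outside the model.
#'
#' @param compound_id Identifier for the compound (e.g. a KEGG \code{C#####}
#'   ID or a novel \code{N#####} ID); used in error messages and as the key
#'   in compound tables.
#' @param structure InChI or SMILES string.
#' @return A \code{compound_record}: a list with fields \code{compound_id},
#'   \code{inchi}, \code{canonical_smiles}, \code{heavy_atom_count},
#'   \code{formal_charge}, \code{num_protons} and \code{elements} (named
#'   integer vector of element counts, hydrogens included).
#' @examples
#' \dontrun{
#' parse_compound("X1", "O")            # water: 1 heavy atom, 2 protons
#' parse_compound("X2", "C[C@@H](O)CC") # stereocentre kept in canonical form
#' }
#' @export
parse_compound <- function(compound_id, structure) {
  stopifnot(is.character(compound_id), length(compound_id) == 1,
            is.character(structure), length(structure) == 1)
  rec <- mt_parse_structures(structure)[[1]]
  if (!isTRUE(rec$ok)) {
    cls <- switch(rec$error_class,
                  parse = "mt_parse_error",
                  valence = "mt_valence_error",
                  "mt_unsupported_structure_error")
    mt_error(sprintf("compound '%s': %s", compound_id, rec$error), cls,
             compound_id = compound_id)
  }
  structure(list(
    compound_id = compound_id,
    inchi = rec$inchi,
    canonical_smiles = rec$canonical_smiles,
    heavy_atom_count = as.integer(rec$heavy_atom_count),
    formal_charge = as.integer(rec$formal_charge),
    num_protons = as.integer(rec$num_protons),
    elements = unlist(rec$elements)
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound %s> %s  (%d heavy atoms, charge %+d, %d H)\n",
              x$compound_id, x$canonical_smiles, x$heavy_atom_count,
              x$formal_charge, x$num_protons))
  invisible(x)
}

#' Build a compound table from IDs and structures
#'
#' @param compound_ids Character vector of unique compound IDs.
#' @param structures Character vector of InChI or SMILES strings, parallel to
#'   \code{compound_ids}.
#' @return A \code{compound_table}: a data frame with one row per compound
#'   (columns \code{compound_id}, \code{canonical_smiles}, \code{inchi},
#'   \code{heavy_atom_count}, \code{formal_charge}, \code{num_protons}, plus a
#'   list-column \code{elements}), carrying the toolkit name/version as
#'   attributes.
#' @export
compound_table <- function(compound_ids, structures) {
  stopifnot(length(compound_ids) == length(structures))
  if (anyDuplicated(compound_ids)) {
    mt_error(paste0("duplicate compound IDs: ",
                    paste(unique(compound_ids[duplicated(compound_ids)]),
                          collapse = ", ")), "mt_input_error")
  }
  recs <- lapply(seq_along(compound_ids), function(i)
    parse_compound(compound_ids[[i]], structures[[i]]))
  tab <- data.frame(
    compound_id = vapply(recs, `[[`, character(1), "compound_id"),
    canonical_smiles = vapply(recs, `[[`, character(1), "canonical_smiles"),
    inchi = vapply(recs, `[[`, character(1), "inchi"),
    heavy_atom_count = vapply(recs, `[[`, integer(1), "heavy_atom_count"),
    formal_charge = vapply(recs, `[[`, integer(1), "formal_charge"),
    num_protons = vapply(recs, `[[`, integer(1), "num_protons"),
    stringsAsFactors = FALSE
  )
  tab$elements <- lapply(recs, `[[`, "elements")
  rownames(tab) <- tab$compound_id
  tk <- mt_toolkit()
  structure(tab, class = c("compound_table", "data.frame"),
            toolkit = tk$name, toolkit_version = tk$version)
}

#' Load a compound table from a TSV file
#'
#' The file must have a \code{compound_id} column and an \code{inchi} or
#' \code{smiles} column (if both are present, \code{inchi} wins).
#'
#' @param path Path to a tab-separated file.
#' @return A \code{\link{compound_table}}.
#' @export
load_compound_table <- function(path) {
  if (!file.exists(path)) {
    mt_error(sprintf("compound table '%s' not found", path), "mt_input_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) {
    warning("compound table '", path, "' is empty")
    return(compound_table(character(0), character(0)))
  }
  if (!"compound_id" %in% names(tab)) {
    mt_error("compound table must have a 'compound_id' column", "mt_input_error")
  }
  col <- intersect(c("inchi", "smiles"), names(tab))
  if (!length(col)) {
    mt_error("compound table must have an 'inchi' or 'smiles' column", "mt_input_error")
  }
  compound_table(as.character(tab$compound_id), as.character(tab[[col[[1]]]]))
}
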