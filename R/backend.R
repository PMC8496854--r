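#' @keywords internal
"_PACKAGE"

# package-level state: python discovery, toolkit version, per-molecule caches
.mt_state <- new.env(parent = emptyenv())

mt_error <- function(message, class, ...) {
  stop(structure(
    class = c(class, "moietherm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Locate the Python interpreter used for the cheminformatics backend
#'
#' The fragmentation engine canonicalizes structures and extracts atom
#' environments with RDKit, driven through a small bundled Python worker.
#' The interpreter is resolved once per session from, in order, the
#' \code{moietherm.python} option, the \code{MOIETHERM_PYTHON} environment
#' variable, and \code{python3}/\code{python} on the \code{PATH}; it must be
#' able to \code{import rdkit}.
#'
#' @return Path to the interpreter (invisibly cached for the session).
#' @export
mt_python <- function() {
  if (!is.null(.mt_state$python)) return(.mt_state$python)
  candidates <- c(
    getOption("moietherm.python", ""),
    Sys.getenv("MOIETHERM_PYTHON", ""),
    Sys.which("python3"),
    Sys.which("python")
  )
  candidates <- candidates[nzchar(candidates)]
  for (py in candidates) {
    ok <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                   stdout = FALSE, stderr = FALSE))
    if (identical(ok, 0L)) {
      .mt_state$python <- py
      return(py)
    }
  }
  mt_error(paste0(
    "no Python interpreter with RDKit found; set options(moietherm.python=) ",
    "or the MOIETHERM_PYTHON environment variable"), "mt_backend_error")
}

# run one JSON request through the worker
mt_chem_call <- function(req) {
  helper <- system.file("python", "moiety_tool.py", package = "moietherm")
  if (!nzchar(helper)) {
    # source-tree fallback (used by devtools::load_all during development)
    helper <- file.path("inst", "python", "moiety_tool.py")
  }
  req_file <- tempfile(fileext = ".json")
  err_file <- tempfile(fileext = ".log")
  on.exit(unlink(c(req_file, err_file)), add = TRUE)
  jsonlite::write_json(req, req_file, auto_unbox = TRUE, digits = NA, null = "null")
  out <- suppressWarnings(system2(mt_python(), shQuote(helper),
                                  stdin = req_file, stdout = TRUE, stderr = err_file))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    mt_error(paste0("cheminformatics worker failed: ",
                    paste(readLines(err_file, warn = FALSE), collapse = "\n")),
             "mt_backend_error")
  }
  resp <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) {
    mt_error(paste0("cheminformatics worker error: ", resp$error), "mt_backend_error")
  }
  .mt_state$toolkit <- list(name = resp$toolkit, version = resp$toolkit_version)
  resp
}

#' Report the cheminformatics toolkit behind the fragmentation engine
#'
#' Moiety keys are canonicalization-dependent, so models record the toolkit
#' name and version; this returns them (triggering backend discovery if
#' needed).
#'
#' @return A list with elements \code{name} and \code{version}.
#' @export
mt_toolkit <- function() {
  if (is.null(.mt_state$toolkit)) {
    mt_chem_call(list(op = "parse", structures = list(list(id = "x", structure = "C"))))
  }
  .mt_state$toolkit
}

# ---- cached, batched primitives -------------------------------------------

mt_cache_get <- function(cache, keys) {
  if (is.null(.mt_state[[cache]])) .mt_state[[cache]] <- new.env(parent = emptyenv())
  env <- .mt_state[[cache]]
  lapply(keys, function(k) if (exists(k, envir = env, inherits = FALSE))
    get(k, envir = env) else NULL)
}

mt_cache_set <- function(cache, keys, values) {
  env <- .mt_state[[cache]]
  for (i in seq_along(keys)) assign(keys[[i]], values[[i]], envir = env)
}

# parse a character vector of structures; returns list of per-structure records
mt_parse_structures <- function(structures) {
  hits <- mt_cache_get("parse_cache", structures)
  miss <- which(vapply(hits, is.null, logical(1)))
  if (length(miss)) {
    uniq <- unique(structures[miss])
    resp <- mt_chem_call(list(
      op = "parse",
      structures = lapply(seq_along(uniq), function(i)
        list(id = as.character(i), structure = uniq[[i]]))
    ))
    recs <- resp$results
    names(recs) <- uniq
    mt_cache_set("parse_cache", uniq, recs)
    hits[miss] <- recs[structures[miss]]
  }
  hits
}

# per-atom environment keys for a vector of (already canonical) structures;
# returns list: one list per structure with one character vector per radius
mt_environments <- function(structures, radii, stereo) {
  tag <- function(s) paste0(paste(radii, collapse = ","), "|", stereo, "|", s)
  keys <- vapply(structures, tag, character(1), USE.NAMES = FALSE)
  hits <- mt_cache_get("env_cache", keys)
  miss <- which(vapply(hits, is.null, logical(1)))
  if (length(miss)) {
    uniq_idx <- miss[!duplicated(structures[miss])]
    resp <- mt_chem_call(list(
      op = "decompose",
      molecules = lapply(uniq_idx, function(i)
        list(id = as.character(i), structure = structures[[i]])),
      radii = as.list(radii), stereo = isTRUE(stereo)
    ))
    recs <- resp$results
    names(recs) <- keys[uniq_idx]
    mt_cache_set("env_cache", keys[uniq_idx], recs)
    hits[miss] <- recs[keys[miss]]
  }
  lapply(hits, function(r) {
    if (!isTRUE(r$ok)) {
      mt_error(paste0("decomposition failed: ", r$error),
               switch(r$error_class, parse = "mt_parse_error",
                      valence = "mt_valence_error", "mt_unsupported_structure_error"))
    }
    lapply(r$environments, function(e) vapply(e, identity, character(1)))
  })
}

# canonical re-canonicalization of fragment keys (NULL -> NA)
mt_canonical_fragment <- function(keys) {
  resp <- mt_chem_call(list(op = "canonical", keys = as.list(keys)))
  vapply(resp$results, function(x) if (is.null(x)) NA_character_ else x, character(1))
}
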