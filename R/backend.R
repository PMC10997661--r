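# Cheminformatics backend: a thin batched bridge to RDKit.
#
# All SMILES parsing, SMARTS matching, BRICS perception, fragment
# canonicalization and 2D depiction go through a single bundled helper
# script executed with the system `python`. Requests/responses are JSON;
# results are memoised per session so repeated lookups are free.

the <- new.env(parent = emptyenv())
the$parse_cache <- new.env(parent = emptyenv())
the$match_cache <- new.env(parent = emptyenv())
the$brics_cache <- new.env(parent = emptyenv())

python_binary <- function() {
  bin <- getOption("redgraph.python", Sys.getenv("REDGRAPH_PYTHON", ""))
  if (!nzchar(bin)) bin <- Sys.which("python")
  if (!nzchar(bin)) bin <- Sys.which("python3")
  if (!nzchar(bin)) {
    stop("no `python` interpreter with RDKit found on PATH", call. = FALSE)
  }
  bin
}

backend_script <- function() {
  path <- system.file("python", "chemtools.py", package = "redgraph")
  if (!nzchar(path)) stop("bundled chemtools.py not found", call. = FALSE)
  path
}

#' Run one request against the RDKit helper
#' @noRd
pychem <- function(request) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(request, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- suppressWarnings(
    system2(python_binary(), c(shQuote(backend_script()), shQuote(infile),
                               shQuote(outfile)),
            stdout = FALSE, stderr = FALSE)
  )
  if (!identical(status, 0L) || !file.exists(outfile)) {
    stop("chemistry backend call failed (op = ", request$op, ")",
         call. = FALSE)
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# --- parsing ----------------------------------------------------------------

#' Parse SMILES into molecule descriptions
#'
#' Returns, for each input SMILES, either `NULL` (unparseable) or a list
#' with canonical SMILES, per-atom and per-bond property tables, smallest
#' set of smallest rings (1-based atom indices), and fragment count.
#' Results are cached for the session.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list parallel to `smiles` of `mol_info` lists (or `NULL`).
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles))
  missing <- unique(smiles[!vapply(smiles, function(s)
    exists(s, envir = the$parse_cache), logical(1))])
  if (length(missing) > 0) {
    res <- pychem(list(op = "parse", smiles = as.list(missing)))
    for (k in seq_along(missing)) {
      assign(missing[k], convert_parse(res[[k]]), envir = the$parse_cache)
    }
  }
  lapply(smiles, function(s) get(s, envir = the$parse_cache))
}

convert_parse <- function(x) {
  if (is.null(x) || !isTRUE(x$ok)) return(NULL)
  atoms <- data.frame(
    element = vapply(x$atoms, `[[`, character(1), "el"),
    degree = vapply(x$atoms, `[[`, integer(1), "deg"),
    charge = vapply(x$atoms, `[[`, integer(1), "chg"),
    aromatic = vapply(x$atoms, `[[`, logical(1), "arom"),
    hybridization = vapply(x$atoms, `[[`, character(1), "hyb"),
    num_h = vapply(x$atoms, `[[`, integer(1), "nh"),
    in_ring = vapply(x$atoms, `[[`, logical(1), "ring"),
    stringsAsFactors = FALSE
  )
  if (length(x$bonds) > 0) {
    bonds <- data.frame(
      a1 = vapply(x$bonds, `[[`, integer(1), "a1") + 1L,
      a2 = vapply(x$bonds, `[[`, integer(1), "a2") + 1L,
      order = vapply(x$bonds, `[[`, integer(1), "order"),
      aromatic = vapply(x$bonds, `[[`, logical(1), "arom"),
      conjugated = vapply(x$bonds, `[[`, logical(1), "conj"),
      in_ring = vapply(x$bonds, `[[`, logical(1), "ring")
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0), conjugated = logical(0),
                        in_ring = logical(0))
  }
  structure(list(
    smiles = x$canonical,
    n_atoms = x$natoms,
    n_bonds = x$nbonds,
    n_fragments = x$nfrag,
    atoms = atoms,
    bonds = bonds,
    rings = lapply(x$rings, function(r) as.integer(unlist(r)) + 1L)
  ), class = "mol_info")
}

#' Canonicalize SMILES strings
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES; `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  info <- parse_molecules(smiles)
  vapply(info, function(m) if (is.null(m)) NA_character_ else m$smiles,
         character(1))
}

# --- SMARTS matching --------------------------------------------------------

#' Match SMARTS patterns against molecules
#'
#' @param smiles character vector of SMILES.
#' @param smarts character vector of SMARTS patterns.
#' @return nested list: `[[molecule]][[pattern]]` = list of integer vectors
#'   of matched atom indices (1-based); unparseable molecules give `NULL`.
#' @export
match_smarts <- function(smiles, smarts) {
  stopifnot(is.character(smiles), is.character(smarts), length(smarts) > 0)
  key <- function(s) paste(s, paste(smarts, collapse = "\1"), sep = "\2")
  need <- unique(smiles[!vapply(smiles, function(s)
    exists(key(s), envir = the$match_cache), logical(1))])
  if (length(need) > 0) {
    res <- pychem(list(op = "match", smiles = as.list(need),
                       smarts = as.list(smarts)))
    for (k in seq_along(need)) {
      row <- res[[k]]
      conv <- if (is.null(row)) NULL else lapply(row, function(pm)
        lapply(pm, function(m) as.integer(unlist(m)) + 1L))
      if (!is.null(conv)) names(conv) <- smarts
      assign(key(need[k]), conv, envir = the$match_cache)
    }
  }
  lapply(smiles, function(s) get(key(s), envir = the$match_cache))
}

#' Canonical SMILES of molecule fragments given atom subsets
#' @param smiles character vector, one parent per atom set.
#' @param atom_sets list of integer vectors (1-based atom indices).
#' @return character vector of fragment SMILES (`NA` on failure).
#' @export
fragment_smiles <- function(smiles, atom_sets) {
  stopifnot(length(smiles) == length(atom_sets))
  if (length(smiles) == 0) return(character(0))
  res <- pychem(list(
    op = "frag_smiles", smiles = as.list(smiles),
    atomsets = lapply(atom_sets, function(a) as.list(as.integer(a) - 1L))
  ))
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' BRICS-cleavable bonds of molecules
#' @param smiles character vector.
#' @return list of two-column integer matrices of atom pairs (1-based).
#' @export
brics_bonds <- function(smiles) {
  need <- unique(smiles[!vapply(smiles, function(s)
    exists(s, envir = the$brics_cache), logical(1))])
  if (length(need) > 0) {
    res <- pychem(list(op = "brics", smiles = as.list(need)))
    for (k in seq_along(need)) {
      row <- res[[k]]
      conv <- if (is.null(row) || length(row) == 0) {
        matrix(integer(0), ncol = 2)
      } else {
        do.call(rbind, lapply(row, function(b) as.integer(unlist(b)) + 1L))
      }
      assign(need[k], conv, envir = the$brics_cache)
    }
  }
  lapply(smiles, function(s) get(s, envir = the$brics_cache))
}

depict_svg <- function(smiles, weights, width = 450, height = 350) {
  res <- pychem(list(op = "depict", smiles = smiles,
                     weights = as.list(as.numeric(weights)),
                     width = width, height = height))
  if (!isTRUE(res$ok)) return(NULL)
  res$svg
}
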