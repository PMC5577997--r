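#' Read a protein structure from a PDB file
#'
#' Parses the `ATOM` records of a PDB coordinate file into a tidy atom table,
#' one row per atom. Only the 20 standard amino acids are retained: `HETATM`
#' records, waters and nucleic acids never enter the analysis. Hydrogens are
#' kept if present. Alternate locations are resolved at parse time, so each
#' atom name occurs at most once per residue downstream.
#'
#' Residue numbering is preserved verbatim from the file (author numbering);
#' the package never renumbers. This matters when interaction pairs are
#' labelled by residue number and compared across models whose numbering is
#' model-local (for example a homology model missing its N-terminal segment).
#'
#' @param path Path to a PDB file.
#' @param altloc_policy How to resolve alternate locations: pick the highest
#'   occupancy conformer (ties broken by altloc letter order), or the first
#'   one encountered in the file.
#' @return A tibble with one row per atom and columns `chain`, `resno`
#'   (integer, as authored), `icode` (insertion code, `""` if none), `resid`
#'   (3-letter residue code), `elety` (PDB atom name, e.g. `"OD1"`),
#'   `element`, `x`, `y`, `z` (Angstrom), `occ` and `altloc`. The source path
#'   is attached as attribute `"source"`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(make_ion_pair(3.5)$structure, pdb)
#' read_structure(pdb)
#' @seealso [write_structure()], [extract_sequence()]
#' @export
read_structure <- function(path, altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) {
    stop("cannot read structure file: '", path, "' does not exist", call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% STANDARD_AA, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no ATOM records of standard amino acids in '", path, "'", call. = FALSE)
  }
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0L) {
    stop("malformed ATOM record (non-numeric coordinates) for atom serial ",
         at$eleno[bad[1]], " in '", path, "'", call. = FALSE)
  }

  atoms <- tibble::tibble(
    chain = dplyr::coalesce(as.character(at$chain), ""),
    resno = as.integer(at$resno),
    icode = dplyr::coalesce(as.character(at$insert), ""),
    resid = at$resid,
    elety = at$elety,
    element = pdb_element(at$elety, at$elesy),
    x = at$x, y = at$y, z = at$z,
    occ = dplyr::coalesce(at$o, 1),
    altloc = dplyr::coalesce(as.character(at$alt), "")
  )
  atoms <- resolve_altlocs(atoms, altloc_policy)
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resno, .data$icode)
  attr(atoms, "source") <- path
  atoms
}

# Derive the element symbol from the elesy column when present, otherwise
# from the atom name with leading digits stripped.
pdb_element <- function(elety, elesy = NULL) {
  el <- if (!is.null(elesy)) stringr::str_trim(as.character(elesy)) else rep("", length(elety))
  el[is.na(el)] <- ""
  fallback <- stringr::str_sub(stringr::str_remove(elety, "^[0-9]+"), 1, 1)
  ifelse(el == "", toupper(fallback), toupper(el))
}

resolve_altlocs <- function(atoms, policy) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  if (policy == "highest_occupancy") {
    atoms |>
      dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
      dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  } else {
    atoms |>
      dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column `ATOM` records. Reading the file back with
#' [read_structure()] recovers the chain, residue and atom identities,
#' numbering, occupancies and coordinates (to the PDB precision of
#' 0.001 Angstrom).
#'
#' @param structure An atom tibble as returned by [read_structure()] or the
#'   synthetic generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  check_structure(structure)
  if (nrow(structure) == 0L) {
    stop("refusing to write an empty structure", call. = FALSE)
  }
  xyz <- as.numeric(t(as.matrix(structure[, c("x", "y", "z")])))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = xyz,
      type = rep("ATOM", nrow(structure)),
      resno = structure$resno,
      resid = structure$resid,
      eleno = seq_len(nrow(structure)),
      elety = structure$elety,
      chain = ifelse(structure$chain == "", " ", structure$chain),
      insert = ifelse(structure$icode == "", "", structure$icode),
      o = structure$occ,
      b = rep(0, nrow(structure)),
      elesy = structure$element
    )
    TRUE
  }, error = function(e) {
    stop("cannot write PDB file '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

check_structure <- function(structure) {
  needed <- c("chain", "resno", "icode", "resid", "elety", "element",
              "x", "y", "z", "occ", "altloc")
  missing <- setdiff(needed, names(structure))
  if (length(missing) > 0L) {
    stop("not a structure tibble; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(structure)
}

#' Extract the one-letter amino-acid sequence of a chain
#'
#' Maps the residues of a single chain to the IUPAC one-letter alphabet, in
#' residue order. The returned string has exactly one letter per residue.
#'
#' @param structure An atom tibble.
#' @param chain Chain identifier to extract; defaults to the only chain
#'   present (an error if the structure has several).
#' @return A one-letter amino-acid string.
#' @export
extract_sequence <- function(structure, chain = NULL) {
  check_structure(structure)
  structure <- pick_chain(structure, chain)
  res <- dplyr::distinct(structure, .data$resno, .data$icode, .data$resid)
  bad <- res$resid[!is_standard_aa(res$resid)]
  if (length(bad) > 0L) {
    stop("non-standard residue(s) in chain: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste(AA_321[res$resid], collapse = "")
}

pick_chain <- function(structure, chain = NULL) {
  if (is.null(chain)) {
    chains <- unique(structure$chain)
    if (length(chains) > 1L) {
      stop("structure has ", length(chains),
           " chains; supply `chain` explicitly", call. = FALSE)
    }
    return(structure)
  }
  out <- dplyr::filter(structure, .data$chain == !!chain)
  if (nrow(out) == 0L) {
    stop("no chain '", chain, "' in structure", call. = FALSE)
  }
  out
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file. An empty file yields an empty tibble.
#' @return A tibble with columns `header` and `sequence` (uppercased,
#'   whitespace-free), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: '", path, "' does not exist", call. = FALSE)
  }
  if (file.size(path) == 0L ||
      !any(stringr::str_detect(readLines(path, warn = FALSE), "\\S"))) {
    return(tibble::tibble(header = character(), sequence = character()))
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  tibble::tibble(
    header = names(set),
    sequence = unname(toupper(as.character(set)))
  )
}
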