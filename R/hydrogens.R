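# Polar-hydrogen inference for heavy-atom models (homology models carry no
# hydrogens). Donors with rigid sp2 geometry get explicit hydrogens built
# from their antecedent atoms; rotatable donors are flagged ambiguous and
# handled by heavy-atom-only criteria in the detector.

H_BOND_LENGTH <- 1.0  # N-H / O-H placement length, Angstrom
PEPTIDE_CN_MAX <- 1.8 # C(i)-N(i+1) distance regarded as a peptide bond

#' Infer polar hydrogen positions on a heavy-atom chain
#'
#' Places explicit hydrogens on donors whose geometry is fixed by their
#' heavy-atom neighbours: the backbone amide H (in the C-N-CA plane along
#' the external bisector, N-H = 1.0 Angstrom), Arg NE/NH1/NH2, Asn ND2,
#' Gln NE2, Trp NE1 and His ND1/NE2. Rotatable donors (Ser/Thr/Tyr
#' hydroxyls, Lys NZ, Cys SG) and amides lacking their antecedent atoms
#' (chain-initial N, broken backbone) are flagged `"ambiguous"` and receive
#' no hydrogen. Donors that already carry an explicit hydrogen in the input
#' keep it and are flagged `"explicit"`.
#'
#' @param structure An atom tibble (see [read_structure()]); may contain
#'   several chains.
#' @return A list with `structure` (the input plus inferred `H` atom rows)
#'   and `donors`, a tibble with one row per donor heavy atom and columns
#'   `chain`, `resno`, `icode`, `resid`, `atom` and
#'   `status` (`"explicit"`, `"placed"` or `"ambiguous"`).
#' @export
infer_polar_hydrogens <- function(structure) {
  check_structure(structure)
  res <- purrr::map(split_chains(structure), donor_table)
  donors <- purrr::map_dfr(res, function(d) {
    dplyr::select(d, "chain", "resno", "icode", "resid", "atom", "status")
  })
  new_h <- purrr::map_dfr(res, function(d) {
    placed <- d[d$status == "placed", , drop = FALSE]
    purrr::pmap_dfr(
      list(placed$chain, placed$resno, placed$icode, placed$resid,
           placed$h_names, placed$h_xyz),
      function(chain, resno, icode, resid, h_names, h_xyz) {
        tibble::tibble(
          chain = chain, resno = resno, icode = icode, resid = resid,
          elety = h_names, element = "H",
          x = h_xyz[, 1], y = h_xyz[, 2], z = h_xyz[, 3],
          occ = 1, altloc = ""
        )
      }
    )
  })
  out <- dplyr::bind_rows(structure, new_h)
  out <- dplyr::arrange(out, .data$chain, .data$resno, .data$icode)
  list(structure = out, donors = donors)
}

split_chains <- function(structure) {
  split(structure, structure$chain)
}

# All donor heavy atoms of one chain, with hydrogen positions where the
# geometry is unambiguous. Returns a tibble with list-columns `h_names`
# (character) and `h_xyz` (matrix, one row per hydrogen).
donor_table <- function(atoms) {
  res_split <- split(atoms, interaction(atoms$resno, atoms$icode, drop = TRUE, lex.order = TRUE))
  res_order <- order(vapply(res_split, function(r) r$resno[1], integer(1)),
                     vapply(res_split, function(r) r$icode[1], character(1)))
  res_split <- res_split[res_order]
  n_res <- length(res_split)

  rows <- list()
  for (i in seq_len(n_res)) {
    r <- res_split[[i]]
    resid <- r$resid[1]
    get_xyz <- function(name, from = r) {
      j <- which(from$elety == name)
      if (length(j) == 0L) return(NULL)
      as.numeric(from[j[1], c("x", "y", "z")])
    }
    explicit_h <- function(d_xyz) {
      h <- r[r$element == "H", , drop = FALSE]
      if (nrow(h) == 0L) return(NULL)
      hx <- as.matrix(h[, c("x", "y", "z")])
      keep <- sqrt(rowSums((hx - matrix(d_xyz, nrow(hx), 3, byrow = TRUE))^2)) <= 1.15
      if (!any(keep)) return(NULL)
      list(names = h$elety[keep], xyz = hx[keep, , drop = FALSE])
    }
    add_row <- function(atom, status, h_names = character(), h_xyz = matrix(numeric(0), 0, 3)) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        chain = r$chain[1], resno = r$resno[1], icode = r$icode[1],
        resid = resid, atom = atom, status = status,
        h_names = list(h_names), h_xyz = list(h_xyz)
      )
    }
    handle <- function(atom, placer) {
      d_xyz <- get_xyz(atom)
      if (is.null(d_xyz)) return(invisible())
      eh <- explicit_h(d_xyz)
      if (!is.null(eh)) {
        add_row(atom, "explicit", eh$names, eh$xyz)
        return(invisible())
      }
      placed <- placer(d_xyz)
      if (is.null(placed)) {
        add_row(atom, "ambiguous")
      } else {
        add_row(atom, "placed", placed$names, placed$xyz)
      }
    }

    # backbone amide N (Pro has no amide hydrogen and never donates)
    if (resid != "PRO") {
      handle("N", function(n_xyz) {
        ca <- get_xyz("CA")
        prev_c <- if (i > 1L) get_xyz("C", res_split[[i - 1L]]) else NULL
        if (is.null(ca) || is.null(prev_c)) return(NULL)
        if (vec_norm(prev_c - n_xyz) > PEPTIDE_CN_MAX) return(NULL)
        list(names = "H", xyz = matrix(bisector_h(n_xyz, prev_c, ca), 1, 3))
      })
    }

    sc <- DONOR_ATOMS[[resid]]
    for (atom in names(sc)) {
      spec <- sc[[atom]]
      handle(atom, function(d_xyz) {
        if (spec$kind == "rotatable") return(NULL)
        if (spec$kind == "placed") {
          a1 <- get_xyz(spec$antecedents[1])
          a2 <- get_xyz(spec$antecedents[2])
          if (is.null(a1) || is.null(a2)) return(NULL)
          nm <- paste0("H", substring(atom, 2))
          return(list(names = nm, xyz = matrix(bisector_h(d_xyz, a1, a2), 1, 3)))
        }
        # sp2 amine with two hydrogens in the stem plane
        s <- get_xyz(spec$stem)
        p <- get_xyz(spec$plane)
        if (is.null(s) || is.null(p)) return(NULL)
        h2 <- sp2_pair_h(d_xyz, s, p)
        base <- substring(atom, 2)
        list(names = paste0("H", base, 1:2), xyz = h2)
      })
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      chain = character(), resno = integer(), icode = character(),
      resid = character(), atom = character(), status = character(),
      h_names = list(), h_xyz = list()
    ))
  }
  dplyr::bind_rows(rows)
}

# H on donor D along the external bisector of neighbours a1, a2.
bisector_h <- function(d, a1, a2) {
  dir <- -(unit(a1 - d) + unit(a2 - d))
  d + H_BOND_LENGTH * unit(dir)
}

# Two sp2 hydrogens on amine N bonded to stem S, in the plane containing
# the reference atom P bonded to S; H-N-S angles of 120 degrees.
sp2_pair_h <- function(n, s, p) {
  u <- unit(n - s)
  nrm <- unit(cross3(s - p, n - s))
  m <- cross3(nrm, u)
  h1 <- n + H_BOND_LENGTH * unit(0.5 * u + sqrt(3) / 2 * m)
  h2 <- n + H_BOND_LENGTH * unit(0.5 * u - sqrt(3) / 2 * m)
  rbind(h1, h2)
}
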