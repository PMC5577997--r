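#' Charged side-chain atoms of a residue
#'
#' Returns the atom names carrying formal side-chain charge for salt-bridge
#' detection: Asp OD1/OD2 and Glu OE1/OE2 (acidic), Lys NZ, Arg NE/NH1/NH2
#' and, when `include_his` is set, His ND1/NE2 (basic). Atom names absent
#' from `atoms_present` are silently dropped, so a residue with a disordered
#' side chain simply contributes fewer (possibly zero) charged atoms.
#'
#' @param resid 3-letter residue code.
#' @param criteria A [salt_bridge_criteria()] object.
#' @param atoms_present Optional character vector of atom names actually
#'   present; if given, the result is restricted to it.
#' @return Character vector of atom names (possibly empty).
#' @export
charged_atoms <- function(resid, criteria = salt_bridge_criteria(),
                          atoms_present = NULL) {
  resid <- toupper(resid)
  out <- CHARGED_ATOMS[[resid]]
  if (is.null(out)) out <- character()
  if (resid == "HIS" && !criteria$include_his) out <- character()
  if (!is.null(atoms_present)) out <- intersect(out, atoms_present)
  out
}

#' Detect intrachain salt bridges
#'
#' Scores every (acidic residue, basic residue) pair within each chain: a
#' salt bridge is reported when the minimum distance between any charged
#' carboxylate oxygen and any charged nitrogen is within
#' `criteria$max_no_distance`. Exactly one row is emitted per residue pair,
#' however many atom pairs qualify.
#'
#' @param structure An atom tibble (see [read_structure()]).
#' @param criteria A [salt_bridge_criteria()] object.
#' @return A tibble sorted by `(chain, acidic_resno, basic_resno)` with one
#'   row per bridging residue pair: `chain`, `acidic_resid`, `acidic_resno`,
#'   `acidic_icode`, `basic_resid`, `basic_resno`, `basic_icode`,
#'   `min_distance` (Angstrom), `acidic_atom`, `basic_atom` (the closest
#'   atom pair), and `pair` (the canonical `"Xxx<N>||Yyy<M>"` label).
#' @examples
#' fx <- make_ion_pair(3.5, "GLU", "LYS")
#' detect_salt_bridges(fx$structure)
#' @export
detect_salt_bridges <- function(structure, criteria = salt_bridge_criteria()) {
  check_structure(structure)
  stopifnot(inherits(criteria, "salt_bridge_criteria"))
  out <- purrr::map_dfr(split_chains(structure), detect_salt_bridges_chain,
                        criteria = criteria)
  if (nrow(out) == 0L) return(empty_salt_bridge_tbl())
  dplyr::arrange(out, .data$chain, .data$acidic_resno, .data$acidic_icode,
                 .data$basic_resno, .data$basic_icode)
}

empty_salt_bridge_tbl <- function() {
  tibble::tibble(
    chain = character(), acidic_resid = character(), acidic_resno = integer(),
    acidic_icode = character(), basic_resid = character(),
    basic_resno = integer(), basic_icode = character(),
    min_distance = numeric(), acidic_atom = character(),
    basic_atom = character(), pair = character()
  )
}

detect_salt_bridges_chain <- function(atoms, criteria) {
  sets <- charged_atom_sets(atoms, criteria)
  aci <- sets$acidic
  bas <- sets$basic
  if (nrow(aci) == 0L || nrow(bas) == 0L) return(empty_salt_bridge_tbl())

  d <- cross_dist(as.matrix(aci[, c("x", "y", "z")]),
                  as.matrix(bas[, c("x", "y", "z")]))
  hit <- which(d <= criteria$max_no_distance, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_salt_bridge_tbl())

  hits <- tibble::tibble(
    chain = aci$chain[hit[, 1]],
    acidic_resid = aci$resid[hit[, 1]],
    acidic_resno = aci$resno[hit[, 1]],
    acidic_icode = aci$icode[hit[, 1]],
    basic_resid = bas$resid[hit[, 2]],
    basic_resno = bas$resno[hit[, 2]],
    basic_icode = bas$icode[hit[, 2]],
    distance = d[hit],
    acidic_atom = aci$elety[hit[, 1]],
    basic_atom = bas$elety[hit[, 2]]
  )
  hits |>
    dplyr::group_by(.data$chain, .data$acidic_resid, .data$acidic_resno,
                    .data$acidic_icode, .data$basic_resid, .data$basic_resno,
                    .data$basic_icode) |>
    dplyr::arrange(.data$distance, .data$acidic_atom, .data$basic_atom,
                   .by_group = TRUE) |>
    dplyr::summarise(
      min_distance = .data$distance[1],
      acidic_atom = .data$acidic_atom[1],
      basic_atom = .data$basic_atom[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(pair = pair_label_text(
      .data$acidic_resid, .data$acidic_resno,
      .data$basic_resid, .data$basic_resno
    ))
}

# Charged-atom rows of a chain, split into acidic O and basic N tables.
charged_atom_sets <- function(atoms, criteria) {
  aci <- atoms |>
    dplyr::filter(.data$resid %in% ACIDIC_RESIDUES) |>
    dplyr::group_by(.data$resno, .data$icode) |>
    dplyr::filter(.data$elety %in% charged_atoms(.data$resid[1], criteria)) |>
    dplyr::ungroup()
  bas <- atoms |>
    dplyr::filter(.data$resid %in% BASIC_RESIDUES) |>
    dplyr::group_by(.data$resno, .data$icode) |>
    dplyr::filter(.data$elety %in% charged_atoms(.data$resid[1], criteria)) |>
    dplyr::ungroup()
  if (criteria$include_termini && nrow(atoms) > 0L) {
    first_res <- atoms |>
      dplyr::filter(.data$resno == min(.data$resno)) |>
      dplyr::filter(.data$icode == min(.data$icode))
    nt <- dplyr::filter(first_res, .data$elety == "N")
    bas <- dplyr::bind_rows(bas, nt)
    last_res <- atoms |>
      dplyr::filter(.data$resno == max(.data$resno)) |>
      dplyr::filter(.data$icode == max(.data$icode))
    ct <- dplyr::filter(last_res, .data$elety %in% c("OXT"))
    aci <- dplyr::bind_rows(aci, ct)
  }
  list(acidic = aci, basic = bas)
}

#' Detect intrachain hydrogen bonds
#'
#' Enumerates donor-acceptor atom pairs within each chain under geometric
#' criteria. Donors are N/O/S atoms bearing (or inferably bearing) a
#' hydrogen; acceptors are carbonyl, carboxylate and hydroxyl oxygens.
#' Where a hydrogen is present or can be placed ([infer_polar_hydrogens()]),
#' the bond requires d(D,A) <= `max_da`, d(H,A) <= `max_ha` and a
#' D-H...A angle of at least `min_dha_angle`. Donors whose hydrogen
#' position is ambiguous (hydroxyls, Lys NZ, chain-initial amides) use the
#' heavy-atom-only fallback: d(D,A) <= `heavy_only_max_da` and a
#' D...A-antecedent angle of at least `min_daa_angle`. Covalently bonded
#' (1-2), angle-related (1-3) and intra-residue pairs are excluded. One row
#' is reported per (donor atom, acceptor atom) pair.
#'
#' @param structure An atom tibble (see [read_structure()]).
#' @param criteria An [hbond_criteria()] object.
#' @return A tibble sorted by donor then acceptor with columns `chain`,
#'   `donor_resid`, `donor_resno`, `donor_icode`, `donor_atom`,
#'   `acceptor_resid`, `acceptor_resno`, `acceptor_icode`, `acceptor_atom`,
#'   `d_da`, `d_ha`, `angle_dha` (both `NA` on the heavy-atom path) and
#'   `path` (`"hydrogen"` or `"heavy"`).
#' @examples
#' hx <- make_helix(12)
#' detect_hbonds(hx$structure)
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria()) {
  check_structure(structure)
  stopifnot(inherits(criteria, "hbond_criteria"))
  out <- purrr::map_dfr(split_chains(structure), detect_hbonds_chain,
                        criteria = criteria)
  if (nrow(out) == 0L) return(empty_hbond_tbl())
  dplyr::arrange(out, .data$chain, .data$donor_resno, .data$donor_icode,
                 .data$donor_atom, .data$acceptor_resno,
                 .data$acceptor_icode, .data$acceptor_atom)
}

empty_hbond_tbl <- function() {
  tibble::tibble(
    chain = character(), donor_resid = character(), donor_resno = integer(),
    donor_icode = character(), donor_atom = character(),
    acceptor_resid = character(), acceptor_resno = integer(),
    acceptor_icode = character(), acceptor_atom = character(),
    d_da = numeric(), d_ha = numeric(), angle_dha = numeric(),
    path = character()
  )
}

detect_hbonds_chain <- function(atoms, criteria) {
  if (nrow(atoms) == 0L) return(empty_hbond_tbl())
  atoms$.id <- seq_len(nrow(atoms))
  nbrs <- bond_neighbours(atoms)
  donors <- donor_table(atoms)
  donors <- dplyr::left_join(
    donors,
    dplyr::select(atoms, ".id", "resno", "icode", "elety"),
    by = c(resno = "resno", icode = "icode", atom = "elety")
  )
  acceptors <- acceptor_table(atoms)
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(empty_hbond_tbl())

  dxyz <- as.matrix(atoms[donors$.id, c("x", "y", "z")])
  axyz <- as.matrix(atoms[acceptors$.id, c("x", "y", "z")])
  dd <- cross_dist(dxyz, axyz)
  hit <- which(dd <= criteria$max_da, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_hbond_tbl())

  rows <- vector("list", nrow(hit))
  for (k in seq_len(nrow(hit))) {
    di <- hit[k, 1]; ai <- hit[k, 2]
    don <- donors[di, ]
    acc <- acceptors[ai, ]
    if (don$resno == acc$resno && don$icode == acc$icode) next
    id_d <- don$.id; id_a <- acc$.id
    if (id_a %in% nbrs[[id_d]]) next                 # 1-2
    if (length(intersect(nbrs[[id_d]], nbrs[[id_a]])) > 0L) next  # 1-3
    d_da <- dd[di, ai]
    d_pos <- dxyz[di, ]
    a_pos <- axyz[ai, ]

    if (don$status %in% c("explicit", "placed")) {
      hx <- don$h_xyz[[1]]
      if (nrow(hx) == 0L) next
      d_ha <- sqrt(rowSums((hx - matrix(a_pos, nrow(hx), 3, byrow = TRUE))^2))
      ang <- vapply(seq_len(nrow(hx)), function(j) {
        angle_deg(d_pos, hx[j, ], a_pos)
      }, numeric(1))
      ok <- d_ha <= criteria$max_ha & ang >= criteria$min_dha_angle
      if (!any(ok)) next
      j <- which(ok)[which.min(d_ha[which(ok)])]
      rows[[k]] <- hbond_row(don, acc, d_da, d_ha[j], ang[j], "hydrogen")
    } else {
      if (d_da > criteria$heavy_only_max_da) next
      ant <- acc$ant_xyz[[1]]
      if (is.null(ant)) next
      ang <- angle_deg(d_pos, a_pos, ant)
      if (ang < criteria$min_daa_angle) next
      rows[[k]] <- hbond_row(don, acc, d_da, NA_real_, NA_real_, "heavy")
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_hbond_tbl())
  dplyr::bind_rows(rows)
}

hbond_row <- function(don, acc, d_da, d_ha, ang, path) {
  tibble::tibble(
    chain = don$chain, donor_resid = don$resid, donor_resno = don$resno,
    donor_icode = don$icode, donor_atom = don$atom,
    acceptor_resid = acc$resid, acceptor_resno = acc$resno,
    acceptor_icode = acc$icode, acceptor_atom = acc$atom,
    d_da = d_da, d_ha = d_ha, angle_dha = ang, path = path
  )
}

# Acceptor atoms of one chain with the antecedent position used for the
# donor-acceptor-antecedent angle on the heavy-atom path.
acceptor_table <- function(atoms) {
  res_split <- split(atoms, interaction(atoms$resno, atoms$icode, drop = TRUE, lex.order = TRUE))
  rows <- list()
  for (r in res_split) {
    resid <- r$resid[1]
    get <- function(name) {
      j <- which(r$elety == name)
      if (length(j) == 0L) return(NULL)
      list(id = r$.id[j[1]], xyz = as.numeric(r[j[1], c("x", "y", "z")]))
    }
    add <- function(atom, ant_name) {
      a <- get(atom)
      if (is.null(a)) return(invisible())
      ant <- get(ant_name)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        chain = r$chain[1], resno = r$resno[1], icode = r$icode[1],
        resid = resid, atom = atom, .id = a$id,
        ant_xyz = list(if (is.null(ant)) NULL else ant$xyz)
      )
    }
    add("O", "C")
    add("OXT", "C")
    sc <- ACCEPTOR_ATOMS[[resid]]
    for (atom in names(sc)) add(atom, sc[[atom]])
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(chain = character(), resno = integer(),
                          icode = character(), resid = character(),
                          atom = character(), .id = integer(),
                          ant_xyz = list()))
  }
  dplyr::bind_rows(rows)
}

# Covalent neighbour lists (heavy-atom topology plus peptide bonds and any
# explicit hydrogens attached to their nearest heavy atom).
bond_neighbours <- function(atoms) {
  n <- nrow(atoms)
  edges_from <- integer(0)
  edges_to <- integer(0)
  add_edge <- function(i, j) {
    edges_from <<- c(edges_from, i, j)
    edges_to <<- c(edges_to, j, i)
  }
  res_split <- split(seq_len(n), interaction(atoms$resno, atoms$icode, drop = TRUE, lex.order = TRUE))
  order_key <- vapply(res_split, function(ix) atoms$resno[ix[1]] * 1000 +
                        match(atoms$icode[ix[1]], c("", LETTERS)), numeric(1))
  res_split <- res_split[order(order_key)]

  backbone <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                   c("CA", "CB"))
  prev_c <- NULL
  for (ix in res_split) {
    elety <- atoms$elety[ix]
    resid <- atoms$resid[ix][1]
    lookup <- function(name) {
      j <- which(elety == name)
      if (length(j) == 0L) NULL else ix[j[1]]
    }
    bonds <- c(backbone, SIDECHAIN_BONDS[[resid]])
    for (b in bonds) {
      i1 <- lookup(b[1]); i2 <- lookup(b[2])
      if (!is.null(i1) && !is.null(i2)) add_edge(i1, i2)
    }
    # peptide bond to previous residue, verified geometrically
    n_idx <- lookup("N")
    if (!is.null(prev_c) && !is.null(n_idx)) {
      d <- sqrt(sum((as.numeric(atoms[prev_c, c("x", "y", "z")]) -
                       as.numeric(atoms[n_idx, c("x", "y", "z")]))^2))
      if (d <= PEPTIDE_CN_MAX) add_edge(prev_c, n_idx)
    }
    prev_c <- lookup("C")
    # explicit hydrogens bond to the nearest heavy atom of the residue
    h_idx <- ix[atoms$element[ix] == "H"]
    heavy_idx <- setdiff(ix, h_idx)
    if (length(h_idx) > 0L && length(heavy_idx) > 0L) {
      hm <- as.matrix(atoms[h_idx, c("x", "y", "z")])
      vm <- as.matrix(atoms[heavy_idx, c("x", "y", "z")])
      dmat <- cross_dist(hm, vm)
      for (q in seq_along(h_idx)) {
        j <- which.min(dmat[q, ])
        if (dmat[q, j] <= 1.3) add_edge(h_idx[q], heavy_idx[j])
      }
    }
  }
  nbrs <- vector("list", n)
  for (i in seq_len(n)) nbrs[[i]] <- integer(0)
  if (length(edges_from) > 0L) {
    sp <- split(edges_to, edges_from)
    for (key in names(sp)) nbrs[[as.integer(key)]] <- unique(sp[[key]])
  }
  nbrs
}

#' Count hydrogen bonds and salt bridges per chain
#'
#' @param structure An atom tibble.
#' @param hbond An [hbond_criteria()] object.
#' @param salt_bridge A [salt_bridge_criteria()] object.
#' @return A tibble with one row per chain: `chain`, `hbonds`, `saltbridges`.
#' @export
count_interactions <- function(structure, hbond = hbond_criteria(),
                               salt_bridge = salt_bridge_criteria()) {
  check_structure(structure)
  chains <- unique(structure$chain)
  hb <- detect_hbonds(structure, hbond)
  sb <- detect_salt_bridges(structure, salt_bridge)
  tibble::tibble(
    chain = chains,
    hbonds = vapply(chains, function(ch) sum(hb$chain == ch), integer(1),
                    USE.NAMES = FALSE),
    saltbridges = vapply(chains, function(ch) sum(sb$chain == ch), integer(1),
                         USE.NAMES = FALSE)
  )
}
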