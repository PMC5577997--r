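# Seeded generators of toy single-chain structures with ground-truth
# interaction manifests. Side chains are built with idealized internal
# geometry (standard bond lengths and angles, extended rotamers); realism
# beyond the placement of the interacting groups is a non-goal. Every
# planted interaction is kept at least 0.2 Angstrom away from the default
# detection cutoffs (guard band), so coordinate round-off and small jitter
# can never flip an expectation.

GUARD_BAND <- 0.2

# Internal-coordinate side-chain recipes: atom, the three reference atoms,
# bond length (A), bond angle (deg), dihedral (deg). Extended chi = 180
# throughout; carboxylates/amides planar by construction.
SIDECHAIN_ZMAT <- list(
  ALA = list(),
  GLY = list(),
  SER = list(list("OG",  c("N", "CA", "CB"), 1.417, 110.8, 180)),
  THR = list(list("OG1", c("N", "CA", "CB"), 1.433, 109.6, 180),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, -60)),
  LEU = list(list("CG",  c("N", "CA", "CB"), 1.530, 116.3, 180),
             list("CD1", c("CA", "CB", "CG"), 1.521, 110.7, 180),
             list("CD2", c("CA", "CB", "CG"), 1.521, 110.7, 60)),
  VAL = list(list("CG1", c("N", "CA", "CB"), 1.521, 110.5, 180),
             list("CG2", c("N", "CA", "CB"), 1.521, 110.5, -60)),
  ASP = list(list("CG",  c("N", "CA", "CB"), 1.516, 112.6, 180),
             list("OD1", c("CA", "CB", "CG"), 1.249, 118.5, 0),
             list("OD2", c("CA", "CB", "CG"), 1.249, 118.5, 180)),
  GLU = list(list("CG",  c("N", "CA", "CB"), 1.520, 112.6, 180),
             list("CD",  c("CA", "CB", "CG"), 1.516, 112.6, 180),
             list("OE1", c("CB", "CG", "CD"), 1.249, 118.5, 0),
             list("OE2", c("CB", "CG", "CD"), 1.249, 118.5, 180)),
  ASN = list(list("CG",  c("N", "CA", "CB"), 1.516, 112.6, 180),
             list("OD1", c("CA", "CB", "CG"), 1.231, 120.8, 0),
             list("ND2", c("CA", "CB", "CG"), 1.328, 116.4, 180)),
  GLN = list(list("CG",  c("N", "CA", "CB"), 1.520, 112.6, 180),
             list("CD",  c("CA", "CB", "CG"), 1.516, 112.6, 180),
             list("OE1", c("CB", "CG", "CD"), 1.231, 120.8, 0),
             list("NE2", c("CB", "CG", "CD"), 1.328, 116.4, 180)),
  LYS = list(list("CG",  c("N", "CA", "CB"), 1.520, 111.3, 180),
             list("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 180),
             list("CE",  c("CB", "CG", "CD"), 1.520, 111.3, 180),
             list("NZ",  c("CG", "CD", "CE"), 1.489, 111.9, 180)),
  ARG = list(list("CG",  c("N", "CA", "CB"), 1.520, 112.6, 180),
             list("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 180),
             list("NE",  c("CB", "CG", "CD"), 1.461, 112.0, 180),
             list("CZ",  c("CG", "CD", "NE"), 1.330, 124.2, 180),
             list("NH1", c("CD", "NE", "CZ"), 1.326, 120.0, 0),
             list("NH2", c("CD", "NE", "CZ"), 1.326, 120.0, 180)),
  HIS = list(list("CG",  c("N", "CA", "CB"), 1.497, 113.8, 180))
)

SYNTH_RESIDUES <- names(SIDECHAIN_ZMAT)

#' Build a single idealized residue
#'
#' Constructs one residue with standard internal geometry (extended side
#' chain) in a local frame with N at the origin. Used as the building block
#' of the synthetic fixtures.
#'
#' @param resid 3-letter residue code (one of
#'   ALA, GLY, SER, THR, LEU, VAL, ASP, GLU, ASN, GLN, LYS, ARG, HIS).
#' @param resno Residue number to assign.
#' @param chain Chain identifier.
#' @return An atom tibble.
#' @export
make_residue <- function(resid, resno = 1L, chain = "A") {
  resid <- toupper(resid)
  if (!resid %in% SYNTH_RESIDUES) {
    stop("no idealized template for residue '", resid, "'", call. = FALSE)
  }
  pos <- list(
    N = c(0, 0, 0),
    CA = c(1.458, 0, 0)
  )
  ang <- 111.2 * pi / 180
  pos$C <- pos$CA + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  pos$O <- place_atom(pos$N, pos$CA, pos$C, 1.231, 120.5, -60)
  if (resid != "GLY") {
    pos$CB <- place_atom(pos$C, pos$N, pos$CA, 1.530, 110.5, 122.5)
  }
  for (step in SIDECHAIN_ZMAT[[resid]]) {
    refs <- step[[2]]
    pos[[step[[1]]]] <- place_atom(pos[[refs[1]]], pos[[refs[2]]], pos[[refs[3]]],
                                   step[[3]], step[[4]], step[[5]])
  }
  if (resid == "HIS") pos <- c(pos, his_ring(pos))
  nm <- names(pos)
  xyz <- do.call(rbind, pos)
  tibble::tibble(
    chain = chain, resno = as.integer(resno), icode = "", resid = resid,
    elety = nm, element = pdb_element(nm),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, altloc = ""
  )
}

# Imidazole ring as an exact planar regular pentagon (side 1.37 A) attached
# at CG, in the plane defined by CA-CB-CG.
his_ring <- function(pos) {
  side <- 1.37
  r <- side / (2 * sin(pi / 5))
  u <- unit(pos$CG - pos$CB)
  nrm <- unit(cross3(pos$CG - pos$CB, pos$CB - pos$CA))
  m <- cross3(nrm, u)
  center <- pos$CG + r * u
  vertex <- function(theta_deg) {
    th <- theta_deg * pi / 180
    center + r * (cos(th) * (-u) + sin(th) * m)
  }
  list(ND1 = vertex(72), CE1 = vertex(144), NE2 = vertex(-144), CD2 = vertex(-72))
}

# Rotation matrix taking unit vector a onto unit vector b (Rodrigues).
rotation_align <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b)
  s <- vec_norm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 degrees about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unit(cross3(a, p))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

structure_xyz <- function(structure) as.matrix(structure[, c("x", "y", "z")])

min_charged_distance <- function(acid_res, base_res, criteria = salt_bridge_criteria()) {
  ao <- acid_res[acid_res$elety %in% charged_atoms(acid_res$resid[1], criteria), ]
  bn <- base_res[base_res$elety %in% charged_atoms(base_res$resid[1],
                                                   salt_bridge_criteria(include_his = TRUE)), ]
  min(cross_dist(structure_xyz(ao), structure_xyz(bn)))
}

#' Synthetic two-residue ion pair with a designed separation
#'
#' Builds an acidic and a basic residue, oriented side chain to side chain,
#' and rigidly positions the basic residue so that the minimum distance
#' between charged carboxylate oxygens and charged nitrogens equals
#' `separation` to within 0.01 Angstrom. The manifest records whether the
#' pair should be detected under the default 4.0 Angstrom criterion.
#'
#' @param separation Designed minimum charged O to N distance, Angstrom
#'   (> 2.0).
#' @param acidic `"ASP"` or `"GLU"`.
#' @param basic `"LYS"`, `"ARG"` or `"HIS"`.
#' @param resno Length-2 integer vector of residue numbers.
#' @param chain Chain identifier.
#' @return A list with `structure` (atom tibble) and `manifest` (tibble with
#'   columns `kind`, `resno_a`, `resno_b`, `designed_distance`,
#'   `expect_detected`).
#' @export
make_ion_pair <- function(separation, acidic = "GLU", basic = "LYS",
                          resno = c(1L, 2L), chain = "A") {
  acidic <- toupper(acidic); basic <- toupper(basic)
  stopifnot(acidic %in% ACIDIC_RESIDUES, basic %in% BASIC_RESIDUES)
  if (separation <= 2.0) {
    stop("separation must exceed 2.0 Angstrom", call. = FALSE)
  }
  a <- make_residue(acidic, resno[1], chain)
  b <- make_residue(basic, resno[2], chain)

  his_crit <- salt_bridge_criteria(include_his = TRUE)
  a_charged <- a[a$elety %in% charged_atoms(acidic, his_crit), ]
  b_charged <- b[b$elety %in% charged_atoms(basic, his_crit), ]
  o_ref <- as.numeric(a_charged[1, c("x", "y", "z")])
  u <- unit(o_ref - colMeans(structure_xyz(a)))

  # orient the basic residue so its body points away from the acidic one
  n_ref <- as.numeric(b_charged[1, c("x", "y", "z")])
  body <- colMeans(structure_xyz(b)) - n_ref
  rot <- rotation_align(body, u)
  b <- transform_structure(b, rot, -as.numeric(rot %*% n_ref))

  # slide along u until the minimum charged O...N distance hits the target
  slide <- function(t) {
    bt <- transform_structure(b, diag(3), o_ref + t * u)
    min_charged_distance(a, bt) - separation
  }
  root <- stats::uniroot(slide, c(0, separation + 10), tol = 1e-6,
                         extendInt = "upX")
  b <- transform_structure(b, diag(3), o_ref + root$root * u)

  structure <- dplyr::arrange(dplyr::bind_rows(a, b), .data$resno)
  defaults <- salt_bridge_criteria()
  manifest <- tibble::tibble(
    kind = "saltbridge",
    resno_a = as.integer(resno[1]), resno_b = as.integer(resno[2]),
    designed_distance = separation,
    expect_detected = separation <= defaults$max_no_distance
  )
  list(structure = structure, manifest = manifest)
}

#' Ideal poly-alanine alpha-helix with a backbone hydrogen-bond manifest
#'
#' Builds an `n_residues`-long poly-alanine chain on ideal alpha-helical
#' dihedrals (phi = -57, psi = -47, omega = 180 degrees) with standard
#' backbone bond geometry. The manifest lists the i -> i-4 backbone
#' amide-to-carbonyl hydrogen bonds, one for each i in `5:n_residues`.
#'
#' @param n_residues Number of residues (>= 5).
#' @param chain Chain identifier.
#' @return A list with `structure` and `manifest` (columns `kind`,
#'   `donor_resno`, `acceptor_resno`).
#' @export
make_helix <- function(n_residues, chain = "A") {
  if (n_residues < 5) {
    stop("a helix fixture needs at least 5 residues", call. = FALSE)
  }
  phi <- -57; psi <- -47; omega <- 180
  n_pos <- ca_pos <- c_pos <- vector("list", n_residues)
  n_pos[[1]] <- c(0, 0, 0)
  ca_pos[[1]] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  c_pos[[1]] <- ca_pos[[1]] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in 2:n_residues) {
    n_pos[[i]] <- place_atom(n_pos[[i - 1]], ca_pos[[i - 1]], c_pos[[i - 1]],
                             1.329, 116.2, psi)
    ca_pos[[i]] <- place_atom(ca_pos[[i - 1]], c_pos[[i - 1]], n_pos[[i]],
                              1.458, 121.7, omega)
    c_pos[[i]] <- place_atom(c_pos[[i - 1]], n_pos[[i]], ca_pos[[i]],
                             1.525, 111.2, phi)
  }
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    o <- place_atom(n_pos[[i]], ca_pos[[i]], c_pos[[i]], 1.231, 120.5, psi + 180)
    cb <- place_atom(c_pos[[i]], n_pos[[i]], ca_pos[[i]], 1.530, 110.5, 122.5)
    xyz <- rbind(n_pos[[i]], ca_pos[[i]], c_pos[[i]], o, cb)
    nm <- c("N", "CA", "C", "O", "CB")
    rows[[i]] <- tibble::tibble(
      chain = chain, resno = i, icode = "", resid = "ALA",
      elety = nm, element = pdb_element(nm),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, altloc = ""
    )
  }
  manifest <- tibble::tibble(
    kind = "hbond",
    donor_resno = 5:n_residues,
    acceptor_resno = 1:(n_residues - 4)
  )
  list(structure = dplyr::bind_rows(rows), manifest = manifest)
}

#' Random synthetic chain for detector stress tests
#'
#' Places `n_residues` idealized residues (drawn from the synthetic residue
#' set) at uniform random positions and orientations inside a cubic box.
#' Residues are numbered consecutively but are not peptide-linked in space,
#' which makes the chain a dense, unstructured field of donors, acceptors
#' and charged groups — ideal for comparing the detectors against a
#' brute-force oracle.
#'
#' @param n_residues Number of residues.
#' @param box Edge length of the placement box, Angstrom.
#' @param residues Residue alphabet to sample from.
#' @param chain Chain identifier.
#' @param seed Optional integer seed (uses the current RNG stream if NULL).
#' @return An atom tibble.
#' @export
make_random_chain <- function(n_residues, box = 18,
                              residues = c("ASP", "GLU", "LYS", "ARG", "HIS",
                                           "SER", "ASN", "ALA", "GLY"),
                              chain = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  picks <- sample(residues, n_residues, replace = TRUE)
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    r <- make_residue(picks[i], i, chain)
    rot <- random_rotation()
    shift <- stats::runif(3, 0, box)
    rows[[i]] <- transform_structure(r, rot, shift)
  }
  dplyr::bind_rows(rows)
}

#' Synthetic ortholog trio with a known conservation partition
#'
#' Builds three single-chain "species" structures with identical residue
#' numbering: `shared` salt bridges planted identically in all three, plus
#' species-specific ("private") bridges planted at residue positions unique
#' to each species (the other species carry alanines at those positions).
#' Planted separations sit inside the default 4.0 Angstrom criterion with a
#' 0.2 Angstrom guard band. Sites are laid out on a wide lattice so planted
#' pairs cannot interact across sites.
#'
#' @param shared Number of bridges conserved across all three species.
#' @param private Integer vector of length 3: species-specific bridge counts.
#' @param species Character vector of three species labels.
#' @param separation_range Range the planted O...N separations are drawn
#'   from, Angstrom; must stay at least 0.2 below the default cutoff.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A list with `structures` (named list of atom tibbles), `pairs`
#'   (tibble of planted pairs: `species`, `pair`, plus residue detail), and
#'   `truth` (tibble `pair`, `status`, `species` giving the expected
#'   conservation partition).
#' @export
make_ortholog_trio <- function(shared = 2, private = c(1, 1, 1),
                               species = c("sp_a", "sp_b", "sp_c"),
                               separation_range = c(3.0, 3.6), seed = 1L) {
  stopifnot(length(private) == 3, length(species) == 3,
            all(private >= 0), shared >= 0)
  defaults <- salt_bridge_criteria()
  if (max(separation_range) > defaults$max_no_distance - GUARD_BAND) {
    stop("separation_range must respect the 0.2 Angstrom guard band below ",
         "the default cutoff", call. = FALSE)
  }
  set.seed(seed)
  n_sites <- shared + sum(private)
  if (n_sites == 0L) {
    base <- dplyr::bind_rows(
      make_residue("ALA", 1L),
      transform_structure(make_residue("ALA", 2L), diag(3), c(20, 0, 0))
    )
    structures <- stats::setNames(rep(list(base), 3), species)
    empty <- tibble::tibble(pair = character(), status = character(),
                            species = character())
    return(list(structures = structures,
                pairs = tibble::tibble(species = character(), pair = character()),
                truth = empty))
  }
  combos <- list(c("GLU", "LYS"), c("ASP", "ARG"), c("GLU", "ARG"),
                 c("ASP", "LYS"), c("ASP", "HIS"), c("GLU", "HIS"))
  site_pos <- site_lattice(n_sites, spacing = 25)
  seps <- stats::runif(n_sites, separation_range[1], separation_range[2])
  kinds <- combos[sample.int(length(combos), n_sites, replace = TRUE)]

  site_info <- tibble::tibble(
    site = seq_len(n_sites),
    owner = c(rep(NA_character_, shared), rep(species, times = private)),
    resno_a = 2L * seq_len(n_sites) - 1L,
    resno_b = 2L * seq_len(n_sites),
    separation = seps
  )

  structures <- lapply(species, function(sp) {
    rows <- vector("list", n_sites)
    for (k in seq_len(n_sites)) {
      owns <- is.na(site_info$owner[k]) || site_info$owner[k] == sp
      if (owns) {
        fx <- make_ion_pair(site_info$separation[k], kinds[[k]][1], kinds[[k]][2],
                            resno = c(site_info$resno_a[k], site_info$resno_b[k]))
        rows[[k]] <- transform_structure(fx$structure, diag(3), site_pos[k, ])
      } else {
        a1 <- transform_structure(make_residue("ALA", site_info$resno_a[k]),
                                  diag(3), site_pos[k, ])
        a2 <- transform_structure(make_residue("ALA", site_info$resno_b[k]),
                                  diag(3), site_pos[k, ] + c(8, 0, 0))
        rows[[k]] <- dplyr::bind_rows(a1, a2)
      }
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$resno)
  })
  names(structures) <- species

  pairs <- purrr::pmap_dfr(site_info, function(site, owner, resno_a, resno_b, separation) {
    sp <- if (is.na(owner)) species else owner
    tibble::tibble(
      species = sp,
      acidic_resid = kinds[[site]][1], acidic_resno = resno_a,
      basic_resid = kinds[[site]][2], basic_resno = resno_b,
      pair = pair_label_text(kinds[[site]][1], resno_a, kinds[[site]][2], resno_b)
    )
  })
  truth <- site_info |>
    dplyr::mutate(
      pair = purrr::map_chr(.data$site, function(k) {
        pair_label_text(kinds[[k]][1], site_info$resno_a[k],
                        kinds[[k]][2], site_info$resno_b[k])
      }),
      status = ifelse(is.na(.data$owner), "conserved", "unique"),
      species = ifelse(is.na(.data$owner), paste(species, collapse = ";"), .data$owner)
    ) |>
    dplyr::select("pair", "status", "species")

  list(structures = structures, pairs = pairs, truth = truth)
}

site_lattice <- function(n, spacing = 25) {
  k <- ceiling(n^(1 / 3))
  grid <- expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1))
  as.matrix(grid[seq_len(n), , drop = FALSE]) * spacing
}

#' Add isotropic Gaussian coordinate noise
#'
#' @param structure An atom tibble.
#' @param sigma Noise scale per coordinate, Angstrom (>= 0).
#' @param seed Optional integer seed.
#' @return The perturbed atom tibble.
#' @export
perturb_structure <- function(structure, sigma, seed = NULL) {
  check_structure(structure)
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(structure)
  n <- nrow(structure)
  structure$x <- structure$x + stats::rnorm(n, 0, sigma)
  structure$y <- structure$y + stats::rnorm(n, 0, sigma)
  structure$z <- structure$z + stats::rnorm(n, 0, sigma)
  structure
}
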