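# Independent brute-force oracles: exhaustive all-pairs scans written with
# plain loops and their own geometry helpers, kept deliberately separate
# from the package's detection path.

.o_dist <- function(p, q) sqrt(sum((p - q)^2))

.o_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.o_xyz <- function(df, i) c(df$x[i], df$y[i], df$z[i])

# Exhaustive residue-pair / atom-pair scan for salt bridges.
oracle_salt_bridges <- function(atoms, cutoff = 4.0, include_his = TRUE) {
  acid_map <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  base_map <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (include_his) base_map$HIS <- c("ND1", "NE2")
  res_keys <- unique(paste(atoms$resno, atoms$icode))
  out <- list()
  for (ka in res_keys) {
    ra <- atoms[paste(atoms$resno, atoms$icode) == ka, ]
    aa <- acid_map[[ra$resid[1]]]
    if (is.null(aa)) next
    ai <- which(ra$elety %in% aa)
    if (length(ai) == 0) next
    for (kb in res_keys) {
      rb <- atoms[paste(atoms$resno, atoms$icode) == kb, ]
      bb <- base_map[[rb$resid[1]]]
      if (is.null(bb)) next
      bi <- which(rb$elety %in% bb)
      if (length(bi) == 0) next
      best <- Inf
      for (i in ai) for (j in bi) {
        d <- .o_dist(.o_xyz(ra, i), .o_xyz(rb, j))
        if (d < best) best <- d
      }
      if (best <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          acidic_resno = ra$resno[1], acidic_icode = ra$icode[1],
          basic_resno = rb$resno[1], basic_icode = rb$icode[1],
          min_distance = best
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(acidic_resno = integer(), acidic_icode = character(),
                      basic_resno = integer(), basic_icode = character(),
                      min_distance = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$acidic_resno, out$acidic_icode, out$basic_resno, out$basic_icode), ]
}

# Covalent adjacency for the oracle: its own loop-based construction from
# the residue topology tables (those tables are chemistry definitions).
.o_adjacency <- function(atoms) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  link <- function(i, j) {
    adj[[i]] <<- union(adj[[i]], j)
    adj[[j]] <<- union(adj[[j]], i)
  }
  keys <- paste(atoms$resno, atoms$icode)
  res_keys <- unique(keys)
  backbone <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                   c("CA", "CB"))
  prev_c <- NA
  for (k in res_keys) {
    ix <- which(keys == k)
    resid <- atoms$resid[ix[1]]
    find <- function(nm) {
      j <- ix[atoms$elety[ix] == nm]
      if (length(j) == 0) NA else j[1]
    }
    for (b in c(backbone, icebonds:::SIDECHAIN_BONDS[[resid]])) {
      i1 <- find(b[1]); i2 <- find(b[2])
      if (!is.na(i1) && !is.na(i2)) link(i1, i2)
    }
    ni <- find("N")
    if (!is.na(prev_c) && !is.na(ni) &&
        .o_dist(.o_xyz(atoms, prev_c), .o_xyz(atoms, ni)) <= 1.8) {
      link(prev_c, ni)
    }
    prev_c <- find("C")
    for (hi in ix[atoms$element[ix] == "H"]) {
      heavy <- ix[atoms$element[ix] != "H"]
      dd <- sapply(heavy, function(j) .o_dist(.o_xyz(atoms, hi), .o_xyz(atoms, j)))
      j <- heavy[which.min(dd)]
      if (min(dd) <= 1.3) link(hi, j)
    }
  }
  adj
}

# Exhaustive donor x acceptor scan for hydrogen bonds. Takes the
# hydrogen-augmented structure and the donor-status table from
# infer_polar_hydrogens() and re-derives everything else with loops.
oracle_hbonds <- function(aug, donors, criteria = icebonds::hbond_criteria()) {
  keys <- paste(aug$resno, aug$icode)
  adj <- .o_adjacency(aug)
  find_atom <- function(resno, icode, nm) {
    j <- which(aug$resno == resno & aug$icode == icode & aug$elety == nm)
    if (length(j) == 0) NA else j[1]
  }
  # acceptors: backbone O/OXT plus side-chain carbonyl/carboxylate/hydroxyl O
  acc <- list()
  for (k in unique(keys)) {
    ix <- which(keys == k)
    resid <- aug$resid[ix[1]]
    side <- icebonds:::ACCEPTOR_ATOMS[[resid]]
    cand <- c(list(O = "C", OXT = "C"), side)
    for (nm in names(cand)) {
      j <- ix[aug$elety[ix] == nm]
      if (length(j) == 0) next
      antj <- ix[aug$elety[ix] == cand[[nm]]]
      acc[[length(acc) + 1]] <- list(idx = j[1],
                                     ant = if (length(antj) == 0) NA else antj[1])
    }
  }
  out <- list()
  for (d in seq_len(nrow(donors))) {
    di <- find_atom(donors$resno[d], donors$icode[d], donors$atom[d])
    if (is.na(di)) next
    dpos <- .o_xyz(aug, di)
    # hydrogens on this donor: H atoms of the residue within 1.15 A
    hs <- which(aug$resno == donors$resno[d] & aug$icode == donors$icode[d] &
                  aug$element == "H")
    if (length(hs) > 0) {
      hs <- hs[vapply(hs, function(h) .o_dist(.o_xyz(aug, h), dpos) <= 1.15,
                      logical(1))]
    }
    for (a in acc) {
      ai <- a$idx
      if (aug$resno[ai] == donors$resno[d] && aug$icode[ai] == donors$icode[d]) next
      if (ai %in% adj[[di]]) next
      if (length(intersect(adj[[di]], adj[[ai]])) > 0) next
      apos <- .o_xyz(aug, ai)
      d_da <- .o_dist(dpos, apos)
      if (d_da > criteria$max_da) next
      if (donors$status[d] %in% c("explicit", "placed") && length(hs) > 0) {
        hit <- FALSE
        for (h in hs) {
          hpos <- .o_xyz(aug, h)
          if (.o_dist(hpos, apos) <= criteria$max_ha &&
              .o_angle(dpos, hpos, apos) >= criteria$min_dha_angle) hit <- TRUE
        }
        if (!hit) next
      } else {
        if (d_da > criteria$heavy_only_max_da) next
        if (is.na(a$ant)) next
        if (.o_angle(dpos, apos, .o_xyz(aug, a$ant)) < criteria$min_daa_angle) next
      }
      out[[length(out) + 1]] <- data.frame(
        donor_resno = donors$resno[d], donor_icode = donors$icode[d],
        donor_atom = donors$atom[d],
        acceptor_resno = aug$resno[ai], acceptor_icode = aug$icode[ai],
        acceptor_atom = aug$elety[ai], d_da = d_da
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_resno = integer(), donor_icode = character(),
                      donor_atom = character(), acceptor_resno = integer(),
                      acceptor_icode = character(), acceptor_atom = character(),
                      d_da = numeric()))
  }
  out <- do.call(rbind, out)
  out[order(out$donor_resno, out$donor_icode, out$donor_atom,
            out$acceptor_resno, out$acceptor_icode, out$acceptor_atom), ]
}

# Affine-gap global alignment score by Gotoh dynamic programming
# (gap of length L costs open + L * extend, end gaps penalized).
gotoh_score <- function(a, b, open = 10, extend = 0.5, mat) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * extend)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + extend),
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + extend),
                              Iy[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Set-equality helper for detector-vs-oracle comparisons.
expect_same_interaction_set <- function(got, want, keys, dist_col = NULL,
                                        tol = 1e-9) {
  got <- as.data.frame(got)[, c(keys, dist_col), drop = FALSE]
  want <- as.data.frame(want)[, c(keys, dist_col), drop = FALSE]
  ord <- function(df) df[do.call(order, df[keys]), , drop = FALSE]
  got <- ord(got); want <- ord(want)
  rownames(got) <- rownames(want) <- NULL
  expect_equal(nrow(got), nrow(want))
  for (k in keys) expect_identical(as.vector(got[[k]]), as.vector(want[[k]]))
  if (!is.null(dist_col) && nrow(got) > 0) {
    expect_true(max(abs(got[[dist_col]] - want[[dist_col]])) < tol)
  }
}
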