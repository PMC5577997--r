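test_that("charged atom sets follow side-chain chemistry", {
  expect_setequal(charged_atoms("GLU"), c("OE1", "OE2"))
  expect_setequal(charged_atoms("ASP"), c("OD1", "OD2"))
  expect_equal(charged_atoms("LYS"), "NZ")
  expect_setequal(charged_atoms("ARG"), c("NE", "NH1", "NH2"))
  expect_setequal(charged_atoms("HIS"), c("ND1", "NE2"))
  expect_equal(charged_atoms("HIS", salt_bridge_criteria(include_his = FALSE)),
               character(0))
  expect_equal(charged_atoms("ALA"), character(0))
  # missing side-chain atoms are silently omitted
  expect_equal(charged_atoms("GLU", atoms_present = c("N", "CA", "OE1")), "OE1")
})

test_that("salt bridges are found below the cutoff and not above", {
  fx <- make_ion_pair(3.5, "GLU", "LYS")
  sb <- detect_salt_bridges(fx$structure)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_distance, 3.5, tolerance = 0.01)
  expect_equal(sb$pair, "Glu1||Lys2")

  far <- make_ion_pair(5.0, "GLU", "LYS")
  expect_equal(nrow(detect_salt_bridges(far$structure)), 0L)

  his <- make_ion_pair(3.5, "ASP", "HIS")
  expect_equal(nrow(detect_salt_bridges(his$structure)), 1L)
  expect_equal(nrow(detect_salt_bridges(
    his$structure, salt_bridge_criteria(include_his = FALSE))), 0L)
})

test_that("one record per residue pair regardless of qualifying atom pairs", {
  fx <- make_ion_pair(2.8, "ASP", "ARG")  # several O...N contacts qualify
  sb <- detect_salt_bridges(fx$structure)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$min_distance, 2.8, tolerance = 0.01)
})

test_that("detectors agree with the brute-force oracle on random chains", {
  set.seed(101)
  for (k in 1:15) {
    ch <- make_random_chain(sample(8:14, 1), box = 18)
    sb <- detect_salt_bridges(ch)
    expect_same_interaction_set(
      sb, oracle_salt_bridges(ch),
      keys = c("acidic_resno", "basic_resno"), dist_col = "min_distance"
    )
    aug <- infer_polar_hydrogens(ch)
    hb <- detect_hbonds(ch)
    expect_same_interaction_set(
      hb, oracle_hbonds(aug$structure, aug$donors),
      keys = c("donor_resno", "donor_atom", "acceptor_resno", "acceptor_atom"),
      dist_col = "d_da"
    )
  }
})

test_that("detection is invariant under rigid motion", {
  set.seed(202)
  ch <- make_random_chain(12, box = 16)
  rot <- icebonds:::random_rotation()
  moved <- icebonds:::transform_structure(ch, rot, c(11.3, -40.2, 7.7))
  sb0 <- detect_salt_bridges(ch); sb1 <- detect_salt_bridges(moved)
  expect_identical(sb0$pair, sb1$pair)
  expect_lt(max(abs(sb0$min_distance - sb1$min_distance), 0), 1e-6)
  hb0 <- detect_hbonds(ch); hb1 <- detect_hbonds(moved)
  expect_identical(hb0[c("donor_resno", "donor_atom", "acceptor_resno",
                         "acceptor_atom")],
                   hb1[c("donor_resno", "donor_atom", "acceptor_resno",
                         "acceptor_atom")])
  expect_lt(max(abs(hb0$d_da - hb1$d_da), 0), 1e-6)
})

test_that("bridge sets grow monotonically with the cutoff", {
  set.seed(303)
  ch <- make_random_chain(14, box = 15)
  cuts <- c(3.0, 3.5, 4.0, 4.5, 5.0)
  sets <- lapply(cuts, function(cc) {
    detect_salt_bridges(ch, salt_bridge_criteria(max_no_distance = cc))$pair
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  expect_true(all(diff(lengths(sets)) >= 0))
})

test_that("detection does not depend on atom row order and is deterministic", {
  set.seed(404)
  ch <- make_random_chain(12, box = 15)
  shuffled <- ch[sample(nrow(ch)), ]
  expect_identical(detect_salt_bridges(ch), detect_salt_bridges(shuffled))
  expect_identical(detect_hbonds(ch), detect_hbonds(ch))
  hb_shuffled <- detect_hbonds(shuffled)
  expect_identical(detect_hbonds(ch), hb_shuffled)
})

test_that("polar hydrogen inference places and flags donors as specified", {
  hx <- make_helix(8)$structure
  res <- infer_polar_hydrogens(hx)
  d <- res$donors
  expect_equal(d$status[d$resno == 1 & d$atom == "N"], "ambiguous")
  expect_true(all(d$status[d$resno > 1 & d$atom == "N"] == "placed"))
  # placed amide H sits 1.0 A from N
  h <- res$structure
  for (i in 2:8) {
    nh <- as.numeric(h[h$resno == i & h$elety == "H", c("x", "y", "z")])
    nn <- as.numeric(h[h$resno == i & h$elety == "N", c("x", "y", "z")])
    expect_equal(sqrt(sum((nh - nn)^2)), 1.0, tolerance = 0.01)
  }
  ser <- make_residue("SER", 1)
  dd <- infer_polar_hydrogens(ser)$donors
  expect_equal(dd$status[dd$atom == "OG"], "ambiguous")
  expect_false("HG" %in% infer_polar_hydrogens(ser)$structure$elety)
})

test_that("an ideal linear D-H...A geometry is a bond, a distant one is not", {
  two_res <- function(da_dist) {
    tibble::tibble(
      chain = "A",
      resno = c(1L, 1L, 1L, 10L, 10L),
      icode = "",
      resid = c("ALA", "ALA", "ALA", "ALA", "ALA"),
      elety = c("N", "CA", "H", "O", "C"),
      element = c("N", "C", "H", "O", "C"),
      x = c(0, -1.0, 1.0, da_dist, da_dist + 0.6),
      y = c(0, 1.0, 0, 0, 1.1),
      z = 0,
      occ = 1, altloc = ""
    )
  }
  hb <- detect_hbonds(two_res(2.9))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$d_da, 2.9)
  expect_equal(hb$angle_dha, 180, tolerance = 1e-6)
  expect_equal(hb$path, "hydrogen")
  expect_equal(nrow(detect_hbonds(two_res(4.5))), 0L)
})

test_that("helix backbone ladder matches its manifest and the oracle", {
  hx <- make_helix(12)
  hb <- detect_hbonds(hx$structure)
  expect_equal(nrow(hb), nrow(hx$manifest))
  expect_identical(hb$donor_resno, hx$manifest$donor_resno)
  expect_identical(hb$acceptor_resno, hx$manifest$acceptor_resno)
  expect_true(all(hb$donor_atom == "N" & hb$acceptor_atom == "O"))
  aug <- infer_polar_hydrogens(hx$structure)
  expect_same_interaction_set(
    hb, oracle_hbonds(aug$structure, aug$donors),
    keys = c("donor_resno", "donor_atom", "acceptor_resno", "acceptor_atom"),
    dist_col = "d_da"
  )
})

test_that("per-chain counts equal detector set sizes", {
  hx <- make_helix(9)$structure
  counts <- count_interactions(hx)
  expect_equal(counts$hbonds, nrow(detect_hbonds(hx)))
  expect_equal(counts$saltbridges, 0L)  # poly-alanine has no charged residues

  trio3 <- dplyr::bind_rows(
    make_ion_pair(3.2, "GLU", "LYS", resno = c(1L, 2L))$structure,
    icebonds:::transform_structure(
      make_ion_pair(3.4, "ASP", "ARG", resno = c(3L, 4L))$structure,
      diag(3), c(30, 0, 0)),
    icebonds:::transform_structure(
      make_ion_pair(3.6, "GLU", "HIS", resno = c(5L, 6L))$structure,
      diag(3), c(0, 30, 0))
  )
  expect_equal(count_interactions(trio3)$saltbridges, 3L)
})

test_that("empty or chargeless chains yield empty results, not errors", {
  ala <- make_residue("ALA", 1)
  expect_equal(nrow(detect_salt_bridges(ala)), 0L)
  expect_equal(nrow(detect_hbonds(ala)), 0L)
})
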