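test_that("run_detect summarises structure files and writes provenance", {
  dir <- tempfile()
  dir.create(dir)
  helix <- file.path(dir, "helix.pdb")
  write_structure(make_helix(12)$structure, helix)
  ion <- file.path(dir, "ion.pdb")
  write_structure(make_ion_pair(3.5)$structure, ion)

  out_dir <- file.path(dir, "out")
  res <- run_detect(c(helix, ion), output_dir = out_dir)
  expect_equal(res$counts$hbonds[res$counts$file == helix], 8L)
  expect_equal(res$counts$saltbridges[res$counts$file == ion], 1L)
  expect_true(file.exists(file.path(out_dir, "interaction_counts.tsv")))
  json <- jsonlite::read_json(file.path(out_dir, "detect_summary.json"))
  expect_equal(json$criteria$salt_bridge_criteria$max_no_distance, 4.0)

  expect_error(run_detect(file.path(dir, "missing.pdb")), "does not exist")
  expect_error(run_detect(character()), "no input")
})

test_that("run_compare reproduces totals, conservation and ranking from tables", {
  counts <- system.file("extdata", "subunit_interaction_counts.tsv",
                        package = "icebonds")
  pairs <- system.file("extdata", "salt_bridge_pairs.tsv",
                       package = "icebonds")
  out_dir <- tempfile()
  res <- run_compare(counts = counts, pairs = pairs, output_dir = out_dir)

  expect_equal(sort(res$profiles$hbonds), c(483L, 486L, 503L))
  expect_equal(sort(res$profiles$saltbridges), c(20L, 22L, 25L))
  expect_equal(res$ranking$species,
               c("T. bernacchii", "C. hamatus", "D. labrax"))
  cc <- res$conservation_counts
  expect_equal(cc$conserved[cc$chain == "beta1"], 5L)
  expect_equal(cc$conserved[cc$chain == "beta2"], 5L)
  expect_equal(cc$conserved[cc$chain == "beta5"], 3L)
  hb_diff <- dplyr::filter(res$diffs, .data$interaction == "hbonds",
                           .data$species_a == "C. hamatus",
                           .data$species_b == "D. labrax")
  expect_equal(hb_diff$absolute_difference, 3L)
  expect_equal(hb_diff$percent_of_larger, 0.6)
  expect_true(file.exists(file.path(out_dir, "compare_report.json")))

  single <- tibble::tibble(species = "x", chain = "beta1",
                           hbonds = 1L, saltbridges = 1L)
  expect_error(run_compare(counts = single), "at least two species")
  expect_error(run_compare(), "supply")
})

test_that("run_compare reports a synthetic trio consistently with its truth", {
  trio <- make_ortholog_trio(shared = 3, private = c(1, 2, 0), seed = 21)
  part <- crosslink_with_detection(trio$structures)
  expect_equal(glance(part)$conserved, 3L)
  expect_equal(sum(part$status == "unique"), 3L)
  expect_setequal(part$pair, trio$truth$pair)
})

test_that("run_seqcomp produces identity matrices and substitution lists", {
  res <- run_seqcomp(c(a = "ACDE", b = "ACDE"))
  expect_equal(res$identity$percent_identity, 100)
  expect_equal(nrow(res$substitutions), 0L)

  res2 <- run_seqcomp(c(a = "ACDE", b = "ACDQ"))
  expect_equal(res2$identity$percent_identity, 75)
  expect_equal(nrow(res2$substitutions), 1L)

  f <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE", ">s2", "ACDQ", ">s3", "ACDE"), f)
  res3 <- run_seqcomp(f)
  expect_equal(nrow(res3$identity), 3L)  # all unordered pairs

  expect_error(run_seqcomp(c(a = "ACDE")), "at least two")
})

test_that("the fixture suite writer materializes structures and manifests", {
  dir <- tempfile()
  write_fixture_suite(dir, seed = 2)
  expect_true(file.exists(file.path(dir, "helix_12.pdb")))
  expect_true(file.exists(file.path(dir, "trio_truth.json")))
  reread <- read_structure(file.path(dir, "ion_pair_3.5A.pdb"))
  expect_equal(nrow(detect_salt_bridges(reread)), 1L)
})

test_that("plot helpers return ggplot objects", {
  counts <- read_count_table(system.file("extdata",
                                         "subunit_interaction_counts.tsv",
                                         package = "icebonds"))
  expect_s3_class(plot_interaction_counts(counts), "ggplot")
  profiles <- species_profiles(counts)
  expect_s3_class(autoplot(profiles), "ggplot")
  pairs <- read_pair_table(system.file("extdata", "salt_bridge_pairs.tsv",
                                       package = "icebonds"))
  part <- conserved_partition(dplyr::filter(pairs, .data$chain == "beta5"))
  expect_s3_class(autoplot(part), "ggplot")
})
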