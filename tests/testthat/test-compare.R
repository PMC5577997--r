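counts_file <- system.file("extdata", "subunit_interaction_counts.tsv",
                           package = "icebonds")
pairs_file <- system.file("extdata", "salt_bridge_pairs.tsv",
                          package = "icebonds")

test_that("pair labels parse, canonicalize and round-trip", {
  p <- parse_pair_label("Glu184||Arg211")
  expect_equal(p$acidic_name, "GLU")
  expect_equal(p$acidic_number, 184L)
  expect_equal(p$basic_name, "ARG")
  expect_equal(p$basic_number, 211L)
  expect_equal(p$pair, "Glu184||Arg211")

  # whitespace and case are tolerated
  q <- parse_pair_label("ASP 52||HIS 99")
  expect_equal(q$pair, "Asp52||His99")

  # basic-first labels are swapped into canonical order, with a message
  expect_message(sw <- parse_pair_label("Arg211||Glu184"), "swapped")
  expect_equal(sw$pair, "Glu184||Arg211")

  expect_identical(parse_pair_label(sw$pair)$pair, sw$pair)

  expect_error(parse_pair_label("Glu184-Arg211"), "malformed")
  expect_error(parse_pair_label("Glu1||Glu2"), "acidic")
  expect_error(parse_pair_label("Lys1||Arg2"), "acidic")
  expect_error(parse_pair_label("Ala1||Lys2"), "neither")
})

test_that("the transcribed pair table yields the published per-set sizes", {
  pairs <- read_pair_table(pairs_file)
  sizes <- dplyr::count(pairs, .data$species, .data$chain)
  get <- function(sp, ch) sizes$n[sizes$species == sp & sizes$chain == ch]
  expect_equal(get("C. hamatus", "beta1"), 7L)
  expect_equal(get("D. labrax", "beta1"), 6L)
  expect_equal(get("T. bernacchii", "beta1"), 9L)
  expect_equal(get("C. hamatus", "beta2"), 10L)
  expect_equal(get("D. labrax", "beta2"), 9L)
  expect_equal(get("T. bernacchii", "beta2"), 10L)
  expect_equal(get("C. hamatus", "beta5"), 5L)
  expect_equal(get("D. labrax", "beta5"), 5L)
  expect_equal(get("T. bernacchii", "beta5"), 6L)
  # pair-set sizes equal the declared per-chain salt-bridge counts
  counts <- read_count_table(counts_file)
  joined <- dplyr::left_join(sizes, counts, by = c("species", "chain"))
  expect_identical(joined$n, joined$saltbridges)
})

test_that("degenerate and duplicated pair tables are handled", {
  empty <- tempfile(fileext = ".tsv")
  writeLines("species\tchain\tpair_label", empty)
  expect_equal(nrow(read_pair_table(empty)), 0L)

  dashes <- tempfile(fileext = ".tsv")
  writeLines(c("species\tchain\tpair_label", "x\tbeta1\t-", "x\tbeta1\t"),
             dashes)
  expect_equal(nrow(read_pair_table(dashes)), 0L)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("species\tchain\tpair_label",
               "x\tbeta1\tGlu1||Lys2", "x\tbeta1\tGlu1||Lys2"), dup)
  expect_error(read_pair_table(dup), "Glu1||Lys2", fixed = TRUE)
})

test_that("species profiles sum per-chain counts into totals", {
  profiles <- species_profiles(read_count_table(counts_file))
  expect_equal(profiles$hbonds[profiles$species == "C. hamatus"], 483L)
  expect_equal(profiles$saltbridges[profiles$species == "C. hamatus"], 22L)

  zero <- tibble::tibble(species = "z", chain = c("a", "b"),
                         hbonds = 0L, saltbridges = 0L)
  expect_equal(species_profiles(zero)$hbonds, 0L)

  dup <- tibble::tibble(species = "z", chain = c("a", "a"),
                        hbonds = 1L, saltbridges = 1L)
  expect_error(species_profiles(dup), "duplicated")
  neg <- tibble::tibble(species = "z", chain = "a",
                        hbonds = -1L, saltbridges = 0L)
  expect_error(species_profiles(neg), "negative")
})

test_that("difference statistics are symmetric and round half-up", {
  expect_equal(diff_stats(483, 486),
               tibble::tibble(absolute_difference = 3L,
                              percent_of_larger = 0.6))
  expect_identical(diff_stats(486, 483), diff_stats(483, 486))
  expect_equal(diff_stats(100, 100)$percent_of_larger, 0)
  expect_equal(diff_stats(503, 486)$absolute_difference, 17L)
  expect_equal(diff_stats(503, 486)$percent_of_larger, 3.4)
  # half-up at the boundary: 0.25 -> 0.3, where round() would give 0.2
  expect_equal(diff_stats(4000, 3990)$percent_of_larger, 0.3)
  expect_equal(diff_stats(0, 0)$percent_of_larger, 0)
})

test_that("conserved partitions classify pairs by species membership", {
  pairs <- tibble::tibble(
    species = c("a", "b", "c", "a", "b", "a"),
    pair = c("Glu1||Lys2", "Glu1||Lys2", "Glu1||Lys2",
             "Asp3||Arg4", "Asp3||Arg4", "Glu5||His6")
  )
  part <- conserved_partition(pairs)
  expect_equal(part$status[part$pair == "Glu1||Lys2"], "conserved")
  expect_equal(part$status[part$pair == "Asp3||Arg4"], "shared_partial")
  expect_equal(part$status[part$pair == "Glu5||His6"], "unique")
  expect_equal(glance(part)$conserved, 1L)

  ident <- tibble::tibble(species = rep(c("a", "b", "c"), each = 2),
                          pair = rep(c("Glu1||Lys2", "Asp3||Arg4"), 3))
  pi <- conserved_partition(ident)
  expect_true(all(pi$status == "conserved"))

  mixed <- dplyr::mutate(pairs, chain = c("b1", "b1", "b2", "b1", "b1", "b1"))
  expect_error(conserved_partition(mixed), "one chain at a time")
})

test_that("partition completeness holds on random pair sets", {
  set.seed(88)
  for (k in 1:25) {
    species <- paste0("s", 1:3)
    pool <- pair_label_text(sample(c("ASP", "GLU"), 12, TRUE), 1:12,
                            sample(c("LYS", "ARG", "HIS"), 12, TRUE), 101:112)
    pairs <- purrr::map_dfr(species, function(sp) {
      tibble::tibble(species = sp,
                     pair = sample(pool, sample(0:12, 1)))
    })
    if (nrow(pairs) == 0) next
    part <- conserved_partition(pairs, species = species)
    # each species' set is exactly recovered from the partition rows
    for (sp in species) {
      member <- part$pair[vapply(strsplit(part$species, ";"),
                                 function(x) sp %in% x, logical(1))]
      expect_setequal(member, pairs$pair[pairs$species == sp])
    }
    expect_equal(sum(part$n_species), nrow(pairs))
    expect_true(all(part$status %in% c("conserved", "shared_partial", "unique")))
  }
})

test_that("stability ranking orders species by totals with flagged ties", {
  profiles <- tibble::tibble(
    species = c("C. hamatus", "D. labrax", "T. bernacchii"),
    hbonds = c(483L, 486L, 503L),
    saltbridges = c(22L, 20L, 25L)
  )
  r <- rank_stability(profiles, "saltbridges")
  expect_equal(r$species, c("T. bernacchii", "C. hamatus", "D. labrax"))
  expect_false(any(r$tied))
  # invariant under input permutation
  expect_identical(rank_stability(profiles[c(3, 1, 2), ], "saltbridges"), r)

  single <- rank_stability(profiles[1, ], "hbonds")
  expect_equal(single$species, "C. hamatus")

  tied <- tibble::tibble(species = c("b", "a"), saltbridges = c(5L, 5L))
  rt <- rank_stability(tied, "saltbridges")
  expect_equal(rt$species, c("a", "b"))  # alphabetical on ties
  expect_true(all(rt$tied))
})

test_that("tidiers expose partitions and profiles as plain tibbles", {
  profiles <- species_profiles(read_count_table(counts_file))
  expect_s3_class(glance(profiles), "tbl_df")
  expect_equal(nrow(tidy(profiles)), 9L)
  pairs <- read_pair_table(pairs_file)
  part <- conserved_partition(dplyr::filter(pairs, .data$chain == "beta1"))
  expect_false(inherits(tidy(part), "conservation_partition"))
  expect_equal(glance(part)$n_species, 3L)
  u <- unique_pair_counts(part)
  expect_setequal(u$species, c("C. hamatus", "D. labrax", "T. bernacchii"))
})
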