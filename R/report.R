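# Pipeline front-ends: the functions behind the command-line script in
# inst/cli/icebonds.R. Each one runs the corresponding analysis over files,
# optionally writes TSV/JSON outputs, and echoes the exact criteria used so
# results carry their provenance.

criteria_provenance <- function(hbond = NULL, salt_bridge = NULL) {
  out <- list()
  if (!is.null(hbond)) out$hbond_criteria <- unclass(hbond)
  if (!is.null(salt_bridge)) out$salt_bridge_criteria <- unclass(salt_bridge)
  out
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Detect interactions in structure files
#'
#' Reads one or more PDB files, runs both detectors on every chain, and
#' (optionally) writes one interaction TSV per input plus a JSON summary
#' that echoes the criteria used.
#'
#' @param paths Character vector of PDB file paths.
#' @param hbond An [hbond_criteria()] object.
#' @param salt_bridge A [salt_bridge_criteria()] object.
#' @param output_dir Directory for TSV/JSON outputs, or `NULL` to skip
#'   writing.
#' @return A list with `counts` (tibble: `file`, `chain`, `hbonds`,
#'   `saltbridges`), `hbonds` and `salt_bridges` (per-interaction tibbles
#'   with a `file` column), and `criteria`.
#' @export
run_detect <- function(paths, hbond = hbond_criteria(),
                       salt_bridge = salt_bridge_criteria(),
                       output_dir = NULL) {
  if (length(paths) < 1L) stop("no input structures", call. = FALSE)
  per_file <- purrr::map(paths, function(p) {
    s <- read_structure(p)
    list(
      hb = dplyr::mutate(detect_hbonds(s, hbond), file = p, .before = 1),
      sb = dplyr::mutate(detect_salt_bridges(s, salt_bridge), file = p, .before = 1),
      counts = dplyr::mutate(count_interactions(s, hbond, salt_bridge),
                             file = p, .before = 1)
    )
  })
  out <- list(
    counts = purrr::map_dfr(per_file, "counts"),
    hbonds = purrr::map_dfr(per_file, "hb"),
    salt_bridges = purrr::map_dfr(per_file, "sb"),
    criteria = criteria_provenance(hbond, salt_bridge)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$counts, file.path(output_dir, "interaction_counts.tsv"))
    readr::write_tsv(out$hbonds, file.path(output_dir, "hbonds.tsv"))
    readr::write_tsv(out$salt_bridges, file.path(output_dir, "salt_bridges.tsv"))
    write_report_json(
      c(list(counts = out$counts), out["criteria"]),
      file.path(output_dir, "detect_summary.json")
    )
  }
  out
}

#' Cross-species comparison report
#'
#' Builds the full comparison from either a per-chain count table, a
#' salt-bridge pair table, or both: species totals, pairwise difference
#' statistics, per-chain conservation partitions, and the stability
#' ranking.
#'
#' @param counts Optional tibble of per-chain counts (`species`, `chain`,
#'   `hbonds`, `saltbridges`) or path to such a TSV.
#' @param pairs Optional tibble of pair labels (`species`, `chain`, `pair`)
#'   or path to a TSV with columns `species`, `chain`, `pair_label`.
#' @param ranking_key Interaction type used for the stability ranking.
#' @param output_dir Directory for outputs, or `NULL` to skip writing.
#' @return A list with `profiles`, `diffs` (pairwise difference statistics
#'   by interaction type), `partitions` (named list of
#'   `conservation_partition` objects, one per chain), `conservation_counts`
#'   (tibble by chain), and `ranking`.
#' @export
run_compare <- function(counts = NULL, pairs = NULL,
                        ranking_key = c("saltbridges", "hbonds"),
                        output_dir = NULL) {
  ranking_key <- match.arg(ranking_key)
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(pairs)) pairs <- read_pair_table(pairs)
  if (is.null(counts) && is.null(pairs)) {
    stop("supply `counts`, `pairs`, or both", call. = FALSE)
  }
  out <- list()
  if (!is.null(counts)) {
    if (dplyr::n_distinct(counts$species) < 2L) {
      stop("comparison needs at least two species; run_detect() handles the ",
           "single-structure case", call. = FALSE)
    }
    profiles <- species_profiles(counts)
    out$profiles <- profiles
    combos <- utils::combn(profiles$species, 2, simplify = FALSE)
    out$diffs <- purrr::map_dfr(combos, function(pr) {
      i <- match(pr, profiles$species)
      dplyr::bind_rows(
        dplyr::mutate(diff_stats(profiles$hbonds[i[1]], profiles$hbonds[i[2]]),
                      interaction = "hbonds", .before = 1),
        dplyr::mutate(diff_stats(profiles$saltbridges[i[1]],
                                 profiles$saltbridges[i[2]]),
                      interaction = "saltbridges", .before = 1)
      ) |>
        dplyr::mutate(species_a = pr[1], species_b = pr[2], .before = 1)
    })
    out$ranking <- rank_stability(profiles, ranking_key)
  }
  if (!is.null(pairs)) {
    chains <- sort(unique(pairs$chain))
    out$partitions <- purrr::map(chains, function(ch) {
      conserved_partition(dplyr::filter(pairs, .data$chain == ch))
    })
    names(out$partitions) <- chains
    out$conservation_counts <- purrr::imap_dfr(out$partitions, function(p, ch) {
      dplyr::mutate(glance(p), chain = ch, .before = 1)
    })
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$profiles)) {
      readr::write_tsv(tibble::as_tibble(out$profiles),
                       file.path(output_dir, "species_totals.tsv"))
      readr::write_tsv(out$diffs, file.path(output_dir, "diff_stats.tsv"))
      readr::write_tsv(out$ranking, file.path(output_dir, "stability_ranking.tsv"))
    }
    if (!is.null(out$partitions)) {
      partition_tbl <- purrr::imap_dfr(out$partitions, function(p, ch) {
        dplyr::mutate(tidy(p), chain = ch, .before = 1)
      })
      readr::write_tsv(partition_tbl, file.path(output_dir, "conservation.tsv"))
    }
    json <- list(
      profiles = if (!is.null(out$profiles)) tibble::as_tibble(out$profiles),
      diffs = out$diffs,
      conservation_counts = out$conservation_counts,
      ranking = out$ranking,
      ranking_key = ranking_key
    )
    write_report_json(json[!vapply(json, is.null, logical(1))],
                      file.path(output_dir, "compare_report.json"))
  }
  out
}

#' Pairwise sequence comparison report
#'
#' All-against-all global alignment of a set of protein sequences:
#' pairwise percent-identity matrix plus a substitution report (with
#' conservation classes and polarity-change flags) for every pair.
#'
#' @param sequences A named character vector of sequences, a tibble with
#'   columns `header`/`sequence`, or a path to a FASTA file.
#' @param denominator Identity denominator, see [percent_identity()].
#' @param output_dir Directory for outputs, or `NULL` to skip writing.
#' @return A list with `identity` (tibble `seq_a`, `seq_b`,
#'   `percent_identity`), `substitutions` (tibble of per-pair substitution
#'   records), and `summaries` (per-pair glance rows).
#' @export
run_seqcomp <- function(sequences, denominator = "alignment_length",
                        output_dir = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  if (is.data.frame(sequences)) {
    seqs <- stats::setNames(sequences$sequence, sequences$header)
  } else {
    seqs <- sequences
  }
  if (length(seqs) < 2L) {
    stop("sequence comparison needs at least two sequences", call. = FALSE)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  combos <- utils::combn(names(seqs), 2, simplify = FALSE)
  per_pair <- purrr::map(combos, function(pr) {
    aln <- align_global(seqs[[pr[1]]], seqs[[pr[2]]])
    rep <- substitution_report(aln)
    list(
      identity = tibble::tibble(
        seq_a = pr[1], seq_b = pr[2],
        percent_identity = percent_identity(aln, denominator)
      ),
      records = dplyr::mutate(tidy(rep), seq_a = pr[1], seq_b = pr[2],
                              .before = 1),
      summary = dplyr::mutate(glance(rep), seq_a = pr[1], seq_b = pr[2],
                              .before = 1)
    )
  })
  out <- list(
    identity = purrr::map_dfr(per_pair, "identity"),
    substitutions = purrr::map_dfr(per_pair, "records"),
    summaries = purrr::map_dfr(per_pair, "summary")
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$identity, file.path(output_dir, "identity.tsv"))
    readr::write_tsv(out$substitutions, file.path(output_dir, "substitutions.tsv"))
    write_report_json(out["summaries"], file.path(output_dir, "seqcomp_summary.json"))
  }
  out
}

#' Write the synthetic fixture suite to a directory
#'
#' Materializes a standard set of synthetic fixtures (ion pairs around the
#' salt-bridge cutoff, an alpha-helix, and an ortholog trio) as PDB files
#' with JSON manifests, for use outside R.
#'
#' @param output_dir Output directory.
#' @param seed Integer seed for the ortholog trio.
#' @return The output directory, invisibly.
#' @export
write_fixture_suite <- function(output_dir, seed = 1L) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seps <- c(3.0, 3.5, 4.5, 5.0)
  for (s in seps) {
    fx <- make_ion_pair(s)
    stem <- file.path(output_dir, sprintf("ion_pair_%.1fA", s))
    write_structure(fx$structure, paste0(stem, ".pdb"))
    write_report_json(fx$manifest, paste0(stem, ".json"))
  }
  hx <- make_helix(12)
  write_structure(hx$structure, file.path(output_dir, "helix_12.pdb"))
  write_report_json(hx$manifest, file.path(output_dir, "helix_12.json"))
  trio <- make_ortholog_trio(seed = seed)
  for (sp in names(trio$structures)) {
    write_structure(trio$structures[[sp]],
                    file.path(output_dir, paste0("trio_", sp, ".pdb")))
  }
  write_report_json(trio$truth, file.path(output_dir, "trio_truth.json"))
  invisible(output_dir)
}
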