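#' Canonical salt-bridge pair label
#'
#' Formats residue pairs in the `"Xxx<N>||Yyy<M>"` notation used for
#' cross-species comparison, acidic residue first, title-case names.
#'
#' @param acidic_resid,basic_resid 3-letter residue codes.
#' @param acidic_resno,basic_resno Residue numbers.
#' @return Character vector of labels like `"Glu184||Arg211"`.
#' @export
pair_label_text <- function(acidic_resid, acidic_resno, basic_resid, basic_resno) {
  paste0(stringr::str_to_title(acidic_resid), acidic_resno, "||",
         stringr::str_to_title(basic_resid), basic_resno)
}

#' Parse salt-bridge pair labels
#'
#' Parses labels of the form `"Glu184||Arg211"` (case-insensitive, internal
#' spaces tolerated, e.g. `"ASP 52||HIS 99"`) into their components and
#' canonicalizes them acidic-residue-first. Labels written basic-first are
#' swapped, with a message. A label whose two residues are both acidic or
#' both basic is a chemistry error.
#'
#' @param text Character vector of pair labels.
#' @return A tibble with columns `acidic_name`, `acidic_number`,
#'   `basic_name`, `basic_number` and the canonical `pair` text.
#' @examples
#' parse_pair_label(c("Glu184||Arg211", "ASP 52||HIS 99"))
#' @export
parse_pair_label <- function(text) {
  m <- stringr::str_match(
    stringr::str_trim(text),
    "^([A-Za-z]{3})\\s*(\\d+)\\s*\\|\\|\\s*([A-Za-z]{3})\\s*(\\d+)$"
  )
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0L) {
    stop("malformed pair label: '", text[bad[1]], "'", call. = FALSE)
  }
  name1 <- toupper(m[, 2]); num1 <- as.integer(m[, 3])
  name2 <- toupper(m[, 4]); num2 <- as.integer(m[, 5])
  ok1 <- name1 %in% c(ACIDIC_RESIDUES, BASIC_RESIDUES)
  ok2 <- name2 %in% c(ACIDIC_RESIDUES, BASIC_RESIDUES)
  if (any(!ok1 | !ok2)) {
    i <- which(!ok1 | !ok2)[1]
    stop("residue in '", text[i], "' is neither acidic (Asp/Glu) nor basic ",
         "(Lys/Arg/His)", call. = FALSE)
  }
  both_acid <- name1 %in% ACIDIC_RESIDUES & name2 %in% ACIDIC_RESIDUES
  both_base <- name1 %in% BASIC_RESIDUES & name2 %in% BASIC_RESIDUES
  if (any(both_acid | both_base)) {
    i <- which(both_acid | both_base)[1]
    stop("'", text[i], "' does not pair an acidic with a basic residue",
         call. = FALSE)
  }
  swap <- name1 %in% BASIC_RESIDUES
  if (any(swap)) {
    message(sum(swap), " pair label(s) were written basic-first; swapped to ",
            "canonical acidic-first order")
  }
  out <- tibble::tibble(
    acidic_name = ifelse(swap, name2, name1),
    acidic_number = ifelse(swap, num2, num1),
    basic_name = ifelse(swap, name1, name2),
    basic_number = ifelse(swap, num1, num2)
  )
  out$pair <- pair_label_text(out$acidic_name, out$acidic_number,
                              out$basic_name, out$basic_number)
  out
}

#' Read a salt-bridge pair table
#'
#' Reads a TSV with columns `species`, `chain` and `pair_label` into a tidy
#' pair table, one row per (species, chain, pair). Cells that are empty or
#' `"-"` are skipped. Labels are canonicalized with [parse_pair_label()];
#' a pair duplicated within one (species, chain) is an error.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with columns `species`, `chain`, `pair` and the parsed
#'   label components.
#' @export
read_pair_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0L) {
    return(tibble::tibble(species = character(), chain = character(),
                          pair = character()))
  }
  needed <- c("species", "chain", "pair_label")
  if (!all(needed %in% names(raw))) {
    stop("pair table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  raw <- dplyr::filter(raw, !is.na(.data$pair_label),
                       stringr::str_trim(.data$pair_label) != "",
                       stringr::str_trim(.data$pair_label) != "-")
  if (nrow(raw) == 0L) {
    return(tibble::tibble(species = character(), chain = character(),
                          pair = character()))
  }
  parsed <- parse_pair_label(raw$pair_label)
  out <- dplyr::bind_cols(dplyr::select(raw, "species", "chain"), parsed)
  dup <- out |>
    dplyr::count(.data$species, .data$chain, .data$pair) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0L) {
    stop("duplicated pair within a (species, chain): ", dup$pair[1],
         " [", dup$species[1], ", ", dup$chain[1], "]", call. = FALSE)
  }
  out
}

#' Read a per-chain interaction count table
#'
#' Reads a TSV with columns `species`, `chain`, `hbonds`, `saltbridges`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of per-chain counts.
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    chain = readr::col_character(),
    hbonds = readr::col_integer(),
    saltbridges = readr::col_integer()
  ))
}

#' Species-level interaction-count profiles
#'
#' Sums per-chain hydrogen-bond and salt-bridge counts into species totals.
#'
#' @param counts A tibble with columns `species`, `chain`, `hbonds`,
#'   `saltbridges` (one row per species-chain).
#' @return A tibble of class `icebonds_profiles` with one row per species:
#'   `species`, `n_chains`, `hbonds`, `saltbridges` (totals). The per-chain
#'   input is attached as attribute `"per_chain"`.
#' @examples
#' counts <- tibble::tibble(
#'   species = "sp_a", chain = c("beta1", "beta2", "beta5"),
#'   hbonds = c(10L, 12L, 9L), saltbridges = c(2L, 1L, 3L)
#' )
#' species_profiles(counts)
#' @export
species_profiles <- function(counts) {
  needed <- c("species", "chain", "hbonds", "saltbridges")
  if (!all(needed %in% names(counts))) {
    stop("counts must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$hbonds < 0 | counts$saltbridges < 0)) {
    stop("negative interaction counts", call. = FALSE)
  }
  dup <- dplyr::count(counts, .data$species, .data$chain) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0L) {
    stop("duplicated (species, chain) in counts: ", dup$species[1], "/",
         dup$chain[1], call. = FALSE)
  }
  out <- counts |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_chains = dplyr::n(),
      hbonds = sum(.data$hbonds),
      saltbridges = sum(.data$saltbridges),
      .groups = "drop"
    )
  attr(out, "per_chain") <- counts
  class(out) <- c("icebonds_profiles", class(out))
  out
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Difference statistics between two interaction totals
#'
#' Absolute difference and its size as a percentage of the larger total,
#' rounded half-up to one decimal. Symmetric in its arguments.
#'
#' @param total_a,total_b Non-negative interaction totals.
#' @return A tibble with `absolute_difference` and `percent_of_larger`.
#' @examples
#' diff_stats(483, 486)  # 3 bonds, 0.6 percent
#' @export
diff_stats <- function(total_a, total_b) {
  stopifnot(length(total_a) == 1, length(total_b) == 1,
            total_a >= 0, total_b >= 0)
  d <- abs(total_a - total_b)
  pct <- if (max(total_a, total_b) == 0) 0 else 100 * d / max(total_a, total_b)
  tibble::tibble(
    absolute_difference = as.integer(d),
    percent_of_larger = round_half_up(pct, 1)
  )
}

#' Partition salt-bridge pairs into conserved and species-specific sets
#'
#' Matches pair labels across species by exact label equality (residue name
#' plus number) and classifies every distinct pair as `"conserved"`
#' (present in every species), `"unique"` (present in exactly one) or
#' `"shared_partial"` (present in at least two but not all). The three
#' classes form a disjoint partition of each species' pair set, which is
#' checked on every call.
#'
#' @param pairs A tibble with columns `species` and `pair` (and optionally a
#'   single-valued `chain` column); one row per species-pair.
#' @param species Optional character vector fixing the species universe;
#'   defaults to the species present in `pairs`.
#' @return A tibble of class `conservation_partition`, one row per distinct
#'   pair: `pair`, `n_species`, `species` (semicolon-collapsed) and
#'   `status`.
#' @export
conserved_partition <- function(pairs, species = NULL) {
  if (!all(c("species", "pair") %in% names(pairs))) {
    stop("pairs must have columns `species` and `pair`", call. = FALSE)
  }
  if ("chain" %in% names(pairs) && dplyr::n_distinct(pairs$chain) > 1) {
    stop("pairs spans several chains; partition one chain at a time ",
         "(e.g. split by chain first)", call. = FALSE)
  }
  if (is.null(species)) species <- unique(pairs$species)
  extra <- setdiff(unique(pairs$species), species)
  if (length(extra) > 0L) {
    stop("pairs contains species outside the stated universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  n_total <- length(species)
  dup <- dplyr::count(pairs, .data$species, .data$pair) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0L) {
    stop("duplicated pair within a species: ", dup$pair[1], call. = FALSE)
  }
  out <- pairs |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      species = paste(sort(unique(.data$species)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$n_species == n_total ~ "conserved",
      .data$n_species == 1 ~ "unique",
      TRUE ~ "shared_partial"
    )) |>
    dplyr::arrange(dplyr::desc(.data$n_species), .data$pair)
  # partition completeness: every input (species, pair) lands in exactly
  # one class, and classes are disjoint by construction over distinct pairs
  stopifnot(sum(out$n_species) == nrow(pairs))
  attr(out, "species_universe") <- species
  class(out) <- c("conservation_partition", class(out))
  out
}

#' Rank species by an interaction-count stability proxy
#'
#' Orders species by descending total count of the chosen interaction type.
#' A larger count of stabilizing intrachain interactions is read as a proxy
#' for higher structural stability. Ties are broken by ascending species
#' label and flagged.
#'
#' @param profiles A tibble with columns `species` and the chosen `key`
#'   column (e.g. from [species_profiles()]).
#' @param key `"saltbridges"` or `"hbonds"`.
#' @return A tibble with `rank`, `species`, `total` and `tied`, ordered from
#'   most to least stabilized. Invariant under input row order.
#' @export
rank_stability <- function(profiles, key = c("saltbridges", "hbonds")) {
  key <- match.arg(key)
  if (!all(c("species", key) %in% names(profiles))) {
    stop("profiles must have columns `species` and `", key, "`", call. = FALSE)
  }
  if (nrow(profiles) == 0L) stop("no profiles to rank", call. = FALSE)
  out <- tibble::tibble(species = profiles$species,
                        total = profiles[[key]]) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$species) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      tied = duplicated(.data$total) | duplicated(.data$total, fromLast = TRUE)
    ) |>
    dplyr::select("rank", "species", "total", "tied")
  attr(out, "key") <- key
  out
}

#' End-to-end conservation partition from coordinates
#'
#' Runs [detect_salt_bridges()] on one chain per species, converts the
#' detected bridges to canonical pair labels, and partitions them across
#' species with [conserved_partition()]. Cross-species matching is by exact
#' residue name and number, which presumes a common numbering across the
#' orthologs (equal-length orthologs, or models numbered alike).
#'
#' @param structures Named list of atom tibbles, one per species (names are
#'   the species labels).
#' @param criteria A [salt_bridge_criteria()] object.
#' @return A `conservation_partition` tibble (see [conserved_partition()]).
#' @export
crosslink_with_detection <- function(structures, criteria = salt_bridge_criteria()) {
  if (is.null(names(structures)) || any(names(structures) == "")) {
    stop("structures must be a named list (names = species labels)",
         call. = FALSE)
  }
  pairs <- purrr::imap_dfr(structures, function(s, sp) {
    sb <- detect_salt_bridges(s, criteria)
    if (nrow(sb) == 0L) return(tibble::tibble(species = character(), pair = character()))
    tibble::tibble(species = sp, pair = sb$pair)
  })
  conserved_partition(pairs, species = names(structures))
}
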