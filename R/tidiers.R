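#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conservation partition
#'
#' @param x A `conservation_partition` from [conserved_partition()].
#' @param ... Unused.
#' @return A plain tibble, one row per distinct pair.
#' @export
tidy.conservation_partition <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "conservation_partition")
  attr(out, "species_universe") <- NULL
  out
}

#' Summarise a conservation partition
#'
#' @param x A `conservation_partition`.
#' @param ... Unused.
#' @return A one-row tibble: number of species, distinct pairs, and counts
#'   of conserved / shared-partial / unique pairs.
#' @export
glance.conservation_partition <- function(x, ...) {
  tibble::tibble(
    n_species = length(attr(x, "species_universe")),
    n_pairs = nrow(x),
    conserved = sum(x$status == "conserved"),
    shared_partial = sum(x$status == "shared_partial"),
    unique = sum(x$status == "unique")
  )
}

#' Per-species unique-pair counts of a conservation partition
#'
#' @param partition A `conservation_partition`.
#' @return A tibble `species`, `unique_pairs`, covering every species in
#'   the partition's universe (zero counts included).
#' @export
unique_pair_counts <- function(partition) {
  universe <- attr(partition, "species_universe")
  uniq <- partition[partition$status == "unique", , drop = FALSE]
  tibble::tibble(
    species = universe,
    unique_pairs = vapply(universe, function(sp) sum(uniq$species == sp),
                          integer(1), USE.NAMES = FALSE)
  )
}

#' Tidy species profiles
#'
#' @param x An `icebonds_profiles` object from [species_profiles()].
#' @param ... Unused.
#' @return The per-chain counts the profiles were built from.
#' @export
tidy.icebonds_profiles <- function(x, ...) {
  attr(x, "per_chain")
}

#' Summarise species profiles
#'
#' @param x An `icebonds_profiles` object.
#' @param ... Unused.
#' @return A one-row tibble with the species count and grand totals.
#' @export
glance.icebonds_profiles <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x),
    hbonds_grand_total = sum(x$hbonds),
    saltbridges_grand_total = sum(x$saltbridges)
  )
}

#' Tidy a pairwise alignment into per-column records
#'
#' @param x A `pairwise_alignment` from [align_global()].
#' @param ... Unused.
#' @return A tibble with `column` (0-based), `residue_a`, `residue_b`.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  alignment_columns(x)
}

#' Summarise a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A one-row tibble with score, lengths and percent identity.
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    alignment_length = nchar(x$aligned_a),
    length_a = nchar(x$seq_a),
    length_b = nchar(x$seq_b),
    percent_identity = percent_identity(x)
  )
}

#' Tidy a substitution report
#'
#' @param x A `substitution_report` from [substitution_report()].
#' @param ... Unused.
#' @return A plain tibble of substitution records.
#' @export
tidy.substitution_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "substitution_report")
  attr(out, "summary") <- NULL
  out
}

#' Summarise a substitution report
#'
#' @param x A `substitution_report`.
#' @param ... Unused.
#' @return A one-row tibble with identity, per-class substitution counts,
#'   polarity changes and gap columns.
#' @export
glance.substitution_report <- function(x, ...) {
  attr(x, "summary")
}
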