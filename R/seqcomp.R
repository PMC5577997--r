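# Pairwise ortholog sequence comparison: global alignment, percent
# identity, and per-substitution conservation class / polarity-change
# annotation.

AA_ALPHABET <- unname(AA_321)

# Clustal-style similarity groups: substitutions within a "strong" group
# are conservative, within a "weak" group (only) semi-conservative.
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF",
                   "HY", "FYW")
WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SDEQK",
                 "NDEQHK", "NEQHRK", "FVLIM", "HFY")

# Three-class polarity scheme used for polarity-change flags.
POLARITY_CLASS <- c(
  A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
  M = "nonpolar", F = "nonpolar", W = "nonpolar", P = "nonpolar",
  G = "nonpolar",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
  Q = "polar",
  D = "charged", E = "charged", K = "charged", R = "charged", H = "charged"
)

check_protein_string <- function(seq, arg = "sequence") {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop(arg, " must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-standard character '", chars[bad[1]], "' at position ", bad[1],
         " of ", arg, call. = FALSE)
  }
  invisible(seq)
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with the BLOSUM62 substitution matrix
#' and affine gap penalties (defaults: open 10, extend 0.5). At the
#' 91-99 percent identity typical of close orthologs the alignment is
#' insensitive to these choices; they are exposed for completeness.
#'
#' @param seq_a,seq_b Uppercase one-letter protein sequences (non-empty,
#'   standard 20-letter alphabet).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param substitution_matrix Name of the substitution matrix
#'   (a matrix shipped with Biostrings, e.g. `"BLOSUM62"`).
#' @return An object of class `pairwise_alignment`: a list with `seq_a`,
#'   `seq_b`, equal-length gapped strings `aligned_a` / `aligned_b`, and
#'   the alignment `score`.
#' @examples
#' align_global("ACDE", "ACE")
#' @export
align_global <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                         substitution_matrix = "BLOSUM62") {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  check_protein_string(seq_a, "seq_a")
  check_protein_string(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  out <- list(
    seq_a = seq_a,
    seq_b = seq_b,
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
  stopifnot(gsub("-", "", out$aligned_a) == seq_a,
            gsub("-", "", out$aligned_b) == seq_b)
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global pairwise alignment (score ", format(x$score), ")\n", sep = "")
  cat("  a: ", x$aligned_a, "\n  b: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

alignment_columns <- function(aln) {
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  tibble::tibble(column = seq_along(a) - 1L, residue_a = a, residue_b = b)
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment` from [align_global()].
#' @param denominator Divide the identical-column count by the full
#'   alignment length (default) or by the shorter sequence length.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln, denominator = c("alignment_length", "shorter_seq")) {
  denominator <- match.arg(denominator)
  cols <- alignment_columns(aln)
  if (nrow(cols) == 0L) stop("zero-length alignment", call. = FALSE)
  ident <- sum(cols$residue_a == cols$residue_b & cols$residue_a != "-")
  denom <- switch(denominator,
    alignment_length = nrow(cols),
    shorter_seq = min(nchar(aln$seq_a), nchar(aln$seq_b))
  )
  100 * ident / denom
}

#' Classify an amino-acid substitution
#'
#' Conservation class follows the Clustal similarity-group convention:
#' `conservative` when both residues share a strong group,
#' `semi_conservative` when they share only a weak group, otherwise
#' `non_conservative`; equal residues are `identical`. The
#' `polarity_change` flag is set when the two residues fall into different
#' classes of the three-way polarity scheme nonpolar (A V L I M F W P G) /
#' polar uncharged (S T C Y N Q) / charged (D E K R H).
#'
#' @param residue_a,residue_b One-letter residue codes (vectorized; equal
#'   length or length one). Gap characters are an error: gaps are reported
#'   separately by [substitution_report()], not classified.
#' @return A tibble with columns `residue_a`, `residue_b`, `klass` and
#'   `polarity_change`.
#' @examples
#' classify_substitution("K", "R")
#' classify_substitution("S", "A")
#' @export
classify_substitution <- function(residue_a, residue_b) {
  n <- max(length(residue_a), length(residue_b))
  residue_a <- rep_len(toupper(residue_a), n)
  residue_b <- rep_len(toupper(residue_b), n)
  bad <- which(!(residue_a %in% AA_ALPHABET) | !(residue_b %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    stop("cannot classify '", residue_a[bad[1]], "'/'", residue_b[bad[1]],
         "': not standard residues (gaps are reported separately)",
         call. = FALSE)
  }
  share_group <- function(groups) {
    vapply(seq_len(n), function(i) {
      any(vapply(groups, function(g) {
        grepl(residue_a[i], g, fixed = TRUE) && grepl(residue_b[i], g, fixed = TRUE)
      }, logical(1)))
    }, logical(1))
  }
  strong <- share_group(STRONG_GROUPS)
  weak <- share_group(WEAK_GROUPS)
  klass <- dplyr::case_when(
    residue_a == residue_b ~ "identical",
    strong ~ "conservative",
    weak ~ "semi_conservative",
    TRUE ~ "non_conservative"
  )
  tibble::tibble(
    residue_a = residue_a,
    residue_b = residue_b,
    klass = klass,
    polarity_change = unname(klass != "identical" &
      POLARITY_CLASS[residue_a] != POLARITY_CLASS[residue_b])
  )
}

#' Per-column substitution report for a pairwise alignment
#'
#' One record per aligned column whose residues differ and are both
#' non-gap, annotated with the conservation class and polarity-change flag
#' of [classify_substitution()]. Gap columns are excluded from the records
#' and counted in the summary.
#'
#' @param aln A `pairwise_alignment` from [align_global()].
#' @return A tibble of class `substitution_report` with columns `column`
#'   (0-based aligned column), `residue_a`, `residue_b`, `klass`,
#'   `polarity_change`. Summary counts (identical, per-class substitution
#'   counts, polarity changes, gap columns) are available via
#'   [glance.substitution_report()].
#' @export
substitution_report <- function(aln) {
  cols <- alignment_columns(aln)
  is_gap <- cols$residue_a == "-" | cols$residue_b == "-"
  subs <- cols[!is_gap & cols$residue_a != cols$residue_b, , drop = FALSE]
  if (nrow(subs) > 0L) {
    cls <- classify_substitution(subs$residue_a, subs$residue_b)
    records <- dplyr::bind_cols(subs["column"], cls)
  } else {
    records <- tibble::tibble(
      column = integer(), residue_a = character(), residue_b = character(),
      klass = character(), polarity_change = logical()
    )
  }
  summary <- tibble::tibble(
    alignment_length = nrow(cols),
    identical = sum(!is_gap & cols$residue_a == cols$residue_b),
    conservative = sum(records$klass == "conservative"),
    semi_conservative = sum(records$klass == "semi_conservative"),
    non_conservative = sum(records$klass == "non_conservative"),
    polarity_changes = sum(records$polarity_change),
    gap_columns = sum(is_gap),
    percent_identity = percent_identity(aln)
  )
  attr(records, "summary") <- summary
  class(records) <- c("substitution_report", class(records))
  records
}
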