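#' Hydrogen-bond geometric criteria
#'
#' Distance and angle thresholds for hydrogen-bond detection. The defaults
#' follow the widely used HBplus-style geometry: a donor-acceptor distance of
#' at most 3.9 Angstrom, hydrogen-acceptor distance of at most 2.5 Angstrom,
#' and donor-hydrogen-acceptor angle of at least 90 degrees. When no hydrogen
#' is present or inferable on a donor (rotatable hydroxyls, lysine ammonium,
#' chain-initial amides), a stricter heavy-atom-only distance cutoff applies
#' together with a donor-acceptor-antecedent angle test.
#'
#' @param max_da Maximum donor-acceptor heavy-atom distance, Angstrom.
#' @param max_ha Maximum hydrogen-acceptor distance, Angstrom.
#' @param min_dha_angle Minimum donor-hydrogen-acceptor angle, degrees.
#' @param min_daa_angle Minimum donor-acceptor-antecedent angle, degrees
#'   (used on the heavy-atom-only path).
#' @param heavy_only_max_da Maximum donor-acceptor distance when no hydrogen
#'   is available, Angstrom.
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da = 3.9, max_ha = 2.5, min_dha_angle = 90,
                           min_daa_angle = 90, heavy_only_max_da = 3.5) {
  stopifnot(max_da > 0, max_ha > 0, heavy_only_max_da > 0)
  stopifnot(min_dha_angle >= 0, min_dha_angle <= 180,
            min_daa_angle >= 0, min_daa_angle <= 180)
  structure(
    list(max_da = max_da, max_ha = max_ha, min_dha_angle = min_dha_angle,
         min_daa_angle = min_daa_angle, heavy_only_max_da = heavy_only_max_da),
    class = "hbond_criteria"
  )
}

#' Salt-bridge geometric criteria
#'
#' A salt bridge is scored between an acidic side-chain carboxylate oxygen
#' (Asp OD1/OD2, Glu OE1/OE2) and a basic side-chain nitrogen (Lys NZ, Arg
#' NE/NH1/NH2, and optionally His ND1/NE2) when the minimum oxygen-nitrogen
#' distance does not exceed `max_no_distance`. The default 4.0 Angstrom is
#' the common Barlow-Thornton convention. Histidine is included as basic by
#' default; charged chain termini are excluded by default so only side-chain
#' pairs are reported.
#'
#' @param max_no_distance Maximum charged O to charged N distance, Angstrom.
#' @param include_his Count His ND1/NE2 as basic charged atoms?
#' @param include_termini Count the N-terminal amide N and C-terminal OXT as
#'   charged groups?
#' @return A list of class `salt_bridge_criteria`.
#' @export
salt_bridge_criteria <- function(max_no_distance = 4.0, include_his = TRUE,
                                 include_termini = FALSE) {
  stopifnot(max_no_distance > 0)
  structure(
    list(max_no_distance = max_no_distance, include_his = include_his,
         include_termini = include_termini),
    class = "salt_bridge_criteria"
  )
}
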