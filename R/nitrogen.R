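# Nitrogen derivation and nitrogen-corrected substitution of amino acid
# profiles.  Nitrogen is never measured here: it is always derived from
# crude protein through a food-group-specific nitrogen-to-protein
# conversion factor, so target and similar food may legitimately use
# different factors.

#' Derive nitrogen content from crude protein
#'
#' N (g/100 g) = protein (g/100 g) / conversion factor.  The factor is the
#' food-group-specific nitrogen-to-protein divisor (e.g. 6.25 for general
#' foods, 5.83 for cereals).
#'
#' @param protein crude protein, g per 100 g edible portion (>= 0).
#' @param factor nitrogen-to-protein conversion factor (> 0).
#' @return nitrogen, g per 100 g edible portion.
#' @examples
#' nitrogen_from_protein(12.5, 6.25)  # 2.0
#' @export
nitrogen_from_protein <- function(protein, factor) {
  if (!is.finite(factor) || factor <= 0) {
    stop_config("nitrogen-to-protein conversion factor must be > 0")
  }
  if (any(protein < 0)) stop_validation("protein must be >= 0")
  protein / factor
}

#' Nitrogen-corrected amino acid profile
#'
#' Rescales a similar food's amino acid profile to the target food's
#' nitrogen level:
#' \deqn{AA_{target} = AA_{similar} \times N_{target} / N_{similar}}
#' Every present amino acid is multiplied by the same nitrogen ratio;
#' missing amino acids stay missing (the key set is preserved exactly).
#' This is the "calculated value" route of database construction: when a
#' nutritionally similar food has analytical data but its macronutrients
#' differ from the target by more than the tolerance, the profile is
#' borrowed and corrected for the protein (nitrogen) difference rather than
#' copied verbatim.
#'
#' @param similar amino acid profile of the similar food (mg/100 g); any
#'   representation accepted by [as_profile()].
#' @param n_target nitrogen content of the target food (g/100 g, >= 0).
#' @param n_similar nitrogen content of the similar food (g/100 g, > 0).
#' @return named numeric profile over the full vocabulary, mg/100 g.
#' @examples
#' nitrogen_corrected_profile(c(LYS = 500), 1.6, 2.0)[["LYS"]]  # 400
#' @export
nitrogen_corrected_profile <- function(similar, n_target, n_similar) {
  p <- as_profile(similar)
  if (!has_profile(p)) stop_validation("similar profile is empty")
  if (!is.finite(n_similar) || n_similar <= 0) {
    stop_validation("similar food has non-positive nitrogen; cannot scale")
  }
  if (n_target < 0) stop_validation("negative nitrogen content")
  p * (n_target / n_similar)
}
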