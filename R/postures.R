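# Canonical class order. The order is load-bearing: vote and dominance ties
# are broken toward the earliest class in this vector.
.posture_levels <- c("Stand", "Supine", "RightLateral", "LeftLateral", "Prone")

#' Posture classes in canonical order
#'
#' The five body postures the pipeline recognises: `Stand` (upright),
#' `Supine` (face up), `RightLateral` / `LeftLateral` (side-lying) and
#' `Prone` (face down). The returned order is the fixed tie-breaking order
#' used throughout the package (earlier wins).
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' posture_levels()
posture_levels <- function() .posture_levels

#' Coerce labels to the posture factor
#'
#' @param x Character or factor of posture names.
#' @return Factor with the five canonical levels, in canonical order.
#' @export
as_posture <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), .posture_levels)
  if (length(bad) > 0) {
    abort(paste0("Unknown posture label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = .posture_levels)
}
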