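#' Canonical iEEG frequency bands
#'
#' The five bands used throughout the pipeline: delta (2-4 Hz), theta
#' (4-8 Hz), alpha (8-12 Hz), beta (12-25 Hz) and gamma (25-55 Hz). Band
#' edges are half-open `[low, high)` so that the shared edges at 4, 8, 12
#' and 25 Hz are unambiguous; the bands are contiguous and non-overlapping.
#'
#' @return A data frame with columns `band`, `low`, `high` (Hz).
#' @examples
#' canonical_bands()
#' @export
canonical_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(2, 4, 8, 12, 25),
    high = c(4, 8, 12, 25, 55),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$high <= bands$low)) stopf("band edges must satisfy low < high")
  bands
}
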