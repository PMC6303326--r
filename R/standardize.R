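#' Standardize a predictor by two standard deviations
#'
#' Centers a predictor at its sample mean and divides by twice its sample
#' standard deviation (n-1 denominator), so a one-unit change on the
#' standardized scale spans two SDs of the raw variable and slope magnitudes
#' are comparable across continuous and binary predictors. The resulting
#' vector has mean 0 and SD 0.5; a vector already on that scale is a fixed
#' point of the transform.
#'
#' @param x Numeric vector with positive variance.
#' @return The standardized vector, with attributes `center` (the mean) and
#'   `scale` (the SD) for back-transformation.
#' @export
standardize_2sd <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) {
    abort("Cannot standardize a constant (zero-variance) vector.")
  }
  out <- (x - m) / (2 * s)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}
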