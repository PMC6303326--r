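#' Aridity index from plot climate
#'
#' Deterministic stand-in for the ratio of annual precipitation to potential
#' evapotranspiration (PET). PET is approximated as a linear function of mean
#' annual temperature, floored so the index stays positive in cold climates.
#' The index increases with precipitation and decreases with temperature,
#' which is all downstream stages rely on: only the aridity *class* labels
#' (arid / semi-arid / dry sub-humid / humid) matter for the analysis.
#'
#' @param mat Mean annual temperature, degrees C.
#' @param tap Total annual precipitation, mm.
#' @return Numeric vector of positive aridity indices.
#' @export
aridity_index <- function(mat, tap) {
  pet <- pmax(400 + 65 * mat, 50)
  tap / pet
}

#' BPR regime map: planted richness effects across climate space
#'
#' Maps plot climate to the true linear (`b17`) and quadratic (`b18`) effects
#' of standardized richness on log productivity used by the synthetic
#' generator. A `"constant"` map plants the same pair everywhere; a `"blend"`
#' map plants the `dry` pair where the aridity index is below `threshold` and
#' the `wet` pair above it, with a smooth (cosine) ramp of half-width `width`
#' centred on the threshold. The default threshold 0.5 is the semi-arid /
#' dry sub-humid class boundary, so the planted regime division falls at that
#' border of climate space.
#'
#' @param kind `"constant"` or `"blend"`.
#' @param dry,wet Length-2 numeric vectors `c(b17, b18)`.
#' @param threshold Aridity index at the regime centre line.
#' @param width Half-width of the smooth transition band (aridity units).
#' @return An object of class `bpr_regime_map`.
#' @export
bpr_regime_map <- function(kind = c("constant", "blend"),
                           dry = c(0, 0), wet = dry,
                           threshold = 0.5, width = 0.04) {
  kind <- match.arg(kind)
  stopifnot(length(dry) == 2, length(wet) == 2, width > 0, threshold > 0)
  structure(
    list(kind = kind, dry = as.numeric(dry), wet = as.numeric(wet),
         threshold = threshold, width = width),
    class = "bpr_regime_map"
  )
}

#' Evaluate a regime map at plot climates
#'
#' @param map A [bpr_regime_map()].
#' @param mat,tap Plot climate vectors.
#' @return A tibble with columns `b17`, `b18` (planted per-plot effects) and
#'   `regime` (`"dry"` or `"wet"` by which side of the threshold the plot
#'   falls on).
#' @export
regime_coefficients <- function(map, mat, tap) {
  stopifnot(inherits(map, "bpr_regime_map"))
  arid <- aridity_index(mat, tap)
  if (map$kind == "constant") {
    return(tibble(
      b17 = rep(map$dry[1], length(mat)),
      b18 = rep(map$dry[2], length(mat)),
      regime = ifelse(arid < map$threshold, "dry", "wet")
    ))
  }
  lo <- map$threshold - map$width
  hi <- map$threshold + map$width
  # dry-side weight: exactly 1 below the band, exactly 0 above it
  w <- ifelse(arid <= lo, 1,
       ifelse(arid >= hi, 0,
              0.5 * (1 + cos(pi * (arid - lo) / (hi - lo)))))
  tibble(
    b17 = w * map$dry[1] + (1 - w) * map$wet[1],
    b18 = w * map$dry[2] + (1 - w) * map$wet[2],
    regime = ifelse(arid < map$threshold, "dry", "wet")
  )
}

beta_labels <- function() paste0("b", 1:18)

default_structural_betas <- function() {
  setNames(c(
    -0.3,  0.3,   # MAT, TAP -> log stem density
    -0.1,  0.1,   # MAT, TAP -> log stand age
     0.1, -0.1,   # MAT, TAP -> log soil C:N
     0.1,  0.2, 0.3, 0.2, -0.1,   # MAT, TAP, density, age, C:N -> richness
     0.2,  0.2, 0.3, -0.2,  0.1,  # MAT, TAP, density, age, C:N -> productivity
     0.4,  0.0    # richness, richness^2 -> productivity (nominal dry values)
  ), beta_labels())
}

#' Default generator parameters for a named scenario
#'
#' Scenario presets for the synthetic FIA-like plot generator:
#' * `"null"` — no richness-productivity association anywhere: the direct
#'   effects are zero (`b17* = b18* = 0`) and, because this scenario is the
#'   instrument for measuring the classifier's false-positive rate, the
#'   indirect pathways are severed too (richness is i.i.d. Poisson:
#'   no climate or stand-structure effects on richness, no ecoregion
#'   intercepts).
#' * `"dry_positive"` — a positive linear richness effect everywhere.
#' * `"mesic_hump"` — a hump-shaped (negative quadratic) effect everywhere.
#' * `"continental"` — a dry regime (positive linear, no curvature) below the
#'   semi-arid / dry sub-humid aridity boundary and a hump-shaped regime above
#'   it, blended smoothly in a narrow band at the boundary. Climate ranges
#'   span a full continental gradient (MAT −3.8–23.9 °C, TAP 79–3375 mm).
#'
#' @param scenario One of `"null"`, `"dry_positive"`, `"mesic_hump"`,
#'   `"continental"`.
#' @return A `bpr_generator_params` list. Fields can be modified before
#'   passing to [generate_climate()] / [generate_plots()].
#' @export
default_params <- function(scenario = "continental") {
  valid <- c("null", "dry_positive", "mesic_hump", "continental")
  if (length(scenario) != 1 || !scenario %in% valid) {
    abort(paste0("Unknown scenario '", paste(scenario, collapse = ","),
                 "'. Valid scenarios: ", paste(valid, collapse = ", "), "."))
  }
  betas <- default_structural_betas()
  map <- switch(scenario,
    null         = bpr_regime_map("constant", dry = c(0, 0)),
    dry_positive = bpr_regime_map("constant", dry = c(0.4, 0)),
    mesic_hump   = bpr_regime_map("constant", dry = c(0.2, -0.55)),
    continental  = bpr_regime_map("blend", dry = c(0.4, 0), wet = c(0.2, -0.55))
  )
  betas["b17"] <- map$dry[1]
  betas["b18"] <- map$dry[2]
  # The null scenario is the type-I calibration instrument: it severs every
  # pathway tying richness to anything productivity responds to — the
  # direct effect, the stand-structure confounders, the shared climate
  # drivers, and ecoregion shifts — leaving richness i.i.d. Poisson, so the
  # classifier's intrinsic false-positive rate is what gets measured.
  eco_sd <- 0.2
  if (scenario == "null") {
    betas[c("b7", "b8", "b9", "b10", "b11")] <- 0
    eco_sd <- 0
  }
  structure(list(
    scenario = scenario,
    n_plots = 20000L,
    n_ecoregions = 30L,
    mat_range = c(-3.8, 23.9),
    tap_range = c(79, 3375),
    climate_correlation = 0.3,
    ecoregion_sd = eco_sd,
    structural_betas = betas,
    bpr_regime_map = map,
    intercepts = c(density = log(800), age = log(60), soil_cn = log(15),
                   richness = log(8), productivity = log(3)),
    noise_sds = c(density = 0.4, age = 0.4, soil_cn = 0.3,
                  productivity = 0.4),
    missing_rate = 0.02,
    seed = 42L
  ), class = "bpr_generator_params")
}

validate_generator_params <- function(params) {
  stopifnot(inherits(params, "bpr_generator_params"))
  if (params$n_plots < 1) abort("n_plots must be a positive integer.")
  if (params$n_ecoregions < 1) abort("n_ecoregions must be a positive integer.")
  if (params$mat_range[1] >= params$mat_range[2])
    abort("mat_range must be an ordered (low, high) pair.")
  if (params$tap_range[1] >= params$tap_range[2])
    abort("tap_range must be an ordered (low, high) pair.")
  if (abs(params$climate_correlation) >= 1)
    abort("climate_correlation must lie in (-1, 1).")
  if (params$ecoregion_sd < 0) abort("ecoregion_sd must be nonnegative.")
  if (!identical(sort(names(params$structural_betas)), sort(beta_labels())))
    abort("structural_betas must have exactly 18 entries named b1..b18.")
  if (params$missing_rate < 0 || params$missing_rate >= 1)
    abort("missing_rate must lie in [0, 1).")
  invisible(params)
}

#' @export
print.bpr_generator_params <- function(x, ...) {
  cat("<bpr_generator_params>\n")
  cat("  scenario:", x$scenario, " n_plots:", x$n_plots,
      " n_ecoregions:", x$n_ecoregions, "\n")
  cat("  MAT range:", paste(x$mat_range, collapse = " to "), "degC;",
      "TAP range:", paste(x$tap_range, collapse = " to "), "mm\n")
  cat("  regime map:", x$bpr_regime_map$kind,
      " dry=(", paste(x$bpr_regime_map$dry, collapse = ", "), ")",
      " wet=(", paste(x$bpr_regime_map$wet, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
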