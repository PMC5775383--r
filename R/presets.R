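#' Condition presets
#'
#' Construct a [ConditionPreset-class], optionally starting from one of the
#' shipped condition names and overriding individual parameters.
#'
#' The shipped presets emulate the three lipoplex charge-ratio conditions:
#' \describe{
#'   \item{R5}{HP prevalence 0.1527, viability 0.75, HP slope multiplier 4.}
#'   \item{R3}{HP prevalence 0.0872, viability 0.71, HP slope multiplier 4.}
#'   \item{R1.5}{HP prevalence 0.0488, viability 0.88, HP slope multiplier 6
#'     (fewer HPs, each producing more).}
#'   \item{null}{no HP subpopulation (prevalence 0), viability 0.81; a
#'     producing population with no high-producer tail, used as the negative
#'     control for threshold and skewness behavior.}
#' }
#' Shared defaults: Poisson loading mean 0.45 cells/droplet; LP slopes
#' lognormal with mean 2.5 and sd 0.125 counts/h; HP diameters 1.15 x the LP
#' draw; LP diameters Normal(13, 1.5) um truncated to (8, 27) um; baseline
#' green intensity Normal(150, 10) counts; no constitutive non-producers.
#'
#' @param name preset name ("R5", "R3", "R1.5", "null") or an arbitrary
#'   label when all parameters are given explicitly.
#' @param ... named parameter overrides matching the class slots
#'   (e.g. \code{hpPrevalence}, \code{viability}, \code{lam}).
#' @return a validated [ConditionPreset-class].
#' @examples
#' conditionPreset("R5")
#' conditionPreset("R5", hpPrevalence = 0)  # R5 noise model, no HPs
#' @export
conditionPreset <- function(name = "R5", ...) {
  base <- list(
    hpPrevalence = 0, hpSlopeMultiplier = 4, viability = 0.81,
    lpSlopeMean = 2.5, lpSlopeSd = 0.125,
    hpDiameterMultiplier = 1.15, nonproducerFraction = 0, lam = 0.45,
    lpDiameterMean = 13, lpDiameterSd = 1.5, diameterRange = c(8, 27),
    baselineMean = 150, baselineSd = 10)
  known <- list(
    "R5"   = list(hpPrevalence = 0.1527, viability = 0.75),
    "R3"   = list(hpPrevalence = 0.0872, viability = 0.71),
    "R1.5" = list(hpPrevalence = 0.0488, viability = 0.88,
                  hpSlopeMultiplier = 6),
    "null" = list(hpPrevalence = 0, viability = 0.81))
  if (name %in% names(known)) base[names(known[[name]])] <- known[[name]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  stopIf(length(bad) > 0, "unknown preset parameter(s): ",
         paste(bad, collapse = ", "))
  base[names(dots)] <- dots
  do.call(new, c(list("ConditionPreset", name = name), base))
}

setMethod("show", "ConditionPreset", function(object) {
  cat(sprintf(
    paste0("ConditionPreset '%s': HP prevalence %.4f (slope x%g, diameter x%g),\n",
           "  LP slope %.3g +/- %.3g counts/h, viability %.2f, lam %.2f\n"),
    object@name, object@hpPrevalence, object@hpSlopeMultiplier,
    object@hpDiameterMultiplier, object@lpSlopeMean, object@lpSlopeSd,
    object@viability, object@lam))
})
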