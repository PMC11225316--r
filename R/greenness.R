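#' Power-law penalty points
#'
#' y = a x^b, the modified eco-scale penalty for a consumed quantity x
#' (ml of solvent or ml of waste); y(0) = 0 by continuity for b > 0.
#'
#' @param x consumed quantity, >= 0
#' @param a,b penalty coefficients
#' @export
penaltyPoints <- function(x, a, b) {
  if (any(x < 0)) stop("quantity must be >= 0")
  ifelse(x == 0, 0, a * x^b)
}

#' Default penalty coefficients
#'
#' Published coefficients of the modified eco-scale: a = 0.61 (+/- 0.05),
#' b = 0.31 (+/- 0.02) for solvent consumption; a = 1.50 (+/- 0.08),
#' b = 0.40 (+/- 0.02) for produced waste. Uncertainties are carried as
#' attributes.
#' @return list(solvent = c(a, b), waste = c(a, b))
#' @export
penaltyCoefficients <- function() {
  out <- list(solvent = c(a = 0.61, b = 0.31), waste = c(a = 1.50, b = 0.40))
  attr(out, "uncertainty") <- list(solvent = c(a = 0.05, b = 0.02),
                                   waste = c(a = 0.08, b = 0.02))
  out
}

#' Greenness penalty ledger
#'
#' @param solvent_volume_ml solvent consumed (ml)
#' @param hazard_multiplier hazard penalty multiplying the solvent penalty
#' @param energy_pp energy penalty points
#' @param occupational_pp occupational-hazard penalty points
#' @param waste_ml waste produced (ml)
#' @return a "penaltyLedger" list
#' @export
penaltyLedger <- function(solvent_volume_ml, hazard_multiplier = 1,
                          energy_pp = 0, occupational_pp = 0, waste_ml = 0) {
  vals <- c(solvent_volume_ml, hazard_multiplier, energy_pp,
            occupational_pp, waste_ml)
  if (any(vals < 0)) stop("ledger inputs must be >= 0")
  structure(list(solvent_volume_ml = solvent_volume_ml,
                 hazard_multiplier = hazard_multiplier,
                 energy_pp = energy_pp, occupational_pp = occupational_pp,
                 waste_ml = waste_ml), class = "penaltyLedger")
}

#' Default seven-class boundaries
#'
#' The published tool maps total penalty points to seven classes only
#' graphically, so the boundaries are a configuration input; the default is
#' equal-width bins over 0-30 penalty points (six boundaries; totals of 30
#' or more fall in the worst class).
#' @return numeric vector of six upper boundaries
#' @export
defaultClassBoundaries <- function() seq(30 / 7, 30 - 30 / 7, length.out = 6)

#' Green certificate from a penalty ledger
#'
#' total = solvent_pp * hazard + energy + occupational + waste_pp, with the
#' power-law penalties of \code{\link{penaltyPoints}}; the class is found
#' by thresholding against the seven-class boundaries. A total exactly on a
#' boundary lands in the better (lower-penalty) class.
#'
#' @param ledger a \code{\link{penaltyLedger}}
#' @param coefficients a \code{\link{penaltyCoefficients}} list
#' @param class_boundaries six increasing upper boundaries
#' @return list: solvent_pp, waste_pp, total_pp, class (1 best - 7 worst)
#' @export
certify <- function(ledger, coefficients = penaltyCoefficients(),
                    class_boundaries = defaultClassBoundaries()) {
  if (length(class_boundaries) != 6L || is.unsorted(class_boundaries))
    stop("class_boundaries must be six increasing values")
  sp <- penaltyPoints(ledger$solvent_volume_ml,
                      coefficients$solvent["a"], coefficients$solvent["b"])
  wp <- penaltyPoints(ledger$waste_ml,
                      coefficients$waste["a"], coefficients$waste["b"])
  total <- sp * ledger$hazard_multiplier + ledger$energy_pp +
    ledger$occupational_pp + wp
  cls <- 1L + sum(total > class_boundaries)
  list(solvent_pp = unname(sp), waste_pp = unname(wp),
       total_pp = unname(total), class = cls)
}

#' RGB-12 whiteness score
#'
#' Twelve criteria scored 0-100 in three groups — red (safety, toxicity,
#' energy), green (trueness, precision, detection limit, quantification
#' limit), blue (cost, speed, simplicity) — aggregated as unweighted group
#' means whose mean is the whiteness.
#'
#' @param red,green,blue numeric criterion scores in [0, 100] (3-4 each)
#' @return a \linkS4class{WhitenessScore}
#' @export
whiteness <- function(red, green, blue) {
  for (g in list(red, green, blue))
    if (length(g) < 3L || length(g) > 4L)
      stop("each group needs 3-4 criterion scores")
  gm <- c(red = mean(red), green = mean(green), blue = mean(blue))
  new("WhitenessScore", red = red, green = green, blue = blue,
      group_means = gm, whiteness = mean(gm))
}

setMethod("show", "WhitenessScore", function(object) {
  cat(sprintf("WhitenessScore: %.2f (red %.1f, green %.1f, blue %.1f)\n",
              object@whiteness, object@group_means["red"],
              object@group_means["green"], object@group_means["blue"]))
})
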