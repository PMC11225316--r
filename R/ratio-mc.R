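#' Mean-center a vector
#'
#' Subtracts the arithmetic mean, annihilating any constant contribution:
#' the mean-centered value of a constant is exactly zero. \code{NA} entries
#' (masked points) are excluded from the mean and stay \code{NA}.
#'
#' @param v numeric vector of length >= 2
#' @return v - mean(v)
#' @examples
#' meanCenter(c(3, 6, 3))  # -1 2 -1
#' @export
meanCenter <- function(v) {
  if (length(v) < 2L) stop("need at least 2 values to mean-center")
  v - mean(v, na.rm = TRUE)
}

#' Ratio-spectrum mean-centering pipeline
#'
#' Slice the mixture and divisor to the working range, divide pointwise
#' (with floor masking), then mean-center over the unmasked points of the
#' range. A mixture containing only the divisor's component gives a
#' constant ratio, so the output collapses to zero: the remaining signal
#' belongs solely to the other component.
#'
#' @param mixture a \linkS4class{Spectrum}
#' @param cal_divisor pure-component divisor \linkS4class{Spectrum} on the
#'   same grid
#' @param range_nm length-2 numeric window (nm)
#' @param floor division floor (AU), see \code{\link{divideSpectrum}}
#' @return mean-centered ratio \linkS4class{Spectrum} on the sliced grid
#' @export
mcPipeline <- function(mixture, cal_divisor, range_nm, floor = 1e-3) {
  if (!sameGrid(mixture@grid, cal_divisor@grid))
    stop("grid mismatch between mixture and divisor")
  num <- sliceRange(mixture, range_nm[1], range_nm[2])
  den <- sliceRange(cal_divisor, range_nm[1], range_nm[2])
  ratio <- divideSpectrum(num, den, floor)
  spectrum(ratio@grid, meanCenter(ratio@absorbance), mixture@label)
}

mcSignalMatrix <- function(set, divisor, range_nm, floor = 1e-3) {
  vapply(seq_len(nSpectra(set)), function(i)
    mcPipeline(getSpectrum(set, i), divisor, range_nm, floor)@absorbance,
    numeric(length(sliceIndices(set@grid, range_nm[1], range_nm[2]))))
}

#' Build a mean-centering calibration
#'
#' The measurement wavelength is elected as the point of maximum response:
#' the wavelength within the range whose mean-centered signal has the
#' largest calibration-slope magnitude against concentration (the
#' generalization of reading the mean-centered signal at its maximum).
#' An ordinary least-squares line is then fitted there.
#'
#' @param analyte_set pure-analyte \linkS4class{SpectrumSet} with a
#'   1-column concentration matrix
#' @param divisor pure-interferent divisor \linkS4class{Spectrum}
#' @param divisor_conc divisor concentration (ug/ml), bookkeeping only
#' @param range_nm length-2 numeric window (nm)
#' @param floor division floor (AU)
#' @return a \linkS4class{McCalibration}
#' @export
calibrateMc <- function(analyte_set, divisor, divisor_conc = NA_real_,
                        range_nm, floor = 1e-3) {
  conc <- analyteConcs(analyte_set)
  if (length(unique(conc)) < 2L)
    stop("degenerate design: need >= 2 distinct concentrations")
  sig <- mcSignalMatrix(analyte_set, divisor, range_nm, floor)
  ok <- !apply(is.na(sig), 1, any)
  if (!any(ok)) stop("entire range masked by the division floor")
  slopes <- rep(NA_real_, nrow(sig))
  xc <- conc - mean(conc)
  slopes[ok] <- (sig[ok, , drop = FALSE] %*% xc) / sum(xc^2)
  jmax <- which.max(abs(slopes))
  idx <- sliceIndices(analyte_set@grid, range_nm[1], range_nm[2])
  lam <- wavelengths(analyte_set@grid)[idx[jmax]]
  fit <- fitLinear(conc, sig[jmax, ])
  new("McCalibration", divisor = divisor,
      divisor_conc = as.numeric(divisor_conc),
      range_nm = as.numeric(range_nm), lambda_max_nm = lam, fit = fit,
      floor = floor)
}

#' Predict a concentration by ratio-spectra mean-centering
#'
#' @param mixture a \linkS4class{Spectrum} on the calibration grid
#' @param cal a \linkS4class{McCalibration}
#' @return estimated concentration (ug/ml)
#' @export
predictMc <- function(mixture, cal) {
  if (!sameGrid(mixture@grid, cal@divisor@grid))
    stop("grid mismatch: mixture is not on the calibration grid")
  mc <- mcPipeline(mixture, cal@divisor, cal@range_nm, cal@floor)
  s <- mc@absorbance[gridIndex(mc@grid, cal@lambda_max_nm)]
  if (is.na(s)) stop("elected wavelength is masked in this mixture")
  (s - cal@fit@intercept) / cal@fit@slope
}

mcRecoveryLoss <- function(analyte_set, divisor, divisor_conc, range_nm,
                           validation_mixes, component, floor = 1e-3) {
  cal <- calibrateMc(analyte_set, divisor, divisor_conc, range_nm, floor)
  truth <- validation_mixes@concentrations[, component]
  pred <- vapply(seq_len(nSpectra(validation_mixes)), function(i)
    predictMc(getSpectrum(validation_mixes, i), cal), numeric(1))
  rec <- 100 * pred[truth > 0] / truth[truth > 0]
  list(cal = cal, pred = pred, recoveries = rec,
       loss = mean(abs(rec - 100)))
}

#' Elect the divisor by validation recovery
#'
#' Runs the full calibrate-and-predict cycle for every candidate divisor
#' and returns the one minimizing the mean absolute deviation of recovery
#' from 100\% over the validation mixtures. Ties (within 0.01 percentage
#' points) go to the lowest divisor concentration.
#'
#' @param candidates pure-interferent \linkS4class{SpectrumSet} whose
#'   1-column concentration matrix gives the candidate divisor
#'   concentrations
#' @param analyte_set pure-analyte calibration \linkS4class{SpectrumSet}
#' @param validation_mixes mixture \linkS4class{SpectrumSet} with known
#'   concentrations
#' @param range_nm length-2 numeric window (nm)
#' @param component column of the validation concentration matrix holding
#'   the analyte
#' @param floor division floor (AU)
#' @return list(divisor, divisor_conc, loss)
#' @export
selectDivisor <- function(candidates, analyte_set, validation_mixes,
                          range_nm, component = 1L, floor = 1e-3) {
  dconc <- analyteConcs(candidates)
  losses <- vapply(seq_len(nSpectra(candidates)), function(i)
    mcRecoveryLoss(analyte_set, getSpectrum(candidates, i), dconc[i],
                   range_nm, validation_mixes, component, floor)$loss,
    numeric(1))
  near <- which(losses <= min(losses) + 0.01)
  pick <- near[which.min(dconc[near])]
  list(divisor = getSpectrum(candidates, pick), divisor_conc = dconc[pick],
       loss = losses[pick])
}

#' Scan candidate mean-centering ranges
#'
#' Calibrates and predicts over every candidate range and reports, per
#' range, the fitted line and the recovery of each validation mixture —
#' the survey from which the working range is elected (closest mean
#' recovery to 100\%). Ranges whose masked fraction exceeds 10\% are
#' disqualified; ties go to the narrower range.
#'
#' @param candidate_ranges list of length-2 numeric windows (nm)
#' @param analyte_set pure-analyte calibration \linkS4class{SpectrumSet}
#' @param validation_mixes mixture \linkS4class{SpectrumSet} with known
#'   concentrations
#' @param divisor pure-interferent divisor \linkS4class{Spectrum}
#' @param divisor_conc divisor concentration (ug/ml)
#' @param component analyte column of the validation concentrations
#' @param floor division floor (AU)
#' @return list(range_nm, report); report has one row per candidate with
#'   slope, intercept, per-mixture recoveries and mean |recovery - 100|
#' @export
selectRange <- function(candidate_ranges, analyte_set, validation_mixes,
                        divisor, divisor_conc = NA_real_, component = 1L,
                        floor = 1e-3) {
  rows <- lapply(candidate_ranges, function(rg) {
    idx <- sliceIndices(analyte_set@grid, rg[1], rg[2])
    dv <- divisor@absorbance[idx]
    masked_frac <- mean(abs(dv) < floor | is.na(dv))
    if (masked_frac > 0.10)
      return(data.frame(lo_nm = rg[1], hi_nm = rg[2], slope = NA,
                        intercept = NA, loss = NA, disqualified = TRUE))
    r <- mcRecoveryLoss(analyte_set, divisor, divisor_conc, rg,
                        validation_mixes, component, floor)
    out <- data.frame(lo_nm = rg[1], hi_nm = rg[2],
                      slope = r$cal@fit@slope,
                      intercept = r$cal@fit@intercept, loss = r$loss,
                      disqualified = FALSE)
    for (i in seq_along(r$recoveries))
      out[[paste0("recovery_mix", i)]] <- r$recoveries[i]
    out
  })
  report <- do.call(rbind, lapply(rows, function(d) {
    miss <- setdiff(unlist(lapply(rows, names)), names(d))
    d[miss] <- NA
    d
  }))
  ok <- which(!report$disqualified)
  if (!length(ok)) stop("every candidate range is disqualified by masking")
  width <- report$hi_nm - report$lo_nm
  best <- ok[order(report$loss[ok], width[ok])][1]
  list(range_nm = c(report$lo_nm[best], report$hi_nm[best]),
       report = report)
}
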