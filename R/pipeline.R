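#' Published calibration lines (reference constants)
#'
#' The straight-line calibrations reported for the real drugs; packaged for
#' comparison only — they depend on the real instrument spectra and are not
#' reproduced by the synthetic pipeline.
#' @return data.frame: method, component, wavelength_nm, slope, intercept
#' @export
referenceCalibrationLines <- function() {
  data.frame(
    method = c("fsd", "fsd", "mc", "mc"),
    component = c("CI", "OR", "CI", "OR"),
    wavelength_nm = c(280.1, 314.2, 272.0, 306.2),
    slope = c(0.2732, 0.0778, 0.2091, 0.0571),
    intercept = c(0.0031, 0.002, 0.0026, 0.0042))
}

#' Recompute every desk-reproducible published number
#'
#' From packaged fixtures alone (no simulation): the test-table mean
#' recoveries, the single-factor ANOVA F statistics from the published
#' sums of squares, the critical values quoted for the method-comparison
#' tests, and the worked mean-centering example.
#'
#' @return data.frame: quantity, computed, published, ok
#' @export
reproduceTables <- function() {
  tab2 <- referenceTestPredictions()
  a_ci <- anovaOneway(ss_between = 0.828673, df_between = 3,
                      ss_within = 29.91456, df_within = 16)
  a_or <- anovaOneway(ss_between = 2.901019, df_between = 3,
                      ss_within = 33.48746, df_within = 16)
  mc_example <- meanCenter(c(3, 6, 3))
  rows <- data.frame(
    quantity = c("mean_recovery_ci", "mean_recovery_or",
                 "anova_f_ci", "anova_f_or", "anova_f_crit_3_16",
                 "t_crit_0.05_8", "f_crit_0.05_4_4",
                 "mc_example_second_entry", "mc_example_mean"),
    computed = c(mean(tab2$rec_ci, na.rm = TRUE),
                 mean(tab2$rec_or, na.rm = TRUE),
                 a_ci$f_value, a_or$f_value, a_ci$f_crit,
                 tCritical(0.05, 8), fCritical(0.05, 4, 4),
                 mc_example[2], mean(mc_example)),
    published = c(100.05, 99.84, 0.14774, 0.462027, 3.238872,
                  2.306, 6.388, 2, 0))
  rows$ok <- abs(rows$computed - rows$published) <
    c(0.005, 0.005, 5e-5, 5e-6, 5e-6, 5e-3, 5e-3, 1e-12, 1e-12)
  rows
}

#' Default mean-centering candidate ranges surveyed for each component
#' @param component "CI" or "OR"
#' @return list of length-2 numeric windows (nm)
#' @export
defaultMcRanges <- function(component = c("CI", "OR")) {
  component <- match.arg(component)
  if (component == "CI")
    list(c(240, 290), c(230, 300), c(260, 290), c(240, 325), c(250, 300))
  else
    list(c(260, 340), c(290, 330), c(240, 340), c(260, 330), c(280, 340))
}

pipelineComponents <- function() list(ciLikeModel(), orLikeModel())

calibrationLevels <- function(component) {
  if (component == 1L) c(2, 4, 6, 8, 10, 12, 15) else c(3, 5, 10, 15, 20, 25)
}

#' End-to-end synthetic quantification run
#'
#' Generates calibration scans and mixture spectra of a concentration
#' design, performs the method's own parameter elections (deconvolution
#' width and zero-crossing wavelength for "fsd"; divisor and wavelength
#' range for "mc"; architecture as given for "ann"), calibrates both
#' components, predicts every design mixture, and reports predictions with
#' the full metric set. All randomness is governed by \code{seed}.
#'
#' @param method "mc", "fsd" or "ann"
#' @param seed integer seed
#' @param design mixture concentration matrix (columns CI, OR)
#' @param noise_sd photometric noise sd (AU)
#' @param out_dir optional directory; when given, predictions, elections
#'   and the run configuration are written as CSV/JSON files
#' @param ann_hidden hidden-layer spec for "ann"
#' @param max_epochs training cap for "ann"
#' @return list: method, elections, predictions (data.frame), metrics
#'   (per component), seed
#' @export
runPipeline <- function(method = c("mc", "fsd", "ann"), seed = 1L,
                        design = referenceTestDesign(), noise_sd = 0.002,
                        out_dir = NULL, ann_hidden = 2L,
                        max_epochs = 1000L) {
  method <- match.arg(method)
  comps <- pipelineComponents()
  sg <- scanGrid()
  noise <- function(off) noiseModel(noise_sd, 0, seed + off)
  mixes <- makeMixtureSet(comps, design, noise(900L), sg)
  calset <- function(k, off)
    makeCalibrationSet(comps[[k]], calibrationLevels(k), noise(off), sg)
  elections <- list()
  if (method == "ann") {
    d <- annDataset(seed, noiseModel(noise_sd, 0, 0L), comps)
    ag <- annGrid()
    cfg <- netConfig(ncol(d$X_train), ann_hidden)
    net <- trainBr(d$X_train, d$Y_train, cfg,
                   brParams(max_epochs = max_epochs, seed = seed))
    X <- t(vapply(seq_len(nSpectra(mixes)), function(i)
      resample(getSpectrum(mixes, i), ag)@absorbance,
      numeric(ag@n_points)))
    pred <- annForward(net, X)
    elections$architecture <- paste(ann_hidden, collapse = "x")
    elections$epochs <- net@epochs_run
    elections$gamma <- net@gamma
  } else {
    pred <- matrix(NA_real_, nrow(design), 2)
    for (k in 1:2) {
      analyte <- calset(k, 100L + k)
      interf <- calset(3L - k, 200L + k)
      if (method == "fsd") {
        sel <- selectFsdFwhm(analyte, interf)
        if (is.null(sel))
          stop("no deconvolution width produced a usable zero crossing")
        cal <- calibrateFsd(analyte, sel$wavelength_nm, sel$params)
        elections[[paste0("fsd_", comps[[k]]$name)]] <-
          list(fwhm_nm = sel$fwhm_nm, wavelength_nm = sel$wavelength_nm)
        pred[, k] <- vapply(seq_len(nSpectra(mixes)), function(i)
          predictFsd(getSpectrum(mixes, i), cal), numeric(1))
      } else {
        dconc <- if (k == 1L) 20 else 10    # interferent divisor level
        divisor <- getSpectrum(makeCalibrationSet(
          comps[[3L - k]], dconc, noise(300L + k), sg), 1L)
        vdesign <- matrix(c(10, 5, 5, 15, 3, 10), ncol = 2, byrow = TRUE)
        vmix <- makeMixtureSet(comps, vdesign, noise(400L + k), sg)
        rg <- selectRange(defaultMcRanges(comps[[k]]$name), analyte, vmix,
                          divisor, dconc, component = k)
        cal <- calibrateMc(analyte, divisor, dconc, rg$range_nm)
        elections[[paste0("mc_", comps[[k]]$name)]] <-
          list(divisor_conc = dconc, range_nm = rg$range_nm,
               lambda_max_nm = cal@lambda_max_nm)
        pred[, k] <- vapply(seq_len(nSpectra(mixes)), function(i)
          predictMc(getSpectrum(mixes, i), cal), numeric(1))
      }
    }
  }
  predictions <- data.frame(
    real_ci = design[, 1], real_or = design[, 2],
    pred_ci = pred[, 1], pred_or = pred[, 2],
    rec_ci = ifelse(design[, 1] > 0, 100 * pred[, 1] / design[, 1], NA),
    rec_or = ifelse(design[, 2] > 0, 100 * pred[, 2] / design[, 2], NA))
  metrics <- list(CI = predictionMetrics(design[, 1], pred[, 1]),
                  OR = predictionMetrics(design[, 2], pred[, 2]))
  out <- list(method = method, elections = elections,
              predictions = predictions, metrics = metrics, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(predictions,
                     file.path(out_dir, paste0(method, "_predictions.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(method = method, seed = seed, noise_sd = noise_sd,
           elections = elections),
      file.path(out_dir, paste0(method, "_run.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
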