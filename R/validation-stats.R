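#' Ordinary least-squares line fit
#'
#' @param x concentrations (or any predictor)
#' @param y signals
#' @return a \linkS4class{LinearFit}
#' @export
fitLinear <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 2L) stop("need >= 2 points")
  if (length(unique(x)) < 2L) stop("degenerate design: x has no spread")
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(res^2) / sstot
  rsd <- if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else 0
  new("LinearFit", slope = slope, intercept = intercept,
      r_squared = min(max(r2, 0), 1), residual_sd = rsd, n = as.integer(n))
}

setMethod("show", "LinearFit", function(object) {
  cat(sprintf("LinearFit: Y = %.5g X %s %.5g, R2 = %.6f, n = %d\n",
              object@slope, if (object@intercept < 0) "-" else "+",
              abs(object@intercept), object@r_squared, object@n))
})

#' Mean squared error of prediction
#'
#' MSEP = sum((c' - c)^2) / n.
#' @param c_true true concentrations
#' @param c_pred predicted concentrations
#' @export
msep <- function(c_true, c_pred) {
  checkPredPair(c_true, c_pred)
  mean((c_pred - c_true)^2)
}

#' Relative root mean squared error of prediction (\%)
#'
#' RRMSEP = (100 / mean(c_true)) * sqrt(MSEP).
#' @inheritParams msep
#' @export
rrmsep <- function(c_true, c_pred) {
  checkPredPair(c_true, c_pred)
  cbar <- mean(c_true)
  if (cbar == 0) stop("mean true concentration is zero")
  100 * sqrt(msep(c_true, c_pred)) / cbar
}

#' Bias-corrected MSEP
#'
#' The default \code{form = "corrected"} is the sample variance of the
#' prediction errors, [sum(d^2) - (sum d)^2/n] / (n - 1): insensitive to a
#' constant bias, which is what "bias-corrected" demands. The
#' \code{"printed"} form [sum(d^2) - sum(d^2)/n] / (n - 1) is retained for
#' reference; it simplifies algebraically to MSEP.
#'
#' @inheritParams msep
#' @param form "corrected" (default) or "printed"
#' @export
bcmsep <- function(c_true, c_pred, form = c("corrected", "printed")) {
  form <- match.arg(form)
  checkPredPair(c_true, c_pred)
  d <- c_pred - c_true
  n <- length(d)
  if (form == "corrected")
    (sum(d^2) - sum(d)^2 / n) / (n - 1)
  else
    (sum(d^2) - sum(d^2) / n) / (n - 1)
}

checkPredPair <- function(c_true, c_pred) {
  if (length(c_true) != length(c_pred)) stop("length mismatch")
  if (length(c_true) < 2L) stop("need >= 2 samples")
  invisible(TRUE)
}

#' Per-sample and mean recovery
#'
#' recovery_i = 100 * predicted_i / true_i; samples with a true
#' concentration of zero have undefined recovery and are excluded from the
#' mean (flagged NA).
#'
#' @inheritParams msep
#' @return list: recoveries (\% with NA where true = 0), mean_recovery,
#'   sd_recovery, n_defined
#' @export
recoveryStats <- function(c_true, c_pred) {
  if (length(c_true) != length(c_pred)) stop("length mismatch")
  rec <- ifelse(c_true > 0, 100 * c_pred / c_true, NA_real_)
  def <- rec[!is.na(rec)]
  list(recoveries = rec,
       mean_recovery = if (length(def)) mean(def) else NA_real_,
       sd_recovery = if (length(def) > 1) stats::sd(def) else NA_real_,
       n_defined = length(def))
}

#' Full prediction-quality metric set
#'
#' @inheritParams msep
#' @return list: msep, rrmsep, bcmsep, rmse, recoveries, mean_recovery,
#'   sd_recovery
#' @export
predictionMetrics <- function(c_true, c_pred) {
  r <- recoveryStats(c_true, c_pred)
  m <- msep(c_true, c_pred)
  list(msep = m, rrmsep = rrmsep(c_true, c_pred),
       bcmsep = bcmsep(c_true, c_pred), rmse = sqrt(m),
       recoveries = r$recoveries, mean_recovery = r$mean_recovery,
       sd_recovery = r$sd_recovery)
}

#' ICH detection and quantitation limits
#'
#' DL = 3.3 sigma / slope, QL = 10 sigma / slope, with sigma the residual
#' standard deviation of the calibration line.
#'
#' @param fit a \linkS4class{LinearFit}
#' @return list(dl, ql) in concentration units
#' @export
detectionLimits <- function(fit) {
  if (fit@slope == 0) stop("zero slope: detection limit undefined")
  s <- abs(fit@slope)
  list(dl = 3.3 * fit@residual_sd / s, ql = 10 * fit@residual_sd / s)
}

#' Relative standard deviation (\%)
#'
#' 100 * sd / mean, sample sd (n - 1 denominator).
#' @param values numeric vector
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  100 * stats::sd(values) / m
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' Two-tailed, equal-variance form: the one used to compare a candidate
#' method's assay means against a reference method's.
#'
#' @param a_mean,a_sd,a_n first group summary
#' @param b_mean,b_sd,b_n second group summary
#' @param alpha significance level for the critical value
#' @return list(t, df, t_crit, p)
#' @export
twoSampleT <- function(a_mean, a_sd, a_n, b_mean, b_sd, b_n, alpha = 0.05) {
  df <- a_n + b_n - 2
  sp2 <- ((a_n - 1) * a_sd^2 + (b_n - 1) * b_sd^2) / df
  t <- (a_mean - b_mean) / sqrt(sp2 * (1 / a_n + 1 / b_n))
  list(t = t, df = df, t_crit = tCritical(alpha, df),
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Variance-ratio F test from summary statistics
#'
#' F = larger variance / smaller variance, degrees of freedom ordered
#' accordingly; one-tailed critical value.
#'
#' @param a_var,a_n first group variance and size
#' @param b_var,b_n second group variance and size
#' @param alpha significance level
#' @return list(f, df1, df2, f_crit)
#' @export
varianceRatioF <- function(a_var, a_n, b_var, b_n, alpha = 0.05) {
  if (a_var >= b_var) {
    f <- a_var / b_var; df1 <- a_n - 1; df2 <- b_n - 1
  } else {
    f <- b_var / a_var; df1 <- b_n - 1; df2 <- a_n - 1
  }
  list(f = f, df1 = df1, df2 = df2, f_crit = fCritical(alpha, df1, df2))
}

#' One-way (single-factor) ANOVA
#'
#' Accepts either raw groups (a list of numeric vectors) or the summary
#' sums of squares and degrees of freedom; both produce the full table with
#' the p-value and the critical F at \code{alpha}.
#'
#' @param groups list of numeric vectors (raw entry point)
#' @param ss_between,df_between,ss_within,df_within summary entry point
#' @param alpha significance level
#' @return data.frame-free list mirroring a single-factor ANOVA table:
#'   ss_between, df_between, ms_between, ss_within, df_within, ms_within,
#'   f_value, p_value, f_crit
#' @export
anovaOneway <- function(groups = NULL, ss_between = NULL, df_between = NULL,
                        ss_within = NULL, df_within = NULL, alpha = 0.05) {
  if (!is.null(groups)) {
    all <- unlist(groups)
    gm <- mean(all)
    ss_between <- sum(vapply(groups, function(g)
      length(g) * (mean(g) - gm)^2, numeric(1)))
    ss_within <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1)))
    df_between <- length(groups) - 1L
    df_within <- length(all) - length(groups)
  }
  if (is.null(ss_between) || is.null(df_between) ||
      is.null(ss_within) || is.null(df_within))
    stop("give either raw groups or the four summary values")
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  f <- ms_b / ms_w
  list(ss_between = ss_between, df_between = df_between, ms_between = ms_b,
       ss_within = ss_within, df_within = df_within, ms_within = ms_w,
       f_value = f,
       p_value = stats::pf(f, df_between, df_within, lower.tail = FALSE),
       f_crit = fCritical(alpha, df_between, df_within))
}

#' Two-tailed t critical value
#' @param alpha significance level (two-tailed)
#' @param df degrees of freedom
#' @export
tCritical <- function(alpha, df) stats::qt(1 - alpha / 2, df)

#' One-tailed F critical value
#' @param alpha significance level
#' @param df1,df2 numerator and denominator degrees of freedom
#' @export
fCritical <- function(alpha, df1, df2) stats::qf(1 - alpha, df1, df2)

#' Standard-addition recovery
#'
#' recovery_i = 100 * (measured_total_i - base_conc) / added_i.
#'
#' @param base_conc concentration of the unspiked sample
#' @param added_concs spiked amounts
#' @param measured_totals measured total concentrations
#' @return list: recoveries, mean, sd
#' @export
standardAddition <- function(base_conc, added_concs, measured_totals) {
  if (length(added_concs) != length(measured_totals))
    stop("length mismatch")
  if (any(added_concs <= 0)) stop("added concentrations must be > 0")
  rec <- 100 * (measured_totals - base_conc) / added_concs
  list(recoveries = rec, mean = mean(rec),
       sd = if (length(rec) > 1) stats::sd(rec) else NA_real_)
}
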