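#' Read a spectrum-set CSV
#'
#' Expected layout: header row; first column \code{wavelength_nm}; one
#' column per spectrum. Comma separator, '.' decimal. The wavelength column
#' must form a regular grid.
#'
#' @param path file path
#' @return a \linkS4class{SpectrumSet} (no concentrations)
#' @export
readSpectraCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("CSV must have wavelength_nm plus >= 1 spectrum column")
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be named 'wavelength_nm'")
  wl <- df[[1]]
  steps <- diff(wl)
  if (length(unique(round(steps, 9))) != 1L)
    stop("wavelength column is not a regular grid")
  g <- wavelengthGrid(wl[1], steps[1], length(wl))
  mat <- as.matrix(df[, -1, drop = FALSE])
  spectrumSet(mat, grid = g)
}

#' Write a spectrum set as CSV
#'
#' Full double precision (17 significant digits), so a read/write round trip
#' is lossless to better than 1e-12.
#'
#' @param x a \linkS4class{SpectrumSet} or \linkS4class{Spectrum}
#' @param path file path
#' @return \code{path}, invisibly
#' @export
writeSpectraCsv <- function(x, path) {
  if (is(x, "Spectrum")) x <- spectrumSet(list(x))
  labs <- colnames(x@absorbance)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- paste0("s", seq_len(ncol(x@absorbance)))
  df <- data.frame(wavelength_nm = wavelengths(x), x@absorbance,
                   check.names = FALSE)
  names(df) <- c("wavelength_nm", labs)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, fmt), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a spectrum as a minimal JCAMP-DX file
#'
#' Single-block AFFN XYDATA=(X++(Y..Y)) form with XFACTOR/YFACTOR/DELTAX.
#' Absorbances are quantized to \code{yfactor}; the round trip is exact to
#' within that quantization.
#'
#' @param s a \linkS4class{Spectrum} (no masked points)
#' @param path file path
#' @param title JCAMP TITLE field
#' @param yfactor quantization of stored Y integers
#' @return \code{path}, invisibly
#' @export
writeJcampdx <- function(s, path, title = s@label, yfactor = 1e-8) {
  if (anyNA(s@absorbance)) stop("cannot write a spectrum with masked points")
  g <- s@grid
  yi <- round(s@absorbance / yfactor)
  per_line <- 6L
  starts <- seq(1L, g@n_points, by = per_line)
  data_lines <- vapply(starts, function(i0) {
    idx <- i0:min(i0 + per_line - 1L, g@n_points)
    x <- g@start_nm + (i0 - 1L) * g@step_nm
    paste(c(formatC(x, digits = 10, format = "f"),
            formatC(yi[idx], format = "d")), collapse = " ")
  }, character(1))
  lines <- c(
    paste0("##TITLE=", if (nzchar(title)) title else "spectrum"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=UV/VIS SPECTRUM",
    "##XUNITS=NANOMETERS",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1.0",
    paste0("##YFACTOR=", formatC(yfactor, format = "e", digits = 6)),
    paste0("##FIRSTX=", formatC(g@start_nm, digits = 10, format = "f")),
    paste0("##LASTX=", formatC(gridEnd(g), digits = 10, format = "f")),
    paste0("##DELTAX=", formatC(g@step_nm, digits = 10, format = "f")),
    paste0("##NPOINTS=", g@n_points),
    paste0("##FIRSTY=", formatC(s@absorbance[1], digits = 10, format = "g")),
    "##XYDATA=(X++(Y..Y))",
    data_lines,
    "##END=")
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal JCAMP-DX spectrum
#'
#' Supports the single-block AFFN/PAC XYDATA=(X++(Y..Y)) subset written by
#' \code{\link{writeJcampdx}}. Multi-block (compound) files are rejected.
#'
#' @param path file path
#' @return a \linkS4class{Spectrum}
#' @export
readJcampdx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^##TITLE=", lines)) > 1L || any(grepl("^##BLOCKS=", lines)))
    stop("multi-block JCAMP-DX files are not supported")
  field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  xfactor <- as.numeric(field("XFACTOR")); if (is.na(xfactor)) xfactor <- 1
  yfactor <- as.numeric(field("YFACTOR")); if (is.na(yfactor)) yfactor <- 1
  firstx <- as.numeric(field("FIRSTX"))
  deltax <- as.numeric(field("DELTAX"))
  npoints <- as.integer(field("NPOINTS"))
  title <- field("TITLE"); if (is.na(title)) title <- ""
  i0 <- grep("^##XYDATA=", lines)
  if (!length(i0)) stop("no XYDATA block found")
  form <- sub("^##XYDATA=", "", lines[i0[1]])
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    stop("unsupported XYDATA form: ", form)
  iend <- grep("^##END", lines)
  iend <- iend[iend > i0[1]][1]
  if (is.na(iend)) iend <- length(lines) + 1L
  body <- lines[(i0[1] + 1L):(iend - 1L)]
  body <- body[!grepl("^##", body) & nzchar(trimws(body))]
  ys <- numeric(0)
  first_x_seen <- NA_real_
  for (ln in body) {
    # PAC allows +/- as separators; normalize then split on whitespace
    ln2 <- gsub("([0-9.])([+-])", "\\1 \\2", trimws(ln))
    toks <- strsplit(ln2, "[ \t]+")[[1]]
    vals <- as.numeric(toks)
    if (anyNA(vals)) stop("unparseable XYDATA line: ", ln)
    if (is.na(first_x_seen)) first_x_seen <- vals[1] * xfactor
    ys <- c(ys, vals[-1])
  }
  # FIRSTX/DELTAX headers are in real units; XFACTOR scales in-line X values
  if (is.na(firstx)) firstx <- first_x_seen
  if (is.na(deltax)) stop("DELTAX missing and not inferable")
  n <- if (!is.na(npoints)) npoints else length(ys)
  if (length(ys) != n)
    stop("NPOINTS (", n, ") disagrees with parsed Y count (", length(ys), ")")
  g <- wavelengthGrid(firstx, deltax, n)
  spectrum(g, ys * yfactor, title)
}
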