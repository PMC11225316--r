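# Shared fixtures: small grids and component models used across tests.

fineGrid <- function() wavelengthGrid(200, 0.1, end_nm = 400)

lorentzianSpectrum <- function(center, fwhm, height = 1, grid = fineGrid()) {
  l <- wavelengths(grid)
  spectrum(grid, height / (1 + (2 * (l - center) / fwhm)^2))
}

measuredFwhm <- function(s) {
  y <- absorbance(s)
  above <- which(y > max(y) / 2)
  (max(above) - min(above)) * s@grid@step_nm
}

majorMaxima <- function(s, rel = 0.2) {
  y <- absorbance(s)
  pk <- which(diff(sign(diff(y))) == -2) + 1L
  pk[y[pk] > rel * max(y)]
}

defaultComponents <- function() list(ciLikeModel(), orLikeModel())
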