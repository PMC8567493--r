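# Spectra and per-pixel band-ratio computation.
#
# A spectrum is absorbance (arbitrary units) on a strictly increasing
# wavenumber axis (cm^-1). Four dimensionless ratios are computed per
# 6 x 6 um bone pixel: mineral-to-matrix (mmr), carbonate-to-phosphate
# (cpr), crystallinity (1030/1020 sub-band height ratio) and the collagen
# cross-link ratio (1660/1690, xlr).

#' Construct an FTIR spectrum
#'
#' @param wavenumbers Strictly increasing, non-negative wavenumber axis
#'   (cm^-1), length >= 2.
#' @param absorbance Absorbance values (arbitrary units), same length.
#' @return An object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2L)
    stop("spectrum needs at least 2 samples")
  if (length(absorbance) != length(wavenumbers))
    stop("wavenumbers and absorbance differ in length")
  if (any(wavenumbers < 0))
    stop("negative wavenumbers")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumber axis must be strictly increasing")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance),
            class = "ftir_spectrum")
}

#' Default band configuration
#'
#' Integration bands and height-ratio positions for the four bone FTIR
#' parameters: phosphate nu1nu3 area 900-1200 cm^-1, amide I area
#' 1585-1720 cm^-1, carbonate nu2 area 840-890 cm^-1, crystallinity
#' heights at 1030/1020 cm^-1 (half-window 4 cm^-1) and cross-link
#' heights at 1660/1690 cm^-1 (half-window 6 cm^-1). These are
#' conventional FTIR bone-analysis choices and every limit is
#' configurable.
#'
#' @return A list with elements `areas` (named lo/hi intervals) and
#'   `heights` (named numerator/denominator positions + half-window).
#' @export
default_band_config <- function() {
  structure(list(
    areas = list(
      mineral   = c(lo = 900,  hi = 1200),
      matrix    = c(lo = 1585, hi = 1720),
      carbonate = c(lo = 840,  hi = 890)
    ),
    heights = list(
      crystallinity = c(num = 1030, den = 1020, hw = 4),
      xlr           = c(num = 1660, den = 1690, hw = 6)
    )
  ), class = "band_config")
}

validate_band_config <- function(bands, wavenumbers) {
  rng <- range(wavenumbers)
  for (nm in names(bands$areas)) {
    b <- bands$areas[[nm]]
    if (b[["lo"]] >= b[["hi"]])
      stop("band '", nm, "': lo must be < hi")
    if (b[["lo"]] < rng[1] || b[["hi"]] > rng[2])
      stop("band '", nm, "' [", b[["lo"]], ", ", b[["hi"]],
           "] outside wavenumber axis [", rng[1], ", ", rng[2], "]")
  }
  for (nm in names(bands$heights)) {
    h <- bands$heights[[nm]]
    if (h[["hw"]] <= 0) stop("height pair '", nm, "': half-window must be > 0")
    for (pos in h[c("num", "den")])
      if (pos - h[["hw"]] < rng[1] || pos + h[["hw"]] > rng[2])
        stop("height window for '", nm, "' outside wavenumber axis")
  }
  invisible(TRUE)
}

#' Trapezoidal band integral
#'
#' Integrates absorbance over `[lo, hi]` by the trapezoid rule. The band
#' endpoints are included exactly (linear interpolation between the
#' neighbouring samples), so the result is linear in the absorbance.
#'
#' @param spec An `ftir_spectrum`.
#' @param band Numeric `c(lo, hi)` in cm^-1; must lie within the axis.
#' @return The integrated area (absorbance x cm^-1).
#' @export
integrate_band <- function(spec, band) {
  wn <- spec$wavenumbers; ab <- spec$absorbance
  lo <- band[[1]]; hi <- band[[2]]
  if (lo >= hi) stop("band lo must be < hi")
  if (lo < wn[1] || hi > wn[length(wn)])
    stop("band [", lo, ", ", hi, "] outside wavenumber axis")
  inside <- wn > lo & wn < hi
  x <- c(lo, wn[inside], hi)
  y <- c(stats::approx(wn, ab, xout = lo)$y,
         ab[inside],
         stats::approx(wn, ab, xout = hi)$y)
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Peak height within a window
#'
#' Maximum absorbance over `[position - half_window, position + half_window]`.
#'
#' @param spec An `ftir_spectrum`.
#' @param position Window centre (cm^-1).
#' @param half_window Half-width of the window (cm^-1), > 0.
#' @return Maximum absorbance in the window.
#' @export
peak_height <- function(spec, position, half_window) {
  if (half_window <= 0) stop("half_window must be > 0")
  wn <- spec$wavenumbers
  sel <- wn >= position - half_window & wn <= position + half_window
  if (!any(sel)) stop("empty peak window at ", position, " cm^-1")
  max(spec$absorbance[sel])
}

# Band area after subtracting a linear baseline anchored at the band
# endpoints. Linear in the absorbance, which the vectorized map
# extraction exploits.
baseline_band_area <- function(spec, band) {
  wn <- spec$wavenumbers; ab <- spec$absorbance
  lo <- band[[1]]; hi <- band[[2]]
  a_lo <- stats::approx(wn, ab, xout = lo)$y
  a_hi <- stats::approx(wn, ab, xout = hi)$y
  integrate_band(spec, band) - (a_lo + a_hi) / 2 * (hi - lo)
}

#' Per-pixel FTIR parameters from one spectrum
#'
#' Computes the four bone-quality ratios for a single 6 x 6 um pixel.
#' Area ratios use trapezoidal band integrals after subtracting a linear
#' baseline anchored at the band endpoints; height ratios use raw peak
#' maxima inside the configured windows. All four ratios are invariant
#' under scaling of the spectrum by a positive constant. A zero
#' denominator flags the pixel invalid (`valid = FALSE`, the offending
#' ratio `NA`) rather than raising an error, so such pixels can be
#' excluded downstream.
#'
#' @param spec An `ftir_spectrum`.
#' @param bands A band configuration, see [default_band_config()].
#' @param pixel_size Pixel edge length in um (default 6).
#' @return A one-row data.frame with columns `mmr`, `cpr`,
#'   `crystallinity`, `xlr`, `area_um2`, `valid`.
#' @export
compute_pixel_params <- function(spec, bands = default_band_config(),
                                 pixel_size = 6) {
  validate_band_config(bands, spec$wavenumbers)
  mineral <- max(baseline_band_area(spec, bands$areas$mineral), 0)
  matrix_ <- max(baseline_band_area(spec, bands$areas$matrix), 0)
  carb    <- max(baseline_band_area(spec, bands$areas$carbonate), 0)
  hc <- bands$heights$crystallinity
  hx <- bands$heights$xlr
  h1030 <- peak_height(spec, hc[["num"]], hc[["hw"]])
  h1020 <- peak_height(spec, hc[["den"]], hc[["hw"]])
  h1660 <- peak_height(spec, hx[["num"]], hx[["hw"]])
  h1690 <- peak_height(spec, hx[["den"]], hx[["hw"]])

  mmr <- if (matrix_ > 0) mineral / matrix_ else NA_real_
  cpr <- if (mineral > 0) carb / mineral else NA_real_
  cry <- if (h1020 > 0) h1030 / h1020 else NA_real_
  xlr <- if (h1690 > 0) h1660 / h1690 else NA_real_
  # Zero mineral band: mmr is 0 by convention, cpr cannot be formed.
  if (matrix_ > 0 && mineral == 0) mmr <- 0
  valid <- !anyNA(c(mmr, cpr, cry, xlr))
  data.frame(mmr = mmr, cpr = cpr, crystallinity = cry, xlr = xlr,
             area_um2 = pixel_size^2, valid = valid)
}

# Linear functionals (weight vectors on the absorbance samples) that
# reproduce baseline_band_area on a fixed axis, built by probing the
# reference implementation with unit vectors. Cached per (axis, band)
# since maps of one cohort share the wavenumber axis.
.band_weight_cache <- new.env(parent = emptyenv())

band_weight_vector <- function(wavenumbers, band) {
  key <- paste(length(wavenumbers), wavenumbers[1],
               wavenumbers[length(wavenumbers)], band[[1]], band[[2]],
               sep = "|")
  hit <- .band_weight_cache[[key]]
  if (!is.null(hit) && identical(hit$wn, wavenumbers)) return(hit$w)
  w <- band_weight_vector_impl(wavenumbers, band)
  .band_weight_cache[[key]] <- list(wn = wavenumbers, w = w)
  w
}

band_weight_vector_impl <- function(wavenumbers, band) {
  n <- length(wavenumbers)
  w <- numeric(n)
  lo <- band[[1]]; hi <- band[[2]]
  # only samples in (or adjacent to) the band carry weight
  touch <- which(wavenumbers >= lo & wavenumbers <= hi)
  idx <- unique(pmin(pmax(c(min(touch) - 1L, touch, max(touch) + 1L), 1L), n))
  for (i in idx) {
    a <- numeric(n); a[i] <- 1
    w[i] <- baseline_band_area(
      structure(list(wavenumbers = wavenumbers, absorbance = a),
                class = "ftir_spectrum"), band)
  }
  w
}
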