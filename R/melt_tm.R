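#' Melting curve
#'
#' A temperature-fluorescence profile on a strictly increasing,
#' near-uniform temperature grid (nominal instrument spacing 0.2 degrees C;
#' spacing must be uniform within 1%). At least 25 points are required so
#' smoothing and differentiation are meaningful.
#'
#' @param temps temperatures, degrees C.
#' @param fluor fluorescence intensities, arbitrary units.
#' @param condition free-text condition label (e.g. "duplex" vs
#'   "duplex+RNA").
#' @return a `melt_curve`.
#' @export
melt_curve <- function(temps, fluor, condition = "") {
  temps <- as.numeric(temps); fluor <- as.numeric(fluor)
  if (length(temps) != length(fluor)) stop("temps and fluor lengths differ")
  if (length(temps) < 25L) stop("melting curve needs >= 25 points")
  d <- diff(temps)
  if (any(d <= 0)) stop("temperature grid must be strictly increasing")
  if (max(abs(d - mean(d))) > 0.01 * mean(d))
    stop("temperature spacing must be uniform within 1%")
  structure(list(temps = temps, fluor = fluor, condition = condition),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve%s: %d points, %.1f-%.1f C>\n",
              if (nzchar(x$condition)) paste0(" '", x$condition, "'") else "",
              length(x$temps), min(x$temps), max(x$temps)))
  invisible(x)
}

#' Read melting curves from CSV
#'
#' Columns: `temperature`, `fluorescence`, optional `condition` (one curve
#' per condition level).
#'
#' @param path CSV file.
#' @return named list of `melt_curve`.
#' @export
read_melt_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "fluorescence")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (!"condition" %in% names(tab)) tab$condition <- "curve"
  out <- lapply(split(tab, tab$condition), function(g) {
    g <- g[order(g$temperature), , drop = FALSE]
    melt_curve(g$temperature, g$fluorescence, condition = g$condition[1L])
  })
  out[unique(tab$condition)]
}

#' Estimate melting temperature from a melting curve
#'
#' Tm is the standard derivative-peak definition: the temperature where
#' -dF/dT is maximal. Fluorescence is first smoothed by a centered moving
#' average over `smooth_span` points, the negative derivative is taken by
#' central differences, and the peak location is refined to sub-grid
#' resolution by fitting a least-squares quadratic to the derivative over
#' the peak and its `smooth_span` neighbours on each side — without
#' refinement the 0.2 degree C grid would quantize a ~1 degree C
#' triplex-induced shift. A flat profile (no transition) yields
#' an explicit no-estimate result (`ok = FALSE`, `tm = NA`) rather than an
#' error.
#'
#' @param curve a `melt_curve`.
#' @param smooth_span odd integer >= 3; smoothing window in points.
#' @return a `tm_estimate`: list with `tm`, `peak_height`
#'   (-dF/dT at the peak), `window`, `ok`.
#' @export
estimate_tm <- function(curve, smooth_span = 5L) {
  stopifnot(inherits(curve, "melt_curve"))
  smooth_span <- as.integer(smooth_span)
  if (smooth_span < 3L || smooth_span %% 2L == 0L)
    stop("smooth_span must be an odd integer >= 3")
  f <- as.numeric(stats::filter(curve$fluor,
                                rep(1 / smooth_span, smooth_span), sides = 2))
  ok <- !is.na(f)
  f <- f[ok]; t <- curve$temps[ok]
  no_est <- structure(list(tm = NA_real_, peak_height = NA_real_,
                           window = smooth_span, ok = FALSE),
                      class = "tm_estimate")
  if (length(f) < 3L || diff(range(f)) == 0) return(no_est)
  n <- length(f)
  deriv <- -(f[3:n] - f[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  td <- t[2:(n - 1L)]
  if (max(deriv) <= 0) return(no_est)
  i <- which.max(deriv)
  # sub-grid refinement: least-squares parabola over the peak neighbourhood
  # (peak +/- smooth_span derivative points); a symmetric window around a
  # symmetric peak leaves a noiseless estimate exactly on the true Tm,
  # while averaging over ~2*span points suppresses derivative noise far
  # better than 3-point interpolation
  w <- max(1L, i - smooth_span):min(length(deriv), i + smooth_span)
  tm <- td[i]; height <- deriv[i]
  if (length(w) >= 3L) {
    x <- td[w] - td[i]
    co <- unname(stats::lm.fit(cbind(1, x, x^2), deriv[w])$coefficients)
    if (is.finite(co[3L]) && co[3L] < 0) {
      vertex <- -co[2L] / (2 * co[3L])
      if (abs(vertex) <= max(abs(x))) {
        tm <- td[i] + vertex
        height <- co[1L] + co[2L] * vertex + co[3L] * vertex^2
      }
    }
  }
  structure(list(tm = tm, peak_height = height, window = smooth_span,
                 ok = TRUE),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  if (x$ok) cat(sprintf("<tm_estimate: Tm = %.2f C (peak %.3g, window %d)>\n",
                        x$tm, x$peak_height, x$window))
  else cat("<tm_estimate: no estimate (flat profile)>\n")
  invisible(x)
}

#' Tm shift between two conditions
#'
#' `tm(curve_a) - tm(curve_b)`: positive when condition b melts lower, the
#' direction expected when RNA binding to a DNA duplex (triplex formation)
#' destabilizes it. Returns `NA` (with a warning) if either curve has no
#' estimable transition.
#'
#' @param curve_a,curve_b `melt_curve` objects (a = reference, e.g. duplex
#'   alone; b = comparison, e.g. duplex + RNA).
#' @param smooth_span passed to [estimate_tm()].
#' @return numeric Tm difference in degrees C, or `NA`.
#' @export
tm_shift <- function(curve_a, curve_b, smooth_span = 5L) {
  a <- estimate_tm(curve_a, smooth_span)
  b <- estimate_tm(curve_b, smooth_span)
  if (!a$ok || !b$ok) {
    warning("no Tm estimate for at least one curve; returning NA")
    return(NA_real_)
  }
  a$tm - b$tm
}
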