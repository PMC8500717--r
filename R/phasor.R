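#' Convert a frequency response to phasor coordinates
#'
#' The phasor representation plots, at one modulation frequency, the
#' Cartesian pair `d = m cos(phi)`, `n = m sin(phi)`. Single-exponential
#' decays fall on the universal circle of radius 1/2 centered at (1/2, 0);
#' multiexponential or distance-distributed decays fall inside it; intensity
#' mixtures of two populations fall on the chord between the parent phasors.
#' Responses should be background- and time-shift-corrected first (see
#' [correct_response()]).
#'
#' @param response A [frequency_response()].
#' @param frequency Modulation frequency (MHz); must be present in
#'   `response`.
#' @param group Optional label attached to the point.
#' @return A one-row data frame of class `phasor_point` with columns
#'   `frequency_mhz`, `d`, `n`, `group`.
#' @export
to_phasor <- function(response, frequency, group = NA_character_) {
  stopifnot(inherits(response, "frequency_response"))
  i <- match(frequency, response$frequency_mhz)
  if (is.na(i)) stop("frequency ", frequency, " MHz not present in response")
  phi <- response$phase_deg[i] * pi / 180
  out <- data.frame(frequency_mhz = frequency,
                    d = response$modulation[i] * cos(phi),
                    n = response$modulation[i] * sin(phi),
                    group = group)
  class(out) <- c("phasor_point", "data.frame")
  out
}

#' Signed distance from the universal circle
#'
#' Returns `sqrt((d - 1/2)^2 + n^2) - 1/2`: approximately zero for
#' single-exponential decays, negative (inside the circle) for
#' multiexponential or distance-distributed decays.
#'
#' @param point A `phasor_point` (or any data frame with `d`, `n` columns).
#' @return Signed residual, one value per row.
#' @export
universal_circle_residual <- function(point) {
  sqrt((point$d - 0.5)^2 + point$n^2) - 0.5
}

#' Fractional position of a phasor along the chord between two parents
#'
#' Projects `point` orthogonally onto the segment from `parent_a` to
#' `parent_b` and reports the projection as a fraction in `[0, 1]` (clamped).
#' For an intensity mixture of the two parent decays the fraction equals the
#' intensity fraction contributed by `parent_b`; see
#' [phasor_population_fraction()] to convert to a population (mole) fraction.
#' The perpendicular off-chord distance is attached as attribute
#' `off_chord` as a quality metric.
#'
#' @param point,parent_a,parent_b `phasor_point`s at the same frequency.
#' @return Fraction along the chord (0 at `parent_a`, 1 at `parent_b`).
#' @export
chord_fraction <- function(point, parent_a, parent_b) {
  v <- c(parent_b$d - parent_a$d, parent_b$n - parent_a$n)
  len2 <- sum(v^2)
  if (len2 < 1e-20) stop("parent phasors coincide; chord is degenerate")
  if (!isTRUE(all.equal(parent_a$frequency_mhz, parent_b$frequency_mhz)) ||
      !isTRUE(all.equal(point$frequency_mhz, parent_a$frequency_mhz)))
    stop("point and parents must share one modulation frequency")
  w <- c(point$d - parent_a$d, point$n - parent_a$n)
  t <- sum(w * v) / len2
  off <- abs(w[1] * v[2] - w[2] * v[1]) / sqrt(len2)
  structure(min(max(t, 0), 1), off_chord = off)
}

#' Convert an intensity chord fraction to a population fraction
#'
#' The chord fraction weighs each population by its relative steady-state
#' brightness (quenched populations contribute less intensity per molecule).
#' Given the relative brightness of population b versus population a
#' (the ratio of their `J` normalization factors, e.g. from fitted models via
#' [model_response()] kernels or `1 - E` ratios), this inverts the intensity
#' weighting to a mole fraction.
#'
#' @param fraction Intensity fraction along the chord (from
#'   [chord_fraction()]).
#' @param relative_brightness Brightness of population b relative to
#'   population a (dimensionless, > 0).
#' @return Population fraction of b.
#' @export
phasor_population_fraction <- function(fraction, relative_brightness) {
  stopifnot(relative_brightness > 0, fraction >= 0, fraction <= 1)
  x <- fraction / relative_brightness
  x / (x + (1 - fraction))
}

#' Phasor centroid of a group of per-pixel points
#'
#' Arithmetic mean of the (d, n) coordinates, the standard way a pixel cloud
#' is summarized before chord analysis.
#'
#' @param points Data frame with `d`, `n` (and optionally `group`).
#' @param by Optional grouping column name; when given, one centroid per
#'   group is returned.
#' @return A `phasor_point` data frame of centroids.
#' @export
phasor_centroid <- function(points, by = NULL) {
  if (is.null(by)) {
    out <- data.frame(frequency_mhz = points$frequency_mhz[1],
                      d = mean(points$d), n = mean(points$n),
                      group = if ("group" %in% names(points)) points$group[1] else NA)
  } else {
    sp <- split(points, points[[by]])
    out <- do.call(rbind, lapply(sp, function(g)
      data.frame(frequency_mhz = g$frequency_mhz[1], d = mean(g$d),
                 n = mean(g$n), group = g[[by]][1])))
    rownames(out) <- NULL
  }
  class(out) <- c("phasor_point", "data.frame")
  out
}
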