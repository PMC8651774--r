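#' Mean diameter from area
#'
#' The equivalent-disc diameter `sqrt(area / pi)` — note this is the
#' device's convention (radius-like scale of the equal-area circle), kept
#' exactly as defined.
#'
#' @param area cell area, um^2 (vectorized), > 0.
#' @return mean diameter, um.
#' @examples mean_diameter(pi)  # 1
#' @export
mean_diameter <- function(area) {
  if (any(!is.finite(area)) || any(area <= 0)) abort("area must be positive")
  sqrt(area / pi)
}

#' Circularity shape descriptor
#'
#' `4 * pi * area / perimeter^2`; equals 1 for a perfect circle and falls
#' below 1 as the outline departs from circular. With the Crofton perimeter
#' estimator, large rasterized discs land within about 0.03 of 1; convex
#' shapes can overshoot 1 by the estimator tolerance (about 0.05).
#'
#' @param area area, um^2 (or px^2), > 0. Vectorized.
#' @param perimeter perimeter in matching units, > 0.
#' @return dimensionless circularity.
#' @examples circularity(pi * 25, 2 * pi * 5)  # 1
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0)) abort("area must be positive")
  if (any(!is.finite(perimeter)) || any(perimeter <= 0))
    abort("perimeter must be positive")
  4 * pi * area / perimeter^2
}

# Convex hull of the pixel-corner points of a region, as an (h x 2)
# matrix of (row, col) coordinates in pixel units, counter-clockwise.
corner_hull <- function(px) {
  r <- px[, 1]; cc <- px[, 2]
  pts <- cbind(
    row = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
    col = c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
  )
  pts <- unique(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  pts[h, , drop = FALSE]
}

# Shoelace area of a polygon given as (row, col) vertices.
polygon_area <- function(v) {
  x <- v[, 2]; y <- v[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Maximum and minimum Feret (caliper) diameters of a region
#'
#' Caliper widths of the convex hull of the pixel corner points, so a
#' region has nonzero extent in every direction. The maximum Feret is the
#' hull diameter (exact, equivalent to rotating calipers); the minimum is
#' the smallest width over hull-edge normals (exact for convex polygons).
#' A single-pixel region returns both Ferets equal to the pixel size, by
#' convention.
#'
#' @param pixels integer matrix of (row, col) pixel coordinates, or an
#'   `rbc_regions` row's `pixels[[i]]`.
#' @param pixel_scale um per pixel.
#' @return named numeric: `max_feret`, `min_feret` (um).
#' @export
feret_extremes <- function(pixels, pixel_scale = 1) {
  n <- nrow(pixels)
  if (n == 0L) abort("empty region")
  if (n == 1L)
    return(c(max_feret = pixel_scale, min_feret = pixel_scale))
  hull <- corner_hull(pixels)
  x <- hull[, 2]; y <- hull[, 1]
  # max: hull diameter
  dmax <- sqrt(max(outer(x, x, `-`)^2 + outer(y, y, `-`)^2))
  # min: smallest width over edge normals
  h <- nrow(hull)
  nxt <- c(seq_len(h)[-1], 1L)
  ex <- x[nxt] - x; ey <- y[nxt] - y
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 0
  widths <- vapply(which(ok), function(i) {
    nxv <- -ey[i] / len[i]; nyv <- ex[i] / len[i]
    pr <- (x - x[i]) * nxv + (y - y[i]) * nyv
    max(pr) - min(pr)
  }, numeric(1))
  c(max_feret = dmax * pixel_scale, min_feret = min(widths) * pixel_scale)
}

#' Per-cell morphometry in physical units
#'
#' Converts segmented regions into the device's per-cell descriptors:
#' area (um^2), perimeter (um), mean diameter `sqrt(area/pi)`, Feret
#' extremes, axis ratio `MaxFeret/MinFeret`, and circularity
#' `4*pi*area/perimeter^2`. Regions flagged as stacked or touching the
#' border are excluded by default.
#'
#' @param regions an `rbc_regions` tibble ([segment_frame()] output).
#' @param pixel_scale um per pixel; defaults to the regions attribute.
#' @param include_rejected,include_border include flagged regions.
#' @return tibble: `cell_id`, `area`, `perimeter`, `mean_diameter`,
#'   `max_feret`, `min_feret`, `axis_ratio`, `circularity`,
#'   `centroid_x`, `centroid_y` (um, x = column direction), `area_px`.
#' @export
measure_cells <- function(regions, pixel_scale = attr(regions, "pixel_scale"),
                          include_rejected = FALSE, include_border = FALSE) {
  if (is.null(pixel_scale)) abort("pixel_scale is required")
  keep <- rep(TRUE, nrow(regions))
  if (!include_rejected) keep <- keep & !regions$rejected_stacked
  if (!include_border) keep <- keep & !regions$touches_border
  r <- regions[keep, ]
  if (nrow(r) == 0L) {
    return(tibble(cell_id = integer(), area = numeric(), perimeter = numeric(),
                  mean_diameter = numeric(), max_feret = numeric(),
                  min_feret = numeric(), axis_ratio = numeric(),
                  circularity = numeric(), centroid_x = numeric(),
                  centroid_y = numeric(), area_px = integer()))
  }
  fer <- t(vapply(r$pixels, feret_extremes, numeric(2),
                  pixel_scale = pixel_scale))
  area <- r$area_px * pixel_scale^2
  per <- r$perimeter_px * pixel_scale
  tibble(
    cell_id = r$label_id,
    area = area,
    perimeter = per,
    mean_diameter = mean_diameter(area),
    max_feret = fer[, 1],
    min_feret = fer[, 2],
    axis_ratio = fer[, 1] / fer[, 2],
    circularity = circularity(area, per),
    centroid_x = (r$centroid_col - 0.5) * pixel_scale,
    centroid_y = (r$centroid_row - 0.5) * pixel_scale,
    area_px = r$area_px
  )
}

#' Population summary: the 8-dimensional parameter vector
#'
#' Arithmetic means of diameter, circularity and axis ratio with their
#' distribution widths, plus the deformability mean and width when per-cell
#' Dr values are supplied. Distribution width follows the hematology RDW
#' convention: `100 * SD / mean` (coefficient of variation, percent) with
#' the sample SD (n - 1); `width = "sd"` switches to the plain SD.
#'
#' @param cells per-cell morphometry tibble from [measure_cells()].
#' @param dr optional per-cell deformation indices (any length >= 1;
#'   typically from [match_cells()] pairs).
#' @param volume_ml optional sampled volume; when given, concentration =
#'   `n_cells / volume_ml` (cells/mL).
#' @param width `"cv"` (default, percent) or `"sd"` distribution width.
#' @return one-row tibble of class `rbc_population_summary`: `n_cells`,
#'   `concentration`, `diameter_mean`, `diameter_dw`, `circularity_mean`,
#'   `circularity_dw`, `axis_ratio_mean`, `axis_ratio_dw`, `dr_mean`,
#'   `dr_dw`.
#' @seealso [population_vector()] for the fixed-order 8-vector.
#' @export
summarize_population <- function(cells, dr = NULL, volume_ml = NULL,
                                 width = c("cv", "sd")) {
  width <- match.arg(width)
  if (nrow(cells) == 0L) abort("cannot summarize an empty population")
  dw <- function(x) {
    m <- mean(x)
    s <- if (length(x) > 1L) sd(x) else 0
    if (width == "sd") return(s)
    if (m == 0) abort("distribution width undefined for zero mean")
    100 * s / m
  }
  out <- tibble(
    n_cells = nrow(cells),
    concentration = if (is.null(volume_ml)) NA_real_ else nrow(cells) / volume_ml,
    diameter_mean = mean(cells$mean_diameter),
    diameter_dw = dw(cells$mean_diameter),
    circularity_mean = mean(cells$circularity),
    circularity_dw = dw(cells$circularity),
    axis_ratio_mean = mean(cells$axis_ratio),
    axis_ratio_dw = dw(cells$axis_ratio),
    dr_mean = if (is.null(dr)) NA_real_ else mean(dr),
    dr_dw = if (is.null(dr)) NA_real_ else dw(dr)
  )
  class(out) <- c("rbc_population_summary", class(out))
  out
}

#' The fixed-order 8-parameter vector of a population summary
#'
#' Order (documented contract, matching the classifier's 8 variable
#' inputs): diameter mean, diameter width, circularity mean, circularity
#' width, axis-ratio mean, axis-ratio width, Dr mean, Dr width.
#'
#' @param summary an `rbc_population_summary`.
#' @return named numeric vector of length 8.
#' @export
population_vector <- function(summary) {
  keys <- c("diameter_mean", "diameter_dw", "circularity_mean",
            "circularity_dw", "axis_ratio_mean", "axis_ratio_dw",
            "dr_mean", "dr_dw")
  setNames(as.numeric(summary[1, keys]), keys)
}

#' Imaging-chamber volume for concentration estimates
#'
#' Field area times chamber depth (default 20 um, the chip cavity depth),
#' in mL; multiply the resulting concentration by any dilution factor
#' applied to the sample.
#'
#' @param field_width,field_height imaged field, um.
#' @param depth_um chamber depth, um (default 20).
#' @return volume in mL.
#' @export
chamber_volume_ml <- function(field_width, field_height, depth_um = 20) {
  field_width * field_height * depth_um * 1e-12
}
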