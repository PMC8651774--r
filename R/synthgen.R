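#' Scene configuration for the synthetic RBC field generator
#'
#' Describes one simulated optical field: physical size, pixel scale,
#' cell count and stacking rate, the compression setting, and the imaging
#' nuisances (sensor noise, illumination gradient). Field dimensions must be
#' integer multiples of the pixel scale so the raster size is exact.
#'
#' Defaults emulate a small sub-field of the device's view at 0.25 um/px
#' (a 7.5 um cell spans 30 px, which keeps perimeter estimation stable),
#' with mild sensor noise and a gentle illumination ramp.
#'
#' @param field_width,field_height physical field size, um.
#' @param pixel_scale um per pixel.
#' @param n_cells number of cells to place.
#' @param stacking_fraction fraction of cells placed overlapping a host cell
#'   (both members of an overlap are flagged `is_stacked` in the truth).
#' @param stress_level `"none"`, `"low"` or `"high"` compression setting.
#' @param noise_sd additive Gaussian sensor noise, gray levels (8-bit).
#' @param illumination_gradient fractional left-to-right linear shading
#'   (0 = flat field).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return an object of class `rbc_scene_config`.
#' @export
scene_config <- function(field_width = 250, field_height = 250,
                         pixel_scale = 0.25, n_cells = 150,
                         stacking_fraction = 0.1,
                         stress_level = c("high", "low", "none"),
                         noise_sd = 4, illumination_gradient = 0.05,
                         seed = 1L) {
  stress_level <- match.arg(stress_level)
  stopifnot_scalar_pos(pixel_scale, "pixel_scale")
  stopifnot_scalar_pos(field_width, "field_width")
  stopifnot_scalar_pos(field_height, "field_height")
  if (n_cells < 0) abort("n_cells must be >= 0")
  if (stacking_fraction < 0 || stacking_fraction > 1)
    abort("stacking_fraction must be in [0, 1]")
  nc <- field_width / pixel_scale
  nr <- field_height / pixel_scale
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    abort("field dimensions must be integer multiples of pixel_scale")
  structure(list(
    field_width = field_width, field_height = field_height,
    pixel_scale = pixel_scale, n_cells = as.integer(n_cells),
    stacking_fraction = stacking_fraction, stress_level = stress_level,
    noise_sd = noise_sd, illumination_gradient = illumination_gradient,
    seed = as.integer(seed)
  ), class = "rbc_scene_config")
}

#' Sample a ground-truth cell population (pre-compression geometry)
#'
#' Draws per-cell diameter and axis ratio from the profile's truncated
#' normal distributions (diameter truncated at zero, axis ratio reflected
#' into `>= 1`), derives the pre-compression area and the ellipse
#' circularity, and returns one truth record per cell. Centroids are
#' assigned later, when the scene is rendered.
#'
#' @param profile an [class_profile()].
#' @param n number of cells (>= 0).
#' @param seed integer seed; sampling is deterministic given it.
#' @return tibble with one row per cell: `cell_id`, `true_diameter` (um),
#'   `true_axis_ratio`, `true_circularity`, `true_area_pre` (um^2),
#'   `true_area_post`, `true_dr` (NA until [apply_stress()]), `orientation`
#'   (rad), `is_stacked`, `clipped`, `centroid_x`/`centroid_y` (um, NA until
#'   rendering).
#' @export
sample_population <- function(profile, n, seed = 1L) {
  if (!inherits(profile, "rbc_class_profile")) abort("profile must be an rbc_class_profile")
  if (n < 0) abort("n must be >= 0")
  n <- as.integer(n)
  with_seed(seed, {
    d <- rtruncnorm_pos(n, profile$diameter_mean, profile$diameter_sd)
    q <- rnorm(n, profile$axis_ratio_mean, profile$axis_ratio_sd)
    q <- 1 + abs(q - 1)                       # reflect into q >= 1
    phi <- runif(n, 0, pi)
    tibble(
      cell_id = seq_len(n),
      class_label = rep(profile$class_label, n),
      true_diameter = d,
      true_axis_ratio = q,
      true_circularity = if (n) ellipse_circularity(q) else numeric(0),
      true_area_pre = pi * (d / 2)^2,
      true_area_post = NA_real_,
      true_dr = NA_real_,
      orientation = phi,
      is_stacked = rep(FALSE, n),
      clipped = rep(FALSE, n),
      centroid_x = rep(NA_real_, n),
      centroid_y = rep(NA_real_, n)
    )
  })
}

#' Apply the compression setting to a sampled population
#'
#' Samples a per-cell deformation index Dr from the profile's distribution
#' for the chosen stress level and sets the post-compression area to
#' `area_pre * Dr^2` (in-plane isotropic expansion: the compressed cell
#' spreads laterally, its shape preserved). `stress_level = "none"` fixes
#' Dr = 1. Negative draws are resampled (documented retry cap of 100 rounds).
#'
#' @param records tibble from [sample_population()].
#' @param profile the [class_profile()] the records came from.
#' @param stress_level `"none"`, `"low"` or `"high"`.
#' @param seed integer seed.
#' @return `records` with `true_dr` and `true_area_post` filled in.
#' @export
apply_stress <- function(records, profile,
                         stress_level = c("high", "low", "none"), seed = 1L) {
  stress_level <- match.arg(stress_level)
  n <- nrow(records)
  dr <- switch(stress_level,
    none = rep(1, n),
    low  = with_seed(seed, rtruncnorm_pos(n, profile$dr_mean, profile$dr_sd)),
    high = with_seed(seed, rtruncnorm_pos(n, profile$dr_mean_high, profile$dr_sd_high))
  )
  records$true_dr <- dr
  records$true_area_post <- records$true_area_pre * dr^2
  records
}

# Rendering photometry: bright background, darker cell with a dark rim and
# a brighter (biconcave) center. Values are package constants, not knobs the
# device specifies.
.render_const <- list(background = 220, depth = 140, concavity = 0.45,
                      gap_px = 3)

#' Render a pre/post image pair with per-cell ground truth
#'
#' Places the cells in the field (uniform random positions with a minimum
#' separation; stacked cells are deliberately placed overlapping a host),
#' renders each as an ellipse with a biconcave radial intensity profile
#' (dark rim, brighter center) on a bright background, applies the linear
#' illumination gradient and additive Gaussian sensor noise, and clamps to
#' 8-bit. Cell placement is identical in the two frames (cells are
#' immobilized in the gel); only the in-plane size differs, by the per-cell
#' Dr.
#'
#' @param config an [scene_config()].
#' @param records stressed records from [apply_stress()].
#' @return list with `pre` and `post` [image_frame()]s and `truth`
#'   (the records with centroids filled in), class `rbc_scene`.
#' @export
render_pair <- function(config, records) {
  ps <- config$pixel_scale
  nr <- as.integer(round(config$field_height / ps))
  nc <- as.integer(round(config$field_width / ps))
  n <- nrow(records)
  if (n > 0) {
    if (anyNA(records$true_area_post))
      abort("records lack post-stress geometry; run apply_stress() first")
    rad_post <- sqrt(records$true_area_post / pi * records$true_axis_ratio)
    if (2 * max(rad_post) > min(config$field_width, config$field_height))
      abort("field smaller than the largest cell; enlarge the field")
  }

  seeds <- seed_stream(config$seed, 3L)
  records <- .place_cells(records, config, seeds[1])

  pre  <- .render_frame(records, config, nr, nc, which = "pre",
                        noise_seed = seeds[2])
  post <- .render_frame(records, config, nr, nc, which = "post",
                        noise_seed = seeds[3])
  structure(list(
    pre  = image_frame(pre, ps, role = "pre_stress"),
    post = image_frame(post, ps, role = "post_stress"),
    truth = records,
    config = config
  ), class = "rbc_scene")
}

# Dart-throwing placement. Non-stacked cells keep a guard gap so their
# rendered masks stay disjoint; stacked cells are attached to a host at
# 0.6-0.95 of the sum of radii so the pair merges into one region.
.place_cells <- function(records, config, seed) {
  n <- nrow(records)
  if (n == 0L) return(records)
  ps <- config$pixel_scale
  W <- config$field_width; H <- config$field_height
  n_stack <- as.integer(round(config$stacking_fraction * n))
  stack_idx <- if (n_stack > 0) seq(n - n_stack + 1L, n) else integer(0)
  # post-stress major semi-axis bounds the rendered footprint in either frame
  r_eff <- sqrt(records$true_area_post / pi * records$true_axis_ratio)
  gap <- .render_const$gap_px * ps
  with_seed(seed, {
    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
    placed <- integer(0)
    for (i in seq_len(n)) {
      stacked_i <- i %in% stack_idx
      hosts <- setdiff(placed, stack_idx)
      ok <- FALSE
      for (try in seq_len(4000L)) {
        if (stacked_i && length(hosts) > 0) {
          h <- hosts[sample.int(length(hosts), 1L)]
          dfac <- runif(1, 0.6, 0.95)
          dist <- dfac * (r_eff[i] + r_eff[h])
          ang <- runif(1, 0, 2 * pi)
          xi <- x[h] + dist * cos(ang); yi <- y[h] + dist * sin(ang)
          others <- setdiff(placed, h)
        } else {
          xi <- runif(1, r_eff[i] + gap, W - r_eff[i] - gap)
          yi <- runif(1, r_eff[i] + gap, H - r_eff[i] - gap)
          others <- placed
        }
        inside <- xi > r_eff[i] && xi < W - r_eff[i] &&
                  yi > r_eff[i] && yi < H - r_eff[i]
        clear <- !length(others) ||
          all(sqrt((x[others] - xi)^2 + (y[others] - yi)^2) >
                r_eff[others] + r_eff[i] + gap)
        if (inside && clear) { ok <- TRUE; break }
      }
      if (!ok) abort("could not place all cells; reduce n_cells or enlarge the field")
      x[i] <- xi; y[i] <- yi
      if (stacked_i && length(hosts) > 0) records$is_stacked[c(i, h)] <- TRUE
      placed <- c(placed, i)
    }
    records$centroid_x <- x
    records$centroid_y <- y
  })
  records
}

.render_frame <- function(records, config, nr, nc, which, noise_seed) {
  ps <- config$pixel_scale
  k <- .render_const
  img <- matrix(k$background, nr, nc)
  scale <- if (which == "pre") rep(1, nrow(records)) else records$true_dr
  for (i in seq_len(nrow(records))) {
    d <- records$true_diameter[i] * scale[i]
    q <- records$true_axis_ratio[i]
    a <- (d / 2) * sqrt(q); b <- (d / 2) / sqrt(q)
    cx <- records$centroid_x[i]; cy <- records$centroid_y[i]
    phi <- records$orientation[i]
    rows <- max(1L, floor((cy - a) / ps)):min(nr, ceiling((cy + a) / ps))
    cols <- max(1L, floor((cx - a) / ps)):min(nc, ceiling((cx + a) / ps))
    yy <- (rows - 0.5) * ps - cy
    xx <- (cols - 0.5) * ps - cx
    dx <- matrix(xx, length(rows), length(cols), byrow = TRUE)
    dy <- matrix(yy, length(rows), length(cols))
    u <- cos(phi) * dx + sin(phi) * dy
    v <- -sin(phi) * dx + cos(phi) * dy
    m <- (u / a)^2 + (v / b)^2
    inside <- m <= 1
    if (!any(inside)) next
    val <- k$background - k$depth * (k$concavity + (1 - k$concavity) * m)
    patch <- img[rows, cols, drop = FALSE]
    patch[inside] <- pmin(patch[inside], val[inside])
    img[rows, cols] <- patch
  }
  if (config$illumination_gradient != 0) {
    ramp <- 1 + config$illumination_gradient * (((seq_len(nc) - 0.5) / nc) - 0.5)
    img <- sweep(img, 2, ramp, `*`)
  }
  if (config$noise_sd > 0) {
    img <- img + with_seed(noise_seed, matrix(rnorm(nr * nc, 0, config$noise_sd), nr, nc))
  }
  matrix(as.integer(pmax(0, pmin(255, round(img)))), nr, nc)
}

#' Simulate one ground-truthed scene
#'
#' Convenience wrapper: sample a population for `profile`, apply the
#' configured compression, and render the pre/post pair. Fully deterministic
#' given `config$seed`.
#'
#' @param profile an [class_profile()].
#' @param config an [scene_config()].
#' @return an `rbc_scene` (see [render_pair()]).
#' @export
simulate_scene <- function(profile, config = scene_config()) {
  seeds <- seed_stream(config$seed, 10L)
  rec <- sample_population(profile, config$n_cells, seed = seeds[4])
  rec <- apply_stress(rec, profile, config$stress_level, seed = seeds[5])
  render_pair(config, rec)
}

#' Write a scene to disk
#'
#' Writes `pre.<fmt>` and `post.<fmt>` (8-bit), `truth.csv`, and
#' `config.yaml` into `dir`.
#'
#' @param scene an `rbc_scene`.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image_frame(scene$pre, file.path(dir, paste0("pre.", format)))
  write_image_frame(scene$post, file.path(dir, paste0("post.", format)))
  utils::write.csv(scene$truth[setdiff(names(scene$truth), "orientation")],
                   file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(scene$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @export
print.rbc_scene <- function(x, ...) {
  cat(sprintf("<rbc_scene> %d cells, %dx%d px @ %.3g um/px, stress=%s\n",
              nrow(x$truth), nrow(x$pre$pixels), ncol(x$pre$pixels),
              x$pre$pixel_scale, x$config$stress_level))
  invisible(x)
}
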