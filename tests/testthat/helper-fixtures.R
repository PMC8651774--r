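# Fixtures built in code: rasterized shapes and small noise-free scenes.

# Pixel coordinates of a rasterized ellipse (pixel-center inclusion).
raster_ellipse <- function(diameter_um, axis_ratio = 1, phi = 0,
                           pixel_scale = 0.25) {
  a <- diameter_um / 2 * sqrt(axis_ratio)
  b <- diameter_um / 2 / sqrt(axis_ratio)
  n <- ceiling(2 * a / pixel_scale) + 6
  cen <- (n / 2) * pixel_scale
  xs <- (seq_len(n) - 0.5) * pixel_scale
  dx <- outer(rep(1, n), xs - cen)
  dy <- outer(xs - cen, rep(1, n))
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  which((u / a)^2 + (v / b)^2 <= 1, arr.ind = TRUE)
}

# Logical mask with a disc of given radius (pixels) centred in a square.
disc_mask <- function(radius_px, pad = 3L, centre = NULL, side = NULL,
                      pixel_scale = 1) {
  side <- side %||% (2L * (radius_px + pad) + 1L)
  centre <- centre %||% c((side + 1) / 2, (side + 1) / 2)
  rc <- expand.grid(r = seq_len(side), c = seq_len(side))
  m <- matrix((rc$r - centre[1])^2 + (rc$c - centre[2])^2 <= radius_px^2,
              side, side)
  attr(m, "pixel_scale") <- pixel_scale
  m
}

# A clean (noise- and gradient-free) scene for recovery checks.
clean_scene <- function(profile = class_profile("healthy"), n_cells = 30,
                        field = 120, pixel_scale = 0.25,
                        stress = "high", stacking = 0, seed = 1) {
  simulate_scene(profile, scene_config(
    field_width = field, field_height = field, pixel_scale = pixel_scale,
    n_cells = n_cells, stacking_fraction = stacking, stress_level = stress,
    noise_sd = 0, illumination_gradient = 0, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
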