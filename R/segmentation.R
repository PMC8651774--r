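#' Convert a raw frame to 8-bit grayscale
#'
#' RGB frames are collapsed with the ITU-R 601 luma weights by default and
#' rounded back to 8-bit; already-grayscale frames pass through unchanged.
#'
#' @param frame an [image_frame()], grayscale or RGB.
#' @param weights length-3 channel weights (summing to 1).
#' @return a grayscale [image_frame()].
#' @export
to_grayscale <- function(frame, weights = c(0.299, 0.587, 0.114)) {
  px <- frame$pixels
  if (is.matrix(px)) return(frame)
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    abort("expected a grayscale matrix or a 3-channel RGB array")
  g <- weights[1] * px[, , 1] + weights[2] * px[, , 2] + weights[3] * px[, , 3]
  g <- matrix(as.integer(pmax(0, pmin(255, round(g)))), dim(px)[1], dim(px)[2])
  image_frame(g, frame$pixel_scale, frame$role)
}

#' Automatic intensity and contrast adjustment
#'
#' Percentile-based linear rescale: the `p_low` quantile maps to 0 and the
#' `p_high` quantile to 255 (values beyond them clamp). Strictly monotone in
#' the input intensities, so thresholding decisions are unaffected in order.
#' A constant image is returned unchanged with a warning.
#'
#' @param frame grayscale [image_frame()].
#' @param p_low,p_high rescale percentiles (defaults 0.01 and 0.99).
#' @return adjusted [image_frame()].
#' @export
adjust_intensity <- function(frame, p_low = 0.01, p_high = 0.99) {
  px <- frame$pixels
  lo <- quantile(px, p_low, names = FALSE)
  hi <- quantile(px, p_high, names = FALSE)
  if (hi <= lo) {
    warn("constant (or near-constant) image; intensity adjustment skipped")
    return(frame)
  }
  out <- (px - lo) / (hi - lo) * 255
  out <- matrix(as.integer(pmax(0, pmin(255, round(out)))), nrow(px), ncol(px))
  image_frame(out, frame$pixel_scale, frame$role)
}

#' Threshold a grayscale frame into a cell mask
#'
#' Default polarity is cells-darker-than-background: foreground pixels are
#' those at or below the threshold. `method = "otsu"` picks the threshold
#' maximizing between-class variance on the 256-bin histogram;
#' `method = "fixed"` uses the supplied `threshold` (gray levels).
#'
#' @param frame grayscale [image_frame()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold gray level for `method = "fixed"`.
#' @param invert set `TRUE` when cells are brighter than the background.
#' @return logical mask matrix with attributes `pixel_scale` and
#'   `threshold`.
#' @export
binarize <- function(frame, method = c("otsu", "fixed"), threshold = NULL,
                     invert = FALSE) {
  method <- match.arg(method)
  px <- frame$pixels
  thr <- switch(method,
    otsu = otsu_threshold(px),
    fixed = {
      if (is.null(threshold)) abort("method = 'fixed' needs a threshold")
      threshold
    }
  )
  mask <- if (invert) px > thr else px <= thr
  if (!any(mask)) warn("binarize produced an empty foreground")
  attr(mask, "pixel_scale") <- frame$pixel_scale
  attr(mask, "threshold") <- as.numeric(thr)
  mask
}

#' Fill holes in a binary mask
#'
#' Background components not connected to the image border become
#' foreground (foreground 8-connected, background 4-connected). Idempotent.
#' Recovers the full cell disc when the bright biconcave center thresholds
#' out as a hole.
#'
#' @param mask logical matrix.
#' @return logical matrix, same attributes.
#' @export
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  out <- matrix(as.logical(filled), nrow(mask), ncol(mask))
  attr(out, "pixel_scale") <- attr(mask, "pixel_scale")
  out
}

# Otsu threshold on the 256-bin 8-bit histogram via cumulative moments:
# the gray level t maximizing the between-class variance
# w0(t) w1(t) (mu0(t) - mu1(t))^2 when splitting into [0, t] and [t+1, 255].
otsu_threshold <- function(px) {
  h <- tabulate(as.vector(px) + 1L, 256L)
  p <- h / sum(h)
  lv <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * lv)
  mt <- m0[256]
  t_all <- seq_len(255L)                       # candidate splits t = 0..254
  w0t <- w0[t_all]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(0, 255)
  bcv[valid] <- (mt * w0t[valid] - m0[t_all][valid])^2 /
    (w0t[valid] * w1t[valid])
  which.max(bcv) - 1L
}

# Crofton 4-direction perimeter of a logical matrix, in pixel units.
# Counts boundary crossings along rows, columns and both diagonals of a
# background-padded mask. Exact-in-the-limit for discs; squares come out
# ~8% short (isotropic estimator), documented with the morphometry ops.
crofton_perimeter <- function(m) {
  nr <- nrow(m) + 2L; nc <- ncol(m) + 2L
  p <- matrix(FALSE, nr, nc)
  p[2:(nr - 1L), 2:(nc - 1L)] <- m
  i0   <- sum(p[, -1L] != p[, -nc])
  i90  <- sum(p[-1L, ] != p[-nr, ])
  i45  <- sum(p[-1L, -1L] != p[-nr, -nc])
  i135 <- sum(p[-1L, -nc] != p[-nr, -1L])
  (pi / 8) * (i0 + i90 + (i45 + i135) / sqrt(2))
}

#' Label connected cell regions and measure raw pixel properties
#'
#' 8-connected components of the foreground. Each region carries its pixel
#' set, pixel area, Crofton 4-direction perimeter, real-valued centroid
#' (row, col) and a border-contact flag.
#'
#' @param mask logical matrix (with a `pixel_scale` attribute, as produced
#'   by [binarize()]/[fill_holes()]), or any logical matrix plus
#'   `pixel_scale`.
#' @param pixel_scale um per pixel; defaults to the mask attribute.
#' @return tibble of class `rbc_regions`: `label_id`, `area_px`,
#'   `perimeter_px`, `centroid_row`, `centroid_col`, `touches_border`,
#'   `rejected_stacked` (initialized `FALSE`), and a `pixels` list-column of
#'   (row, col) integer matrices. Attributes: `pixel_scale`, `mask_dim`.
#' @export
label_regions <- function(mask, pixel_scale = attr(mask, "pixel_scale")) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  L <- matrix(as.integer(lab), nr, nc)
  nlab <- max(L)
  if (nlab > 0L) {
    # bwlabel is 4-connected; merge labels that touch diagonally
    a1 <- L[-nr, -nc]; b1 <- L[-1L, -1L]
    a2 <- L[-nr, -1L]; b2 <- L[-1L, -nc]
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(edges) > 0L) {
      g <- igraph::make_empty_graph(n = nlab, directed = FALSE)
      g <- igraph::add_edges(g, t(edges))
      map <- igraph::components(g)$membership
      L[L > 0L] <- map[L[L > 0L]]
    }
  }
  fg <- which(L > 0L)
  if (length(fg) == 0L) {
    out <- tibble(label_id = integer(), area_px = integer(),
                  perimeter_px = numeric(), centroid_row = numeric(),
                  centroid_col = numeric(), touches_border = logical(),
                  rejected_stacked = logical(), pixels = list())
  } else {
    labs <- L[fg]
    rows <- (fg - 1L) %% nr + 1L
    cols <- (fg - 1L) %/% nr + 1L
    ord <- order(labs, fg)
    labs <- labs[ord]; rows <- rows[ord]; cols <- cols[ord]
    idx <- split(seq_along(labs), labs)
    out <- purrr::map_dfr(seq_along(idx), function(k) {
      ii <- idx[[k]]
      r <- rows[ii]; cc <- cols[ii]
      rmin <- min(r); rmax <- max(r); cmin <- min(cc); cmax <- max(cc)
      crop <- matrix(FALSE, rmax - rmin + 1L, cmax - cmin + 1L)
      crop[cbind(r - rmin + 1L, cc - cmin + 1L)] <- TRUE
      tibble(
        label_id = k,
        area_px = length(ii),
        perimeter_px = crofton_perimeter(crop),
        centroid_row = mean(r),
        centroid_col = mean(cc),
        touches_border = any(r == 1L | r == nr | cc == 1L | cc == nc),
        rejected_stacked = FALSE,
        pixels = list(cbind(row = r, col = cc))
      )
    })
  }
  attr(out, "pixel_scale") <- pixel_scale
  attr(out, "mask_dim") <- c(nr, nc)
  class(out) <- c("rbc_regions", class(out))
  out
}

#' Remove stacked (overlapping) cells from a region list
#'
#' A region is rejected when any enabled rule fires: pixel area above
#' `k_area` times the median region area (skipped when fewer than 3 regions
#' are present), solidity (pixel area over convex-hull area) below `s_min`,
#' or circularity below `c_min`. Overlapping cells are removed, not split.
#' Idempotent: re-applying to the kept set rejects nothing new given the
#' same median.
#'
#' @param regions an `rbc_regions` tibble from [label_regions()].
#' @param k_area,s_min,c_min rule thresholds (defaults 1.8, 0.85, 0.6).
#' @param use_area,use_solidity,use_circularity individual rule switches.
#' @return list with `kept` and `rejected` `rbc_regions` tibbles (the
#'   `rejected_stacked` flag is set accordingly); `kept` plus `rejected`
#'   partitions the input.
#' @export
remove_stacked <- function(regions, k_area = 1.8, s_min = 0.85, c_min = 0.6,
                           use_area = TRUE, use_solidity = TRUE,
                           use_circularity = TRUE) {
  n <- nrow(regions)
  if (n == 0L) {
    return(list(kept = regions, rejected = regions[0, ]))
  }
  rej <- rep(FALSE, n)
  if (use_area && n >= 3L) {
    rej <- rej | regions$area_px > k_area * median(regions$area_px)
  }
  if (use_solidity || use_circularity) {
    sol <- purrr::map_dbl(regions$pixels, function(px) {
      hull <- corner_hull(px)
      length(px[, 1]) / polygon_area(hull)
    })
    circ <- 4 * pi * regions$area_px / regions$perimeter_px^2
    if (use_solidity) rej <- rej | sol < s_min
    if (use_circularity) rej <- rej | circ < c_min
  }
  regions$rejected_stacked <- rej
  at <- attributes(regions)
  kept <- regions[!rej, ]
  rejected <- regions[rej, ]
  for (nm in c("pixel_scale", "mask_dim")) {
    attr(kept, nm) <- at[[nm]]
    attr(rejected, nm) <- at[[nm]]
  }
  class(kept) <- class(regions); class(rejected) <- class(regions)
  list(kept = kept, rejected = rejected)
}

#' Full segmentation chain for one frame
#'
#' grayscale -> intensity adjustment -> threshold -> hole fill -> 8-connected
#' labeling -> stacked-cell removal. Returns every region with its
#' `rejected_stacked` flag set; border-touching regions keep their flag so
#' downstream morphometry can exclude them.
#'
#' @param frame an [image_frame()] (grayscale or RGB).
#' @param adjust apply [adjust_intensity()] first (default `TRUE`).
#' @param method,threshold,invert passed to [binarize()].
#' @param stacked_params named list overriding [remove_stacked()] defaults.
#' @return an `rbc_regions` tibble (all regions, flags set).
#' @export
segment_frame <- function(frame, adjust = TRUE,
                          method = c("otsu", "fixed"), threshold = NULL,
                          invert = FALSE, stacked_params = list()) {
  method <- match.arg(method)
  g <- to_grayscale(frame)
  if (adjust) g <- adjust_intensity(g)
  mask <- binarize(g, method = method, threshold = threshold, invert = invert)
  mask <- fill_holes(mask)
  regions <- label_regions(mask)
  parts <- do.call(remove_stacked, c(list(regions), stacked_params))
  out <- dplyr::bind_rows(parts$kept, parts$rejected)
  out <- out[order(out$label_id), ]
  for (nm in c("pixel_scale", "mask_dim"))
    attr(out, nm) <- attr(regions, nm)
  class(out) <- class(regions)
  out
}
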