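#' Classifier configuration
#'
#' Settings of the fused image-plus-parameters diagnostic model. The head
#' widths follow the device architecture: a 40-wide first fully connected
#' input (32 image-embedding values concatenated with the 8 population
#' parameters), then hidden layers of 64 and 20 units, then the class
#' layer. `features` selects the ablation variant: parameters only
#' (morphology, optionally mechanics) or the full fusion with the image
#' embedding.
#'
#' @param features any of `"morphology"` (6 shape parameters),
#'   `"mechanics"` (Dr mean + width), `"image"` (32-d embedding).
#' @param backbone image feature extractor; `"compact_cnn"` is the built-in
#'   seeded convolutional random-feature backbone (no external weights).
#' @param embedding_dim image embedding width (32, fixed by the
#'   architecture).
#' @param hidden hidden layer widths after the concat layer.
#' @param dropout_rate dropout on hidden activations during training.
#' @param lr,epochs Adam learning rate and full-batch epochs (defaults
#'   chosen for reliable convergence of the small head at desk scale).
#' @param n_cycles number of 90/10 training/validation cycles; the split is
#'   re-shuffled each cycle.
#' @param split_fraction development fraction (default 0.9).
#' @param augment apply random augmentation to images before embedding.
#' @param crop_um,input_side physical crop (um) and raster side fed to the
#'   backbone (0.1 mm resized to 224 px).
#' @param seed master seed fixing splits, initialization, dropout and
#'   augmentation.
#' @return a `rbc_classifier_config` list.
#' @export
classifier_config <- function(features = c("morphology", "mechanics", "image"),
                              backbone = "compact_cnn",
                              embedding_dim = 32L,
                              hidden = c(64L, 20L),
                              dropout_rate = 0.5,
                              lr = 1e-2, epochs = 500L,
                              n_cycles = 5L, split_fraction = 0.9,
                              augment = FALSE,
                              crop_um = 100, input_side = 224L,
                              seed = 1L) {
  features <- match.arg(features, several.ok = TRUE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort("dropout_rate must be in [0, 1)")
  if (split_fraction <= 0 || split_fraction >= 1)
    abort("split_fraction must be in (0, 1)")
  structure(list(
    features = features, backbone = backbone,
    embedding_dim = as.integer(embedding_dim), hidden = as.integer(hidden),
    dropout_rate = dropout_rate, lr = lr, epochs = as.integer(epochs),
    n_cycles = as.integer(n_cycles), split_fraction = split_fraction,
    augment = augment, crop_um = crop_um, input_side = as.integer(input_side),
    seed = as.integer(seed)
  ), class = "rbc_classifier_config")
}

#' Preprocess a frame for the image backbone
#'
#' Center-crops exactly `crop_um` x `crop_um` (0.1 mm by default) from the
#' field, resizes to `out_side` x `out_side` pixels (bilinear), and scales
#' intensities to `[0, 1]`. Errors when the field is smaller than the crop.
#'
#' @param frame an [image_frame()] (grayscale).
#' @param crop_um physical crop side, um.
#' @param out_side output raster side, px.
#' @return numeric matrix `out_side` x `out_side` in `[0, 1]`.
#' @export
preprocess_frame <- function(frame, crop_um = 100, out_side = 224L) {
  px <- to_grayscale(frame)$pixels
  side <- round(crop_um / frame$pixel_scale)
  nr <- nrow(px); nc <- ncol(px)
  if (side > nr || side > nc)
    abort("field smaller than the requested crop")
  r0 <- floor((nr - side) / 2); c0 <- floor((nc - side) / 2)
  crop <- px[r0 + seq_len(side), c0 + seq_len(side)] / 255
  if (side == out_side) return(crop)
  out <- EBImage::resize(EBImage::Image(crop), w = out_side, h = out_side)
  matrix(as.numeric(out), out_side, out_side)
}

reflect_index <- function(i, n) {
  # reflect out-of-range indices back into 1..n (mirror padding)
  p <- 2L * n - 2L
  if (p <= 0L) return(rep(1L, length(i)))
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j < n, j + 1L, p - j + 1L))
}

#' Random augmentation of a model input image
#'
#' Random rotation (0-360 degrees, mirror padding, nearest-neighbor
#' sampling), random crop jitter (90-100% sub-crop resized back), and
#' random horizontal/vertical flips. Deterministic given `seed`; with all
#' switches off the image passes through unchanged.
#'
#' @param img square numeric matrix in `[0, 1]` (a [preprocess_frame()]
#'   output).
#' @param rotate,crop,flip stage switches.
#' @param seed integer seed.
#' @return augmented matrix, same size.
#' @export
augment_image <- function(img, rotate = TRUE, crop = TRUE, flip = TRUE,
                          seed = 1L) {
  if (!rotate && !crop && !flip) return(img)
  n <- nrow(img)
  with_seed(seed, {
    if (rotate) {
      theta <- runif(1, 0, 2 * pi)
      ct <- cos(theta); st <- sin(theta)
      cen <- (n + 1) / 2
      g <- expand.grid(r = seq_len(n), c = seq_len(n))
      dr <- g$r - cen; dc <- g$c - cen
      sr <- round(cen + ct * dr - st * dc)
      sc <- round(cen + st * dr + ct * dc)
      img <- matrix(img[cbind(reflect_index(sr, n), reflect_index(sc, n))],
                    n, n)
    }
    if (crop) {
      s <- runif(1, 0.9, 1)
      side <- max(2L, round(s * n))
      r0 <- sample.int(n - side + 1L, 1L) - 1L
      c0 <- sample.int(n - side + 1L, 1L) - 1L
      sub <- img[r0 + seq_len(side), c0 + seq_len(side)]
      img <- matrix(as.numeric(EBImage::resize(EBImage::Image(sub),
                                               w = n, h = n)), n, n)
    }
    if (flip) {
      if (stats::rbinom(1, 1, 0.5) == 1) img <- img[n:1, ]
      if (stats::rbinom(1, 1, 0.5) == 1) img <- img[, n:1]
    }
  })
  img
}

#' Seeded convolutional random-feature backbone
#'
#' Three convolution blocks (8, 16 and 32 filters with ReLU and average
#' pooling, then global average pooling) whose weights are drawn once from
#' a seeded He-scaled Gaussian and then frozen: a random convolutional
#' feature extractor. Only the fusion head on top of it is trained. The
#' same seed always yields the same embedding function.
#'
#' @param embedding_dim output width (32).
#' @param seed weight seed.
#' @return a `rbc_backbone` list of filter banks.
#' @export
rbc_backbone <- function(embedding_dim = 32L, seed = 42L) {
  mk <- function(kh, kw, cin, cout) {
    array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
          dim = c(kh, kw, cin, cout))
  }
  with_seed(seed, {
    structure(list(
      w1 = mk(5, 5, 1, 8),
      w2 = mk(3, 3, 8, 16),
      w3 = mk(3, 3, 16, as.integer(embedding_dim)),
      embedding_dim = as.integer(embedding_dim), seed = as.integer(seed)
    ), class = "rbc_backbone")
  })
}

conv_valid <- function(x, w) {
  # x: H x W x Cin array (or matrix), w: kh x kw x Cin x Cout
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  H <- dim(x)[1] - kh + 1L; W <- dim(x)[2] - kw + 1L
  out <- array(0, dim = c(H, W, cout))
  for (o in seq_len(cout)) {
    acc <- matrix(0, H, W)
    for (ci in seq_len(cin)) {
      xi <- x[, , ci]
      for (di in seq_len(kh)) for (dj in seq_len(kw)) {
        wv <- w[di, dj, ci, o]
        if (wv != 0)
          acc <- acc + wv * xi[di:(di + H - 1L), dj:(dj + W - 1L)]
      }
    }
    out[, , o] <- acc
  }
  out
}

avg_pool <- function(x, k) {
  H <- (dim(x)[1] %/% k) * k; W <- (dim(x)[2] %/% k) * k
  C <- dim(x)[3]
  out <- array(0, dim = c(H %/% k, W %/% k, C))
  rg <- rep(seq_len(H %/% k), each = k)
  cg <- rep(seq_len(W %/% k), each = k)
  for (ci in seq_len(C)) {
    m <- x[seq_len(H), seq_len(W), ci]
    t1 <- rowsum(m, rg)
    t2 <- t(rowsum(t(t1), cg))
    out[, , ci] <- t2 / k^2
  }
  out
}

#' Embed a model input image into the 32-dimensional feature space
#'
#' @param backbone a [rbc_backbone()].
#' @param img square numeric matrix in `[0, 1]` (see [preprocess_frame()]).
#' @return numeric vector of length `backbone$embedding_dim`.
#' @export
embed_image <- function(backbone, img) {
  if (!inherits(backbone, "rbc_backbone")) abort("backbone is not initialized")
  s <- stats::sd(img)
  x <- if (s > 0) (img - mean(img)) / s else img - mean(img)
  h <- pmax(conv_valid(x, backbone$w1), 0)
  h <- avg_pool(h, 4L)
  h <- pmax(conv_valid(h, backbone$w2), 0)
  h <- avg_pool(h, 4L)
  h <- pmax(conv_valid(h, backbone$w3), 0)
  apply(h, 3, mean)
}

#' Assemble the combined feature vector
#'
#' Concatenates the 32-value image embedding with the 8 population
#' parameters into the 40-wide first fully connected input.
#'
#' @param embedding numeric vector (length = embedding width, 32).
#' @param params8 numeric vector of the 8 population parameters (see
#'   [population_vector()]).
#' @return numeric vector of length `length(embedding) + length(params8)`.
#' @export
assemble_features <- function(embedding, params8) {
  if (length(embedding) != 32L)
    abort("image embedding must have length 32")
  if (length(params8) != 8L)
    abort("parameter vector must have length 8")
  c(embedding, params8)
}

.param_cols <- list(
  morphology = c("diameter_mean", "diameter_dw", "circularity_mean",
                 "circularity_dw", "axis_ratio_mean", "axis_ratio_dw"),
  mechanics = c("dr_mean", "dr_dw")
)

# Build the raw design matrix from a dataset tibble per the feature switch.
.design_matrix <- function(data, config, backbone, seed = NULL) {
  blocks <- list()
  if ("image" %in% config$features) {
    has_img <- "image" %in% names(data)
    has_emb <- "embedding" %in% names(data)
    if (!has_img && !has_emb)
      abort("features include 'image' but the data has no image/embedding column")
    if (has_emb) {
      E <- do.call(rbind, data$embedding)
    } else {
      seeds <- seed_stream(seed %||% config$seed, nrow(data))
      E <- t(vapply(seq_len(nrow(data)), function(i) {
        im <- data$image[[i]]
        if (inherits(im, "rbc_frame"))
          im <- preprocess_frame(im, config$crop_um, config$input_side)
        if (isTRUE(config$augment))
          im <- augment_image(im, seed = seeds[i])
        embed_image(backbone, im)
      }, numeric(config$embedding_dim)))
    }
    colnames(E) <- paste0("emb", seq_len(ncol(E)))
    blocks$image <- E
  }
  P <- do.call(rbind, lapply(data$params, function(p) {
    unlist(p)[c(.param_cols$morphology, .param_cols$mechanics)]
  }))
  sel <- unlist(.param_cols[intersect(c("morphology", "mechanics"),
                                      config$features)])
  if (length(sel)) blocks$params <- P[, sel, drop = FALSE]
  do.call(cbind, blocks)
}

#' Train the fused diagnostic classifier
#'
#' Runs `n_cycles` stratified random development/validation splits (90/10
#' by default, re-shuffled each cycle). In each cycle the input columns are
#' standardized by the training-split mean/SD (stored with the model),
#' and the fusion head (concat -> 64 -> 20 -> classes, ReLU, dropout during
#' training only, Adam on softmax cross-entropy) is trained on the
#' development split. Deterministic given `config$seed`.
#'
#' @param data tibble with columns `label` (class), `params` (list-column
#'   of named 8-parameter vectors, see [population_vector()]), and, when
#'   the `image` feature is enabled, `image` (list of [image_frame()]s or
#'   preprocessed matrices) or `embedding` (list of 32-vectors).
#' @param config a [classifier_config()].
#' @return object of class `rbc_classifier`: final fitted head (from the
#'   last cycle), standardization constants, class levels, the backbone,
#'   and `metrics` (tibble: cycle, n_train, n_val, val_accuracy).
#' @export
train_classifier <- function(data, config = classifier_config()) {
  labels <- factor(data$label)
  classes <- levels(labels)
  if (length(classes) < 2L) abort("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2L)) abort("every class needs at least 2 samples")
  y <- as.integer(labels)
  backbone <- if ("image" %in% config$features)
    rbc_backbone(config$embedding_dim) else NULL
  X <- .design_matrix(data, config, backbone, seed = config$seed)
  n <- nrow(X)
  seeds <- seed_stream(config$seed, 2L * config$n_cycles)
  metrics <- vector("list", config$n_cycles)
  fit <- NULL; center <- NULL; scl <- NULL
  for (cyc in seq_len(config$n_cycles)) {
    idx_val <- with_seed(seeds[cyc], {
      unlist(lapply(classes, function(cl) {
        ii <- which(labels == cl)
        n_val <- max(1L, round((1 - config$split_fraction) * length(ii)))
        sample(ii, n_val)
      }))
    })
    idx_tr <- setdiff(seq_len(n), idx_val)
    center <- colMeans(X[idx_tr, , drop = FALSE])
    scl <- apply(X[idx_tr, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scl, `/`)
    sizes <- c(ncol(X), config$hidden, length(classes))
    fit <- mlp_train(Xs[idx_tr, , drop = FALSE], y[idx_tr], sizes,
                     epochs = config$epochs, lr = config$lr,
                     dropout = config$dropout_rate,
                     seed = seeds[config$n_cycles + cyc])
    pv <- mlp_predict_proba(fit, Xs[idx_val, , drop = FALSE])
    acc <- mean(max.col(pv) == y[idx_val])
    metrics[[cyc]] <- tibble(cycle = cyc, n_train = length(idx_tr),
                             n_val = length(idx_val), val_accuracy = acc)
  }
  structure(list(
    fit = fit, center = center, scale = scl, classes = classes,
    config = config, backbone = backbone,
    metrics = dplyr::bind_rows(metrics)
  ), class = "rbc_classifier")
}

#' Predict class probabilities and labels
#'
#' @param object an `rbc_classifier`.
#' @param newdata tibble shaped like the training data (see
#'   [train_classifier()]).
#' @param ... unused.
#' @return tibble with one probability column per class (`.prob_<class>`,
#'   rows sum to 1) and the argmax `.pred_class`.
#' @export
predict.rbc_classifier <- function(object, newdata, ...) {
  X <- .design_matrix(newdata, object$config, object$backbone,
                      seed = object$config$seed + 1L)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  P <- mlp_predict_proba(object$fit, Xs)
  colnames(P) <- paste0(".prob_", object$classes)
  out <- as_tibble(P)
  out$.pred_class <- factor(object$classes[max.col(P)], levels = object$classes)
  out
}

#' @export
print.rbc_classifier <- function(x, ...) {
  cat(sprintf("<rbc_classifier> %d classes, features: %s\n",
              length(x$classes), paste(x$config$features, collapse = "+")))
  cat(sprintf("  mean validation accuracy over %d cycles: %.3f\n",
              nrow(x$metrics), mean(x$metrics$val_accuracy)))
  invisible(x)
}

#' Confusion matrix helper
#'
#' @param truth true class labels.
#' @param estimate predicted class labels.
#' @return a contingency `table` (rows = truth, cols = estimate); row sums
#'   equal the per-class sample counts.
#' @export
confusion_matrix <- function(truth, estimate) {
  lv <- union(levels(factor(truth)), levels(factor(estimate)))
  table(truth = factor(truth, levels = lv),
        estimate = factor(estimate, levels = lv))
}
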