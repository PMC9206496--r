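#' The global-intensity threshold baseline
#'
#' The simplest highlight predictor: each pixel is judged purely by its own
#' intensity. Below the threshold `t` the prediction is exactly 0; above it
#' the prediction rises continuously into (0, 1) as
#' `2 * (logistic(gain * (x - t)) - 0.5)`. Because the mapping is
#' per-pixel, the model has no spatial context at all and is fooled by any
#' bright texture marking.
#'
#' `fit_threshold()` minimizes the mean per-pixel binary cross-entropy
#' between the prediction and the (soft, in `[0,1]`) ground-truth specular
#' map by direct 2-parameter optimization with seeded restarts; this is
#' mathematically equivalent to training the 1x1-convolution network it
#' replaces, whose composition of ReLU and squashing is exactly a
#' thresholded monotone map.
#'
#' @param images List of image matrices (or `gloss_stimulus` objects), or a
#'   `gloss_catalog` (all stimuli are used).
#' @param gt List of matching ground-truth specular matrices; ignored when
#'   `images` is a catalog.
#' @param epochs Optimizer iteration budget per restart (default 50).
#' @param n_pixels Maximum number of pixels subsampled (seeded) for the
#'   fit; `Inf` uses all pixels.
#' @param n_restarts Seeded restarts to escape the dead-zone optimum.
#' @param seed Integer seed.
#' @return A `gloss_threshold` model: list with `threshold`, `gain`, `loss`.
#' @export
fit_threshold <- function(images, gt = NULL, epochs = 50, n_pixels = 2e5,
                          n_restarts = 5, seed = 1) {
  if (inherits(images, "gloss_catalog")) {
    cat <- images
    images <- list(); gt <- list()
    for (i in seq_len(nrow(cat$meta))) {
      st <- get_stimulus(cat, cat$meta$scene_id[i], cat$meta$condition[i])
      images[[i]] <- st$image
      gt[[i]] <- st$components$specular
    }
  } else if (inherits(images, "gloss_stimulus")) {
    gt <- list(images$components$specular)
    images <- list(images$image)
  }
  if (length(images) != length(gt)) stop("images and ground truth are not aligned")
  x <- unlist(lapply(images, as.numeric), use.names = FALSE)
  y <- unlist(lapply(gt, as.numeric), use.names = FALSE)
  y <- clamp01(y)
  if (all(y <= GLOSS_EPSILON) || all(y > GLOSS_EPSILON)) {
    stop("degenerate ground truth: need both specular and non-specular pixels")
  }
  if (length(x) > n_pixels) {
    keep <- with_seed(derive_seed(seed, "tm-pixels"),
                      sample.int(length(x), n_pixels))
    x <- x[keep]; y <- y[keep]
  }

  obj <- function(par) threshold_bce(par[1], exp(par[2]), x, y)
  starts <- with_seed(derive_seed(seed, "tm-starts"), {
    cbind(runif(n_restarts, 0.3, 0.95), log(runif(n_restarts, 5, 80)))
  })
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- optim(starts[r, ], obj, method = "Nelder-Mead",
                 control = list(maxit = epochs * 10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(
    list(threshold = unname(best$par[1]), gain = exp(unname(best$par[2])),
         loss = best$value),
    class = "gloss_threshold"
  )
}

threshold_map <- function(x, t, gain) {
  p <- 2 * (plogis(gain * (x - t)) - 0.5)
  p[x <= t] <- 0
  p
}

threshold_bce <- function(t, gain, x, y) {
  p <- pmin(pmax(threshold_map(x, t, gain), 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname fit_threshold
#' @param model A fitted `gloss_threshold`.
#' @param image Image matrix (any shape; applied elementwise).
#' @return `predict_threshold()` returns a prediction map of the same
#'   shape, in `[0, 1)`, exactly 0 at or below the threshold.
#' @export
predict_threshold <- function(model, image) {
  stopifnot(inherits(model, "gloss_threshold"))
  out <- threshold_map(image, model$threshold, model$gain)
  if (is.matrix(image)) dim(out) <- dim(image)
  out
}

#' @export
print.gloss_threshold <- function(x, ...) {
  cat(sprintf("gloss_threshold: t = %.4f, gain = %.2f (BCE %.4f)\n",
              x$threshold, x$gain, x$loss))
  invisible(x)
}

#' @rdname fit_threshold
#' @param path File path for JSON persistence.
#' @export
write_threshold <- function(model, path) {
  jsonlite::write_json(list(threshold = model$threshold, gain = model$gain,
                            loss = model$loss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fit_threshold
#' @export
read_threshold <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(threshold = x$threshold, gain = x$gain, loss = x$loss),
            class = "gloss_threshold")
}
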