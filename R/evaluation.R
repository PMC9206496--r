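#' Compare two predictor vectors
#'
#' Standard Pearson correlation between two aligned per-probe predictor
#' vectors (threshold model, ground truth, full or masked network, or
#' observer means), with the derived R^2 and the elementwise RMSE.
#'
#' @param predictor,target Aligned numeric vectors, length >= 3.
#' @return List with `r`, `r_squared`, `rmse`, `n`.
#' @export
correlate <- function(predictor, target) {
  if (length(predictor) != length(target)) stop("vectors are not aligned")
  if (length(predictor) < 3) stop("need at least 3 values")
  if (sd(predictor) == 0) stop("`predictor` has zero variance")
  if (sd(target) == 0) stop("`target` has zero variance")
  r <- cor(predictor, target)
  list(r = r, r_squared = r^2,
       rmse = sqrt(mean((predictor - target)^2)), n = length(predictor))
}

#' Mean network response per pixel group
#'
#' Partitions every image's pixels into three groups -- specular (ground
#' truth above the highlight floor), bright texture patches (composed
#' intensity above the fitted global threshold, excluding specular
#' overlap), and all other pixels -- and averages the per-pixel network
#' predictions within each group across the image set. The brightness
#' cutoff for "bright texture" reuses the threshold model's fitted
#' threshold, the one principled brightness criterion in the system.
#'
#' @param predictions Named list of prediction matrices keyed by
#'   `stimulus_id` (or a function `stimulus_id -> matrix`).
#' @param catalog The catalog.
#' @param ids Stimulus ids to include.
#' @param tmodel Fitted `gloss_threshold` (brightness cutoff).
#' @return List with `means` (named: specular, bright_texture, other;
#'   `NA` with a `missing` flag if a group is empty) and `counts`.
#' @export
category_means <- function(predictions, catalog, ids, tmodel) {
  get <- if (is.function(predictions)) predictions else function(id) predictions[[id]]
  sums <- c(specular = 0, bright_texture = 0, other = 0)
  counts <- c(specular = 0, bright_texture = 0, other = 0)
  for (id in ids) {
    st <- get_stimulus(catalog, stimulus_id = id)
    p <- get(id)
    spec <- st$components$specular > catalog$epsilon
    bright <- (st$image > tmodel$threshold) & !spec
    other <- !spec & !bright
    stopifnot(sum(spec) + sum(bright) + sum(other) == length(p))
    sums <- sums + c(sum(p[spec]), sum(p[bright]), sum(p[other]))
    counts <- counts + c(sum(spec), sum(bright), sum(other))
  }
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  names(means) <- names(counts)
  list(means = means, counts = counts, missing = names(counts)[counts == 0])
}

#' Decision-rate curves for probe predictors
#'
#' For every sweep threshold, the rate of true-positive (and complementary
#' false-negative) binary decisions over the ground-truth-highlight probes
#' and of false-positive (true-negative) decisions over the non-highlight
#' probes, when the predictor value itself serves as the decision
#' threshold (decision = prediction >= theta). Thresholds sweep the sorted
#' unique predictor values plus 0 and 1.
#'
#' @param predictor Numeric predictor vector at the probes.
#' @param gt_at_probes Ground-truth specular values at the probes.
#' @param thresholds Optional explicit threshold vector.
#' @param epsilon Highlight floor binarizing the ground truth.
#' @return data.frame with `threshold`, `tpr`, `fnr`, `fpr`, `tnr`;
#'   undefined curves (no positive or no negative probes) are flagged via
#'   attribute `undefined`.
#' @export
decision_rate_curves <- function(predictor, gt_at_probes, thresholds = NULL,
                                 epsilon = gloss_epsilon()) {
  pos <- gt_at_probes > epsilon
  if (is.null(thresholds)) thresholds <- sort(unique(c(0, 1, predictor)))
  undef <- character(0)
  if (!any(pos)) undef <- c(undef, "tpr")
  if (all(pos)) undef <- c(undef, "fpr")
  out <- data.frame(threshold = thresholds)
  out$tpr <- if (any(pos)) {
    vapply(thresholds, function(th) mean(predictor[pos] >= th), numeric(1))
  } else NA_real_
  out$fnr <- 1 - out$tpr
  out$fpr <- if (!all(pos)) {
    vapply(thresholds, function(th) mean(predictor[!pos] >= th), numeric(1))
  } else NA_real_
  out$tnr <- 1 - out$fpr
  attr(out, "undefined") <- undef
  out
}

#' Rotated-highlight test
#'
#' For each plain stimulus and each global rotation of its specular
#' component (0, 90, 180, 270 degrees), recomposes the image, runs the
#' network, and measures the RMSE between the prediction and the
#' (correctly or wrongly oriented) specular component. If highlight
#' detection respects photo-geometric congruence, the unrotated condition
#' yields the lowest RMSE.
#'
#' @param net A trained `gloss_net`.
#' @param stimuli List of plain-condition `gloss_stimulus` objects.
#' @param angles Rotation angles (default `c(0, 90, 180, 270)`).
#' @param mask Optional connection mask.
#' @return data.frame with `angle`, `mean_rmse`, `sd_rmse`, `n`.
#' @export
rotation_rmse <- function(net, stimuli, angles = c(0, 90, 180, 270),
                          mask = NULL) {
  if (inherits(stimuli, "gloss_stimulus")) stimuli <- list(stimuli)
  for (st in stimuli) {
    if (st$condition != "plain") stop("rotation test requires untextured (plain) stimuli")
  }
  rows <- lapply(angles, function(ang) {
    rmse <- vapply(stimuli, function(st) {
      rot <- rotate_specular(st, ang)
      pred <- predict(net, rot$image, mask = mask)
      sqrt(mean((pred - rot$components$specular)^2))
    }, numeric(1))
    data.frame(angle = ang, mean_rmse = mean(rmse), sd_rmse = sd(rmse),
               n = length(rmse))
  })
  do.call(rbind, rows)
}

#' RMSE baseline between random noise images
#'
#' The scale reference for rotation effects: mean and SD of the RMSE
#' between independent pairs of uniform-[0,1] noise images. The analytic
#' large-image limit is `sqrt(1/6) ~ 0.408` (E[(X - Y)^2] = 2 Var(U[0,1])
#' = 1/6).
#'
#' @param n_pairs Number of image pairs (default 1,000).
#' @param size Image side length (default 256).
#' @param seed Integer seed.
#' @param dist Noise distribution: `"uniform"` (default) or a function
#'   `n -> numeric(n)`.
#' @return List with `mean`, `sd`, `analytic` (uniform closed form), `n_pairs`.
#' @export
noise_rmse_baseline <- function(n_pairs = 1000, size = 256, seed = 1,
                                dist = "uniform") {
  rfun <- if (is.function(dist)) dist else switch(dist,
    uniform = function(n) runif(n),
    stop("unknown noise distribution: ", dist))
  rmse <- with_seed(derive_seed(seed, "noise-rmse"), {
    vapply(seq_len(n_pairs), function(i) {
      a <- rfun(size * size)
      b <- rfun(size * size)
      sqrt(mean((a - b)^2))
    }, numeric(1))
  })
  list(mean = mean(rmse), sd = sd(rmse), analytic = sqrt(1 / 6),
       n_pairs = n_pairs)
}
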