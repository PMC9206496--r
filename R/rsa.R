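#' Predictor categories of the 34-predictor bank
#'
#' @return Named character vector mapping each predictor name to one of
#'   the seven categories: input_image (1), summary_statistics (4),
#'   edge_detection (4), gradients_anisotropy (3), geometry (11),
#'   intrinsic (7), scene_information (4).
#' @export
predictor_categories <- function() {
  c(input_image = "input_image",
    img_mean = "summary_statistics", img_sd = "summary_statistics",
    img_skewness = "summary_statistics", img_kurtosis = "summary_statistics",
    grad_x = "edge_detection", grad_y = "edge_detection",
    local_contrast = "edge_detection", local_norm = "edge_detection",
    grad_orientation_x = "gradients_anisotropy",
    grad_orientation_y = "gradients_anisotropy",
    anisotropy = "gradients_anisotropy",
    camera_distance = "geometry", angle_to_camera = "geometry",
    light_distance = "geometry", angle_to_light = "geometry",
    convexity = "geometry", pointiness = "geometry",
    normal_x = "geometry", normal_y = "geometry", normal_z = "geometry",
    occluding_edges = "geometry", occluding_edge_distance = "geometry",
    texture = "intrinsic", matte_shading = "intrinsic",
    specular = "intrinsic", specular_direct = "intrinsic",
    specular_indirect = "intrinsic", specular_coverage = "intrinsic",
    texture_coverage = "intrinsic",
    surface_scale = "scene_information", texture_type = "scene_information",
    texture_condition = "scene_information", scene = "scene_information")
}

# separable Gaussian blur via dense band matrices (renormalized at borders)
blur_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= n
    K[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

gauss_blur <- function(img, sigma) {
  K <- blur_matrix(nrow(img), sigma)
  K %*% img %*% t(K)
}

box_matrix <- function(n, r) {
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - r):min(n, i + r)
    K[i, idx] <- 1 / length(idx)
  }
  K
}

local_stats <- function(img, r = 2L) {
  K <- box_matrix(nrow(img), r)
  mu <- K %*% img %*% t(K)
  mu2 <- K %*% img^2 %*% t(K)
  list(mean = mu, sd = sqrt(pmax(mu2 - mu^2, 0)))
}

moment_stats <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  list(mean = m, sd = sqrt(v),
       skewness = if (v > 0) mean((x - m)^3) / v^1.5 else 0,
       kurtosis = if (v > 0) mean((x - m)^4) / v^2 else 0)
}

# exact Euclidean distance transform to a (sparse) mask
distance_to_mask <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(matrix(sqrt(n^2 + m^2), n, m))
  rr <- matrix(seq_len(n), n, m)
  cc <- matrix(seq_len(m), n, m, byrow = TRUE)
  best <- matrix(Inf, n, m)
  for (i in seq_len(nrow(pts))) {
    d2 <- (rr - pts[i, 1])^2 + (cc - pts[i, 2])^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Compute the 34-predictor bank for one stimulus
#'
#' Image-computable predictors are derived from the image itself
#' (finite-difference gradients, 5x5 local SD contrast, divisive local
#' normalization, structure-tensor orientation and anisotropy of the
#' Gaussian-smoothed gradient); geometry and intrinsic predictors are read
#' from the renderer's per-pixel buffers. The renderer has no indirect
#' light paths, so `specular_direct` equals `specular` and
#' `specular_indirect` is identically zero. Coverage predictors are the
#' fraction of pixels whose component exceeds the highlight floor
#' (for texture: deviates from the plain value 1). Scene information is
#' one-hot encoded; the `scene` predictor is encoded over `scene_levels`.
#'
#' Every predictor is represented as a flat numeric vector (maps
#' flattened, scalars length 1) so that image-by-image representational
#' dissimilarities are Euclidean distances between these vectors.
#'
#' @param record A `gloss_stimulus` whose components carry geometry
#'   buffers (render with `keep_geometry = TRUE`).
#' @param smooth_sigma Gaussian sigma in pixels for the
#'   gradient/anisotropy predictors; default scales as `4 * size / 128`.
#' @param scene_levels Scene ids spanned by the one-hot `scene` predictor.
#' @param edge_quantile Depth-gradient quantile defining occluding edges.
#' @return Named list of 34 numeric vectors with attribute `categories`.
#' @export
compute_predictor_bank <- function(record, smooth_sigma = NULL,
                                   scene_levels = NULL,
                                   edge_quantile = 0.99) {
  stopifnot(inherits(record, "gloss_stimulus"))
  comp <- record$components
  if (is.null(comp$geometry)) {
    stop("geometry buffers are missing (render with keep_geometry = TRUE); ",
         "absent predictors: camera_distance, angle_to_camera, light_distance, ",
         "angle_to_light, convexity, pointiness, normal_x/y/z, occluding_edges, ",
         "occluding_edge_distance")
  }
  img <- record$image
  size <- nrow(img)
  if (is.null(smooth_sigma)) smooth_sigma <- 4 * size / 128
  if (is.null(scene_levels)) scene_levels <- record$scene$scene_id

  g <- grad_central(img)
  ls <- local_stats(img, r = 2L)
  sm <- gauss_blur(img, smooth_sigma)
  sg <- grad_central(sm)
  mag <- sqrt(sg$gx^2 + sg$gy^2)
  # structure tensor of the smoothed gradient
  Jxx <- gauss_blur(sg$gx^2, smooth_sigma)
  Jyy <- gauss_blur(sg$gy^2, smooth_sigma)
  Jxy <- gauss_blur(sg$gx * sg$gy, smooth_sigma)
  tr <- Jxx + Jyy
  det_ <- Jxx * Jyy - Jxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  aniso <- ifelse(tr > 1e-12, (l1 - l2) / (l1 + l2), 0)

  geo <- comp$geometry
  dg <- grad_central(comp$depth)
  dmag <- sqrt(dg$gx^2 + dg$gy^2)
  occ <- dmag > stats::quantile(dmag, edge_quantile)
  occ_dist <- distance_to_mask(occ)

  ms <- moment_stats(as.numeric(img))
  one_hot <- function(value, levels) as.numeric(levels == value)

  bank <- list(
    input_image = as.numeric(img),
    img_mean = ms$mean, img_sd = ms$sd,
    img_skewness = ms$skewness, img_kurtosis = ms$kurtosis,
    grad_x = as.numeric(g$gx), grad_y = as.numeric(g$gy),
    local_contrast = as.numeric(ls$sd),
    local_norm = as.numeric((img - ls$mean) / (ls$sd + 1e-3)),
    grad_orientation_x = as.numeric(ifelse(mag > 1e-12, sg$gx / mag, 0)),
    grad_orientation_y = as.numeric(ifelse(mag > 1e-12, sg$gy / mag, 0)),
    anisotropy = as.numeric(aniso),
    camera_distance = as.numeric(geo$camera_distance),
    angle_to_camera = as.numeric(geo$angle_to_camera),
    light_distance = as.numeric(geo$light_distance),
    angle_to_light = as.numeric(geo$angle_to_light),
    convexity = as.numeric(sign(geo$curvature)),
    pointiness = as.numeric(abs(geo$curvature)),
    normal_x = as.numeric(geo$normal_x),
    normal_y = as.numeric(geo$normal_y),
    normal_z = as.numeric(geo$normal_z),
    occluding_edges = as.numeric(occ),
    occluding_edge_distance = as.numeric(occ_dist),
    texture = as.numeric(record$texture_map),
    matte_shading = as.numeric(comp$shading),
    specular = as.numeric(comp$specular),
    specular_direct = as.numeric(comp$specular),
    specular_indirect = numeric(size * size),
    specular_coverage = mean(comp$specular > GLOSS_EPSILON),
    texture_coverage = mean(abs(record$texture_map - 1) > GLOSS_EPSILON),
    surface_scale = one_hot(record$scene$scale_level, 0:3),
    texture_type = one_hot(condition_texture_kind(record$condition),
                           c("plain", "voronoi", "marble", "checker", "false")),
    texture_condition = one_hot(record$condition, gloss_conditions()),
    scene = one_hot(record$scene$scene_id, scene_levels)
  )
  structure(bank, categories = predictor_categories())
}

#' First-order representational dissimilarity matrix
#'
#' Pairwise Euclidean distances between per-image representation vectors.
#'
#' @param representations Numeric matrix, one row per image, or a list of
#'   equal-length vectors.
#' @return An `rdm`: symmetric non-negative matrix with zero diagonal and
#'   attribute `metric = "euclidean"`.
#' @export
first_order_rdm <- function(representations) {
  if (is.list(representations)) representations <- do.call(rbind, representations)
  if (nrow(representations) < 3) stop("need at least 3 images for an RDM")
  if (anyNA(representations) || !all(is.finite(representations))) {
    stop("representations contain NA or non-finite values")
  }
  m <- as.matrix(stats::dist(representations))
  dimnames(m) <- NULL
  structure(m, metric = "euclidean", class = c("rdm", "matrix", "array"))
}

#' Upper triangle of an RDM
#' @param rdm A square matrix.
#' @return Numeric vector (strict upper triangle, column-major).
#' @export
upper_tri <- function(rdm) rdm[upper.tri(rdm)]

#' Predictor RDMs over an image set
#'
#' @param records List of `gloss_stimulus` objects (geometry buffers
#'   required).
#' @param smooth_sigma Passed to [compute_predictor_bank()].
#' @return Named list of 34 `rdm` matrices with attribute `categories`.
#' @export
predictor_rdms <- function(records, smooth_sigma = NULL) {
  scene_levels <- sort(unique(vapply(records, function(r) r$scene$scene_id,
                                     numeric(1))))
  banks <- lapply(records, compute_predictor_bank,
                  smooth_sigma = smooth_sigma, scene_levels = scene_levels)
  nms <- names(predictor_categories())
  rdms <- lapply(nms, function(p) {
    first_order_rdm(do.call(rbind, lapply(banks, function(b) b[[p]])))
  })
  names(rdms) <- nms
  structure(rdms, categories = predictor_categories())
}

#' Unit RDMs: one first-order RDM per live filter
#'
#' Runs every image through the network (optionally masked), flattens each
#' filter's response map, and computes its RDM over the image set.
#' Filters with zero response variance across the whole set are "dead":
#' they are listed and excluded.
#'
#' @param net A trained `gloss_net`.
#' @param images List of image matrices (or `gloss_stimulus` objects).
#' @param mask Optional connection mask (use the pruned genome here).
#' @return List with `rdms` (named by unit id), `dead` (integer unit ids),
#'   `units` (the [unit_table()]).
#' @export
unit_rdms <- function(net, images, mask = NULL) {
  ut <- unit_table(net)
  Fc <- net$config$filters_per_layer
  reps <- vector("list", nrow(ut)) # per unit: matrix images x pixels
  n <- length(images)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (inherits(img, "gloss_stimulus")) img <- img$image
    fw <- net_forward(net, img, mask = mask, capture = TRUE)
    u <- 0L
    grab <- function(cube, f) as.numeric(cube[, , f])
    for (tier in 1:3) {
      acts <- fw$acts[[paste0("tier", tier)]]
      for (s in seq_len(net$config$n_scales)) {
        for (f in seq_len(Fc)) {
          u <- u + 1L
          if (i == 1) reps[[u]] <- matrix(0, n, length(grab(acts[[s]], f)))
          reps[[u]][i, ] <- grab(acts[[s]], f)
        }
      }
    }
    for (f in seq_len(Fc)) {
      u <- u + 1L
      if (i == 1) reps[[u]] <- matrix(0, n, length(grab(fw$acts$tier4, f)))
      reps[[u]][i, ] <- grab(fw$acts$tier4, f)
    }
    u <- u + 1L
    if (i == 1) reps[[u]] <- matrix(0, n, length(fw$acts$out))
    reps[[u]][i, ] <- as.numeric(fw$acts$out)
  }
  dead <- which(vapply(reps, function(m) all(apply(m, 2, sd) == 0), logical(1)))
  live <- setdiff(seq_len(nrow(ut)), dead)
  rdms <- lapply(live, function(u) first_order_rdm(reps[[u]]))
  names(rdms) <- as.character(live)
  list(rdms = rdms, dead = dead, units = ut)
}

#' Variance of a unit RDM explained by a predictor category
#'
#' Ordinary least squares of the unit RDM's upper triangle on the upper
#' triangles of all predictor RDMs in the category (plus intercept),
#' returning R^2. Rank-deficient (collinear) predictor sets fall back to
#' the least-norm pivoted-QR solution and are flagged.
#'
#' @param unit_rdm An `rdm`.
#' @param category_rdms List of predictor `rdm`s in one category.
#' @return R^2 scalar with attribute `collinear`.
#' @export
category_similarity <- function(unit_rdm, category_rdms) {
  y <- upper_tri(unit_rdm)
  X <- do.call(cbind, lapply(category_rdms, upper_tri))
  fit <- stats::lm.fit(cbind(1, X), y)
  collinear <- fit$rank < ncol(X) + 1
  res <- fit$residuals
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  structure(r2, collinear = collinear)
}

#' Unit-by-category similarity table
#'
#' @param units_out Result of [unit_rdms()].
#' @param pred_rdms Result of [predictor_rdms()].
#' @return List with `category_r2` (units x 7 matrix), `best_single`
#'   (data.frame: per unit, the single predictor with maximal squared
#'   Pearson correlation of upper triangles, and its category).
#' @export
rsa_similarity <- function(units_out, pred_rdms) {
  cats <- attr(pred_rdms, "categories")
  cat_levels <- unique(cats)
  uts <- lapply(pred_rdms, upper_tri)
  live <- names(units_out$rdms)
  category_r2 <- matrix(NA_real_, length(live), length(cat_levels),
                        dimnames = list(live, cat_levels))
  best_name <- character(length(live))
  best_r2 <- numeric(length(live))
  for (i in seq_along(live)) {
    yu <- upper_tri(units_out$rdms[[i]])
    for (cl in cat_levels) {
      category_r2[i, cl] <- as.numeric(
        category_similarity(units_out$rdms[[i]], pred_rdms[cats == cl]))
    }
    r2s <- vapply(uts, function(x) {
      if (sd(x) == 0 || sd(yu) == 0) 0 else cor(yu, x)^2
    }, numeric(1))
    best_name[i] <- names(r2s)[which.max(r2s)]
    best_r2[i] <- max(r2s)
  }
  list(category_r2 = category_r2,
       best_single = data.frame(unit = as.integer(live),
                                predictor = best_name,
                                r_squared = best_r2,
                                category = unname(cats[best_name]),
                                stringsAsFactors = FALSE))
}

#' Second-order RDM and 2-D embedding of unit representations
#'
#' The second-order dissimilarity between two units is 1 minus the Pearson
#' correlation of the upper triangles of their first-order RDMs. The
#' matrix is embedded in 2 dimensions by metric MDS (SMACOF majorization
#' with seeded random initialization; stress is non-increasing over
#' iterations). When predictor RDMs are supplied, every unit is labelled
#' by the category of its most similar single predictor.
#'
#' @param units_out Result of [unit_rdms()] (needs >= 3 live units).
#' @param pred_rdms Optional result of [predictor_rdms()] for labels.
#' @param seed Integer seed for the MDS initialization.
#' @param n_iter SMACOF iterations (default 100).
#' @return List with `second_order` (units x units matrix), `coords`
#'   (units x 2), `stress_path`, and optionally `labels`.
#' @export
second_order_embedding <- function(units_out, pred_rdms = NULL, seed = 1,
                                   n_iter = 100) {
  rdms <- units_out$rdms
  k <- length(rdms)
  if (k < 3) stop("need at least 3 live units for an embedding")
  U <- do.call(cbind, lapply(rdms, upper_tri))
  sds <- apply(U, 2, sd)
  C <- suppressWarnings(cor(U))
  C[!is.finite(C)] <- 0
  diag(C) <- 1
  D2 <- 1 - C

  X <- with_seed(derive_seed(seed, "mds"), matrix(rnorm(k * 2), k, 2) * 0.1)
  stress_path <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    d <- as.matrix(stats::dist(X))
    stress_path[it] <- sum((D2[upper.tri(D2)] - d[upper.tri(d)])^2)
    B <- ifelse(d > 1e-12, -D2 / d, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / k
  }
  out <- list(second_order = D2, coords = X, stress_path = stress_path)
  if (!is.null(pred_rdms)) {
    sim <- rsa_similarity(units_out, pred_rdms)
    out$labels <- sim$best_single$category
  }
  out
}

# ---- lesion analysis -------------------------------------------------------

lesion_unit <- function(net, unit) {
  ut <- unit_table(net)
  row <- ut[ut$unit == unit, ]
  if (nrow(row) != 1) stop("unknown unit id: ", unit)
  zero_col <- function(layer, f) {
    layer$W[, f] <- 0; layer$b[f] <- 0; layer
  }
  if (row$tier %in% 1:3) {
    key <- paste0("tier", row$tier)
    net$layers[[key]][[row$scale]] <- zero_col(net$layers[[key]][[row$scale]],
                                               row$filter)
  } else if (row$tier == 4) {
    net$layers$tier4 <- zero_col(net$layers$tier4, row$filter)
  } else {
    net$layers$out <- zero_col(net$layers$out, 1L)
  }
  net
}

#' Single-unit lesion sweep
#'
#' Lesions each filter in turn by zeroing all of its weights and bias (so
#' its output becomes constant zero before the nonlinearity), then
#' measures (a) the BCE loss on an evaluation stimulus set and (b) the
#' correlation of probe predictions to the mean observer responses, both
#' as raw values and as deltas against the intact network.
#'
#' @param net A trained `gloss_net`.
#' @param eval_stimuli List of `gloss_stimulus` objects for the loss.
#' @param catalog,probeset,responses Probe correlation inputs:
#'   `responses` is the mean response vector per probe.
#' @param mask Optional connection mask (lesion the pruned network by
#'   passing its genome).
#' @param units Integer unit ids to lesion (default: all 177).
#' @return A `gloss_lesion_report` data.frame: `unit`, `loss`,
#'   `probe_correlation`, `delta_loss`, `delta_correlation`,
#'   `degenerate` (constant probe predictions).
#' @export
lesion_sweep <- function(net, eval_stimuli, catalog, probeset, responses,
                         mask = NULL, units = NULL) {
  if (is.null(units)) units <- unit_table(net)$unit
  probe_preds <- function(nn) {
    probe_values(probeset, function(id) {
      predict(nn, get_stimulus(catalog, stimulus_id = id)$image, mask = mask)
    })
  }
  base_loss <- net_validation_loss(net, eval_stimuli, mask = mask)
  p0 <- probe_preds(net)
  r0 <- safe_cor(p0, responses)
  rows <- lapply(units, function(u) {
    ln <- lesion_unit(net, u)
    loss <- net_validation_loss(ln, eval_stimuli, mask = mask)
    r <- safe_cor(probe_preds(ln), responses)
    data.frame(unit = u, loss = loss, probe_correlation = as.numeric(r),
               delta_loss = loss - base_loss,
               delta_correlation = as.numeric(r) - as.numeric(r0),
               degenerate = attr(r, "degenerate"))
  })
  out <- do.call(rbind, rows)
  attr(out, "intact") <- list(loss = base_loss, probe_correlation = as.numeric(r0))
  class(out) <- c("gloss_lesion_report", "data.frame")
  out
}

#' Correlate lesion effects with representational similarities
#'
#' Squared Pearson correlations, across units, between each lesion score
#' (delta loss, delta probe correlation) and each predictor category's
#' variance-explained vector. Constant vectors give `NA` (reported as
#' missing).
#'
#' @param report A `gloss_lesion_report`.
#' @param category_r2 Units x categories matrix from [rsa_similarity()]
#'   (rows matched to `report$unit` by unit id).
#' @return Matrix 2 x categories of R^2 values.
#' @export
lesion_vs_similarity <- function(report, category_r2) {
  common <- intersect(as.character(report$unit), rownames(category_r2))
  if (!length(common)) stop("no overlapping units between report and similarities")
  rep_sub <- report[match(common, as.character(report$unit)), ]
  sim_sub <- category_r2[common, , drop = FALSE]
  scores <- cbind(delta_loss = rep_sub$delta_loss,
                  delta_correlation = rep_sub$delta_correlation)
  out <- matrix(NA_real_, 2, ncol(sim_sub),
                dimnames = list(colnames(scores), colnames(sim_sub)))
  for (i in 1:2) {
    for (j in seq_len(ncol(sim_sub))) {
      x <- scores[, i]; y <- sim_sub[, j]
      if (sd(x) > 0 && sd(y) > 0) out[i, j] <- cor(x, y)^2
    }
  }
  out
}
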