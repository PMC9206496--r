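#' Configuration of the multi-scale tiered network
#'
#' The architecture processes an image pyramid of 7 resolutions (1/1 down
#' to 1/64 in powers of 2) through 4 tiers: three tiers of 7 parallel
#' convolutional layers (one per scale, 8 filters of 3x3 each), with full
#' cross-scale exchange between consecutive tiers (every scale's output is
#' resampled to every other scale and concatenated, 7 x 8 = 56 input
#' channels), then one full-resolution tier of 8 filters, then a single
#' output filter squashed into (0, 1). Hidden activations are rectified.
#' Only the two inter-tier gaps (1->2 and 2->3) are prunable, giving
#' 2 x 7 x 7 = 98 on/off connections; the network holds
#' 3*7*8 + 8 + 1 = 177 filters.
#'
#' @param image_size Input side length in pixels, divisible by 64.
#' @param seed Integer seed for weight initialization.
#' @param n_scales,filters_per_layer,kernel Architecture constants
#'   (defaults 7, 8, 3; changing them leaves the canonical model).
#' @return A `gloss_net_config` list.
#' @export
net_config <- function(image_size, seed = 1, n_scales = 7L,
                       filters_per_layer = 8L, kernel = 3L) {
  if (image_size %% 64 != 0) stop("`image_size` must be divisible by 64")
  if (kernel != 3L) stop("only 3x3 kernels are implemented")
  structure(
    list(image_size = as.integer(image_size), n_scales = as.integer(n_scales),
         filters_per_layer = as.integer(filters_per_layer), kernel = 3L,
         seed = as.integer(seed)),
    class = "gloss_net_config"
  )
}

#' Pyramid resolutions for an image size
#' @param image_size Input side length.
#' @param n_scales Number of scales (default 7).
#' @return Integer vector of side lengths, full size to 1/64.
#' @export
pyramid_sizes <- function(image_size, n_scales = 7L) {
  as.integer(image_size / 2^(seq_len(n_scales) - 1L))
}

# 1-D resampling matrix (to x from): block average for downscaling,
# bilinear interpolation for upscaling, identity when equal.
resample_matrix <- function(from, to) {
  if (from == to) return(diag(from))
  R <- matrix(0, to, from)
  if (to < from) {
    f <- from / to
    for (i in seq_len(to)) R[i, ((i - 1) * f + 1):(i * f)] <- 1 / f
  } else {
    for (i in seq_len(to)) {
      u <- (i - 0.5) * from / to - 0.5 # 0-based source coordinate
      i0 <- floor(u)
      fr <- u - i0
      lo <- min(max(i0, 0), from - 1)
      hi <- min(max(i0 + 1, 0), from - 1)
      R[i, lo + 1] <- R[i, lo + 1] + (1 - fr)
      R[i, hi + 1] <- R[i, hi + 1] + fr
    }
  }
  R
}

# Separable resampling of an (a, a, c) cube with a (b, a) matrix.
resample_cube <- function(x, R) {
  a <- dim(x)[1]; ch <- dim(x)[3]; b <- nrow(R)
  if (a == b) return(x)
  y <- array(R %*% matrix(x, a, a * ch), c(b, a, ch))
  y <- aperm(y, c(2, 1, 3))
  z <- array(R %*% matrix(y, a, b * ch), c(b, b, ch))
  aperm(z, c(2, 1, 3))
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

new_conv_layer <- function(cin, cout, gain = sqrt(2)) {
  fan_in <- 9 * cin
  list(W = matrix(rnorm(fan_in * cout, sd = gain / sqrt(fan_in)), fan_in, cout),
       b = numeric(cout))
}

#' Build the multi-scale network
#'
#' Initializes all 23 convolutional layers (seeded He-normal weights) and
#' precomputes the inter-scale resampling operators for the configured
#' image size.
#'
#' @param config A `gloss_net_config`.
#' @return A `gloss_net`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "gloss_net_config"))
  S <- config$n_scales
  Fc <- config$filters_per_layer
  sizes <- pyramid_sizes(config$image_size, S)
  layers <- with_seed(derive_seed(config$seed, "net-init"), {
    list(
      tier1 = lapply(seq_len(S), function(s) new_conv_layer(1L, Fc)),
      tier2 = lapply(seq_len(S), function(s) new_conv_layer(S * Fc, Fc)),
      tier3 = lapply(seq_len(S), function(s) new_conv_layer(S * Fc, Fc)),
      tier4 = new_conv_layer(S * Fc, Fc),
      out = new_conv_layer(Fc, 1L, gain = 1)
    )
  })
  # resampling operators between every ordered pair of pyramid sizes
  resamp <- list()
  for (a in sizes) {
    for (b in sizes) {
      key <- paste(a, b)
      if (is.null(resamp[[key]])) resamp[[key]] <- resample_matrix(a, b)
    }
  }
  structure(
    list(config = config, sizes = sizes, layers = layers, resamp = resamp,
         trained = FALSE, log = NULL),
    class = "gloss_net"
  )
}

#' @export
print.gloss_net <- function(x, ...) {
  cat(sprintf("gloss_net: %dpx input, %d scales, %d filters, %s parameters%s\n",
              x$config$image_size, x$config$n_scales, n_filters(x),
              format(count_parameters(x), big.mark = ","),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Count trainable parameters / filters
#'
#' @param net A `gloss_net`.
#' @return `count_parameters()`: total number of trainable scalars
#'   (weights and biases). `n_filters()`: total convolutional filter
#'   (neuron) count, 177 for the canonical architecture.
#' @export
count_parameters <- function(net) {
  sum(vapply(flatten_layers(net$layers),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @rdname count_parameters
#' @export
n_filters <- function(net) {
  sum(vapply(flatten_layers(net$layers), function(l) ncol(l$W), integer(1)))
}

flatten_layers <- function(layers) {
  c(layers$tier1, layers$tier2, layers$tier3,
    list(layers$tier4), list(layers$out))
}

unflatten_layers <- function(flat, S) {
  list(tier1 = flat[1:S], tier2 = flat[(S + 1):(2 * S)],
       tier3 = flat[(2 * S + 1):(3 * S)], tier4 = flat[[3 * S + 1]],
       out = flat[[3 * S + 2]])
}

#' Unit (filter) bookkeeping table
#'
#' One row per convolutional filter, in canonical order (tier 1 scales
#' 1..7 x filters 1..8, tiers 2, 3 likewise, then tier 4, then the output
#' unit).
#'
#' @param net A `gloss_net`.
#' @return data.frame with `unit`, `tier`, `scale` (NA for tiers 4/out),
#'   `filter`.
#' @export
unit_table <- function(net) {
  S <- net$config$n_scales; Fc <- net$config$filters_per_layer
  rows <- list()
  for (tier in 1:3) {
    for (s in seq_len(S)) {
      rows[[length(rows) + 1]] <- data.frame(tier = tier, scale = s,
                                             filter = seq_len(Fc))
    }
  }
  rows[[length(rows) + 1]] <- data.frame(tier = 4, scale = NA_integer_,
                                         filter = seq_len(Fc))
  rows[[length(rows) + 1]] <- data.frame(tier = 5, scale = NA_integer_,
                                         filter = 1L)
  out <- do.call(rbind, rows)
  out$unit <- seq_len(nrow(out))
  out[, c("unit", "tier", "scale", "filter")]
}

# ---- connection masks ------------------------------------------------------

#' Connection masks for inter-tier pruning
#'
#' A mask is a logical vector of length 98, one bit per (gap, source scale,
#' destination scale) connection, where gap 1 is tier 1 -> 2 and gap 2 is
#' tier 2 -> 3. Bit order: gap, then source scale, then destination scale
#' (destination fastest). `full_mask()` is the all-ones genome; applying it
#' is identical to no mask at all.
#'
#' @param gap 1 or 2.
#' @param src,dst Scale indices in 1..7.
#' @return `mask_index()`: integer position in 1..98.
#' @export
mask_index <- function(gap, src, dst, n_scales = 7L) {
  (gap - 1L) * n_scales^2 + (src - 1L) * n_scales + dst
}

#' @rdname mask_index
#' @param n_scales Number of scales (default 7).
#' @export
full_mask <- function(n_scales = 7L) rep(TRUE, 2L * n_scales^2)

check_mask <- function(mask, S) {
  if (is.null(mask)) return(rep(TRUE, 2L * S^2))
  if (length(mask) != 2L * S^2) {
    stop(sprintf("connection mask must have length %d, got %d",
                 2L * S^2, length(mask)))
  }
  as.logical(mask)
}

# ---- forward / backward ----------------------------------------------------

conv_forward <- function(cols, layer) {
  sweep(cols %*% layer$W, 2L, layer$b, "+")
}

# Forward pass. Returns prediction and, when requested, the intermediate
# state needed for backpropagation or the per-unit activation maps.
net_forward <- function(net, image, mask = NULL, keep_state = FALSE,
                        capture = FALSE, cache = NULL) {
  cfg <- net$config
  S <- cfg$n_scales; Fc <- cfg$filters_per_layer
  sizes <- net$sizes
  mask <- check_mask(mask, S)
  rs <- function(a, b) net$resamp[[paste(a, b)]]

  if (is.null(cache)) {
    full <- array(image, c(sizes[1], sizes[1], 1L))
    pyr <- lapply(seq_len(S), function(s) resample_cube(full, rs(sizes[1], sizes[s])))
    cols1 <- lapply(seq_len(S), function(s)
      im2col3x3_cpp(pyr[[s]], sizes[s], sizes[s], 1L))
    z1 <- lapply(seq_len(S), function(s) conv_forward(cols1[[s]], net$layers$tier1[[s]]))
    a1 <- lapply(seq_len(S), function(s)
      array(relu(z1[[s]]), c(sizes[s], sizes[s], Fc)))
    # gap-1 inputs: per destination, all sources resampled and concatenated
    gap1 <- lapply(seq_len(S), function(d) {
      blocks <- lapply(seq_len(S), function(s)
        resample_cube(a1[[s]], rs(sizes[s], sizes[d])))
      array(unlist(blocks, use.names = FALSE), c(sizes[d], sizes[d], S * Fc))
    })
  } else {
    pyr <- cache$pyr; cols1 <- cache$cols1; z1 <- cache$z1
    a1 <- cache$a1; gap1 <- cache$gap1
  }

  apply_mask <- function(gapin, gap_id, d) {
    x <- gapin
    for (s in seq_len(S)) {
      if (!mask[mask_index(gap_id, s, d, S)]) {
        x[, , ((s - 1) * Fc + 1):(s * Fc)] <- 0
      }
    }
    x
  }

  in2 <- lapply(seq_len(S), function(d) apply_mask(gap1[[d]], 1L, d))
  cols2 <- lapply(seq_len(S), function(d)
    im2col3x3_cpp(in2[[d]], sizes[d], sizes[d], S * Fc))
  z2 <- lapply(seq_len(S), function(d) conv_forward(cols2[[d]], net$layers$tier2[[d]]))
  a2 <- lapply(seq_len(S), function(d)
    array(relu(z2[[d]]), c(sizes[d], sizes[d], Fc)))

  gap2 <- lapply(seq_len(S), function(d) {
    blocks <- lapply(seq_len(S), function(s)
      resample_cube(a2[[s]], rs(sizes[s], sizes[d])))
    array(unlist(blocks, use.names = FALSE), c(sizes[d], sizes[d], S * Fc))
  })
  in3 <- lapply(seq_len(S), function(d) apply_mask(gap2[[d]], 2L, d))
  cols3 <- lapply(seq_len(S), function(d)
    im2col3x3_cpp(in3[[d]], sizes[d], sizes[d], S * Fc))
  z3 <- lapply(seq_len(S), function(d) conv_forward(cols3[[d]], net$layers$tier3[[d]]))
  a3 <- lapply(seq_len(S), function(d)
    array(relu(z3[[d]]), c(sizes[d], sizes[d], Fc)))

  # tier 3 -> 4: everything upsampled to full resolution (never masked)
  blocks4 <- lapply(seq_len(S), function(s)
    resample_cube(a3[[s]], rs(sizes[s], sizes[1])))
  in4 <- array(unlist(blocks4, use.names = FALSE), c(sizes[1], sizes[1], S * Fc))
  cols4 <- im2col3x3_cpp(in4, sizes[1], sizes[1], S * Fc)
  z4 <- conv_forward(cols4, net$layers$tier4)
  a4 <- array(relu(z4), c(sizes[1], sizes[1], Fc))

  colsO <- im2col3x3_cpp(a4, sizes[1], sizes[1], Fc)
  zO <- conv_forward(colsO, net$layers$out)
  pred <- matrix(sigmoid(zO), sizes[1], sizes[1])

  res <- list(pred = pred)
  if (keep_state) {
    res$state <- list(cols1 = cols1, z1 = z1, in2 = in2, cols2 = cols2,
                      z2 = z2, in3 = in3, cols3 = cols3, z3 = z3,
                      cols4 = cols4, z4 = z4, colsO = colsO, mask = mask)
  }
  if (capture) {
    res$acts <- list(tier1 = a1, tier2 = a2, tier3 = a3, tier4 = a4,
                     out = pred)
  }
  res
}

# cache of everything upstream of the prunable gaps for one image
net_tier1_cache <- function(net, image) {
  cfg <- net$config
  S <- cfg$n_scales; Fc <- cfg$filters_per_layer
  sizes <- net$sizes
  rs <- function(a, b) net$resamp[[paste(a, b)]]
  full <- array(image, c(sizes[1], sizes[1], 1L))
  pyr <- lapply(seq_len(S), function(s) resample_cube(full, rs(sizes[1], sizes[s])))
  cols1 <- lapply(seq_len(S), function(s)
    im2col3x3_cpp(pyr[[s]], sizes[s], sizes[s], 1L))
  z1 <- lapply(seq_len(S), function(s) conv_forward(cols1[[s]], net$layers$tier1[[s]]))
  a1 <- lapply(seq_len(S), function(s)
    array(relu(z1[[s]]), c(sizes[s], sizes[s], Fc)))
  gap1 <- lapply(seq_len(S), function(d) {
    blocks <- lapply(seq_len(S), function(s)
      resample_cube(a1[[s]], rs(sizes[s], sizes[d])))
    array(unlist(blocks, use.names = FALSE), c(sizes[d], sizes[d], S * Fc))
  })
  list(pyr = pyr, cols1 = cols1, z1 = z1, a1 = a1, gap1 = gap1)
}

# Backpropagation from the output-logit gradient; returns gradients in the
# same nested structure as net$layers.
net_backward <- function(net, state, dzO) {
  cfg <- net$config
  S <- cfg$n_scales; Fc <- cfg$filters_per_layer
  sizes <- net$sizes
  rs <- function(a, b) net$resamp[[paste(a, b)]]
  mask <- state$mask

  gO <- list(W = crossprod(state$colsO, dzO), b = colSums(dzO))
  dA4 <- col2im3x3_cpp(dzO %*% t(net$layers$out$W), sizes[1], sizes[1], Fc)
  dz4 <- matrix(dA4, sizes[1]^2, Fc) * (state$z4 > 0)
  g4 <- list(W = crossprod(state$cols4, dz4), b = colSums(dz4))
  dIn4 <- col2im3x3_cpp(dz4 %*% t(net$layers$tier4$W), sizes[1], sizes[1], S * Fc)

  # split the 56-channel gradient into per-source blocks and push each
  # back through the (transposed) resampling to its source scale
  dA3 <- vector("list", S)
  for (s in seq_len(S)) {
    block <- dIn4[, , ((s - 1) * Fc + 1):(s * Fc), drop = FALSE]
    dA3[[s]] <- resample_cube(block, t(rs(sizes[s], sizes[1])))
  }

  g3 <- vector("list", S)
  dA2 <- lapply(seq_len(S), function(s) array(0, c(sizes[s], sizes[s], Fc)))
  for (d in seq_len(S)) {
    dz3 <- matrix(dA3[[d]], sizes[d]^2, Fc) * (state$z3[[d]] > 0)
    g3[[d]] <- list(W = crossprod(state$cols3[[d]], dz3), b = colSums(dz3))
    dIn3 <- col2im3x3_cpp(dz3 %*% t(net$layers$tier3[[d]]$W),
                          sizes[d], sizes[d], S * Fc)
    for (s in seq_len(S)) {
      if (!mask[mask_index(2L, s, d, S)]) next
      block <- dIn3[, , ((s - 1) * Fc + 1):(s * Fc), drop = FALSE]
      dA2[[s]] <- dA2[[s]] + resample_cube(block, t(rs(sizes[s], sizes[d])))
    }
  }

  g2 <- vector("list", S)
  dA1 <- lapply(seq_len(S), function(s) array(0, c(sizes[s], sizes[s], Fc)))
  for (d in seq_len(S)) {
    dz2 <- matrix(dA2[[d]], sizes[d]^2, Fc) * (state$z2[[d]] > 0)
    g2[[d]] <- list(W = crossprod(state$cols2[[d]], dz2), b = colSums(dz2))
    dIn2 <- col2im3x3_cpp(dz2 %*% t(net$layers$tier2[[d]]$W),
                          sizes[d], sizes[d], S * Fc)
    for (s in seq_len(S)) {
      if (!mask[mask_index(1L, s, d, S)]) next
      block <- dIn2[, , ((s - 1) * Fc + 1):(s * Fc), drop = FALSE]
      dA1[[s]] <- dA1[[s]] + resample_cube(block, t(rs(sizes[s], sizes[d])))
    }
  }

  g1 <- vector("list", S)
  for (s in seq_len(S)) {
    dz1 <- matrix(dA1[[s]], sizes[s]^2, Fc) * (state$z1[[s]] > 0)
    g1[[s]] <- list(W = crossprod(state$cols1[[s]], dz1), b = colSums(dz1))
  }

  list(tier1 = g1, tier2 = g2, tier3 = g3, tier4 = g4, out = gO)
}

#' Predict the specular map for one image
#'
#' @param object A `gloss_net`.
#' @param image Image matrix of the configured size.
#' @param mask Optional 98-bit connection mask; `NULL` (no mask) is
#'   identical to the all-ones mask. Masked-out connections contribute
#'   zeros to the destination tier's input concatenation; weights are
#'   untouched.
#' @param ... Unused.
#' @return Prediction matrix in (0, 1), same size as the input.
#' @export
predict.gloss_net <- function(object, image, mask = NULL, ...) {
  stopifnot(is.matrix(image), nrow(image) == object$config$image_size,
            ncol(image) == object$config$image_size)
  net_forward(object, image, mask = mask)$pred
}

# ---- loss and training -----------------------------------------------------

bce_loss <- function(pred, label) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

zero_like <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else zero_like(l)
  })
}

# elementwise op over the nested layer structure
map2_layers <- function(a, b, f) {
  if (!is.null(a$W)) return(list(W = f(a$W, b$W), b = f(a$b, b$b)))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[[i]] <- map2_layers(a[[i]], b[[i]], f)
  out
}

#' Train the network on a stimulus catalog
#'
#' Supervised training with per-pixel binary cross-entropy against the
#' ground-truth specular maps (soft labels in `[0, 1]`), epoch-shuffled
#' minibatches, and adaptive-moment (Adam) updates. A validation subset is
#' withheld via [split_catalog()] and its loss logged each epoch.
#'
#' @param net An untrained `gloss_net`.
#' @param catalog A rendered `gloss_catalog` whose image size matches.
#' @param epochs Training epochs (full-scale preset: 50; desk: 5).
#' @param batch_size Minibatch size (default 16).
#' @param lr Learning rate (default 1e-3).
#' @param val_fraction Fraction withheld for validation (default 0.15).
#' @param seed Integer seed (shuffling).
#' @param verbose Print per-epoch losses.
#' @return The trained `gloss_net` with a `log` data.frame (epoch,
#'   train_loss, val_loss).
#' @export
train_network <- function(net, catalog, epochs = 5, batch_size = 16,
                          lr = 1e-3, val_fraction = 0.15, seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(net, "gloss_net"), inherits(catalog, "gloss_catalog"))
  if (catalog$size != net$config$image_size) {
    stop("catalog image size does not match the network configuration")
  }
  split <- split_catalog(catalog, val_fraction, seed = derive_seed(seed, "val"))
  dataset <- function(ids) lapply(ids, function(id) {
    st <- get_stimulus(catalog, stimulus_id = id)
    list(image = st$image, label = clamp01(st$components$specular))
  })
  train_set <- dataset(split$train)
  val_set <- dataset(split$val)

  m <- zero_like(net$layers); v <- zero_like(net$layers)
  tstep <- 0
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep),
                     sample.int(length(train_set)))
    ep_loss <- 0; n_seen <- 0
    for (b0 in seq(1, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      grad <- NULL
      for (i in idx) {
        ex <- train_set[[i]]
        fw <- net_forward(net, ex$image, keep_state = TRUE)
        loss <- bce_loss(fw$pred, ex$label)
        if (!is.finite(loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d, example %d", ep, i))
        }
        ep_loss <- ep_loss + loss; n_seen <- n_seen + 1
        npix <- length(ex$label)
        dzO <- matrix((as.numeric(fw$pred) - as.numeric(ex$label)) / npix,
                      ncol = 1)
        g <- net_backward(net, fw$state, dzO)
        grad <- if (is.null(grad)) g else map2_layers(grad, g, `+`)
      }
      grad <- map2_layers(grad, grad, function(a, b) a / length(idx))
      tstep <- tstep + 1
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      m <- map2_layers(m, grad, function(a, g) b1 * a + (1 - b1) * g)
      v <- map2_layers(v, grad, function(a, g) b2 * a + (1 - b2) * g^2)
      corr <- lr * sqrt(1 - b2^tstep) / (1 - b1^tstep)
      upd <- map2_layers(m, v, function(a, b) corr * a / (sqrt(b) + eps))
      net$layers <- map2_layers(net$layers, upd, `-`)
    }
    val_loss <- mean(vapply(val_set, function(ex) {
      bce_loss(net_forward(net, ex$image)$pred, ex$label)
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / n_seen,
                                 val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f, val %.4f", ep,
                      ep_loss / n_seen, val_loss))
    }
  }
  net$trained <- TRUE
  net$log <- log
  net$val_ids <- split$val
  net
}

#' Mean BCE of a network over a set of stimuli
#'
#' @param net A `gloss_net`.
#' @param stimuli List of `gloss_stimulus` objects (or of
#'   `list(image, label)` pairs).
#' @param mask Optional connection mask.
#' @return Scalar mean per-pixel binary cross-entropy.
#' @export
net_validation_loss <- function(net, stimuli, mask = NULL) {
  mean(vapply(stimuli, function(st) {
    if (inherits(st, "gloss_stimulus")) {
      st <- list(image = st$image, label = clamp01(st$components$specular))
    }
    bce_loss(net_forward(net, st$image, mask = mask)$pred, st$label)
  }, numeric(1)))
}

#' Save / load a network checkpoint
#'
#' The checkpoint is an RDS bundle of weights and config with the config
#' additionally embedded as JSON text (self-describing across versions);
#' the training log is written alongside as CSV when present.
#'
#' @param net A `gloss_net`.
#' @param path Checkpoint path (`.rds`); the log goes to `<path>.log.csv`.
#' @return `path` (write) or a `gloss_net` (read).
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "gloss_net"))
  net$config_json <- as.character(
    jsonlite::toJSON(unclass(net$config), auto_unbox = TRUE))
  saveRDS(net, path)
  if (!is.null(net$log)) {
    utils::write.csv(net$log, paste0(path, ".log.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "gloss_net"))
  net
}
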