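#' Generate an undulating height field
#'
#' Synthesizes a wavy surface as a seeded sum of `n_waves` directional
#' sinusoids with 1/f amplitude falloff, emulating ocean-like undulation at
#' four geometric scales. The dominant spatial frequency doubles with each
#' `scale_level` step, so level 0 is the coarsest surface and level 3 the
#' finest. The field is rescaled so that its root-mean-square slope equals
#' `rms_slope`, which keeps the expected highlight coverage comparable
#' across scale levels.
#'
#' Coordinates are row-major and 0-based; pixel centers sit at
#' `(index + 0.5) / size` in surface-plane units, the surface spanning the
#' unit square.
#'
#' @param scale_level Integer in 0..3, spatial scale of the surface waves.
#' @param seed Integer seed; identical arguments give bit-identical fields.
#' @param size Image side length in pixels; must be divisible by 64.
#' @param n_waves Number of sinusoidal components (default 24).
#' @param rms_slope Target root-mean-square surface slope (default 0.35,
#'   part of the generator's default calibration).
#' @return An object of class `gloss_heightfield`: list with `heights`
#'   (size x size matrix, surface-plane units), `normals` (size x size x 3
#'   array of unit vectors), `curvature` (discrete Laplacian of the
#'   heights), and `waves` (the realized wave table: amplitude, frequency,
#'   direction, phase -- including the slope normalization, so
#'   `sum(A * sin(2*pi*f*(x*cos(th) + y*sin(th)) + phi))` reproduces any
#'   height exactly).
#' @export
make_heightfield <- function(scale_level, seed, size,
                             n_waves = 24L, rms_slope = 0.35) {
  if (!scale_level %in% 0:3) stop("`scale_level` must be in 0..3")
  if (size < 64) stop("`size` must be at least 64 pixels")
  if (size %% 64 != 0) {
    stop("`size` must be divisible by 64 so the 1/64 pyramid level is at least 1 pixel")
  }
  f_dom <- 2 * 2^scale_level # cycles per image width

  waves <- with_seed(derive_seed(seed, "heightfield", scale_level, size), {
    theta <- runif(n_waves, 0, 2 * pi)
    # frequencies within one octave of the dominant frequency
    f <- f_dom * 2^runif(n_waves, -0.5, 0.5)
    phi <- runif(n_waves, 0, 2 * pi)
    amp <- 1 / f # 1/f falloff
    data.frame(amplitude = amp, frequency = f, direction = theta, phase = phi)
  })

  xy <- (seq_len(size) - 0.5) / size
  x <- matrix(xy, size, size, byrow = TRUE)  # column coordinate
  y <- matrix(xy, size, size)                # row coordinate

  h <- matrix(0, size, size)
  if (n_waves > 0 && rms_slope > 0) {
    for (k in seq_len(n_waves)) {
      w <- waves[k, ]
      h <- h + w$amplitude *
        sin(2 * pi * w$frequency * (x * cos(w$direction) + y * sin(w$direction)) + w$phase)
    }
    # normalize to the target RMS slope, measured on the grid itself
    g <- grad_central(h, spacing = 1 / size)
    cur <- sqrt(mean(g$gx^2 + g$gy^2))
    scl <- if (cur > 0) rms_slope / cur else 0
    h <- h * scl
    waves$amplitude <- waves$amplitude * scl
  } else {
    waves <- waves[0, ]
  }

  g <- grad_central(h, spacing = 1 / size)
  nz <- 1 / sqrt(g$gx^2 + g$gy^2 + 1)
  normals <- array(c(-g$gx * nz, -g$gy * nz, nz), dim = c(size, size, 3))
  curv <- laplacian(h, spacing = 1 / size)

  structure(
    list(heights = h, normals = normals, curvature = curv,
         waves = waves, scale_level = scale_level, seed = seed, size = size),
    class = "gloss_heightfield"
  )
}

# Central differences in the interior, one-sided at the borders.
# x varies along columns, y along rows.
grad_central <- function(h, spacing = 1) {
  n <- nrow(h); m <- ncol(h)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  gx[, 2:(m - 1)] <- (h[, 3:m] - h[, 1:(m - 2)]) / (2 * spacing)
  gx[, 1] <- (h[, 2] - h[, 1]) / spacing
  gx[, m] <- (h[, m] - h[, m - 1]) / spacing
  gy[2:(n - 1), ] <- (h[3:n, ] - h[1:(n - 2), ]) / (2 * spacing)
  gy[1, ] <- (h[2, ] - h[1, ]) / spacing
  gy[n, ] <- (h[n, ] - h[n - 1, ]) / spacing
  list(gx = gx, gy = gy)
}

# Discrete 5-point Laplacian with replicated borders; mean-curvature proxy.
laplacian <- function(h, spacing = 1) {
  n <- nrow(h); m <- ncol(h)
  up <- h[c(1, 1:(n - 1)), ]
  dn <- h[c(2:n, n), ]
  lf <- h[, c(1, 1:(m - 1))]
  rt <- h[, c(2:m, m)]
  (up + dn + lf + rt - 4 * h) / spacing^2
}
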