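#' Generate a procedural texture map
#'
#' Three texture families at four spatial scales each, used as albedo maps
#' multiplying the diffuse component. Feature size doubles with each
#' `tex_scale` step. Every map is rescaled so that its minimum is at least
#' 0.1 and its maximum equals `t_max`, making the bright patches
#' confusable with specular highlights.
#'
#' * `voronoi`: normalized distance to the nearest of a seeded set of
#'   feature sites (cell count quarters per scale step).
#' * `marble`: sinusoidal bands of a coordinate plus seeded turbulence.
#' * `checker`: binary checkerboard.
#'
#' @param kind One of `"voronoi"`, `"marble"`, `"checker"`.
#' @param tex_scale Integer in 0..3.
#' @param seed Integer seed; identical arguments give identical maps.
#' @param size Side length in pixels.
#' @param t_max Maximum texture value (default 1).
#' @return A size x size numeric matrix in `[0.1, t_max]`.
#' @export
make_texture <- function(kind = c("voronoi", "marble", "checker"),
                         tex_scale, seed, size, t_max = 1) {
  kind <- match.arg(kind)
  if (!tex_scale %in% 0:3) stop("`tex_scale` must be in 0..3")
  raw <- switch(kind,
    voronoi = texture_voronoi(tex_scale, seed, size),
    marble = texture_marble(tex_scale, seed, size),
    checker = texture_checker(tex_scale, size)
  )
  rescale_texture(raw, t_max)
}

rescale_texture <- function(x, t_max = 1, t_min = 0.1) {
  rng <- range(x)
  if (rng[2] > rng[1]) {
    t_min + (x - rng[1]) / (rng[2] - rng[1]) * (t_max - t_min)
  } else {
    matrix(t_max, nrow(x), ncol(x))
  }
}

# pixel-center coordinates in [0,1]
coord_grids <- function(size) {
  xy <- (seq_len(size) - 0.5) / size
  list(x = matrix(xy, size, size, byrow = TRUE), y = matrix(xy, size, size))
}

voronoi_site_count <- function(tex_scale) c(256L, 64L, 16L, 4L)[tex_scale + 1L]

voronoi_sites <- function(tex_scale, seed) {
  n <- voronoi_site_count(tex_scale)
  with_seed(derive_seed(seed, "voronoi", tex_scale),
            cbind(runif(n), runif(n)))
}

texture_voronoi <- function(tex_scale, seed, size) {
  sites <- voronoi_sites(tex_scale, seed)
  g <- coord_grids(size)
  px <- as.numeric(g$x); py <- as.numeric(g$y)
  best <- rep(Inf, size * size)
  for (i in seq_len(nrow(sites))) {
    d2 <- (px - sites[i, 1])^2 + (py - sites[i, 2])^2
    best <- pmin(best, d2)
  }
  matrix(sqrt(best), size, size)
}

texture_marble <- function(tex_scale, seed, size) {
  f <- 8 / 2^tex_scale # band frequency, cycles per image
  g <- coord_grids(size)
  turb <- matrix(0, size, size)
  pars <- with_seed(derive_seed(seed, "marble", tex_scale), {
    list(theta = runif(6, 0, 2 * pi), phase = runif(6, 0, 2 * pi),
         freq = f * 2^runif(6, 0.5, 1.5))
  })
  for (k in 1:6) {
    turb <- turb + sin(2 * pi * pars$freq[k] *
                         (g$x * cos(pars$theta[k]) + g$y * sin(pars$theta[k])) +
                         pars$phase[k]) / k
  }
  sin(2 * pi * f * g$x + 1.5 * turb)
}

texture_checker <- function(tex_scale, size) {
  ncells <- 16 / 2^tex_scale # cells per image side
  g <- coord_grids(size)
  (floor(g$x * ncells) + floor(g$y * ncells)) %% 2
}

#' Build a false-highlight texture from another scene's specular map
#'
#' Turns the ground-truth specular component of a *different* surface into
#' an albedo map, producing bright highlight-like patches whose positions
#' and orientations are incongruent with the target surface's geometry.
#' The map is `1 + gain * donor` rescaled so its maximum is 1; a zero donor
#' therefore reduces exactly to the plain (all-ones) condition.
#'
#' @param donor_specular Specular matrix from the donor scene.
#' @param gain Contrast of the transplanted patches (default 4, giving a
#'   roughly 5:1 patch-to-background ratio).
#' @param donor_scene_id,target_scene_id Optional ids; if both given they
#'   must differ (a surface may not donate to itself).
#' @return A texture matrix in `(0, 1]`.
#' @export
make_false_highlight_texture <- function(donor_specular, gain = 4,
                                         donor_scene_id = NULL,
                                         target_scene_id = NULL) {
  if (!is.null(donor_scene_id) && !is.null(target_scene_id) &&
      donor_scene_id == target_scene_id) {
    stop("false-highlight donor must come from a different scene")
  }
  if (any(donor_specular < 0)) stop("donor specular map must be non-negative")
  tex <- 1 + gain * donor_specular
  tex / max(tex)
}
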