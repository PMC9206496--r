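#' Scene specification for one rendered surface
#'
#' Bundles everything needed to deterministically re-render one scene: the
#' surface scale level and seed, the image size, and the square light
#' source geometry. The camera views the surface at a fixed 45 degree
#' elevation from the negative-y side, at unit vertical distance above the
#' surface plane; the light source is a square parallel to the surface at
#' `light_height` times that vertical distance (drawn uniformly from
#' [3.8, 4.8] when unspecified), centered above `light_center`.
#'
#' @param scene_id Integer scene identifier.
#' @param scale_level Integer in 0..3, surface perturbation scale.
#' @param seed Integer seed controlling geometry and light placement.
#' @param image_size Side length in pixels (default 256); divisible by 64.
#' @param light_center Length-2 vector in surface-plane units, or `NULL` to
#'   draw uniformly from `[0.2, 0.8]^2`.
#' @param light_height Height of the light plane in camera-vertical-distance
#'   units, or `NULL` to draw from `[3.8, 4.8]`.
#' @param light_half_width Half side length of the square source (default 0.30).
#' @param rms_slope Surface RMS slope passed to [make_heightfield()].
#' @return A `gloss_scene` list.
#' @export
scene_spec <- function(scene_id, scale_level, seed, image_size = 256,
                       light_center = NULL, light_height = NULL,
                       light_half_width = 0.30, rms_slope = 0.35) {
  if (image_size %% 64 != 0) stop("`image_size` must be divisible by 64")
  drawn <- with_seed(derive_seed(seed, "scene", scene_id), {
    list(center = runif(2, 0.2, 0.8), height = runif(1, 3.8, 4.8))
  })
  if (is.null(light_center)) light_center <- drawn$center
  if (is.null(light_height)) light_height <- drawn$height
  if (light_height < 3.8 || light_height > 4.8) {
    stop("`light_height` must lie in [3.8, 4.8] camera-distance units")
  }
  structure(
    list(scene_id = as.integer(scene_id), scale_level = as.integer(scale_level),
         seed = as.integer(seed), image_size = as.integer(image_size),
         light_center = as.numeric(light_center),
         light_height = light_height, light_half_width = light_half_width,
         view_elevation = 45, rms_slope = rms_slope),
    class = "gloss_scene"
  )
}

# Fixed viewing geometry: 45 degree elevation from the negative-y side.
VIEW_DIR <- c(0, -1, 1) / sqrt(2)
CAMERA_POS <- c(0.5, -0.5, 1) # unit vertical distance above the plane

#' Render the intrinsic components of a scene
#'
#' A local-illumination replacement for a path tracer: the square light
#' source is sampled on a `j_samples` x `j_samples` grid; diffuse shading is
#' Lambertian with inverse-square distance attenuation, and the specular
#' component is a sharp Blinn-Phong lobe (exponent `alpha`) with the fixed
#' 45 degree view direction. Only direct light is modelled, so the specular
#' map is exact ground truth for direct specular reflection. Gains are
#' calibrated package defaults chosen so that the brightest highlights
#' approach 1 and roughly 3% of pixels carry nonzero specularity under the
#' default generator settings.
#'
#' @param hf A `gloss_heightfield`.
#' @param scene A `gloss_scene` (sizes must agree).
#' @param alpha Blinn-Phong exponent (default 3000; sharp lobe).
#' @param j_samples Light samples per axis (default 5).
#' @param diffuse_gain,specular_gain Fixed output gains (calibrated defaults).
#' @param keep_geometry Keep per-pixel geometry buffers for the predictor
#'   bank (default TRUE).
#' @return A `gloss_components` list: `shading` and `specular` matrices in
#'   `[0, 1]`, `depth` (camera distance), and optionally `geometry`, a list
#'   of per-pixel buffers (angles, distances, normals, curvature).
#' @export
shade_components <- function(hf, scene, alpha = 3000, j_samples = 5,
                             diffuse_gain = 0.75, specular_gain = 18,
                             keep_geometry = TRUE) {
  stopifnot(inherits(hf, "gloss_heightfield"), inherits(scene, "gloss_scene"))
  size <- hf$size
  if (size != scene$image_size) stop("height field and scene sizes disagree")

  nrm <- matrix(hf$normals, size * size, 3) # rows: pixels (column-major)
  nn <- sqrt(rowSums(nrm^2))
  bad <- which(nn < 1e-8)
  if (length(bad)) {
    stop(sprintf("degenerate (zero-norm) normal at pixel index %d (0-based row %d, col %d)",
                 bad[1] - 1L, (bad[1] - 1L) %% size, (bad[1] - 1L) %/% size))
  }

  xy <- (seq_len(size) - 0.5) / size
  px <- rep(xy, each = size)  # column coordinate, column-major order
  py <- rep(xy, times = size) # row coordinate
  pz <- as.numeric(hf$heights)

  off <- if (j_samples == 1) 0 else seq(-scene$light_half_width,
                                        scene$light_half_width,
                                        length.out = j_samples)
  w <- 1 / j_samples^2
  lh <- scene$light_height
  diffuse <- numeric(size * size)
  specular <- numeric(size * size)
  for (ox in off) {
    for (oy in off) {
      lx <- scene$light_center[1] + ox - px
      ly <- scene$light_center[2] + oy - py
      lz <- lh - pz
      d2 <- lx^2 + ly^2 + lz^2
      d <- sqrt(d2)
      ndotl <- (nrm[, 1] * lx + nrm[, 2] * ly + nrm[, 3] * lz) / d
      diffuse <- diffuse + w * pmax(0, ndotl) * (lh^2 / d2)
      hx <- lx / d + VIEW_DIR[1]
      hy <- ly / d + VIEW_DIR[2]
      hz <- lz / d + VIEW_DIR[3]
      hn <- sqrt(hx^2 + hy^2 + hz^2)
      ndoth <- pmax(0, (nrm[, 1] * hx + nrm[, 2] * hy + nrm[, 3] * hz) / hn)
      specular <- specular + w * ndoth^alpha
    }
  }

  shading <- matrix(clamp01(diffuse_gain * diffuse), size, size)
  spec <- matrix(clamp01(specular_gain * specular), size, size)
  cam_dist <- sqrt((px - CAMERA_POS[1])^2 + (py - CAMERA_POS[2])^2 +
                     (pz - CAMERA_POS[3])^2)
  depth <- matrix(cam_dist, size, size)

  geometry <- NULL
  if (keep_geometry) {
    lcx <- scene$light_center[1] - px
    lcy <- scene$light_center[2] - py
    lcz <- lh - pz
    ld <- sqrt(lcx^2 + lcy^2 + lcz^2)
    ndotlc <- (nrm[, 1] * lcx + nrm[, 2] * lcy + nrm[, 3] * lcz) / ld
    ndotv <- nrm[, 1] * VIEW_DIR[1] + nrm[, 2] * VIEW_DIR[2] + nrm[, 3] * VIEW_DIR[3]
    geometry <- list(
      camera_distance = depth,
      angle_to_camera = matrix(acos(pmin(1, pmax(-1, ndotv))), size, size),
      light_distance = matrix(ld, size, size),
      angle_to_light = matrix(acos(pmin(1, pmax(-1, ndotlc))), size, size),
      normal_x = matrix(nrm[, 1], size, size),
      normal_y = matrix(nrm[, 2], size, size),
      normal_z = matrix(nrm[, 3], size, size),
      curvature = hf$curvature
    )
  }

  structure(
    list(shading = shading, specular = spec, depth = depth,
         geometry = geometry, size = size, scene = scene),
    class = "gloss_components"
  )
}
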