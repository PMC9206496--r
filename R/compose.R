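#' Stimulus condition names
#'
#' The 15 conditions rendered for every scene: one plain (untextured)
#' surface, four spatial scales each of voronoi, marble and checker
#' textures, and two false-highlight conditions whose texture is another
#' scene's specular map.
#'
#' @param false_highlights Include the two false-highlight conditions
#'   (default TRUE).
#' @return Character vector of condition names (length 15, or 13).
#' @export
gloss_conditions <- function(false_highlights = TRUE) {
  conds <- c("plain",
             paste0("voronoi_", 0:3),
             paste0("marble_", 0:3),
             paste0("checker_", 0:3))
  if (false_highlights) conds <- c(conds, "false_1", "false_2")
  conds
}

condition_texture_kind <- function(condition) {
  ifelse(condition == "plain", "plain",
         ifelse(grepl("^false_", condition), "false", sub("_[0-3]$", "", condition)))
}

#' Compose a stimulus image from its intrinsic components
#'
#' The compositing convention is the standard dichromatic model:
#' `image = clip(shading * texture + specular, 0, 1)`. The texture map acts
#' as albedo on the diffuse component only, so the ground-truth specular
#' map is identical across all texture conditions of a scene and is exactly
#' additive in the image.
#'
#' @param components A `gloss_components` object.
#' @param texture Texture matrix of the same size (use a matrix of ones, or
#'   `NULL`, for the plain condition).
#' @param condition Condition name (see [gloss_conditions()]).
#' @return A `gloss_stimulus`: list with `image`, `components`,
#'   `texture_map`, `condition` and `scene`.
#' @export
compose <- function(components, texture = NULL, condition = "plain") {
  stopifnot(inherits(components, "gloss_components"))
  size <- components$size
  if (is.null(texture)) texture <- matrix(1, size, size)
  if (!all(dim(texture) == c(size, size))) {
    stop(sprintf("texture is %dx%d but components are %dx%d",
                 nrow(texture), ncol(texture), size, size))
  }
  image <- clamp01(components$shading * texture + components$specular)
  structure(
    list(image = image, components = components, texture_map = texture,
         condition = condition, scene = components$scene),
    class = "gloss_stimulus"
  )
}

# Rotate a matrix 90 degrees counter-clockwise about the image center.
rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

#' Rotate the specular component of a plain stimulus
#'
#' Globally rotates the entire ground-truth specular map by a multiple of
#' 90 degrees (counter-clockwise) about the image center and recomposes the
#' image from the *unrotated* shading plus the rotated specular component.
#' Used to test sensitivity to the photo-geometric congruence of highlights
#' with surface shading. Only untextured (plain) stimuli may be rotated.
#'
#' @param record A plain-condition `gloss_stimulus`.
#' @param angle One of 0, 90, 180, 270 (degrees counter-clockwise).
#' @return A `gloss_stimulus` whose stored ground truth is the rotated map.
#' @export
rotate_specular <- function(record, angle) {
  stopifnot(inherits(record, "gloss_stimulus"))
  if (record$condition != "plain") {
    stop("only plain (untextured) stimuli can have their specular component rotated")
  }
  if (!angle %in% c(0, 90, 180, 270)) {
    stop("`angle` must be one of 0, 90, 180, 270 degrees")
  }
  if (angle == 0) return(record)
  spec <- record$components$specular
  for (i in seq_len(angle / 90)) spec <- rot90_ccw(spec)
  comp <- record$components
  comp$specular <- spec
  out <- record
  out$components <- comp
  out$image <- clamp01(comp$shading * record$texture_map + spec)
  out$rotation <- angle
  out
}
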