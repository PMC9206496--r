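#' Build a catalog of rendered stimuli
#'
#' Renders `n_scenes` surfaces (scale levels balanced across the four
#' levels) and enumerates the 15 conditions of each: 1 plain + 12 textured
#' + 2 false-highlight. Shading and specular components are rendered once
#' per scene and shared across all of its conditions; texture maps are
#' deterministic in their seeds and are re-synthesized on demand by
#' [get_stimulus()], which keeps the catalog small. False-highlight donor
#' scenes are drawn (seeded) from the other scenes in the catalog.
#'
#' With `render = FALSE` only the metadata table is enumerated, which
#' supports combinatorial checks at full scale (10,939 scenes enumerate to
#' 164,085 records) without rendering.
#'
#' @param n_scenes Number of surfaces (>= 2 when false highlights are on).
#' @param size Image side length in pixels, divisible by 64 (default 128).
#' @param seed Integer master seed.
#' @param false_highlights Include the two false-highlight conditions.
#' @param render Render components (default TRUE); FALSE = metadata only.
#' @param keep_geometry Keep per-pixel geometry buffers (needed by the
#'   predictor bank; default FALSE to save memory).
#' @param rms_slope,light_half_width Generator calibration, passed through.
#' @return A `gloss_catalog`: list with `scenes` (per-scene spec,
#'   components, donor ids, texture seeds) and `meta` (one row per
#'   stimulus: `stimulus_id`, `scene_id`, `condition`, `texture_kind`,
#'   `tex_scale`, `scale_level`).
#' @export
build_catalog <- function(n_scenes, size = 128, seed = 1,
                          false_highlights = TRUE, render = TRUE,
                          keep_geometry = FALSE,
                          rms_slope = 0.35, light_half_width = 0.30) {
  if (n_scenes < 1) stop("`n_scenes` must be at least 1")
  if (false_highlights && n_scenes < 2) {
    stop("false-highlight conditions need at least 2 scenes (no donor available)")
  }
  scale_levels <- rep(0:3, length.out = n_scenes)
  conds <- gloss_conditions(false_highlights)

  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene_seed <- derive_seed(seed, "scene-seed", i)
    spec <- scene_spec(scene_id = i, scale_level = scale_levels[i],
                       seed = scene_seed, image_size = size,
                       light_half_width = light_half_width,
                       rms_slope = rms_slope)
    donors <- if (false_highlights) {
      others <- setdiff(seq_len(n_scenes), i)
      with_seed(derive_seed(seed, "donor", i),
                others[sample.int(length(others), 2, replace = n_scenes < 3)])
    } else integer(0)
    comp <- NULL
    if (render) {
      hf <- make_heightfield(scale_levels[i], scene_seed, size,
                             rms_slope = rms_slope)
      comp <- shade_components(hf, spec, keep_geometry = keep_geometry)
    }
    scenes[[i]] <- list(spec = spec, components = comp, donors = donors)
  }

  meta <- data.frame(
    scene_id = rep(seq_len(n_scenes), each = length(conds)),
    condition = rep(conds, times = n_scenes),
    stringsAsFactors = FALSE
  )
  meta$stimulus_id <- sprintf("s%04d_%s", meta$scene_id, meta$condition)
  meta$texture_kind <- condition_texture_kind(meta$condition)
  meta$tex_scale <- rep(NA_integer_, nrow(meta))
  sel <- grepl("_[0-3]$", meta$condition) & meta$texture_kind != "false"
  meta$tex_scale[sel] <- as.integer(sub("^.*_", "", meta$condition[sel]))
  meta$scale_level <- scale_levels[meta$scene_id]

  structure(
    list(scenes = scenes, meta = meta, size = size, seed = seed,
         n_scenes = n_scenes, false_highlights = false_highlights,
         rendered = render, epsilon = GLOSS_EPSILON),
    class = "gloss_catalog"
  )
}

#' @export
print.gloss_catalog <- function(x, ...) {
  cat(sprintf("gloss_catalog: %d scenes x %d conditions = %d stimuli (%dpx, %s)\n",
              x$n_scenes, length(gloss_conditions(x$false_highlights)),
              nrow(x$meta), x$size,
              if (x$rendered) "rendered" else "metadata only"))
  invisible(x)
}

#' Materialize one stimulus from a catalog
#'
#' Composes the stimulus image for one catalog row, re-synthesizing the
#' texture map deterministically from its seed.
#'
#' @param catalog A rendered `gloss_catalog`.
#' @param scene_id Scene number.
#' @param condition Condition name, or a `stimulus_id` via `stimulus_id=`.
#' @param stimulus_id Alternative lookup by id string.
#' @return A `gloss_stimulus`.
#' @export
get_stimulus <- function(catalog, scene_id = NULL, condition = NULL,
                         stimulus_id = NULL) {
  stopifnot(inherits(catalog, "gloss_catalog"))
  if (!catalog$rendered) stop("catalog was built with render = FALSE")
  if (!is.null(stimulus_id)) {
    row <- catalog$meta[catalog$meta$stimulus_id == stimulus_id, ]
    if (nrow(row) != 1) stop("unknown stimulus_id: ", stimulus_id)
    scene_id <- row$scene_id; condition <- row$condition
  }
  sc <- catalog$scenes[[scene_id]]
  size <- catalog$size
  kind <- condition_texture_kind(condition)
  texture <- switch(kind,
    plain = NULL,
    false = {
      k <- as.integer(sub("^false_", "", condition))
      donor <- sc$donors[k]
      make_false_highlight_texture(
        catalog$scenes[[donor]]$components$specular,
        donor_scene_id = donor, target_scene_id = scene_id)
    },
    make_texture(kind, tex_scale = as.integer(sub("^.*_", "", condition)),
                 seed = derive_seed(catalog$seed, "texture", scene_id, condition),
                 size = size)
  )
  compose(sc$components, texture, condition)
}

#' Split a catalog into training and validation stimuli
#'
#' Withholds a validation subset balanced over surface scale level and
#' texture condition: within every (scale_level, condition) cell a
#' proportional, seeded sample of stimuli is withheld.
#'
#' @param catalog A `gloss_catalog`.
#' @param val_fraction Fraction of stimuli to withhold (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `val`, character vectors of stimulus ids.
#' @export
split_catalog <- function(catalog, val_fraction = 0.2, seed = 1) {
  meta <- catalog$meta
  cells <- split(seq_len(nrow(meta)),
                 paste(meta$scale_level, meta$condition))
  val <- with_seed(derive_seed(seed, "split"), {
    v <- unlist(lapply(cells, function(idx) {
      k <- round(length(idx) * val_fraction)
      if (k == 0) return(integer(0))
      idx[sample.int(length(idx), k)]
    }), use.names = FALSE)
    # tiny catalogs: never return an empty validation set
    if (!length(v) && val_fraction > 0 && nrow(meta) > 1) {
      v <- sample.int(nrow(meta), max(1L, round(nrow(meta) * val_fraction)))
    }
    v
  })
  list(train = meta$stimulus_id[setdiff(seq_len(nrow(meta)), val)],
       val = meta$stimulus_id[sort(val)])
}

#' Mean fraction of specular pixels in a catalog
#'
#' The calibration statistic of the stimulus generator: the fraction of
#' pixels whose ground-truth specular value exceeds the highlight floor
#' [gloss_epsilon()], averaged over scenes. The generator's defaults are
#' calibrated so this is approximately 0.03.
#'
#' @param catalog A rendered `gloss_catalog`.
#' @return Scalar mean fraction.
#' @export
specular_fraction <- function(catalog) {
  stopifnot(inherits(catalog, "gloss_catalog"), catalog$rendered)
  mean(vapply(catalog$scenes, function(sc) {
    mean(sc$components$specular > GLOSS_EPSILON)
  }, numeric(1)))
}

#' Write a catalog to disk
#'
#' Writes a JSON-lines manifest (one record per stimulus), 16-bit ASCII PGM
#' display copies of the images, and full-precision component bundles (RDS)
#' per scene.
#'
#' @param catalog A rendered `gloss_catalog`.
#' @param dir Output directory (created if absent).
#' @param images Write PGM images (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir, images = TRUE) {
  stopifnot(inherits(catalog, "gloss_catalog"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (images) dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "components"), showWarnings = FALSE)
  man <- file(file.path(dir, "manifest.jsonl"), "w")
  on.exit(close(man))
  for (i in seq_len(nrow(catalog$meta))) {
    row <- catalog$meta[i, ]
    sc <- catalog$scenes[[row$scene_id]]
    rec <- list(stimulus_id = row$stimulus_id, scene_id = row$scene_id,
                condition = row$condition, scale_level = row$scale_level,
                seed = sc$spec$seed, light_center = sc$spec$light_center,
                light_height = sc$spec$light_height,
                image = if (images) file.path("images", paste0(row$stimulus_id, ".pgm")) else NULL,
                components = file.path("components", sprintf("s%04d.rds", row$scene_id)))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), man)
    if (images) {
      stim <- get_stimulus(catalog, row$scene_id, row$condition)
      write_pgm(stim$image, file.path(dir, "images", paste0(row$stimulus_id, ".pgm")))
    }
  }
  for (i in seq_len(catalog$n_scenes)) {
    saveRDS(catalog$scenes[[i]],
            file.path(dir, "components", sprintf("s%04d.rds", i)))
  }
  invisible(dir)
}
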