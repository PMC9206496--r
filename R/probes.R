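#' Categorize pixels by ground-truth / threshold-model agreement
#'
#' Crosses the binarized ground truth (specular value above the highlight
#' floor) with the binarized threshold prediction (nonzero or zero):
#' * `a` - both say highlight,
#' * `b` - threshold only (bright but not specular),
#' * `c` - ground truth only (specular but below threshold),
#' * `d` - both say none.
#'
#' @param gt Ground-truth specular matrix.
#' @param tm Threshold-model prediction matrix of the same shape.
#' @param epsilon Highlight floor (default [gloss_epsilon()]).
#' @return Character matrix of labels in `{"a","b","c","d"}` partitioning
#'   all pixels.
#' @export
categorize_pixels <- function(gt, tm, epsilon = gloss_epsilon()) {
  if (!all(dim(gt) == dim(tm))) stop("gt and tm maps have different shapes")
  g <- gt > epsilon
  t <- tm > 0
  out <- matrix("d", nrow(gt), ncol(gt))
  out[g & t] <- "a"
  out[!g & t] <- "b"
  out[g & !t] <- "c"
  out
}

# Per-category continuous selection scores; -Inf outside the category.
# Each score maximizes the confidence of the defining pattern: a = strength
# of agreement, b = threshold confidence, c = ground-truth strength, d =
# the threshold model's sub-threshold intensity margin (t - x): the most
# confidently non-highlight pixel, i.e. the "easy baseline" of the design.
probe_scores <- function(category, image, gt, tm, tmodel, epsilon) {
  g <- gt > epsilon
  t <- tm > 0
  s <- matrix(-Inf, nrow(gt), ncol(gt))
  switch(category,
    a = { m <- g & t;  s[m] <- pmin(gt, tm)[m] },
    b = { m <- !g & t; s[m] <- tm[m] },
    c = { m <- g & !t; s[m] <- gt[m] },
    d = { m <- !g & !t & image <= tmodel$threshold
          s[m] <- tmodel$threshold - image[m] }
  )
  s
}

# Row-major argmax with ties broken by lowest (row, col); returns 0-based
# coordinates and the score.
argmax_rowmajor <- function(s) {
  v <- as.numeric(t(s))
  i <- which.max(v)
  if (!is.finite(v[i])) return(NULL)
  list(row = (i - 1L) %/% ncol(s), col = (i - 1L) %% ncol(s), score = v[i])
}

#' Select probe pixels for behavioral testing
#'
#' Implements the probe design: `n_four` images carry one probe from each
#' of the four categories, and `n_two` further images carry probes only
#' from the disagreement categories b and c (the default design yields
#' 120x4 + 120x2 = 720 probes on 240 images). Within each image and
#' category the selected pixel maximizes the category's continuous score
#' (see [categorize_pixels()] and `probe_scores`), ties broken by lowest
#' (row, col) in row-major order. Image assignment to the two groups is
#' seeded-random and balanced jointly across texture condition and surface
#' scale level; images lacking a required category are skipped and a
#' replacement is drawn.
#'
#' @param catalog A rendered `gloss_catalog` (the candidate pool).
#' @param tmodel A fitted `gloss_threshold`.
#' @param n_four Number of images probed in all four categories.
#' @param n_two Number of images probed in categories b and c only.
#' @param seed Integer seed.
#' @return A `gloss_probeset`: list with `probes` (data.frame: `image_id`,
#'   `row`, `col` 0-based, `category`, `selection_score`) and `design`.
#' @export
select_probes <- function(catalog, tmodel, n_four = 120, n_two = 120, seed = 1) {
  stopifnot(inherits(catalog, "gloss_catalog"), inherits(tmodel, "gloss_threshold"))
  meta <- catalog$meta
  cells <- split(meta$stimulus_id, paste(meta$condition, meta$scale_level))
  order_in_cell <- with_seed(derive_seed(seed, "probe-cells"), {
    cells <- lapply(cells, function(ids) ids[sample.int(length(ids))])
    cells[sample.int(length(cells))]
  })

  need <- c(four = n_four, two = n_two)
  chosen <- list(four = character(0), two = character(0))
  probes <- list()
  ptr <- rep(1L, length(order_in_cell))
  skipped <- c(four = 0L, two = 0L)
  repeat {
    if (sum(need) == 0) break
    advanced <- FALSE
    for (ci in seq_along(order_in_cell)) {
      if (sum(need) == 0) break
      ids <- order_in_cell[[ci]]
      if (ptr[ci] > length(ids)) next
      id <- ids[ptr[ci]]
      ptr[ci] <- ptr[ci] + 1L
      advanced <- TRUE
      stim <- get_stimulus(catalog, stimulus_id = id)
      gt <- stim$components$specular
      tm <- predict_threshold(tmodel, stim$image)
      group <- names(need)[which.max(need)] # fill the larger deficit first
      cats <- if (group == "four") c("a", "b", "c", "d") else c("b", "c")
      picks <- lapply(cats, function(cat) {
        argmax_rowmajor(probe_scores(cat, stim$image, gt, tm, tmodel,
                                     catalog$epsilon))
      })
      if (any(vapply(picks, is.null, logical(1)))) {
        # try the other group before giving up on this image
        other <- setdiff(names(need), group)
        ok <- FALSE
        if (need[other] > 0) {
          cats <- if (other == "four") c("a", "b", "c", "d") else c("b", "c")
          picks <- lapply(cats, function(cat) {
            argmax_rowmajor(probe_scores(cat, stim$image, gt, tm, tmodel,
                                         catalog$epsilon))
          })
          if (!any(vapply(picks, is.null, logical(1)))) { group <- other; ok <- TRUE }
        }
        if (!ok) { skipped[group] <- skipped[group] + 1L; next }
      }
      chosen[[group]] <- c(chosen[[group]], id)
      need[group] <- need[group] - 1L
      for (k in seq_along(cats)) {
        p <- picks[[k]]
        probes[[length(probes) + 1L]] <-
          data.frame(image_id = id, row = p$row, col = p$col,
                     category = cats[k], selection_score = p$score,
                     stringsAsFactors = FALSE)
      }
    }
    if (!advanced) {
      stop(sprintf(paste0("probe selection exhausted the catalog: still need ",
                          "%d four-category and %d two-category images ",
                          "(%d and %d images skipped for missing categories)"),
                   need["four"], need["two"], skipped["four"], skipped["two"]))
    }
  }

  structure(
    list(probes = do.call(rbind, probes),
         design = list(n_four = n_four, n_two = n_two,
                       four_ids = chosen$four, two_ids = chosen$two),
         epsilon = catalog$epsilon, seed = seed),
    class = "gloss_probeset"
  )
}

#' @export
print.gloss_probeset <- function(x, ...) {
  cat(sprintf("gloss_probeset: %d probes on %d images (%d x4 + %d x2)\n",
              nrow(x$probes),
              length(x$design$four_ids) + length(x$design$two_ids),
              length(x$design$four_ids), length(x$design$two_ids)))
  invisible(x)
}

#' Extract per-probe values from image-space maps
#'
#' Looks up each probe's pixel in a map produced for its image, giving the
#' predictor vectors that all downstream comparisons use.
#'
#' @param probeset A `gloss_probeset`.
#' @param maps Named list of matrices keyed by `image_id` (or a function
#'   `image_id -> matrix`).
#' @return Numeric vector, one value per probe, in probe order.
#' @export
probe_values <- function(probeset, maps) {
  pr <- probeset$probes
  get <- if (is.function(maps)) maps else function(id) maps[[id]]
  ids <- unique(pr$image_id)
  out <- numeric(nrow(pr))
  for (id in ids) {
    m <- get(id)
    sel <- pr$image_id == id
    out[sel] <- m[cbind(pr$row[sel] + 1L, pr$col[sel] + 1L)]
  }
  out
}

#' Re-categorize stored probes against freshly computed maps
#'
#' Round-trip consistency check: recomputes the category of every probe
#' from the catalog and threshold model and compares with the stored label.
#'
#' @param probeset A `gloss_probeset`.
#' @param catalog The catalog it was selected from.
#' @param tmodel The threshold model used at selection.
#' @return Logical vector, one per probe (`TRUE` = consistent).
#' @export
verify_probes <- function(probeset, catalog, tmodel) {
  pr <- probeset$probes
  ok <- logical(nrow(pr))
  for (id in unique(pr$image_id)) {
    stim <- get_stimulus(catalog, stimulus_id = id)
    cm <- categorize_pixels(stim$components$specular,
                            predict_threshold(tmodel, stim$image),
                            probeset$epsilon)
    sel <- which(pr$image_id == id)
    ok[sel] <- cm[cbind(pr$row[sel] + 1L, pr$col[sel] + 1L)] == pr$category[sel]
  }
  ok
}

#' Write / read a probe set as CSV (+ JSON design sidecar)
#'
#' @param probeset A `gloss_probeset`.
#' @param path CSV path; the design sidecar gets the extension `.design.json`.
#' @return The path (write) or a `gloss_probeset` (read).
#' @export
write_probes <- function(probeset, path) {
  utils::write.csv(probeset$probes, path, row.names = FALSE)
  jsonlite::write_json(probeset$design, sub("\\.csv$", ".design.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_probes
#' @export
read_probes <- function(path) {
  probes <- utils::read.csv(path, stringsAsFactors = FALSE)
  design_path <- sub("\\.csv$", ".design.json", path)
  design <- if (file.exists(design_path)) {
    jsonlite::read_json(design_path, simplifyVector = TRUE)
  } else NULL
  structure(list(probes = probes, design = design,
                 epsilon = GLOSS_EPSILON, seed = NA),
            class = "gloss_probeset")
}
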