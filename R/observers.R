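#' Parameters of the synthetic observer model
#'
#' A generative stand-in for human observers judging single probe pixels.
#' Each observer o responds "highlight" with probability
#' `lapse/2 + (1 - lapse) *
#'   logistic(j_o * (w_gt * g + w_int * z + w_ctx * c) + b_o)`,
#' built from three cues:
#' * `g` -- the probe's ground-truth specularity scaled to `[0, 1]` over
#'   the probe set (what a physically correct observer would use);
#' * `z` -- the threshold-relative intensity, `(x - t) / 0.3` clamped to
#'   `[-1.5, 1.5]` (the saturating brightness heuristic that the threshold
#'   baseline formalizes);
#' * `c` -- local brightness contrast, `(x - boxmean) / (boxsd + 0.01)`
#'   over a 5x5 neighborhood, clamped to `[-3, 3]` and scaled by 1/3: a
#'   *contextual* cue that neither pixelwise baseline can represent, so
#'   mean responses are not fully explained by either baseline (as in
#'   real observers, where both baselines correlate only ~0.57).
#'
#' `b_o ~ Normal(bias_mean, bias_sd)` is a per-observer criterion and
#' `j_o = exp(Normal(0, weight_jitter_sd))` a per-observer multiplicative
#' sensitivity jitter. The bias and jitter terms produce *idiosyncratic
#' but stable* behavior, so that intra-rater agreement exceeds inter-rater
#' agreement; the lapse term adds pure response noise.
#'
#' Defaults are the package's one-time calibration to the published
#' qualitative response structure (see the methods vignette): category
#' ordering a > {b, c} > d, both baselines partially but not fully
#' predictive, intra > inter consistency.
#'
#' @param w_gt,w_int,w_ctx Population weights on the three cues.
#' @param bias_mean,bias_sd Per-observer criterion distribution.
#' @param weight_jitter_sd SD of the log sensitivity jitter.
#' @param lapse Lapse rate in `[0, 1]`.
#' @param n_observers Number of simulated observers.
#' @param seed Integer seed.
#' @return A `gloss_observer_params` list.
#' @export
observer_params <- function(w_gt = 2, w_int = 1.2, w_ctx = 2,
                            bias_mean = -1.2, bias_sd = 1.5,
                            weight_jitter_sd = 0.5,
                            lapse = 0.05, n_observers = 15, seed = 1) {
  if (lapse < 0 || lapse > 1) stop("`lapse` must lie in [0, 1]")
  structure(as.list(environment()), class = "gloss_observer_params")
}

#' Simulate binary observer responses at the probe pixels
#'
#' @param probeset A `gloss_probeset`.
#' @param catalog The catalog the probes refer to.
#' @param tmodel The fitted threshold model (defines the intensity cue).
#' @param params A `gloss_observer_params`.
#' @return A `gloss_responses`: list with `table` (data.frame:
#'   `observer_id`, `image_id`, `row`, `col`, `category`, `response`),
#'   and the per-observer latent parameters in `observers`.
#' @export
simulate_observers <- function(probeset, catalog, tmodel, params) {
  stopifnot(inherits(probeset, "gloss_probeset"),
            inherits(params, "gloss_observer_params"))
  pr <- probeset$probes
  missing_ids <- setdiff(unique(pr$image_id), catalog$meta$stimulus_id)
  if (length(missing_ids)) {
    stop("probe image(s) not found in catalog: ",
         paste(missing_ids, collapse = ", "))
  }
  gt <- probe_values(probeset, function(id) {
    get_stimulus(catalog, stimulus_id = id)$components$specular
  })
  intens <- probe_values(probeset, function(id) {
    get_stimulus(catalog, stimulus_id = id)$image
  })
  ctx <- probe_values(probeset, function(id) {
    img <- get_stimulus(catalog, stimulus_id = id)$image
    ls <- local_stats(img, 2L)
    (img - ls$mean) / (ls$sd + 0.01)
  })
  g <- if (max(gt) > 0) gt / max(gt) else gt
  z <- pmin(pmax((intens - tmodel$threshold) / 0.3, -1.5), 1.5)
  cx <- pmin(pmax(ctx, -3), 3) / 3

  n <- params$n_observers
  obs <- with_seed(derive_seed(params$seed, "observers"), {
    data.frame(observer_id = seq_len(n),
               bias = rnorm(n, params$bias_mean, params$bias_sd),
               jitter = exp(rnorm(n, 0, params$weight_jitter_sd)))
  })
  rows <- vector("list", n)
  for (o in seq_len(n)) {
    eta <- obs$jitter[o] * (params$w_gt * g + params$w_int * z +
                              params$w_ctx * cx) + obs$bias[o]
    p <- params$lapse / 2 + (1 - params$lapse) * plogis(eta)
    resp <- with_seed(derive_seed(params$seed, "responses", o),
                      rbinom(length(p), 1, p))
    rows[[o]] <- data.frame(observer_id = o, image_id = pr$image_id,
                            row = pr$row, col = pr$col,
                            category = pr$category, response = resp,
                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), observers = obs,
                 params = params),
            class = "gloss_responses")
}

#' Mean response per probe across observers
#'
#' @param responses A `gloss_responses` (or its `table` data.frame).
#' @param probeset Probe set defining the probe order.
#' @return Numeric vector of mean responses, aligned with the probes.
#' @export
mean_responses <- function(responses, probeset) {
  tab <- if (inherits(responses, "gloss_responses")) responses$table else responses
  pr <- probeset$probes
  key <- paste(pr$image_id, pr$row, pr$col, pr$category)
  tkey <- paste(tab$image_id, tab$row, tab$col, tab$category)
  agg <- tapply(tab$response, tkey, mean)
  out <- as.numeric(agg[key])
  if (anyNA(out)) stop("response table does not cover every probe")
  out
}

#' Read / write response tables as CSV
#' @param responses A `gloss_responses` or its table.
#' @param path CSV path.
#' @return The path (write) or a `gloss_responses` (read). A real human
#'   response CSV in the same schema (observer_id, image_id, row, col,
#'   category, response) can be read in place of simulated data.
#' @export
write_responses <- function(responses, path) {
  tab <- if (inherits(responses, "gloss_responses")) responses$table else responses
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observer_id", "image_id", "row", "col", "category", "response")
  if (!all(need %in% names(tab))) {
    stop("response CSV must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(table = tab, observers = NULL, params = NULL),
            class = "gloss_responses")
}

#' Split-half correlation of the observer group
#'
#' Randomly divides the observers in two halves `n_iter` times (sizes
#' differing by at most 1 for odd counts) and correlates the two halves'
#' mean response vectors over probes each time.
#'
#' @param responses A `gloss_responses`.
#' @param probeset The probe set (defines probe order).
#' @param n_iter Number of random splits (default 10,000).
#' @param seed Integer seed.
#' @return List with `correlations` (length `n_iter`, `NA` for excluded
#'   degenerate splits), `n_excluded`, `mean`, `max`.
#' @export
split_half_observer_correlation <- function(responses, probeset,
                                            n_iter = 10000, seed = 1) {
  tab <- responses$table
  obs <- sort(unique(tab$observer_id))
  if (length(obs) < 4) stop("need at least 4 observers for split-half analysis")
  pr <- probeset$probes
  key <- paste(pr$image_id, pr$row, pr$col, pr$category)
  # observer x probe response matrix
  R <- matrix(NA_real_, length(obs), nrow(pr),
              dimnames = list(obs, NULL))
  for (i in seq_along(obs)) {
    sub <- tab[tab$observer_id == obs[i], ]
    skey <- paste(sub$image_id, sub$row, sub$col, sub$category)
    R[i, ] <- sub$response[match(key, skey)]
  }
  half <- length(obs) %/% 2
  cors <- with_seed(derive_seed(seed, "split-half"), {
    vapply(seq_len(n_iter), function(it) {
      g1 <- sample(seq_along(obs), half)
      m1 <- colMeans(R[g1, , drop = FALSE])
      m2 <- colMeans(R[-g1, , drop = FALSE])
      if (sd(m1) == 0 || sd(m2) == 0) return(NA_real_)
      cor(m1, m2)
    }, numeric(1))
  })
  list(correlations = cors, n_excluded = sum(is.na(cors)),
       mean = mean(cors, na.rm = TRUE), max = max(cors, na.rm = TRUE))
}

#' Intra- vs inter-rater consistency
#'
#' Probes are grouped into comparability cells by (probe category, texture
#' kind of the image, surface scale level). Each iteration splits every
#' cell in half at random and pairs probes across the halves (seeded
#' random matching). Intra-rater consistency is the rate of agreement of
#' an observer with their own responses across paired probes; inter-rater
#' consistency the rate of agreement with every other observer (both pair
#' directions averaged). A paired t-test across observers compares the
#' two, with paired Cohen's d = mean(diff) / sd(diff).
#'
#' @param responses A `gloss_responses`.
#' @param probeset The probe set.
#' @param catalog Catalog providing texture kind and scale level per image.
#' @param n_iter Number of random pairings (default 1,000).
#' @param seed Integer seed.
#' @return A `gloss_consistency` list: `intra_rate`, `inter_rate`
#'   (means), per-observer means, `t`, `df`, `p`, `cohens_d`, `n_iter`,
#'   `dropped_cells`.
#' @export
rater_consistency <- function(responses, probeset, catalog, n_iter = 1000,
                              seed = 1) {
  tab <- responses$table
  pr <- probeset$probes
  obs <- sort(unique(tab$observer_id))
  meta <- catalog$meta
  mi <- match(pr$image_id, meta$stimulus_id)
  cell <- paste(pr$category, meta$texture_kind[mi], meta$scale_level[mi])

  key <- paste(pr$image_id, pr$row, pr$col, pr$category)
  R <- matrix(NA_real_, length(obs), nrow(pr))
  for (i in seq_along(obs)) {
    sub <- tab[tab$observer_id == obs[i], ]
    skey <- paste(sub$image_id, sub$row, sub$col, sub$category)
    R[i, ] <- sub$response[match(key, skey)]
  }

  cells <- split(seq_len(nrow(pr)), cell)
  small <- vapply(cells, function(ix) length(ix) < 2, logical(1))
  if (any(small)) {
    warning(sprintf("%d comparability cell(s) with < 2 probes dropped",
                    sum(small)))
    cells <- cells[!small]
  }
  if (!length(cells)) stop("no comparability cell has at least 2 probes")

  n <- length(obs)
  intra <- matrix(0, n, n_iter)
  inter <- matrix(0, n, n_iter)
  with_seed(derive_seed(seed, "consistency"), {
    for (it in seq_len(n_iter)) {
      i1 <- integer(0); i2 <- integer(0)
      for (ix in cells) {
        ix <- ix[sample.int(length(ix))]
        h <- length(ix) %/% 2
        i1 <- c(i1, ix[seq_len(h)])
        i2 <- c(i2, ix[h + seq_len(h)])
      }
      A <- R[, i1, drop = FALSE]
      B <- R[, i2, drop = FALSE]
      # agreement between every observer pair, both pair directions
      agree <- (tcrossprod(A, B) + tcrossprod(1 - A, 1 - B) +
                  tcrossprod(B, A) + tcrossprod(1 - B, 1 - A)) /
        (2 * length(i1))
      intra[, it] <- diag(agree)
      inter[, it] <- (rowSums(agree) - diag(agree)) / (n - 1)
    }
  })
  intra_obs <- rowMeans(intra)
  inter_obs <- rowMeans(inter)
  d <- intra_obs - inter_obs
  if (sd(d) == 0) {
    tt <- list(statistic = NA_real_, parameter = n - 1, p.value = NA_real_)
    cd <- NA_real_
  } else {
    tt <- stats::t.test(intra_obs, inter_obs, paired = TRUE)
    cd <- mean(d) / sd(d)
  }
  structure(
    list(intra_rate = mean(intra_obs), inter_rate = mean(inter_obs),
         intra_by_observer = intra_obs, inter_by_observer = inter_obs,
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohens_d = cd, n_iter = n_iter,
         dropped_cells = sum(small)),
    class = "gloss_consistency"
  )
}

#' @export
print.gloss_consistency <- function(x, ...) {
  cat(sprintf(
    "gloss_consistency: intra %.3f vs inter %.3f (t(%d) = %.2f, d = %.2f)\n",
    x$intra_rate, x$inter_rate, x$df,
    ifelse(is.na(x$t), NaN, x$t), ifelse(is.na(x$cohens_d), NaN, x$cohens_d)))
  invisible(x)
}

#' Write a consistency report as JSON
#'
#' @param report A `gloss_consistency`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consistency <- function(report, path) {
  stopifnot(inherits(report, "gloss_consistency"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
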