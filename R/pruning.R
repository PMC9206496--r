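#' Genetic-algorithm parameters for connection pruning
#'
#' Defaults follow the published procedure: populations of 100 genomes,
#' 10 elite survivors, 10 mutated elite copies (5% per-bit flip chance),
#' 80 children from fitness-weighted uniform crossover (1% per-bit flip
#' chance), 30 generations. `n_elites + n_mutated_elites + n_crossover`
#' must equal `population_size`.
#'
#' @param population_size,n_elites,n_mutated_elites,n_crossover Population
#'   composition.
#' @param elite_mutation_rate,crossover_mutation_rate Per-bit flip
#'   probabilities.
#' @param generations Generations per run.
#' @param n_runs Independent GA restarts (full scale: 300).
#' @param seed Integer seed.
#' @return A `gloss_ga_params` list.
#' @export
ga_params <- function(population_size = 100, n_elites = 10,
                      n_mutated_elites = 10, n_crossover = 80,
                      elite_mutation_rate = 0.05,
                      crossover_mutation_rate = 0.01,
                      generations = 30, n_runs = 1, seed = 1) {
  if (n_elites + n_mutated_elites + n_crossover != population_size) {
    stop("n_elites + n_mutated_elites + n_crossover must equal population_size")
  }
  structure(as.list(environment()), class = "gloss_ga_params")
}

#' Initialize a GA population
#'
#' `population_size - 1` genomes with every bit Bernoulli(0.5), plus the
#' all-ones (full network) genome.
#'
#' @param seed Integer seed.
#' @param population_size Number of genomes (default 100).
#' @param n_bits Genome length (default 98).
#' @return List of logical vectors.
#' @export
init_population <- function(seed, population_size = 100, n_bits = 98L) {
  pop <- with_seed(derive_seed(seed, "ga-init"), {
    lapply(seq_len(population_size - 1), function(i) runif(n_bits) < 0.5)
  })
  c(pop, list(rep(TRUE, n_bits)))
}

#' Advance a GA population by one generation
#'
#' Keeps the `n_elites` fittest genomes unchanged, adds a mutated copy of
#' each (per-bit flip probability `elite_mutation_rate`), and fills the
#' rest with children of per-bit uniform crossover between two parents
#' sampled with probability proportional to fitness (fitness is shifted to
#' positive mass; if all fitnesses are equal and non-positive, parents are
#' sampled uniformly and the result is flagged). Children mutate with
#' per-bit probability `crossover_mutation_rate`. Uses the current RNG
#' state; seed at the call site (as [run_ga()] does) for determinism.
#'
#' @param population List of logical genomes.
#' @param fitnesses Numeric vector, one per genome.
#' @param params A `gloss_ga_params`.
#' @return List of logical genomes of the same size, with attribute
#'   `uniform_parents` when the fallback triggered.
#' @export
step_generation <- function(population, fitnesses, params) {
  stopifnot(length(population) == length(fitnesses),
            length(population) == params$population_size)
  n_bits <- length(population[[1]])
  ord <- order(fitnesses, decreasing = TRUE)
  elites <- population[ord[seq_len(params$n_elites)]]
  mutated <- lapply(elites, function(g) {
    xor(g, runif(n_bits) < params$elite_mutation_rate)
  })
  w <- fitnesses - min(fitnesses)
  uniform <- FALSE
  if (sum(w) <= 0) { w <- rep(1, length(fitnesses)); uniform <- TRUE }
  children <- lapply(seq_len(params$n_crossover), function(i) {
    par <- sample.int(length(population), 2, replace = TRUE, prob = w)
    pick <- runif(n_bits) < 0.5
    child <- ifelse(pick, population[[par[1]]], population[[par[2]]])
    xor(child, runif(n_bits) < params$crossover_mutation_rate)
  })
  structure(c(elites, mutated, children), uniform_parents = uniform)
}

#' Run the genetic algorithm against an arbitrary fitness function
#'
#' The generic engine behind [prune_network()]; the fitness function maps
#' a logical genome to a scalar. Elitism guarantees that the best-so-far
#' fitness is monotone non-decreasing across generations.
#'
#' @param fitness_fn Function `genome -> numeric(1)`.
#' @param params A `gloss_ga_params`.
#' @param n_bits Genome length (default 98).
#' @return A `gloss_ga_history`: list with `history` (data.frame: run,
#'   generation, member, fitness), `best` (best-so-far per generation and
#'   run), and `final` (final population and fitnesses per run).
#' @export
run_ga <- function(fitness_fn, params, n_bits = 98L) {
  history <- list(); best_rows <- list(); final <- list()
  for (run in seq_len(params$n_runs)) {
    run_seed <- derive_seed(params$seed, "ga-run", run)
    pop <- init_population(run_seed, params$population_size, n_bits)
    with_seed(derive_seed(run_seed, "steps"), {
      best_fit <- -Inf; best_genome <- NULL
      for (gen in seq_len(params$generations)) {
        fit <- vapply(pop, fitness_fn, numeric(1))
        if (max(fit) > best_fit) {
          best_fit <- max(fit)
          best_genome <- pop[[which.max(fit)]]
        }
        history[[length(history) + 1]] <- data.frame(
          run = run, generation = gen, member = seq_along(fit), fitness = fit)
        best_rows[[length(best_rows) + 1]] <- data.frame(
          run = run, generation = gen, best_fitness = best_fit,
          genome = genome_to_hex(best_genome))
        if (gen < params$generations) pop <- step_generation(pop, fit, params)
      }
      final[[run]] <- list(population = pop,
                            fitnesses = vapply(pop, fitness_fn, numeric(1)),
                            best_genome = best_genome, best_fitness = best_fit)
    })
  }
  structure(list(history = do.call(rbind, history),
                 best = do.call(rbind, best_rows),
                 final = final, params = params),
            class = "gloss_ga_history")
}

#' @export
print.gloss_ga_history <- function(x, ...) {
  cat(sprintf("gloss_ga_history: %d run(s) x %d generations; best fitness %.4f\n",
              x$params$n_runs, x$params$generations,
              max(vapply(x$final, function(f) f$best_fitness, numeric(1)))))
  invisible(x)
}

#' Serialize a genome as a hex string
#' @param genome Logical vector.
#' @return `genome_to_hex()`: character scalar; `hex_to_genome()` inverts
#'   it given the bit length.
#' @export
genome_to_hex <- function(genome) {
  pad <- c(as.integer(genome), rep(0L, (4 - length(genome) %% 4) %% 4))
  nib <- matrix(pad, nrow = 4)
  paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
}

#' @rdname genome_to_hex
#' @param hex Character scalar.
#' @param n_bits Genome length (default 98).
#' @export
hex_to_genome <- function(hex, n_bits = 98L) {
  nib <- strtoi(strsplit(hex, "")[[1]], 16L)
  bits <- as.logical(unlist(lapply(nib, function(v) bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0)))
  bits[seq_len(n_bits)]
}

# ---- probe-prediction caching ---------------------------------------------

#' Cache probe-image state for fast masked evaluation
#'
#' Tier-1 activations and their cross-scale resamplings are independent of
#' the connection genome, so they are computed once per probe image; each
#' genome evaluation then only runs tiers 2-4.
#'
#' @param net A trained `gloss_net`.
#' @param catalog The catalog the probes were selected from.
#' @param probeset A `gloss_probeset`.
#' @return A `gloss_probe_cache`.
#' @export
probe_prediction_cache <- function(net, catalog, probeset) {
  ids <- unique(probeset$probes$image_id)
  caches <- lapply(ids, function(id) {
    st <- get_stimulus(catalog, stimulus_id = id)
    net_tier1_cache(net, st$image)
  })
  names(caches) <- ids
  structure(list(caches = caches, probeset = probeset, ids = ids),
            class = "gloss_probe_cache")
}

#' Masked network predictions at the probe pixels
#'
#' @param net A trained `gloss_net`.
#' @param cache A `gloss_probe_cache` (or `NULL` to forward from scratch,
#'   in which case `catalog` must be given).
#' @param mask 98-bit connection mask (or `NULL` for the full network).
#' @param catalog Catalog, needed only when `cache` is `NULL`.
#' @return Numeric vector, one prediction per probe.
#' @export
masked_probe_predictions <- function(net, cache, mask = NULL, catalog = NULL) {
  if (is.null(cache)) {
    stopifnot(!is.null(catalog))
    probeset <- NULL
    stop("a gloss_probe_cache is required")
  }
  preds <- lapply(cache$caches, function(cc) {
    net_forward(net, image = NULL, mask = mask, cache = cc)$pred
  })
  probe_values(cache$probeset, preds)
}

#' Fitness of one genome: correlation to mean observer responses
#'
#' Pearson correlation between the masked network's predictions at the
#' probe pixels and the mean observer response vector. Zero-variance
#' prediction vectors (e.g. fully severed networks) score 0 and are
#' flagged.
#'
#' @param net A trained `gloss_net`.
#' @param genome 98-bit logical genome.
#' @param cache A `gloss_probe_cache`.
#' @param mean_responses Mean response per probe, aligned with the cache's
#'   probe set.
#' @return A `gloss_fitness` list: `genome`, `fitness`, `degenerate`.
#' @export
evaluate_fitness <- function(net, genome, cache, mean_responses) {
  preds <- masked_probe_predictions(net, cache, mask = genome)
  if (length(preds) != length(mean_responses)) {
    stop("probe predictions and responses are not aligned")
  }
  r <- safe_cor(preds, mean_responses)
  structure(list(genome = genome, fitness = as.numeric(r),
                 degenerate = attr(r, "degenerate")),
            class = "gloss_fitness")
}

#' Prune a trained network to observer responses
#'
#' Full pipeline: builds the probe cache and runs [run_ga()] with
#' correlation-to-mean-responses fitness.
#'
#' @inheritParams evaluate_fitness
#' @param catalog Catalog for the probe images.
#' @param probeset The probe set the responses refer to.
#' @param params A `gloss_ga_params`.
#' @return A `gloss_ga_history` (see [run_ga()]), with the cache attached
#'   as attribute `cache`.
#' @export
prune_network <- function(net, catalog, probeset, mean_responses, params) {
  cache <- probe_prediction_cache(net, catalog, probeset)
  fitness_fn <- function(genome) {
    evaluate_fitness(net, genome, cache, mean_responses)$fitness
  }
  hist <- run_ga(fitness_fn, params, n_bits = 2L * net$config$n_scales^2)
  attr(hist, "cache") <- cache
  hist
}

# ---- candidate selection ---------------------------------------------------

#' Select the final pruned candidate by multi-criterion rank sum
#'
#' For every genome, four criteria are computed from its probe
#' predictions: R^2 to the mean observer responses, R^2 to ground truth,
#' R^2 between the error vectors (prediction - gt vs response - gt), and
#' RMSE to the mean responses. Genomes are ranked on each criterion
#' (descending for the R^2 terms, ascending for RMSE) and the genome with
#' the lowest rank sum wins; ties break toward higher R^2 to the mean
#' responses.
#'
#' @param genomes List of logical genomes.
#' @param predictions Matrix of probe predictions, one row per genome.
#' @param mean_responses Mean observer response per probe.
#' @param gt_at_probes Ground-truth specular value per probe.
#' @return List with `genome`, `index`, and `criteria` (data.frame with
#'   the four criteria and the rank sum for every genome).
#' @export
select_candidate <- function(genomes, predictions, mean_responses,
                             gt_at_probes) {
  stopifnot(length(genomes) >= 1, nrow(predictions) == length(genomes))
  r2 <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)^2
  }
  crit <- t(apply(predictions, 1L, function(p) {
    c(r2_mean = r2(p, mean_responses),
      r2_gt = r2(p, gt_at_probes),
      r2_error = r2(p - gt_at_probes, mean_responses - gt_at_probes),
      rmse = sqrt(mean((p - mean_responses)^2)))
  }))
  crit <- as.data.frame(crit)
  if (length(genomes) == 1) {
    crit$rank_sum <- 4
    return(list(genome = genomes[[1]], index = 1L, criteria = crit))
  }
  ranks <- cbind(rank(-crit$r2_mean), rank(-crit$r2_gt),
                 rank(-crit$r2_error), rank(crit$rmse))
  crit$rank_sum <- rowSums(ranks)
  best <- which(crit$rank_sum == min(crit$rank_sum))
  if (length(best) > 1) best <- best[which.max(crit$r2_mean[best])]
  list(genome = genomes[[best]], index = best, criteria = crit)
}

#' Write a GA history as JSON lines
#'
#' One record per (run, generation): the best-so-far genome as a hex
#' string and its fitness, plus the final population of each run.
#'
#' @param history A `gloss_ga_history`.
#' @param path Output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_ga_history <- function(history, path) {
  stopifnot(inherits(history, "gloss_ga_history"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(history$best))) {
    row <- history$best[i, ]
    writeLines(jsonlite::toJSON(
      list(run = row$run, generation = row$generation,
           genome = row$genome, fitness = row$best_fitness),
      auto_unbox = TRUE, digits = NA), con)
  }
  for (r in seq_along(history$final)) {
    fin <- history$final[[r]]
    for (m in seq_along(fin$population)) {
      writeLines(jsonlite::toJSON(
        list(run = r, generation = "final", member = m,
             genome = genome_to_hex(fin$population[[m]]),
             fitness = fin$fitnesses[m]),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
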