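geo_record <- function(scene = 1, cond = "plain") {
  get_stimulus(fx_geo_catalog(), scene, cond)
}

test_that("predictor bank has 34 predictors in category counts {1,4,4,3,11,7,4}", {
  cats <- predictor_categories()
  expect_length(cats, 34L)
  counts <- as.numeric(table(factor(cats, levels = unique(cats))))
  expect_equal(counts, c(1, 4, 4, 3, 11, 7, 4))
  bank <- compute_predictor_bank(geo_record())
  expect_setequal(names(bank), names(cats))
})

test_that("missing geometry buffers are reported with the absent predictors", {
  st <- get_stimulus(fx_catalog(), 1, "plain") # built without geometry
  expect_error(compute_predictor_bank(st), "camera_distance.*pointiness")
})

test_that("flat untextured scene: anisotropy ~ 0, convexity = 0", {
  hf <- make_heightfield(0, 1, 64, rms_slope = 0)
  co <- shade_components(hf, scene_spec(1, 0, 1, image_size = 64),
                         keep_geometry = TRUE)
  # featureless limit: constant diffuse term, no specular
  co$specular <- matrix(0, 64, 64)
  co$shading <- matrix(0.5, 64, 64)
  st <- compose(co, NULL, "plain")
  bank <- compute_predictor_bank(st)
  expect_equal(max(abs(bank$anisotropy)), 0) # no orientation signal at all
  expect_equal(max(abs(bank$grad_x)), 0)
  expect_equal(bank$convexity, rep(0, 64 * 64))
  expect_equal(bank$specular_indirect, rep(0, 64 * 64))
  expect_equal(bank$specular_coverage, 0)
  expect_equal(bank$texture_coverage, 0)
})

test_that("x-gradient of a hand-written ramp matches manual stencil arithmetic", {
  # 4x4 ramp in the column direction with slope 2 per pixel
  ramp <- matrix(rep(c(1, 3, 5, 7), each = 4), 4, 4)
  g <- glossprobe:::grad_central(ramp)
  # central differences interior, one-sided at borders
  expect_equal(g$gx, matrix(2, 4, 4))
  expect_equal(g$gy, matrix(0, 4, 4))
  mixed <- matrix(c(0, 1, 0, 2,
                    4, 2, 1, 0,
                    0, 0, 3, 1,
                    5, 0, 2, 2), 4, 4, byrow = TRUE)
  gm <- glossprobe:::grad_central(mixed)
  expect_equal(gm$gx[2, 2], (mixed[2, 3] - mixed[2, 1]) / 2)
  expect_equal(gm$gx[3, 1], mixed[3, 2] - mixed[3, 1])
  expect_equal(gm$gy[2, 3], (mixed[3, 3] - mixed[1, 3]) / 2)
})

test_that("coverage predictors and scene one-hots encode the stimulus", {
  st <- geo_record(2, "checker_1")
  bank <- compute_predictor_bank(st, scene_levels = 1:3)
  expect_equal(bank$specular_coverage,
               mean(st$components$specular > gloss_epsilon()))
  expect_gt(bank$texture_coverage, 0.4) # checker deviates from 1 broadly
  expect_equal(sum(bank$surface_scale), 1)
  expect_equal(bank$texture_type,
               as.numeric(c("plain", "voronoi", "marble", "checker",
                            "false") == "checker"))
  expect_equal(sum(bank$texture_condition), 1)
  expect_equal(bank$scene, c(0, 1, 0))
})

test_that("first-order RDM satisfies metric axioms and hand arithmetic", {
  reps <- rbind(c(0, 0), c(3, 4), c(6, 8))
  rdm <- first_order_rdm(reps)
  expect_equal(diag(rdm), rep(0, 3))
  expect_equal(rdm[1, 2], 5)
  expect_equal(rdm[1, 3], 10)
  expect_equal(rdm[2, 3], 5)
  expect_identical(rdm, t(rdm))
  expect_true(all(rdm >= 0))
  # identical representations -> all-zero RDM
  z <- first_order_rdm(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_true(all(z == 0))
  expect_error(first_order_rdm(rbind(c(1, NA), c(0, 0), c(1, 1))), "NA")
  # triangle inequality on sampled triples of a random RDM
  set.seed(2)
  reps2 <- matrix(rnorm(10 * 6), 10, 6)
  rdm2 <- first_order_rdm(reps2)
  for (k in 1:200) {
    ijk <- sample(10, 3)
    expect_lte(rdm2[ijk[1], ijk[3]],
               rdm2[ijk[1], ijk[2]] + rdm2[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("unit RDMs: dead filters are excluded, live RDMs match manual extraction", {
  net <- fx_net()
  # kill one tier-2 filter deterministically
  net$layers$tier2[[3]]$W[, 5] <- 0
  net$layers$tier2[[3]]$b[5] <- -1 # relu(-1) = 0 everywhere: dead
  catal <- fx_catalog()
  imgs <- lapply(catal$meta$stimulus_id[c(1, 5, 20, 33, 48)], function(id)
    get_stimulus(catal, stimulus_id = id)$image)
  ur <- unit_rdms(net, imgs)
  ut <- ur$units
  dead_unit <- ut$unit[ut$tier == 2 & ut$scale == 3 & ut$filter == 5]
  expect_true(dead_unit %in% ur$dead)
  expect_false(as.character(dead_unit) %in% names(ur$rdms))
  expect_equal(length(ur$rdms) + length(ur$dead), 177L)
  # manual extraction oracle for one tier-1 unit (scale 2, filter 3)
  target <- ut$unit[ut$tier == 1 & ut$scale == 2 & ut$filter == 3]
  reps <- t(vapply(imgs, function(img) {
    fw <- glossprobe:::net_forward(net, img, capture = TRUE)
    as.numeric(fw$acts$tier1[[2]][, , 3])
  }, numeric(32 * 32)))
  expect_equal(unclass(ur$rdms[[as.character(target)]]),
               unclass(first_order_rdm(reps)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("category similarity: R^2 = 1 for a matching predictor, ~0 for noise", {
  set.seed(3)
  reps <- matrix(rnorm(8 * 5), 8, 5)
  rdm <- first_order_rdm(reps)
  expect_equal(as.numeric(category_similarity(rdm, list(rdm))), 1)
  # independent random predictor: low R^2
  other <- first_order_rdm(matrix(rnorm(8 * 5), 8, 5))
  expect_lt(as.numeric(category_similarity(rdm, list(other))), 0.5)
  # 2-predictor category on 6 images vs hand-solved normal equations
  r1 <- first_order_rdm(matrix(rnorm(6 * 4), 6, 4))
  r2 <- first_order_rdm(matrix(rnorm(6 * 4), 6, 4))
  y <- upper_tri(rdm <- first_order_rdm(matrix(rnorm(6 * 4), 6, 4)))
  X <- cbind(1, upper_tri(r1), upper_tri(r2))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r2_hand <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(as.numeric(category_similarity(rdm, list(r1, r2))), r2_hand,
               tolerance = 1e-10)
  # collinear predictors are flagged
  flagged <- category_similarity(rdm, list(r1, r1))
  expect_true(attr(flagged, "collinear"))
})

test_that("second-order embedding: 1 - r arithmetic, twins, stress descent", {
  set.seed(5)
  base <- matrix(rnorm(6 * 4), 6, 4)
  rdm1 <- first_order_rdm(base)
  rdm2 <- first_order_rdm(base) # twin of rdm1
  rdm3 <- first_order_rdm(matrix(rnorm(6 * 4), 6, 4))
  rdm4 <- first_order_rdm(matrix(rnorm(6 * 4), 6, 4))
  fake_units <- list(rdms = list(`1` = rdm1, `2` = rdm2, `3` = rdm3,
                                 `4` = rdm4),
                     dead = integer(0), units = NULL)
  emb <- second_order_embedding(fake_units, seed = 4, n_iter = 60)
  # hand-computed 1 - r for all pairs
  for (i in 1:4) for (j in 1:4) {
    expected <- 1 - cor(upper_tri(fake_units$rdms[[i]]),
                        upper_tri(fake_units$rdms[[j]]))
    expect_equal(emb$second_order[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(emb$second_order[1, 2], 0, tolerance = 1e-12)
  expect_true(all(diff(emb$stress_path) <= 1e-10)) # SMACOF monotonicity
  expect_equal(dim(emb$coords), c(4L, 2L))
  expect_error(second_order_embedding(list(rdms = fake_units$rdms[1:2])),
               "at least 3")
})

test_that("lesioning a dead filter changes nothing; output lesion is fatal", {
  net <- fx_net()
  net$layers$tier3[[2]]$W[, 1] <- 0
  net$layers$tier3[[2]]$b[1] <- 0 # dead unit
  catal <- fx_catalog()
  ps <- fx_probes()
  sts <- lapply(catal$meta$stimulus_id[c(2, 10)], function(id)
    get_stimulus(catal, stimulus_id = id))
  mr <- probe_values(ps, function(id)
    get_stimulus(catal, stimulus_id = id)$components$specular)
  ut <- unit_table(net)
  dead_unit <- ut$unit[ut$tier == 3 & ut$scale == 2 & ut$filter == 1]
  out_unit <- ut$unit[ut$tier == 5]
  rep <- lesion_sweep(net, sts, catal, ps, mr, units = c(dead_unit, out_unit))
  expect_equal(rep$delta_loss[1], 0, tolerance = 1e-12)
  expect_equal(rep$delta_correlation[1], 0, tolerance = 1e-12)
  # lesioned output unit: constant prediction, flagged degenerate, and the
  # loss equals the constant-output baseline
  expect_true(rep$degenerate[2])
  const_pred <- 1 / (1 + exp(0)) # sigmoid(0)
  baseline <- mean(vapply(sts, function(st) {
    y <- pmin(pmax(st$components$specular, 0), 1)
    p <- const_pred
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1)))
  expect_equal(rep$loss[2], baseline, tolerance = 1e-10)
})

test_that("lesion differencing oracle: zeroing a filter equals zeroing its activation", {
  net <- fx_net()
  catal <- fx_catalog()
  img <- fx_image()
  ut <- unit_table(net)
  u <- ut$unit[ut$tier == 4 & ut$filter == 6]
  lesioned <- glossprobe:::lesion_unit(net, u)
  p1 <- predict(lesioned, img)
  # oracle: forward pass with that activation channel forced to zero
  fw <- glossprobe:::net_forward(net, img, keep_state = TRUE, capture = TRUE)
  a4 <- fw$acts$tier4
  a4[, , 6] <- 0
  cols <- glossprobe:::im2col3x3_cpp(a4, 64, 64, 8)
  z <- glossprobe:::conv_forward(cols, net$layers$out)
  p2 <- matrix(1 / (1 + exp(-z)), 64, 64)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("lesion_vs_similarity matches direct r^2 and flags constants", {
  report <- data.frame(unit = 1:5,
                       delta_loss = c(0.1, 0.3, 0.2, 0.5, 0.4),
                       delta_correlation = c(-0.01, -0.2, -0.1, -0.4, -0.3))
  sims <- cbind(geom = c(0.2, 0.5, 0.3, 0.9, 0.7),
                flat = rep(0.5, 5))
  rownames(sims) <- as.character(1:5)
  out <- lesion_vs_similarity(report, sims)
  expect_equal(out["delta_loss", "geom"],
               cor(report$delta_loss, sims[, "geom"])^2, tolerance = 1e-12)
  expect_equal(out["delta_correlation", "geom"],
               cor(report$delta_correlation, sims[, "geom"])^2,
               tolerance = 1e-12)
  expect_true(all(is.na(out[, "flat"])))
  # similarity vector identical to the lesion delta: R^2 = 1
  sims2 <- cbind(self = report$delta_loss)
  rownames(sims2) <- as.character(1:5)
  expect_equal(lesion_vs_similarity(report, sims2)["delta_loss", "self"], 1)
})
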