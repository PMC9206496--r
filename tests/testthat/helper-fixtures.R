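# Shared fixtures, built once per test run and memoized. Everything is
# generated in code at test time; sizes are kept small (64 px, handfuls of
# scenes) so the whole suite stays within a desk-scale compute budget.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# tiny rendered catalog: 4 scenes x 15 conditions at 64 px
fx_catalog <- function() memo("catalog", function() {
  build_catalog(4, size = 64, seed = 101)
})

# catalog with geometry buffers, for predictor-bank tests
fx_geo_catalog <- function() memo("geo_catalog", function() {
  build_catalog(3, size = 64, seed = 202, keep_geometry = TRUE)
})

fx_threshold <- function() memo("threshold", function() {
  fit_threshold(fx_catalog(), n_pixels = 5e4, seed = 11)
})

fx_probes <- function() memo("probes", function() {
  select_probes(fx_catalog(), fx_threshold(), n_four = 3, n_two = 3, seed = 12)
})

# an untrained (random-weight) 64 px network: sufficient for all structural
# and oracle-equivalence tests that do not require learned behavior
fx_net <- function() memo("net", function() {
  build_network(net_config(64, seed = 33))
})

fx_image <- function() memo("image", function() {
  get_stimulus(fx_catalog(), 1, "plain")$image
})

# The trained end-to-end fixture behind the acceptance property suite:
# a 15-scene catalog at 64 px, fitted threshold model, a network trained
# for 20 epochs (a few minutes of CPU), probes, and simulated observers.
# Scales are reduced from the published procedures (156,885 images at
# 256 px, 50 epochs) to fit a desk/CI compute budget; the acceptance tests
# verify the procedures' qualitative signatures, not full-scale effect
# sizes.
fx_trained <- function() memo("trained", function() {
  catal <- build_catalog(15, size = 64, seed = 7001)
  tm <- fit_threshold(catal, n_pixels = 1e5, seed = 7002)
  net <- build_network(net_config(64, seed = 7003))
  net <- train_network(net, catal, epochs = 20, batch_size = 4, lr = 3e-3,
                       seed = 7004)
  ps <- select_probes(catal, tm, n_four = 6, n_two = 6, seed = 7005)
  resp <- simulate_observers(ps, catal, tm, observer_params(seed = 7006))
  list(catalog = catal, tm = tm, net = net, probes = ps, responses = resp,
       mean_resp = mean_responses(resp, ps))
})
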