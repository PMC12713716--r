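## Shared small-scale fixtures, built once per test run.
## The small landscape (24 x 24 cells, 2 years) keeps unit tests fast; the
## acceptance tests build the full-scale landscape themselves.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

small_config <- function(seed = 1L)
  landscape_config(n_rows = 24, n_cols = 24, cell_size_km = 10,
                   years = 2015:2016, seed = seed)

small_stack <- function() fixture("small_stack", function()
  generate_env_stack(small_config()))

small_species <- function() virtual_species()

small_presences <- function() fixture("small_presences", function()
  thin_occurrences(sample_occurrences(small_species(), small_stack(),
                                      25, seed = 42), small_stack()))

model_vars <- c("MINTEMP", "PRECIPI", "EVAPO", "NDVI", "RFD")

## a single-month balanced model dataset (July, RS absences)
small_july_dataset <- function() fixture("small_july_dataset", function() {
  st <- small_stack()
  pj <- small_presences()
  pj <- pj[pj$month == 7, ]
  pa <- sample_rs(pj, st, sampler_config(radius_km = 150, n_sets = 1,
                                         seed = 9), model_vars)
  make_model_dataset(pj, pa, st, model_vars, 1, "July")
})

## tiny hand-built stack: one variable, values = cell_id, for lookup oracles
lookup_stack <- function(n = 4, years = 2013, months = c(6, 7)) {
  layers <- list()
  for (yr in years) for (mo in months)
    layers[[layer_key("NDVI", yr, mo)]] <-
      matrix(seq_len(n * n) * (mo + yr / 1000), n, n, byrow = TRUE)
  env_stack(layers, n, n, cell_size = 1)
}

## logistic data with known coefficients (no year structure)
simulate_logistic <- function(n, beta0, beta1, seed, x = NULL) {
  set.seed(seed)
  x <- x %||% rnorm(n)
  eta <- beta0 + beta1 * x
  data.frame(label = rbinom(n, 1, plogis(eta)), x = x)
}
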