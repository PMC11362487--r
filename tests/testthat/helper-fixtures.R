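# Shared fixtures. Fits are expensive, so one small well-specified
# beta-family fit (and its normal-family counterpart) is built lazily
# and reused across test files.

table1_columns <- function() {
  list(w1 = c("de", "de", "de", "de", "de"),
       w2 = c("jongen", "jongen", "jongen", "jongen", "hond"),
       w3 = c("ziet", "ziet", "zag", "zag", "zoekt"),
       w4 = c("een", "de", "[B]", "geen", "een"),
       w5 = c("kikkert", "[X]", "kokkin", "kikkers", "[X]"))
}

# Direct evaluation of the normalized-entropy formula from type counts.
entropy_from_counts <- function(counts) {
  J <- sum(counts)
  p <- counts / J
  -sum(p * log2(p)) / log2(J)
}

small_design <- function(words = c(3L, 5L)) {
  design_config(n_speakers_per_group = 4L, n_blocks = 2L,
                listeners_per_block = 5L, sentences_per_speaker = 3L,
                words_range = words, words_mean = mean(words), words_sd = 1)
}

.fixture_env <- new.env(parent = emptyenv())

# 24-sentence, ~96-obs dataset simulated from the beta family, plus
# quick model 7 (beta) and model 1 (normal) fits on it.
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(small_design(), true_params(), seed = 42)
  }
  .fixture_env$sim
}

shared_beta_fit <- function() {
  if (is.null(.fixture_env$beta_fit)) {
    .fixture_env$beta_fit <- fit_model(10, shared_sim()$data, chains = 2,
                                       iterations = 700, warmup = 300,
                                       seed = 5)
  }
  .fixture_env$beta_fit
}

shared_normal_fit <- function() {
  if (is.null(.fixture_env$normal_fit)) {
    .fixture_env$normal_fit <- fit_model(4, shared_sim()$data, chains = 2,
                                         iterations = 700, warmup = 300,
                                         seed = 5)
  }
  .fixture_env$normal_fit
}

# Reproducible draws fixtures shared with the frozen cross-implementation
# oracle values (see test-diagnostics.R / test-comparison.R).
oracle_ll_fixture <- function() {
  set.seed(42)
  matrix(rnorm(400 * 20, mean = 0.5, sd = 1), 400, 20)
}

oracle_draws_fixture <- function() {
  set.seed(42)
  invisible(rnorm(400 * 20, mean = 0.5, sd = 1))  # keep RNG stream aligned
  ar1 <- function(n, rho) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1) * sqrt(1 - rho^2)
    x
  }
  sapply(1:4, function(c) ar1(500, 0.7) + 0.1 * c)
}

make_ar1_chains <- function(n, m, rho, seed = 1) {
  set.seed(seed)
  sapply(seq_len(m), function(c) {
    x <- numeric(n)
    x[1] <- rnorm(1)
    for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1) * sqrt(1 - rho^2)
    x
  })
}
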