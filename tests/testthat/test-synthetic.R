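test_that("the default design matches the emulated study layout", {
  d <- generate_design(design_config(), seed = 3)
  expect_equal(nrow(d$speakers), 32L)
  expect_equal(as.vector(table(d$speakers$hearing_status)[c("NH", "HI/CI")]),
               c(16L, 16L))
  expect_equal(nrow(d$sentences), 320L)
  expect_equal(as.vector(table(d$sentences$block)), rep(64L, 5))
  expect_true(all(d$sentences$n_words >= 3 & d$sentences$n_words <= 11))
  # each sentence sits in exactly one block, and both groups appear in
  # every block
  expect_equal(anyDuplicated(d$sentences$sentence), 0L)
  grp_by_block <- tapply(d$speakers$hearing_status[d$sentences$speaker],
                         d$sentences$block, function(g) length(unique(g)))
  expect_true(all(grp_by_block == 2L))
  # ages honor the printed group bounds
  nh <- d$speakers$age_months[d$speakers$hearing_status == "NH"]
  hi <- d$speakers$age_months[d$speakers$hearing_status == "HI/CI"]
  expect_true(all(nh >= 68 & nh <= 104))
  expect_true(all(hi >= 78 & hi <= 98))
})

test_that("designs are deterministic given a seed and degenerate configs error", {
  expect_identical(generate_design(design_config(), seed = 11),
                   generate_design(design_config(), seed = 11))
  expect_false(identical(generate_design(design_config(), seed = 11)$speakers,
                         generate_design(design_config(), seed = 12)$speakers))
  tiny <- design_config(n_speakers_per_group = 1L, sentences_per_speaker = 1L,
                        n_blocks = 2L)
  expect_equal(nrow(generate_design(tiny, seed = 1)$sentences), 2L)
  expect_error(design_config(n_speakers_per_group = 1L,
                             sentences_per_speaker = 1L, n_blocks = 5L),
               "divisible")
})

test_that("the word-count sampler hits the target moments", {
  cfg <- design_config()
  set.seed(7)
  w <- entropySI:::sample_word_counts(10000L, cfg)
  expect_true(all(w >= 3 & w <= 11))
  expect_lt(abs(mean(w) - 7.1), 0.1)
  expect_lt(abs(sd(w) - 1.1), 0.2)
})

test_that("latent simulation follows the structural equation", {
  d <- generate_design(design_config(), seed = 2)
  # degenerate noise: SI collapses to the fixed part
  p0 <- true_params(sd_e = 1e-9, sd_u = 1e-9, s_b = 1e-9,
                    alpha = 0.4, alpha_HS = c(0, 0), beta_A_HS = 0)
  l0 <- simulate_latent(d, p0, seed = 1)
  expect_equal(l0$SI, rep(0.4, 32), tolerance = 1e-6)

  # slopes: NH group spans at least 0.1 * (age spread)
  p1 <- true_params(sd_e = 1e-9, sd_u = 1e-9, s_b = 1e-9,
                    alpha_HS = c(0, 0), beta_A_HS = c(0.1, 0.06))
  l1 <- simulate_latent(d, p1, seed = 1)
  nh <- d$speakers$hearing_status == "NH"
  spread <- diff(range(d$speakers$age_months[nh]))
  expect_gte(diff(range(l1$SI[nh])), 0.1 * spread - 1e-6)
  # assembled exactly per the structural equation
  agec <- d$speakers$age_months - min(d$speakers$age_months)
  g <- ifelse(d$speakers$hearing_status == "NH", 1, 2)
  u_bar <- tapply(l1$u, d$sentences$speaker, mean)
  expect_equal(l1$SI,
               as.numeric(p1$alpha + p1$alpha_HS[g] + p1$beta_A_HS[g] * agec +
                            l1$e + u_bar[as.character(1:32)]),
               tolerance = 1e-12)

  # speaker-effect scale recovered across replicates
  p2 <- true_params(sd_e = 0.3)
  es <- replicate(500, {
    simulate_latent(d, p2, seed = sample.int(1e6, 1))$e
  })
  expect_lt(abs(sd(as.vector(es)) - 0.3) / 0.3, 0.1)
})

test_that("entropy simulation matches the beta-proportion moments", {
  d <- generate_design(design_config(n_speakers_per_group = 2,
                                     sentences_per_speaker = 10,
                                     n_blocks = 2), seed = 5)
  # fixed mu = 0.3: alpha s.t. ilogit(-SI) = 0.3, no noise, M = 10
  alpha <- -logit(0.3)
  p <- true_params(alpha = alpha, alpha_HS = c(0, 0), beta_A_HS = 0,
                   sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12, M = 10)
  l <- simulate_latent(d, p, seed = 1)
  draws <- unlist(lapply(1:200, function(s)
    simulate_entropy(d, l, p, seed = s)$entropy))
  expect_gt(length(draws), 50000)
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - 0.3), 0.005)
  expect_lt(abs(var(draws) - 0.3 * 0.7 / 11) / (0.3 * 0.7 / 11), 0.1)

  # concentration limit: huge M pins the draws at mu
  pM <- true_params(alpha = alpha, alpha_HS = c(0, 0), beta_A_HS = 0,
                    sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12, M = 1e6)
  hM <- simulate_entropy(d, simulate_latent(d, pM, seed = 1), pM, seed = 2)$entropy
  expect_lt(sd(hM), 1e-3)

  # monotonicity: larger SI at fixed block effect lowers expected entropy
  p_hi <- true_params(alpha = alpha + 1, alpha_HS = c(0, 0), beta_A_HS = 0,
                      sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12, M = 10)
  h_hi <- simulate_entropy(d, simulate_latent(d, p_hi, seed = 1), p_hi, seed = 2)$entropy
  expect_lt(mean(h_hi), mean(hM) - 0.05)
})

test_that("same master seed gives byte-identical datasets", {
  a <- simulate_dataset(small_design(), true_params(), seed = 77)
  b <- simulate_dataset(small_design(), true_params(), seed = 77)
  expect_identical(a$data, b$data)
  expect_identical(a$latent$SI, b$latent$SI)
})

test_that("simulated grids reflect the latent intelligibility", {
  d <- generate_design(small_design(), seed = 5)
  # q = 1 (mu ~ 0): perfect agreement everywhere
  p_easy <- true_params(alpha = 30, alpha_HS = c(0, 0), beta_A_HS = 0,
                        sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12)
  l_easy <- simulate_latent(d, p_easy, seed = 1)
  g_easy <- simulate_grids(d, l_easy, p_easy, seed = 2)
  expect_true(all(batch_entropies(g_easy)$entropy == 0))

  # q = 0 with confusion = 0: everything [X], all types distinct
  p_hard <- true_params(alpha = -30, alpha_HS = c(0, 0), beta_A_HS = 0,
                        sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12)
  l_hard <- simulate_latent(d, p_hard, seed = 1)
  g_hard <- simulate_grids(d, l_hard, p_hard, confusion = 0, seed = 2)
  expect_true(all(batch_entropies(g_hard)$entropy == 1))
})

test_that("grid entropies match the exact binomial mixture at q = 0.8, c = 1, J = 5", {
  # with a shared confusion word, a column with m errors has type
  # counts (5 - m, m); enumerate the binomial mixture exactly
  exp_h <- sum(vapply(0:5, function(m) {
    counts <- c(5 - m, m)
    h <- if (any(counts == 0) || any(counts == 5)) 0 else
      entropy_from_counts(counts[counts > 0])
    dbinom(m, 5, 0.2) * h
  }, numeric(1)))

  d <- generate_design(design_config(n_speakers_per_group = 2,
                                     sentences_per_speaker = 5,
                                     listeners_per_block = 5,
                                     n_blocks = 2,
                                     words_range = c(8, 11)), seed = 5)
  alpha <- -logit(0.2)  # mu = 0.2 so q = 0.8
  p <- true_params(alpha = alpha, alpha_HS = c(0, 0), beta_A_HS = 0,
                   sd_e = 1e-12, sd_u = 1e-12, s_b = 1e-12)
  l <- simulate_latent(d, p, seed = 1)
  hs <- unlist(lapply(1:40, function(s)
    batch_entropies(simulate_grids(d, l, p, confusion = 1, seed = s))$entropy))
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - exp_h), 4 * se + 0.005)
})
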