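test_that("hpdi finds the shortest interval", {
  # uniform grid: any 95% window has the same length
  g <- seq(0, 1, length.out = 1001)
  h <- hpdi(g, 0.95)
  expect_lt(abs((h[["upper"]] - h[["lower"]]) - 0.95), 0.002)

  set.seed(14)
  z <- rnorm(1e5)
  h <- hpdi(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.03)
  expect_lt(abs(h[["upper"]] - 1.96), 0.03)

  expect_error(hpdi(z, 0), "prob")
  expect_error(hpdi(z, 1.2), "prob")
})

test_that("hpdi matches exhaustive window search on small samples", {
  set.seed(15)
  for (r in 1:20) {
    x <- sort(rgamma(200, shape = 2))
    m <- ceiling(0.95 * 200)
    best <- Inf; lo <- hi <- NA
    for (i in 1:(200 - m)) {
      wdt <- x[i + m] - x[i]
      if (wdt < best) { best <- wdt; lo <- x[i]; hi <- x[i + m] }
    }
    expect_equal(unname(hpdi(x, 0.95)), c(lo, hi), tolerance = 1e-12)
  }
})

test_that("hpdi is translation-equivariant", {
  set.seed(16)
  x <- rbeta(500, 2, 5)
  expect_equal(hpdi(x + 3.2), hpdi(x) + 3.2, tolerance = 1e-12)
})

test_that("latent intelligibility assembles linearly from the draws", {
  fit <- shared_beta_fit()
  lp <- extract_si(fit)
  I <- fit$index$n_speakers
  expect_equal(ncol(lp$draws), I)
  expect_equal(sort(lp$summary$rank), 1:I)
  expect_true(all(lp$summary$hpdi_lo < lp$summary$hpdi_hi))

  # model 10: SI_i = alpha + e_i + mean(u_si) draw by draw
  D <- draws_matrix(fit)
  i <- 3L
  ucols <- paste0("u[", which(fit$index$sent_speaker == i), "]")
  manual <- D[, "alpha"] + D[, paste0("e[", i, "]")] +
    rowMeans(D[, ucols, drop = FALSE])
  expect_equal(unname(lp$draws[, i]), unname(manual), tolerance = 1e-12)

  # shifting alpha by c shifts every SI_i by c exactly
  fit2 <- fit
  fit2$draws[, , "alpha"] <- fit$draws[, , "alpha"] + 0.7
  lp2 <- extract_si(fit2)
  expect_equal(lp2$draws, lp$draws + 0.7, tolerance = 1e-12)

  # degenerate draws: all SI equal, ranks fall back to speaker order
  fit3 <- fit
  for (p in dimnames(fit3$draws)[[3]]) fit3$draws[, , p] <- 0
  fit3$draws[, , "alpha"] <- 0.4
  lp3 <- extract_si(fit3)
  expect_true(all(abs(lp3$draws - 0.4) < 1e-12))
  expect_equal(lp3$summary$rank, seq_len(I))
})

test_that("latent extraction requires the beta family and complete draws", {
  expect_error(extract_si(shared_normal_fit()), "normal LMM")
  fit <- shared_beta_fit()
  broken <- fit
  dn <- dimnames(broken$draws)[[3]]
  broken$draws <- broken$draws[, , dn != "alpha", drop = FALSE]
  expect_error(extract_si(broken))
})

test_that("speaker contrasts are antisymmetric and self-contrasts are null", {
  lp <- extract_si(shared_beta_fit())
  c12 <- speaker_contrast(lp, 1, 2)
  c21 <- speaker_contrast(lp, 2, 1)
  expect_equal(c12$draws, -c21$draws)
  expect_equal(unname(c12$hpdi), unname(-rev(c21$hpdi)), tolerance = 1e-12)
  expect_equal(c12$significant, c21$significant)

  self <- speaker_contrast(lp, 4, 4)
  expect_true(all(self$draws == 0))
  expect_false(self$significant)

  expect_error(speaker_contrast(lp, 1, 999), "unknown speaker")
})

test_that("group contrasts exist exactly for covariate models", {
  expect_error(group_contrasts(shared_beta_fit()), "no group parameters")
  sim <- shared_sim()
  fit11 <- fit_model(11, sim$data, chains = 2, iterations = 500, warmup = 250,
                     seed = 6)
  gc <- group_contrasts(fit11)
  expect_named(gc, "alpha_HS")
  expect_equal(length(gc$alpha_HS$draws), 500L)
  fit12 <- fit_model(12, sim$data, chains = 2, iterations = 500, warmup = 250,
                     seed = 6)
  gc12 <- group_contrasts(fit12)
  expect_named(gc12, c("alpha_HS", "beta_A_HS"))
})

test_that("ranking recovers a strong latent ordering", {
  # large speaker spread relative to noise: posterior-mean ranks track
  # the true latent ordering
  cfg <- design_config(n_speakers_per_group = 8, sentences_per_speaker = 3,
                       words_range = c(4, 6), words_mean = 5, words_sd = 1,
                       n_blocks = 4, listeners_per_block = 5)
  p <- true_params(alpha_HS = c(0, 0), beta_A_HS = 0, sd_e = 1.2,
                   sd_u = 0.1, s_b = 0.05, M = 30)
  sim <- simulate_dataset(cfg, p, seed = 33)
  fit <- fit_model(10, sim$data, chains = 2, iterations = 800, warmup = 400,
                   seed = 7)
  lp <- extract_si(fit)
  expect_gt(cor(lp$summary$mean, sim$latent$SI, method = "spearman"), 0.8)
})

test_that("the group-intercept contrast recovers a strong generative gap", {
  # generative condition: intercept gap -0.55 with a common age slope
  cfg <- design_config(n_speakers_per_group = 8, sentences_per_speaker = 3,
                       words_range = c(5, 5), words_mean = 5, words_sd = 0.1,
                       n_blocks = 4)
  tp <- true_params(alpha_HS = c(0.53, -0.02), beta_A_HS = 0.07)
  gap <- tp$alpha_HS[2] - tp$alpha_HS[1]
  covered <- logical(10)
  for (s in 1:10) {
    sim <- simulate_dataset(cfg, tp, seed = 400 + s)
    fit <- fit_model(11, sim$data, chains = 2, iterations = 800,
                     warmup = 400, seed = s)
    h <- group_contrasts(fit)$alpha_HS$hpdi
    covered[s] <- h[["lower"]] <= gap && gap <= h[["upper"]]
  }
  expect_gte(sum(covered), 9)
})

test_that("a zero slope gap is rarely declared significant", {
  cfg <- design_config(n_speakers_per_group = 8, sentences_per_speaker = 3,
                       words_range = c(5, 5), words_mean = 5, words_sd = 0.1,
                       n_blocks = 4)
  tp <- true_params(alpha_HS = c(0.2, 0.2), beta_A_HS = 0.08)  # equal slopes
  signif <- logical(10)
  for (s in 1:10) {
    sim <- simulate_dataset(cfg, tp, seed = 500 + s)
    fit <- fit_model(12, sim$data, chains = 2, iterations = 600,
                     warmup = 300, seed = s)
    signif[s] <- group_contrasts(fit)$beta_A_HS$significant
  }
  expect_lte(sum(signif), 2)
})

test_that("posterior predictive checks respect the outcome support", {
  ppb <- posterior_predictive(shared_beta_fit(), max_draws = 400)
  expect_equal(ppb$fraction_outside, 0)
  expect_equal(nrow(ppb$table), nrow(shared_sim()$data))
  expect_true(all(ppb$table$lo < ppb$table$hi))
  expect_gt(ppb$coverage, 0.8)

  ppn <- posterior_predictive(shared_normal_fit(), max_draws = 400)
  expect_gt(ppn$fraction_outside, 0)
})
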