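test_that("the model table encodes the twelve variants", {
  tab <- model_table()
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$family, rep(c("normal", "beta"), each = 6))
  m10 <- model_spec(10)
  expect_equal(m10$family, "beta")
  expect_true(m10$robust)
  expect_equal(m10$fixed_effects, "intercept_only")
  m4 <- model_spec(4)
  expect_equal(m4$family, "normal")
  expect_true(m4$robust)
  expect_equal(m4$fixed_effects, "intercept_only")
  m2 <- model_spec(2)
  expect_false(m2$robust)
  expect_equal(m2$fixed_effects, "group_intercepts_plus_common_slope")
  expect_error(model_spec(13), "1..12")
  expect_error(model_spec(0), "1..12")
})

test_that("default priors reproduce the documented scales in the model code", {
  # normal family: alpha sd 0.05 -> precision 400; alpha_HS sd 0.2 -> 25
  code_n <- build_model(6)$code
  expect_match(code_n, "alpha ~ dnorm\\(0, 400\\)")
  # group intercepts are sampled at the group-mean age with the
  # conditional prior whose marginal is Normal(0, 0.2) -> precision 25
  expect_match(code_n, "aHSc\\[k\\] ~ dnorm\\(bAHS\\[k\\] \\* abar\\[k\\], 25\\)")
  expect_match(code_n, "bAHS\\[k\\] ~ dnorm\\(0, 100\\)")
  expect_match(code_n, "sigma\\[i\\] ~ dexp\\(rS\\)")
  expect_match(code_n, "rS ~ dexp\\(2\\)")
  # beta family: alpha_HS sd 0.3 -> precision 11.11; robust M_i
  code_b <- build_model(12)$code
  expect_match(code_b, "aHSc\\[k\\] ~ dnorm\\(bAHS\\[k\\] \\* abar\\[k\\], 11\\.1111")
  expect_match(code_b, "M\\[i\\] ~ dexp\\(rM\\)")
  # non-robust: one shared scale
  expect_match(build_model(7)$code, "M0 ~ dexp\\(rM\\)")
  expect_match(build_model(1)$code, "sigma0 ~ dexp\\(rS\\)")
  # shared hyper structure of the random effects
  for (code in c(code_n, code_b)) {
    expect_match(code, "m_e ~ dnorm\\(0, 400\\)")
    expect_match(code, "s_e ~ dexp\\(2\\)")
    expect_match(code, "s_u ~ dexp\\(2\\)")
    expect_match(code, "m_b ~ dnorm\\(0, 400\\)")
  }
  expect_error(build_model(model_spec(10), prior_set("normal")), "family")
})

test_that("the beta link is monotone decreasing in latent intelligibility", {
  a_b <- 0.3
  si <- seq(-5, 5, length.out = 200)
  mu <- inverse_logit(a_b - si)
  expect_true(all(diff(mu) < 0))
})

test_that("prior predictive draws respect each family's support", {
  dat <- shared_sim()$data
  pp_b <- prior_predictive(10, dat, n_draws = 50, seed = 2)
  expect_true(all(pp_b$draws > 0 & pp_b$draws < 1))
  expect_equal(pp_b$fraction_outside, 0)

  pp_n <- prior_predictive(4, dat, n_draws = 50, seed = 2)
  expect_gt(pp_n$fraction_outside, 0)

  pp0 <- prior_predictive(10, dat, n_draws = 0)
  expect_equal(nrow(pp0$draws), 0L)
})

test_that("fitting is deterministic given the seed and yields the documented shape", {
  dat <- shared_sim()$data
  f1 <- shared_beta_fit()
  f2 <- fit_model(10, dat, chains = 2, iterations = 700, warmup = 300, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$draws)[1:2], c(400L, 2L))
  expect_equal(f1$mcmc$retained, 800L)
  pars <- dimnames(f1$draws)[[3]]
  expect_true(all(c("alpha", "s_u", "s_e", "m_e", "a_b[1]", "M[1]", "r_M") %in% pars))
  f3 <- fit_model(10, dat, chains = 2, iterations = 700, warmup = 300, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the pointwise log-likelihood matches a closed-form oracle", {
  fit <- shared_normal_fit()  # model 4: robust normal, intercept only
  ll <- loglik_matrix(fit)
  expect_true(all(is.finite(ll)))
  expect_equal(ncol(ll), nrow(fit$data))
  D <- draws_matrix(fit)
  idx <- fit$index
  y <- fit$data$.y
  set.seed(31)
  for (k in 1:25) {
    s <- sample(nrow(D), 1); n <- sample(length(y), 1)
    mu <- D[s, "alpha"] +
      D[s, paste0("e[", idx$spk[n], "]")] +
      D[s, paste0("u[", idx$sent[n], "]")] +
      D[s, paste0("a_b[", idx$blk[n], "]")]
    sg <- D[s, paste0("sigma[", idx$spk[n], "]")]
    expect_equal(ll[s, n], dnorm(y[n], mu, sg, log = TRUE), tolerance = 1e-10)
  }

  fitb <- shared_beta_fit()  # model 10: robust beta, intercept only
  llb <- loglik_matrix(fitb)
  Db <- draws_matrix(fitb)
  for (k in 1:25) {
    s <- sample(nrow(Db), 1); n <- sample(length(y), 1)
    si <- Db[s, "alpha"] +
      Db[s, paste0("e[", idx$spk[n], "]")] +
      Db[s, paste0("u[", idx$sent[n], "]")]
    mu <- inverse_logit(Db[s, paste0("a_b[", idx$blk[n], "]")] - si)
    M <- Db[s, paste0("M[", idx$spk[n], "]")]
    expect_equal(unname(llb[s, n]),
                 unname(dbeta(y[n], mu * M, (1 - mu) * M, log = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("covariate-free models ignore permuted covariate columns", {
  dat <- shared_sim()$data
  dat2 <- dat
  set.seed(8)
  perm <- sample(nrow(dat2))
  dat2$age_months <- dat2$age_months[perm]
  dat2$hearing_status <- dat2$hearing_status[perm]
  f1 <- fit_model(1, dat, chains = 2, iterations = 300, warmup = 150, seed = 9)
  f2 <- fit_model(1, dat2, chains = 2, iterations = 300, warmup = 150, seed = 9)
  expect_identical(f1$draws, f2$draws)
})

test_that("missing covariates or unknown group labels are rejected", {
  dat <- shared_sim()$data
  expect_error(fit_model(12, dat[, c("word", "sentence", "speaker", "block",
                                     "entropy")],
                         chains = 2, iterations = 100, warmup = 50),
               "hearing_status")
  bad <- dat
  bad$hearing_status[1] <- "UNKNOWN"
  expect_error(fit_model(12, bad, chains = 2, iterations = 100, warmup = 50),
               "hearing_status label")
})

test_that("a well-specified fit on a 160-observation set converges", {
  cfg <- design_config(n_speakers_per_group = 8, sentences_per_speaker = 2,
                       words_range = c(5, 5), words_mean = 5, words_sd = 0.5,
                       n_blocks = 4)
  sim <- simulate_dataset(cfg, true_params(), seed = 21)
  expect_equal(nrow(sim$data), 160L)
  fit <- fit_model(10, sim$data, chains = 2, iterations = 2500, warmup = 1250,
                   seed = 4)
  rep <- diagnose(fit)
  expect_equal(attr(rep, "n_flagged"), 0L)
  expect_true(all(rep$rhat < 1.05))
})

test_that("overparameterized covariate variants still converge under the default priors", {
  cfg <- design_config(n_speakers_per_group = 8, sentences_per_speaker = 2,
                       words_range = c(5, 5), words_mean = 5, words_sd = 0.5,
                       n_blocks = 4)
  # entropy scores are bounded by construction, so both families are
  # exercised on beta-generated data; the conjugate normal variants
  # sample so fast that they get much longer chains
  sim_b <- simulate_dataset(cfg, true_params(), seed = 22)
  for (m in c(2L, 6L, 9L, 11L)) {
    iters <- if (m <= 6L) 15000L else 4000L
    fit <- fit_model(m, sim_b$data, chains = 2, iterations = iters,
                     warmup = if (m <= 6L) 3000L else 1500L,
                     seed = 30 + m)
    rep <- diagnose(fit)
    expect_true(all(rep$rhat < 1.05),
                info = sprintf("model %d max rhat %.3f", m,
                               max(rep$rhat, na.rm = TRUE)))
  }
})
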