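#' True generative parameters for synthetic data
#'
#' Defaults are realistic magnitudes for entropy-score studies of child
#' speech, mirroring the scale of posterior estimates typically reported
#' for the two-group design: no overall offset, a lower latent
#' intelligibility intercept for the HI/CI group, positive age slopes
#' (intelligibility grows with age) with slower HI/CI growth, and
#' random-effect scales of a few tenths on the logit scale.
#'
#' @param family \code{"beta"} (beta-proportion likelihood) or
#'   \code{"normal"}.
#' @param alpha Global intercept (sets the latent scale).
#' @param alpha_HS Length-2 group intercepts (NH, HI/CI). Use
#'   \code{c(0, 0)} for an intercept-only generative model.
#' @param beta_A_HS Length-2 group age slopes per month (NH, HI/CI); a
#'   scalar is recycled to a common slope.
#' @param sd_e Speaker random-effect SD.
#' @param sd_u Sentence-within-speaker random-effect SD.
#' @param m_b,s_b Block random-effect mean and SD.
#' @param M Beta-proportion dispersion (scalar, or one value per
#'   speaker for heteroscedastic data). Small M pushes scores toward
#'   the 0/1 boundaries.
#' @param sigma Normal-family residual SD.
#' @return A \code{true_params} list.
#' @export
true_params <- function(family = c("beta", "normal"),
                        alpha = 0.01,
                        alpha_HS = c(0.21, 0.23),
                        beta_A_HS = c(0.10, 0.06),
                        sd_e = 0.3, sd_u = 0.2,
                        m_b = 0, s_b = 0.2,
                        M = 5, sigma = 0.15) {
  family <- match.arg(family)
  if (length(beta_A_HS) == 1L) beta_A_HS <- rep(beta_A_HS, 2L)
  stopifnot(length(alpha_HS) == 2L, length(beta_A_HS) == 2L,
            sd_e > 0, sd_u > 0, s_b > 0, all(M > 0), sigma > 0)
  structure(list(family = family, alpha = alpha, alpha_HS = alpha_HS,
                 beta_A_HS = beta_A_HS, sd_e = sd_e, sd_u = sd_u,
                 m_b = m_b, s_b = s_b, M = M, sigma = sigma),
            class = "true_params")
}

#' Draw the latent state of a synthetic study
#'
#' Draws speaker effects \code{e_i ~ Normal(0, sd_e)}, sentence effects
#' \code{u_si ~ Normal(0, sd_u)} and block effects
#' \code{a_b ~ Normal(m_b, s_b)}, then assembles each speaker's latent
#' potential intelligibility
#' \deqn{SI_i = \alpha + \alpha_{HS[i]} + \beta_{A,HS[i]} (A_i - \bar A)
#'   + e_i + u_i,}
#' where \eqn{u_i} is the average of the speaker's sentence effects and
#' \eqn{\bar A} is the minimum age in the design.
#'
#' @param design A [generate_design()] result.
#' @param params A [true_params()].
#' @param seed Integer seed.
#' @return A \code{latent_state} list with \code{e}, \code{u}
#'   (per sentence), \code{a_b}, \code{SI} (per speaker), \code{SI_sent}
#'   (per sentence: speaker structural part + that sentence's u_si),
#'   \code{A_bar}.
#' @export
simulate_latent <- function(design, params, seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(params, "true_params"))
  set.seed(seed)
  spk <- design$speakers
  sent <- design$sentences
  n_spk <- nrow(spk)
  g <- ifelse(spk$hearing_status == "NH", 1L, 2L)
  A_bar <- min(spk$age_months)
  agec <- spk$age_months - A_bar

  e <- stats::rnorm(n_spk, 0, params$sd_e)
  u <- stats::rnorm(nrow(sent), 0, params$sd_u)
  a_b <- stats::rnorm(design$config$n_blocks, params$m_b, params$s_b)

  fixed <- params$alpha + params$alpha_HS[g] + params$beta_A_HS[g] * agec
  u_bar <- tapply(u, sent$speaker, mean)[as.character(seq_len(n_spk))]
  SI <- fixed + e + as.numeric(u_bar)
  SI_sent <- fixed[sent$speaker] + e[sent$speaker] + u
  structure(list(e = e, u = u, a_b = a_b, SI = SI, SI_sent = SI_sent,
                 A_bar = A_bar, group = g, seed = seed),
            class = "latent_state")
}

#' Simulate a tidy entropy dataset from the latent state
#'
#' For every word of sentence s by speaker i in block b the expected
#' entropy is \code{mu = inverse_logit(a_b - SI_si)} and the observed
#' score is drawn from \code{BetaProp(mu, M)} (beta family) or, for the
#' normal family, from \code{Normal(mu_lin, sigma)} with the direct
#' (identity-link) predictor \code{mu_lin = a_b + SI-components} and no
#' clamping, so normal draws can fall outside [0, 1].
#'
#' @inheritParams simulate_latent
#' @param latent A [simulate_latent()] result.
#' @return A data.frame with columns \code{word, sentence, speaker,
#'   block, entropy, n_transcriptions, hearing_status, age_months}.
#' @export
simulate_entropy <- function(design, latent, params, seed = 1L) {
  stopifnot(inherits(latent, "latent_state"), inherits(params, "true_params"))
  set.seed(seed)
  sent <- design$sentences
  spk <- design$speakers
  obs_sent <- rep(sent$sentence, sent$n_words)
  word <- unlist(lapply(sent$n_words, seq_len), use.names = FALSE)
  obs_spk <- sent$speaker[obs_sent]
  obs_blk <- sent$block[obs_sent]
  n <- length(obs_sent)

  if (params$family == "beta") {
    mu <- inverse_logit(latent$a_b[obs_blk] - latent$SI_sent[obs_sent])
    if (any(!is.finite(mu))) stop("non-finite mean entropy mu")
    M <- if (length(params$M) > 1L) params$M[obs_spk] else params$M
    h <- rbetaprop(n, mu, M)
  } else {
    # Direct link: the latent components enter additively, no sign flip.
    mu_lin <- latent$a_b[obs_blk] + latent$SI_sent[obs_sent]
    if (any(!is.finite(mu_lin))) stop("non-finite mean entropy mu")
    sig <- if (length(params$sigma) > 1L) params$sigma[obs_spk] else params$sigma
    h <- stats::rnorm(n, mu_lin, sig)
  }
  data.frame(word = word,
             sentence = obs_sent,
             speaker = obs_spk,
             block = obs_blk,
             entropy = h,
             n_transcriptions = design$config$listeners_per_block,
             hearing_status = spk$hearing_status[obs_spk],
             age_months = spk$age_months[obs_spk])
}

#' Simulate raw aligned transcription grids
#'
#' Links the latent model to listener behaviour: for each word the
#' probability of a correct transcription is \code{q = 1 - mu} (an
#' intelligible word, low expected entropy, is transcribed correctly by
#' most listeners). An erroneous listener writes a shared confusion
#' word with probability \code{confusion} and an unidentifiable
#' \code{[X]} otherwise.
#'
#' @inheritParams simulate_entropy
#' @param confusion Probability that a transcription error is a shared
#'   confusion word rather than \code{[X]}.
#' @return List of [aligned_grid()] objects, one per sentence, each
#'   with J = \code{listeners_per_block} rows.
#' @export
simulate_grids <- function(design, latent, params, confusion = 0.5,
                           seed = 1L) {
  stopifnot(confusion >= 0, confusion <= 1)
  set.seed(seed)
  J <- design$config$listeners_per_block
  sent <- design$sentences
  grids <- vector("list", nrow(sent))
  for (sidx in seq_len(nrow(sent))) {
    W <- sent$n_words[sidx]
    b <- sent$block[sidx]
    mu <- inverse_logit(latent$a_b[b] - latent$SI_sent[sidx])
    q <- 1 - mu
    if (q < 0 || q > 1) stop("correct-transcription probability outside [0,1]")
    cells <- matrix("", nrow = J, ncol = W)
    for (w in seq_len(W)) {
      target <- sprintf("w%d_%d", sidx, w)
      confused <- sprintf("c%d_%d", sidx, w)
      correct <- stats::runif(J) < q
      err_conf <- stats::runif(J) < confusion
      cells[, w] <- ifelse(correct, target,
                           ifelse(err_conf, confused, TOKEN_UNID))
    }
    grids[[sidx]] <- aligned_grid(cells, sentence_id = sent$sentence[sidx],
                                  speaker_id = sent$speaker[sidx],
                                  block_id = b)
  }
  grids
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining [generate_design()],
#' [simulate_latent()] and [simulate_entropy()] with sub-seeds derived
#' from one master seed.
#'
#' @param config A [design_config()].
#' @param params A [true_params()].
#' @param seed Master seed.
#' @return List with \code{design}, \code{latent}, \code{data}.
#' @export
simulate_dataset <- function(config = design_config(),
                             params = true_params(), seed = 1L) {
  design <- generate_design(config, seed = seed)
  latent <- simulate_latent(design, params, seed = seed + 1L)
  data <- simulate_entropy(design, latent, params, seed = seed + 2L)
  list(design = design, latent = latent, data = data)
}
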