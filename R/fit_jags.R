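# JAGS model construction and fitting.
#
# Both families share the random-effect structure: speaker effects e_i,
# sentence-within-speaker effects u_si, block effects a_b. The beta
# family places the latent predictor behind the negative inverse-logit
# link, mu = ilogit(a_b - SI_si), so higher latent intelligibility
# means lower expected entropy; the normal family uses the direct link
# mu = fixed + u_si + e_i + a_b.

jags_model_code <- function(spec, priors) {
  # The group intercept/slope pairs are sampled as (intercept at the
  # group's mean centered age, slope): aHS_c[k] = aHS[k] + b * abar[k]
  # with the prior written conditionally, which leaves the joint prior
  # of (aHS, slope) exactly Normal(0, alpha_HS_scale) x
  # Normal(0, beta_scale) while decorrelating the two coordinates for
  # the sampler. aHS[k] itself is recovered as a deterministic node.
  fe <- switch(spec$fixed_effects,
    intercept_only = "",
    group_intercepts_plus_common_slope =
      " + aHSc[g[spk[n]]] + bA*(agec[spk[n]] - abar[g[spk[n]]])",
    group_intercepts_plus_group_slopes =
      " + aHSc[g[spk[n]]] + bAHS[g[spk[n]]]*(agec[spk[n]] - abar[g[spk[n]]])")
  lin <- paste0("alpha", fe, " + e[spk[n]] + u[sent[n]]")
  if (spec$family == "beta") {
    lik <- paste0(
      "    mu[n] <- ilogit(ab[blk[n]] - (", lin, "))\n",
      if (spec$robust)
        "    y[n] ~ dbeta(mu[n]*M[spk[n]], (1-mu[n])*M[spk[n]])\n"
      else
        "    y[n] ~ dbeta(mu[n]*M0, (1-mu[n])*M0)\n")
    scale_prior <- if (spec$robust)
      "  for (i in 1:I) { M[i] ~ dexp(rM) }\n  rM ~ dexp(%g)\n"
    else
      "  M0 ~ dexp(rM)\n  rM ~ dexp(%g)\n"
  } else {
    lik <- paste0(
      "    mu[n] <- ", lin, " + ab[blk[n]]\n",
      if (spec$robust)
        "    y[n] ~ dnorm(mu[n], pow(sigma[spk[n]], -2))\n"
      else
        "    y[n] ~ dnorm(mu[n], pow(sigma0, -2))\n")
    scale_prior <- if (spec$robust)
      "  for (i in 1:I) { sigma[i] ~ dexp(rS) }\n  rS ~ dexp(%g)\n"
    else
      "  sigma0 ~ dexp(rS)\n  rS ~ dexp(%g)\n"
  }
  fe_prior <- switch(spec$fixed_effects,
    intercept_only = "",
    group_intercepts_plus_common_slope = sprintf(
      paste0("  bA ~ dnorm(0, %g)\n",
             "  for (k in 1:2) { aHSc[k] ~ dnorm(bA * abar[k], %g)\n",
             "               aHS[k] <- aHSc[k] - bA * abar[k] }\n"),
      priors$beta_scale^-2, priors$alpha_HS_scale^-2),
    group_intercepts_plus_group_slopes = sprintf(
      paste0("  for (k in 1:2) { bAHS[k] ~ dnorm(0, %g)\n",
             "               aHSc[k] ~ dnorm(bAHS[k] * abar[k], %g)\n",
             "               aHS[k] <- aHSc[k] - bAHS[k] * abar[k] }\n"),
      priors$beta_scale^-2, priors$alpha_HS_scale^-2))
  paste0(
    "model {\n",
    "  for (n in 1:N) {\n", lik, "  }\n",
    sprintf(scale_prior, priors$scale_rate),
    # speaker and sentence effects are sampled non-centered so their
    # scale parameters mix well; the data-rich block effects are
    # sampled centered
    "  for (i in 1:I) { z_e[i] ~ dnorm(0, 1)\n               e[i] <- m_e + s_e * z_e[i] }\n",
    sprintf("  m_e ~ dnorm(0, %g)\n  s_e ~ dexp(%g)\n",
            priors$m_e_scale^-2, priors$s_e_rate),
    "  for (m in 1:Ns) { z_u[m] ~ dnorm(0, 1)\n                u[m] <- s_u * z_u[m] }\n",
    sprintf("  s_u ~ dexp(%g)\n", priors$s_u_rate),
    "  for (b in 1:B) { ab[b] ~ dnorm(m_b, pow(s_b, -2)) }\n",
    sprintf("  m_b ~ dnorm(0, %g)\n  s_b ~ dexp(%g)\n",
            priors$m_b_scale^-2, priors$s_b_rate),
    sprintf("  alpha ~ dnorm(0, %g)\n", priors$alpha_scale^-2),
    fe_prior,
    "}\n")
}

# Map an entropy data.frame to index vectors. Speaker/sentence/block
# labels may be arbitrary; they are re-indexed densely in order of
# first appearance of the sorted unique labels.
build_index <- function(data, spec) {
  need <- c("word", "sentence", "speaker", "block", "entropy")
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("data lacks columns: ", paste(missing, collapse = ", "))
  spk_levels <- sort(unique(data$speaker))
  sent_levels <- sort(unique(data$sentence))
  blk_levels <- sort(unique(data$block))
  spk <- match(data$speaker, spk_levels)
  sent <- match(data$sentence, sent_levels)
  blk <- match(data$block, blk_levels)

  uses_fe <- spec$fixed_effects != "intercept_only"
  if (uses_fe) {
    if (!all(c("hearing_status", "age_months") %in% names(data))) {
      stop("model ", spec$model_id,
           " needs hearing_status and age_months columns")
    }
    gl <- data$hearing_status[match(spk_levels, data$speaker)]
    if (!all(gl %in% c("NH", "HI/CI"))) {
      stop("unknown hearing_status label(s): ",
           paste(setdiff(unique(gl), c("NH", "HI/CI")), collapse = ", "))
    }
    g <- ifelse(gl == "NH", 1L, 2L)
    ages <- data$age_months[match(spk_levels, data$speaker)]
    A_bar <- min(data$age_months)
    agec <- ages - A_bar
  } else {
    g <- rep(1L, length(spk_levels))
    agec <- rep(0, length(spk_levels))
    A_bar <- NA_real_
  }
  abar <- c(0, 0)
  for (k in 1:2) if (any(g == k)) abar[k] <- mean(agec[g == k])
  list(spk = spk, sent = sent, blk = blk, g = g, agec = agec,
       abar = abar, A_bar = A_bar,
       spk_levels = spk_levels, sent_levels = sent_levels,
       blk_levels = blk_levels,
       sent_speaker = spk[match(sent_levels, data$sentence)],
       n_speakers = length(spk_levels),
       n_sentences = length(sent_levels),
       n_blocks = length(blk_levels))
}

jags_monitors <- function(spec) {
  mon <- c("alpha", "e", "u", "ab", "m_e", "s_e", "m_b", "s_b", "s_u")
  mon <- c(mon, switch(spec$fixed_effects,
                       intercept_only = character(0),
                       group_intercepts_plus_common_slope = c("aHS", "bA"),
                       group_intercepts_plus_group_slopes = c("aHS", "bAHS")))
  if (spec$family == "beta") {
    c(mon, if (spec$robust) "M" else "M0", "rM")
  } else {
    c(mon, if (spec$robust) "sigma" else "sigma0", "rS")
  }
}

# Canonical parameter names used everywhere downstream.
rename_jags <- function(x) {
  x <- sub("^aHS\\[", "alpha_HS[", x)
  x <- sub("^bAHS\\[", "beta_A_HS[", x)
  x <- sub("^bA$", "beta_A", x)
  x <- sub("^ab\\[", "a_b[", x)
  x <- sub("^M0$", "M", x)
  x <- sub("^sigma0$", "sigma", x)
  x <- sub("^rM$", "r_M", x)
  x <- sub("^rS$", "r_S", x)
  x
}

# Overdispersed chain inits drawn around the priors.
jags_inits <- function(spec, idx, chain_seed) {
  set.seed(chain_seed)
  ini <- list(
    alpha = stats::rnorm(1, 0, 0.05),
    z_e = stats::rnorm(idx$n_speakers),
    z_u = stats::rnorm(idx$n_sentences),
    ab = stats::rnorm(idx$n_blocks, 0, 0.1),
    m_e = stats::rnorm(1, 0, 0.05), s_e = stats::runif(1, 0.1, 0.5),
    m_b = stats::rnorm(1, 0, 0.05), s_b = stats::runif(1, 0.1, 0.5),
    s_u = stats::runif(1, 0.1, 0.5),
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = chain_seed)
  if (spec$fixed_effects != "intercept_only") {
    ini$aHSc <- stats::rnorm(2, 0, 0.2)
    if (spec$fixed_effects == "group_intercepts_plus_common_slope") {
      ini$bA <- stats::rnorm(1, 0, 0.05)
    } else {
      ini$bAHS <- stats::rnorm(2, 0, 0.05)
    }
  }
  if (spec$family == "beta") {
    ini$rM <- stats::runif(1, 1, 3)
    if (spec$robust) ini$M <- stats::runif(idx$n_speakers, 2, 10)
    else ini$M0 <- stats::runif(1, 2, 10)
  } else {
    ini$rS <- stats::runif(1, 1, 3)
    if (spec$robust) ini$sigma <- stats::runif(idx$n_speakers, 0.05, 0.3)
    else ini$sigma0 <- stats::runif(1, 0.05, 0.3)
  }
  ini
}

#' Build a fittable model object
#'
#' Assembles the JAGS model code and data block for one model variant
#' with its default (or user-supplied) priors, without running MCMC.
#'
#' @param spec A [model_spec()] or a model id 1-12.
#' @param priors A [prior_set()]; defaults to the family's standard
#'   priors.
#' @return An \code{si_model} list with \code{spec}, \code{priors},
#'   \code{code} (JAGS model string) and \code{monitors}.
#' @export
build_model <- function(spec, priors = NULL) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  if (is.null(priors)) priors <- prior_set(spec$family)
  if (priors$family != spec$family) {
    stop("priors built for family '", priors$family,
         "' but model is '", spec$family, "'")
  }
  structure(list(spec = spec, priors = priors,
                 code = jags_model_code(spec, priors),
                 monitors = jags_monitors(spec)),
            class = "si_model")
}

#' Fit a model by MCMC
#'
#' Runs JAGS with the given chain protocol. The default protocol is 4
#' chains of 4000 iterations with the first 2000 as warmup (adaptation
#' plus burn-in), retaining 8000 draws. The entropy outcome is first
#' compressed into (0, 1) by [transform_bounds()] (identically for both
#' families, so information criteria computed from the fits are
#' comparable).
#'
#' @param model An [build_model()] object, a [model_spec()], or a model
#'   id 1-12.
#' @param data Tidy entropy data.frame (columns \code{word, sentence,
#'   speaker, block, entropy}, plus \code{hearing_status, age_months}
#'   for covariate models).
#' @param chains,iterations,warmup MCMC protocol; the retained draws
#'   are \code{chains * (iterations - warmup)}.
#' @param seed Master seed; per-chain RNG seeds are derived from it, so
#'   refits with the same seed give identical draws.
#' @param transform Boundary-transform method, see [transform_bounds()].
#' @param quiet Suppress JAGS progress output.
#' @return An \code{si_fit} with the draws array
#'   \code{[iteration, chain, parameter]} (canonical parameter names),
#'   the analyzed data, index structures and run metadata.
#' @export
fit_model <- function(model, data, chains = 4L, iterations = 4000L,
                      warmup = 2000L, seed = 1L,
                      transform = c("compress", "clamp"), quiet = TRUE) {
  if (!inherits(model, "si_model")) model <- build_model(model)
  transform <- match.arg(transform)
  spec <- model$spec
  stopifnot(iterations > warmup, warmup >= 2L, chains >= 1L)
  idx <- build_index(data, spec)
  n <- nrow(data)
  y <- transform_bounds(data$entropy, n, method = transform)

  jdata <- list(y = y, N = n, spk = idx$spk, sent = idx$sent,
                blk = idx$blk, I = idx$n_speakers, Ns = idx$n_sentences,
                B = idx$n_blocks)
  if (spec$fixed_effects != "intercept_only") {
    jdata$g <- idx$g
    jdata$agec <- idx$agec
    jdata$abar <- idx$abar
  }
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  inits <- lapply(chain_seeds, function(cs) jags_inits(spec, idx, cs))

  adapt <- max(2L, min(1000L, warmup %/% 2L))
  burn <- warmup - adapt
  t0 <- Sys.time()
  run <- function() {
    jm <- rjags::jags.model(textConnection(model$code), data = jdata,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = quiet)
    if (burn > 0L) update(jm, burn, progress.bar = "none")
    rjags::coda.samples(jm, model$monitors, n.iter = iterations - warmup,
                        progress.bar = "none")
  }
  sm <- if (quiet) suppressWarnings(run()) else run()
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")

  n_iter <- nrow(sm[[1]])
  pars <- rename_jags(colnames(sm[[1]]))
  draws <- array(NA_real_, dim = c(n_iter, chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (c in seq_len(chains)) draws[, c, ] <- as.matrix(sm[[c]])

  dat <- data
  dat$.y <- y
  structure(list(draws = draws, spec = spec, priors = model$priors,
                 data = dat, index = idx,
                 transform = list(method = transform, n = n),
                 mcmc = list(chains = chains, iterations = iterations,
                             warmup = warmup, seed = seed,
                             chain_seeds = chain_seeds,
                             retained = chains * n_iter,
                             divergences = 0L),
                 A_bar = idx$A_bar,
                 runtime_s = elapsed),
            class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  cat(sprintf("<si_fit model %d (%s): %d obs, %d chains x %d retained draws, %.1fs>\n",
              x$spec$model_id, x$spec$family, nrow(x$data),
              x$mcmc$chains, dim(x$draws)[1], x$runtime_s))
  invisible(x)
}

#' Stack the chains of a fit into a draws matrix
#'
#' @param fit An \code{si_fit}.
#' @return Matrix of retained draws (rows, chain-major) by named
#'   parameters (columns).
#' @export
draws_matrix <- function(fit) {
  d <- fit$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[2]), function(c) d[, c, ]))
  colnames(out) <- dimnames(d)[[3]]
  out
}

# Column names of a parameter vector, e.g. par_cols(fit, "e") ->
# "e[1]" ... "e[I]", in index order. Returns the bare name for scalars.
par_cols <- function(fit, name, n = NULL) {
  pars <- dimnames(fit$draws)[[3]]
  if (name %in% pars && is.null(n)) return(name)
  got <- pars[grepl(paste0("^", gsub("\\[", "\\\\[", name), "\\["), pars)]
  ord <- order(as.integer(sub(".*\\[(\\d+)\\]$", "\\1", got)))
  got[ord]
}
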