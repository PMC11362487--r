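# Predictive model comparison: WAIC, PSIS-LOO (with generalized-Pareto
# tail smoothing of the importance weights), DIC, evidence weights and
# influential-observation flags.

#' Widely applicable information criterion
#'
#' \code{lppd_i = log mean_s exp(ll_si)}, \code{p_i = Var_s(ll_si)},
#' \code{WAIC = -2 sum_i (lppd_i - p_i)}, with standard error
#' \code{sqrt(n * Var_i(-2 (lppd_i - p_i)))}.
#'
#' @param ll Pointwise log-likelihood matrix, draws x observations.
#' @return List with \code{waic}, \code{se}, \code{p_waic} and a
#'   \code{pointwise} data.frame (\code{lppd}, \code{p}, \code{elpd},
#'   \code{ic}).
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) stop("waic() needs at least 2 posterior draws")
  lppd <- apply(ll, 2L, log_mean_exp)
  p <- apply(ll, 2L, stats::var)
  elpd <- lppd - p
  ic <- -2 * elpd
  list(waic = sum(ic), se = sqrt(ncol(ll) * stats::var(ic)),
       p_waic = sum(p),
       pointwise = data.frame(lppd = lppd, p = p, elpd = elpd, ic = ic))
}

# Zhang & Stephens (2009) posterior-mean estimator for the generalized
# Pareto shape k and scale sigma, fitted to exceedances x > 0, with the
# weakly informative shape regularization used in PSIS practice.
gpd_fit <- function(x, wip = TRUE) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || stats::sd(x) == 0) return(list(k = NaN, sigma = NaN))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  if (wip) k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth one vector of log importance ratios. Returns the
# smoothed log weights (same location as input) and the tail-shape k.
psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  shift <- max(lw)
  r <- exp(lw - shift)
  ord <- order(r)
  cut_idx <- S - M
  if (cut_idx < 1L) return(list(lw = lw, k = NaN))
  u <- r[ord[cut_idx]]
  exc <- r[ord[(cut_idx + 1L):S]] - u
  if (all(exc <= .Machine$double.eps) ) return(list(lw = lw, k = NaN))
  fit <- gpd_fit(exc[exc > 0])
  if (is.nan(fit$k)) return(list(lw = lw, k = NaN))
  smoothed <- u + vapply((seq_len(M) - 0.5) / M, qgpd, numeric(1),
                         k = fit$k, sigma = fit$sigma)
  smoothed <- pmin(smoothed, max(r))  # never exceed the raw maximum
  r[ord[(cut_idx + 1L):S]] <- smoothed
  list(lw = log(r) + shift, k = fit$k)
}

#' PSIS-LOO cross-validation criterion
#'
#' Leave-one-out predictive accuracy by Pareto-smoothed importance
#' sampling: per observation the raw importance ratios
#' \code{exp(-ll_si)} are tail-smoothed by replacing the largest
#' \code{M = ceiling(min(0.2 S, 3 sqrt(S)))} ratios with expected order
#' statistics of a fitted generalized Pareto distribution (truncated at
#' the raw maximum), and the smoothed weights reweight the likelihood.
#' The per-observation tail shape \code{k} diagnoses influential
#' observations.
#'
#' @inheritParams waic
#' @return List with \code{psis}, \code{se}, \code{p_psis},
#'   \code{pareto_k} (per observation) and \code{pointwise}
#'   (\code{loo}, \code{ic}).
#' @export
psis_loo <- function(ll) {
  ll <- as.matrix(ll)
  S <- nrow(ll)
  if (S < 2L) stop("psis_loo() needs at least 2 posterior draws")
  if (S < 100L) warning("fewer than 100 draws: Pareto tail fit unstable")
  if (any(!is.finite(ll))) {
    bad <- which(apply(!is.finite(ll), 2L, any))
    stop("non-finite log-likelihood for observation(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  N <- ncol(ll)
  loo_i <- numeric(N)
  k_i <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth(-ll[, i])
    k_i[i] <- sm$k
    lw <- sm$lw - log_sum_exp(sm$lw)
    loo_i[i] <- log_sum_exp(lw + ll[, i])
  }
  lppd <- apply(ll, 2L, log_mean_exp)
  ic <- -2 * loo_i
  list(psis = sum(ic), se = sqrt(N * stats::var(ic)),
       p_psis = sum(lppd - loo_i), pareto_k = k_i,
       pointwise = data.frame(loo = loo_i, ic = ic))
}

#' Deviance information criterion
#'
#' \code{p_DIC} is the mean posterior deviance minus the deviance at
#' the posterior mean; \code{DIC = deviance at mean + 2 p_DIC}.
#'
#' @param dev_draws Vector of posterior deviance draws
#'   (\code{-2 * rowSums(ll)}).
#' @param dev_at_mean Deviance evaluated at the posterior mean of the
#'   parameters.
#' @return List with \code{dic}, \code{p_dic}.
#' @export
dic <- function(dev_draws, dev_at_mean) {
  stopifnot(length(dev_at_mean) == 1L, is.finite(dev_at_mean))
  p_dic <- mean(dev_draws) - dev_at_mean
  list(dic = dev_at_mean + 2 * p_dic, p_dic = p_dic)
}

#' Flag influential observations by Pareto k
#'
#' @param pareto_k Per-observation tail shapes from [psis_loo()].
#' @param threshold Flag threshold (0.7, the conventional cutoff above
#'   which importance-sampling estimates become unreliable).
#' @param data Optional entropy data.frame to map flags back to
#'   \code{(word, sentence, speaker, block)}.
#' @return Data.frame of flagged observations (possibly 0 rows).
#' @export
flag_influential <- function(pareto_k, threshold = 0.7, data = NULL) {
  idx <- which(!is.nan(pareto_k) & pareto_k > threshold)
  out <- data.frame(observation = idx, pareto_k = pareto_k[idx])
  if (!is.null(data) && length(idx)) {
    out <- cbind(out, data[idx, intersect(c("word", "sentence", "speaker",
                                            "block", "entropy"),
                                          names(data)), drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Score one fitted model on all three criteria
#'
#' @param fit An \code{si_fit}.
#' @return An \code{si_score} list bundling DIC, WAIC, PSIS, pointwise
#'   contributions, Pareto k values and the outcome fingerprint used to
#'   guarantee comparability across models.
#' @export
score_model <- function(fit) {
  ll <- loglik_matrix(fit)
  w <- waic(ll)
  p <- psis_loo(ll)
  d <- dic(-2 * rowSums(ll), -2 * sum(loglik_at_mean(fit)))
  y <- fit$data$.y
  structure(list(model_id = fit$spec$model_id, family = fit$spec$family,
                 n_obs = ncol(ll),
                 dic = d$dic, p_dic = d$p_dic,
                 waic = w$waic, waic_se = w$se, p_waic = w$p_waic,
                 psis = p$psis, psis_se = p$se, p_psis = p$p_psis,
                 pareto_k = p$pareto_k,
                 pointwise_waic = w$pointwise$ic,
                 pointwise_psis = p$pointwise$ic,
                 outcome = y),
            class = "si_score")
}

#' Compare scored models
#'
#' Builds the comparison table: criteria with their standard errors,
#' differences to the best (lowest) model with difference SEs computed
#' from the paired pointwise contributions, complexity penalties, the
#' count of Pareto-k flags, and exp(-d/2) evidence weights (computed
#' separately for WAIC and PSIS). All models must have been scored on
#' the identical outcome vector.
#'
#' @param scores List of [score_model()] results.
#' @param k_threshold Pareto-k flag threshold.
#' @return A data.frame sorted ascending by WAIC.
#' @export
compare_models <- function(scores, k_threshold = 0.7) {
  stopifnot(length(scores) >= 1L,
            all(vapply(scores, inherits, logical(1), "si_score")))
  y0 <- scores[[1L]]$outcome
  for (s in scores) {
    if (!isTRUE(all.equal(s$outcome, y0, tolerance = 0))) {
      stop("models were scored on different outcome vectors; criteria not comparable")
    }
  }
  n <- length(scores)
  tab <- do.call(rbind, lapply(scores, function(s) {
    data.frame(model_id = s$model_id, family = s$family,
               dic = s$dic, waic = s$waic, waic_se = s$waic_se,
               p_waic = s$p_waic, psis = s$psis, psis_se = s$psis_se,
               p_psis = s$p_psis,
               n_high_pareto_k = sum(!is.nan(s$pareto_k) &
                                       s$pareto_k > k_threshold))
  }))
  n_obs <- scores[[1L]]$n_obs
  d_se <- function(field, best) {
    vapply(scores, function(s) {
      sqrt(n_obs * stats::var(s[[field]] - scores[[best]][[field]]))
    }, numeric(1))
  }
  best_w <- which.min(tab$waic)
  best_p <- which.min(tab$psis)
  tab$d_waic <- tab$waic - tab$waic[best_w]
  tab$d_waic_se <- d_se("pointwise_waic", best_w)
  tab$d_psis <- tab$psis - tab$psis[best_p]
  tab$d_psis_se <- d_se("pointwise_psis", best_p)
  wts <- function(d) { w <- exp(-0.5 * d); w / sum(w) }
  tab$weight_waic <- wts(tab$d_waic)
  tab$weight_psis <- wts(tab$d_psis)
  if (any(tab$p_waic < 0) || any(tab$p_psis < 0)) {
    warning("negative complexity penalty encountered (reported as computed)")
  }
  tab <- tab[order(tab$waic), ]
  rownames(tab) <- NULL
  tab
}
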