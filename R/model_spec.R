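#' The twelve fitted model variants
#'
#' Models 1-6 are normal linear mixed models, models 7-12
#' beta-proportion GLLAMMs. Within each family the six variants cross
#' the robust feature (per-speaker outcome scale sigma_i or M_i versus
#' a single shared one) with three fixed-effect structures: intercept
#' only, group intercepts plus a common age slope, and group intercepts
#' plus group-specific age slopes.
#'
#' @return A data.frame with one row per model id.
#' @export
model_table <- function() {
  fe <- c("intercept_only",
          "group_intercepts_plus_common_slope",
          "group_intercepts_plus_group_slopes")
  data.frame(
    model_id = 1:12,
    family = rep(c("normal", "beta"), each = 6),
    robust = rep(rep(c(FALSE, TRUE), each = 3), 2),
    fixed_effects = rep(fe, 4),
    stringsAsFactors = FALSE)
}

#' Specification of one model variant
#'
#' @param model_id Integer 1-12 (see [model_table()]).
#' @return A \code{model_spec} list with \code{model_id},
#'   \code{family}, \code{robust}, \code{fixed_effects}.
#' @export
model_spec <- function(model_id) {
  tab <- model_table()
  if (!is.numeric(model_id) || length(model_id) != 1L ||
      !(model_id %in% tab$model_id)) {
    stop("model_id must be a single integer in 1..12")
  }
  row <- tab[tab$model_id == model_id, ]
  structure(list(model_id = as.integer(model_id), family = row$family,
                 robust = row$robust, fixed_effects = row$fixed_effects),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model %d: %s, %s, %s>\n", x$model_id,
              if (x$family == "beta") "beta-proportion GLLAMM" else "normal LMM",
              if (x$robust) "robust (per-speaker scale)" else "shared scale",
              x$fixed_effects))
  invisible(x)
}

#' Prior and hyperprior scales
#'
#' The default priors: the outcome-scale parameters (sigma_i or M_i)
#' get an Exponential(r) prior with hyper-rate r ~ Exponential(2);
#' speaker effects e_i ~ Normal(m_e, s_e) with m_e ~ Normal(0, 0.05)
#' and s_e ~ Exponential(2); block effects a_b ~ Normal(m_b, s_b) with
#' the same hyper structure; sentence effects u_si ~ Normal(0, s_u)
#' with s_u ~ Exponential(2); alpha ~ Normal(0, 0.05);
#' alpha_HS ~ Normal(0, 0.2) for the normal family and Normal(0, 0.3)
#' for the beta family; age slopes ~ Normal(0, 0.1).
#'
#' @param family \code{"normal"} or \code{"beta"}.
#' @param scale_rate Rate of the exponential hyperprior on the
#'   outcome-scale rate parameter.
#' @param alpha_scale,alpha_HS_scale,beta_scale Normal prior SDs of the
#'   fixed effects (\code{alpha_HS_scale} defaults by family).
#' @param m_e_scale,m_b_scale Normal hyperprior SDs of the random-effect
#'   means.
#' @param s_e_rate,s_b_rate,s_u_rate Exponential hyperprior rates of the
#'   random-effect SDs.
#' @return A \code{prior_set} list.
#' @export
prior_set <- function(family = c("normal", "beta"),
                      scale_rate = 2,
                      alpha_scale = 0.05,
                      alpha_HS_scale = if (family[1] == "beta") 0.3 else 0.2,
                      beta_scale = 0.1,
                      m_e_scale = 0.05, s_e_rate = 2,
                      m_b_scale = 0.05, s_b_rate = 2,
                      s_u_rate = 2) {
  family <- match.arg(family)
  ps <- list(family = family, scale_rate = scale_rate,
             alpha_scale = alpha_scale, alpha_HS_scale = alpha_HS_scale,
             beta_scale = beta_scale, m_e_scale = m_e_scale,
             s_e_rate = s_e_rate, m_b_scale = m_b_scale,
             s_b_rate = s_b_rate, s_u_rate = s_u_rate)
  stopifnot(all(unlist(ps[-1]) > 0))
  class(ps) <- "prior_set"
  ps
}
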