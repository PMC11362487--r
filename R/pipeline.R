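#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate -> entropy -> fit (one or more model variants)
#' -> diagnose -> compare -> rank/contrast, writing every stage's
#' tables and a provenance manifest into a run directory. Any stage
#' failure is recorded and the downstream stages are skipped.
#'
#' @param config A named list, or the path of a YAML file, with
#'   (optional) sections:
#'   \describe{
#'     \item{output_dir}{Run directory (required).}
#'     \item{seed}{Master seed (default 1).}
#'     \item{design}{Arguments for [design_config()].}
#'     \item{params}{Arguments for [true_params()].}
#'     \item{models}{Model ids to fit (default \code{c(4, 10)}).}
#'     \item{mcmc}{\code{chains}, \code{iterations}, \code{warmup}
#'       (defaults 4 / 4000 / 2000).}
#'     \item{comparison}{\code{k_threshold} (default 0.7).}
#'   }
#' @return Invisibly, the manifest list. Its \code{status$gate} field
#'   is nonzero when any fitted parameter failed the R-hat gate.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  models <- if (is.null(config$models)) c(4L, 10L) else as.integer(config$models)
  stopifnot(all(models %in% 1:12))
  mc <- utils::modifyList(list(chains = 4L, iterations = 4000L,
                               warmup = 2000L), config$mcmc %||% list())
  k_thr <- (config$comparison %||% list())$k_threshold %||% 0.7

  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- list(seed = seed, models = models, mcmc = mc,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   stages = list(), artifacts = list())
  record <- function(stage, status, files = character(0)) {
    manifest$stages[[stage]] <<- list(status = status, seconds = NULL)
    for (f in files) {
      manifest$artifacts[[basename(f)]] <<- unname(tools::md5sum(f))
    }
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(list(value = expr, error = NULL),
                    error = function(e) list(value = NULL,
                                             error = conditionMessage(e)))
    el <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    manifest$stages[[stage]] <<- list(
      status = if (is.null(res$error)) "ok" else "failed",
      error = res$error, seconds = el)
    message(sprintf("[%s] %s (%.1fs)", stage,
                    manifest$stages[[stage]]$status, el))
    res
  }
  add_artifact <- function(f) {
    manifest$artifacts[[basename(f)]] <<- unname(tools::md5sum(f))
  }
  finish <- function(gate = 1L) {
    manifest$status <- list(gate = gate)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }

  # simulate
  sim <- run_stage("simulate", {
    d <- do.call(design_config, config$design %||% list())
    p <- do.call(true_params, config$params %||% list())
    simulate_dataset(d, p, seed = seed)
  })
  if (!is.null(sim$error)) return(finish())
  data_csv <- file.path(out, "entropy_data.csv")
  write_entropy_table(sim$value$data, data_csv)
  add_artifact(data_csv)

  # fit + diagnose per model
  fits <- list()
  flags <- 0L
  for (m in models) {
    stage <- sprintf("fit_model_%02d", m)
    f <- run_stage(stage, {
      fit_model(m, sim$value$data, chains = mc$chains,
                iterations = mc$iterations, warmup = mc$warmup,
                seed = seed + m)
    })
    if (!is.null(f$error)) return(finish())
    fits[[as.character(m)]] <- f$value
    rep <- diagnose(f$value)
    dcsv <- file.path(out, sprintf("diagnostics_model_%02d.csv", m))
    write_diagnostics(rep, dcsv)
    add_artifact(dcsv)
    flags <- flags + attr(rep, "n_flagged")
  }

  # compare
  cmp <- run_stage("compare", {
    compare_models(lapply(fits, score_model), k_threshold = k_thr)
  })
  if (!is.null(cmp$error)) return(finish())
  ccsv <- file.path(out, "comparison.csv")
  utils::write.csv(cmp$value, ccsv, row.names = FALSE)
  add_artifact(ccsv)
  infl <- do.call(rbind, lapply(fits, function(f) {
    s <- score_model(f)
    fl <- flag_influential(s$pareto_k, k_thr, f$data)
    if (nrow(fl)) cbind(model_id = f$spec$model_id, fl) else NULL
  }))
  icsv <- file.path(out, "influential.csv")
  utils::write.csv(infl %||% data.frame(), icsv, row.names = FALSE)
  add_artifact(icsv)

  # rank + contrasts on the best beta-family fit (if any)
  beta_ids <- models[models >= 7L]
  if (length(beta_ids)) {
    best_beta <- beta_ids[which.min(vapply(beta_ids, function(m) {
      cmp$value$waic[cmp$value$model_id == m]
    }, numeric(1)))]
    rk <- run_stage("rank", {
      lp <- extract_si(fits[[as.character(best_beta)]])
      rank_speakers(lp)
    })
    if (is.null(rk$error)) {
      rcsv <- file.path(out, "speaker_ranking.csv")
      utils::write.csv(rk$value, rcsv, row.names = FALSE)
      add_artifact(rcsv)
    }
    ct <- run_stage("contrast", {
      fbest <- fits[[as.character(best_beta)]]
      if (fbest$spec$fixed_effects == "intercept_only") NULL else {
        do.call(rbind, lapply(group_contrasts(fbest), function(co) {
          data.frame(label = co$label, mean = co$mean,
                     hpdi_lo = co$hpdi[["lower"]],
                     hpdi_hi = co$hpdi[["upper"]],
                     significant = co$significant)
        }))
      }
    })
    if (is.null(ct$error) && !is.null(ct$value)) {
      ctcsv <- file.path(out, "group_contrasts.csv")
      utils::write.csv(ct$value, ctcsv, row.names = FALSE)
      add_artifact(ctcsv)
    }
  }
  finish(gate = as.integer(flags > 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
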