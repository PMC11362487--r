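#' Configuration of a synthetic transcription study design
#'
#' Defaults emulate the two-group child-speech transcription study the
#' package's models were developed for: 16 normal-hearing (NH) and 16
#' cochlear-implanted (HI/CI) speakers, ages in months drawn from
#' truncated normals matching the groups' printed summaries (NH: mean
#' 86.3, SD 9.0, range 68-104; HI/CI: mean 86.3, SD 6.7, range 78-98),
#' 10 sentences per speaker with 3-11 words (mean 7.1, SD 1.1), and 5
#' experimental blocks of 21 listeners and 64 sentences each, every
#' sentence belonging to exactly one block.
#'
#' @param n_speakers_per_group Speakers per hearing-status group.
#' @param n_blocks Number of experimental blocks.
#' @param listeners_per_block Listeners (transcriptions per word) J.
#' @param sentences_per_speaker Sentences S per speaker.
#' @param words_range Integer bounds on words per sentence.
#' @param words_mean,words_sd Target mean/SD of the discretized
#'   truncated-normal word-count sampler.
#' @param age_nh,age_hici Lists with \code{mean}, \code{sd},
#'   \code{lower}, \code{upper} (months) for the two groups' age
#'   distributions.
#' @return A \code{design_config} list.
#' @export
design_config <- function(n_speakers_per_group = 16L,
                          n_blocks = 5L,
                          listeners_per_block = 21L,
                          sentences_per_speaker = 10L,
                          words_range = c(3L, 11L),
                          words_mean = 7.1,
                          words_sd = 1.1,
                          age_nh = list(mean = 86.3, sd = 9.0,
                                        lower = 68, upper = 104),
                          age_hici = list(mean = 86.3, sd = 6.7,
                                          lower = 78, upper = 98)) {
  cfg <- list(n_speakers_per_group = as.integer(n_speakers_per_group),
              n_blocks = as.integer(n_blocks),
              listeners_per_block = as.integer(listeners_per_block),
              sentences_per_speaker = as.integer(sentences_per_speaker),
              words_range = as.integer(words_range),
              words_mean = words_mean, words_sd = words_sd,
              age_nh = age_nh, age_hici = age_hici)
  stopifnot(cfg$n_speakers_per_group >= 1, cfg$n_blocks >= 1,
            cfg$listeners_per_block >= 2, cfg$sentences_per_speaker >= 1,
            cfg$words_range[1] >= 1, cfg$words_range[1] <= cfg$words_range[2],
            age_nh$lower < age_nh$upper, age_hici$lower < age_hici$upper)
  n_sent <- 2L * cfg$n_speakers_per_group * cfg$sentences_per_speaker
  if (n_sent %% cfg$n_blocks != 0L) {
    stop("total sentences (", n_sent, ") not divisible into ",
         cfg$n_blocks, " equal blocks")
  }
  class(cfg) <- "design_config"
  cfg
}

# Discretized truncated normal on the integer word-count range.
sample_word_counts <- function(n, cfg) {
  lo <- cfg$words_range[1]; hi <- cfg$words_range[2]
  x <- rtruncnorm(n, cfg$words_mean, cfg$words_sd, lo - 0.5 + 1e-9, hi + 0.5 - 1e-9)
  pmin(pmax(as.integer(round(x)), lo), hi)
}

#' Generate a synthetic study design
#'
#' Draws speaker ages and group labels, assigns each speaker's sentences
#' to blocks (blocks are filled sequentially so that every block holds
#' the same number of sentences and each sentence belongs to exactly one
#' block), and draws per-sentence word counts.
#'
#' @param config A [design_config()].
#' @param seed Integer seed; the design is deterministic given the seed.
#' @return A \code{study_design} list with \code{speakers} (speaker,
#'   hearing_status, age_months) and \code{sentences} (sentence,
#'   speaker, block, n_words) data.frames, plus the config.
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  set.seed(seed)
  ng <- config$n_speakers_per_group
  n_spk <- 2L * ng
  speakers <- data.frame(
    speaker = seq_len(n_spk),
    hearing_status = rep(c("NH", "HI/CI"), each = ng),
    age_months = c(rtruncnorm(ng, config$age_nh$mean, config$age_nh$sd,
                              config$age_nh$lower, config$age_nh$upper),
                   rtruncnorm(ng, config$age_hici$mean, config$age_hici$sd,
                              config$age_hici$lower, config$age_hici$upper)))
  S <- config$sentences_per_speaker
  n_sent <- n_spk * S
  per_block <- n_sent %/% config$n_blocks
  # Interleave the groups before the sequential fill so every block
  # mixes NH and HI/CI speakers.
  spk_order <- as.vector(rbind(seq_len(ng), ng + seq_len(ng)))
  sentences <- data.frame(
    sentence = seq_len(n_sent),
    speaker = rep(spk_order, each = S),
    block = rep(seq_len(config$n_blocks), each = per_block),
    n_words = sample_word_counts(n_sent, config))
  structure(list(speakers = speakers, sentences = sentences,
                 config = config, seed = seed),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design: %d speakers (%s), %d sentences, %d blocks, J=%d>\n",
              nrow(x$speakers),
              paste(table(x$speakers$hearing_status), collapse = "+"),
              nrow(x$sentences), x$config$n_blocks,
              x$config$listeners_per_block))
  invisible(x)
}
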