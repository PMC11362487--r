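#' Read aligned transcription grids from a TSV file
#'
#' The grid dialect stores one or more sentences per file. Each grid
#' starts with a header line \code{#sentence=<s> speaker=<i> block=<b>}
#' followed by J rows of W tab-separated tokens (one row per listener).
#' Literal \code{[B]} and \code{[X]} mark blanks and unidentifiable
#' speech; empty cells are read as blanks. Blank lines between grids are
#' ignored.
#'
#' @param path Path to the TSV file.
#' @param case_fold Passed to [aligned_grid()].
#' @return A list of [aligned_grid()] objects (empty list for an empty
#'   file).
#' @export
read_grids <- function(path, case_fold = TRUE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(list())

  starts <- grep("^#", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    stop("grid file must start with a '#sentence=... speaker=... block=...' header")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  grids <- vector("list", length(starts))
  for (g in seq_along(starts)) {
    hdr <- lines[starts[g]]
    get_field <- function(name) {
      m <- regmatches(hdr, regexec(paste0(name, "=(-?[0-9]+)"), hdr))[[1]]
      if (length(m) < 2L) stop("grid header missing field '", name, "': ", hdr)
      as.integer(m[2])
    }
    s <- get_field("sentence")
    i <- get_field("speaker")
    b <- get_field("block")
    body <- lines[(starts[g] + 1L):ends[g]]
    if (starts[g] + 1L > ends[g] || length(body) < 2L) {
      stop("sentence ", s, ": needs at least 2 listener rows")
    }
    rows <- strsplit(body, "\t", fixed = TRUE)
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      stop("sentence ", s, ": ragged rows (widths ",
           paste(widths, collapse = ","), ")")
    }
    cells <- do.call(rbind, rows)
    grids[[g]] <- aligned_grid(cells, sentence_id = s, speaker_id = i,
                               block_id = b, case_fold = case_fold)
  }
  grids
}

#' Write aligned grids to the grid TSV dialect
#'
#' @param grids List of [aligned_grid()] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_grids <- function(grids, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in grids) {
    writeLines(sprintf("#sentence=%d speaker=%d block=%d",
                       g$sentence_id, g$speaker_id, g$block_id), con)
    apply(g$cells, 1L, function(r) writeLines(paste(r, collapse = "\t"), con))
  }
  invisible(path)
}

#' Write a tidy entropy table to CSV
#'
#' Columns are exactly \code{word, sentence, speaker, block, entropy,
#' n_transcriptions, n_types} (plus any extra covariate columns present,
#' e.g. \code{hearing_status}, \code{age_months}).
#'
#' @param records Entropy data.frame from [grid_entropies()] /
#'   [batch_entropies()] / [simulate_entropy()].
#' @param path Output path.
#' @param round4 Round entropies to 4 decimals for display parity with
#'   printed tables? Default \code{FALSE} (full precision).
#' @return \code{path}, invisibly.
#' @export
write_entropy_table <- function(records, path, round4 = FALSE) {
  core <- c("word", "sentence", "speaker", "block", "entropy")
  stopifnot(all(core %in% names(records)))
  extra <- setdiff(names(records), c(core, "n_transcriptions", "n_types"))
  keep <- c(core, intersect(c("n_transcriptions", "n_types"), names(records)), extra)
  out <- records[, keep, drop = FALSE]
  if (round4) out$entropy <- round(out$entropy, 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy entropy table from CSV
#'
#' @param path CSV path as written by [write_entropy_table()].
#' @return A data.frame.
#' @export
read_entropy_table <- function(path) {
  stopifnot(file.exists(path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' The worked-example transcription grid
#'
#' A five-listener, five-word aligned grid (in Belgian Dutch) used
#' throughout the documentation to illustrate the entropy computation,
#' including the blank and unidentifiable-speech conventions. Shipped as
#' \code{inst/extdata/example_grid.tsv}.
#'
#' @return An [aligned_grid()].
#' @export
example_grid <- function() {
  read_grids(system.file("extdata", "example_grid.tsv",
                         package = "entropySI", mustWork = TRUE))[[1]]
}
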