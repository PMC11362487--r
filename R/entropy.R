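#' Token kinds
#'
#' Listener transcriptions are normalized into three kinds of tokens:
#' ordinary words, blanks (the listener left the position empty, surface
#' form \code{"[B]"}), and unidentifiable speech (surface form
#' \code{"[X]"}).
#'
#' @name tokens
NULL

TOKEN_BLANK <- "[B]"
TOKEN_UNID <- "[X]"

#' Normalize a raw transcription cell into a token
#'
#' Empty or whitespace-only cells and the literal marker \code{"[B]"}
#' become blanks; the literal marker \code{"[X]"} becomes an
#' unidentifiable-speech token; anything else is a word, trimmed and
#' (by default) case-folded.
#'
#' @param raw Character scalar, the raw cell content.
#' @param case_fold Lower-case word tokens before comparison? Default
#'   \code{TRUE}.
#' @return A list with elements \code{text} and \code{kind} (one of
#'   \code{"WORD"}, \code{"BLANK"}, \code{"UNIDENTIFIABLE"}).
#' @export
normalize_token <- function(raw, case_fold = TRUE) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  txt <- trimws(raw)
  if (txt == "" || txt == TOKEN_BLANK) {
    return(list(text = TOKEN_BLANK, kind = "BLANK"))
  }
  if (txt == TOKEN_UNID) {
    return(list(text = TOKEN_UNID, kind = "UNIDENTIFIABLE"))
  }
  if (case_fold) txt <- tolower(txt)
  list(text = txt, kind = "WORD")
}

# Vectorized normalization to canonical surface strings. Word tokens keep
# their (folded) text; blanks collapse to "[B]"; "[X]" stays literal.
normalize_cells <- function(x, case_fold = TRUE) {
  vapply(x, function(r) normalize_token(r, case_fold)$text, character(1),
         USE.NAMES = FALSE)
}

#' Construct an aligned transcription grid
#'
#' One sentence's listener-by-word-position matrix of transcription
#' tokens, as produced by aligning all listeners' orthographic
#' transcriptions of the same sentence.
#'
#' @param cells Character matrix, J listeners (rows) by W word positions
#'   (columns). Cells are raw strings; they are normalized on
#'   construction.
#' @param sentence_id,speaker_id,block_id Integer indices of the
#'   sentence, the speaker who produced it, and the experimental block.
#' @param case_fold Passed to [normalize_token()].
#' @return An object of class \code{aligned_grid}.
#' @export
aligned_grid <- function(cells, sentence_id = 1L, speaker_id = 1L,
                         block_id = 1L, case_fold = TRUE) {
  stopifnot(is.matrix(cells), nrow(cells) >= 2L, ncol(cells) >= 1L)
  norm <- matrix(normalize_cells(as.vector(cells), case_fold),
                 nrow = nrow(cells), ncol = ncol(cells))
  structure(
    list(cells = norm,
         sentence_id = as.integer(sentence_id),
         speaker_id = as.integer(speaker_id),
         block_id = as.integer(block_id)),
    class = "aligned_grid")
}

#' @export
print.aligned_grid <- function(x, ...) {
  cat(sprintf("<aligned_grid sentence=%d speaker=%d block=%d: %d listeners x %d words>\n",
              x$sentence_id, x$speaker_id, x$block_id,
              nrow(x$cells), ncol(x$cells)))
  invisible(x)
}

# Tally transcription types in one word column. Word and blank tokens
# form types by exact string equality; every "[X]" is its own type
# (unidentifiable speech cannot be asserted equal to anything). With
# blank_distinct = TRUE blanks are likewise pairwise distinct.
type_counts <- function(column, blank_distinct = FALSE) {
  is_x <- column == TOKEN_UNID
  if (blank_distinct) is_x <- is_x | column == TOKEN_BLANK
  counts <- as.integer(table(column[!is_x]))
  c(counts, rep.int(1L, sum(is_x)))
}

#' Normalized Shannon entropy of one word's transcriptions
#'
#' Computes \eqn{H = -\sum_k p_k \log_2 p_k / \log_2 J} over the
#' transcription types in a word column, where \eqn{p_k} is the
#' proportion of the J listener transcriptions falling in type k. A
#' score of 0 means all listeners agreed (a single type, fully
#' intelligible word); 1 means every transcription was distinct.
#'
#' Types are formed by exact equality of word and blank tokens, while
#' each unidentifiable-speech token \code{"[X]"} counts as its own
#' distinct type.
#'
#' @param column Character vector of J >= 2 normalized tokens (a word
#'   column of an aligned grid), or a list of tokens from
#'   [normalize_token()].
#' @param blank_distinct Treat each \code{"[B]"} as its own type too?
#'   Default \code{FALSE}: blanks form one shared "nothing heard" type.
#' @return Entropy in [0, 1].
#' @export
word_entropy <- function(column, blank_distinct = FALSE) {
  if (is.list(column)) {
    column <- vapply(column, function(t) t$text, character(1))
  }
  stopifnot(is.character(column))
  J <- length(column)
  if (J < 2L) {
    stop("word_entropy() needs at least 2 transcriptions (J >= 2); got J = ", J)
  }
  counts <- type_counts(column, blank_distinct)
  p <- counts / J
  # + 0 normalizes the negative zero produced by -sum() when K = 1
  -sum(p * log2(p)) / log2(J) + 0
}

#' Entropy scores for every word position of a grid
#'
#' @param grid An [aligned_grid()].
#' @param blank_distinct Passed to [word_entropy()].
#' @return A data.frame with one row per word position and columns
#'   \code{word}, \code{sentence}, \code{speaker}, \code{block},
#'   \code{entropy}, \code{n_transcriptions}, \code{n_types}.
#' @export
grid_entropies <- function(grid, blank_distinct = FALSE) {
  stopifnot(inherits(grid, "aligned_grid"))
  W <- ncol(grid$cells)
  J <- nrow(grid$cells)
  ent <- numeric(W)
  k <- integer(W)
  for (w in seq_len(W)) {
    col <- grid$cells[, w]
    counts <- type_counts(col, blank_distinct)
    k[w] <- length(counts)
    ent[w] <- tryCatch(
      word_entropy(col, blank_distinct),
      error = function(e) stop("word position ", w, " of sentence ",
                               grid$sentence_id, ": ", conditionMessage(e)))
  }
  data.frame(word = seq_len(W),
             sentence = grid$sentence_id,
             speaker = grid$speaker_id,
             block = grid$block_id,
             entropy = ent,
             n_transcriptions = J,
             n_types = k)
}

#' Entropy table for a batch of grids
#'
#' @param grids List of [aligned_grid()] objects.
#' @inheritParams grid_entropies
#' @return Row-bound entropy records for all grids.
#' @export
batch_entropies <- function(grids, blank_distinct = FALSE) {
  do.call(rbind, lapply(grids, grid_entropies, blank_distinct = blank_distinct))
}
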