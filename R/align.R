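#' Pairwise sequence identity
#'
#' Three modes: `global` aligns with Needleman-Wunsch (match +1, mismatch -1,
#' gap -2, deterministic traceback preferring diagonal, then up, then left)
#' and counts gap columns in the denominator; `local` reports the best
#' ungapped local segment pair under +1/-1 scoring; `ungapped` compares the
#' two sequences position by position and requires equal lengths. Ambiguity
#' symbols (N, X) and gaps always count as mismatches.
#'
#' @param a,b Sequences (character scalars, same alphabet).
#' @param mode `"global"`, `"local"` or `"ungapped"`.
#' @return An `identity_result` list: `matches`, `columns`, `identity`,
#'   `mode`, plus the aligned strings for global mode.
#' @examples
#' pairwise_identity("VPIS", "APIT", "ungapped")  # 2/4 = 0.5
#' @export
pairwise_identity <- function(a, b, mode = c("global", "local", "ungapped")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  res <- switch(mode,
    global = {
      al <- cpp_nw_align(a, b)
      list(matches = al$matches, columns = al$columns,
           aligned_a = al$a, aligned_b = al$b, score = al$score)
    },
    local = {
      h <- cpp_best_local_match(a, b, 1L)
      if (length(h) == 0) list(matches = 0L, columns = 0L)
      else list(matches = h[5], columns = h[2] - h[1] + 1L)
    },
    ungapped = {
      if (nchar(a) != nchar(b)) stop("ungapped mode requires equal lengths")
      m <- ungapped_matches(a, b)
      list(matches = m, columns = nchar(a))
    })
  out <- c(res[setdiff(names(res), c("matches", "columns"))],
           list(matches = as.integer(res$matches),
                columns = as.integer(res$columns),
                identity = if (res$columns > 0) res$matches / res$columns else NA_real_,
                mode = mode))
  structure(out, class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%s identity: %d/%d = %s\n", x$mode, x$matches, x$columns,
              ifelse(is.na(x$identity), "NA", sprintf("%.3f", x$identity))))
  invisible(x)
}

# positionwise identical, unambiguous columns of two equal-length strings
ungapped_matches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca == cb & !(ca %in% c("N", "X", "-")))
}

#' Non-overlapping sliding-window identity profile of an alignment
#'
#' Tiles two pre-aligned, equal-length sequences left to right into windows
#' of `window_size` columns; per-window identity is matches over window
#' columns with gap and ambiguity columns counting as mismatches. The final
#' window may be shorter and its true width is recorded.
#'
#' @param aligned_a,aligned_b Aligned sequences (may contain `-`).
#' @param window_size Window width in columns (>= 1).
#' @return A `window_profile` list with a `windows` data frame
#'   (`start`, `end`, `matches`, `identity`) and `final_window_width`.
#' @export
window_identity_profile <- function(aligned_a, aligned_b, window_size) {
  if (nchar(aligned_a) != nchar(aligned_b)) stop("sequences must be aligned (equal length)")
  if (window_size < 1) stop("window_size must be >= 1")
  n <- nchar(aligned_a)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  eq <- ca == cb & !(ca %in% c("N", "X", "-"))
  starts <- seq(1L, n, by = window_size)
  ends <- pmin(starts + window_size - 1L, n)
  matches <- vapply(seq_along(starts),
                    function(i) sum(eq[starts[i]:ends[i]]), integer(1))
  width <- ends - starts + 1L
  structure(list(
    window_size = as.integer(window_size),
    windows = data.frame(start = starts, end = ends, matches = matches,
                         identity = matches / width),
    final_window_width = width[length(width)]
  ), class = "window_profile")
}

#' Best ungapped local segment pair between two sequences
#'
#' Finds the highest-scoring ungapped segment pair under +1/-1 scoring with
#' length at least `min_length`; ties are broken by longer segment, then
#' smaller start in `a`, then smaller start in `b`. This is the machinery
#' behind interdomain similarity searches such as the 25 bp / 84% stretch
#' that can seed unequal crossing-over between tandem ICK domains.
#'
#' @param a,b Sequences.
#' @param min_length Minimum reported segment length.
#' @param match,mismatch Scoring (defaults +1/-1).
#' @return A `local_match` list (`a_start`, `a_end`, `b_start`, `b_end`,
#'   `length`, `matches`, `identity`, `score`) or `NULL` when no
#'   positive-scoring segment of the required length exists.
#' @export
best_local_match <- function(a, b, min_length = 1, match = 1, mismatch = -1) {
  if (min_length < 1) stop("min_length must be >= 1")
  h <- cpp_best_local_match(a, b, as.integer(min_length), match, mismatch)
  if (length(h) == 0) return(NULL)
  len <- h[2] - h[1] + 1L
  structure(list(a_start = h[1], a_end = h[2], b_start = h[3], b_end = h[4],
                 length = len, matches = h[5], identity = h[5] / len,
                 score = h[5] * match + (len - h[5]) * mismatch),
            class = "local_match")
}

#' @export
print.local_match <- function(x, ...) {
  cat(sprintf("local match: a %d-%d / b %d-%d, %d/%d bp (%.0f%%)\n",
              x$a_start, x$a_end, x$b_start, x$b_end,
              x$matches, x$length, 100 * x$identity))
  invisible(x)
}

#' Find inverted repeats (palindromic arm pairs) in a DNA sequence
#'
#' Reports all maximal non-overlapping arm pairs in which one arm matches
#' the reverse complement of the other with at most `max_mismatch`
#' mismatches -- the inverted-repeat diagonals of a self dot-plot against
#' the reverse complement. Used to screen for hairpin-capable palindromes
#' as an alternative explanation for domain fusions.
#'
#' @param seq DNA string.
#' @param min_arm Minimum arm length (>= 3).
#' @param max_mismatch Mismatch budget per arm pair.
#' @return Data frame with columns `left_start`, `left_end`, `right_start`,
#'   `right_end`, `arm_length`, `mismatches`, `loop`. Zero rows when none.
#' @export
find_inverted_repeats <- function(seq, min_arm = 3, max_mismatch = 0) {
  if (min_arm < 3) stop("min_arm must be >= 3")
  M <- cpp_inverted_repeats(seq, as.integer(min_arm), as.integer(max_mismatch))
  df <- as.data.frame(M)
  df$loop <- df$right_start - df$left_end - 1L
  df
}
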