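# RNA is matched with T treated as U throughout; scanning is always on the
# provided (sense) strand.
normalize_rna <- function(seq) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0)
    stop("invalid nucleotide '", substr(s, bad, bad), "' at position ", bad)
  s
}

#' Find non-overlapping YCAY motif sites
#'
#' Left-to-right greedy matching of the NOVA-family binding motif
#' `[C/U]CA[C/U]`: after a match the search resumes at the match end, so
#' overlapping occurrences yield only the leftmost. T and U are
#' equivalent; case-insensitive; `N` never matches.
#'
#' @param seq a nucleotide string over `{A,C,G,T,U,N}`.
#' @return integer vector of 0-based motif start positions.
#' @examples
#' find_ycay_sites("UCAUCAU")   # 0 (position 3 overlaps and is skipped)
#' find_ycay_sites("UCAUUCAU")  # 0, 4
#' @export
find_ycay_sites <- function(seq) {
  s <- normalize_rna(seq)
  m <- gregexpr("[CU]CA[CU]", s)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Score one 45-nt window for YCAY clustering
#'
#' Motifs are found with [find_ycay_sites()] and grouped greedily from the
#' left, each motif belonging to at most one scored group. With gaps
#' measured as the number of nucleotides between one motif's end and the
#' next motif's start, the pattern scores are: a triple with both gaps
#' <= 2 scores 8; a triple with one gap <= 2 and the other 3-6 scores 4;
#' a pair with gap <= 2 scores 2; a pair with gap 3-6 scores 1; a pair
#' with gap >= 7 scores 0 and, because such motifs are not part of one
#' cluster, the second motif of that pair remains available for later
#' groups. A triple with both gaps 3-6 has no defined pattern score and is
#' scored as its leading 3-6 pair (1), with the third motif carried
#' forward; this case is reported via `options(inexr.verbose = TRUE)`.
#' The window's raw score is the sum over groups; fewer than two motifs
#' score 0.
#'
#' @param seq45 a nucleotide string of length exactly 45.
#' @return non-negative integer raw score.
#' @export
score_window <- function(seq45) {
  if (nchar(seq45) != 45L)
    stop("score_window() expects exactly 45 nt, got ", nchar(seq45))
  score_motif_starts(find_ycay_sites(seq45))
}

# Grouping/scoring on 0-based motif start positions (motif length 4).
score_motif_starts <- function(starts) {
  k <- length(starts)
  if (k < 2L) return(0L)
  gaps <- starts[-1L] - (starts[-k] + 4L)
  score <- 0L
  i <- 1L
  while (i <= k - 1L) {
    g1 <- gaps[i]
    if (g1 >= 7L) { i <- i + 1L; next }
    g2 <- if (i + 1L <= k - 1L) gaps[i + 1L] else Inf
    if (g2 <= 6L) {
      if (g1 <= 2L && g2 <= 2L) {
        score <- score + 8L
      } else if (g1 <= 2L || g2 <= 2L) {
        score <- score + 4L
      } else {
        verbose_msg("triple with gaps (3-6, 3-6) has no pattern score; ",
                    "scored as a 3-6 pair (1), third motif carried forward")
        score <- score + 1L
        i <- i + 2L
        next
      }
      i <- i + 3L
    } else {
      score <- score + if (g1 <= 2L) 2L else 1L
      i <- i + 2L
    }
  }
  score
}

#' Slide a 45-nt scoring window along a sequence
#'
#' One window per start `0 .. L - window`, advancing by `step` (the
#' analysis uses window 45, step 1). Each window is scored independently
#' with [score_window()]; `log_score = log10(raw_score)` for raw >= 1 and
#' 0 otherwise, so raw scores of at least 4 — at least one triple or two
#' pair groups — reach the 0.6 display threshold while 1-3 stay below it.
#'
#' @param seq a nucleotide string of length >= `window`.
#' @param window window width in nt (default 45).
#' @param step step in nt (default 1).
#' @param sequence_id identifier recorded in the track.
#' @return a `data.table` track: `sequence_id`, `window_start` (0-based),
#'   `raw_score`, `log_score`.
#' @export
scan_sequence <- function(seq, window = 45L, step = 1L,
                          sequence_id = "seq") {
  s <- normalize_rna(seq)
  L <- nchar(s)
  if (L < window)
    stop("sequence length ", L, " is shorter than the window (", window, ")")
  starts0 <- seq.int(0L, L - window, by = step)
  raw <- vapply(starts0, function(st) {
    score_motif_starts(find_ycay_sites(substr(s, st + 1L, st + window)))
  }, integer(1))
  data.table::data.table(
    sequence_id = sequence_id, window_start = starts0,
    raw_score = raw,
    log_score = ifelse(raw >= 1L, log10(raw), 0))
}

#' Find GU-rich stretches
#'
#' Maximal runs of consecutive G or U (T treated as U) of at least
#' `min_len` nucleotides, reported in 0-based half-open coordinates.
#'
#' @param seq a nucleotide string.
#' @param min_len minimum run length (default 4).
#' @param sequence_id identifier recorded in the result.
#' @return a `data.table`: `sequence_id`, `start`, `end` (0-based
#'   half-open), `length`; zero rows when there is no qualifying run.
#' @export
find_gu_runs <- function(seq, min_len = 4L, sequence_id = "seq") {
  s <- normalize_rna(seq)
  isgu <- strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "U")
  r <- rle(isgu)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.table::data.table(
    sequence_id = sequence_id,
    start = starts[keep] - 1L, end = ends[keep],
    length = r$lengths[keep])
}

#' Write motif tracks and GU runs
#'
#' `write_track_bedgraph()` writes one bedGraph line per window
#' (`sequence_id, start, start+1, log_score`, 0-based half-open);
#' `write_track_tsv()` writes the full track table; `write_gu_bed()`
#' writes GU runs as 4-column BED.
#'
#' @param track a track from [scan_sequence()] (tracks for several
#'   sequences may be row-bound).
#' @param path file path.
#' @export
write_track_bedgraph <- function(track, path) {
  dt <- data.table::as.data.table(track)
  out <- dt[, .(sequence_id, start = window_start,
                end = window_start + 1L, log_score)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_track_bedgraph
#' @export
write_track_tsv <- function(track, path) {
  write_tsv_prov(data.table::as.data.table(track), path)
}

#' @rdname write_track_bedgraph
#' @param runs GU runs from [find_gu_runs()].
#' @export
write_gu_bed <- function(runs, path) {
  dt <- data.table::as.data.table(runs)
  out <- dt[, .(sequence_id, start, end,
                name = sprintf("GU_run_%d", length))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
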