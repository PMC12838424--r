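#' Control-subtracted differential track
#'
#' At each (position, strand) covered by the test track, the differential
#' fraction is `max(0, f_test - f_control)`; a missing control value counts
#' as 0 (pass-through), and positions missing in the test stay missing.
#' Subtracting the unmodified control removes false modification calls the
#' caller makes systematically at particular sequence contexts.
#'
#' @param test,control [fraction_track]s over the same genome.
#' @return A [fraction_track] of differential fractions.
#' @export
differential_track <- function(test, control) {
  stopifnot(inherits(test, "fraction_track"), inherits(control, "fraction_track"))
  if (test$genome_name != control$genome_name || test$length != control$length) {
    stop(sprintf("test ('%s', %d bp) and control ('%s', %d bp) do not match",
                 test$genome_name, test$length,
                 control$genome_name, control$length))
  }
  out <- test
  for (f in c("plus", "minus")) {
    ctl <- control[[f]]
    ctl[is.na(ctl)] <- 0
    out[[f]] <- pmax(0, test[[f]] - ctl)   # NA in test stays NA
  }
  out
}

#' Extract the top-K most strongly modified fixed-width windows
#'
#' Every window start is a candidate; a window's score is the sum of
#' non-missing differential fractions on both strands over its bases.
#' Windows are selected greedily in descending score (ties to the smaller
#' start) subject to pairwise disjointness, so each returned region is
#' independent motif evidence. If fewer than `k` positive-score disjoint
#' windows exist, fewer are returned with a warning.
#'
#' @param track A [fraction_track] (normally a differential track).
#' @param g The [genome] the track annotates.
#' @param width Window width in bases (default 10).
#' @param k Number of windows to return (default 100).
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `score`, `seq` (plus-strand sequence), sorted by descending score.
#' @export
top_windows <- function(track, g, width = 10L, k = 100L) {
  stopifnot(inherits(track, "fraction_track"), inherits(g, "genome"),
            width >= 1, k >= 1)
  L <- track$length
  if (L < width) stop("genome shorter than window width")
  combined <- ifelse(is.na(track$plus), 0, track$plus) +
    ifelse(is.na(track$minus), 0, track$minus)
  cs <- cumsum(c(0, combined))
  starts <- 0:(L - width)                      # 0-based
  scores <- cs[starts + width + 1L] - cs[starts + 1L]
  # equal-sum windows must tie exactly for the smaller-start tie-break;
  # rounding at 1e-9 removes cumulative floating-point noise
  scores <- round(scores, 9L)

  ord <- order(-scores, starts)
  occupied <- logical(L)
  sel <- integer(0)
  for (i in ord) {
    if (scores[i] <= 0) break                  # ord is score-descending
    s <- starts[i]
    span <- (s + 1L):(s + width)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      sel <- c(sel, i)
      if (length(sel) == as.integer(k)) break
    }
  }
  if (length(sel) < k) {
    warning(sprintf("only %d positive-score disjoint windows available (k = %d)",
                    length(sel), k))
  }
  win <- data.frame(start = starts[sel], end = starts[sel] + width,
                    score = scores[sel], stringsAsFactors = FALSE)
  win$seq <- window_sequences(win, g)
  win
}

#' Plus-strand sequences of windows
#'
#' Windows crossing the end of a circular genome wrap around; on a linear
#' genome an out-of-bounds window is an error.
#'
#' @param windows A data.frame with `start`, `end` columns (0-based half-open).
#' @param g A [genome].
#' @return Character vector of sequences in window order.
#' @export
window_sequences <- function(windows, g) {
  stopifnot(inherits(g, "genome"))
  if (nrow(windows) == 0L) return(character(0))
  L <- genome_length(g)
  vapply(seq_len(nrow(windows)), function(i) {
    s <- windows$start[i]; e <- windows$end[i]
    if (s < 0L || s >= e) stop(sprintf("invalid window [%d, %d)", s, e))
    if (e <= L) {
      substr(g$seq, s + 1L, e)
    } else if (g$circular && s < L && e - s <= L) {
      paste0(substr(g$seq, s + 1L, L), substr(g$seq, 1L, e - L))
    } else {
      stop(sprintf("window [%d, %d) outside linear genome of length %d", s, e, L))
    }
  }, "")
}

#' Write windows as a BED file (0-based half-open, score column)
#' @param windows Window data.frame from [top_windows()].
#' @param genome_name Chromosome/contig name for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, genome_name, path) {
  writeLines(sprintf("%s\t%d\t%d\twindow_%d\t%.6g", genome_name,
                     windows$start, windows$end,
                     seq_len(nrow(windows)), windows$score), path)
  invisible(path)
}
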