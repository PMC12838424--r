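#' Convert a Phred quality score to percent error
#'
#' \eqn{100 \cdot 10^{-q/10}}: Q7 is roughly 20% wrongly called bases, Q13
#' roughly 5%.
#'
#' @param q Non-negative quality score(s).
#' @return Percent error, same length as `q`.
#' @export
qscore_to_error_percent <- function(q) {
  if (any(q < 0)) stop("quality scores must be non-negative")
  100 * 10^(-q / 10)
}

#' Mean quality score of a read from its per-base scores
#'
#' The nanopore-tooling convention: convert each per-base Q to an error
#' probability, average the probabilities, and convert back
#' (\eqn{-10 \log_{10} \bar p}) — not the arithmetic mean of Q, which would
#' overstate accuracy.
#'
#' @param per_base_q Non-empty numeric vector of per-base quality scores.
#' @return The per-read mean quality score.
#' @export
mean_read_qscore <- function(per_base_q) {
  if (length(per_base_q) == 0L) stop("empty quality vector")
  if (any(per_base_q < 0)) stop("quality scores must be non-negative")
  -10 * log10(mean(10^(-per_base_q / 10)))
}

#' Summary statistics of per-read quality scores
#'
#' Median and quartiles by linear interpolation (quantile type 7);
#' `mean_error_percent` is the percent error of the error-domain mean score.
#'
#' @param qscores Non-empty numeric vector of per-read quality scores.
#' @return One-row data.frame: `n`, `median`, `q1`, `q3`,
#'   `mean_error_percent`.
#' @export
summarize_qscores <- function(qscores) {
  if (length(qscores) == 0L) stop("no quality scores")
  qs <- stats::quantile(qscores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(qscores), median = qs[2L], q1 = qs[1L], q3 = qs[3L],
             mean_error_percent = mean(qscore_to_error_percent(qscores)))
}

#' Read per-read quality scores from a file
#'
#' Accepts either a plain text file with one per-read mean quality score per
#' line, or a FASTQ file (Phred+33) from which per-read means are computed
#' via [mean_read_qscore()].
#'
#' @param path Input path.
#' @return Numeric vector of per-read mean quality scores.
#' @export
read_qscores_file <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty file: %s", path))
  if (startsWith(first, "@")) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) stop("malformed FASTQ: length not a multiple of 4")
    quals <- lines[seq(4L, length(lines), by = 4L)]
    vapply(quals, function(qq) mean_read_qscore(utf8ToInt(qq) - 33L), 0,
           USE.NAMES = FALSE)
  } else {
    as.numeric(readLines(path))
  }
}
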