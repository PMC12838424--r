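#' Per-position, per-strand modification-fraction tracks
#'
#' A `fraction_track` stores one modified-base fraction in \[0,1\] per covered
#' (position, strand) pair of a genome. Positions not covered are *missing*,
#' which is distinct from a stored 0: nanopore modification callers emit
#' fractions only for the bases their model scores (here, adenines).
#' Internally the track is a pair of dense numeric vectors (one per strand)
#' with `NA` marking missing; all public accessors take 0-based positions.
#'
#' @param genome_name Name of the genome the track belongs to.
#' @param length Genome length in bases.
#' @return An empty `fraction_track`.
#' @export
fraction_track <- function(genome_name, length) {
  stopifnot(is.character(genome_name), length(genome_name) == 1L,
            length >= 0)
  structure(list(genome_name = genome_name, length = as.integer(length),
                 plus = rep(NA_real_, length), minus = rep(NA_real_, length)),
            class = "fraction_track")
}

#' @export
print.fraction_track <- function(x, ...) {
  cat(sprintf("<fraction_track> %s: %s bp, %s covered (+), %s covered (-)\n",
              x$genome_name, format(x$length, big.mark = ","),
              sum(!is.na(x$plus)), sum(!is.na(x$minus))))
  invisible(x)
}

.strand_field <- function(strand) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse(strand == "+", "plus", "minus")
}

#' Set fractions on a track
#' @param track A [fraction_track].
#' @param pos 0-based positions.
#' @param strand `"+"` or `"-"` (scalar or vector).
#' @param value Fractions in \[0,1\].
#' @return The modified track.
#' @export
track_set <- function(track, pos, strand, value) {
  stopifnot(inherits(track, "fraction_track"))
  if (length(pos) == 0L) return(track)
  if (any(pos < 0L | pos >= track$length)) {
    stop(sprintf("position out of range for genome '%s' (length %d)",
                 track$genome_name, track$length))
  }
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("fractions must lie in [0, 1]")
  }
  strand <- rep_len(strand, length(pos))
  for (st in unique(strand)) {
    f <- .strand_field(st)
    sel <- strand == st
    track[[f]][pos[sel] + 1L] <- rep_len(value, length(pos))[sel]
  }
  track
}

#' Get fractions from a track
#' @inheritParams track_set
#' @return Numeric vector; `NA` for missing positions.
#' @export
track_get <- function(track, pos, strand) {
  stopifnot(inherits(track, "fraction_track"))
  strand <- rep_len(strand, length(pos))
  out <- numeric(length(pos))
  for (st in unique(strand)) {
    f <- .strand_field(st)
    sel <- strand == st
    out[sel] <- track[[f]][pos[sel] + 1L]
  }
  out
}

#' Covered positions of a track
#' @param track A [fraction_track].
#' @return A data.frame with columns `pos` (0-based), `strand`, `fraction`,
#'   sorted by position within strand (`+` first).
#' @export
track_covered <- function(track) {
  p <- which(!is.na(track$plus))
  m <- which(!is.na(track$minus))
  data.frame(
    pos = c(p - 1L, m - 1L),
    strand = rep(c("+", "-"), c(length(p), length(m))),
    fraction = c(track$plus[p], track$minus[m]),
    stringsAsFactors = FALSE
  )
}

#' Read a modification-fraction track from a bedGraph file
#'
#' Accepts 4-column bedGraph rows (`name start end value`, 0-based half-open)
#' with an optional 5th strand column; rows lacking a strand are assigned
#' `strand_default`. `track` and comment lines are ignored. Each covered base
#' in `[start, end)` receives the row's value; where rows overlap, the last
#' row wins and a warning is issued.
#'
#' @param path Path to a bedGraph file (tab- or space-separated).
#' @param genome The [genome] the track annotates (for name/bounds checks).
#' @param strand_default Strand assigned to 4-column rows (default `"+"`).
#' @return A [fraction_track].
#' @export
read_track <- function(path, genome, strand_default = "+") {
  stopifnot(inherits(genome, "genome"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|#)", lines)]
  track <- fraction_track(genome$name, genome_length(genome))
  seen_plus <- logical(track$length)
  seen_minus <- logical(track$length)
  n_overlap <- 0L
  for (ln in lines) {
    f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
    if (length(f) < 4L) stop(sprintf("malformed bedGraph row: '%s'", ln))
    if (f[1L] != genome$name) {
      stop(sprintf("track row names '%s' but genome is '%s'", f[1L], genome$name))
    }
    start <- as.integer(f[2L]); end <- as.integer(f[3L])
    value <- as.numeric(f[4L])
    if (is.na(start) || is.na(end) || is.na(value)) {
      stop(sprintf("malformed bedGraph row: '%s'", ln))
    }
    if (start < 0L || end > track$length || start >= end) {
      stop(sprintf("row coordinates [%d, %d) outside genome '%s' (length %d)",
                   start, end, genome$name, track$length))
    }
    if (value < 0 || value > 1) {
      stop(sprintf("fraction %s out of [0, 1] in row '%s'", f[4L], ln))
    }
    strand <- if (length(f) >= 5L) f[5L] else strand_default
    fld <- .strand_field(strand)
    idx <- (start + 1L):end
    seen <- if (strand == "+") seen_plus else seen_minus
    n_overlap <- n_overlap + sum(seen[idx])
    track[[fld]][idx] <- value
    if (strand == "+") seen_plus[idx] <- TRUE else seen_minus[idx] <- TRUE
  }
  if (n_overlap > 0L) {
    warning(sprintf("%d overlapping base assignments in %s; last row wins",
                    n_overlap, path))
  }
  track
}

#' Write a track as 5-column bedGraph
#'
#' One row per covered base, full double precision, so that
#' `read_track(write_track(x))` reproduces the track exactly. Runs of
#' consecutive positions with bitwise-identical values on the same strand are
#' merged into a single half-open interval.
#'
#' @param track A [fraction_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (st in c("+", "-")) {
    v <- track[[.strand_field(st)]]
    pos <- which(!is.na(v))
    if (length(pos) == 0L) next
    # merge runs: same value and consecutive position
    brk <- c(TRUE, diff(pos) != 1L | v[pos[-1L]] != v[pos[-length(pos)]])
    grp <- cumsum(brk)
    starts <- pos[brk] - 1L
    ends <- pos[c(which(brk[-1L]), length(pos))]
    vals <- v[pos[brk]]
    writeLines(sprintf("%s\t%d\t%d\t%.17g\t%s", track$genome_name,
                       starts, ends, vals, st), con)
  }
  invisible(path)
}
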