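#' Genome objects
#'
#' A `genome` is a named nucleotide sequence over A/C/G/T (N permitted on
#' input, never emitted by the simulator) with an optional circular topology.
#' All interval accessors in the package use 0-based, half-open coordinates.
#'
#' @param name Sequence identifier.
#' @param seq Nucleotide string; uppercased on construction.
#' @param circular Logical; circular topology (default `FALSE`).
#' @return An object of class `genome` with fields `name`, `seq`, `circular`.
#' @export
genome <- function(name, seq, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L,
            is.logical(circular), length(circular) == 1L)
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' in sequence '%s' at offset %d (0-based)",
                 substr(seq, bad, bad), name, bad - 1L))
  }
  structure(list(name = name, seq = seq, circular = circular),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp%s\n", x$name, format(nchar(x$seq), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Genome length in bases
#' @param g A [genome] object.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$seq)

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and validated against the A/C/G/T/N alphabet;
#' any other character is an error naming the offending record and 0-based
#' offset. Record names must be unique.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical, applied to all records (default `FALSE`).
#' @return A list of [genome] objects in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop(sprintf("empty FASTA file: %s", path))
  nms <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate record name in %s: %s", path,
                 nms[anyDuplicated(nms)]))
  }
  lapply(seq_along(recs), function(i) {
    genome(nms[i], as.character(recs[[i]]), circular = circular)
  })
}

#' Write genomes to a FASTA file
#' @param genomes A [genome] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# IUPAC alphabet; complement table covers every degenerate code.
.IUPAC_FROM <- "ACGTMRWSYKVHDBN"
.IUPAC_TO   <- "TGCAKYWSRMBDHVN"

#' Reverse complement of a nucleotide string
#'
#' Accepts the full IUPAC alphabet (degeneracy codes complement to their
#' mirrored sets, e.g. `R -> Y`); `reverse_complement()` is an involution.
#' `U` is rejected: the package works on DNA only.
#'
#' @param seq Nucleotide string (possibly empty).
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl(sprintf("[^%s]", .IUPAC_FROM), seq)) {
    bad <- regexpr(sprintf("[^%s]", .IUPAC_FROM), seq)
    stop(sprintf("non-IUPAC character '%s' at offset %d", substr(seq, bad, bad), bad - 1L))
  }
  if (!nzchar(seq)) return(seq)
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

.iupac_sets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
}

#' Match a sequence against an IUPAC degenerate pattern
#'
#' True iff at every position the degeneracy set of the sequence symbol is
#' contained in the degeneracy set of the pattern symbol (so `N` in the
#' pattern matches anything, and `N` in the sequence is matched only by
#' pattern symbols covering all four bases).
#'
#' @param pattern IUPAC string.
#' @param seq Nucleotide string of the same length.
#' @return Logical scalar.
#' @export
iupac_match <- function(pattern, seq) {
  stopifnot(is.character(pattern), is.character(seq),
            length(pattern) == 1L, length(seq) == 1L)
  if (nchar(pattern) != nchar(seq)) {
    stop(sprintf("pattern length %d != sequence length %d",
                 nchar(pattern), nchar(seq)))
  }
  if (!nzchar(pattern)) return(TRUE)
  sets <- .iupac_sets()
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (!all(p %in% names(sets))) stop("non-IUPAC character in pattern")
  if (!all(s %in% names(sets))) stop("non-IUPAC character in sequence")
  all(mapply(function(pc, sc) all(sets[[sc]] %in% sets[[pc]]), p, s))
}
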