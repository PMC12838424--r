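#' Configuration for the synthetic planted-motif generator
#'
#' The generator emulates the downstream view of a nanopore modification
#' caller run on a genome whose adenines are methylated in a fixed sequence
#' context: per-adenine modified fractions on both strands, high at planted
#' motif sites, low at background adenines and everywhere in an unmodified
#' control, with the signal positionally blurred over a few bases because
#' the caller cannot localise a modification more precisely than roughly
#' five bases.
#'
#' @param genome_length Genome size in bases (default 200000).
#' @param gc GC content in \[0,1\] (default 0.5).
#' @param motif Planted recognition motif (default `"ATC"`).
#' @param mod_offset 0-based index of the modified base within the motif
#'   (default 0, the adenine of ATC).
#' @param p_hi_alpha,p_hi_beta Beta shape parameters for planted-site
#'   fractions (default 8, 2: mean 0.8).
#' @param p_bg_alpha,p_bg_beta Beta shapes for background adenines and for
#'   the whole control track (default 1, 19: mean 0.05).
#' @param blur_halfwidth Positional blur half-width in bases (default 2,
#'   i.e. a ~5-base footprint).
#' @param blur_decay Geometric decay of blurred signal per base (default 0.5).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L, gc = 0.5, motif = "ATC",
                       mod_offset = 0L, p_hi_alpha = 8, p_hi_beta = 2,
                       p_bg_alpha = 1, p_bg_beta = 19,
                       blur_halfwidth = 2L, blur_decay = 0.5, seed = 1L) {
  stopifnot(genome_length >= 0, gc >= 0, gc <= 1,
            nchar(motif) >= 1, mod_offset >= 0, mod_offset < nchar(motif),
            p_hi_alpha > 0, p_hi_beta > 0, p_bg_alpha > 0, p_bg_beta > 0,
            blur_halfwidth >= 0, blur_decay >= 0, blur_decay <= 1)
  structure(list(genome_length = as.integer(genome_length), gc = gc,
                 motif = toupper(motif), mod_offset = as.integer(mod_offset),
                 p_hi_alpha = p_hi_alpha, p_hi_beta = p_hi_beta,
                 p_bg_alpha = p_bg_alpha, p_bg_beta = p_bg_beta,
                 blur_halfwidth = as.integer(blur_halfwidth),
                 blur_decay = blur_decay, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome
#'
#' I.i.d. bases with \eqn{P(G)=P(C)=gc/2} and \eqn{P(A)=P(T)=(1-gc)/2}.
#'
#' @param length Genome length in bases.
#' @param gc GC content in \[0,1\].
#' @param seed Integer seed.
#' @param name Genome name (default `"sim"`).
#' @return A [genome].
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L, name = "sim") {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  set.seed(seed)
  if (length == 0L) return(genome(name, ""))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome(name, paste(bases, collapse = ""))
}

# 0-based positions of the modified base for all occurrences of the motif,
# per strand. A minus-strand occurrence is an occurrence of the reverse
# complement on the plus strand; its modified base sits mirrored within the
# footprint.
.planted_positions <- function(g, motif, mod_offset) {
  w <- nchar(motif)
  subj <- Biostrings::DNAString(g$seq)
  plus <- Biostrings::start(Biostrings::matchPattern(motif, subj)) - 1L
  minus_fp <- Biostrings::start(
    Biostrings::matchPattern(reverse_complement(motif), subj)) - 1L
  list(plus = plus + mod_offset,
       minus = minus_fp + (w - 1L - mod_offset))
}

#' Simulate test and control modification-fraction tracks
#'
#' Plants high modified fractions (Beta draws) at the modified base of every
#' motif occurrence on both strands, background-level fractions at every
#' other adenine (strand-resolved: plus-strand A positions on `+`, T
#' positions — adenines of the minus strand — on `-`), then blurs each
#' planted site geometrically over covered same-strand neighbours within
#' `blur_halfwidth` bases (`max(current, f * blur_decay^d)`). The control
#' track draws background fractions at every adenine on both strands.
#' Non-adenine positions are missing in both tracks.
#'
#' @param g A [genome].
#' @param config A [sim_config].
#' @return A list with elements `test` and `control`, both [fraction_track]s,
#'   and `planted` (data.frame of planted modified-base positions and strands).
#' @export
simulate_tracks <- function(g, config) {
  stopifnot(inherits(g, "genome"), inherits(config, "sim_config"))
  L <- genome_length(g)
  if (L == 0L) stop("genome is empty")
  if (config$mod_offset >= nchar(config$motif))
    stop("mod_offset outside motif")
  set.seed(config$seed)

  chars <- strsplit(g$seq, "", fixed = TRUE)[[1L]]
  a_plus <- which(chars == "A")            # 1-based
  a_minus <- which(chars == "T")
  pl <- .planted_positions(g, config$motif, config$mod_offset)
  if (length(pl$plus) + length(pl$minus) == 0L) {
    warning(sprintf("motif %s does not occur in genome '%s'",
                    config$motif, g$name))
  }

  test <- fraction_track(g$name, L)
  control <- fraction_track(g$name, L)

  # background at every strand-resolved adenine
  test$plus[a_plus] <- stats::rbeta(length(a_plus), config$p_bg_alpha, config$p_bg_beta)
  test$minus[a_minus] <- stats::rbeta(length(a_minus), config$p_bg_alpha, config$p_bg_beta)
  # planted draws overwrite the background at motif sites
  f_plus <- stats::rbeta(length(pl$plus), config$p_hi_alpha, config$p_hi_beta)
  f_minus <- stats::rbeta(length(pl$minus), config$p_hi_alpha, config$p_hi_beta)
  test$plus[pl$plus + 1L] <- f_plus
  test$minus[pl$minus + 1L] <- f_minus

  # geometric positional blur around planted sites, covered neighbours only
  blur <- function(vec, centers, f) {
    for (d in seq_len(config$blur_halfwidth)) {
      for (sgn in c(-1L, 1L)) {
        np <- centers + sgn * d
        ok <- np >= 1L & np <= L
        np <- np[ok]
        fd <- f[ok] * config$blur_decay^d
        cov <- !is.na(vec[np])
        vec[np[cov]] <- pmax(vec[np[cov]], fd[cov])
      }
    }
    vec
  }
  test$plus <- blur(test$plus, pl$plus + 1L, f_plus)
  test$minus <- blur(test$minus, pl$minus + 1L, f_minus)

  control$plus[a_plus] <- stats::rbeta(length(a_plus), config$p_bg_alpha, config$p_bg_beta)
  control$minus[a_minus] <- stats::rbeta(length(a_minus), config$p_bg_alpha, config$p_bg_beta)

  planted <- data.frame(
    pos = c(pl$plus, pl$minus),
    strand = rep(c("+", "-"), c(length(pl$plus), length(pl$minus))),
    stringsAsFactors = FALSE
  )
  list(test = test, control = control, planted = planted)
}

#' Simulate per-read mean quality scores
#'
#' Draws truncated-normal per-read mean Phred scores emulating nanopore
#' libraries: native DNA reads centre near Q7.5 (modified bases confuse the
#' basecaller), PCR-amplified reads near Q11.5. Truncation to \[1, 30\] by
#' inverse-CDF sampling.
#'
#' @param n Number of reads.
#' @param library `"native"` or `"pcr"`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_read_qscores <- function(n, library = c("native", "pcr"), seed = 1L) {
  stopifnot(n >= 0)
  library <- match.arg(library)
  mu <- if (library == "native") 7.5 else 11.5
  sigma <- if (library == "native") 1.5 else 2.0
  set.seed(seed)
  if (n == 0L) return(numeric(0))
  lo <- stats::pnorm(1, mu, sigma)
  hi <- stats::pnorm(30, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}

#' Run the generator and write all artefacts to disk
#'
#' Writes `genome.fasta`, `test.bedgraph`, `control.bedgraph` and a
#' `metadata.txt` key-value file recording the full configuration, into
#' `out_dir`.
#'
#' @param config A [sim_config].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the list from [simulate_tracks()] plus the genome.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genome(config$genome_length, config$gc, seed = config$seed)
  sim <- simulate_tracks(g, config)
  write_fasta(g, file.path(out_dir, "genome.fasta"))
  write_track(sim$test, file.path(out_dir, "test.bedgraph"))
  write_track(sim$control, file.path(out_dir, "control.bedgraph"))
  meta <- vapply(names(unclass(config)), function(k)
    sprintf("%s: %s", k, format(config[[k]], digits = 15)), "")
  writeLines(meta, file.path(out_dir, "metadata.txt"))
  invisible(c(list(genome = g), sim))
}
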