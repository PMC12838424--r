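# Shared fixtures. The default simulation (200 kb genome, planted ATC) is
# computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = seed)
    g <- simulate_genome(cfg$genome_length, cfg$gc, seed = cfg$seed)
    sim <- simulate_tracks(g, cfg)
    .fixture_env[[key]] <- c(list(genome = g, config = cfg), sim)
  }
  .fixture_env[[key]]
}

# uniform random A/C/G/T string
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sequences of length `len` with `site` planted at a random offset in
# otherwise uniform-random flanks
planted_seqs <- function(n, len, site, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    off <- sample.int(len - nchar(site) + 1L, 1L)
    s <- strsplit(random_seq(len), "", fixed = TRUE)[[1L]]
    s[off:(off + nchar(site) - 1L)] <- strsplit(site, "", fixed = TRUE)[[1L]]
    paste(s, collapse = "")
  }, "")
}

# planted sequences containing `site` exactly once and its reverse
# complement not at all, so the planted ground truth is unambiguous
planted_seqs_clean <- function(n, len, site, seed) {
  set.seed(seed)
  rc <- reverse_complement(site)
  vapply(seq_len(n), function(i) {
    repeat {
      off <- sample.int(len - nchar(site) + 1L, 1L)
      s <- strsplit(random_seq(len), "", fixed = TRUE)[[1L]]
      s[off:(off + nchar(site) - 1L)] <- strsplit(site, "", fixed = TRUE)[[1L]]
      out <- paste(s, collapse = "")
      n_fwd <- length(gregexpr(site, out, fixed = TRUE)[[1L]]) -
        (gregexpr(site, out, fixed = TRUE)[[1L]][1L] == -1L)
      has_rc <- grepl(rc, out, fixed = TRUE)
      if (n_fwd == 1L && !has_rc) return(out)
    }
  }, "")
}

# independent greedy re-implementation used as the top-window oracle on
# small genomes: enumerate all starts, compute scores by direct summation,
# pick non-overlapping windows in (score desc, start asc) order
oracle_top_windows <- function(track, g, width, k) {
  L <- genome_length(g)
  starts <- 0:(L - width)
  score1 <- function(s) {
    idx <- (s + 1L):(s + width)
    round(sum(track$plus[idx], na.rm = TRUE) + sum(track$minus[idx], na.rm = TRUE), 9L)
  }
  scores <- vapply(starts, score1, 0)
  ord <- order(-scores, starts)
  chosen <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  taken <- logical(L)
  for (i in ord) {
    if (scores[i] <= 0) next
    span <- (starts[i] + 1L):(starts[i] + width)
    if (any(taken[span])) next
    taken[span] <- TRUE
    chosen <- rbind(chosen, data.frame(start = starts[i],
                                       end = starts[i] + width,
                                       score = scores[i]))
    if (nrow(chosen) == k) break
  }
  chosen
}
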