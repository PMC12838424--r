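#' Motif model: PWM + ZOOPS occurrence prior + background
#'
#' The ZOOPS ("zero or one occurrence per sequence") model assumes each input
#' sequence contains at most one motif site; `lam` is the prior probability
#' that a sequence contains a site at all. The PWM rows give per-position
#' base probabilities in the fixed order A, C, G, T.
#'
#' @param pwm width x 4 matrix of probabilities (columns A, C, G, T; each row
#'   sums to 1).
#' @param background Length-4 probability vector (A, C, G, T).
#' @param lam ZOOPS site prior in \[0,1\].
#' @return A `motif_model`.
#' @export
motif_model <- function(pwm, background, lam) {
  pwm <- as.matrix(pwm)
  stopifnot(ncol(pwm) == 4L, nrow(pwm) >= 1L,
            length(background) == 4L, lam >= 0, lam <= 1)
  if (any(abs(rowSums(pwm) - 1) > 1e-9)) stop("pwm rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  colnames(pwm) <- c("A", "C", "G", "T")
  structure(list(width = nrow(pwm), pwm = pwm,
                 background = stats::setNames(background, c("A", "C", "G", "T")),
                 lam = lam),
            class = "motif_model")
}

.BASES <- c("A", "C", "G", "T")

.encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], .BASES)
  if (anyNA(v)) stop(sprintf("sequence '%s' contains a base outside A/C/G/T", s))
  v
}

# Site-base index matrix for one sequence: one row per candidate site state
# (all + starts, then all - starts), one column per motif position. Minus
# states read the complement of the window right to left.
.state_rows <- function(enc, width, revcomp) {
  m <- length(enc) - width + 1L
  plus <- sapply(seq_len(width), function(i) enc[(0:(m - 1L)) + i])
  plus <- matrix(plus, nrow = m)
  if (!revcomp) return(plus)
  minus <- sapply(seq_len(width), function(i) 5L - enc[(0:(m - 1L)) + (width - i + 1L)])
  rbind(plus, matrix(minus, nrow = m))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Observed-data log-likelihood of sequences under a ZOOPS motif model
#'
#' For each sequence the likelihood mixes "no site" (all background, weight
#' `1 - lam`) with a site at each possible (start, strand), each with weight
#' `lam / n_states`.
#'
#' @param model A [motif_model].
#' @param seqs Character vector of A/C/G/T sequences, all at least `width` long.
#' @param revcomp Allow sites on either strand (default `TRUE`).
#' @return Total log-likelihood (natural log).
#' @export
score_motif <- function(model, seqs, revcomp = TRUE) {
  stopifnot(inherits(model, "motif_model"), length(seqs) >= 1L)
  w <- model$width
  lbg <- log(model$background)
  lpwm_ratio <- log(model$pwm) - matrix(lbg, nrow = w, ncol = 4L, byrow = TRUE)
  lam <- min(max(model$lam, 1e-12), 1 - 1e-12)
  total <- 0
  for (s in seqs) {
    enc <- .encode_seq(s)
    if (length(enc) < w) stop("sequence shorter than motif width")
    idx <- .state_rows(enc, w, revcomp)
    sc <- rowSums(matrix(lpwm_ratio[cbind(rep(seq_len(w), each = nrow(idx)),
                                          as.vector(idx))], nrow = nrow(idx)))
    lw <- c(log1p(-lam), log(lam) - log(nrow(idx)) + sc)
    total <- total + sum(lbg[enc]) + .logsumexp(lw)
  }
  total
}

#' De novo ZOOPS motif discovery by expectation-maximisation
#'
#' Fits the two-strand ZOOPS model to a set of sequences. The E-step computes
#' each sequence's posterior over \{no site\} and all (start, strand) site
#' placements; the M-step re-estimates the PWM (with a pseudocount of 0.25
#' per base) and the site prior `lam`. Iteration stops when the
#' log-likelihood gain drops below `tol` or after `max_iter` iterations;
#' `n_starts` seeded initialisations (PWM seeded from a randomly chosen
#' width-`width` subsequence) are run and the best final log-likelihood is
#' returned. The background is fixed at the 0-order base composition of the
#' input. Within a start the log-likelihood is non-decreasing (standard EM
#' guarantee); the trace is returned for inspection.
#'
#' @param seqs Character vector of A/C/G/T sequences.
#' @param width Motif width (>= 2, <= shortest sequence).
#' @param revcomp Search both strands (default `TRUE`).
#' @param n_starts Number of random restarts (default 10).
#' @param seed Integer seed for the restarts.
#' @param max_iter,tol EM stopping rule (defaults 500, 1e-6).
#' @return A `motif_result`: list with `model` ([motif_model]), `assignments`
#'   (data.frame, per sequence: `site_start` 0-based or `NA`, `strand`),
#'   `loglik`, `n_rc` (number of minus-strand assignments), `loglik_trace`
#'   (best start), `n_iter`.
#' @export
discover_motif <- function(seqs, width, revcomp = TRUE, n_starts = 10L,
                           seed = 1L, max_iter = 500L, tol = 1e-6) {
  if (length(seqs) == 0L) stop("no input sequences")
  stopifnot(width >= 2L)
  if (min(nchar(seqs)) < width) {
    stop(sprintf("motif width %d exceeds shortest sequence (%d bp)",
                 width, min(nchar(seqs))))
  }
  encs <- lapply(seqs, .encode_seq)
  n <- length(encs)

  # fixed 0-order background from the input (1-count smoothing avoids log 0)
  counts <- tabulate(unlist(encs), 4L) + 1
  bg <- counts / sum(counts)
  lbg <- log(bg)

  # stack all site states of all sequences into one matrix
  idx_list <- lapply(encs, .state_rows, width = width, revcomp = revcomp)
  n_states <- vapply(idx_list, nrow, 0L)
  IDX <- do.call(rbind, idx_list)
  seq_of_row <- rep(seq_len(n), n_states)
  rows_of_seq <- split(seq_len(nrow(IDX)), seq_of_row)
  log_nstates <- log(n_states)
  lbg_seq <- vapply(encs, function(e) sum(lbg[e]), 0)
  idx_flat <- cbind(rep(seq_len(width), each = nrow(IDX)), as.vector(IDX))

  run_start <- function(start_id) {
    set.seed(seed + start_id - 1L)
    si <- sample.int(n, 1L)
    off <- sample.int(length(encs[[si]]) - width + 1L, 1L)
    seed_bases <- encs[[si]][off:(off + width - 1L)]
    pwm <- matrix(0.1, nrow = width, ncol = 4L)
    pwm[cbind(seq_len(width), seed_bases)] <- 0.7
    lam <- 0.5
    trace <- numeric(0)
    g0 <- numeric(n); gam <- numeric(nrow(IDX))
    for (it in seq_len(max_iter)) {
      lam <- min(max(lam, 1e-12), 1 - 1e-12)
      lratio <- log(pwm) - matrix(lbg, nrow = width, ncol = 4L, byrow = TRUE)
      sc <- rowSums(matrix(lratio[idx_flat], nrow = nrow(IDX)))
      lw <- log(lam) - log_nstates[seq_of_row] + sc
      ll <- 0
      for (s in seq_len(n)) {
        r <- rows_of_seq[[s]]
        den <- .logsumexp(c(log1p(-lam), lw[r]))
        g0[s] <- exp(log1p(-lam) - den)
        gam[r] <- exp(lw[r] - den)
        ll <- ll + lbg_seq[s] + den
      }
      trace <- c(trace, ll)
      if (it > 1L && trace[it] - trace[it - 1L] < tol) break
      # M-step
      cnt <- matrix(0.25, nrow = width, ncol = 4L)
      for (i in seq_len(width)) {
        add <- rowsum(gam, IDX[, i])
        cnt[i, as.integer(rownames(add))] <- cnt[i, as.integer(rownames(add))] + add
      }
      pwm <- cnt / rowSums(cnt)
      lam <- mean(1 - g0)
    }
    list(pwm = pwm, lam = lam, loglik = trace[length(trace)],
         trace = trace, g0 = g0, gam = gam)
  }

  best <- NULL
  for (t in seq_len(max(1L, n_starts))) {
    res <- run_start(t)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  # The two-strand objective is invariant under reverse-complementing the
  # model and swapping every site's strand, so which orientation EM lands in
  # depends only on the initialisation. Report the lexicographically smaller
  # consensus orientation for determinism.
  flip <- FALSE
  if (revcomp) {
    cons_now <- paste(.BASES[apply(best$pwm, 1L, which.max)], collapse = "")
    flip <- reverse_complement(cons_now) < cons_now
    if (flip) best$pwm <- best$pwm[rev(seq_len(width)), 4:1, drop = FALSE]
  }

  # maximum-posterior assignments; ties resolved to the earliest state in
  # the fixed order (no site, then + starts ascending, then - starts)
  site_start <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  for (s in seq_len(n)) {
    r <- rows_of_seq[[s]]
    post <- c(best$g0[s], best$gam[r])
    j <- which.max(post)
    if (j > 1L) {
      st <- j - 1L
      m <- length(encs[[s]]) - width + 1L
      if (revcomp && st > m) {
        site_start[s] <- st - m - 1L
        strand[s] <- "-"
      } else {
        site_start[s] <- st - 1L
        strand[s] <- "+"
      }
    }
  }
  # flipping the model orientation swaps the strand of every site while the
  # footprint (and hence site_start) is unchanged
  if (flip) strand <- chartr("+-", "-+", strand)
  model <- motif_model(best$pwm, bg, best$lam)
  structure(list(model = model,
                 assignments = data.frame(site_start = site_start,
                                          strand = strand,
                                          stringsAsFactors = FALSE),
                 loglik = best$loglik,
                 n_rc = sum(strand == "-", na.rm = TRUE),
                 loglik_trace = best$trace,
                 n_iter = length(best$trace)),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf("<motif_result> width %d, consensus %s, lam %.3f, loglik %.3f, %d/%d sites on -\n",
              x$model$width, consensus(x$model), x$model$lam, x$loglik,
              x$n_rc, sum(!is.na(x$assignments$site_start))))
  invisible(x)
}

#' Consensus sequence of a motif model
#'
#' Per-position argmax base; ties broken in the fixed order A < C < G < T.
#'
#' @param model A [motif_model].
#' @return Nucleotide string of length `width`.
#' @export
consensus <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  paste(.BASES[apply(model$pwm, 1L, which.max)], collapse = "")
}

#' Per-position information content of a motif model (bits)
#'
#' \eqn{IC_j = \sum_b p_{jb} \log_2(p_{jb}/bg_b)} with \eqn{0 \log 0 = 0};
#' the per-column heights of a sequence logo relative to the background.
#'
#' @param model A [motif_model].
#' @return Numeric vector, one value per motif position.
#' @export
information_content <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  apply(model$pwm, 1L, function(p) {
    terms <- ifelse(p == 0, 0, p * log2(p / model$background))
    sum(terms)
  })
}

#' Count sequences containing a consensus (optionally on either strand)
#'
#' @param seqs Character vector of sequences.
#' @param consensus Non-empty consensus string.
#' @param revcomp Also accept the reverse complement as a match.
#' @return Integer count of sequences containing the consensus (or, if
#'   `revcomp`, its reverse complement) as a substring.
#' @export
count_matching <- function(seqs, consensus, revcomp = TRUE) {
  stopifnot(nzchar(consensus))
  if (length(seqs) == 0L) return(0L)
  hit <- grepl(consensus, seqs, fixed = TRUE)
  if (revcomp) hit <- hit | grepl(reverse_complement(consensus), seqs, fixed = TRUE)
  sum(hit)
}

#' Scan candidate motif widths and rank fitted models by BIC
#'
#' Runs [discover_motif()] at each width and ranks the fitted models by
#' Bayesian information criterion, `BIC = -2 loglik + p log(n)` with
#' `p = 3 width + 1` free parameters (3 per PWM column plus `lam`), so wider
#' motifs must earn their extra columns.
#'
#' @inheritParams discover_motif
#' @param widths Integer vector of widths to try (default `3:8`).
#' @return List with `results` (per width), `summary` (data.frame: width,
#'   loglik, bic, consensus) and `best` (the lowest-BIC `motif_result`).
#' @export
scan_motif_widths <- function(seqs, widths = 3:8, revcomp = TRUE,
                              n_starts = 10L, seed = 1L) {
  widths <- widths[widths <= min(nchar(seqs))]
  if (length(widths) == 0L) stop("no candidate width fits the sequences")
  results <- lapply(widths, function(w)
    discover_motif(seqs, w, revcomp = revcomp, n_starts = n_starts, seed = seed))
  n <- length(seqs)
  bic <- vapply(seq_along(widths), function(i)
    -2 * results[[i]]$loglik + (3 * widths[i] + 1) * log(n), 0)
  summary <- data.frame(width = widths,
                        loglik = vapply(results, `[[`, 0, "loglik"),
                        bic = bic,
                        consensus = vapply(results, function(r) consensus(r$model), ""),
                        stringsAsFactors = FALSE)
  list(results = results, summary = summary,
       best = results[[which.min(bic)]])
}

#' Serialize a motif result to JSON
#' @param result A `motif_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_json <- function(result, path) {
  obj <- list(width = result$model$width,
              consensus = consensus(result$model),
              pwm = unname(apply(result$model$pwm, 1L, as.list)),
              background = as.list(result$model$background),
              lam = result$model$lam,
              loglik = result$loglik,
              n_rc = result$n_rc,
              assignments = result$assignments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}
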