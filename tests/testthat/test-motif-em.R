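# Exhaustive consensus oracle: score every width-3 word by the number of
# sequences containing it (or, optionally, its reverse complement) exactly.
oracle_best_3mer <- function(seqs, revcomp = TRUE) {
  words <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             c("A", "C", "G", "T")), 1L,
                 function(r) paste(rev(r), collapse = ""))
  hits <- vapply(words, function(w) count_matching(seqs, w, revcomp), 0L)
  words[which.max(hits)]
}

test_that("EM recovers a planted 3-mer and agrees with the exhaustive oracle", {
  seqs <- planted_seqs(50L, 10L, "ATC", seed = 101L)
  res <- discover_motif(seqs, 3L, revcomp = TRUE, n_starts = 10L, seed = 101L)
  expect_identical(consensus(res$model), "ATC")
  expect_identical(oracle_best_3mer(seqs), "ATC")
})

test_that("identical repeat sequences drive lam to 1 with all sites on plus", {
  seqs <- rep("ATCATCATCA", 20L)
  res <- discover_motif(seqs, 3L, revcomp = TRUE, n_starts = 5L, seed = 1L)
  expect_lt(abs(res$model$lam - 1), 1e-3)
  # a periodic repeat makes the likelihood exactly invariant under the
  # one-step rotation ATC -> TCA (both have three exact sites per sequence)
  expect_true(consensus(res$model) %in% c("ATC", "TCA"))
  expect_true(all(res$assignments$strand == "+"))
  expect_identical(res$n_rc, 0L)
})

test_that("two-strand search recovers the planted strand split", {
  seqs <- c(planted_seqs_clean(43L, 12L, "ATC", seed = 303L),
            planted_seqs_clean(43L, 12L, "GAT", seed = 404L))
  res <- discover_motif(seqs, 3L, revcomp = TRUE, n_starts = 10L, seed = 202L)
  expect_identical(consensus(res$model), "ATC")
  planted_minus <- 43L   # GAT carriers hold the motif on their minus strand
  expect_lt(abs(res$n_rc - planted_minus), 0.1 * planted_minus + 1)
})

test_that("log-likelihood is monotone within a start on every fixture", {
  fixtures <- list(
    planted_seqs(30L, 10L, "ATC", seed = 1L),
    planted_seqs(20L, 8L, "GGC", seed = 2L),
    rep("ATCATCATCA", 10L),
    planted_seqs(15L, 12L, "TTAA", seed = 3L)
  )
  for (seqs in fixtures) {
    for (w in c(3L, 4L)) {
      res <- discover_motif(seqs, w, revcomp = TRUE, n_starts = 3L, seed = 9L)
      expect_true(all(diff(res$loglik_trace) >= -1e-9))
    }
  }
})

test_that("PWM rows, background and lam stay simplex-valued after fitting", {
  seqs <- planted_seqs(25L, 10L, "ATC", seed = 55L)
  res <- discover_motif(seqs, 4L, revcomp = TRUE, n_starts = 5L, seed = 55L)
  expect_true(all(abs(rowSums(res$model$pwm) - 1) < 1e-9))
  expect_true(all(res$model$pwm > 0))
  expect_lt(abs(sum(res$model$background) - 1), 1e-9)
  expect_true(res$model$lam >= 0 && res$model$lam <= 1)
})

test_that("EM finds the optimal hard assignment on a high-signal tiny fixture", {
  # 4 sequences of length 6 with an unambiguous planted ATC; the oracle
  # enumerates every hard assignment (none or (start, strand) per sequence)
  # and scores its complete-data profile log-likelihood: model parameters
  # implied by the assignment (pseudocount 0.25, lam = share assigned,
  # background = input composition), sites scored under the PWM, the rest
  # and unassigned sequences under the background
  seqs <- c("GGATCG", "CATCGG", "ATCGGC", "GGGATC")
  width <- 3L
  m <- nchar(seqs[1L]) - width + 1L
  states <- c(list(NULL), unlist(lapply(0:(m - 1L), function(j)
    list(c(j, 1L), c(j, 2L))), recursive = FALSE))
  counts <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                         levels = c("A", "C", "G", "T"))) + 1
  bg <- as.numeric(counts / sum(counts))
  site_of <- function(s, st) {
    win <- substr(s, st[1L] + 1L, st[1L] + width)
    if (st[2L] == 2L) win <- reverse_complement(win)
    strsplit(win, "")[[1L]]
  }
  complete_ll <- function(assign_list) {
    cnt <- matrix(0.25, width, 4L)
    n_assigned <- 0L
    for (i in seq_along(seqs)) {
      st <- assign_list[[i]]
      if (is.null(st)) next
      n_assigned <- n_assigned + 1L
      b <- match(site_of(seqs[i], st), c("A", "C", "G", "T"))
      cnt[cbind(seq_len(width), b)] <- cnt[cbind(seq_len(width), b)] + 1
    }
    lam <- min(max(n_assigned / length(seqs), 1e-12), 1 - 1e-12)
    pwm <- cnt / rowSums(cnt)
    ll <- 0
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1L]]
      ll <- ll + sum(log(bg[match(ch, c("A", "C", "G", "T"))]))
      st <- assign_list[[i]]
      if (is.null(st)) {
        ll <- ll + log1p(-lam)
      } else {
        b <- match(site_of(seqs[i], st), c("A", "C", "G", "T"))
        bwin <- match(ch[(st[1L] + 1L):(st[1L] + width)], c("A", "C", "G", "T"))
        ll <- ll + log(lam) - log(2 * m) +
          sum(log(pwm[cbind(seq_len(width), b)])) - sum(log(bg[bwin]))
      }
    }
    ll
  }
  best_ll <- -Inf
  grid <- expand.grid(rep(list(seq_along(states)), length(seqs)))
  for (r in seq_len(nrow(grid))) {
    best_ll <- max(best_ll, complete_ll(lapply(as.integer(grid[r, ]),
                                               function(j) states[[j]])))
  }

  res <- discover_motif(seqs, width, revcomp = TRUE, n_starts = 10L, seed = 3L)
  em_assign <- lapply(seq_along(seqs), function(i) {
    st <- res$assignments$site_start[i]
    if (is.na(st)) NULL else c(st, if (res$assignments$strand[i] == "+") 1L else 2L)
  })
  expect_equal(complete_ll(em_assign), best_ll, tolerance = 1e-6)
})

test_that("reverse-complementing all inputs preserves likelihood and mirrors sites", {
  seqs <- planted_seqs_clean(20L, 10L, "ATC", seed = 77L)
  rc_seqs <- vapply(seqs, reverse_complement, "", USE.NAMES = FALSE)
  a <- discover_motif(seqs, 3L, revcomp = TRUE, n_starts = 8L, seed = 7L)
  b <- discover_motif(rc_seqs, 3L, revcomp = TRUE, n_starts = 8L, seed = 7L)
  expect_lt(abs(a$loglik - b$loglik), 1e-6)
  expect_identical(consensus(b$model), consensus(a$model))
  n_sites_a <- sum(!is.na(a$assignments$site_start))
  n_sites_b <- sum(!is.na(b$assignments$site_start))
  expect_identical(n_sites_a, n_sites_b)
  # strand labels swap and footprints mirror
  expect_identical(a$n_rc, n_sites_b - b$n_rc)
  mirrored <- 10L - 3L - b$assignments$site_start
  expect_identical(a$assignments$site_start, mirrored)
})

test_that("degenerate inputs are rejected", {
  expect_error(discover_motif(character(0), 3L), "no input")
  expect_error(discover_motif(c("ATCG", "AT"), 3L), "exceeds shortest")
  expect_error(discover_motif("ATNG", 3L), "outside A/C/G/T")
})

test_that("consensus takes the per-position argmax with A<C<G<T ties", {
  pwm <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 1, 0, 0))
  m <- motif_model(pwm, rep(0.25, 4L), 0.5)
  expect_identical(consensus(m), "ATC")
  m2 <- motif_model(matrix(0.25, 1L, 4L), rep(0.25, 4L), 0.5)
  expect_identical(consensus(m2), "A")
})

test_that("information content matches closed forms", {
  bg <- rep(0.25, 4L)
  m <- motif_model(rbind(c(0.25, 0.25, 0.25, 0.25),
                         c(1, 0, 0, 0),
                         c(0.5, 0.5, 0, 0)), bg, 0.5)
  expect_equal(information_content(m), c(0, 2, 1))
})

test_that("count_matching checks substrings on both strands", {
  expect_identical(count_matching(c("GGATCG", "CCGATC", "TTTTT"), "ATC", TRUE), 2L)
  expect_identical(count_matching(character(0), "ATC", TRUE), 0L)
  expect_identical(count_matching("GATGAT", "ATC", TRUE), 1L)
  expect_identical(count_matching("GATGAT", "ATC", FALSE), 0L)
})

test_that("width scan ranks the true width best on planted data by BIC", {
  seqs <- planted_seqs(60L, 10L, "ATC", seed = 88L)
  scan <- scan_motif_widths(seqs, widths = 3:6, n_starts = 5L, seed = 88L)
  expect_identical(scan$best$model$width, 3L)
  expect_identical(consensus(scan$best$model), "ATC")
})

test_that("motif results serialize to JSON and read back consistently", {
  seqs <- planted_seqs(10L, 8L, "ATC", seed = 5L)
  res <- discover_motif(seqs, 3L, n_starts = 3L, seed = 5L)
  p <- withr::local_tempfile(fileext = ".json")
  write_motif_json(res, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_identical(back$consensus, consensus(res$model))
  expect_equal(back$lam, res$model$lam)
  expect_equal(back$loglik, res$loglik)
})
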