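test_that("scan_sites reports all occurrences, strands and palindromes", {
  g <- genome("g", "GGATCC")
  s <- scan_sites(g, "GATC", both_strands = TRUE)
  expect_identical(s$start, c(1L, 1L))
  expect_setequal(s$strand, c("+", "-"))

  expect_identical(nrow(scan_sites(genome("g", "AAAA"), "ATC")), 0L)

  s <- scan_sites(genome("g", "ATCATC"), "ATC", both_strands = FALSE)
  expect_identical(s$start, c(0L, 3L))
  expect_identical(s$strand, c("+", "+"))

  # IUPAC degeneracy and overlapping matches
  s <- scan_sites(genome("g", "GGATCAAA"), "NNATCNN", both_strands = FALSE)
  expect_identical(s$start, 0L)
  s <- scan_sites(genome("g", "AAAA"), "AA", both_strands = FALSE)
  expect_identical(s$start, c(0L, 1L, 2L))

  # footprints containing N never match
  s <- scan_sites(genome("g", "ATNATC"), "ATC", both_strands = FALSE)
  expect_identical(s$start, 3L)
})

test_that("motif mean fraction averages the modified base across both strands", {
  g <- genome("g", "CATCGATG")   # ATC at 1 (+); GAT at 4 => ATC at 4 (-)
  tr <- fraction_track("g", 8L)
  tr <- track_set(tr, 1L, "+", 0.8)   # A of plus-strand ATC
  tr <- track_set(tr, 6L, "-", 0.4)   # A of minus-strand ATC (plus-T at 6)
  st <- motif_mean_fraction(g, tr, "ATC", 0L)
  expect_identical(st$n_loci, 2L)
  expect_equal(st$mean_fraction, 0.6)

  # uniform track at every adenine gives the uniform value
  chars <- strsplit(g$seq, "")[[1L]]
  tru <- fraction_track("g", 8L)
  tru <- track_set(tru, which(chars == "A") - 1L, "+", 0.3)
  tru <- track_set(tru, which(chars == "T") - 1L, "-", 0.3)
  expect_equal(motif_mean_fraction(g, tru, "ATC", 0L)$mean_fraction, 0.3)

  # absent pattern: zero loci, NA mean, warning
  expect_warning(st0 <- motif_mean_fraction(g, tr, "CCCCC", 0L), "no occurrence")
  expect_identical(st0$n_loci, 0L)
  expect_true(is.na(st0$mean_fraction))
})

test_that("single-base pattern 'A' recovers the track-wide adenine mean", {
  set.seed(23)
  g <- genome("g", random_seq(500))
  sim <- simulate_tracks(g, sim_config(seed = 23L))
  st <- motif_mean_fraction(g, sim$test, "A", 0L)
  vals <- track_covered(sim$test)$fraction
  expect_identical(st$n_loci, length(vals))
  expect_equal(st$mean_fraction, mean(vals))
})

test_that("the planted motif far outscores a background motif", {
  sim <- default_sim()
  atc <- motif_mean_fraction(sim$genome, sim$test, "ATC", 0L)
  acc <- motif_mean_fraction(sim$genome, sim$test, "ACC", 0L)
  expect_gt(atc$mean_fraction - acc$mean_fraction, 0.5)
})

test_that("extension ladder: d=0 equals the bare core and rows partition loci", {
  sim <- default_sim()
  g <- sim$genome
  lad <- extension_ladder(g, sim$test, "ATC", 0L, max_ext = 0L)
  expect_identical(nrow(lad), 1L)
  expect_equal(lad$mean_fraction, motif_mean_fraction(g, sim$test, "ATC", 0L)$mean_fraction)

  # partition identity away from genome ends: pad so no core occurrence sits
  # within max_ext of a boundary
  set.seed(29)
  gp <- genome("g", paste0("CCC", random_seq(2000), "CCC"))
  tr <- simulate_tracks(gp, sim_config(seed = 29L))$test
  lad <- extension_ladder(gp, tr, "ATC", 0L, max_ext = 3L)
  n_core <- lad$n_loci[lad$direction == "core"]
  for (d in 1:3) {
    for (dir in c("up", "down")) {
      expect_identical(sum(lad$n_loci[lad$direction == dir & lad$distance == d]),
                       n_core)
    }
  }
})

test_that("context-free planting leaves the upstream d=1 rows flat", {
  sim <- default_sim()
  lad <- extension_ladder(sim$genome, sim$test, "ATC", 0L, max_ext = 1L)
  up <- lad$mean_fraction[lad$direction == "up" & lad$distance == 1L]
  expect_identical(length(up), 4L)
  expect_lt(max(up) - min(up), 0.05)
})

test_that("planting only GATC shows up as an upstream-G preference", {
  cfg <- sim_config(genome_length = 50000L, motif = "GATC", mod_offset = 1L,
                    seed = 37L)
  g <- simulate_genome(cfg$genome_length, cfg$gc, seed = cfg$seed)
  sim <- simulate_tracks(g, cfg)
  lad <- extension_ladder(g, sim$test, "ATC", 0L, max_ext = 1L)
  up <- lad[lad$direction == "up" & lad$distance == 1L, ]
  expect_gte(up$mean_fraction[up$base == "G"], 0.7)
  expect_true(all(up$mean_fraction[up$base != "G"] <= 0.1))
})

test_that("DpnI digestion follows the methylation rules", {
  g <- genome("g", "AAGATCAA")
  dpni <- dpni_profile()
  full <- data.frame(start = c(2L, 2L), strand = c("+", "-"),
                     stringsAsFactors = FALSE)
  expect_identical(digest(g, dpni, full), c(4L, 4L))
  expect_identical(digest(g, dpni, NULL), 8L)
  # hemimethylated GATC (one strand only) does not cut
  hemi <- data.frame(start = 2L, strand = "+", stringsAsFactors = FALSE)
  expect_identical(digest(g, dpni, hemi), 8L)

  # circular genome with one methylated site: one fragment spanning the join
  gc <- genome("g", paste0("AAGATCAA", strrep("C", 12)), circular = TRUE)
  expect_identical(digest(gc, dpni, full), 20L)

  # without the methylation requirement every site cuts
  sau <- enzyme_profile("Sau3AI-like", "GATC", cut_offset = 0L,
                        requires_methylation = FALSE, methyl_offset = 1L)
  g2 <- genome("g", "AAGATCAAGATCAA")
  expect_identical(digest(g2, sau, NULL), c(2L, 6L, 6L))
})

test_that("secondary sites cut on single-strand methylation only when enabled", {
  g <- genome("g", "AACATCAA")   # CATC at 2, no GATC
  dpni <- dpni_profile()
  meth <- data.frame(start = 2L, strand = "+", stringsAsFactors = FALSE)
  expect_identical(digest(g, dpni, meth, include_secondary = FALSE), 8L)
  expect_identical(digest(g, dpni, meth, include_secondary = TRUE), c(4L, 4L))
})

test_that("fragment lengths always sum to the genome length", {
  set.seed(41)
  dpni <- dpni_profile()
  for (i in 1:1000) {
    L <- sample(20:300, 1L)
    g <- genome("g", random_seq(L), circular = sample(c(TRUE, FALSE), 1L))
    sites <- scan_sites(g, "GATC", both_strands = TRUE)
    meth <- sites[stats::runif(nrow(sites)) < 0.7, , drop = FALSE]
    fr <- digest(g, dpni, meth, include_secondary = sample(c(TRUE, FALSE), 1L))
    expect_identical(sum(fr), L)
  }
})

test_that("methylated_sites_from_track thresholds the modified-base fraction", {
  g <- genome("g", "AAGATCAAGATCAA")
  tr <- fraction_track("g", 14L)
  # first GATC fully methylated, second only on plus
  tr <- track_set(tr, c(3L, 9L), "+", 0.9)
  tr <- track_set(tr, c(4L), "-", 0.8)
  ms <- methylated_sites_from_track(g, tr, "GATC", 1L, threshold = 0.5)
  expect_identical(ms$start, c(2L, 2L, 8L))
  fr <- digest(g, dpni_profile(), ms)
  expect_identical(fr, c(4L, 10L))
})
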