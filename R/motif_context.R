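#' Scan a genome for all occurrences of an IUPAC pattern
#'
#' Plus-strand matches are reported directly; minus-strand matches are
#' occurrences of the reverse complement on the plus strand, reported with
#' the start of their plus-strand footprint and strand `"-"`. Overlapping
#' matches are all reported, and a self-reverse-complementary (palindromic)
#' pattern yields one record per strand per locus. Footprints containing `N`
#' never match (an unknown base is never a modification site).
#'
#' @param g A [genome].
#' @param pattern IUPAC pattern string.
#' @param both_strands Also scan the minus strand (default `TRUE`).
#' @return A data.frame with columns `start` (0-based footprint start) and
#'   `strand`.
#' @export
scan_sites <- function(g, pattern, both_strands = TRUE) {
  stopifnot(inherits(g, "genome"), nzchar(pattern))
  pattern <- toupper(pattern)
  if (nchar(pattern) > genome_length(g)) stop("pattern longer than genome")
  subj <- Biostrings::DNAString(g$seq)
  fixed <- c(pattern = FALSE, subject = TRUE)
  scan1 <- function(pat) {
    st <- Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = fixed)) - 1L
    if (length(st) == 0L) return(st)
    # drop footprints containing N
    keep <- !vapply(st, function(s)
      grepl("N", substr(g$seq, s + 1L, s + nchar(pat)), fixed = TRUE), TRUE)
    st[keep]
  }
  plus <- scan1(pattern)
  out <- data.frame(start = plus, strand = rep("+", length(plus)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    minus <- scan1(reverse_complement(pattern))
    out <- rbind(out, data.frame(start = minus,
                                 strand = rep("-", length(minus)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand, method = "radix"), , drop = FALSE]
}

# 0-based genome position of the modified base for each site record
.mod_positions <- function(sites, pattern_len, mod_offset) {
  ifelse(sites$strand == "+",
         sites$start + mod_offset,
         sites$start + (pattern_len - 1L - mod_offset))
}

#' Mean modified fraction across all occurrences of a motif
#'
#' Averages the track fraction at the modified base over every occurrence of
#' the pattern on both strands (minus-strand offsets are mapped through the
#' footprint); a missing fraction counts as 0. A palindromic locus
#' contributes one observation per strand, since each strand's adenine is a
#' distinct modifiable base.
#'
#' @param g A [genome].
#' @param track A [fraction_track].
#' @param pattern IUPAC pattern.
#' @param mod_offset 0-based index of the modified base within the pattern.
#' @return One-row data.frame: `pattern`, `mod_offset`, `n_loci`,
#'   `mean_fraction` (`NA` with a warning when no locus matches).
#' @export
motif_mean_fraction <- function(g, track, pattern, mod_offset = 0L) {
  stopifnot(mod_offset >= 0L, mod_offset < nchar(pattern))
  sites <- scan_sites(g, pattern, both_strands = TRUE)
  if (nrow(sites) == 0L) {
    warning(sprintf("no occurrence of %s in genome '%s'", pattern, g$name))
    return(data.frame(pattern = pattern, mod_offset = mod_offset,
                      n_loci = 0L, mean_fraction = NA_real_,
                      stringsAsFactors = FALSE))
  }
  mp <- .mod_positions(sites, nchar(pattern), mod_offset)
  f <- track_get(track, mp, sites$strand)
  f[is.na(f)] <- 0
  data.frame(pattern = pattern, mod_offset = mod_offset,
             n_loci = nrow(sites), mean_fraction = mean(f),
             stringsAsFactors = FALSE)
}

#' One-position extension ladder around a core motif
#'
#' For each extension distance `d = 1..max_ext` and each concrete base, the
#' core is extended by that base placed `d` positions upstream (separately,
#' downstream) with all intervening extended positions `N`, and the mean
#' modified fraction over all genomic occurrences of the extended pattern is
#' computed. The `d = 0` row is the bare core. A flat profile across the
#' four upstream bases at a given distance indicates no sequence preference
#' at that position.
#'
#' @inheritParams motif_mean_fraction
#' @param core Core IUPAC pattern.
#' @param max_ext Maximum extension distance (default 3).
#' @return A data.frame with columns `direction` (`core`/`up`/`down`),
#'   `distance`, `base`, and the [motif_mean_fraction()] columns.
#' @export
extension_ladder <- function(g, track, core, mod_offset = 0L, max_ext = 3L) {
  stopifnot(max_ext >= 0L)
  row0 <- motif_mean_fraction(g, track, core, mod_offset)
  rows <- list(cbind(data.frame(direction = "core", distance = 0L, base = NA_character_,
                                stringsAsFactors = FALSE), row0))
  for (d in seq_len(max_ext)) {
    pad <- strrep("N", d - 1L)
    for (b in .BASES) {
      up <- motif_mean_fraction(g, track, paste0(b, pad, core), mod_offset + d)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(direction = "up", distance = d, base = b,
                         stringsAsFactors = FALSE), up)
      down <- motif_mean_fraction(g, track, paste0(core, pad, b), mod_offset)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(direction = "down", distance = d, base = b,
                         stringsAsFactors = FALSE), down)
    }
  }
  do.call(rbind, rows)
}

#' Restriction enzyme profile
#'
#' Describes a (possibly methylation-dependent) restriction enzyme by its
#' primary and secondary recognition sites, cut offset and the position of
#' the adenine whose methylation licenses cleavage.
#'
#' @param name Enzyme name.
#' @param primary_sites Character vector of IUPAC sites (cleaved at full
#'   efficiency).
#' @param secondary_sites Character vector of IUPAC sites cleaved only when
#'   `include_secondary` is set in [digest()].
#' @param cut_offset Bases of the site before the top-strand cut.
#' @param requires_methylation Logical; if `TRUE` only methylated sites cut.
#' @param methyl_offset 0-based position of the adenine that must be
#'   methylated within the site.
#' @return An `enzyme_profile`.
#' @export
enzyme_profile <- function(name, primary_sites, secondary_sites = character(0),
                           cut_offset, requires_methylation = TRUE,
                           methyl_offset = 0L) {
  lens <- nchar(c(primary_sites, secondary_sites))
  stopifnot(cut_offset >= 0L, all(cut_offset <= lens),
            all(methyl_offset >= 0L), all(methyl_offset < lens))
  structure(list(name = name, primary_sites = toupper(primary_sites),
                 secondary_sites = toupper(secondary_sites),
                 cut_offset = as.integer(cut_offset),
                 requires_methylation = isTRUE(requires_methylation),
                 methyl_offset = as.integer(methyl_offset)),
            class = "enzyme_profile")
}

#' DpnI profile
#'
#' DpnI cleaves fully methylated GATC (blunt, GA^TC) and, to a lesser
#' extent, hemi-contexts CATC/GATG carried as secondary sites.
#'
#' @return An [enzyme_profile].
#' @export
dpni_profile <- function() {
  enzyme_profile("DpnI", primary_sites = "GATC",
                 secondary_sites = c("CATC", "GATG"),
                 cut_offset = 2L, requires_methylation = TRUE,
                 methyl_offset = 1L)
}

.site_key <- function(start, strand) paste(start, strand)

#' Methylation-aware in-silico restriction digestion
#'
#' A primary palindromic site is cut only when its adenine is methylated on
#' both strands ("fully methylated"); a secondary (non-palindromic) site is
#' cut on single-strand methylation and only when `include_secondary` is
#' set. With `requires_methylation = FALSE` every site is cut. Cut positions
#' are deduplicated and sorted; a linear genome with `c` cuts yields `c + 1`
#' fragments, a circular genome with `c >= 1` cuts yields `c` fragments.
#'
#' @param g A [genome].
#' @param enzyme An [enzyme_profile].
#' @param methylated_sites data.frame with `start`, `strand` columns (a
#'   subset of [scan_sites()] records for the enzyme's sites), or `NULL`
#'   for none.
#' @param include_secondary Also cut secondary sites (default `FALSE`).
#' @return Integer vector of fragment lengths in genomic order.
#' @export
digest <- function(g, enzyme, methylated_sites = NULL, include_secondary = FALSE) {
  stopifnot(inherits(g, "genome"), inherits(enzyme, "enzyme_profile"))
  L <- genome_length(g)
  meth <- if (is.null(methylated_sites) || nrow(methylated_sites) == 0L) {
    character(0)
  } else {
    .site_key(methylated_sites$start, methylated_sites$strand)
  }
  cuts <- integer(0)
  site_cut <- function(sites, len, need_both) {
    # a palindromic site is one duplex locus: keep the plus-footprint record
    # and place the fragment boundary at the top-strand cut
    if (need_both) sites <- sites[sites$strand == "+", , drop = FALSE]
    if (nrow(sites) == 0L) return(integer(0))
    if (!enzyme$requires_methylation) {
      ok <- rep(TRUE, nrow(sites))
    } else if (need_both) {
      ok <- .site_key(sites$start, "+") %in% meth &
        .site_key(sites$start, "-") %in% meth
    } else {
      ok <- .site_key(sites$start, sites$strand) %in% meth
    }
    s <- sites[ok, , drop = FALSE]
    ifelse(s$strand == "+", s$start + enzyme$cut_offset,
           s$start + (len - enzyme$cut_offset))
  }
  for (pat in enzyme$primary_sites) {
    sites <- scan_sites(g, pat, both_strands = TRUE)
    palindromic <- identical(pat, reverse_complement(pat))
    cuts <- c(cuts, site_cut(sites, nchar(pat), need_both = palindromic))
  }
  if (include_secondary) {
    for (pat in enzyme$secondary_sites) {
      sites <- scan_sites(g, pat, both_strands = TRUE)
      cuts <- c(cuts, site_cut(sites, nchar(pat), need_both = FALSE))
    }
  }
  cuts <- sort(unique(cuts))
  stopifnot(all(cuts >= 0L & cuts <= L))
  cuts <- cuts[cuts > 0L & cuts < L]  # a cut at a boundary of a linear genome is a no-op
  if (g$circular) {
    if (length(cuts) == 0L) return(L)
    frags <- diff(c(cuts, cuts[1L] + L))
  } else {
    frags <- diff(c(0L, cuts, L))
  }
  as.integer(frags)
}

#' Methylated site records derived from a fraction track
#'
#' Convenience selector: site records (as from [scan_sites()]) whose
#' modified-base fraction on the respective strand reaches a threshold.
#'
#' @inheritParams motif_mean_fraction
#' @param threshold Minimum fraction to call a site methylated (default 0.5).
#' @return data.frame with `start`, `strand`.
#' @export
methylated_sites_from_track <- function(g, track, pattern, mod_offset = 0L,
                                        threshold = 0.5) {
  sites <- scan_sites(g, pattern, both_strands = TRUE)
  if (nrow(sites) == 0L) return(sites)
  mp <- .mod_positions(sites, nchar(pattern), mod_offset)
  f <- track_get(track, mp, sites$strand)
  f[is.na(f)] <- 0
  sites[f >= threshold, , drop = FALSE]
}
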