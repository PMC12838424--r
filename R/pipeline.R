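#' End-to-end motif discovery pipeline
#'
#' Wires the whole analysis in the order a modification-calling study runs
#' it: subtract the unmodified control from the test track, extract the
#' top-`k` most strongly modified `width`-bp windows, fit two-strand ZOOPS
#' motif models over a range of widths and keep the lowest-BIC one, then
#' profile the winning consensus on the genome (match count in the windows,
#' extension ladder on the differential track). When `out_dir` is given,
#' all artefacts are written: windows as BED and FASTA, the motif as JSON,
#' the ladder as TSV, a plain-text report and the resolved configuration.
#'
#' @param g A [genome].
#' @param test,control [fraction_track]s for the modified sample and the
#'   unmodified control.
#' @param width Window width in bases (default 10).
#' @param k Number of windows (default 100).
#' @param motif_widths Candidate motif widths for the scan (default `3:8`).
#' @param revcomp Two-strand motif search (default `TRUE`).
#' @param n_starts EM restarts per width (default 10).
#' @param max_ext Extension-ladder reach (default 3).
#' @param seed Integer seed for the EM restarts.
#' @param out_dir Optional output directory.
#' @return A `discover_report` list: `status` (`"ok"` or `"no signal"`),
#'   `windows`, `scan` (width-scan summary), `motif` (best `motif_result`),
#'   `consensus`, `n_matching`, `ladder`.
#' @export
run_discover <- function(g, test, control, width = 10L, k = 100L,
                         motif_widths = 3:8, revcomp = TRUE, n_starts = 10L,
                         max_ext = 3L, seed = 1L, out_dir = NULL) {
  diff <- differential_track(test, control)
  windows <- withCallingHandlers(
    top_windows(diff, g, width = width, k = k),
    warning = function(w) invokeRestart("muffleWarning"))
  if (nrow(windows) == 0L) {
    warning("no signal: no positive-score window after control subtraction")
    return(structure(list(status = "no signal", windows = windows,
                          scan = NULL, motif = NULL, consensus = NA_character_,
                          n_matching = NA_integer_, ladder = NULL),
                     class = "discover_report"))
  }
  scan <- scan_motif_widths(windows$seq, widths = motif_widths,
                            revcomp = revcomp, n_starts = n_starts, seed = seed)
  best <- scan$best
  cons <- consensus(best$model)
  n_match <- count_matching(windows$seq, cons, revcomp = revcomp)
  # anchor the ladder on the modified adenine: first A of the consensus, or
  # the most informative position when the consensus carries none
  mod_off <- regexpr("A", cons, fixed = TRUE)
  mod_off <- if (mod_off > 0L) mod_off - 1L else which.max(information_content(best$model)) - 1L
  ladder <- extension_ladder(g, diff, cons, mod_offset = mod_off,
                             max_ext = max_ext)
  report <- structure(list(status = "ok", windows = windows, scan = scan$summary,
                           motif = best, consensus = cons,
                           n_matching = n_match, ladder = ladder),
                      class = "discover_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_windows_bed(windows, g$name, file.path(out_dir, "windows.bed"))
    writeLines(paste0(">window_", seq_len(nrow(windows)), "\n", windows$seq),
               file.path(out_dir, "windows.fasta"))
    write_motif_json(best, file.path(out_dir, "motif.json"))
    utils::write.table(ladder, file.path(out_dir, "extension_ladder.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg <- c(width = width, k = k,
             motif_widths = paste(motif_widths, collapse = ","),
             revcomp = revcomp, n_starts = n_starts, max_ext = max_ext,
             seed = seed)
    writeLines(sprintf("%s: %s", names(cfg), cfg),
               file.path(out_dir, "config.txt"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.discover_report <- function(x, ...) {
  cat("== motif discovery report ==\n")
  cat(sprintf("status:     %s\n", x$status))
  if (x$status != "ok") return(invisible(x))
  cat(sprintf("windows:    %d (best score %.3f)\n", nrow(x$windows),
              x$windows$score[1L]))
  cat(sprintf("consensus:  %s (width %d, lam %.3f, loglik %.2f)\n",
              x$consensus, x$motif$model$width, x$motif$model$lam,
              x$motif$loglik))
  cat(sprintf("matching:   %d/%d windows contain %s or %s\n",
              x$n_matching, nrow(x$windows), x$consensus,
              reverse_complement(x$consensus)))
  cat(sprintf("revcomped:  %d of %d assigned sites on the minus strand\n",
              x$motif$n_rc, sum(!is.na(x$motif$assignments$site_start))))
  cat("width scan:\n")
  print(x$scan, row.names = FALSE)
  invisible(x)
}
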