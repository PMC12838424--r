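#!/usr/bin/env Rscript

# Stage 5: monoisotopic-mass annotation of the observed m/z peak list.
#
# Each chromatogram peak is matched against the shipped base/nucleotide
# library plus modification deltas at its stated tolerance; the tandem-MS
# fragments of the unknown 438/360 species are assigned by neutral losses
# from the pentosylated deoxycytidine precursor.

suppressPackageStartupMessages(library(modmotif))

peaks <- read.csv(system.file("extdata", "observed_peaks.csv",
                              package = "modmotif"))
dir.create("results/mass", showWarnings = FALSE, recursive = TRUE)

annot <- do.call(rbind, lapply(which(peaks$kind != "fragment"), function(i) {
  adduct <- if (peaks$mode[i] == "positive") "[M+H]+" else "[M-H]-"
  hits <- explain_peak(peaks$mz[i], adduct = adduct, tol_da = peaks$tol_da[i])
  if (nrow(hits) == 0L) {
    # an isolation mass printed coarsely may only resolve in the other mode
    other <- if (adduct == "[M+H]+") "[M-H]-" else "[M+H]+"
    hits <- explain_peak(peaks$mz[i], adduct = other, tol_da = peaks$tol_da[i])
  }
  if (nrow(hits) == 0L) return(NULL)
  cbind(note = peaks$note[i], hits[1L, ])
}))
write.table(annot, "results/mass/peak_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("peak annotations (best candidate each):\n")
print(annot[, c("observed_mz", "base", "delta", "theoretical_mz", "abs_error",
                "adduct")], row.names = FALSE)

frag_mzs <- peaks$mz[peaks$kind == "fragment"]
fr <- explain_fragments("C14H21N3O8", "[M+H]+", frag_mzs, tol_da = 0.005)
write.table(fr$assignments, "results/mass/fragment_assignments.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nfragment assignments from the C14H21N3O8 precursor:\n")
print(fr$assignments, row.names = FALSE)
if (length(fr$unassigned)) {
  cat("unassigned fragments:", paste(fr$unassigned, collapse = ", "), "\n")
}
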