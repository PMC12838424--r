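#!/usr/bin/env Rscript

# Stage 4: per-read quality summaries of the native vs PCR libraries.
#
# Native DNA carrying base modifications confuses the basecaller, so native
# reads score lower; converting the medians through the Phred formula puts
# numbers on the accuracy gap.

suppressPackageStartupMessages(library(modmotif))

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
rows <- do.call(rbind, lapply(c("native", "pcr"), function(lib) {
  q <- read_qscores_file(file.path("results/sim", paste0(lib, "_qscores.txt")))
  s <- summarize_qscores(q)
  cbind(library = lib, s,
        median_error_percent = qscore_to_error_percent(s$median))
}))
write.table(rows, "results/qc/summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(rows, row.names = FALSE)
cat(sprintf("\nQ7 corresponds to %.1f%% wrongly called bases; Q13 to %.1f%%\n",
            qscore_to_error_percent(7), qscore_to_error_percent(13)))
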