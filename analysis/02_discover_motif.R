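#!/usr/bin/env Rscript

# Stage 2: de novo motif discovery from the fraction tracks.
#
# Control subtraction -> top-100 10-bp windows -> two-strand ZOOPS EM over
# widths 3..8 (BIC-ranked) -> consensus, window match count, extension
# ladder. Reads the stage-1 artefacts from disk exactly as a real run would
# consume caller output.

suppressPackageStartupMessages(library(modmotif))

g <- read_fasta("results/sim/genome.fasta")[[1L]]
test <- read_track("results/sim/test.bedgraph", g)
control <- read_track("results/sim/control.bedgraph", g)

rep <- run_discover(g, test, control, width = 10L, k = 100L,
                    motif_widths = 3:8, n_starts = 10L, max_ext = 3L,
                    seed = 1L, out_dir = "results/discover")
print(rep)
cat("\nwrote results/discover/{windows.bed,windows.fasta,motif.json,extension_ladder.tsv,report.txt,config.txt}\n")
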