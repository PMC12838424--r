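#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study dataset.
#
# A 200 kb random genome in which every ATC (and, on the minus strand, GAT)
# carries a highly modified adenine; per-adenine modified fractions for a
# test sample and an unmodified control, positionally blurred the way a
# nanopore modification caller smears signal over ~5 bases; plus per-read
# mean quality scores for a native and a PCR-amplified library.

suppressPackageStartupMessages(library(modmotif))

out <- "results/sim"
cfg <- sim_config(seed = 1L)
sim <- run_simulate(cfg, out)

cat(sprintf("genome: %d bp, planted modified adenines: %d (%d on +, %d on -)\n",
            genome_length(sim$genome), nrow(sim$planted),
            sum(sim$planted$strand == "+"), sum(sim$planted$strand == "-")))

for (lib in c("native", "pcr")) {
  q <- simulate_read_qscores(5000L, lib, seed = cfg$seed + 100L)
  writeLines(sprintf("%.6f", q), file.path(out, paste0(lib, "_qscores.txt")))
  cat(sprintf("%s library: %d reads, median Q %.2f\n", lib, length(q),
              stats::median(q)))
}
cat(sprintf("wrote %s/{genome.fasta,test.bedgraph,control.bedgraph,metadata.txt,*_qscores.txt}\n", out))
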