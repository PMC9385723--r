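#!/usr/bin/env Rscript
# Resolve the simulated unitig graph with long-read support and check the
# reconstructed master circle against the planted genome.

suppressMessages(library(organellr))
ind <- "results/simulated/assembly"
out <- "results"
stopifnot(file.exists(file.path(ind, "unitigs.gfa")))

g <- run_resolve(file.path(ind, "unitigs.gfa"),
                 file.path(ind, "reads.fastq"),
                 out_fasta = file.path(out, "resolved_genome.fasta"),
                 decisions_tsv = file.path(out, "resolve_decisions.tsv"))
truth <- read_fasta(file.path(ind, "genome.fasta"), circular = TRUE)[[1]]
ok <- circular_equal(g$seq, truth$seq)
cat("resolved circle: ", genome_length(g), "bp; matches planted genome ",
    "(up to rotation/revcomp): ", ok, "\n", sep = "")
dec <- utils::read.delim(file.path(out, "resolve_decisions.tsv"))
cat("DBS decisions:\n")
print(dec)
if (!ok) stop("resolution failed to recover the planted circle")
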