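#!/usr/bin/env Rscript
# Homologous fragments between the simulated plastome/mitogenome pair,
# origin classification against the simulated outgroup pair, and dotplot
# data; recall is checked against the planted truth.

suppressMessages(library(organellr))
ind <- "results/simulated"
out <- "results/homology"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cp <- read_fasta(file.path(ind, "pair_plastome.fasta"), circular = TRUE)[[1]]
mt <- read_fasta(file.path(ind, "pair_mitogenome.fasta"), circular = TRUE)[[1]]
ocp <- read_fasta(file.path(ind, "outgroup_plastome.fasta"), circular = TRUE)[[1]]
omt <- read_fasta(file.path(ind, "outgroup_mitogenome.fasta"), circular = TRUE)[[1]]
truth <- utils::read.delim(file.path(ind, "pair_truth.tsv"))

fr <- find_fragments(cp, mt, evalue_cutoff = 1e-5)
write_tsv_report(fr, file.path(out, "fragments.tsv"))
st <- fragment_stats(fr, mt)
write_json_report(st, file.path(out, "fragment_stats.json"))
cat(st$count, " fragments, total ", st$total_bp, " bp = ",
    st$percent_of_genome_sum, "% of the mitogenome (longest ", st$max_len,
    " bp, shortest ", st$min_len, " bp)\n", sep = "")

recall <- mean(vapply(seq_len(nrow(truth)), function(i)
  any(fr$b_start <= truth$mt_end[i] & fr$b_end >= truth$mt_start[i]), TRUE))
cat("recall of planted fragments: ", 100 * recall, "%\n", sep = "")

oc <- classify_origin(fr, cp, ocp, omt)
write_tsv_report(oc, file.path(out, "origin.tsv"))
cat("origin calls: ", paste(names(table(oc$call)), table(oc$call),
                            sep = "=", collapse = ", "), "\n", sep = "")

dd <- dotplot_data(cp, mt)
write_tsv_report(dd, file.path(out, "dotplot.tsv"))
cat("dotplot rows: ", nrow(dd), "\n", sep = "")
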