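#!/usr/bin/env Rscript
# Repeat landscape and quadripartite structure of the simulated plastome,
# plus the SSC-inversion comparison between the two plastome isomers.

suppressMessages(library(organellr))
out <- "results/repeats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cp <- read_fasta("results/simulated/plastome.fasta", circular = TRUE)[[1]]

ssrs <- find_ssrs(cp)
disp <- find_dispersed(cp)
write_tsv_report(ssrs, file.path(out, "ssr.tsv"))
write_tsv_report(disp, file.path(out, "dispersed.tsv"))
sm <- summarize_repeats(ssrs, disp)
write_json_report(sm, file.path(out, "repeat_summary.json"))
cat("plastome repeats: ", sm$ssr_total, " SSRs, ", sm$dispersed_total,
    " dispersed (", sm$dispersed_counts$forward, " forward / ",
    sm$dispersed_counts$palindromic, " palindromic / ",
    sm$dispersed_counts$reverse, " reverse)\n", sep = "")

quad <- detect_quadripartite(cp)
L <- genome_length(cp)
st <- list(lsc_bp = ((quad$lsc[2] - quad$lsc[1]) %% L) + 1,
           ir_bp = quad$ir_length,
           ssc_bp = ((quad$ssc[2] - quad$ssc[1]) %% L) + 1,
           total_bp = L)
write_json_report(st, file.path(out, "structure.json"))
cat("quadripartite: LSC ", st$lsc_bp, " + 2 x IR ", st$ir_bp, " + SSC ",
    st$ssc_bp, " = ", st$total_bp, " bp\n", sep = "")

# the SSC-flipped isomer is the same molecule under the comparison
flipped <- genome("isomer", organellr:::flip_region(cp$seq, quad$ssc),
                  circular = TRUE)
cat("isomer comparison: ", compare_up_to_ssc_flip(cp, flipped), "\n", sep = "")
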