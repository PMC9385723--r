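#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: a repeat-bearing circular "mitogenome" with its unitig graph
# and spanning long reads, a quadripartite plastome at the real study's
# region sizes, an organelle pair with planted shared fragments, and an
# 18-species panel with IGS variation. All stages carry planted ground
# truth, so every later script can state exactly how well it did.

suppressMessages(library(organellr))
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260926L

# repeat-bearing circle -> unitig graph + reads (the assembly-finishing input)
cfg <- sim_config(seed = seed, genome_length = 24000,
                  repeat_spec = list(list(arm_length = 2000,
                                          orientation = "forward")))
ds <- write_simulated_dataset(cfg, file.path(out, "assembly"),
                              min_repeat = 500, n_reads = 80,
                              mean_len = 4200)
cat("assembly input: ", genome_length(ds$sim$genome), "bp circle, ",
    length(ds$graph$graph$segments), "unitigs, ",
    length(ds$reads$reads), "reads\n", sep = "")

# quadripartite plastome at the study's region sizes (LSC 82,838 /
# IR 24,959 / SSC 18,316)
qp <- make_quadripartite_plastome(82838, 24959, 18316, seed = seed + 1)
write_fasta(qp$genome, file.path(out, "plastome.fasta"))
cat("plastome: ", genome_length(qp$genome), "bp (quadripartite)\n", sep = "")

# organelle pair with planted shared fragments + outgroup pair
op <- make_organelle_pair(n_fragments = 5, frag_len = c(900, 500, 250, 150, 100),
                          identity = c(1, 1, 0.95, 0.92, 0.9),
                          n_horizontal = 1, cp_len = 100000, mt_len = 150000,
                          seed = seed + 2)
write_fasta(op$plastome, file.path(out, "pair_plastome.fasta"))
write_fasta(op$mitogenome, file.path(out, "pair_mitogenome.fasta"))
write_fasta(op$outgroup_plastome, file.path(out, "outgroup_plastome.fasta"))
write_fasta(op$outgroup_mito, file.path(out, "outgroup_mitogenome.fasta"))
write_tsv_report(op$truth, file.path(out, "pair_truth.tsv"))
cat("organelle pair: ", nrow(op$truth), " planted fragments (",
    sum(op$truth$origin == "horizontal"), " horizontal)\n", sep = "")

# annotated ancestor -> 18-species panel (variation only in the IGS)
anc <- make_quadripartite_plastome(9000, 1200, 2000, seed = seed + 3,
                                   n_genes = 10)
pan <- make_species_panel(anc$genome, n_species = 18,
                          igs_mutation_rate = 0.004, indel_rate = 0.001,
                          seed = seed + 4)
dir.create(file.path(out, "panel"), showWarnings = FALSE)
for (sp in names(pan$panel))
  write_genbank(pan$panel[[sp]], file.path(out, "panel", paste0(sp, ".gb")))
write_tsv_report(pan$truth$private_variants,
                 file.path(out, "panel_truth.tsv"))
cat("species panel: ", length(pan$panel), " species, ",
    nrow(pan$truth$private_variants), " planted private variants\n", sep = "")
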