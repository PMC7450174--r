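#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study and write every input in its
# standard on-disk format (GTF, FASTA, TSV, BED6, bedGraph), so later
# stages consume files exactly as a re-analysis of real data would.
suppressPackageStartupMessages(library(isoscope))
seed <- 20240101L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
dir.create("scratch", showWarnings = FALSE)

sim <- simulate_study(n_loci = 120L, design = design_spec(seed = seed),
                      n_mirnas = 24L)
saveRDS(sim, "scratch/sim.rds")   # scratch cache for later stages

write_annotation(sim$genes, "results/data/annotation.gtf")
write_genome_fasta(sim$genome, "results/data/genome.fa")
write_junctions_bed(sim$junctions, "results/data/junctions.bed")
write_bedgraph(sim$coverage, "results/data/coverage.bedGraph")
write_abundance_tsv(sim$abundance, "results/data/abundance.tsv")
write_genome_fasta(chartr("U", "T", sim$mirnas), "results/data/mirnas.fa")
write.table(sim$peptides, "results/data/peptides.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$events, "results/data/planted_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d loci (%d isoforms, %d planted events),\n",
            length(sim$genes), nrow(sim$truth), nrow(sim$events)))
cat(sprintf("  %d planted miRNA sites, %d peptides (%d junction-spanning)\n",
            nrow(sim$mirna_ledger), nrow(sim$peptides),
            sum(sim$peptide_ledger$class == "junction")))
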