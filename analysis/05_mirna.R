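#!/usr/bin/env Rscript
# Stage 5: miRNA target scanning (penalty scheme: mismatch 1, wobble 0.5,
# seed 2-13 doubled, cutoff 5) and AS-coupled target classification.
suppressPackageStartupMessages(library(isoscope))
genes <- read_annotation("results/data/annotation.gtf")
genome <- read_fasta("results/data/genome.fa")
mirnas <- read_fasta("results/data/mirnas.fa", rna = TRUE)
events <- read.table("results/as_events.tsv", sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
sites <- scan_gene_targets(genes, genome, mirnas)
write.table(sites, "results/mirna_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
rows <- list()
for (g in genes) {
  s <- sites[sites$gene_id == g$gene_id, , drop = FALSE]
  if (!nrow(s)) next
  cp <- coupled_as_mirna(g, events[events$gene_id == g$gene_id, ,
                                   drop = FALSE], s)
  rows[[g$gene_id]] <- cbind(cp$by_mirna, multi_site = cp$multi_site)
}
coupled <- do.call(rbind, rows)
write.table(coupled, "results/mirna_coupled.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d target sites; %d (gene, miRNA) pairs AS-coupled; %d genes multi-site\n",
            nrow(sites), sum(coupled$as_coupled),
            length(unique(coupled$gene_id[coupled$multi_site]))))
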