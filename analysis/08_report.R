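#!/usr/bin/env Rscript
# Stage 8: summary report: isoform-number histogram with percentages,
# headline AS/NMD fractions of this run, and the published-table
# percentages recomputed for comparison.
suppressPackageStartupMessages(library(isoscope))
genes <- read_annotation("results/data/annotation.gtf")
orf <- read.table("results/orf_nmd.tsv", sep = "\t", header = TRUE,
                  stringsAsFactors = FALSE)
events <- read.table("results/as_events.tsv", sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
iso_counts <- table(vapply(genes, function(g) length(g$transcripts), 1L))
hist <- isoform_histogram_percentages(setNames(as.integer(iso_counts),
                                               names(iso_counts)))
write.table(hist, "results/isoform_histogram.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
as_genes <- unique(events$gene_id)
ok <- orf$verdict == "ok"
as_orf <- intersect(as_genes, orf$gene_id[ok])
nmd_genes <- intersect(unique(orf$gene_id[ok & orf$nmd_candidate]), as_orf)
h <- headline_fractions(length(as_genes), length(genes),
                        length(nmd_genes), length(as_orf))
cat("this run:\n")
cat(sprintf("  AS genes: %d of %d (%.2f%%)\n", length(as_genes),
            length(genes), h$as_gene_percent))
cat(sprintf("  NMD genes: %d of %d AS genes with ORFs (%.1f%%)\n",
            length(nmd_genes), length(as_orf), h$nmd_gene_percent))
tab <- isoform_count_table()
ph <- isoform_histogram_percentages(setNames(tab$meja_genes, tab$isoforms))
cat("published assembly column, recomputed: class 1 =",
    ph$percent[ph$isoforms == 1], "%, class 2 =",
    ph$percent[ph$isoforms == 2], "%\n")
cat("published headline fractions:",
    headline_fractions(4446, 13647)$as_gene_percent, "% AS genes;",
    headline_fractions(4446, 13647, 1106, 3220)$nmd_gene_percent,
    "% NMD among AS genes with ORFs\n")
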