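#!/usr/bin/env Rscript
# Stage 2: transcript-set filtering with the study criteria: every
# junction supported by >= 3 reads, tiered coverage over retained
# introns (4/5/6 at 100/90/80%), and the isoform abundance floor of 5.
suppressPackageStartupMessages(library(isoscope))
genes <- read_annotation("results/data/annotation.gtf")
junctions <- read_junctions_bed("results/data/junctions.bed")
abundance <- read_abundance_tsv("results/data/abundance.tsv")
genome <- read_fasta("results/data/genome.fa")
coverage <- read_bedgraph("results/data/coverage.bedGraph",
                          setNames(nchar(genome), names(genome)))

res <- filter_transcripts(genes, junctions, coverage, abundance)
write.table(res$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n <- nrow(res$report)
cat(sprintf("filtering: %d/%d transcripts retained\n", length(res$keep), n))
cat(sprintf("  junction-support failures: %d\n", sum(!res$report$junction_pass)))
cat(sprintf("  IR-coverage failures:      %d\n", sum(!res$report$ir_pass)))
cat(sprintf("  abundance-floor failures:  %d\n", sum(!res$report$abundance_pass)))
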