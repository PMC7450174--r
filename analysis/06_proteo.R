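#!/usr/bin/env Rscript
# Stage 6: protein-level validation of AS isoforms: confidence >= 95%,
# unique gene mapping, junction-spanning peptides.
suppressPackageStartupMessages(library(isoscope))
genes <- read_annotation("results/data/annotation.gtf")
genome <- read_fasta("results/data/genome.fa")
peptides <- read.table("results/data/peptides.tsv", sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
events <- read.table("results/as_events.tsv", sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
orfs <- list()
for (g in genes) for (tx in g$transcripts)
  orfs[[tx$transcript_id]] <- find_orf(transcript_sequence(tx, genome), 100)
proteome <- do.call(rbind, lapply(genes, function(g)
  do.call(rbind, lapply(g$transcripts, function(tx) {
    o <- orfs[[tx$transcript_id]]
    if (o$verdict != "ok") return(NULL)
    data.frame(transcript_id = tx$transcript_id, gene_id = g$gene_id,
               protein = o$protein, stringsAsFactors = FALSE)
  }))))
val <- validate_isoforms(peptides, proteome, genes, orfs, events)
write.table(val$validated, "results/validated_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d peptides in, %d confident, %d ambiguous (multi-gene),\n",
            val$n_input, val$n_confident, length(val$ambiguous)))
cat(sprintf("  %d junction-spanning validations over %d events in %d genes\n",
            nrow(val$validated),
            length(unique(paste(val$validated$gene_id, val$validated$region))),
            length(unique(val$validated$gene_id))))
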