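#!/usr/bin/env Rscript
# Stage 4: ORF prediction per isoform and NMD calling by the two rules
# (3'UTR > 350 nt; stop > 55 nt upstream of the last junction).
suppressPackageStartupMessages(library(isoscope))
genes <- read_annotation("results/data/annotation.gtf")
genome <- read_fasta("results/data/genome.fa")
rows <- list(); prot <- character()
for (g in genes) for (tx in g$transcripts) {
  orf <- find_orf(transcript_sequence(tx, genome), 100)
  if (orf$verdict != "ok") {
    rows[[tx$transcript_id]] <- data.frame(
      gene_id = g$gene_id, transcript_id = tx$transcript_id,
      verdict = orf$verdict, utr3_len = NA, stop_to_last_junction = NA,
      nmd_candidate = NA)
    next
  }
  v <- nmd_call(tx, orf)
  prot[tx$transcript_id] <- orf$protein
  rows[[tx$transcript_id]] <- data.frame(
    gene_id = g$gene_id, transcript_id = tx$transcript_id, verdict = "ok",
    utr3_len = v$utr3_len, stop_to_last_junction = v$stop_to_last_junction,
    nmd_candidate = v$nmd_candidate)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/orf_nmd.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                            "results/proteome.fa")
ok <- tab$verdict == "ok"
cat(sprintf("ORFs: %d ok, %d excluded (none/ambiguous)\n", sum(ok), sum(!ok)))
cat(sprintf("NMD candidates: %d transcripts in %d genes\n",
            sum(tab$nmd_candidate[ok]),
            length(unique(tab$gene_id[ok & tab$nmd_candidate]))))
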