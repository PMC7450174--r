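# Readers/writers for the standard formats: GTF/GFF3 annotation, FASTA
# genomes, BED6 junction lists, bedGraph coverage and TSV abundance tables.

#' Read a GTF or GFF3 annotation into gene models
#'
#' File coordinates (1-based inclusive) are converted to the package's
#' internal 0-based half-open convention. Exon (and CDS) records are grouped
#' by `transcript_id` and transcripts by `gene_id`; only these two attributes
#' are interpreted. GFF3 files using `Parent`/`ID` chains are handled by
#' `rtracklayer`'s importer.
#'
#' @param path Path to a `.gtf`, `.gff` or `.gff3` file.
#' @return Named list of [gene_model()] objects, ordered by gene_id.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  body_lines <- grep("^[^#]", readLines(path), value = TRUE)
  if (length(body_lines) == 0L)
    return(structure(list(), names = character()))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) stop("no feature type column in ", path)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  if (is.null(df$transcript_id)) {
    # GFF3 dialect: exon Parent is the transcript
    if (!is.null(df$Parent)) {
      df$transcript_id <- vapply(df$Parent, function(p)
        if (length(p)) sub("^transcript:", "", p[[1]]) else NA_character_, "")
    }
  }
  if (is.null(df$gene_id) && !is.null(df$ID))
    df$gene_id <- sub("\\.[0-9]+$", "", df$transcript_id)
  if (is.null(df$transcript_id) || is.null(df$gene_id))
    stop("records in ", path, " lack gene_id/transcript_id attributes")
  df$start0 <- df$start - 1L  # to 0-based half-open
  genes <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cd <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) next
    gid <- as.character(ex$gene_id[1])
    tx <- transcript_model(
      tid, gid, as.character(ex$seqnames[1]), as.character(ex$strand[1]),
      ex$start0, ex$end,
      cds_starts = if (nrow(cd)) cd$start0 else NULL,
      cds_ends = if (nrow(cd)) cd$end else NULL)
    genes[[gid]] <- c(genes[[gid]], list(tx))
  }
  out <- lapply(names(genes), function(g) gene_model(g, genes[[g]]))
  names(out) <- names(genes)
  out[order(names(out))]
}

#' Write gene models as GTF (Ensembl attribute dialect)
#'
#' Output is byte-stable for a given input: genes in list order, transcripts
#' in gene order, exon and CDS rows in genomic order. Round-tripping through
#' [read_annotation()] reproduces the models exactly.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  lines <- c("##gtf-file written by isoscope")
  for (g in genes) {
    for (tx in g$transcripts) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       tx$gene_id, tx$transcript_id)
      lines <- c(lines,
        sprintf("%s\tisoscope\texon\t%d\t%d\t.\t%s\t.\t%s",
                tx$chrom, tx$exon_starts + 1L, tx$exon_ends, tx$strand, attrs))
      if (!is.null(tx$cds_starts)) {
        lines <- c(lines,
          sprintf("%s\tisoscope\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  tx$chrom, tx$cds_starts + 1L, tx$cds_ends, tx$strand, attrs))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the mature (spliced) transcript sequence
#'
#' Exon sequences are concatenated in transcript order; minus-strand
#' transcripts are reverse-complemented, so the result always reads 5'->3'.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return Single uppercase DNA string.
#' @export
transcript_sequence <- function(tx, genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!tx$chrom %in% names(genome)) stop("contig missing: ", tx$chrom)
  contig <- genome[[tx$chrom]]
  if (max(tx$exon_ends) > nchar(contig))
    stop("exon out of contig bounds in ", tx$transcript_id)
  pieces <- substring(contig, tx$exon_starts + 1L, tx$exon_ends)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  toupper(s)
}

#' Reverse-complement a DNA string
#' @param s DNA string (A/C/G/T/N, either case).
#' @return Reverse complement, preserving case convention of `chartr`.
#' @export
revcomp <- function(s) {
  chartr("ACGTacgtN", "TGCAtgcaN",
         vapply(strsplit(s, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), ""))
}

#' Write contig sequences as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @param rna Return RNA alphabet (T converted to U on read, so both DNA-
#'   and RNA-alphabet miRNA FASTA files are accepted).
#' @return Named character vector, uppercase.
#' @export
read_fasta <- function(path, rna = FALSE) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  if (rna) out <- chartr("T", "U", out)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Export splice junctions as BED6
#'
#' One BED row per junction covering the intron `[donor_end,
#' acceptor_start)`; the score column carries the read support.
#'
#' @param junctions Data.frame with `chrom`, `donor_end`, `acceptor_start`,
#'   `strand`, `read_support`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  lines <- sprintf("%s\t%d\t%d\tjunc%d\t%d\t%s",
                   junctions$chrom, junctions$donor_end,
                   junctions$acceptor_start, seq_len(nrow(junctions)),
                   junctions$read_support, junctions$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 junction file
#' @param path BED6 path written by [write_junctions_bed()].
#' @return Data.frame with junction columns.
#' @export
read_junctions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  data.frame(chrom = df$chrom, donor_end = df$start,
             acceptor_start = df$end, strand = df$strand,
             read_support = df$score)
}

#' Write per-base coverage as bedGraph
#'
#' Adjacent bases with equal depth are merged into one record.
#'
#' @param coverage Named list of per-contig coverage: each element a list
#'   with `start` (0-based) and `depth` (numeric vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  lines <- character()
  for (chrom in names(coverage)) {
    cv <- coverage[[chrom]]
    d <- cv$depth
    if (length(d) == 0L) next
    r <- rle(d)
    ends <- cv$start + cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    lines <- c(lines, sprintf("%s\t%d\t%d\t%g", chrom, starts[keep],
                              ends[keep], r$values[keep]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into per-contig coverage tracks
#' @param path bedGraph path.
#' @param contig_lengths Named integer vector giving each contig's length
#'   (depth is zero-filled outside recorded intervals).
#' @return Named list of coverage tracks (`start = 0`, `depth` vector).
#' @export
read_bedgraph <- function(path, contig_lengths) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "depth"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  out <- lapply(names(contig_lengths), function(chrom) {
    depth <- numeric(contig_lengths[[chrom]])
    sub <- df[df$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      depth[(sub$start[i] + 1L):sub$end[i]] <- sub$depth[i]
    list(start = 0L, depth = depth)
  })
  names(out) <- names(contig_lengths)
  out
}

#' Read/write per-isoform abundance tables
#'
#' The abundance table is a long-format data.frame with one row per
#' (transcript, condition, replicate): columns `transcript_id`, `gene_id`,
#' `condition`, `replicate`, `abundance` (FPKM-like, non-negative).
#'
#' @param table Abundance data.frame.
#' @param path TSV path.
#' @return `path` / the table.
#' @export
write_abundance_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (any(df$abundance < 0)) stop("negative abundance in ", path)
  df
}
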