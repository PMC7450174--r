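Package: isoscope
Title: Isoform-Level Alternative Splicing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isoform-resolved analysis of alternative splicing (AS) in
    RNA-seq transcript assemblies. Provides coordinate-aware gene and transcript
    models with GTF/GFF3 input and output; read-support and coverage-based
    transcript filtering; pairwise classification of AS events (intron retention,
    alternative acceptor and donor, exon skipping, alternative first and last
    exons); ORF prediction with nonsense-mediated decay (NMD) rule calling;
    protein domain projection between isoforms; miRNA target-site scanning with
    an AS-coupled target classification; validation of AS isoforms from
    junction-spanning peptides; and differential isoform-usage statistics based
    on the Jensen-Shannon divergence with a replicate-label permutation null.
    A synthetic-data module generates fully annotated loci with planted ground
    truth emulating a multi-genotype, multi-tissue hormone-treatment study, so
    the entire pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
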