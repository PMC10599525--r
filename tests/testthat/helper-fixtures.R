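# In-code fixtures: tiny annotated-genome flat files and codon helpers.

# 12-codon gene: ATG + 10 sense codons + TAA (36 nt), no internal stop
FIX_GENE <- "ATGAAACCCGGGTTTACGCATGAAGATCTTTCTTAA"

codons_of <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# genome = 12 nt pad | payload | 12 nt pad
make_genome_seq <- function(payload) {
  paste0("ACGTACGTACGT", payload, "TGCATGCATGCA")
}

wrap_seq_lines <- function(seq, prefix = "        1 ") {
  starts <- seq(1, nchar(seq), 60)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59, nchar(seq)))
    inner <- paste(substring(chunk, seq(1, nchar(chunk), 10),
                             pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk))),
                   collapse = " ")
    sprintf("%9d %s", s, tolower(inner))
  }, "")
}

write_genbank_fixture <- function(path, payload = FIX_GENE,
                                  loc = sprintf("13..%d", 12 + nchar(payload)),
                                  tag = "g1") {
  genome <- make_genome_seq(payload)
  lines <- c(
    sprintf("LOCUS       TESTGB    %d bp    DNA     linear   BCT 01-JAN-2020",
            nchar(genome)),
    "ACCESSION   TESTGB",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    sprintf("     CDS             %s", loc),
    sprintf("                     /locus_tag=\"%s\"", tag),
    "ORIGIN",
    wrap_seq_lines(genome),
    "//"
  )
  writeLines(lines, path)
  invisible(genome)
}

write_embl_fixture <- function(path, payload = FIX_GENE,
                               loc = sprintf("13..%d", 12 + nchar(payload)),
                               tag = "g1") {
  genome <- make_genome_seq(payload)
  lines <- c(
    sprintf("ID   TESTEM; SV 1; linear; genomic DNA; STD; PRO; %d BP.",
            nchar(genome)),
    "AC   TESTEM;",
    "FH   Key             Location/Qualifiers",
    sprintf("FT   CDS             %s", loc),
    sprintf("FT                   /locus_tag=\"%s\"", tag),
    sprintf("SQ   Sequence %d BP;", nchar(genome)),
    paste0("     ", tolower(genome)),
    "//"
  )
  writeLines(lines, path)
  invisible(genome)
}

write_fasta_fixture <- function(path, seqs) {
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  invisible(path)
}

# quick cds_record builder for filter/window tests
rec <- function(seq, id = "g") codonIO:::new_cds_record(id, "test", seq)

# codon_counts from a flat codon character vector
counts_of <- function(codons, code = genetic_code_partition()) {
  count_codons(list(codons), code)
}
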