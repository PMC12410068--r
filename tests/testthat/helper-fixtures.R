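# fixtures built in code: FASTA/SAM/GFF writers and small reference sets

write_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

# the packaged C. elegans-style SL reference set
celegans_refs <- function() {
  loadSLReferences(system.file("extdata", "celegans_sl_synthetic.fasta",
                               package = "SLcallR"))
}

# minimal SAM with a single reference sequence; records are character
# vectors of the 11 mandatory fields
write_sam <- function(records, chrom = "chr1", chrlen = 100000L,
                      path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen),
               vapply(records, paste, character(1), collapse = "\t")),
             path)
  path
}

sam_record <- function(qname, flag, pos, cigar, seq, chrom = "chr1") {
  c(qname, flag, chrom, pos, "60", cigar, "*", "0", "0", seq, "*")
}

# small two-gene annotation on one chromosome; exon coordinates given as
# list(gene_id = list(strand, list(c(start, end), ...)))
write_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  ln <- "##gff-version 3"
  for (gid in names(genes)) {
    g <- genes[[gid]]
    ex <- g$exons
    st <- min(vapply(ex, `[`, numeric(1), 1))
    en <- max(vapply(ex, `[`, numeric(1), 2))
    ln <- c(ln,
            sprintf("chr1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    st, en, g$strand, gid),
            sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                    st, en, g$strand, gid, gid))
    for (i in seq_along(ex))
      ln <- c(ln, sprintf(
        "chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
        ex[[i]][1], ex[[i]][2], g$strand, gid, i, gid))
  }
  writeLines(ln, path)
  path
}

# gene summary row constructor for role/operon tests
summary_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], n_SL1 = r[[2]], n_SL2 = r[[3]],
               n_total = r[[4]], stringsAsFactors = FALSE)))
}
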