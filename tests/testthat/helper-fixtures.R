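# shared fixture builders; everything is generated in code at test time

tiny_genome <- function(seq, id = "chr") strainlift:::make_genome_set(seq, id)

write_fasta_tmp <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

write_gff3_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

# minimal GenBank record with one forward CDS and one complement-join
# pseudo CDS carrying an antiSMASH-style gene_kind qualifier
write_genbank_tmp <- function() {
  path <- withr::local_tempfile(fileext = ".gbk", .local_envir = parent.frame())
  writeLines(c(
    "LOCUS       TESTREC                  60 bp    DNA     circular BCT 01-JAN-2020",
    "DEFINITION  synthetic test record.",
    "ACCESSION   TESTREC",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"synthetic\"",
    "     CDS             1..9",
    "                     /locus_tag=\"t0001\"",
    "                     /product=\"demo protein\"",
    "                     /translation=\"MKL\"",
    "     CDS             complement(join(20..28,31..39))",
    "                     /locus_tag=\"t0002\"",
    "                     /gene_kind=\"biosynthetic\"",
    "                     /pseudo",
    "ORIGIN",
    "        1 atgaaactga aaaaaaaaaa acccggtacc gtaaagggcc cttaaggtac catgacgtaa",
    "//"), path)
  path
}

# hand-built placement table for adjacency arithmetic tests
manual_placements <- function(starts, ends, strand = "+", mapped = TRUE,
                              nrun = 10L) {
  n <- length(starts)
  data.frame(
    fragment_id = seq_len(n), mapped = rep_len(mapped, n),
    ref_replicon = "chr", ref_start = starts, ref_end = ends,
    strand = rep_len(strand, n), left_clip_bp = 0L, right_clip_bp = 0L,
    identity_fraction = 1, score = ends - starts, n_best = 1L, reason = "",
    source_replicon = "chr_draft",
    preceding_nrun_bp = c(NA_integer_, rep_len(nrun, n - 1L)),
    stringsAsFactors = FALSE
  )
}

# tiny BGC table: one cluster, two genes
tiny_bgc_table <- function(cluster_id = "bgcX", genome_id = "gA",
                           core_seq = strrep("MKTAYIAKQR", 12),
                           reg_seq = strrep("MLNPDEQWCH", 12)) {
  data.frame(
    cluster_id = cluster_id, genome_id = genome_id, replicon_id = genome_id,
    start = 1000L, end = 4000L, product_type = "ectoine",
    gene_id = paste0(cluster_id, c("_core1", "_reg1")),
    role = c("core_biosynthetic", "regulatory"),
    protein_seq = c(core_seq, reg_seq), stringsAsFactors = FALSE
  )
}

label_recovery <- function(truth, categories) {
  lab <- stats::setNames(categories$label, categories$subject_id)
  vapply(split(names(truth), unname(truth)),
         function(ids) mean(lab[ids] == truth[ids], na.rm = TRUE),
         numeric(1))
}
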