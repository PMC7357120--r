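test_that("identical CDS pairs yield no variants", {
  cds <- generate_cds(100, seed = 1)
  expect_identical(nrow(align_cds_pair(cds, cds)), 0L)
  expect_error(align_cds_pair("", cds), "empty")
})

test_that("the single-C deletion preset is called at position 505, codon 169", {
  p <- mutate_cds(preset = "cmlI_case")
  expect_gte(nchar(p$ref), 600L)
  expect_identical(substr(p$ref, 505, 505), "C")
  v <- align_cds_pair(p$ref, p$alt)
  expect_identical(v$kind, "deletion")
  expect_identical(v$cds_position, 505L)
  expect_identical(v$ref_allele, "C")
  eff <- frameshift_effect(v, p$ref)
  expect_true(eff$frameshift)
  expect_identical(eff$first_affected_codon, 169L)
  expect_identical(eff$net_indel_bp, -1L)
})

test_that("an in-frame 3 bp deletion at a codon boundary is not a frameshift", {
  cds <- generate_cds(100, seed = 2)          # 300 nt, stop at codon 100
  v <- data.frame(kind = "deletion", cds_position = 241L,
                  ref_allele = substr(cds, 241, 243), alt_allele = "",
                  length = 3L, stringsAsFactors = FALSE)
  eff <- frameshift_effect(v, cds)
  expect_false(eff$frameshift)
  expect_identical(eff$net_indel_bp, -3L)
  expect_true(is.na(eff$first_affected_codon))
  # one whole residue is removed, the rest is unchanged
  aa_ref <- strsplit(translate_cds(cds), "")[[1]]
  aa_alt <- strsplit(translate_cds(apply_variants(cds, v)), "")[[1]]
  expect_identical(aa_alt, aa_ref[-81])  # codon 81 removed, rest unchanged
})

test_that("indels are left-aligned to their leftmost equivalent position", {
  # deleting any A from the A-run reports the run's first position
  ref <- "ATGCCCAAAAAGGGTCCTGA"
  alt <- "ATGCCCAAAAGGGTCCTGA"
  v <- align_cds_pair(ref, alt)
  expect_identical(v$kind, "deletion")
  expect_identical(v$cds_position, 7L)
})

test_that("planted substitutions and indels are recovered exactly with round-trip", {
  for (s in c(5, 6, 7)) {
    m <- mutate_cds(generate_cds(334, seed = s), n_subs = 50,
                    indel_spec = list(n_ins = 1, n_del = 2,
                                      len_range = c(1, 3)), seed = s)
    called <- align_cds_pair(m$ref, m$alt)
    expect_equal(called, m$edits, ignore_attr = TRUE)
    expect_identical(apply_variants(m$ref, called), m$alt)
  }
})

test_that("frameshift prediction agrees with a translate-and-compare oracle", {
  skip_if_not_installed("seqinr")
  n_cases <- 120
  for (case in seq_len(n_cases)) {
    sd <- 1000 + case
    n_codons <- withr::with_seed(sd, sample(60:140, 1))
    cds <- generate_cds(n_codons, seed = sd)
    is_ins <- withr::with_seed(sd + 1, sample(c(TRUE, FALSE), 1))
    spec <- if (is_ins) list(n_ins = 1, n_del = 0, len_range = c(1, 4))
            else list(n_ins = 0, n_del = 1, len_range = c(1, 4))
    m <- mutate_cds(cds, n_subs = 0, indel_spec = spec, seed = sd + 2)
    called <- align_cds_pair(m$ref, m$alt)
    eff <- frameshift_effect(called, m$ref)
    # oracle route: translate both raw sequences with an independent library
    tr <- function(x) {
      n <- nchar(x) - nchar(x) %% 3
      seqinr::translate(strsplit(tolower(substr(x, 1, n)), "")[[1]], numcode = 11)
    }
    aa_ref <- tr(m$ref); aa_alt <- tr(m$alt)
    expect_identical(eff$frameshift,
                     (nchar(m$alt) - nchar(m$ref)) %% 3 != 0)
    if (eff$frameshift) {
      fc <- eff$first_affected_codon
      if (fc > 1) expect_identical(aa_alt[seq_len(fc - 1)],
                                   aa_ref[seq_len(fc - 1)])
      ref_stop <- c(which(aa_ref == "*"), length(aa_ref) + 1L)[1]
      alt_stop <- which(aa_alt == "*")
      oracle_stop <- if (length(alt_stop) && alt_stop[1] < ref_stop)
        alt_stop[1] else NA_integer_
      expect_identical(eff$premature_stop_codon, oracle_stop)
    }
  }
})

test_that("difference-site counting matches hand counts and is label-symmetric", {
  expect_identical(count_diff_sites(c(a = "MKLVST", b = "MKLVST",
                                      c = "MKLVST"))$diff_sites, 0L)
  one <- count_diff_sites(c(a = "MKLVST", b = "MKIVST", c = "MKLVST"))
  expect_identical(one$diff_sites, 1L)
  expect_identical(one$aligned_length, 6L)
  # a gap column counts as a difference
  gapd <- count_diff_sites(c(a = "MKLVVST", b = "MKLVST", c = "MKLVST"))
  expect_identical(gapd$diff_sites, 1L)
  # symmetric under strain relabeling
  seqs <- c(x = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
            y = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVA",
            z = "MKTAYIGKQRQISFVKSHFSRQLEERLGLIEVQ")
  a <- count_diff_sites(seqs)$diff_sites
  b <- count_diff_sites(seqs[c(3, 1, 2)])$diff_sites
  expect_identical(a, b)
  expect_identical(a, 2L)  # columns 7 and 33 disagree somewhere
  # a strain missing the gene is excluded and noted
  mis <- count_diff_sites(c(a = "MKLVST", b = "MKIVST", c = ""))
  expect_identical(mis$excluded, "c")
  expect_identical(mis$diff_sites, 1L)
  expect_error(count_diff_sites(c(a = "MKL", b = "")), "two strains")
})

test_that("the repeated upstream octamer is found with four copies", {
  flank <- withr::with_seed(50, paste(sample(c("A", "C", "G", "T"), 40,
                                             replace = TRUE), collapse = ""))
  seq <- paste0(flank, strrep("CCCGTTTC", 4), "AAGG")
  hits <- find_tandem_repeats(seq, 8, 16)
  hit <- hits[hits$motif == "CCCGTTTC", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$copies, 4L)
  expect_identical(hit$start, 40L)
  expect_identical(hit$span_bp, 32L)
})

test_that("planted repeat arrays are recovered exactly and maximally", {
  pr <- plant_repeats(n = 100, seed = 9)
  hits <- find_tandem_repeats(pr$sequence, 8, 16)
  merged <- merge(pr$truth, hits, by = c("motif", "unit_length", "start"))
  expect_identical(nrow(merged), 100L)
  expect_identical(merged$copies.x, merged$copies.y)
  # maximality: one more unit on either side breaks exact identity
  s <- pr$sequence
  for (i in sample(nrow(hits), 10)) {
    u <- hits$unit_length[i]; st <- hits$start[i]; sp <- hits$span_bp[i]
    left_ext <- substring(s, st - u + 1, st)
    right_ext <- substring(s, st + sp + 1, st + sp + u)
    if (st - u >= 0) expect_false(identical(left_ext, hits$motif[i]))
    if (st + sp + u <= nchar(s)) expect_false(identical(right_ext, hits$motif[i]))
  }
})

test_that("a repeat-free random sequence yields no 8-16 bp arrays", {
  seq <- withr::with_seed(60, paste(sample(c("A", "C", "G", "T"), 300,
                                           replace = TRUE), collapse = ""))
  expect_identical(nrow(find_tandem_repeats(seq, 8, 16)), 0L)
})

test_that("intergenic regions measure the half-open separation", {
  genome <- tiny_genome(strrep("ACGT", 100))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"), locus_tag = "", replicon_id = "chr",
    start = c(0L, 104L, 90L), end = c(100L, 200L, 150L),
    strand = "+", feature_kind = "CDS", product = "", pseudo = FALSE,
    compound = FALSE, stringsAsFactors = FALSE)
  r <- intergenic_region(genes, "gA", "gB", genome)
  expect_identical(r$length, 4L)
  expect_identical(nchar(r$sequence), 4L)
  ovl <- intergenic_region(genes, "gA", "gC", genome)
  expect_identical(ovl$length, 0L)
  expect_identical(ovl$separation, -10L)
  genes2 <- genes; genes2$replicon_id[2] <- "other"
  expect_error(intergenic_region(genes2, "gA", "gB", genome),
               "different replicons")
})
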