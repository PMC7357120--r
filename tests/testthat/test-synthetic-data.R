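test_that("genome generation hits the requested GC and is seed-deterministic", {
  g <- generate_genome(100000, 0.725, seed = 1)
  expect_identical(Biostrings::width(g), 100000L)
  expect_lt(abs(sequence_stats(g)$gc_percent - 72.5), 0.5)
  g2 <- generate_genome(100000, 0.725, seed = 1)
  expect_identical(as.character(g[[1]]), as.character(g2[[1]]))
  expect_false(identical(as.character(generate_genome(10000, 0.725, 2)[[1]]),
                         as.character(generate_genome(10000, 0.725, 3)[[1]])))
  expect_error(generate_genome(10000, 1.0, 1), "strictly inside")
  expect_error(generate_genome(100, 0.5, 1), ">= 1000")
})

test_that("assembly degradation plants what its truth table says", {
  ref <- generate_genome(60000, 0.725, seed = 6)
  d <- degrade_assembly(ref, seed = 6)
  tr <- d$truth
  expect_identical(nrow(tr$planted_gaps), 10L)
  expect_identical(nrow(tr$planted_overlaps), 5L)
  # equal-length mode: N-run length equals the replaced length
  expect_identical(tr$planted_gaps$nrun_bp, tr$planted_gaps$length)
  # N-runs appear verbatim in the draft; singleton census closes the loop
  cen <- scan_ambiguities(d$draft)
  expect_identical(cen$counts[c("M", "S", "K")], c(M = 2L, S = 3L, K = 1L))
  expect_identical(unname(cen$counts["N"]),
                   sum(tr$planted_gaps$nrun_bp) +
                     sum(tr$planted_overlaps$nrun_bp))
  # gap sites are disjoint and at least 1 kb apart
  gs <- sort(c(tr$planted_gaps$ref_start, tr$planted_overlaps$ref_boundary))
  expect_true(all(diff(gs) >= 1000L))
  # deterministic under the seed
  d2 <- degrade_assembly(ref, seed = 6)
  expect_identical(as.character(d$draft[[1]]), as.character(d2$draft[[1]]))
})

test_that("gap length jitter decouples N-run length from true gap length", {
  ref <- generate_genome(40000, 0.725, seed = 8)
  d <- degrade_assembly(ref, n_gaps = 3, n_overlaps = 0, gap_len_jitter = 25,
                        ambiguity_singletons = integer(0), seed = 8)
  tr <- d$truth$planted_gaps
  expect_identical(tr$nrun_bp, tr$length + 25L)
  pl <- place_fragments(fragment_at_undetermined(d$draft), d$draft, ref)
  adj <- adjacency_accounting(pl)
  g <- adj$reports[adj$reports$relation == "gap", ]
  # measured gap on the reference is the true length, not the N-run length
  expect_identical(sum(g$length_bp), sum(tr$length))
  expect_identical(g$draft_n_run_bp, g$length_bp + 25L)
})

test_that("annotation perturbation respects its mix and rejects impossible ones", {
  g <- generate_genome(30000, 0.725, seed = 10)
  genes <- generate_genes(g, 20, seed = 10)
  ann <- perturb_annotation(genes, c(Long = 3, Short = 3), seed = 1)
  expect_identical(sum(ann$truth == "Long"), 3L)
  expect_identical(sum(ann$truth == "Identical"), 14L)
  # empty mix leaves everything Identical
  ann0 <- perturb_annotation(genes, c(Long = 0), seed = 1)
  expect_true(all(ann0$truth == "Identical"))
  expect_identical(ann0$draft_genes$start, genes$start)
  expect_error(perturb_annotation(genes, c(Long = 50)), "only 20")
})

test_that("CDS mutation presets and edge cases behave", {
  m0 <- mutate_cds(generate_cds(100, 1), n_subs = 0)
  expect_identical(m0$alt, m0$ref)
  expect_identical(nrow(m0$edits), 0L)
  p1 <- mutate_cds(preset = "cmlI_case")
  p2 <- mutate_cds(preset = "cmlI_case")
  expect_identical(p1$ref, p2$ref)
  expect_error(mutate_cds(preset = "nope"), "unknown preset")
  expect_error(mutate_cds(NULL, n_subs = 1), "cds is required")
  # planted edits always reproduce the alternate sequence
  m <- mutate_cds(generate_cds(200, 3), n_subs = 10,
                  indel_spec = list(n_ins = 2, n_del = 2, len_range = c(1, 3)),
                  seed = 3)
  expect_identical(apply_variants(m$ref, m$edits), m$alt)
})

test_that("planted repeat truth refers to real positions in the sequence", {
  pr <- plant_repeats(n = 20, seed = 2)
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    expect_identical(substring(pr$sequence, tr$start + 1,
                               tr$start + tr$span_bp),
                     strrep(tr$motif, tr$copies))
  }
})

test_that("the full strain-pair preset emits coherent files and truth", {
  dir <- withr::local_tempdir()
  sim <- simulate_strain_pair(seed = 2, genome_length = 60000L, n_genes = 40L,
                              mix = c(Long = 5, Short = 5, Moved = 5,
                                      New = 5, Missing = 5),
                              out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("reference.fa", "draft.fa", "ref.gff3", "draft.gff3",
      "bgc_ref.tsv", "bgc_draft.tsv", "cds_pair.fa", "repeat_region.fa",
      "truth.json")))))
  # files read back to the in-memory objects
  expect_identical(as.character(read_genome(file.path(dir, "reference.fa"))[[1]]),
                   as.character(sim$reference[[1]]))
  genes <- read_annotation(file.path(dir, "ref.gff3"))
  expect_identical(genes$start, sim$ref_genes$start)
  bgc <- parse_bgc_table(file.path(dir, "bgc_ref.tsv"))
  expect_identical(sort(unique(bgc$cluster_id)),
                   sort(names(sim$truth$bgc_labels)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$schema_version, 1L)
  expect_identical(length(truth$gene_labels), length(sim$truth$gene_labels))
})
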