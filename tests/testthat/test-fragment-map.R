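test_that("fragmentation breaks only at maximal N-runs", {
  fr <- fragment_at_undetermined(tiny_genome("AAANNNCCC"))
  expect_identical(fr$draft_start, c(0L, 6L))
  expect_identical(fr$draft_end, c(3L, 9L))
  expect_identical(fr$preceding_nrun_bp, c(NA_integer_, 3L))

  single <- fragment_at_undetermined(tiny_genome("ACGT"))
  expect_identical(nrow(single), 1L)
  expect_identical(single$draft_end, 4L)

  # isolated non-N ambiguity codes do not break fragments
  amb <- fragment_at_undetermined(tiny_genome("AAMSKCC"))
  expect_identical(nrow(amb), 1L)

  # leading/trailing runs yield no empty fragments
  edge <- fragment_at_undetermined(tiny_genome("NNACGTNN"))
  expect_identical(nrow(edge), 1L)
  expect_identical(edge$preceding_nrun_bp, 2L)

  expect_warning(none <- fragment_at_undetermined(tiny_genome("NNNN")),
                 "entirely undetermined")
  expect_identical(nrow(none), 0L)
})

test_that("fragment count equals maximal N-run count plus one without terminal runs", {
  ref <- generate_genome(40000, 0.7, seed = 5)
  d <- degrade_assembly(ref, n_gaps = 6, n_overlaps = 2, seed = 5)
  s <- as.character(d$draft[[1]])
  # independent regex scan of maximal N-runs
  m <- gregexpr("N+", s)[[1]]
  n_runs <- if (m[1] == -1L) 0L else length(m)
  fr <- fragment_at_undetermined(d$draft)
  expect_identical(nrow(fr), n_runs + 1L)
})

test_that("fragments plus recorded N-runs reconstruct the draft exactly", {
  for (s in 1:3) {
    ref <- generate_genome(30000, 0.725, seed = s)
    d <- degrade_assembly(ref, n_gaps = 3, n_overlaps = 2, seed = s)
    fr <- fragment_at_undetermined(d$draft)
    expect_identical(reconstruct_draft(fr, d$draft, names(d$draft)[1]),
                     as.character(d$draft[[1]]))
  }
})

test_that("an exact unique substring places with zero clips and identity 1", {
  ref <- generate_genome(10000, 0.5, seed = 3)
  s <- as.character(ref[[1]])
  frag <- substring(s, 2001, 2500)
  draft <- tiny_genome(frag, "d")
  fr <- fragment_at_undetermined(draft)
  pl <- place_fragments(fr, draft, ref)
  expect_true(pl$mapped)
  expect_identical(pl$ref_start, 2000L)
  expect_identical(pl$ref_end, 2500L)
  expect_identical(pl$strand, "+")
  expect_identical(pl$left_clip_bp + pl$right_clip_bp, 0L)
  expect_identical(pl$identity_fraction, 1)
})

test_that("reverse-complement fragments place on the minus strand at the same locus", {
  ref <- generate_genome(10000, 0.5, seed = 3)
  s <- as.character(ref[[1]])
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(s, 2001, 2500))))
  draft <- tiny_genome(rc, "d")
  pl <- place_fragments(fragment_at_undetermined(draft), draft, ref)
  expect_true(pl$mapped)
  expect_identical(pl$strand, "-")
  expect_identical(pl$ref_start, 2000L)
  expect_identical(pl$ref_end, 2500L)
})

test_that("a fragment without any seed match in the reference stays unmapped", {
  ref <- generate_genome(10000, 0.5, seed = 3)
  alien <- generate_genome(1000, 0.5, seed = 99, id = "alien")
  pl <- place_fragments(fragment_at_undetermined(alien), alien, ref)
  expect_false(pl$mapped)
  expect_match(pl$reason, "no_seed_match|below_thresholds")
})

test_that("raising the similarity fraction never increases the mapped count", {
  ref <- generate_genome(30000, 0.725, seed = 7)
  # draft with heavy substitution noise in part of the genome
  s <- strsplit(as.character(ref[[1]]), "")[[1]]
  idx <- withr::with_seed(7, sample(5000:15000, 2000))
  s[idx] <- withr::with_seed(8, vapply(s[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), ""))
  draft <- tiny_genome(paste(ifelse(seq_along(s) %in% c(10000:10050), "N", s),
                             collapse = ""), "d")
  fr <- fragment_at_undetermined(draft)
  counts <- vapply(c(0.5, 0.8, 0.99), function(sf) {
    p <- alignment_params(similarity_fraction = sf)
    sum(place_fragments(fr, draft, ref, p)$mapped)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("placement is deterministic under a fixed seed, including ties", {
  # reference with an exact duplicated segment: two equal-scoring loci
  core <- as.character(generate_genome(2000, 0.5, seed = 11)[[1]])
  spacer <- as.character(generate_genome(3000, 0.5, seed = 12)[[1]])
  ref <- tiny_genome(paste0(spacer, core, spacer, core), "chr")
  draft <- tiny_genome(core, "d")
  fr <- fragment_at_undetermined(draft)
  p1 <- place_fragments(fr, draft, ref, alignment_params(seed = 5))
  p2 <- place_fragments(fr, draft, ref, alignment_params(seed = 5))
  expect_identical(p1, p2)
  expect_identical(p1$n_best, 2L)
  expect_true(p1$ref_start %in% c(3000L, 8000L))
  # the drop policy leaves ambiguous fragments unmapped
  pd <- place_fragments(fr, draft, ref,
                        alignment_params(nonspecific_policy = "drop"))
  expect_false(pd$mapped)
  expect_identical(pd$reason, "ambiguous")
})

test_that("adjacency arithmetic classifies gap, overlap and abutting pairs", {
  gap <- adjacency_accounting(manual_placements(c(0L, 110L), c(100L, 200L)))
  expect_identical(gap$reports$relation, "gap")
  expect_identical(gap$reports$length_bp, 10L)
  expect_identical(gap$summary$gap_total_bp, 10L)

  ovl <- adjacency_accounting(manual_placements(c(0L, 95L), c(100L, 200L)))
  expect_identical(ovl$reports$relation, "overlap")
  expect_identical(ovl$reports$length_bp, 5L)

  ab <- adjacency_accounting(manual_placements(c(0L, 100L), c(100L, 200L)))
  expect_identical(ab$reports$relation, "abutting")
  expect_identical(ab$summary$gap_count + ab$summary$overlap_count, 0L)

  # unmapped neighbours are unresolved and excluded from both summaries
  un <- manual_placements(c(0L, 110L), c(100L, 200L))
  un$mapped[2] <- FALSE
  res <- adjacency_accounting(un)
  expect_identical(res$reports$relation, "unresolved")
  expect_identical(res$summary$gap_count, 0L)

  # opposite-strand neighbours are unresolved too
  st <- manual_placements(c(0L, 110L), c(100L, 200L))
  st$strand[2] <- "-"
  expect_identical(adjacency_accounting(st)$reports$relation, "unresolved")
})

test_that("equal-length N-run gaps are recovered exactly, count and total", {
  ref <- generate_genome(30000, 0.725, seed = 2)
  d <- degrade_assembly(ref, n_gaps = 3, n_overlaps = 0,
                        ambiguity_singletons = integer(0), seed = 2)
  pl <- place_fragments(fragment_at_undetermined(d$draft), d$draft, ref)
  adj <- adjacency_accounting(pl)
  expect_identical(adj$summary$gap_count, d$truth$expected$gap_count)
  expect_identical(adj$summary$gap_total_bp, d$truth$expected$gap_total_bp)
  # equal-length mode: each gap length equals its draft N-run length
  g <- adj$reports[adj$reports$relation == "gap", ]
  expect_identical(g$length_bp, g$draft_n_run_bp)
  # BED export covers the same intervals
  bed <- gap_bed(pl, adj)
  expect_identical(nrow(bed), 3L)
  expect_identical(sum(bed$end - bed$start), adj$summary$gap_total_bp)
})
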