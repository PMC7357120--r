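test_that("BGC TSV parsing validates schema, roles and core presence", {
  tab <- tiny_bgc_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  parsed <- parse_bgc_table(path)
  expect_identical(nrow(parsed), 2L)
  expect_identical(parsed$role, c("core_biosynthetic", "regulatory"))
  expect_identical(parsed$start, c(1000L, 1000L))

  # unknown role maps to "other" with a warning
  tab2 <- tab; tab2$role[2] <- "mystery"
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(p2 <- parse_bgc_table(path), "other")
  expect_identical(p2$role[2], "other")

  # missing column is a format error
  write.table(tab[, -1], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_bgc_table(path), "cluster_id")

  # cluster without a core gene errors unless partial records are allowed
  tab3 <- tab; tab3$role <- c("regulatory", "transport")
  write.table(tab3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_bgc_table(path), "bgcX")
  expect_identical(nrow(parse_bgc_table(path, allow_partial = TRUE)), 2L)
})

test_that("antiSMASH-style region GenBank maps gene_kind onto roles", {
  gbk <- write_genbank_tmp()
  tab <- parse_bgc_table(gbk, format = "antismash_region_genbank")
  expect_identical(tab$role[tab$gene_id == "t0002"], "core_biosynthetic")
  expect_identical(tab$role[tab$gene_id == "t0001"], "other")
})

test_that("protein matching finds identical and diverged homologs, not noise", {
  withr::with_seed(41, {
    targets <- setNames(
      vapply(sample(150:250, 12, replace = TRUE),
             function(n) paste(c("M", sample(strainlift:::AA20, n - 1,
                                             replace = TRUE)), collapse = ""),
             ""),
      sprintf("t%02d", 1:12))
  })
  # identical protein: identity and coverage 1
  hits <- match_proteins(c(q1 = targets[[3]]), targets)
  expect_identical(hits$hit, "t03")
  expect_identical(hits$identity, 1)
  expect_identical(hits$coverage, 1)

  # 80% identity homologs all recovered at the default thresholds
  homs <- vapply(seq_along(targets), function(i)
    mutate_protein(targets[[i]], 0.8, seed = i), "")
  names(homs) <- paste0("q", names(targets))
  res <- match_proteins(homs, targets)
  expect_identical(res$hit, names(targets))
  expect_true(all(res$identity >= 0.7 & res$identity <= 0.92))

  # an unrelated protein finds nothing above the thresholds
  alien <- withr::with_seed(99, paste(c("M", sample(strainlift:::AA20, 180,
                                                    replace = TRUE)),
                                      collapse = ""))
  expect_true(is.na(match_proteins(c(qa = alien), targets)$hit))
})

# shared simulated conservation benchmark
bgc_pair <- simulate_bgc_pair(seed = 3)
bgc_res <- compare_bgc_sets(bgc_pair$bgc_a, bgc_pair$bgc_b,
                            query_chrom_len = 200000L,
                            target_chrom_len = 200000L)

test_that("all planted conservation classes are recovered", {
  expect_identical(setNames(bgc_res$label, bgc_res$query_cluster),
                   bgc_pair$truth)
})

test_that("conservation evidence obeys the label definitions", {
  expect_true(all(bgc_res$core_frac[bgc_res$label %in%
                                      c("Conserved", "ConservedOtherRegion")] == 1))
  pc <- bgc_res[bgc_res$label == "PartiallyConserved", ]
  expect_true(all(pc$core_frac < 1))
  expect_true(all(pc$accessory_frac > 0 |
                    pc$position_relation == "multi_type_region"))
  ss <- bgc_res[bgc_res$label == "StrainSpecific", ]
  expect_identical(ss$target_perspective, "Missing")
  expect_true(all(table(bgc_res$query_cluster) == 1L))  # one label per query
})

test_that("self-comparison calls every cluster Conserved", {
  self <- compare_bgc_sets(bgc_pair$bgc_a, bgc_pair$bgc_a,
                           query_chrom_len = 200000L,
                           target_chrom_len = 200000L)
  expect_true(all(self$label == "Conserved"))
  expect_true(all(self$core_frac == 1))
})

test_that("lowering the identity threshold never turns Conserved into Missing", {
  strict <- compare_bgc_sets(bgc_pair$bgc_a, bgc_pair$bgc_b,
                             params = match_params(min_protein_identity = 0.9),
                             query_chrom_len = 200000L,
                             target_chrom_len = 200000L)
  lax <- compare_bgc_sets(bgc_pair$bgc_a, bgc_pair$bgc_b,
                          params = match_params(min_protein_identity = 0.5),
                          query_chrom_len = 200000L,
                          target_chrom_len = 200000L)
  was_conserved <- strict$query_cluster[strict$label %in%
                                          c("Conserved", "ConservedOtherRegion")]
  now <- setNames(lax$label, lax$query_cluster)[was_conserved]
  expect_false(any(now == "StrainSpecific"))
})
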