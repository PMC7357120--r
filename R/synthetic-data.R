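#' Synthetic strain pairs with known truth
#'
#' Generators for every structure the comparison pipeline classifies: a
#' completed genome; a draft derived from it carrying N-run gaps,
#' duplicated-overlap misassemblies and isolated ambiguity codes; an
#' annotation set perturbed into known categories; planted BGCs mutated
#' into known conservation classes; CDS pairs with planted edits; and
#' regions with planted tandem repeats. Every generator is deterministic
#' under its seed and returns a machine-readable truth table.
#'
#' @name synthetic_data
NULL

#' Generate a random genome sequence
#'
#' I.i.d. bases at the stated GC content (high-GC actinomycete-like
#' defaults elsewhere in the package use 0.725).
#'
#' @param length sequence length in bp (>= 1000).
#' @param gc GC fraction in (0, 1) exclusive.
#' @param seed integer seed.
#' @param id replicon id.
#' @return single-replicon `DNAStringSet`.
#' @export
generate_genome <- function(length, gc = 0.725, seed = 1L, id = "chr") {
  if (gc <= 0 || gc >= 1) stopf("gc must be strictly inside (0, 1)")
  if (length < 1000L) stopf("genome length must be >= 1000 bp")
  s <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                                    prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                             (1 - gc) / 2)),
                             collapse = ""))
  make_genome_set(s, id)
}

#' Generate a non-overlapping gene annotation on a genome
#'
#' Genes are laid down left to right with random lengths and spacers;
#' strands are random. Errors if the requested number does not fit.
#'
#' @param genome single-replicon `DNAStringSet`.
#' @param n_genes number of genes.
#' @param gene_len_range,spacer_range length ranges in bp.
#' @param seed integer seed.
#' @return gene-model data frame.
#' @export
generate_genes <- function(genome, n_genes, gene_len_range = c(300L, 900L),
                           spacer_range = c(200L, 400L), seed = 1L) {
  L <- Biostrings::width(genome)[1]
  rep_id <- names(genome)[1]
  with_seed(seed, {
    lens <- sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE)
    spacers <- sample(spacer_range[1]:spacer_range[2], n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    starts <- integer(n_genes)
    cur <- 500L
    for (i in seq_len(n_genes)) {
      cur <- cur + spacers[i]
      starts[i] <- cur
      cur <- cur + lens[i]
    }
    if (cur + 500L > L)
      stopf("%d genes need %d bp but the genome has %d", n_genes, cur + 500L, L)
    data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)), locus_tag = "",
      replicon_id = rep_id, start = starts, end = starts + lens,
      strand = strands, feature_kind = "CDS", product = "",
      pseudo = FALSE, compound = FALSE, stringsAsFactors = FALSE
    )
  })
}

#' Degrade a completed genome into a draft with known misassemblies
#'
#' Gaps are disjoint reference segments replaced by N-runs (equal length
#' by default; `gap_len_jitter` decouples the run length from the true gap
#' length). Overlaps duplicate a segment across an adjacent fragment
#' boundary, separated by a short bookkeeping N-run. Isolated ambiguity
#' singletons (M/S/K) are substituted at positions well away from any
#' N-run. All planted features keep at least `spacing` bp apart so
#' fragment placements cannot interact.
#'
#' @param reference single-replicon `DNAStringSet`.
#' @param n_gaps,gap_len_range number and bp range of N-gap events.
#' @param n_overlaps,overlap_len_range number and bp range of duplicated
#'   overlaps.
#' @param ambiguity_singletons named integer vector of isolated codes to
#'   plant, e.g. `c(M = 2, S = 3, K = 1)`.
#' @param overlap_nrun_bp N-run length planted at each overlap boundary.
#' @param gap_len_jitter extra N bases added to each gap's run beyond the
#'   replaced length (0 = equal-length mode).
#' @param spacing minimum distance between planted events.
#' @param seed integer seed.
#' @return list with `draft` (`DNAStringSet`) and `truth` (list with
#'   `planted_gaps`, `planted_overlaps`, `singletons` and an `expected`
#'   gap/overlap summary).
#' @export
degrade_assembly <- function(reference, n_gaps = 10L,
                             gap_len_range = c(50L, 500L),
                             n_overlaps = 5L,
                             overlap_len_range = c(50L, 200L),
                             ambiguity_singletons = c(M = 2L, S = 3L, K = 1L),
                             overlap_nrun_bp = 10L, gap_len_jitter = 0L,
                             spacing = 1000L, seed = 1L) {
  s <- as.character(reference[[1]])
  L <- nchar(s)
  rep_id <- names(reference)[1]
  n_ev <- n_gaps + n_overlaps
  margin <- 2000L
  guard <- spacing + max(gap_len_range[2], overlap_len_range[2]) + overlap_nrun_bp
  gap_len_jitter <- as.integer(gap_len_jitter)
  slack <- (L - 2L * margin) - (n_ev - 1L) * guard
  if (slack <= n_ev) stopf("%d events with %d bp spacing do not fit in %d bp",
                           n_ev, guard, L)
  with_seed(seed, {
    # guaranteed-spacing placement: sorted draws plus fixed offsets
    pos <- margin + sort(sample.int(slack, n_ev)) +
      (seq_len(n_ev) - 1L) * guard
    kind <- sample(rep(c("gap", "overlap"), c(n_gaps, n_overlaps)))
    glen <- sample(gap_len_range[1]:gap_len_range[2], n_ev, replace = TRUE)
    olen <- sample(overlap_len_range[1]:overlap_len_range[2], n_ev, replace = TRUE)

    pieces <- character(0)
    cur0 <- 0L
    gaps <- list(); ovls <- list()
    for (i in seq_len(n_ev)) {
      q0 <- pos[i]
      pieces <- c(pieces, substring(s, cur0 + 1L, q0))
      if (kind[i] == "gap") {
        g <- glen[i]
        pieces <- c(pieces, strrep("N", g + gap_len_jitter))
        gaps[[length(gaps) + 1L]] <- data.frame(
          ref_start = q0, ref_end = q0 + g, length = g,
          nrun_bp = g + gap_len_jitter)
        cur0 <- q0 + g
      } else {
        o <- olen[i]
        pieces <- c(pieces, strrep("N", overlap_nrun_bp))
        ovls[[length(ovls) + 1L]] <- data.frame(
          ref_boundary = q0, length = o, nrun_bp = overlap_nrun_bp)
        cur0 <- q0 - o
      }
    }
    pieces <- c(pieces, substring(s, cur0 + 1L, L))
    draft_seq <- paste(pieces, collapse = "")

    # isolated ambiguity singletons, >= 100 bp from any N and from the ends
    singles <- data.frame(draft_pos = integer(), code = character(),
                          stringsAsFactors = FALSE)
    codes <- rep(names(ambiguity_singletons), ambiguity_singletons)
    if (length(codes)) {
      npos <- gregexpr("N", draft_seq, fixed = TRUE)[[1]]
      npos <- if (npos[1] == -1L) integer(0) else as.integer(npos)
      dlen <- nchar(draft_seq)
      taken <- integer(0)
      dc <- strsplit(draft_seq, "")[[1]]
      for (code in codes) {
        repeat {
          cand <- sample(seq(200L, dlen - 200L), 1L)
          if ((length(npos) == 0L || min(abs(npos - cand)) >= 100L) &&
              (length(taken) == 0L || min(abs(taken - cand)) >= 100L)) break
        }
        taken <- c(taken, cand)
        dc[cand] <- code
        singles <- rbind(singles, data.frame(draft_pos = cand - 1L, code = code,
                                             stringsAsFactors = FALSE))
      }
      draft_seq <- paste(dc, collapse = "")
    }

    gaps_df <- if (length(gaps)) do.call(rbind, gaps) else
      data.frame(ref_start = integer(), ref_end = integer(),
                 length = integer(), nrun_bp = integer())
    ovls_df <- if (length(ovls)) do.call(rbind, ovls) else
      data.frame(ref_boundary = integer(), length = integer(),
                 nrun_bp = integer())
    list(
      draft = make_genome_set(draft_seq, paste0(rep_id, "_draft")),
      truth = list(
        planted_gaps = gaps_df, planted_overlaps = ovls_df,
        singletons = singles, seed = seed,
        expected = list(gap_count = nrow(gaps_df),
                        gap_total_bp = sum(gaps_df$length),
                        overlap_count = nrow(ovls_df),
                        overlap_total_bp = sum(ovls_df$length))
      )
    )
  })
}

#' Perturb an annotation set into known categories
#'
#' Builds a draft annotation from a reference one so that each reference
#' gene's intended category is known: Long genes are truncated in the
#' draft, Short genes extended, Moved genes shifted at both ends keeping
#' more than half overlap, New genes deleted from the draft, and Missing
#' genes added as draft-only models in intergenic space; everything else
#' stays Identical.
#'
#' @param genes reference gene-model data frame (from [generate_genes()]).
#' @param mix named counts per class, e.g.
#'   `c(Long = 40, Short = 40, Moved = 40, New = 40, Missing = 40)`.
#' @param shift_range bp range for end shifts.
#' @param moved_overlap optional forced overlap fraction for Moved genes
#'   (used to probe the 50% rule boundary); default keeps it in
#'   (0.55, 0.9).
#' @param seed integer seed.
#' @return list with `draft_genes` and `truth` (named label vector over
#'   all gene ids, reference and draft-only).
#' @export
perturb_annotation <- function(genes, mix, shift_range = c(30L, 90L),
                               moved_overlap = NULL, seed = 1L) {
  mix <- mix[intersect(names(mix), c("Long", "Short", "Moved", "New", "Missing"))]
  n_assign <- sum(mix[setdiff(names(mix), "Missing")])
  if (n_assign > nrow(genes))
    stopf("mix asks for %d perturbed genes but only %d exist", n_assign,
          nrow(genes))
  with_seed(seed, {
    labels <- setNames(rep("Identical", nrow(genes)), genes$gene_id)
    pool <- sample(genes$gene_id, n_assign)
    off <- 0L
    for (cls in c("Long", "Short", "Moved", "New")) {
      k <- if (cls %in% names(mix)) mix[[cls]] else 0L
      if (k > 0L) labels[pool[(off + 1L):(off + k)]] <- cls
      off <- off + k
    }
    draft <- genes
    draft$gene_id <- sub("^gene_", "draft_", draft$gene_id)
    drop <- logical(nrow(draft))
    for (i in seq_len(nrow(genes))) {
      cls <- labels[[genes$gene_id[i]]]
      len <- genes$end[i] - genes$start[i]
      if (cls == "Identical") next
      if (cls == "New") { drop[i] <- TRUE; next }
      s <- sample(shift_range[1]:shift_range[2], 1L)
      if (cls == "Long") {            # draft copy truncated
        if (sample(2L, 1L) == 1L) draft$start[i] <- genes$start[i] + s
        else draft$end[i] <- genes$end[i] - s
      } else if (cls == "Short") {    # draft copy extended
        if (sample(2L, 1L) == 1L) draft$start[i] <- genes$start[i] - s
        else draft$end[i] <- genes$end[i] + s
      } else {                        # Moved: both ends shifted, length kept
        sh <- if (!is.null(moved_overlap)) as.integer(round((1 - moved_overlap) * len))
              else as.integer(round(stats::runif(1, 0.1, 0.45) * len))
        sh <- max(sh, 1L) * sample(c(-1L, 1L), 1L)
        draft$start[i] <- genes$start[i] + sh
        draft$end[i] <- genes$end[i] + sh
      }
    }
    draft <- draft[!drop, , drop = FALSE]

    k_mis <- if ("Missing" %in% names(mix)) mix[["Missing"]] else 0L
    if (k_mis > 0L) {
      go <- genes[order(genes$start), ]
      spacer_lo <- utils::head(go$end, -1L)
      spacer_hi <- utils::tail(go$start, -1L)
      wide <- which(spacer_hi - spacer_lo >= 160L)
      if (length(wide) < k_mis)
        stopf("not enough intergenic space for %d Missing genes", k_mis)
      sel <- sort(sample(wide, k_mis))
      extra <- data.frame(
        gene_id = sprintf("draftonly_%04d", seq_len(k_mis)), locus_tag = "",
        replicon_id = genes$replicon_id[1],
        start = spacer_lo[sel] + 10L, end = spacer_lo[sel] + 10L + 120L,
        strand = sample(c("+", "-"), k_mis, replace = TRUE),
        feature_kind = "CDS", product = "", pseudo = FALSE, compound = FALSE,
        stringsAsFactors = FALSE
      )
      draft <- rbind(draft, extra)
      labels <- c(labels, setNames(rep("Missing", k_mis), extra$gene_id))
    }
    rownames(draft) <- NULL
    list(draft_genes = draft, truth = labels)
  })
}

# ---- BGC simulation --------------------------------------------------------

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
# one fixed codon per residue: reverse translation for embedding genes
AA2CODON <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

#' Mutate a protein to a target identity
#'
#' Substitutes residues uniformly so the result has approximately the
#' requested identity to the input; used to plant homologs.
#'
#' @param protein amino-acid string.
#' @param identity target identity fraction.
#' @param seed integer seed.
#' @return mutated amino-acid string.
#' @export
mutate_protein <- function(protein, identity = 0.8, seed = 1L) {
  with_seed(seed, {
    p <- strsplit(protein, "")[[1]]
    k <- round((1 - identity) * length(p))
    if (k > 0L) {
      idx <- sample(seq_along(p), k)
      p[idx] <- vapply(p[idx], function(a) sample(setdiff(AA20, a), 1L), "")
    }
    paste(p, collapse = "")
  })
}

make_cluster_genes <- function(cluster_id, n_core = 3L, n_add = 2L,
                               n_reg = 2L, n_tra = 1L,
                               prot_len_range = c(120L, 260L)) {
  roles <- rep(c("core_biosynthetic", "additional_biosynthetic", "regulatory",
                 "transport"), c(n_core, n_add, n_reg, n_tra))
  n <- length(roles)
  data.frame(
    gene_id = sprintf("%s_g%02d", cluster_id, seq_len(n)),
    role = roles,
    protein_seq = unname(vapply(sample(prot_len_range[1]:prot_len_range[2], n,
                                       replace = TRUE),
                                random_protein, "")),
    stringsAsFactors = FALSE
  )
}

# Write a cluster's genes into a genome sequence at `at0` (0-based) and
# return its BGC table rows.
plant_cluster <- function(seq_chr, genes, cluster_id, genome_id, replicon_id,
                          product_type, at0) {
  nts <- unname(vapply(genes$protein_seq, function(p) {
    paste(AA2CODON[strsplit(p, "")[[1]]], collapse = "")
  }, ""))
  spacer <- 50L
  cur <- at0
  for (g in seq_along(nts)) {
    substr(seq_chr, cur + 1L, cur + nchar(nts[g])) <- nts[g]
    cur <- cur + nchar(nts[g]) + spacer
  }
  span_end <- cur - spacer
  list(seq = seq_chr, rows = data.frame(
    cluster_id = cluster_id, genome_id = genome_id, replicon_id = replicon_id,
    start = at0, end = span_end, product_type = product_type,
    gene_id = genes$gene_id, role = genes$role,
    protein_seq = genes$protein_seq, stringsAsFactors = FALSE
  ))
}

#' Plant one BGC in a genome pair under a known mutation
#'
#' The cluster is written into genome A intact; its copy in genome B is
#' transformed by `mutation`: `"none"` keeps it (Conserved),
#' `"delete_core"` keeps everything but the core genes and
#' `"keep_accessory_only"` keeps only the regulatory genes (both
#' PartiallyConserved), `"relocate"` moves the intact cluster into a
#' terminal region of B (ConservedOtherRegion), and `"delete_all"`
#' removes it (StrainSpecific).
#'
#' @param cluster_id cluster name.
#' @param genes cluster gene table from `make_cluster_genes()` (or the
#'   same schema).
#' @param mutation one of `"none"`, `"delete_core"`,
#'   `"keep_accessory_only"`, `"relocate"`, `"delete_all"`.
#' @param seq_a,seq_b genome sequences (character) to write into.
#' @param at_a 0-based position of the cluster in genome A.
#' @param at_b position in genome B (ignored for `"relocate"`, which picks
#'   the 3' terminal region, and `"delete_all"`).
#' @param product_type cluster product label.
#' @param genome_ids length-2 character: ids of genomes A and B.
#' @return list: updated `seq_a`, `seq_b`, `rows_a`, `rows_b` (possibly
#'   `NULL`), `expected_label`.
#' @export
plant_bgc <- function(cluster_id, genes, mutation, seq_a, seq_b, at_a, at_b,
                      product_type, genome_ids = c("genomeA", "genomeB")) {
  mutation <- match.arg(mutation, c("none", "delete_core",
                                    "keep_accessory_only", "relocate",
                                    "delete_all"))
  pa <- plant_cluster(seq_a, genes, cluster_id, genome_ids[1], genome_ids[1],
                      product_type, at_a)
  seq_a <- pa$seq
  keep <- switch(mutation,
    none = , relocate = rep(TRUE, nrow(genes)),
    delete_core = genes$role != "core_biosynthetic",
    keep_accessory_only = genes$role == "regulatory",
    delete_all = rep(FALSE, nrow(genes))
  )
  expected <- switch(mutation,
    none = "Conserved", relocate = "ConservedOtherRegion",
    delete_core = , keep_accessory_only = "PartiallyConserved",
    delete_all = "StrainSpecific"
  )
  rows_b <- NULL
  if (any(keep)) {
    gb <- genes[keep, , drop = FALSE]
    gb$gene_id <- sub(paste0("^", cluster_id), paste0(cluster_id, "B"), gb$gene_id)
    at <- if (mutation == "relocate")
      nchar(seq_b) - as.integer(0.05 * nchar(seq_b)) -
        sum(nchar(gb$protein_seq) * 3L + 50L)
      else at_b
    ptype_b <- if (mutation %in% c("delete_core", "keep_accessory_only"))
      paste0(product_type, "_like_hybrid") else product_type
    pb <- plant_cluster(seq_b, gb, paste0(cluster_id, "_B"), genome_ids[2],
                        genome_ids[2], ptype_b, at)
    seq_b <- pb$seq
    rows_b <- pb$rows
  }
  list(seq_a = seq_a, seq_b = seq_b, rows_a = pa$rows, rows_b = rows_b,
       expected_label = expected)
}

#' Simulate a two-genome BGC conservation benchmark
#'
#' Plants one cluster per conservation class (plus a second Conserved
#' control and a target-only decoy cluster) across a synthetic genome
#' pair.
#'
#' @param seed integer seed.
#' @param genome_length length of each genome in bp.
#' @return list: `genome_a`, `genome_b` (`DNAStringSet`), `bgc_a`,
#'   `bgc_b` (BGC tables), `truth` (named expected-label vector).
#' @export
simulate_bgc_pair <- function(seed = 3L, genome_length = 200000L) {
  with_seed(derive_seed(seed, 31L), {
    seq_a <- as.character(generate_genome(genome_length, 0.725,
                                          derive_seed(seed, 1L), "genomeA")[[1]])
    seq_b <- as.character(generate_genome(genome_length, 0.725,
                                          derive_seed(seed, 2L), "genomeB")[[1]])
    mutations <- c(bgc1 = "none", bgc2 = "none",
                   bgc3 = "keep_accessory_only", bgc4 = "relocate",
                   bgc5 = "delete_all", bgc6 = "delete_core")
    types <- c("ectoine", "T1PKS", "jadomycin_like", "lanthipeptide",
               "chloramphenicol_like", "terpene")
    at <- as.integer(seq(0.25, 0.75, length.out = length(mutations)) *
                       genome_length)
    rows_a <- list(); rows_b <- list(); truth <- character(0)
    for (i in seq_along(mutations)) {
      cid <- names(mutations)[i]
      genes <- make_cluster_genes(cid)
      res <- plant_bgc(cid, genes, mutations[[i]], seq_a, seq_b,
                       at[i], at[i], types[i])
      seq_a <- res$seq_a; seq_b <- res$seq_b
      rows_a[[cid]] <- res$rows_a
      if (!is.null(res$rows_b)) rows_b[[cid]] <- res$rows_b
      truth[cid] <- res$expected_label
    }
    # target-only decoy cluster with its own core genes
    decoy <- make_cluster_genes("decoy")
    pb <- plant_cluster(seq_b, decoy, "decoy_B", "genomeB", "genomeB",
                        "butyrolactone", as.integer(0.15 * genome_length))
    seq_b <- pb$seq
    rows_b[["decoy"]] <- pb$rows
    list(
      genome_a = make_genome_set(seq_a, "genomeA"),
      genome_b = make_genome_set(seq_b, "genomeB"),
      bgc_a = do.call(rbind, c(rows_a, list(make.row.names = FALSE))),
      bgc_b = do.call(rbind, c(rows_b, list(make.row.names = FALSE))),
      truth = truth
    )
  })
}

# ---- CDS variants ----------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a random stop-free CDS
#'
#' @param n_codons total codons including the ATG start and final stop.
#' @param seed integer seed.
#' @return nucleotide string of length `3 * n_codons`.
#' @export
generate_cds <- function(n_codons, seed = 1L) {
  with_seed(seed, {
    all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                        paste0), c("A", "C", "G", "T"), paste0))
    internal <- setdiff(all_codons, STOP_CODONS)
    paste(c("ATG", sample(internal, n_codons - 2L, replace = TRUE), "TAA"),
          collapse = "")
  })
}

#' Plant substitutions and indels in a CDS
#'
#' Edits are spaced at least 8 bp apart and indels are placed in
#' shift-free contexts, so the planted list is already left-normalized
#' and a global alignment of the pair recovers it exactly. The
#' `"cmlI_case"` preset builds a 630 bp CDS and deletes the single
#' cytosine at position 505 (first affected codon 169).
#'
#' @param cds reference CDS (ignored for presets).
#' @param n_subs number of substitutions.
#' @param indel_spec list with `n_ins`, `n_del`, `len_range`.
#' @param seed integer seed.
#' @param preset `NULL` or `"cmlI_case"`.
#' @return list: `ref`, `alt`, `edits` (variant data frame in
#'   [align_cds_pair()] schema).
#' @export
mutate_cds <- function(cds = NULL, n_subs = 0L,
                       indel_spec = list(n_ins = 0L, n_del = 0L,
                                         len_range = c(1L, 3L)),
                       seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    if (preset != "cmlI_case") stopf("unknown preset '%s'", preset)
    ref <- generate_cds(210L, seed = 20200505L)
    # fix codons 168/169 so the C deletion at 505 cannot left-shift
    substr(ref, 502L, 507L) <- "GATCTG"
    edits <- data.frame(kind = "deletion", cds_position = 505L,
                        ref_allele = "C", alt_allele = "", length = 1L,
                        stringsAsFactors = FALSE)
    return(list(ref = ref, alt = apply_variants(ref, edits), edits = edits))
  }
  if (is.null(cds)) stopf("cds is required unless a preset is named")
  ref <- toupper(cds)
  rc <- strsplit(ref, "")[[1]]
  L <- length(rc)
  n_ins <- indel_spec$n_ins %||% 0L
  n_del <- indel_spec$n_del %||% 0L
  len_range <- indel_spec$len_range %||% c(1L, 3L)
  n_ev <- n_subs + n_ins + n_del
  if (n_ev == 0L)
    return(list(ref = ref, alt = ref,
                edits = data.frame(kind = character(), cds_position = integer(),
                                   ref_allele = character(),
                                   alt_allele = character(), length = integer(),
                                   stringsAsFactors = FALSE)))
  with_seed(seed, {
    kinds <- sample(rep(c("substitution", "insertion", "deletion"),
                        c(n_subs, n_ins, n_del)))
    edits <- list()
    taken <- integer(0)
    spacing <- 8L
    for (kind in kinds) {
      for (attempt in 1:500) {
        len <- if (kind == "substitution") 1L
               else sample(len_range[1]:len_range[2], 1L)
        p <- sample(seq(10L, L - 10L - len), 1L)
        if (length(taken) && min(abs(taken - p)) < spacing + len) next
        if (kind == "deletion") {
          # block left/right shifts of the deleted run
          if (rc[p - 1L] == rc[p + len - 1L]) next
          if (rc[p + len] == rc[p]) next
          edits[[length(edits) + 1L]] <- data.frame(
            kind = kind, cds_position = p,
            ref_allele = paste(rc[p:(p + len - 1L)], collapse = ""),
            alt_allele = "", length = len, stringsAsFactors = FALSE)
        } else if (kind == "insertion") {
          ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
          if (ins[len] == rc[p]) next          # no left shift
          if (ins[1] == rc[p + 1L]) next       # no right shift
          edits[[length(edits) + 1L]] <- data.frame(
            kind = kind, cds_position = p, ref_allele = "",
            alt_allele = paste(ins, collapse = ""), length = len,
            stringsAsFactors = FALSE)
        } else {
          alt <- sample(setdiff(c("A", "C", "G", "T"), rc[p]), 1L)
          edits[[length(edits) + 1L]] <- data.frame(
            kind = kind, cds_position = p, ref_allele = rc[p],
            alt_allele = alt, length = 1L, stringsAsFactors = FALSE)
        }
        taken <- c(taken, p)
        break
      }
    }
    edits <- do.call(rbind, edits)
    edits <- edits[order(edits$cds_position), , drop = FALSE]
    rownames(edits) <- NULL
    list(ref = ref, alt = apply_variants(ref, edits), edits = edits)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tandem repeats --------------------------------------------------------

#' Plant exact tandem repeat arrays in a random sequence
#'
#' Arrays use primitive motifs and the flanking bases are chosen so no
#' array extends by a full unit in either direction; the truth table is
#' therefore exactly recoverable.
#'
#' @param n number of arrays.
#' @param unit_range motif length range in bp.
#' @param copies_range copies per array.
#' @param gap_range bp of random background between arrays.
#' @param seed integer seed.
#' @return list: `sequence`, `truth` (data frame in the
#'   [find_tandem_repeats()] schema).
#' @export
plant_repeats <- function(n = 10L, unit_range = c(8L, 16L),
                          copies_range = c(2L, 5L), gap_range = c(40L, 120L),
                          seed = 9L) {
  with_seed(seed, {
    pieces <- character(0)
    truth <- list()
    cur <- 0L
    for (i in seq_len(n)) {
      gap <- sample(gap_range[1]:gap_range[2], 1L)
      bg <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                  collapse = "")
      repeat {
        u <- sample(unit_range[1]:unit_range[2], 1L)
        motif <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
                       collapse = "")
        if (is_primitive_motif(motif)) break
      }
      copies <- sample(copies_range[1]:copies_range[2], 1L)
      # guard flanks: previous base != last motif base, next != first
      last <- substr(motif, u, u); first <- substr(motif, 1L, 1L)
      substr(bg, gap, gap) <- sample(setdiff(c("A", "C", "G", "T"), last), 1L)
      guard <- sample(setdiff(c("A", "C", "G", "T"), first), 1L)
      pieces <- c(pieces, bg, strrep(motif, copies), guard)
      start0 <- cur + gap
      truth[[i]] <- data.frame(motif = motif, unit_length = u,
                               copies = copies, start = start0,
                               span_bp = copies * u, stringsAsFactors = FALSE)
      cur <- start0 + copies * u + 1L
    }
    tail_bg <- paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE),
                     collapse = "")
    list(sequence = paste(c(pieces, tail_bg), collapse = ""),
         truth = do.call(rbind, truth))
  })
}

# ---- full strain-pair preset ----------------------------------------------

#' Simulate a full synthetic strain pair
#'
#' One call builds every benchmark the pipeline consumes: a 200 kb
#' completed genome with 200 genes; a degraded draft (N-run gaps,
#' duplicated overlaps, M/S/K singletons); a category-perturbed draft
#' annotation; a BGC conservation pair; a CDS pair with planted edits;
#' and a repeat-bearing region — all with one truth table.
#'
#' @param seed integer master seed; module seeds derive from it.
#' @param genome_length completed-genome length (default 200 kb).
#' @param n_genes annotated genes (default 200).
#' @param mix category mix for [perturb_annotation()].
#' @param out_dir optional directory: writes `reference.fa`, `draft.fa`,
#'   `ref.gff3`, `draft.gff3`, `bgc_ref.tsv`, `bgc_draft.tsv`,
#'   `cds_pair.fa`, `repeat_region.fa` and `truth.json`.
#' @return list with components `reference`, `draft`, `ref_genes`,
#'   `draft_genes`, `bgc`, `cds`, `repeats`, and `truth`.
#' @export
simulate_strain_pair <- function(seed = 1L, genome_length = 200000L,
                                 n_genes = 200L,
                                 mix = c(Long = 40L, Short = 40L, Moved = 40L,
                                         New = 40L, Missing = 40L),
                                 out_dir = NULL) {
  reference <- generate_genome(genome_length, 0.725, derive_seed(seed, 1L),
                               id = "chr")
  ref_genes <- generate_genes(reference, n_genes, seed = derive_seed(seed, 2L))
  degraded <- degrade_assembly(reference, seed = derive_seed(seed, 3L))
  ann <- perturb_annotation(ref_genes, mix, seed = derive_seed(seed, 4L))
  bgc <- simulate_bgc_pair(seed = derive_seed(seed, 5L))
  cds <- mutate_cds(generate_cds(334L, derive_seed(seed, 6L)), n_subs = 50L,
                    indel_spec = list(n_ins = 1L, n_del = 2L,
                                      len_range = c(1L, 3L)),
                    seed = derive_seed(seed, 7L))
  reps <- plant_repeats(seed = derive_seed(seed, 8L))
  truth <- list(
    schema_version = 1L, seed = seed,
    assembly = degraded$truth,
    gene_labels = as.list(ann$truth),
    bgc_labels = as.list(bgc$truth),
    planted_variants = cds$edits,
    planted_repeats = reps$truth
  )
  sim <- list(reference = reference, draft = degraded$draft,
              ref_genes = ref_genes, draft_genes = ann$draft_genes,
              bgc = bgc, cds = cds, repeats = reps, truth = truth)
  if (!is.null(out_dir)) write_strain_pair(sim, out_dir)
  sim
}

#' Write a simulated strain pair to plain-text files
#'
#' @param sim output of [simulate_strain_pair()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_strain_pair <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$reference, file.path(dir, "reference.fa"))
  write_genome(sim$draft, file.path(dir, "draft.fa"))
  write_annotation(sim$ref_genes, file.path(dir, "ref.gff3"))
  write_annotation(sim$draft_genes, file.path(dir, "draft.gff3"))
  write_tsv(sim$bgc$bgc_a, file.path(dir, "bgc_ref.tsv"))
  write_tsv(sim$bgc$bgc_b, file.path(dir, "bgc_draft.tsv"))
  writeLines(c(">cds_ref", sim$cds$ref, ">cds_alt", sim$cds$alt),
             file.path(dir, "cds_pair.fa"))
  writeLines(c(">repeat_region", sim$repeats$sequence),
             file.path(dir, "repeat_region.fa"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
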