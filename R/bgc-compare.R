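#' Secondary-metabolite BGC conservation classification
#'
#' Clusters are described by per-gene role tables (core biosynthetic,
#' additional biosynthetic, regulatory, transport, other) with protein
#' sequences. A query cluster is Conserved in a target genome when all of
#' its core biosynthetic genes have protein matches inside a single target
#' cluster; accessory-only matches (the jadomycin-regulator pattern) or a
#' match into a region carrying two cluster types give Partially conserved;
#' a fully matched cluster whose position has moved to a chromosome
#' terminus is Conserved in other regions; a cluster matching nothing is
#' strain-specific from the query's perspective and Missing from the
#' target's.
#'
#' @name bgc_compare
NULL

BGC_ROLES <- c("core_biosynthetic", "additional_biosynthetic", "regulatory",
               "transport", "other")
BGC_COLS <- c("cluster_id", "genome_id", "replicon_id", "start", "end",
              "product_type", "gene_id", "role", "protein_seq")

#' Protein match thresholds and positional parameters
#'
#' @param min_protein_identity minimum identity over aligned residue pairs
#'   (default 0.7).
#' @param min_protein_coverage minimum fraction of query residues aligned
#'   to target residues (default 0.7).
#' @param terminal_region_fraction fraction of each chromosome arm treated
#'   as the 5' or 3' terminal region (default 0.1).
#' @return list of class `match_params`.
#' @export
match_params <- function(min_protein_identity = 0.7,
                         min_protein_coverage = 0.7,
                         terminal_region_fraction = 0.1) {
  stopifnot(min_protein_identity > 0, min_protein_identity <= 1,
            min_protein_coverage > 0, min_protein_coverage <= 1,
            terminal_region_fraction > 0, terminal_region_fraction <= 1)
  structure(list(min_protein_identity = min_protein_identity,
                 min_protein_coverage = min_protein_coverage,
                 terminal_region_fraction = terminal_region_fraction),
            class = "match_params")
}

#' Read a BGC description table
#'
#' The TSV schema is one row per cluster gene with columns `cluster_id`,
#' `genome_id`, `replicon_id`, `start`, `end` (0-based half-open),
#' `product_type`, `gene_id`, `role`, `protein_seq`. antiSMASH-style region
#' GenBank files are read through the GenBank parser: each record is one
#' cluster, `gene_kind` qualifiers map onto the role vocabulary, and the
#' region `product` gives the cluster type.
#'
#' @param path input file.
#' @param format `"tsv"` or `"antismash_region_genbank"`.
#' @param allow_partial keep clusters without a core biosynthetic gene
#'   (otherwise an error names them).
#' @return data frame in the TSV schema above.
#' @export
parse_bgc_table <- function(path, format = c("tsv", "antismash_region_genbank"),
                            allow_partial = FALSE) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    missing_cols <- setdiff(BGC_COLS, colnames(tab))
    if (length(missing_cols))
      stopf("BGC table '%s' lacks required column(s): %s", path,
            paste(missing_cols, collapse = ", "))
    tab <- tab[, BGC_COLS]
    tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  } else {
    gb <- read_genbank(path)
    ft <- gb$features
    rows <- list()
    for (rid in names(gb$genome)) {
      f <- ft[ft$replicon_id == rid, , drop = FALSE]
      regf <- f[f$feature_kind == "other" & nzchar(f$product), , drop = FALSE]
      ptype <- if (nrow(regf)) regf$product[1] else "unknown"
      cds <- f[f$feature_kind == "CDS", , drop = FALSE]
      if (nrow(cds) == 0L) next
      role <- c(biosynthetic = "core_biosynthetic",
                `biosynthetic-additional` = "additional_biosynthetic",
                regulatory = "regulatory",
                transport = "transport")[cds$gene_kind]
      role[is.na(role)] <- "other"
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = rid, genome_id = rid, replicon_id = rid,
        start = min(cds$start), end = max(cds$end), product_type = ptype,
        gene_id = cds$gene_id, role = unname(role),
        protein_seq = cds$translation, stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
  }
  bad_role <- !(tab$role %in% BGC_ROLES)
  if (any(bad_role)) {
    warnf("%d gene role(s) outside the vocabulary mapped to 'other'",
          sum(bad_role))
    tab$role[bad_role] <- "other"
  }
  core_per <- tapply(tab$role == "core_biosynthetic", tab$cluster_id, any)
  if (!allow_partial && !all(core_per)) {
    stopf("cluster(s) without a core biosynthetic gene: %s",
          paste(names(core_per)[!core_per], collapse = ", "))
  }
  rownames(tab) <- NULL
  tab
}

# identity over aligned residue pairs; coverage = aligned query residues /
# query length. Query is aligned global-locally (free target ends).
protein_hit_stats <- function(pa, qlen) {
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  both <- pc != "-" & sc != "-"
  m <- sum(pc == sc & both)
  list(identity = if (sum(both)) m / sum(both) else 0,
       coverage = sum(both) / qlen,
       score = Biostrings::score(pa))
}

#' Best protein match per query gene
#'
#' Globally aligns each query protein against every target protein (free
#' target ends) and keeps the best-scoring hit passing the identity and
#' coverage thresholds; ties break by target gene id.
#'
#' @param query_proteins named character vector of query protein sequences.
#' @param target_proteins named character vector of target protein
#'   sequences.
#' @param params a [match_params()] object.
#' @return data frame: `gene_id`, `hit` (`NA` if none), `identity`,
#'   `coverage`.
#' @export
protein_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

match_proteins <- function(query_proteins, target_proteins,
                           params = match_params()) {
  stopifnot(all(nzchar(query_proteins)))
  out <- data.frame(gene_id = names(query_proteins), hit = NA_character_,
                    identity = NA_real_, coverage = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(target_proteins) == 0L) return(out)
  tlens <- nchar(target_proteins)
  tkmers <- lapply(target_proteins, protein_kmers)
  for (i in seq_along(query_proteins)) {
    qlen <- nchar(query_proteins[i])
    # a target shorter than coverage * query length can never pass coverage;
    # homologs above the identity floor always share 5-mers with the query
    qk <- protein_kmers(query_proteins[i])
    cand_j <- which(tlens >= params$min_protein_coverage * qlen &
                      vapply(tkmers, function(tk) any(qk %in% tk), TRUE))
    if (length(cand_j) == 0L) next
    q <- Biostrings::AAString(query_proteins[i])
    tset <- Biostrings::AAStringSet(target_proteins[cand_j])
    pas <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(list(q)), length(tset)), tset,
      type = "global-local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5
    )
    stats <- lapply(seq_along(tset), function(j) protein_hit_stats(pas[j], qlen))
    sc <- vapply(stats, `[[`, 0, "score")
    idn <- vapply(stats, `[[`, 0, "identity")
    cov <- vapply(stats, `[[`, 0, "coverage")
    pass <- idn >= params$min_protein_identity &
            cov >= params$min_protein_coverage
    if (any(pass)) {
      tnames <- names(target_proteins)[cand_j]
      keep <- which(pass)
      keep <- keep[order(-sc[keep], tnames[keep])]
      j <- keep[1]
      out$hit[i] <- tnames[j]
      out$identity[i] <- idn[j]
      out$coverage[i] <- cov[j]
    }
  }
  out
}

chrom_zone <- function(start, end, chrom_len, frac) {
  if (start < frac * chrom_len) "terminal_5prime"
  else if (end > (1 - frac) * chrom_len) "terminal_3prime"
  else "internal"
}

#' Classify conservation of one query cluster in a target genome
#'
#' @param query_cluster rows of a BGC table for one cluster.
#' @param target_bgc full BGC table for the target genome.
#' @param params a [match_params()] object.
#' @param query_chrom_len,target_chrom_len replicon lengths used for the
#'   terminal-region test (default: largest coordinate seen).
#' @param target_proteome optional named character vector of additional
#'   target proteins outside clusters.
#' @return one-row data frame: `query_cluster`, `label`, `partner`,
#'   `core_frac`, `accessory_frac`, `position_relation`, plus
#'   `target_perspective` (`"Missing"` for strain-specific clusters).
#' @export
classify_conservation <- function(query_cluster, target_bgc,
                                  params = match_params(),
                                  query_chrom_len = NULL,
                                  target_chrom_len = NULL,
                                  target_proteome = NULL) {
  qid <- query_cluster$cluster_id[1]
  core <- query_cluster$role == "core_biosynthetic"
  qprot <- setNames(query_cluster$protein_seq, query_cluster$gene_id)
  tprot <- setNames(target_bgc$protein_seq, target_bgc$gene_id)
  if (!is.null(target_proteome)) tprot <- c(tprot, target_proteome)
  hits <- match_proteins(qprot, tprot, params)
  gene2cluster <- setNames(target_bgc$cluster_id, target_bgc$gene_id)
  hit_cluster <- gene2cluster[hits$hit]

  core_hits <- !is.na(hits$hit[core])
  acc_hits <- !is.na(hits$hit[!core])
  core_frac <- if (any(core)) mean(core_hits) else NA_real_
  acc_frac <- if (any(!core)) mean(acc_hits) else NA_real_

  matched_clusters <- unique(hit_cluster[!is.na(hit_cluster)])
  # partner: target cluster with most core matches, then most total matches
  partner <- NA_character_
  if (length(matched_clusters)) {
    score_core <- vapply(matched_clusters, function(cl)
      sum(hit_cluster[core] == cl, na.rm = TRUE), 0L)
    score_all <- vapply(matched_clusters, function(cl)
      sum(hit_cluster == cl, na.rm = TRUE), 0L)
    o <- order(-score_core, -score_all, matched_clusters)
    partner <- matched_clusters[o[1]]
  }

  any_match <- any(!is.na(hits$hit))
  all_core_one_cluster <- isTRUE(core_frac == 1) && !is.na(partner) &&
    all(hit_cluster[core] == partner, na.rm = TRUE) &&
    !anyNA(hit_cluster[core])

  position_relation <- NA_character_
  label <- if (!any_match) {
    "StrainSpecific"
  } else if (all_core_one_cluster) {
    ptab <- target_bgc[target_bgc$cluster_id == partner, , drop = FALSE]
    # a matched region carrying two cluster types is only partially conserved
    tspan <- c(min(ptab$start), max(ptab$end))
    over <- unique(target_bgc$product_type[
      target_bgc$replicon_id == ptab$replicon_id[1] &
        target_bgc$start < tspan[2] & target_bgc$end > tspan[1]])
    if (length(over) >= 2L) {
      position_relation <- "multi_type_region"
      "PartiallyConserved"
    } else {
      qlenc <- if (is.null(query_chrom_len)) max(query_cluster$end) else query_chrom_len
      tlenc <- if (is.null(target_chrom_len)) max(target_bgc$end) else target_chrom_len
      qz <- chrom_zone(query_cluster$start[1], max(query_cluster$end), qlenc,
                       params$terminal_region_fraction)
      tz <- chrom_zone(ptab$start[1], max(ptab$end), tlenc,
                       params$terminal_region_fraction)
      position_relation <- sprintf("query_%s/target_%s", qz, tz)
      if (qz != tz && (qz != "internal" || tz != "internal"))
        "ConservedOtherRegion" else "Conserved"
    }
  } else {
    "PartiallyConserved"
  }
  data.frame(
    query_cluster = qid, label = label, partner = partner,
    core_frac = core_frac, accessory_frac = acc_frac,
    position_relation = position_relation,
    target_perspective = if (label == "StrainSpecific") "Missing" else label,
    stringsAsFactors = FALSE
  )
}

#' Conservation matrix of a query cluster set against a target genome
#'
#' @param query_bgc,target_bgc BGC tables (schema of [parse_bgc_table()]).
#' @param params a [match_params()] object.
#' @param query_chrom_len,target_chrom_len chromosome lengths for the
#'   terminal-region test.
#' @param target_proteome optional extra target proteins.
#' @return data frame with one row per query cluster.
#' @export
compare_bgc_sets <- function(query_bgc, target_bgc, params = match_params(),
                             query_chrom_len = NULL, target_chrom_len = NULL,
                             target_proteome = NULL) {
  rows <- lapply(split(query_bgc, query_bgc$cluster_id), function(qc) {
    classify_conservation(qc, target_bgc, params, query_chrom_len,
                          target_chrom_len, target_proteome)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$query_cluster), , drop = FALSE]
}
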