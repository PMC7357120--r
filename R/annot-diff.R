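#' Gene re-annotation comparison
#'
#' Draft CDSs are lifted onto the completed genome by sequence placement,
#' then every reference gene is classified against its best-matching lifted
#' draft gene as Identical, Long, Short, Moved or New; draft genes never
#' chosen as a partner are Missing.
#'
#' @name annot_diff
NULL

#' Category decision rules
#'
#' @param moved_overlap_fraction minimum overlap fraction (exclusive) for
#'   the Moved category when neither end matches; default 0.5.
#' @param overlap_denominator `"reference_gene"` (default) or
#'   `"shorter_gene"`: whose length the Moved fraction is taken over.
#' @param strand_strict require the partner on the same strand (default
#'   `TRUE`).
#' @return list of class `category_rules`.
#' @export
category_rules <- function(moved_overlap_fraction = 0.5,
                           overlap_denominator = c("reference_gene", "shorter_gene"),
                           strand_strict = TRUE) {
  overlap_denominator <- match.arg(overlap_denominator)
  if (moved_overlap_fraction <= 0 || moved_overlap_fraction > 1)
    stopf("moved_overlap_fraction must be in (0, 1]")
  structure(list(moved_overlap_fraction = moved_overlap_fraction,
                 overlap_denominator = overlap_denominator,
                 strand_strict = strand_strict),
            class = "category_rules")
}

GENE_LABELS <- c("Identical", "Long", "Short", "Moved", "New", "Missing")

#' Lift draft gene models onto the reference by sequence placement
#'
#' Each gene's genomic extent on the draft is placed on the reference with
#' the same seed-and-extend machinery used for assembly fragments. A gene
#' spanning an N-run is lifted by its longest unambiguous part; a fully
#' undetermined gene is unmapped. The lifted strand composes the gene's own
#' strand with the placement strand.
#'
#' @param draft_genes gene-model data frame on the draft.
#' @param draft,reference `DNAStringSet` genomes.
#' @param params an [alignment_params()] object.
#' @return data frame: `gene_id`, `mapped`, `ref_replicon`, `ref_start`,
#'   `ref_end`, `strand`, `identity_fraction`, `reason`.
#' @export
lift_draft_genes <- function(draft_genes, draft, reference,
                             params = alignment_params()) {
  if (anyDuplicated(draft_genes$gene_id))
    stopf("duplicate gene_id in draft annotation: %s",
          draft_genes$gene_id[duplicated(draft_genes$gene_id)][1])
  n <- nrow(draft_genes)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- as.character(draft[[match(draft_genes$replicon_id[i], names(draft))]])
    g <- substring(s, draft_genes$start[i] + 1L, draft_genes$end[i])
    # genes broken by an N-run are lifted by their longest determined part
    if (grepl("N", g, fixed = TRUE)) {
      parts <- strsplit(g, "N+")[[1]]
      parts <- parts[nzchar(parts)]
      g <- if (length(parts)) parts[which.max(nchar(parts))] else ""
    }
    seqs[i] <- g
  }
  ok <- nzchar(seqs)
  out <- data.frame(gene_id = draft_genes$gene_id, unplaced("all_undetermined"),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    pl <- place_queries(seqs[ok], reference, params)
    pl$strand <- ifelse(pl$strand == "+", draft_genes$strand[ok],
                        ifelse(draft_genes$strand[ok] == "+", "-", "+"))
    for (col in c("mapped", "ref_replicon", "ref_start", "ref_end", "strand",
                  "identity_fraction", "reason"))
      out[[col]][ok] <- pl[[col]]
  }
  out[, c("gene_id", "mapped", "ref_replicon", "ref_start", "ref_end",
          "strand", "identity_fraction", "reason")]
}

#' Classify reference genes against lifted draft genes
#'
#' Decision order per reference gene, taken against its best-matching
#' lifted draft gene (maximum overlap, same strand when `strand_strict`):
#' both 5' and 3' ends equal gives Identical; otherwise, with any overlap,
#' a longer reference gene is Long and a shorter one Short; equal-length
#' genes with neither end equal are Moved when the overlap exceeds
#' `moved_overlap_fraction` of the denominator length, else the reference
#' gene is New. Reference genes without any overlapping lifted gene are
#' New; draft genes never retained as a partner are Missing.
#'
#' @param ref_genes gene-model data frame on the reference.
#' @param lifted output of [lift_draft_genes()].
#' @param rules a [category_rules()] object.
#' @return list with `categories` (one row per reference gene plus one per
#'   Missing draft gene: `subject_id`, `label`, `partner_id`, `end5_match`,
#'   `end3_match`, `overlap_bp`, `overlap_frac`) and `counts` (named
#'   integer vector over the six labels).
#' @export
categorize_genes <- function(ref_genes, lifted, rules = category_rules()) {
  if (anyDuplicated(ref_genes$gene_id))
    stopf("duplicate gene_id in reference annotation: %s",
          ref_genes$gene_id[duplicated(ref_genes$gene_id)][1])
  if (anyDuplicated(lifted$gene_id))
    stopf("duplicate gene_id in lifted annotation: %s",
          lifted$gene_id[duplicated(lifted$gene_id)][1])
  lf <- lifted[isTRUE_vec(lifted$mapped), , drop = FALSE]

  # candidate partner pairs: any overlap on the same replicon (and strand)
  pairs <- NULL
  if (nrow(lf) > 0L && nrow(ref_genes) > 0L) {
    rgr <- GenomicRanges::GRanges(ref_genes$replicon_id,
                                  IRanges::IRanges(ref_genes$start + 1L, ref_genes$end),
                                  strand = ref_genes$strand)
    lgr <- GenomicRanges::GRanges(lf$ref_replicon,
                                  IRanges::IRanges(lf$ref_start + 1L, lf$ref_end),
                                  strand = lf$strand)
    ov <- GenomicRanges::findOverlaps(rgr, lgr,
                                      ignore.strand = !rules$strand_strict)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      ov_bp <- pmin(ref_genes$end[qi], lf$ref_end[si]) -
               pmax(ref_genes$start[qi], lf$ref_start[si])
      pairs <- data.frame(ref = qi, drf = si, overlap_bp = ov_bp)
      pairs <- pairs[pairs$overlap_bp > 0L, , drop = FALSE]
    }
  }

  partner <- rep(NA_integer_, nrow(ref_genes))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(-pairs$overlap_bp, ref_genes$start[pairs$ref],
                         lf$gene_id[pairs$drf]), , drop = FALSE]
    used_ref <- logical(nrow(ref_genes)); used_drf <- logical(nrow(lf))
    for (i in seq_len(nrow(pairs))) {
      r <- pairs$ref[i]; d <- pairs$drf[i]
      if (!used_ref[r] && !used_drf[d]) {
        partner[r] <- d; used_ref[r] <- TRUE; used_drf[d] <- TRUE
      }
    }
  }

  n <- nrow(ref_genes)
  label <- character(n); partner_id <- rep(NA_character_, n)
  e5 <- rep(NA, n); e3 <- rep(NA, n)
  ov_bp <- rep(NA_integer_, n); ov_fr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- partner[i]
    if (is.na(d)) { label[i] <- "New"; next }
    rg_len <- ref_genes$end[i] - ref_genes$start[i]
    lf_len <- lf$ref_end[d] - lf$ref_start[d]
    start_eq <- ref_genes$start[i] == lf$ref_start[d]
    end_eq <- ref_genes$end[i] == lf$ref_end[d]
    # 5'/3' naming is strand-aware; equality of both is strand-symmetric
    minus <- ref_genes$strand[i] == "-"
    e5[i] <- if (minus) end_eq else start_eq
    e3[i] <- if (minus) start_eq else end_eq
    obp <- min(ref_genes$end[i], lf$ref_end[d]) -
           max(ref_genes$start[i], lf$ref_start[d])
    denom <- if (rules$overlap_denominator == "reference_gene") rg_len
             else min(rg_len, lf_len)
    ov_bp[i] <- obp; ov_fr[i] <- obp / denom
    if (start_eq && end_eq) {
      label[i] <- "Identical"
    } else if (rg_len > lf_len) {
      label[i] <- "Long"
    } else if (rg_len < lf_len) {
      label[i] <- "Short"
    } else if (!start_eq && !end_eq && obp / denom > rules$moved_overlap_fraction) {
      label[i] <- "Moved"
    } else {
      # equal length, insufficient overlap: not a qualifying partner
      label[i] <- "New"
      partner[i] <- NA_integer_
      next
    }
    partner_id[i] <- lf$gene_id[d]
  }

  cat_ref <- data.frame(
    subject_id = ref_genes$gene_id, label = label, partner_id = partner_id,
    end5_match = e5, end3_match = e3, overlap_bp = ov_bp, overlap_frac = ov_fr,
    stringsAsFactors = FALSE
  )
  missing_ids <- setdiff(lifted$gene_id, partner_id[!is.na(partner_id)])
  n_mis <- length(missing_ids)
  cat_mis <- data.frame(
    subject_id = missing_ids, label = rep("Missing", n_mis),
    partner_id = rep(NA_character_, n_mis), end5_match = rep(NA, n_mis),
    end3_match = rep(NA, n_mis), overlap_bp = rep(NA_integer_, n_mis),
    overlap_frac = rep(NA_real_, n_mis), stringsAsFactors = FALSE
  )
  categories <- rbind(cat_ref, cat_mis)
  counts <- setNames(integer(length(GENE_LABELS)), GENE_LABELS)
  tb <- table(categories$label)
  counts[names(tb)] <- as.integer(tb)
  stopifnot(sum(counts[c("Identical", "Long", "Short", "Moved", "New")]) ==
              nrow(ref_genes))
  list(categories = categories, counts = counts)
}

isTRUE_vec <- function(x) !is.na(x) & x
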