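#' Alignment parameter set
#'
#' The placement cost model: unit match reward, mismatch penalty 2, and a
#' linear insertion/deletion penalty of 3 per base, with two acceptance
#' fractions. A candidate placement is kept only if the aligned part of the
#' query covers at least `length_fraction` of it and the aligned columns are
#' at least `similarity_fraction` identical. Equally scoring candidate
#' locations are resolved by `nonspecific_policy`: `"random_placement"`
#' picks one reproducibly from `seed`, `"drop"` leaves the query unmapped.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost positive alignment
#'   costs. Insertion and deletion costs must be equal (a single linear gap
#'   penalty is used).
#' @param length_fraction,similarity_fraction acceptance fractions in (0,1].
#' @param nonspecific_policy `"random_placement"` or `"drop"`.
#' @param seed integer seed driving random tie-breaks.
#' @param seed_k exact-seed k-mer length for candidate anchoring.
#' @param seed_step spacing between successive seed k-mers on the query.
#' @param max_candidates cap on anchored candidate loci evaluated per query.
#' @param dp_limit longest query extended by full dynamic programming;
#'   longer queries (large assembly fragments) are extended ungapped along
#'   the seeded diagonal, which is exact for N-run-delimited fragments
#'   whose interior is collinear with the reference.
#' @return list of class `alignment_params`.
#' @export
alignment_params <- function(mismatch_cost = 2, insertion_cost = 3,
                             deletion_cost = 3, length_fraction = 0.2,
                             similarity_fraction = 0.5,
                             nonspecific_policy = c("random_placement", "drop"),
                             seed = 1L, seed_k = 31L, seed_step = 15L,
                             max_candidates = 8L, dp_limit = 3000L) {
  nonspecific_policy <- match.arg(nonspecific_policy)
  if (mismatch_cost <= 0 || insertion_cost <= 0 || deletion_cost <= 0)
    stopf("alignment costs must be positive")
  if (insertion_cost != deletion_cost)
    stopf("insertion_cost and deletion_cost must be equal (linear gap model)")
  if (length_fraction <= 0 || length_fraction > 1 ||
      similarity_fraction <= 0 || similarity_fraction > 1)
    stopf("length_fraction and similarity_fraction must be in (0, 1]")
  structure(list(
    mismatch_cost = mismatch_cost, insertion_cost = insertion_cost,
    deletion_cost = deletion_cost, length_fraction = length_fraction,
    similarity_fraction = similarity_fraction,
    nonspecific_policy = nonspecific_policy, seed = as.integer(seed),
    seed_k = as.integer(seed_k), seed_step = as.integer(seed_step),
    max_candidates = as.integer(max_candidates), dp_limit = as.integer(dp_limit)
  ), class = "alignment_params")
}

# Substitution matrix over the IUPAC DNA alphabet: +1 for an identical
# unambiguous base, -mismatch_cost otherwise. Ambiguity codes never match
# anything (including themselves), so M/S/K singletons inside a fragment
# count as mismatches to any base.
iupac_submat <- function(mismatch_cost = 2) {
  m <- matrix(-mismatch_cost, length(IUPAC_DNA), length(IUPAC_DNA),
              dimnames = list(IUPAC_DNA, IUPAC_DNA))
  for (b in c("A", "C", "G", "T")) m[b, b] <- 1
  m
}

# Precompute per-replicon forward and reverse-complement DNAStrings.
build_ref_index <- function(reference) {
  if (length(reference) == 0L || sum(Biostrings::width(reference)) == 0L)
    stopf("reference is empty")
  lapply(seq_along(reference), function(i) {
    fwd <- reference[[i]]
    list(id = names(reference)[i], fwd = fwd,
         rc = Biostrings::reverseComplement(fwd),
         len = length(fwd))
  })
}

# Seed k-mers for one query: offsets every `seed_step` bp, capped at ~48
# seeds, ambiguity-free only. Returns NULL when none qualify.
query_seeds <- function(query, params) {
  qlen <- nchar(query)
  k <- params$seed_k
  if (qlen < k) return(NULL)
  step <- max(params$seed_step, as.integer(ceiling((qlen - k + 1L) / 48)))
  offs <- unique(c(seq(1L, qlen - k + 1L, by = step), qlen - k + 1L))
  km <- substring(query, offs, offs + k - 1L)
  clean <- !grepl("[^ACGT]", km)
  if (!any(clean)) return(list(kmers = character(0), offsets = integer(0)))
  list(kmers = km[clean], offsets = offs[clean])
}

# Batch exact seeding: one PDict over every query's seed k-mers, matched
# against each replicon on both strands. Returns, per query, a data frame
# of candidate diagonals (replicon, strand, 1-based query-start position).
batch_seed_candidates <- function(seed_sets, ref_index) {
  n_per <- vapply(seed_sets, function(s) if (is.null(s)) 0L else length(s$kmers), 0L)
  total <- sum(n_per)
  out <- vector("list", length(seed_sets))
  if (total == 0L) return(out)
  all_kmers <- unlist(lapply(seed_sets, function(s) s$kmers), use.names = FALSE)
  all_offs <- unlist(lapply(seed_sets, function(s) s$offsets), use.names = FALSE)
  owner <- rep(seq_along(seed_sets), n_per)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_kmers))
  diag_q <- list()
  for (ri in ref_index) {
    for (str in c("+", "-")) {
      subj <- if (str == "+") ri$fwd else ri$rc
      hits <- Biostrings::matchPDict(pd, subj)
      starts <- BiocGenerics::start(hits)
      nh <- lengths(starts)
      if (sum(nh) == 0L) next
      idx <- rep.int(seq_along(starts), nh)
      diag_q[[length(diag_q) + 1L]] <- data.frame(
        owner = owner[idx],
        replicon = ri$id, strand = str, rlen = ri$len,
        pos = unlist(starts, use.names = FALSE) - all_offs[idx] + 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(diag_q) == 0L) return(out)
  dd <- do.call(rbind, diag_q)
  for (q in unique(dd$owner)) out[[q]] <- dd[dd$owner == q, , drop = FALSE]
  out
}

# Cluster one query's raw diagonals into candidate loci.
collate_candidates <- function(diags, max_candidates, tol = 30L) {
  parts <- split(diags, paste(diags$replicon, diags$strand))
  cl <- do.call(rbind, lapply(parts, function(p) {
    c1 <- cluster_diagonals(p$pos, tol)
    if (nrow(c1) == 0L) return(NULL)
    c1$replicon <- p$replicon[1]; c1$strand <- p$strand[1]; c1$rlen <- p$rlen[1]
    c1
  }))
  cl <- cl[order(-cl$support, cl$replicon, cl$strand, cl$pos), , drop = FALSE]
  utils::head(cl, max_candidates)
}

# Cluster diagonal values within `tol` bp; returns data.frame(pos, support)
# ordered by descending support then position.
cluster_diagonals <- function(diag, tol = 30L) {
  if (length(diag) == 0L) return(data.frame(pos = integer(), support = integer()))
  d <- sort(diag)
  grp <- cumsum(c(1L, diff(d) > tol))
  pos <- as.integer(round(tapply(d, grp, stats::median)))
  support <- as.integer(tapply(d, grp, length))
  o <- order(-support, pos)
  data.frame(pos = pos[o], support = support[o])
}

# Best-scoring contiguous ungapped segment of the query laid on the strand
# string at diagonal `pos` (1-based): a maximum-subarray over per-position
# match/mismatch scores. Equivalent to the DP local alignment whenever the
# optimal alignment is gap-free. Returns NULL if nothing scores positive.
extend_ungapped <- function(qchars, subj, pos, mismatch_cost) {
  qlen <- length(qchars)
  L <- length(subj)
  q_from <- max(1L, 2L - pos)
  r_from <- pos + q_from - 1L
  n <- min(qlen - q_from + 1L, L - r_from + 1L)
  if (n <= 0L) return(NULL)
  rchars <- strsplit(as.character(Biostrings::subseq(subj, r_from, r_from + n - 1L)),
                     "", fixed = TRUE)[[1]]
  eq <- qchars[q_from:(q_from + n - 1L)] == rchars
  sc <- ifelse(eq, 1, -mismatch_cost)
  pref <- cumsum(sc)
  lowest_before <- cummin(c(0, pref[-n]))
  val <- pref - lowest_before
  j <- which.max(val)
  if (val[j] <= 0) return(NULL)
  start_i <- which(c(0, pref[-n]) == lowest_before[j])[1]
  q1 <- q_from + start_i - 1L
  q2 <- q_from + j - 1L
  list(q1 = q1, q2 = q2, score = val[j],
       identity = mean(eq[start_i:j]))
}

unplaced <- function(reason) {
  data.frame(mapped = FALSE, ref_replicon = NA_character_,
             ref_start = NA_integer_, ref_end = NA_integer_,
             strand = NA_character_, left_clip_bp = NA_integer_,
             right_clip_bp = NA_integer_, identity_fraction = NA_real_,
             score = NA_real_, n_best = 0L, reason = reason,
             stringsAsFactors = FALSE)
}

# Extend precomputed candidate loci for one query and pick the best
# placement. `tie_seed` drives the random choice among equal scorers.
place_query <- function(query, cands, ref_index, params, submat,
                        tie_seed = 0L) {
  qlen <- nchar(query)
  qds <- Biostrings::DNAString(query)
  pad <- 120L + as.integer(round(0.02 * qlen))
  use_dp <- qlen <= params$dp_limit
  qchars <- if (!use_dp) strsplit(query, "", fixed = TRUE)[[1]]
  results <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ci <- cands[i, ]
    ri <- ref_index[[match(ci$replicon, vapply(ref_index, `[[`, "", "id"))]]
    subj <- if (ci$strand == "+") ri$fwd else ri$rc
    if (use_dp) {
      ws <- max(1L, ci$pos - pad)
      we <- min(ri$len, ci$pos + qlen - 1L + pad)
      if (we <= ws) next
      pa <- Biostrings::pairwiseAlignment(
        qds, Biostrings::subseq(subj, ws, we), type = "local",
        substitutionMatrix = submat, gapOpening = 0,
        gapExtension = params$insertion_cost
      )
      cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
      if (cols == 0L) next
      ident <- Biostrings::nmatch(pa) / cols
      ps <- BiocGenerics::start(Biostrings::pattern(pa))
      pe <- BiocGenerics::end(Biostrings::pattern(pa))
      sc <- Biostrings::score(pa)
      s2 <- ws + BiocGenerics::start(Biostrings::subject(pa)) - 1L  # 1-based on strand
      e2 <- ws + BiocGenerics::end(Biostrings::subject(pa)) - 1L
    } else {
      # ungapped extension on the seeded diagonal (long fragments)
      ext <- extend_ungapped(qchars, subj, ci$pos, params$mismatch_cost)
      if (is.null(ext)) next
      ident <- ext$identity
      ps <- ext$q1; pe <- ext$q2
      sc <- ext$score
      s2 <- ci$pos + ps - 1L
      e2 <- ci$pos + pe - 1L
    }
    span_ok <- (pe - ps + 1L) / qlen >= params$length_fraction
    if (!span_ok || ident < params$similarity_fraction) next
    if (ci$strand == "+") {
      r0s <- s2 - 1L; r0e <- e2
    } else {
      r0s <- ri$len - e2; r0e <- ri$len - s2 + 1L
    }
    results[[i]] <- data.frame(
      mapped = TRUE, ref_replicon = ci$replicon, ref_start = r0s, ref_end = r0e,
      strand = ci$strand, left_clip_bp = ps - 1L, right_clip_bp = qlen - pe,
      identity_fraction = ident, score = sc, n_best = 1L,
      reason = "", stringsAsFactors = FALSE
    )
  }
  results <- results[!vapply(results, is.null, TRUE)]
  if (length(results) == 0L) return(unplaced("below_thresholds"))
  res <- do.call(rbind, results)
  # the same locus can be anchored from several diagonals; keep unique loci
  res <- res[!duplicated(res[, c("ref_replicon", "ref_start", "ref_end", "strand")]), ,
             drop = FALSE]
  best <- res$score >= max(res$score) - 1e-9
  res <- res[best, , drop = FALSE]
  if (nrow(res) > 1L) {
    if (params$nonspecific_policy == "drop") return(unplaced("ambiguous"))
    pick <- with_seed(derive_seed(params$seed, tie_seed), sample.int(nrow(res), 1L))
    out <- res[pick, , drop = FALSE]
    out$n_best <- nrow(res)
    rownames(out) <- NULL
    return(out)
  }
  rownames(res) <- NULL
  res
}

# Place many query sequences; returns one row per query in input order.
# All queries' seeds are matched against the reference in one PDict pass.
place_queries <- function(queries, reference, params) {
  ref_index <- build_ref_index(reference)
  submat <- iupac_submat(params$mismatch_cost)
  seed_sets <- lapply(queries, query_seeds, params = params)
  diags <- batch_seed_candidates(seed_sets, ref_index)
  rows <- lapply(seq_along(queries), function(i) {
    if (is.null(seed_sets[[i]])) return(unplaced("shorter_than_seed"))
    if (length(seed_sets[[i]]$kmers) == 0L) return(unplaced("no_clean_seed"))
    if (is.null(diags[[i]])) return(unplaced("no_seed_match"))
    cands <- collate_candidates(diags[[i]], params$max_candidates)
    place_query(queries[i], cands, ref_index, params, submat, tie_seed = i)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
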