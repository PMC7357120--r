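#' Assembly reconciliation: fragment, place, and account
#'
#' A draft assembly is split at every maximal run of the undetermined base
#' 'N' (isolated non-N ambiguity codes such as M/S/K stay inside fragments),
#' the fragments are placed on the completed genome under the
#' [alignment_params()] cost model, and consecutive placements are compared
#' to account the gaps that were filled and the overlapping (duplicated)
#' regions that were corrected in the completed assembly.
#'
#' @name fragment_map
NULL

#' Split a draft replicon set at undetermined-base runs
#'
#' Breaks occur at every maximal 'N' run; leading and trailing runs produce
#' no empty fragments. The returned table carries an `nruns` attribute (the
#' maximal N-run table) so that fragments plus recorded runs reconstruct the
#' draft exactly.
#'
#' @param draft a `DNAStringSet` draft genome.
#' @return data frame with columns `fragment_id`, `source_replicon`,
#'   `draft_start`, `draft_end` (0-based half-open), `preceding_nrun_bp`
#'   (length of the N-run immediately before the fragment; `NA` for a
#'   replicon's first fragment when the replicon does not start with N).
#' @export
fragment_at_undetermined <- function(draft) {
  frags <- list()
  nruns <- list()
  fid <- 0L
  for (i in seq_along(draft)) {
    rep_id <- names(draft)[i]
    s <- as.character(draft[[i]])
    L <- nchar(s)
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L) {
      runs <- data.frame(start = integer(), length = integer())
    } else {
      runs <- data.frame(start = as.integer(m) - 1L,
                         length = attr(m, "match.length"))
    }
    nruns[[i]] <- data.frame(replicon = rep(rep_id, nrow(runs)), runs,
                             stringsAsFactors = FALSE)
    bounds <- c(0L, as.vector(rbind(runs$start, runs$start + runs$length)), L)
    # odd positions in `bounds` pairs are fragment starts
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- ends > starts
    if (!any(keep)) {
      warnf("replicon '%s' is entirely undetermined; no fragments", rep_id)
      next
    }
    starts <- starts[keep]; ends <- ends[keep]
    prec <- vapply(starts, function(st) {
      j <- which(runs$start + runs$length == st)
      if (length(j)) runs$length[j[1]] else NA_integer_
    }, integer(1))
    frags[[length(frags) + 1L]] <- data.frame(
      fragment_id = fid + seq_along(starts), source_replicon = rep_id,
      draft_start = starts, draft_end = ends, preceding_nrun_bp = prec,
      stringsAsFactors = FALSE
    )
    fid <- fid + length(starts)
  }
  out <- if (length(frags)) do.call(rbind, frags) else
    data.frame(fragment_id = integer(), source_replicon = character(),
               draft_start = integer(), draft_end = integer(),
               preceding_nrun_bp = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "nruns") <- do.call(rbind, c(nruns, list(make.row.names = FALSE)))
  out
}

#' Reconstruct a draft replicon from its fragments and recorded N-runs
#'
#' Inverse of [fragment_at_undetermined()]; used to verify the lossless
#' fragmentation invariant.
#'
#' @param fragments output of [fragment_at_undetermined()].
#' @param draft the original draft `DNAStringSet` (sequence source).
#' @param replicon replicon id to reconstruct.
#' @return character string of the rebuilt replicon.
#' @export
reconstruct_draft <- function(fragments, draft, replicon) {
  s <- as.character(draft[[match(replicon, names(draft))]])
  fr <- fragments[fragments$source_replicon == replicon, , drop = FALSE]
  nr <- attr(fragments, "nruns")
  nr <- nr[nr$replicon == replicon, , drop = FALSE]
  pieces <- rbind(
    data.frame(start = fr$draft_start,
               txt = substring(s, fr$draft_start + 1L, fr$draft_end)),
    data.frame(start = nr$start,
               txt = strrep("N", nr$length))
  )
  paste(pieces$txt[order(pieces$start)], collapse = "")
}

#' Place draft fragments on a completed reference genome
#'
#' Each fragment is anchored by exact k-mer seeds and extended by a
#' local alignment under the [alignment_params()] cost model. Placements
#' failing the length or similarity fraction are reported unmapped with a
#' reason; equal-scoring loci are resolved by the nonspecific policy.
#' Unaligned flanks are reported as `left_clip_bp`/`right_clip_bp` in draft
#' orientation (the misassembled sequence at either side of the fragment).
#'
#' @param fragments output of [fragment_at_undetermined()].
#' @param draft the draft `DNAStringSet`.
#' @param reference the completed `DNAStringSet`.
#' @param params an [alignment_params()] object.
#' @return data frame, one row per fragment: `fragment_id`, `mapped`,
#'   `ref_replicon`, `ref_start`, `ref_end` (0-based half-open), `strand`,
#'   `left_clip_bp`, `right_clip_bp`, `identity_fraction`, `score`,
#'   `n_best`, `reason`.
#' @export
place_fragments <- function(fragments, draft, reference,
                            params = alignment_params()) {
  if (nrow(fragments) == 0L)
    return(cbind(fragment_id = integer(), unplaced("no_fragments")[0, ]))
  seqs <- vapply(seq_len(nrow(fragments)), function(i) {
    s <- as.character(draft[[match(fragments$source_replicon[i], names(draft))]])
    substring(s, fragments$draft_start[i] + 1L, fragments$draft_end[i])
  }, character(1))
  out <- place_queries(seqs, reference, params)
  cbind(fragment_id = fragments$fragment_id, out,
        source_replicon = fragments$source_replicon,
        preceding_nrun_bp = fragments$preceding_nrun_bp)
}

#' Gap/overlap accounting between adjacent placed fragments
#'
#' Every pair of consecutively numbered fragments from the same draft
#' replicon yields exactly one report. Pairs in which either side is
#' unmapped, or the two sides sit on different reference replicons or
#' strands, are `unresolved` and excluded from the gap/overlap summary.
#' On the reference, a positive separation between the placements is a
#' `gap` (sequence present in the completed genome but undetermined in the
#' draft), a negative one is an `overlap` (duplicated across the draft
#' fragment boundary), zero is `abutting`.
#'
#' @param placements output of [place_fragments()].
#' @return list with `reports` (data frame: `left_fragment_id`,
#'   `right_fragment_id`, `relation`, `length_bp`, `draft_n_run_bp`) and
#'   `summary` (list `gap_count`, `gap_total_bp`, `overlap_count`,
#'   `overlap_total_bp`, `abutting_count`, `unresolved_count`).
#' @export
adjacency_accounting <- function(placements) {
  pl <- placements[order(placements$fragment_id), , drop = FALSE]
  reports <- list()
  if (nrow(pl) >= 2L) {
    for (i in seq_len(nrow(pl) - 1L)) {
      a <- pl[i, ]; b <- pl[i + 1L, ]
      if (a$source_replicon != b$source_replicon) next
      nrun <- if (is.na(b$preceding_nrun_bp)) 0L else b$preceding_nrun_bp
      if (!isTRUE(a$mapped) || !isTRUE(b$mapped) ||
          a$ref_replicon != b$ref_replicon || a$strand != b$strand) {
        rel <- "unresolved"; len <- NA_integer_
      } else {
        sep <- if (a$strand == "+") b$ref_start - a$ref_end
               else a$ref_start - b$ref_end
        rel <- if (sep > 0L) "gap" else if (sep < 0L) "overlap" else "abutting"
        len <- abs(sep)
      }
      reports[[length(reports) + 1L]] <- data.frame(
        left_fragment_id = a$fragment_id, right_fragment_id = b$fragment_id,
        relation = rel, length_bp = len, draft_n_run_bp = nrun,
        stringsAsFactors = FALSE
      )
    }
  }
  rep_df <- if (length(reports)) do.call(rbind, reports) else
    data.frame(left_fragment_id = integer(), right_fragment_id = integer(),
               relation = character(), length_bp = integer(),
               draft_n_run_bp = integer(), stringsAsFactors = FALSE)
  gaps <- rep_df$relation == "gap"
  ovls <- rep_df$relation == "overlap"
  list(
    reports = rep_df,
    summary = list(
      gap_count = sum(gaps),
      gap_total_bp = sum(rep_df$length_bp[gaps]),
      overlap_count = sum(ovls),
      overlap_total_bp = sum(rep_df$length_bp[ovls]),
      abutting_count = sum(rep_df$relation == "abutting"),
      unresolved_count = sum(rep_df$relation == "unresolved")
    )
  )
}

#' Gap intervals on the reference as a BED table
#'
#' @param placements output of [place_fragments()].
#' @param adjacency output of [adjacency_accounting()] for those placements.
#' @return data frame with BED columns `chrom`, `start`, `end`, `name`
#'   (0-based half-open).
#' @export
gap_bed <- function(placements, adjacency = adjacency_accounting(placements)) {
  rep_df <- adjacency$reports
  g <- rep_df[rep_df$relation == "gap", , drop = FALSE]
  if (nrow(g) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(g)), function(i) {
    a <- placements[placements$fragment_id == g$left_fragment_id[i], ]
    b <- placements[placements$fragment_id == g$right_fragment_id[i], ]
    if (a$strand == "+") {
      st <- a$ref_end; en <- b$ref_start
    } else {
      st <- b$ref_end; en <- a$ref_start
    }
    data.frame(chrom = a$ref_replicon, start = st, end = en,
               name = sprintf("gap_%d_%d", a$fragment_id, b$fragment_id),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}
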