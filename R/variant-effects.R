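#' CDS variant calling and consequence prediction
#'
#' Pairs of coding sequences are globally aligned under the
#' [alignment_params()] cost model; runs of edits are merged into
#' substitution/insertion/deletion variants with 1-based positions on the
#' reference CDS, indels left-aligned to their leftmost equivalent
#' placement. Frameshift consequences follow codon arithmetic (the first
#' affected codon of an indel at nucleotide p is `ceiling(p/3)`) with
#' premature stops located by translating the edited sequence under the
#' bacterial genetic code (table 11).
#'
#' @name variant_effects
NULL

#' Call variants between a reference and an alternate CDS
#'
#' @param ref_cds,alt_cds nucleotide strings (length >= 3).
#' @param params an [alignment_params()] object (cost model only).
#' @return data frame: `kind` (`substitution`/`insertion`/`deletion`),
#'   `cds_position` (1-based on the reference CDS; for an insertion the
#'   position after which the bases are inserted), `ref_allele`,
#'   `alt_allele`, `length`.
#' @export
align_cds_pair <- function(ref_cds, alt_cds, params = alignment_params()) {
  ref_cds <- toupper(ref_cds); alt_cds <- toupper(alt_cds)
  if (!nzchar(ref_cds) || !nzchar(alt_cds)) stopf("empty CDS sequence")
  if (nchar(ref_cds) < 3L || nchar(alt_cds) < 3L) stopf("CDS shorter than one codon")
  # the 0.01 gap-opening term only breaks ties among equal-cost alignments,
  # preferring one contiguous indel over the same bases split around a
  # coincidental match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref_cds), Biostrings::DNAString(alt_cds),
    type = "global", substitutionMatrix = iupac_submat(params$mismatch_cost),
    gapOpening = 0.01, gapExtension = params$insertion_cost
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  state <- ifelse(p == "-", "insertion",
                  ifelse(s == "-", "deletion",
                         ifelse(p == s, "match", "substitution")))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  refpos <- cumsum(p != "-")  # reference coordinate at each column
  vars <- list()
  for (i in seq_along(r$values)) {
    kind <- r$values[i]
    if (kind == "match") next
    cols <- starts[i]:ends[i]
    ref_allele <- paste(p[cols][p[cols] != "-"], collapse = "")
    alt_allele <- paste(s[cols][s[cols] != "-"], collapse = "")
    pos <- if (kind == "insertion") refpos[starts[i]] else refpos[starts[i]]
    if (kind == "insertion" && starts[i] == 1L) pos <- 0L
    vars[[length(vars) + 1L]] <- data.frame(
      kind = kind, cds_position = as.integer(pos),
      ref_allele = ref_allele, alt_allele = alt_allele,
      length = max(nchar(ref_allele), nchar(alt_allele)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(vars)) do.call(rbind, vars) else
    data.frame(kind = character(), cds_position = integer(),
               ref_allele = character(), alt_allele = character(),
               length = integer(), stringsAsFactors = FALSE)
  left_align_variants(out, ref_cds)
}

# Shift indels to their leftmost equivalent placement on the reference.
left_align_variants <- function(vars, ref_cds) {
  if (nrow(vars) == 0L) return(vars)
  rc <- strsplit(ref_cds, "")[[1]]
  for (i in seq_len(nrow(vars))) {
    if (vars$kind[i] == "deletion") {
      p <- vars$cds_position[i]; L <- nchar(vars$ref_allele[i])
      # deleting [p, p+L-1] equals deleting [p-1, p+L-2] iff rc[p-1] == rc[p+L-1]
      while (p > 1L && rc[p - 1L] == rc[p + L - 1L]) p <- p - 1L
      if (p != vars$cds_position[i]) {
        vars$cds_position[i] <- p
        vars$ref_allele[i] <- paste(rc[p:(p + L - 1L)], collapse = "")
      }
    } else if (vars$kind[i] == "insertion") {
      p <- vars$cds_position[i]
      ins <- strsplit(vars$alt_allele[i], "")[[1]]
      while (p > 0L && rc[p] == ins[length(ins)]) {
        ins <- c(rc[p], ins[-length(ins)])
        p <- p - 1L
      }
      vars$cds_position[i] <- p
      vars$alt_allele[i] <- paste(ins, collapse = "")
    }
  }
  vars[order(vars$cds_position), , drop = FALSE]
}

#' Apply called variants to a reference CDS
#'
#' Reconstructs the alternate sequence; with the output of
#' [align_cds_pair()] this is exact (the round-trip invariant).
#'
#' @param ref_cds reference nucleotide string.
#' @param variants variant data frame from [align_cds_pair()].
#' @return the edited nucleotide string.
#' @export
apply_variants <- function(ref_cds, variants) {
  s <- strsplit(toupper(ref_cds), "")[[1]]
  if (nrow(variants) == 0L) return(paste(s, collapse = ""))
  v <- variants[order(-variants$cds_position), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    p <- v$cds_position[i]
    if (v$kind[i] == "substitution") {
      L <- nchar(v$ref_allele[i])
      s <- c(s[seq_len(p - 1L)], strsplit(v$alt_allele[i], "")[[1]],
             if (p + L <= length(s)) s[(p + L):length(s)])
    } else if (v$kind[i] == "deletion") {
      L <- nchar(v$ref_allele[i])
      s <- s[-(p:(p + L - 1L))]
    } else {
      s <- append(s, strsplit(v$alt_allele[i], "")[[1]], after = p)
    }
  }
  paste(s, collapse = "")
}

#' Translate a CDS under the bacterial genetic code
#'
#' Trailing partial codons are dropped; codons containing ambiguity codes
#' translate to `X`.
#'
#' @param nt nucleotide string.
#' @return amino-acid string (stops as `*`).
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) - nchar(nt) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

#' Frameshift consequence of a variant list
#'
#' The first affected codon is `ceiling(p/3)` where p is the first
#' reference nucleotide whose frame is disrupted: the position of the
#' earliest indel at which the cumulative indel length is not a multiple
#' of 3 (for an insertion after position p the disruption starts at p+1).
#' The premature stop is the first stop codon in the translated edited
#' sequence occurring before the reference stop.
#'
#' @param variants variant data frame from [align_cds_pair()].
#' @param ref_cds reference nucleotide string.
#' @return list of class `frameshift_effect`: `frameshift`,
#'   `first_affected_codon`, `premature_stop_codon`, `net_indel_bp`.
#' @export
frameshift_effect <- function(variants, ref_cds) {
  v <- variants[variants$kind %in% c("insertion", "deletion"), , drop = FALSE]
  v <- v[order(v$cds_position), , drop = FALSE]
  net <- 0L
  frameshift <- FALSE
  first_codon <- NA_integer_
  if (nrow(v)) {
    signed <- ifelse(v$kind == "insertion", nchar(v$alt_allele),
                     -nchar(v$ref_allele))
    cums <- cumsum(signed)
    disrupt <- which(cums %% 3L != 0L)
    net <- cums[length(cums)]
    if (length(disrupt)) {
      frameshift <- TRUE
      i <- disrupt[1]
      p <- if (v$kind[i] == "insertion") v$cds_position[i] + 1L else v$cds_position[i]
      first_codon <- as.integer(ceiling(p / 3))
    }
  }
  premature <- NA_integer_
  if (nrow(v)) {
    alt <- apply_variants(ref_cds, variants)
    aa_ref <- strsplit(translate_cds(ref_cds), "")[[1]]
    aa_alt <- strsplit(translate_cds(alt), "")[[1]]
    ref_stop <- which(aa_ref == "*")
    ref_stop <- if (length(ref_stop)) ref_stop[1] else length(aa_ref) + 1L
    alt_stop <- which(aa_alt == "*")
    if (length(alt_stop) && alt_stop[1] < ref_stop) premature <- alt_stop[1]
  }
  structure(list(frameshift = frameshift, first_affected_codon = first_codon,
                 premature_stop_codon = premature, net_indel_bp = as.integer(net)),
            class = "frameshift_effect")
}

#' @export
print.frameshift_effect <- function(x, ...) {
  cat("frameshift:", x$frameshift,
      "| first affected codon:", x$first_affected_codon,
      "| premature stop codon:", x$premature_stop_codon,
      "| net indel bp:", x$net_indel_bp, "\n")
  invisible(x)
}

# ---- multi-strain difference sites ----------------------------------------

# Thread pairwise alignments (each vs the longest sequence) into one
# column-consistent alignment. Returns a character matrix, rows = strains.
progressive_align <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  anchor_i <- which.max(nchar(seqs))
  anchor <- seqs[anchor_i]
  alen <- nchar(anchor)
  others <- setdiff(seq_along(seqs), anchor_i)
  aln <- list()
  ins_after <- integer(alen + 1L)  # insertions after anchor position i (i+1 index)
  for (j in others) {
    pa <- if (type == "protein") {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[j]), Biostrings::AAString(anchor),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
    } else {
      Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[j]), Biostrings::DNAString(anchor),
        type = "global", substitutionMatrix = iupac_submat(),
        gapOpening = 0, gapExtension = 3)
    }
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    a <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    aln[[as.character(j)]] <- list(seq = p, anchor = a)
    # record insertion-run lengths relative to the anchor
    apos <- cumsum(a != "-")
    for (col in which(a == "-")) {
      idx <- apos[col] + 1L
      ins_after[idx] <- ins_after[idx] + 0L  # placeholder, recomputed below
    }
    runs <- rle(a == "-")
    at <- cumsum(runs$lengths)
    for (k in which(runs$values)) {
      start_col <- at[k] - runs$lengths[k] + 1L
      idx <- if (start_col == 1L) 1L else apos[start_col - 1L] + 1L
      ins_after[idx] <- max(ins_after[idx], runs$lengths[k])
    }
  }
  ncols <- alen + sum(ins_after)
  mat <- matrix("-", nrow = length(seqs), ncol = ncols,
                dimnames = list(names(seqs), NULL))
  # anchor row
  col_of_anchor <- integer(alen)
  col <- ins_after[1L]
  achars <- strsplit(anchor, "")[[1]]
  for (i in seq_len(alen)) {
    col <- col + 1L
    mat[anchor_i, col] <- achars[i]
    col_of_anchor[i] <- col
    col <- col + ins_after[i + 1L]
  }
  for (j in others) {
    rec <- aln[[as.character(j)]]
    apos <- cumsum(rec$anchor != "-")
    out_row <- rep("-", ncols)
    # walk alignment columns, tracking how many inserted chars used per slot
    used_ins <- integer(alen + 1L)
    for (col_i in seq_along(rec$seq)) {
      ch <- rec$seq[col_i]
      if (rec$anchor[col_i] != "-") {
        out_row[col_of_anchor[apos[col_i]]] <- ch
      } else {
        idx <- apos[col_i] + 1L  # insertion after anchor position idx-1
        used_ins[idx] <- used_ins[idx] + 1L
        base_col <- if (idx == 1L) 0L else col_of_anchor[idx - 1L]
        out_row[base_col + used_ins[idx]] <- ch
      }
    }
    mat[j, ] <- out_row
  }
  mat
}

#' Count amino-acid difference sites across strains
#'
#' The sequences (2 or 3 strains) are progressively aligned against the
#' longest; a column is a difference site when any two strains disagree
#' there, a gap counting as a difference. Strains missing the gene (empty
#' sequence) are excluded and noted.
#'
#' @param protein_seqs named character vector, one protein per strain.
#' @param gene_id gene label carried into the result.
#' @return list of class `diff_site_count`: `gene_id`, `aligned_length`,
#'   `diff_sites`, `strains`, `excluded`.
#' @export
count_diff_sites <- function(protein_seqs, gene_id = "") {
  excluded <- names(protein_seqs)[!nzchar(protein_seqs)]
  seqs <- protein_seqs[nzchar(protein_seqs)]
  if (length(seqs) < 2L)
    stopf("count_diff_sites needs at least two strains with the gene")
  mat <- progressive_align(seqs, type = "protein")
  diffs <- apply(mat, 2L, function(col) length(unique(col)) > 1L)
  structure(list(gene_id = gene_id, aligned_length = ncol(mat),
                 diff_sites = sum(diffs), strains = names(seqs),
                 excluded = excluded),
            class = "diff_site_count")
}

# ---- tandem repeats --------------------------------------------------------

is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), u / d)) return(FALSE)
  }
  TRUE
}

#' Find exact tandem repeat arrays
#'
#' Reports every maximal array of >= `min_copies` contiguous exact copies
#' of a motif with unit length in `[min_unit, max_unit]`. Arrays are
#' reported once, at their leftmost phase, with a primitive motif (a motif
#' that is itself a repetition of a shorter unit is suppressed in favour
#' of the shorter unit's report).
#'
#' @param seq nucleotide string.
#' @param min_unit,max_unit unit length range (bp).
#' @param min_copies minimum copies (default 2).
#' @return data frame: `motif`, `unit_length`, `copies`, `start` (0-based),
#'   `span_bp`.
#' @export
find_tandem_repeats <- function(seq, min_unit = 2L, max_unit = 16L,
                                min_copies = 2L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (min_unit > max_unit) stopf("min_unit must be <= max_unit")
  if (max_unit > n / 2) max_unit <- floor(n / 2)
  s <- strsplit(seq, "")[[1]]
  hits <- list()
  for (u in seq_len(max(0L, max_unit - min_unit + 1L)) + as.integer(min_unit) - 1L) {
    m <- s[seq_len(n - u)] == s[(u + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= u * (min_copies - 1L))) {
      p <- ends[k] - r$lengths[k] + 1L        # 1-based array start
      copies <- (r$lengths[k] + u) %/% u
      motif <- substr(seq, p, p + u - 1L)
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, unit_length = as.integer(u), copies = as.integer(copies),
        start = as.integer(p - 1L), span_bp = as.integer(copies * u),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(), unit_length = integer(),
               copies = integer(), start = integer(), span_bp = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intergenic sequence between two genes
#'
#' Returns the sequence strictly between the two gene extents (end of the
#' left gene to start of the right gene, half-open). Overlapping genes
#' give length 0 with the negative raw separation recorded.
#'
#' @param genes gene-model data frame.
#' @param a,b gene ids.
#' @param genome `DNAStringSet` the genes live on.
#' @return list: `sequence`, `length`, `separation` (may be negative).
#' @export
intergenic_region <- function(genes, a, b, genome) {
  ga <- genes[genes$gene_id == a, , drop = FALSE]
  gb <- genes[genes$gene_id == b, , drop = FALSE]
  if (nrow(ga) != 1L || nrow(gb) != 1L) stopf("gene ids not found uniquely")
  if (ga$replicon_id != gb$replicon_id)
    stopf("genes '%s' and '%s' are on different replicons", a, b)
  left <- if (ga$start <= gb$start) ga else gb
  right <- if (ga$start <= gb$start) gb else ga
  sep <- right$start - left$end
  if (sep <= 0L)
    return(list(sequence = "", length = 0L, separation = as.integer(sep)))
  s <- as.character(genome[[match(ga$replicon_id, names(genome))]])
  list(sequence = substring(s, left$end + 1L, right$start),
       length = as.integer(sep), separation = as.integer(sep))
}
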