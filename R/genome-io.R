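#' Genome and annotation input/output
#'
#' A genome set is represented as a [Biostrings::DNAStringSet] whose element
#' metadata (`S4Vectors::mcols`) carries `topology` (`"linear"` or
#' `"circular"`) and `description`. Gene models are plain data frames with
#' 0-based half-open coordinates; all file formats (FASTA, GenBank flat file,
#' GFF3) are converted at the boundary so that downstream interval arithmetic
#' never needs a +/-1 adjustment.
#'
#' @name genome_io
NULL

GENE_COLS <- c("gene_id", "locus_tag", "replicon_id", "start", "end",
               "strand", "feature_kind", "product", "pseudo", "compound")

empty_gene_table <- function() {
  data.frame(
    gene_id = character(), locus_tag = character(), replicon_id = character(),
    start = integer(), end = integer(), strand = character(),
    feature_kind = character(), product = character(),
    pseudo = logical(), compound = logical(),
    stringsAsFactors = FALSE
  )
}

validate_iupac <- function(seq, id) {
  bad <- regexpr("[^ACGTNMRWSYKVHDB]", seq)
  if (bad > 0L) {
    stopf("non-IUPAC character '%s' at position %d of record '%s'",
          substr(seq, bad, bad), as.integer(bad), id)
  }
  invisible(TRUE)
}

make_genome_set <- function(seqs, ids, topology = "linear", description = "") {
  if (length(seqs) == 0L) stopf("empty genome set")
  if (anyDuplicated(ids)) stopf("duplicate replicon id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stopf("empty sequence for record '%s'", ids[i])
    validate_iupac(seqs[i], ids[i])
  }
  gs <- Biostrings::DNAStringSet(seqs)
  names(gs) <- ids
  S4Vectors::mcols(gs) <- S4Vectors::DataFrame(
    topology = rep_len(topology, length(gs)),
    description = rep_len(description, length(gs))
  )
  gs
}

#' Read genome sequences
#'
#' Reads one or more replicons from FASTA or a GenBank flat file into a
#' `DNAStringSet` with `topology` and `description` metadata columns.
#' Lowercase (soft-masked) input is uppercased; any character outside the
#' IUPAC DNA alphabet is a format error that names the offending position.
#'
#' @param path input file path.
#' @param format `"fasta"` or `"genbank"`.
#' @return A [Biostrings::DNAStringSet]; record order follows the file.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 demo", "acgtACGT"), fa)
#' g <- read_genome(fa)
#' names(g)
read_genome <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (format == "genbank") return(read_genbank(path)$genome)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("'%s' is not parseable FASTA: %s",
                                            path, conditionMessage(e)))
  if (length(raw) == 0L) stopf("'%s' contains no FASTA records", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  make_genome_set(as.character(raw), ids, topology = "linear", description = desc)
}

#' Write genome sequences to FASTA
#'
#' @param genome a `DNAStringSet` (as returned by [read_genome()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# ---- GenBank flat file -----------------------------------------------------
# Minimal reader for the subset this package consumes: LOCUS topology,
# DEFINITION, FEATURES with location + qualifiers, ORIGIN sequence. Compound
# (join/order) locations collapse to the outer span with compound = TRUE.

parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("complement", loc)) strand <- "-"
  compound <- grepl("join|order", loc)
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 1L) stopf("unparseable GenBank location '%s'", loc)
  start1 <- min(nums)
  end1 <- max(nums)
  if (end1 < start1) stopf("GenBank location end < start: '%s'", loc)
  list(start = as.integer(start1) - 1L, end = as.integer(end1),
       strand = strand, compound = compound)
}

read_genbank <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("'%s' is empty", path)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0L) stopf("'%s' has no LOCUS line; not GenBank", path)
  rec_ends <- grep("^//", lines)
  seqs <- character(); ids <- character(); topo <- character(); desc <- character()
  genes <- list()
  for (r in seq_along(rec_starts)) {
    from <- rec_starts[r]
    to <- if (r <= length(rec_ends)) rec_ends[r] else length(lines)
    block <- lines[from:to]
    locus <- strsplit(trimws(block[1]), "\\s+")[[1]]
    id <- locus[2]
    topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
    dline <- grep("^DEFINITION", block, value = TRUE)
    description <- if (length(dline)) sub("^DEFINITION\\s+", "", dline[1]) else ""
    # accession line overrides LOCUS name when present
    aline <- grep("^ACCESSION\\s+\\S", block, value = TRUE)
    if (length(aline)) {
      acc <- strsplit(trimws(sub("^ACCESSION", "", aline[1])), "\\s+")[[1]][1]
      if (nzchar(acc)) id <- acc
    }
    feat_from <- grep("^FEATURES", block)
    orig_from <- grep("^ORIGIN", block)
    seq <- ""
    if (length(orig_from)) {
      seq_lines <- block[(orig_from[1] + 1L):(length(block) - 1L)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    }
    if (!nzchar(seq)) stopf("GenBank record '%s' has no ORIGIN sequence", id)
    if (length(feat_from)) {
      feat_to <- if (length(orig_from)) orig_from[1] - 1L else length(block)
      flines <- block[(feat_from[1] + 1L):feat_to]
      is_key <- grepl("^ {5}\\S", flines)
      key_idx <- which(is_key)
      for (k in seq_along(key_idx)) {
        i0 <- key_idx[k]
        i1 <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(flines)
        header <- trimws(flines[i0])
        parts <- strsplit(header, "\\s+")[[1]]
        key <- parts[1]
        if (key == "source") next
        qlines <- flines[i0:i1]
        # location may continue over lines until the first qualifier
        body <- sub("^\\s*\\S+\\s+", "", qlines[1])
        j <- 2L
        while (j <= length(qlines) && !grepl("^\\s+/", qlines[j])) {
          body <- paste0(body, trimws(qlines[j])); j <- j + 1L
        }
        loc <- parse_gb_location(body)
        quals <- paste(trimws(qlines[seq_len(length(qlines)) >= j]), collapse = "\n")
        getq <- function(name) {
          m <- regmatches(quals, regexpr(sprintf('/%s="[^"]*"', name), quals))
          if (length(m)) sub(sprintf('^/%s="', name), "", sub('"$', "", m)) else ""
        }
        kind <- if (key %in% c("CDS", "gene", "rRNA", "tRNA")) key else "other"
        gid <- getq("locus_tag")
        if (!nzchar(gid)) gid <- getq("gene")
        if (!nzchar(gid)) gid <- sprintf("%s_%s_%d", id, key, loc$start + 1L)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, locus_tag = getq("locus_tag"), replicon_id = id,
          start = loc$start, end = loc$end, strand = loc$strand,
          feature_kind = kind, product = getq("product"),
          pseudo = grepl("/pseudo\\b", quals), compound = loc$compound,
          gene_kind = getq("gene_kind"),
          translation = gsub("\\s", "", getq("translation")),
          stringsAsFactors = FALSE
        )
      }
    }
    seqs <- c(seqs, seq); ids <- c(ids, id)
    topo <- c(topo, topology); desc <- c(desc, description)
  }
  gtab <- if (length(genes)) do.call(rbind, genes) else
    cbind(empty_gene_table(), gene_kind = character(), translation = character())
  list(genome = make_genome_set(seqs, ids, topo, desc), features = gtab)
}

# ---- annotation ------------------------------------------------------------

#' Read gene annotations
#'
#' Reads gene models from GFF3 or a GenBank flat file. File coordinates are
#' 1-based inclusive; the returned table is 0-based half-open, so feature
#' length is always `end - start`. Multi-part (join) locations are collapsed
#' to their outer span and flagged `compound`.
#'
#' @param path input file path.
#' @param format `"gff3"` or `"genbank"`.
#' @param kinds feature kinds to keep (default CDS only, the unit of every
#'   downstream comparison); `NULL` keeps everything.
#' @param include_pseudo keep pseudogenes (default `TRUE`).
#' @return data frame with columns `gene_id`, `locus_tag`, `replicon_id`,
#'   `start`, `end`, `strand`, `feature_kind`, `product`, `pseudo`,
#'   `compound`.
#' @export
read_annotation <- function(path, format = c("gff3", "genbank"),
                            kinds = "CDS", include_pseudo = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  tab <- if (format == "genbank") {
    read_genbank(path)$features[, GENE_COLS]
  } else {
    read_gff3(path)
  }
  if (!is.null(kinds)) tab <- tab[tab$feature_kind %in% kinds, , drop = FALSE]
  if (!include_pseudo) tab <- tab[!tab$pseudo, , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0L) warnf("'%s': no features retained", path)
  tab
}

read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("'%s' is not parseable GFF3: %s",
                                           path, conditionMessage(e)))
  if (length(gr) == 0L) return(empty_gene_table())
  md <- S4Vectors::mcols(gr)
  pick <- function(col, default = "") {
    if (col %in% colnames(md)) {
      v <- as.character(md[[col]])
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }
  id <- pick("ID")
  no_id <- !nzchar(id)
  id[no_id] <- pick("locus_tag")[no_id]
  no_id <- !nzchar(id)
  id[no_id] <- sprintf("feat_%d", which(no_id))
  type <- as.character(md$type)
  kind <- ifelse(type %in% c("CDS", "gene", "rRNA", "tRNA"), type, "other")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*" & kind == "CDS")) stopf("CDS feature without strand in '%s'", path)
  tab <- data.frame(
    gene_id = id, locus_tag = pick("locus_tag"),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = strand, feature_kind = kind, product = pick("product"),
    pseudo = pick("pseudo", NA) %in% c("true", "TRUE", ""),
    compound = FALSE, stringsAsFactors = FALSE
  )
  tab$pseudo <- "pseudo" %in% colnames(md) & !is.na(pick("pseudo", NA))
  # multi-row features sharing an ID collapse to the outer span
  if (anyDuplicated(tab$gene_id)) {
    sp <- split(tab, tab$gene_id)
    tab <- do.call(rbind, lapply(sp, function(d) {
      if (nrow(d) == 1L) return(d)
      d1 <- d[1, , drop = FALSE]
      d1$start <- min(d$start); d1$end <- max(d$end); d1$compound <- TRUE
      d1
    }))
    tab <- tab[order(tab$replicon_id, tab$start), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write gene annotations as GFF3
#'
#' The inverse of [read_annotation()]: internal 0-based half-open
#' coordinates are converted back to GFF3's 1-based inclusive convention.
#'
#' @param genes gene-model data frame.
#' @param path output path.
#' @param source source column value for the GFF3 records.
#' @return the path, invisibly.
#' @export
write_annotation <- function(genes, path, source = "strainlift") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0L) {
    attrs <- sprintf("ID=%s", genes$gene_id)
    has_lt <- nzchar(genes$locus_tag)
    attrs[has_lt] <- paste0(attrs[has_lt], ";locus_tag=", genes$locus_tag[has_lt])
    has_pr <- nzchar(genes$product)
    attrs[has_pr] <- paste0(attrs[has_pr], ";product=",
                            gsub("[;=&,]", "_", genes$product[has_pr]))
    attrs[genes$pseudo] <- paste0(attrs[genes$pseudo], ";pseudo=true")
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       genes$replicon_id, source, genes$feature_kind,
                       genes$start + 1L, genes$end, genes$strand, attrs), con)
  }
  invisible(path)
}

# ---- sequence statistics ---------------------------------------------------

as_seq_char <- function(x) {
  if (is.character(x)) return(toupper(x[1]))
  as.character(x)  # DNAString / DNAStringSet element
}

#' Census of ambiguity codes in a sequence
#'
#' Counts every non-ACGT position exactly once, and reports maximal runs of
#' consecutive ambiguous positions classified as `"N"` runs or `"other"`
#' (non-N ambiguity codes). Case-insensitive.
#'
#' @param seq a character string, `DNAString`, or single-element
#'   `DNAStringSet`.
#' @return An object of class `ambiguity_census`: list with `counts` (named
#'   integer vector over ambiguity codes), `runs` (data frame `class`,
#'   `start` (0-based), `length`), and `total_ambiguous`.
#' @export
#' @examples
#' scan_ambiguities("ACNNNGTMSK")$counts
scan_ambiguities <- function(seq) {
  if (inherits(seq, "DNAStringSet")) seq <- seq[[1]]
  s <- strsplit(as_seq_char(seq), "", fixed = TRUE)[[1]]
  is_amb <- !(s %in% c("A", "C", "G", "T"))
  counts <- integer(0)
  runs <- data.frame(class = character(), start = integer(), length = integer(),
                     stringsAsFactors = FALSE)
  if (any(is_amb)) {
    tb <- table(s[is_amb])
    counts <- setNames(as.integer(tb), names(tb))
    cls <- ifelse(!is_amb, "base", ifelse(s == "N", "N", "other"))
    r <- rle(cls)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    keep <- r$values != "base"
    runs <- data.frame(class = r$values[keep], start = starts[keep],
                       length = r$lengths[keep], stringsAsFactors = FALSE)
    rownames(runs) <- NULL
  }
  structure(list(counts = counts, runs = runs,
                 total_ambiguous = sum(is_amb)),
            class = "ambiguity_census")
}

#' @export
print.ambiguity_census <- function(x, ...) {
  cat("ambiguity census:", x$total_ambiguous, "ambiguous position(s)\n")
  if (length(x$counts)) {
    cat(paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
    cat(nrow(x$runs), "maximal run(s)\n")
  }
  invisible(x)
}

#' Length and GC content of a sequence
#'
#' GC percent counts S (C-or-G) toward GC; all other ambiguity codes count
#' in the denominator only. Reported to one decimal, matching genome-report
#' convention.
#'
#' @param seq a character string, `DNAString`, or single-element
#'   `DNAStringSet`.
#' @return list with `length` (bp) and `gc_percent`.
#' @export
sequence_stats <- function(seq) {
  if (inherits(seq, "DNAStringSet")) seq <- seq[[1]]
  s <- as_seq_char(seq)
  n <- nchar(s)
  gc <- sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C", "S"))
  list(length = n, gc_percent = round_half_up(100 * gc / n, 1))
}

#' Per-replicon summary table
#'
#' @param genome a `DNAStringSet` genome set.
#' @return data frame with columns `replicon`, `length_bp`, `gc_percent`,
#'   `n_count`, `ambiguous_total`.
#' @export
replicon_stats <- function(genome) {
  rows <- lapply(seq_along(genome), function(i) {
    st <- sequence_stats(genome[[i]])
    cen <- scan_ambiguities(genome[[i]])
    nn <- if ("N" %in% names(cen$counts)) cen$counts[["N"]] else 0L
    data.frame(replicon = names(genome)[i], length_bp = st$length,
               gc_percent = st$gc_percent, n_count = nn,
               ambiguous_total = cen$total_ambiguous, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
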