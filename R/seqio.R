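# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate convention: every coordinate held in memory is 0-based
# half-open. 1-based fields (SAM POS, GFF3 start/end, catalog positions)
# are converted at the file boundary, in both directions.

#' Read a FASTA file into named uppercase sequences
#'
#' @param path path to a FASTA file
#' @return named character vector: names are record ids (first token of the
#'   header), values are uppercase sequences with line wrapping removed
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate FASTA id: ", dup[1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---- CIGAR arithmetic -------------------------------------------------------

# Parse a vector of CIGAR strings into a list of data.tables (op, len).
cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  toks <- regmatches(cigar, m)
  lapply(toks, function(tk) {
    if (length(tk) == 0L || (length(tk) == 1L && tk == "")) {
      return(data.table::data.table(op = character(0), len = integer(0)))
    }
    data.table::data.table(
      op  = substring(tk, nchar(tk), nchar(tk)),
      len = as.integer(substring(tk, 1L, nchar(tk) - 1L))
    )
  })
}

# Reference-consumed length per CIGAR (M, D, N, =, X).
cigar_ref_length <- function(cigar) {
  vapply(cigar_ops(cigar), function(d) {
    sum(d$len[d$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# Query-consumed length per CIGAR (M, I, S, =, X).
cigar_query_length <- function(cigar) {
  vapply(cigar_ops(cigar), function(d) {
    sum(d$len[d$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}

# Leading/trailing soft-clip lengths, vectorized.
cigar_clip_lengths <- function(cigar) {
  left <- integer(length(cigar))
  right <- integer(length(cigar))
  hl <- grepl("^\\d+S", cigar)
  left[hl] <- as.integer(sub("^(\\d+)S.*$", "\\1", cigar[hl]))
  hr <- grepl("\\d+S$", cigar) & !grepl("^\\d+S$", cigar)
  right[hr] <- as.integer(sub("^.*?(\\d+)S$", "\\1", cigar[hr]))
  data.table::data.table(left = left, right = right)
}

# ---- SAM --------------------------------------------------------------------

#' Parse a SAM file into an alignment table
#'
#' Unmapped records and records below `min_mapq` are skipped. Soft-clipped
#' sequences are extracted from the CIGAR and the stored query sequence.
#'
#' @param path path to a SAM file (tab-separated text with `@` header lines)
#' @param min_mapq minimum mapping quality; records below it are dropped.
#'   The long-read and short-read callers in this package pass 40, matching
#'   the common practice of discarding sub-q40 alignments for insertion
#'   evidence; the default 0 keeps everything mapped.
#' @param keep_duplicates keep records flagged as PCR/optical duplicates
#'   (default FALSE: duplicates carry no independent evidence)
#' @return a `data.table` with one row per retained alignment; columns
#'   `read_id, mate, flag, chrom, start, end, strand, mapq, cigar, seq,
#'   clip_left, clip_right, is_proper, is_dup, is_mapped, mate_chrom,
#'   mate_pos, tlen, tags`. `start`/`end` are 0-based half-open.
#' @export
parse_alignments <- function(path, min_mapq = 0L, keep_duplicates = FALSE) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_alignment_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    stop("malformed SAM record at line ", which(nf < 11L)[1L])
  }
  fx <- function(i) vapply(parts, `[[`, character(1), i)
  aln <- data.table::data.table(
    read_id = fx(1L),
    flag    = as.integer(fx(2L)),
    chrom   = fx(3L),
    pos1    = as.integer(fx(4L)),
    mapq    = as.integer(fx(5L)),
    cigar   = fx(6L),
    rnext   = fx(7L),
    pnext   = as.integer(fx(8L)),
    tlen    = as.integer(fx(9L)),
    seq     = fx(10L),
    tags    = vapply(parts, function(p) {
      if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else ""
    }, character(1))
  )
  aln[, is_mapped := bitwAnd(flag, 4L) == 0L]
  aln[, is_dup := bitwAnd(flag, 1024L) != 0L]
  aln[, is_proper := bitwAnd(flag, 2L) != 0L]
  aln[, strand := ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]
  aln[, mate := data.table::fcase(
    bitwAnd(flag, 64L) != 0L, 1L,
    bitwAnd(flag, 128L) != 0L, 2L,
    default = NA_integer_)]
  # validate CIGAR vs sequence length for mapped records carrying a sequence
  chk <- aln$is_mapped & aln$seq != "*" & aln$cigar != "*"
  if (any(chk)) {
    qlen <- cigar_query_length(aln$cigar[chk])
    bad <- qlen != nchar(aln$seq[chk])
    if (any(bad)) {
      stop("CIGAR/sequence length mismatch for read ",
           aln$read_id[chk][bad][1L])
    }
  }
  aln <- aln[is_mapped & mapq >= min_mapq]
  if (!keep_duplicates) aln <- aln[is_dup == FALSE]
  if (nrow(aln) == 0L) return(empty_alignment_table())
  aln[, start := pos1 - 1L]
  aln[, end := start + cigar_ref_length(cigar)]
  cl <- cigar_clip_lengths(aln$cigar)
  qn <- nchar(aln$seq)
  aln[, clip_left := ifelse(cl$left > 0L & seq != "*",
                            substr(seq, 1L, cl$left), "")]
  aln[, clip_right := ifelse(cl$right > 0L & seq != "*",
                             substr(seq, qn - cl$right + 1L, qn), "")]
  aln[, mate_chrom := ifelse(rnext == "=", chrom, rnext)]
  aln[, mate_pos := pnext - 1L]
  aln[, c("pos1", "rnext", "pnext") := NULL]
  data.table::setcolorder(aln, alignment_columns())
  aln[]
}

alignment_columns <- function() {
  c("read_id", "mate", "flag", "chrom", "start", "end", "strand", "mapq",
    "cigar", "seq", "clip_left", "clip_right", "is_proper", "is_dup",
    "is_mapped", "mate_chrom", "mate_pos", "tlen", "tags")
}

empty_alignment_table <- function() {
  data.table::data.table(
    read_id = character(0), mate = integer(0), flag = integer(0),
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), mapq = integer(0), cigar = character(0),
    seq = character(0), clip_left = character(0), clip_right = character(0),
    is_proper = logical(0), is_dup = logical(0), is_mapped = logical(0),
    mate_chrom = character(0), mate_pos = integer(0), tlen = integer(0),
    tags = character(0))
}

#' Write an alignment table to a SAM file
#'
#' @param aln alignment table as returned by [parse_alignments()] or built
#'   by the simulator; an optional `tags` column is appended verbatim
#' @param path output path
#' @param seq_lengths named integer vector of reference sequence lengths
#'   for the `@SQ` header lines
#' @export
write_sam <- function(aln, path, seq_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(aln) > 0L) {
    tags <- if ("tags" %in% names(aln)) aln$tags else rep("", nrow(aln))
    body <- paste(
      aln$read_id, aln$flag,
      ifelse(aln$chrom == "" | is.na(aln$chrom), "*", aln$chrom),
      ifelse(is.na(aln$start), 0L, aln$start + 1L),
      aln$mapq, ifelse(aln$cigar == "" | is.na(aln$cigar), "*", aln$cigar),
      ifelse(is.na(aln$mate_chrom) | aln$mate_chrom == "", "*",
             ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom)),
      ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos + 1L),
      ifelse(is.na(aln$tlen), 0L, aln$tlen),
      ifelse(aln$seq == "" | is.na(aln$seq), "*", aln$seq),
      "*",
      sep = "\t")
    body <- ifelse(tags == "", body, paste(body, tags, sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

# ---- GFF3 -------------------------------------------------------------------

#' Write insertion candidates to a GFF3 file
#'
#' One `te_insertion` feature per candidate. The feature span is the TSD
#' (first to last duplicated base, 1-based closed) or the single junction
#' base when no TSD was called. Attributes carry the TE family, TSD
#' sequence, support counts and the junction clip consensus sequences.
#'
#' @param candidates candidate table as produced by [emit_candidates()]
#' @param path output path
#' @export
write_gff <- function(candidates, path) {
  if (nrow(candidates) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = candidates$chrom,
    ranges = IRanges::IRanges(
      start = candidates$gff_start,
      end = candidates$gff_end),
    strand = "*")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "teclone",
    type = "te_insertion",
    ID = candidates$candidate_id,
    te_family = candidates$te_family,
    tsd_seq = ifelse(is.na(candidates$tsd_seq), "", candidates$tsd_seq),
    split_support = candidates$split_support,
    mate_support = candidates$mate_support,
    clip_5p = ifelse(is.na(candidates$clip_5p), "", candidates$clip_5p),
    clip_3p = ifelse(is.na(candidates$clip_3p), "", candidates$clip_3p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an insertion-candidate GFF3 back into a table
#'
#' Inverse of [write_gff()]; used for round-trips and for consuming
#' candidate files from other runs.
#'
#' @param path GFF3 path
#' @return data.table with the candidate columns that [write_gff()] emits
#' @export
read_gff_candidates <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(data.table::data.table(
      candidate_id = character(0), chrom = character(0),
      gff_start = integer(0), gff_end = integer(0),
      te_family = character(0), tsd_seq = character(0),
      split_support = integer(0), mate_support = integer(0),
      clip_5p = character(0), clip_3p = character(0)))
  }
  mc <- S4Vectors::mcols(gr)
  data.table::data.table(
    candidate_id = as.character(mc$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    gff_start = GenomicRanges::start(gr),
    gff_end = GenomicRanges::end(gr),
    te_family = as.character(mc$te_family),
    tsd_seq = as.character(mc$tsd_seq),
    split_support = as.integer(as.character(mc$split_support)),
    mate_support = as.integer(as.character(mc$mate_support)),
    clip_5p = as.character(mc$clip_5p),
    clip_3p = as.character(mc$clip_3p))
}

# ---- catalogs ---------------------------------------------------------------

catalog_canonical_columns <- function() {
  c("sample_id", "genotype", "tissue", "chrom", "position", "te_family",
    "te_class", "tsd_sequence", "tsd_length", "support_split",
    "support_mate", "allele_frequency")
}

#' Read an insertion catalog table
#'
#' Catalogs are delimited text with a header. Because supplementary-table
#' headers vary between sources, a column mapping (canonical name ->
#' file column name) can be supplied; unmapped canonical columns fall back
#' to identically-named file columns.
#'
#' @param path path to a TSV/CSV catalog
#' @param mapping optional named character vector, names are canonical
#'   column names (see Details), values are the column names used in the
#'   file
#' @details Canonical columns: `sample_id, genotype, tissue, chrom,
#'   position` (1-based insertion point), `te_family, te_class,
#'   tsd_sequence, tsd_length, support_split, support_mate,
#'   allele_frequency`. `position, te_family` and `chrom` are mandatory;
#'   the rest default to NA when absent.
#' @return typed `data.table` in canonical column order
#' @export
read_catalog <- function(path, mapping = NULL) {
  raw <- data.table::fread(path, header = TRUE, sep = "auto",
                           colClasses = list(character = 1))
  canon <- catalog_canonical_columns()
  resolved <- stats::setNames(canon, canon)
  if (!is.null(mapping)) {
    bad <- setdiff(names(mapping), canon)
    if (length(bad) > 0L) stop("unknown canonical column in mapping: ", bad[1L])
    resolved[names(mapping)] <- mapping
  }
  mandatory <- c("chrom", "position", "te_family")
  for (col in mandatory) {
    if (!resolved[[col]] %in% names(raw)) {
      stop("missing mandatory catalog column: ", resolved[[col]])
    }
  }
  out <- data.table::data.table(row_index = seq_len(nrow(raw)))
  for (col in canon) {
    src <- resolved[[col]]
    out[[col]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  out[, row_index := NULL]
  # type coercion with line-number reporting
  coerce_num <- function(col, as_int = FALSE) {
    v <- out[[col]]
    if (all(is.na(v))) return(if (as_int) rep(NA_integer_, nrow(out))
                              else rep(NA_real_, nrow(out)))
    w <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(w))
    if (length(bad) > 0L) {
      stop("catalog column ", col, " fails numeric coercion at data line ",
           bad[1L])
    }
    if (as_int) as.integer(w) else w
  }
  out[, position := coerce_num("position", as_int = TRUE)]
  out[, tsd_length := coerce_num("tsd_length", as_int = TRUE)]
  out[, support_split := coerce_num("support_split", as_int = TRUE)]
  out[, support_mate := coerce_num("support_mate", as_int = TRUE)]
  out[, allele_frequency := coerce_num("allele_frequency")]
  for (col in c("sample_id", "genotype", "tissue", "chrom", "te_family",
                "te_class", "tsd_sequence")) {
    out[[col]] <- as.character(out[[col]])
  }
  # tsd_length must agree with the sequence when both are present
  has_seq <- !is.na(out$tsd_sequence) & out$tsd_sequence != ""
  mism <- which(has_seq & !is.na(out$tsd_length) &
                  nchar(out$tsd_sequence) != out$tsd_length)
  if (length(mism) > 0L) {
    stop("tsd_length disagrees with tsd_sequence at data line ", mism[1L])
  }
  out[is.na(tsd_length) & has_seq, tsd_length := nchar(tsd_sequence)]
  out[]
}

#' Write an insertion catalog
#'
#' @param catalog catalog table with canonical columns
#' @param path output TSV path
#' @export
write_catalog <- function(catalog, path) {
  cols <- intersect(catalog_canonical_columns(), names(catalog))
  data.table::fwrite(catalog[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

# ---- BED tracks -------------------------------------------------------------

#' Read a BED (3-6 column) track as a GRanges
#'
#' @param path BED path
#' @return `GRanges` with track intervals
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "bed")
}
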