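# Evidence tagging: annotate genome alignments with TE homology carried by
# the read itself (a soft-clipped portion aligning to a TE consensus) or by
# its mate (mate aligned to a consensus). Tagged reads are the input units
# for per-locus clustering.

#' Tag genome alignments with TE-homology evidence
#'
#' A genome alignment is tagged with `self` evidence when the same read has
#' an alignment against the TE consensus library whose query interval
#' overlaps a soft-clipped portion of the genome alignment of at least
#' `min_clip` bases. It is tagged with `mate` evidence when its mate
#' aligns to a consensus. When several consensus sequences of the same
#' family hit one read the best-scoring hit per family is kept; across
#' families the best score wins, with ties broken lexicographically by
#' family name and flagged ambiguous.
#'
#' @param genome_aln alignment table against the reference genome
#' @param te_aln alignment table against the TE consensus library
#' @param family_of named character vector mapping consensus name to
#'   family; defaults to the identity (consensus per family)
#' @param min_clip minimum soft-clip length for self evidence
#' @param min_te_len minimum TE-aligned length for a hit to count
#' @return data.table of tagged reads: the genome alignment columns plus
#'   `evidence_source` (`self`/`mate`), `clip_side` (`5p` right-clip /
#'   `3p` left-clip, NA for mate evidence), `te_reference`, `te_family`,
#'   `te_aln_start`, `te_aln_end`, `te_query_start`, `te_query_end`
#'   (0-based half-open on the genome-oriented read), `te_orientation`
#'   (`same`/`opposite` relative to the genome alignment), `te_score`,
#'   `te_ambiguous`
#' @export
tag_reads <- function(genome_aln, te_aln, family_of = NULL,
                      min_clip = 10L, min_te_len = 15L) {
  empty <- .empty_tagged()
  if (nrow(genome_aln) == 0L || nrow(te_aln) == 0L) return(empty)
  te <- data.table::as.data.table(te_aln)
  te <- te[is_mapped == TRUE & seq != "*" & seq != ""]
  n_noseq <- nrow(data.table::as.data.table(te_aln)) - nrow(te)
  if (n_noseq > 0L) {
    warning(n_noseq, " TE alignment(s) without query sequence skipped")
  }
  if (nrow(te) == 0L) return(empty)
  te[, te_score := end - start]
  te <- te[te_score >= min_te_len]
  if (nrow(te) == 0L) return(empty)
  fam <- if (is.null(family_of)) {
    stats::setNames(unique(te$chrom), unique(te$chrom))
  } else family_of
  te[, te_family := unname(fam[chrom])]
  te[is.na(te_family), te_family := chrom]
  # query interval in the stored (consensus) orientation from the CIGAR
  cl <- cigar_clip_lengths(te$cigar)
  qlen <- nchar(te$seq)
  te[, `:=`(q_start = cl$left, q_end = qlen - cl$right, q_len = qlen)]
  # best hit per family, then best per read; deterministic ordering
  data.table::setorder(te, read_id, mate, te_family, -te_score, chrom,
                       start)
  per_fam <- te[, .SD[1L], by = .(read_id, mate, te_family)]
  data.table::setorder(per_fam, read_id, mate, -te_score, te_family)
  best <- per_fam[, {
    amb <- sum(te_score == te_score[1L]) > 1L
    c(.SD[1L], list(te_ambiguous = amb))
  }, by = .(read_id, mate)]

  gen <- data.table::as.data.table(genome_aln)
  gen <- gen[is_mapped == TRUE & is_dup == FALSE &
               bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L]
  if (nrow(gen) == 0L) return(empty)

  hit_cols <- c("chrom", "start", "end", "strand", "q_start", "q_end",
                "q_len", "te_family", "te_score", "te_ambiguous")
  hits <- best[, c("read_id", "mate", hit_cols), with = FALSE]
  data.table::setnames(hits, hit_cols,
                       c("te_reference", "te_aln_start", "te_aln_end",
                         "te_strand", "te_q_start", "te_q_end", "te_q_len",
                         "te_family", "te_score", "te_ambiguous"))

  # ---- self evidence -------------------------------------------------
  self <- merge(gen, hits, by = c("read_id", "mate"))
  if (nrow(self) > 0L) {
    # convert the hit's query interval to the genome-stored orientation
    flip <- self$strand != self$te_strand
    qs <- ifelse(flip, self$te_q_len - self$te_q_end, self$te_q_start)
    qe <- ifelse(flip, self$te_q_len - self$te_q_start, self$te_q_end)
    n <- nchar(self$seq)
    lcl <- nchar(self$clip_left)
    rcl <- nchar(self$clip_right)
    ov_left <- pmin(qe, lcl) - pmax(qs, 0L)
    ov_right <- pmin(qe, n) - pmax(qs, n - rcl)
    right_ok <- rcl >= min_clip & ov_right > 0L
    left_ok <- lcl >= min_clip & ov_left > 0L
    self[, clip_side := data.table::fifelse(
      right_ok & (!left_ok | ov_right >= ov_left), "5p",
      data.table::fifelse(left_ok, "3p", NA_character_))]
    self[, `:=`(evidence_source = "self", te_query_start = as.integer(qs),
                te_query_end = as.integer(qe))]
    self <- self[!is.na(clip_side)]
  } else {
    self[, `:=`(clip_side = character(0), evidence_source = character(0),
                te_query_start = integer(0), te_query_end = integer(0))]
  }

  # ---- mate evidence -------------------------------------------------
  mate_hits <- data.table::copy(hits)
  mate_hits[, mate := 3L - mate]
  mates <- merge(gen, mate_hits, by = c("read_id", "mate"))
  if (nrow(mates) > 0L) {
    mates[, `:=`(evidence_source = "mate", clip_side = NA_character_,
                 te_query_start = te_q_start, te_query_end = te_q_end)]
  } else {
    mates[, `:=`(evidence_source = character(0),
                 clip_side = character(0),
                 te_query_start = integer(0), te_query_end = integer(0))]
  }

  out <- data.table::rbindlist(list(self, mates), use.names = TRUE)
  if (nrow(out) == 0L) return(empty)
  out[, te_orientation := ifelse(strand == te_strand, "same", "opposite")]
  out[, c("te_strand", "te_q_start", "te_q_end", "te_q_len") := NULL]
  data.table::setorder(out, chrom, start, read_id, mate, evidence_source)
  out[]
}

.empty_tagged <- function() {
  out <- empty_alignment_table()
  out[, `:=`(evidence_source = character(0), clip_side = character(0),
             te_reference = character(0), te_family = character(0),
             te_aln_start = integer(0), te_aln_end = integer(0),
             te_query_start = integer(0), te_query_end = integer(0),
             te_orientation = character(0), te_score = integer(0),
             te_ambiguous = logical(0))]
  out
}

# custom SAM tags carrying the TE hit (documented in the README):
#   ts:Z: self-evidence hit, tm:Z: mate-evidence hit
# value: te_reference,family,aln_start,aln_end,query_start,query_end,
#        orientation,score,ambiguous(0/1)[,clip_side]
.format_te_tag <- function(tg) {
  paste(tg$te_reference, tg$te_family, tg$te_aln_start, tg$te_aln_end,
        tg$te_query_start, tg$te_query_end, tg$te_orientation, tg$te_score,
        as.integer(tg$te_ambiguous),
        ifelse(is.na(tg$clip_side), ".", tg$clip_side), sep = ",")
}

#' Serialize tagged reads to a SAM file with custom tags
#'
#' Self evidence is written as a `ts:Z:` tag, mate evidence as `tm:Z:`;
#' both encode the full TE hit (consensus, family, consensus interval,
#' query interval, orientation, score, ambiguity, clip side) so the file
#' can be inspected in a genome browser and parsed back without loss.
#' When `genome_aln` is supplied, untagged alignments pass through
#' unmodified.
#'
#' @param tagged tagged-read table from [tag_reads()]
#' @param path output SAM path
#' @param seq_lengths named reference lengths for the header
#' @param genome_aln optional full alignment table for passthrough mode
#' @export
serialize_tags <- function(tagged, path, seq_lengths, genome_aln = NULL) {
  base <- if (is.null(genome_aln)) tagged else
    data.table::as.data.table(genome_aln)
  base <- base[, alignment_columns(), with = FALSE]
  base <- unique(base, by = c("read_id", "mate", "chrom", "start", "cigar"))
  if (nrow(tagged) > 0L) {
    tg <- data.table::as.data.table(tagged)
    tg[, tagval := .format_te_tag(.SD)]
    tg[, tagstr := paste0(ifelse(evidence_source == "self", "ts:Z:",
                                 "tm:Z:"), tagval)]
    tags <- tg[, .(tags = paste(sort(tagstr), collapse = "\t")),
               by = .(read_id, mate, chrom, start, cigar)]
    data.table::setkey(tags, read_id, mate, chrom, start, cigar)
    data.table::setkey(base, read_id, mate, chrom, start, cigar)
    base[tags, tags := i.tags]
  }
  data.table::setorder(base, chrom, start, read_id, mate)
  write_sam(base, path, seq_lengths)
}

#' Parse a tagged SAM back into a tagged-read table
#'
#' Inverse of [serialize_tags()].
#'
#' @param path SAM path written by [serialize_tags()]
#' @param min_mapq minimum mapping quality
#' @return tagged-read table; untagged records are dropped
#' @export
parse_tagged_sam <- function(path, min_mapq = 0L) {
  aln <- parse_alignments(path, min_mapq = min_mapq)
  if (nrow(aln) == 0L) return(.empty_tagged())
  rows <- list()
  for (i in which(aln$tags != "")) {
    for (tagstr in strsplit(aln$tags[i], "\t", fixed = TRUE)[[1]]) {
      if (!grepl("^t[sm]:Z:", tagstr)) next
      src <- if (startsWith(tagstr, "ts")) "self" else "mate"
      f <- strsplit(sub("^t[sm]:Z:", "", tagstr), ",", fixed = TRUE)[[1]]
      row <- aln[i]
      row[, `:=`(evidence_source = src,
                 te_reference = f[1], te_family = f[2],
                 te_aln_start = as.integer(f[3]),
                 te_aln_end = as.integer(f[4]),
                 te_query_start = as.integer(f[5]),
                 te_query_end = as.integer(f[6]),
                 te_orientation = f[7], te_score = as.integer(f[8]),
                 te_ambiguous = f[9] == "1",
                 clip_side = ifelse(f[10] == ".", NA_character_, f[10]))]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(.empty_tagged())
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, chrom, start, read_id, mate, evidence_source)
  out[]
}
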