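# Long-read arm: read-size normalization across libraries, extraction of
# TE-homologous insert/clip segments from single reads, and
# tissue-specific singleton calling.

#' Normalize read-length distributions across libraries
#'
#' Reads are binned by length on a log-spaced grid; each library is
#' subsampled (seeded, without replacement) to the per-bin minimum count
#' across libraries, so all libraries end with identical binned
#' histograms. Normalizing already-normalized libraries keeps every read.
#'
#' @param libraries named list; each element either a numeric vector of
#'   read lengths or a table with `read_id` and `len` columns
#' @param seed integer seed for the subsampling
#' @param breaks bin boundaries; the default is a fixed log-spaced grid
#'   from 100 bases to 1 Mb (five bins per decade), so normalization is
#'   idempotent and comparable across runs; lengths outside the grid fall
#'   into the terminal bins
#' @return list with `keep` (per-library integer indices of retained
#'   reads, sorted), `breaks` (bin boundaries) and `bin_counts` (the
#'   common post-normalization histogram)
#' @export
normalize_read_sizes <- function(libraries, seed = 1L,
                                 breaks = 10^seq(2, 6, by = 0.2)) {
  if (length(libraries) < 2L) stop("need at least 2 libraries")
  lens <- lapply(libraries, function(x) {
    if (is.numeric(x)) as.numeric(x) else as.numeric(x$len)
  })
  all_len <- unlist(lens)
  if (length(all_len) == 0L) stop("no reads")
  bins <- lapply(lens, function(x) {
    findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  })
  nb <- length(breaks) - 1L
  counts <- vapply(bins, function(b) tabulate(b, nbins = nb),
                   integer(nb))
  target <- apply(counts, 1L, min)
  keep <- with_seed(seed, {
    lapply(bins, function(b) {
      kept <- integer(0)
      for (bin in which(target > 0L)) {
        idx <- which(b == bin)
        kept <- c(kept, if (length(idx) == target[bin]) idx else
          idx[sample.int(length(idx), target[bin])])
      }
      sort(kept)
    })
  })
  names(keep) <- names(libraries)
  list(keep = keep, breaks = breaks, bin_counts = target)
}

#' Local alignment of a segment against the TE consensus library
#'
#' k-mer-seeded, banded Smith-Waterman against each consensus on both
#' strands (linear gap penalty; match 2, mismatch -3, gap -4).
#' Consensus sequences sharing no k-mer with the segment are rejected
#' without alignment. Hits with score below `min_score` are dropped;
#' results are sorted by descending score with deterministic tie-breaks.
#'
#' @param segment nucleotide string (insert or clip sequence)
#' @param te_library named character vector of consensus sequences
#' @param family_of optional consensus-to-family mapping
#' @param min_score minimum alignment score to report
#' @param k seed k-mer size
#' @param band band half-width around the seeded diagonals
#' @return data.table of hits: `te_reference`, `te_family`, `aln_start`,
#'   `aln_end` (0-based half-open on the consensus), `query_start`,
#'   `query_end` (on the segment, forward orientation), `orientation`
#'   (`same`/`opposite`), `score`
#' @export
local_align_te <- function(segment, te_library, family_of = NULL,
                           min_score = 50L, k = 11L, band = 50L) {
  fam <- if (is.null(family_of)) {
    stats::setNames(names(te_library), names(te_library))
  } else family_of
  n <- nchar(segment)
  seg_rc <- revcomp(segment)
  rows <- list()
  for (ref in names(te_library)) {
    cons <- te_library[[ref]]
    for (ori in c("same", "opposite")) {
      qs <- if (ori == "same") segment else seg_rc
      h <- .sw_seeded(qs, cons, k = k, band = band)
      if (h[["score"]] < min_score) next
      q0 <- h[["q_start"]]; q1 <- h[["q_end"]]
      if (ori == "opposite") {   # report on the forward segment
        tmp <- q0; q0 <- n - q1; q1 <- n - tmp
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        te_reference = ref, te_family = unname(fam[ref]),
        aln_start = h[["t_start"]], aln_end = h[["t_end"]],
        query_start = q0, query_end = q1,
        orientation = ori, score = h[["score"]])
    }
  }
  if (length(rows) == 0L) {
    return(data.table::data.table(
      te_reference = character(0), te_family = character(0),
      aln_start = integer(0), aln_end = integer(0),
      query_start = integer(0), query_end = integer(0),
      orientation = character(0), score = integer(0)))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, -score, te_family, te_reference, orientation)
  out[]
}

# TSD detection for a fully-contained insert segment: an aligner folds the
# duplicated copy into the inserted block, so the segment's tail matches
# the reference immediately left of the junction (or its head matches the
# reference immediately right). The longest exact match wins; when no
# exact match exists (sequencing errors) the scan is repeated tolerating
# up to `1 - min_identity` mismatches. Ties prefer the tail convention.
.long_tsd <- function(segment, chrom_seq, junction, max_tsd = 60L,
                      min_identity = 0.9) {
  n <- nchar(segment)
  L <- nchar(chrom_seq)
  scan <- function(thr) {
    t_hi <- min(max_tsd, n - 1L, junction)
    for (t in if (t_hi >= 1L) seq(t_hi, 1L) else integer(0)) {
      tail_seg <- substr(segment, n - t + 1L, n)
      ref_left <- substr(chrom_seq, junction - t + 1L, junction)
      if (nchar(ref_left) == t &&
          string_identity(tail_seg, ref_left) >= thr) {
        return(list(mode = "tail", tsd_len = t, tsd_seq = ref_left,
                    insert_seq = substr(segment, 1L, n - t),
                    tsd_start = junction - t, tsd_end = junction))
      }
    }
    t_hi <- min(max_tsd, n - 1L, L - junction)
    for (t in if (t_hi >= 1L) seq(t_hi, 1L) else integer(0)) {
      head_seg <- substr(segment, 1L, t)
      ref_right <- substr(chrom_seq, junction + 1L, junction + t)
      if (nchar(ref_right) == t &&
          string_identity(head_seg, ref_right) >= thr) {
        return(list(mode = "head", tsd_len = t, tsd_seq = ref_right,
                    insert_seq = substr(segment, t + 1L, n),
                    tsd_start = junction, tsd_end = junction + t))
      }
    }
    NULL
  }
  best <- scan(1.0)
  if (is.null(best) && min_identity < 1.0) best <- scan(min_identity)
  best
}

#' Extract TE-homologous insertion variants from long-read alignments
#'
#' Every CIGAR insertion (`I`) segment and every terminal soft clip of at
#' least `min_insert` bases is tested for TE homology with
#' [local_align_te()]. Alignments below `min_mapq` contribute nothing.
#' For `I` events both genomic flanks are recorded and a TSD is derived
#' from the segment/reference overlap at the junction; clip events carry
#' the single aligned flank.
#'
#' @param aln long-read alignment table (one alignment per read)
#' @param reference named chromosome sequences
#' @param te_library named consensus sequences
#' @param family_of optional consensus-to-family mapping
#' @param min_mapq minimum mapping quality (default 40)
#' @param min_insert minimum segment length tested
#' @param max_tsd,min_identity TSD detection rule
#' @param min_score,k,band passed to [local_align_te()]
#' @return data.table of variants: read, locus, `event_kind`
#'   (`insert_cigar`/`soft_clip`), flank intervals, `insert_seq`
#'   (TSD-stripped), `tsd_seq`/`tsd_length`, `insertion_point` (1-based),
#'   top TE hit (`te_family`, `te_score`), `te_cov` (fraction of the
#'   segment covered by the top hit)
#' @export
extract_long_variants <- function(aln, reference, te_library,
                                  family_of = NULL, min_mapq = 40L,
                                  min_insert = 100L, max_tsd = 60L,
                                  min_identity = 0.9, min_score = 50L,
                                  k = 11L, band = 50L) {
  aln <- data.table::as.data.table(aln)
  aln <- aln[is_mapped == TRUE & mapq >= min_mapq]
  skipped <- 0L
  rows <- list()
  add_variant <- function(rid, chrom, segment, event_kind, junction,
                          fl_l, fl_r) {
    hits <- local_align_te(segment, te_library, family_of = family_of,
                           min_score = min_score, k = k, band = band)
    if (nrow(hits) == 0L) return(invisible(NULL))
    top <- hits[1L]
    tsd <- if (event_kind == "insert_cigar") {
      .long_tsd(segment, reference[[chrom]], junction, max_tsd,
                min_identity)
    } else NULL
    ins_seq <- if (!is.null(tsd)) tsd$insert_seq else segment
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      read_id = rid, chrom = chrom, event_kind = event_kind,
      junction = junction,
      flank_left_start = fl_l[1], flank_left_end = fl_l[2],
      flank_right_start = fl_r[1], flank_right_end = fl_r[2],
      segment = segment, insert_seq = ins_seq,
      tsd_seq = if (!is.null(tsd)) tsd$tsd_seq else NA_character_,
      tsd_length = if (!is.null(tsd)) tsd$tsd_len else NA_integer_,
      insertion_point = if (!is.null(tsd)) tsd$tsd_start + 1L else
        junction + 1L,
      te_reference = top$te_reference, te_family = top$te_family,
      te_orientation = top$orientation, te_score = top$score,
      te_cov = (top$query_end - top$query_start) / nchar(segment))
    invisible(NULL)
  }
  for (i in seq_len(nrow(aln))) {
    if (aln$seq[i] == "*" || aln$seq[i] == "") {
      skipped <- skipped + 1L
      next
    }
    ops <- cigar_ops(aln$cigar[i])[[1]]
    rpos <- aln$start[i]    # reference cursor (0-based)
    qpos <- 0L              # query cursor
    chrom <- aln$chrom[i]
    for (oi in seq_len(nrow(ops))) {
      op <- ops$op[oi]; len <- ops$len[oi]
      if (op == "S") {
        if (len >= min_insert) {
          segment <- substr(aln$seq[i], qpos + 1L, qpos + len)
          if (oi == 1L) {
            add_variant(aln$read_id[i], chrom, segment, "soft_clip",
                        rpos, c(NA_integer_, NA_integer_),
                        c(rpos, aln$end[i]))
          } else {
            add_variant(aln$read_id[i], chrom, segment, "soft_clip",
                        rpos, c(aln$start[i], rpos),
                        c(NA_integer_, NA_integer_))
          }
        }
        qpos <- qpos + len
      } else if (op == "I") {
        if (len >= min_insert) {
          segment <- substr(aln$seq[i], qpos + 1L, qpos + len)
          add_variant(aln$read_id[i], chrom, segment, "insert_cigar",
                      rpos, c(aln$start[i], rpos),
                      c(rpos, aln$end[i]))
        }
        qpos <- qpos + len
      } else if (op %in% c("M", "=", "X")) {
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op %in% c("D", "N")) {
        rpos <- rpos + len
      } else if (op == "H") {
        # hard clip consumes nothing stored
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " long-read alignment(s) without sequence skipped")
  }
  if (length(rows) == 0L) {
    return(.empty_long_variant_table())
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, chrom, insertion_point, read_id)
  out[]
}

.empty_long_variant_table <- function() {
  data.table::data.table(
    read_id = character(0), chrom = character(0),
    event_kind = character(0), junction = integer(0),
    flank_left_start = integer(0), flank_left_end = integer(0),
    flank_right_start = integer(0), flank_right_end = integer(0),
    segment = character(0), insert_seq = character(0),
    tsd_seq = character(0), tsd_length = integer(0),
    insertion_point = integer(0), te_reference = character(0),
    te_family = character(0), te_orientation = character(0),
    te_score = integer(0), te_cov = numeric(0))
}

#' Call tissue-specific singleton insertions from long-read variants
#'
#' Variants are grouped into keys by chromosome, family and position
#' (within `slop`). A key is a singleton in its tissue when exactly one
#' read there supports it, and tissue-specific when no read supports it
#' in any other tissue. Full-length requirements: both genomic flanks at
#' least `min_flank` bases, TE hit covering at least `min_insert_cov` of
#' the segment, and (by default) a valid TSD.
#'
#' @param variants variant table from [extract_long_variants()] with a
#'   `tissue` column (join your read manifest beforehand)
#' @param slop key position window
#' @param min_flank minimum aligned flank on each side
#' @param min_insert_cov minimum TE coverage of the segment
#' @param require_tsd require a valid TSD
#' @param tissue_specific_only drop singletons whose key is also seen in
#'   another tissue (default TRUE: variants detected in both pools are
#'   eliminated as likely germline population variants)
#' @return data.table of singleton calls with `tissue`,
#'   `tissue_specific`, and the variant columns
#' @export
call_singletons <- function(variants, slop = 50L, min_flank = 200L,
                            min_insert_cov = 0.8, require_tsd = TRUE,
                            tissue_specific_only = TRUE) {
  v <- data.table::as.data.table(variants)
  if (!"tissue" %in% names(v)) stop("variants need a tissue column")
  if (nrow(v) == 0L) {
    v[, `:=`(key = integer(0), support_in_tissue = integer(0),
             tissue_specific = logical(0))]
    return(v)
  }
  # single-linkage keys on (chrom, family, position within slop)
  data.table::setorder(v, chrom, te_family, insertion_point, read_id)
  v[, key := cumsum(c(1L, (chrom[-1L] != chrom[-.N]) |
                        (te_family[-1L] != te_family[-.N]) |
                        (diff(insertion_point) > slop)))]
  sup <- v[, .(n = data.table::uniqueN(read_id)), by = .(key, tissue)]
  v <- merge(v, sup, by = c("key", "tissue"))
  data.table::setnames(v, "n", "support_in_tissue")
  other <- sup[, .(n_other = sum(n)), by = key]
  v <- merge(v, other, by = "key")
  v[, n_elsewhere := n_other - support_in_tissue]
  v[, tissue_specific := n_elsewhere == 0L]
  out <- v[support_in_tissue == 1L]
  out <- out[!is.na(flank_left_end - flank_left_start) &
               (flank_left_end - flank_left_start) >= min_flank &
               !is.na(flank_right_end - flank_right_start) &
               (flank_right_end - flank_right_start) >= min_flank]
  out <- out[te_cov >= min_insert_cov]
  if (require_tsd) out <- out[!is.na(tsd_seq) & tsd_seq != ""]
  if (tissue_specific_only) out <- out[tissue_specific == TRUE]
  out[, c("n_other", "n_elsewhere") := NULL]
  data.table::setorder(out, chrom, insertion_point, tissue)
  out[]
}
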