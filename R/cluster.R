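# Per-locus clustering of tagged reads, junction estimation, TSD calling
# and candidate emission.
#
# A cluster gathers evidence for one insertion locus from two sides:
# the 5' side (reads whose alignment ends at the junction: right-clipped
# split reads, or forward-oriented mate-support reads) and the 3' side
# (left-clipped split reads starting where the reference resumes, or
# reverse-oriented mate-support reads). When the 3' junction lies a few
# bases left of the 5' junction the intervening reference bases were
# duplicated at integration: the TSD.

#' Estimate the central 95% interval of the insert-size distribution
#'
#' Computed from absolute template lengths of proper, non-duplicate pairs
#' (one template per pair). The upper bound is the clustering distance for
#' insertion evidence.
#'
#' @param aln alignment table
#' @return list with `low` and `high`, the empirical 2.5th and 97.5th
#'   percentiles (inverse-ECDF, i.e. sort-and-index, quantile type 1)
#' @export
estimate_insert_interval <- function(aln) {
  aln <- data.table::as.data.table(aln)
  x <- aln[is_proper == TRUE & is_dup == FALSE & tlen > 0L, abs(tlen)]
  if (length(x) < 2L) stop("fewer than 2 proper pairs; cannot estimate ",
                           "insert-size interval")
  q <- stats::quantile(x, c(0.025, 0.975), type = 1, names = FALSE)
  list(low = q[1], high = q[2])
}

# Clustering unit per tagged read: one row per (read_id, mate), self
# evidence preferred over mate evidence, with junction side and anchor.
.cluster_units <- function(tagged, min_clip = 10L) {
  tg <- data.table::as.data.table(tagged)
  ord <- order(tg$read_id, tg$mate,
               match(tg$evidence_source, c("self", "mate")))
  tg <- tg[ord]
  tg <- unique(tg, by = c("read_id", "mate"))
  tg[, is_split := evidence_source == "self" & !is.na(clip_side)]
  tg[, side := data.table::fcase(
    is_split & clip_side == "5p", "5p",
    is_split & clip_side == "3p", "3p",
    strand == "+", "5p",
    default = "3p")]
  tg[, anchor := ifelse(side == "5p", end, start)]
  tg[, clip_seq := data.table::fcase(
    is_split & clip_side == "5p", clip_right,
    is_split & clip_side == "3p", clip_left,
    default = "")]
  data.table::setorder(tg, chrom, anchor, read_id, mate)
  tg
}

# Do two clustering units conflict? Only same-side informative clips can
# conflict (both >= min_clip and anchored identity below threshold).
.units_conflict <- function(u1, u2, min_clip, min_identity) {
  if (!u1$is_split || !u2$is_split) return(FALSE)
  if (u1$side != u2$side) return(FALSE)
  cmp <- clips_compatible(u1$clip_seq, u2$clip_seq,
                          side = if (u1$side == "5p") "right" else "left",
                          min_len = min_clip, min_identity = min_identity)
  isFALSE(cmp)
}

#' Group tagged reads into per-locus evidence clusters
#'
#' Single-linkage clustering: two tagged reads join the same cluster when
#' their junction anchors lie within `interval$high` of each other on the
#' same chromosome and their clip sequences do not conflict (same-side
#' clips of at least `min_clip` bases must match with at least
#' `min_identity` anchored identity). Equivalent to connected components
#' of the full pairwise compatibility graph.
#'
#' @param tagged tagged-read table from [tag_reads()]
#' @param interval insert-size interval from [estimate_insert_interval()]
#' @param min_clip minimum informative clip length
#' @param min_identity anchored clip identity threshold
#' @return list with `members` (clustering units with `cluster_id`) and
#'   `clusters` (per-cluster summary: junctions, supports, clip
#'   consensus, family votes), both sorted deterministically
#' @export
find_clusters <- function(tagged, interval, min_clip = 10L,
                          min_identity = 0.9) {
  units <- .cluster_units(tagged, min_clip)
  if (nrow(units) == 0L) {
    return(list(members = units, clusters = .empty_cluster_table()))
  }
  units[, cluster_id := NA_integer_]
  next_id <- 0L
  for (chr in unique(units$chrom)) {
    idx <- which(units$chrom == chr)
    n <- length(idx)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    # units are anchor-sorted: only pairs within the distance window can
    # link, so a sliding window reproduces the full pairwise graph
    anchors <- units$anchor[idx]
    sp <- units$is_split[idx]
    sd_ <- units$side[idx]
    cs <- units$clip_seq[idx]
    conflict <- function(i, j) {
      if (!sp[i] || !sp[j] || sd_[i] != sd_[j]) return(FALSE)
      isFALSE(clips_compatible(
        cs[i], cs[j], side = if (sd_[i] == "5p") "right" else "left",
        min_len = min_clip, min_identity = min_identity))
    }
    for (i in seq_len(n)) {
      j <- i - 1L
      while (j >= 1L && anchors[i] - anchors[j] <= interval$high) {
        ri <- find(i); rj <- find(j)
        if (ri != rj && !conflict(i, j)) {
          parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j - 1L
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    ids <- match(roots, sort(unique(roots)))
    data.table::set(units, i = idx, j = "cluster_id",
                    value = next_id + ids)
    next_id <- next_id + max(ids)
  }
  clusters <- .summarize_clusters(units)
  list(members = units, clusters = clusters)
}

# Consensus clip for one side: most frequent sequence; ties broken by
# length (longer first) then lexicographically.
.consensus_clip <- function(seqs) {
  seqs <- seqs[seqs != ""]
  if (length(seqs) == 0L) return(NA_character_)
  tab <- table(seqs)
  best <- names(tab)[tab == max(tab)]
  best[order(-nchar(best), best)][1L]
}

.summarize_clusters <- function(units) {
  units[, {
    five_split <- is_split & side == "5p"
    three_split <- is_split & side == "3p"
    p1 <- if (any(five_split)) modal_value(anchor[five_split]) else NA_real_
    p2 <- if (any(three_split)) modal_value(anchor[three_split]) else
      NA_real_
    # mate-only junction fallback: midpoint between innermost mate anchors
    mid <- if (!any(is_split)) {
      five_m <- side == "5p"
      inner_l <- if (any(five_m)) max(anchor[five_m]) else min(anchor)
      inner_r <- if (any(!five_m)) min(anchor[!five_m]) else max(anchor)
      floor((inner_l + inner_r) / 2)
    } else NA_real_
    fams <- sort(table(te_family), decreasing = TRUE)
    maj <- names(fams)[fams == max(fams)]
    maj <- sort(maj)[1L]
    list(chrom = chrom[1L],
         start = min(anchor), end = max(anchor),
         n_reads = .N,
         split_support = sum(is_split),
         mate_support = sum(!is_split),
         junction_5p = as.numeric(p1), junction_3p = as.numeric(p2),
         midpoint = as.numeric(mid),
         clip_5p = .consensus_clip(clip_seq[five_split]),
         clip_3p = .consensus_clip(clip_seq[three_split]),
         te_family = maj,
         family_votes = paste(sprintf("%s:%d", names(fams), fams),
                              collapse = ","),
         ambiguity = 1 - max(fams) / .N)
  }, by = cluster_id]
}

.empty_cluster_table <- function() {
  data.table::data.table(
    cluster_id = integer(0), chrom = character(0), start = integer(0),
    end = integer(0), n_reads = integer(0), split_support = integer(0),
    mate_support = integer(0), junction_5p = numeric(0),
    junction_3p = numeric(0), midpoint = numeric(0),
    clip_5p = character(0), clip_3p = character(0),
    te_family = character(0), family_votes = character(0),
    ambiguity = numeric(0))
}

#' Call a target-site duplication for a cluster
#'
#' At a genuine TSD-bearing insertion the reference resumes `t` bases
#' before the 5' junction, so the 3' junction coordinate `p2` lies
#' strictly left of the 5' junction `p1`. When `1 <= p1 - p2 <= max_tsd`
#' the duplicated sequence is `reference[p2, p1)`.
#'
#' @param clusters cluster summary table from [find_clusters()]
#' @param reference named character vector of chromosome sequences
#' @param max_tsd maximum credible TSD length
#' @return the cluster table with `tsd_seq`, `tsd_length` and
#'   `tsd_start`/`tsd_end` (0-based half-open span) columns; NA when no
#'   valid TSD
#' @export
call_tsd <- function(clusters, reference, max_tsd = 60L) {
  cl <- data.table::copy(data.table::as.data.table(clusters))
  cl[, `:=`(tsd_seq = NA_character_, tsd_length = NA_integer_,
            tsd_start = NA_integer_, tsd_end = NA_integer_)]
  ok <- !is.na(cl$junction_5p) & !is.na(cl$junction_3p) &
    cl$junction_3p < cl$junction_5p &
    (cl$junction_5p - cl$junction_3p) <= max_tsd
  for (i in which(ok)) {
    p1 <- as.integer(cl$junction_5p[i]); p2 <- as.integer(cl$junction_3p[i])
    cl[i, `:=`(tsd_seq = substr(reference[[chrom]], p2 + 1L, p1),
               tsd_length = p1 - p2, tsd_start = p2, tsd_end = p1)]
  }
  cl[]
}

#' Build a sample-wide soft-clip index
#'
#' Records every soft clip of at least `min_clip` bases in the sample,
#' keyed by chromosome, junction position and side, so the presence of a
#' given clipped sequence at a position can be checked independently of
#' tagging.
#'
#' @param aln alignment table
#' @param min_clip minimum clip length indexed
#' @return data.table with `chrom`, `pos` (junction coordinate), `side`
#'   (`5p` right clip / `3p` left clip) and `seq`
#' @export
build_clip_index <- function(aln, min_clip = 10L) {
  aln <- data.table::as.data.table(aln)
  aln <- aln[is_mapped == TRUE]
  right <- aln[nchar(clip_right) >= min_clip,
               .(chrom, pos = end, side = "5p", seq = clip_right)]
  left <- aln[nchar(clip_left) >= min_clip,
              .(chrom, pos = start, side = "3p", seq = clip_left)]
  out <- data.table::rbindlist(list(right, left))
  data.table::setorder(out, chrom, pos, side, seq)
  out[]
}

#' Annotate clusters with sample-wide soft-clip linkage counts
#'
#' For each cluster side, counts how many reads in the whole sample carry
#' a clip at the cluster's junction matching the cluster's consensus clip
#' (anchored identity rule); with no consensus clip on a side, any clip at
#' the junction counts. These counts measure how congruent the sample is
#' with the insertion.
#'
#' @param clusters cluster table (after [call_tsd()] or not)
#' @param clip_index from [build_clip_index()]
#' @param min_clip,min_identity clip matching rule parameters
#' @return cluster table with `linkage_5p` and `linkage_3p` counts
#' @export
link_softclips <- function(clusters, clip_index, min_clip = 10L,
                           min_identity = 0.9) {
  cl <- data.table::copy(data.table::as.data.table(clusters))
  cl[, `:=`(linkage_5p = 0L, linkage_3p = 0L)]
  if (nrow(clip_index) == 0L || nrow(cl) == 0L) return(cl[])
  count_side <- function(chr, junction, cons, side_lab) {
    if (is.na(junction)) return(0L)
    cand <- clip_index[chrom == chr & pos == junction & side == side_lab]
    if (nrow(cand) == 0L) return(0L)
    if (is.na(cons)) return(nrow(cand))
    sum(vapply(cand$seq, function(s) {
      isTRUE(clips_compatible(cons, s,
                              side = if (side_lab == "5p") "right" else
                                "left",
                              min_len = min_clip,
                              min_identity = min_identity))
    }, logical(1)))
  }
  for (i in seq_len(nrow(cl))) {
    cl[i, linkage_5p := count_side(chrom, junction_5p, clip_5p, "5p")]
    cl[i, linkage_3p := count_side(chrom, junction_3p, clip_3p, "3p")]
  }
  cl[]
}

#' Emit insertion candidates from clusters
#'
#' One candidate per cluster. The insertion point is the 1-based position
#' of the first duplicated base when a TSD was called, otherwise the
#' junction base (5' split junction, falling back to the mate-evidence
#' midpoint).
#'
#' @param clusters cluster table after [call_tsd()]
#' @param members clustering-unit table from [find_clusters()]
#' @param gff_path optional path: write the candidates as GFF3
#' @return list with `candidates` (candidate table) and `evidence`
#'   (the member reads of all clusters — the evidence alignment subset)
#' @export
emit_candidates <- function(clusters, members, gff_path = NULL) {
  cl <- data.table::as.data.table(clusters)
  if (nrow(cl) == 0L) {
    cand <- .empty_candidate_table()
    if (!is.null(gff_path)) write_gff(cand, gff_path)
    return(list(candidates = cand, evidence = members))
  }
  has_tsd <- !is.na(cl$tsd_seq)
  junction0 <- ifelse(has_tsd, cl$tsd_start,
                      ifelse(!is.na(cl$junction_5p), cl$junction_5p,
                             ifelse(!is.na(cl$junction_3p), cl$junction_3p,
                                    cl$midpoint)))
  cand <- data.table::data.table(
    candidate_id = sprintf("cand_%s_%d", cl$chrom, as.integer(junction0)),
    chrom = cl$chrom,
    insertion_point = as.integer(junction0) + 1L,
    te_family = cl$te_family,
    tsd_seq = cl$tsd_seq,
    tsd_length = ifelse(has_tsd, cl$tsd_length, NA_integer_),
    gff_start = ifelse(has_tsd, cl$tsd_start + 1L,
                       as.integer(junction0) + 1L),
    gff_end = ifelse(has_tsd, cl$tsd_end, as.integer(junction0) + 1L),
    split_support = cl$split_support,
    mate_support = cl$mate_support,
    clip_5p = cl$clip_5p,
    clip_3p = cl$clip_3p,
    ambiguity = cl$ambiguity,
    cluster_id = cl$cluster_id)
  data.table::setorder(cand, chrom, insertion_point, te_family)
  if (!is.null(gff_path)) write_gff(cand, gff_path)
  evidence <- members[!is.na(cluster_id)]
  list(candidates = cand, evidence = evidence)
}

.empty_candidate_table <- function() {
  data.table::data.table(
    candidate_id = character(0), chrom = character(0),
    insertion_point = integer(0), te_family = character(0),
    tsd_seq = character(0), tsd_length = integer(0),
    gff_start = integer(0), gff_end = integer(0),
    split_support = integer(0), mate_support = integer(0),
    clip_5p = character(0), clip_3p = character(0),
    ambiguity = numeric(0), cluster_id = integer(0))
}

#' Run the short-read calling pipeline on one sample
#'
#' Convenience wrapper: tag reads, estimate the insert interval, cluster,
#' call TSDs and emit candidates.
#'
#' @param genome_aln,te_aln alignment tables (genome and TE consensus)
#' @param reference named chromosome sequences
#' @param family_of optional consensus-to-family mapping
#' @param min_clip,min_identity,max_tsd tuning parameters (see the
#'   individual stage functions)
#' @return list with `candidates`, `clusters`, `members`, `interval`
#' @export
call_insertions <- function(genome_aln, te_aln, reference,
                            family_of = NULL, min_clip = 10L,
                            min_identity = 0.9, max_tsd = 60L) {
  tagged <- tag_reads(genome_aln, te_aln, family_of = family_of,
                      min_clip = min_clip)
  interval <- estimate_insert_interval(genome_aln)
  fc <- find_clusters(tagged, interval, min_clip = min_clip,
                      min_identity = min_identity)
  clusters <- call_tsd(fc$clusters, reference, max_tsd = max_tsd)
  out <- emit_candidates(clusters, fc$members)
  list(candidates = out$candidates, clusters = clusters,
       members = fc$members, interval = interval,
       evidence = out$evidence)
}
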