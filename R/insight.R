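# Downstream statistics on call sets: allele frequency and clonal timing,
# TSD and family summaries, integration-site flanks, genic annotation and
# interval-track enrichment.

#' Allele frequency from supporting and opposing pair counts
#'
#' @param support_pairs,opposing_pairs integer vectors (each read pair
#'   counted once)
#' @return data.table with `support_pairs`, `opposing_pairs` and
#'   `allele_frequency` (NA when no informative pairs)
#' @export
allele_frequency <- function(support_pairs, opposing_pairs) {
  if (any(support_pairs < 0L) || any(opposing_pairs < 0L)) {
    stop("negative pair counts")
  }
  tot <- support_pairs + opposing_pairs
  data.table::data.table(
    support_pairs = support_pairs, opposing_pairs = opposing_pairs,
    allele_frequency = ifelse(tot > 0L, support_pairs / tot, NA_real_))
}

#' Count supporting and opposing pairs for insertion candidates
#'
#' Opposing pairs are proper, fully-aligned pairs whose template span
#' strictly contains the insertion point and that carry neither a TE tag
#' nor a junction soft clip (clipped-but-untagged reads are treated as
#' uninformative, not opposing). Supporting molecules are the distinct
#' read pairs assigned to the candidate's evidence cluster; because an
#' insert longer than the fragment size is supported by different
#' molecules on its 5' and its 3' flank while an opposing molecule spans
#' the locus once, the effective supporting count averages the two sides
#' — this keeps the allele-frequency estimator unbiased (each read pair
#' contributes once, on a comparable footing to the opposing pool).
#'
#' @param candidates candidate table with `cluster_id`
#' @param members clustering-unit table (tagged reads with `cluster_id`)
#' @param genome_aln full genome alignment table for the sample
#' @param min_clip clip length regarded as a junction clip
#' @return candidates with `support_pairs` (effective count),
#'   `support_pairs_5p`, `support_pairs_3p`, `opposing_pairs`,
#'   `allele_frequency`
#' @export
estimate_af <- function(candidates, members, genome_aln,
                        min_clip = 10L) {
  cand <- data.table::copy(data.table::as.data.table(candidates))
  aln <- data.table::as.data.table(genome_aln)
  tagged_ids <- unique(members$read_id)
  fwd <- aln[is_proper == TRUE & strand == "+" & tlen > 0L &
               clip_left == "" & clip_right == ""]
  cand[, `:=`(support_pairs = 0, support_pairs_5p = 0L,
              support_pairs_3p = 0L, opposing_pairs = 0L)]
  for (i in seq_len(nrow(cand))) {
    mem <- members[cluster_id == cand$cluster_id[i]]
    n5 <- length(unique(mem[side == "5p", read_id]))
    n3 <- length(unique(mem[side == "3p", read_id]))
    p0 <- cand$insertion_point[i] - 1L
    opp_rows <- fwd[chrom == cand$chrom[i] & start < p0 &
                      start + tlen > p0]
    opp <- setdiff(unique(opp_rows$read_id), tagged_ids)
    cand[i, `:=`(support_pairs = (n5 + n3) / 2,
                 support_pairs_5p = n5, support_pairs_3p = n3,
                 opposing_pairs = length(opp))]
  }
  tot <- cand$support_pairs + cand$opposing_pairs
  cand[, allele_frequency := ifelse(tot > 0, support_pairs / tot,
                                    NA_real_)]
  cand[]
}

#' Convert allele frequency to the fraction of cells carrying a variant
#'
#' Autosomal heterozygous variants occupy one of two homologs, so the
#' cell fraction is twice the allele frequency (capped at 1); variants on
#' the hemizygous sex chromosome of a male use the allele frequency
#' directly.
#'
#' @param af allele frequency vector
#' @param chrom chromosome names
#' @param sex `"male"` or `"female"`
#' @param karyotype list with `autosomes` and `sex_chromosomes` character
#'   vectors
#' @return cell fractions in `[0, 1]`
#' @export
cell_fraction <- function(af, chrom, sex = "male",
                          karyotype = list(
                            autosomes = c("chr2L", "chr2R", "chr3L",
                                          "chr3R", "chr4", "2L", "2R",
                                          "3L", "3R", "4"),
                            sex_chromosomes = c("chrX", "X", "chrY",
                                                "Y"))) {
  unknown <- setdiff(unique(chrom),
                     c(karyotype$autosomes, karyotype$sex_chromosomes))
  if (length(unknown) > 0L) stop("unknown chromosome: ", unknown[1L])
  hemi <- chrom %in% karyotype$sex_chromosomes & sex == "male"
  ifelse(hemi, af, pmin(2 * af, 1.0))
}

#' Classify insertions as pre- or post-clonal-expansion
#'
#' An insertion whose cell fraction is at least that of the
#' neoplasia-initiating event was likely present before the clonal
#' expansion.
#'
#' @param insertion_cf insertion cell fractions
#' @param clonal_event_cf matching clonal-event cell fractions (supplied
#'   externally, e.g. from structural-variant breakpoints)
#' @return character vector: `pre_clonal` / `post_clonal`
#' @export
classify_timing <- function(insertion_cf, clonal_event_cf) {
  if (any(is.na(clonal_event_cf))) {
    stop("missing clonal event cell fraction for ",
         sum(is.na(clonal_event_cf)), " call(s)")
  }
  ifelse(insertion_cf >= clonal_event_cf, "pre_clonal", "post_clonal")
}

#' Per-family TSD length summaries
#'
#' @param catalog catalog table with `te_family` and `tsd_length`
#' @param min_insertions minimum insertions for a family to be reported
#' @return data.table per family: `n`, `median_tsd`, `q25`, `q75`
#' @export
tsd_summary <- function(catalog, min_insertions = 6L) {
  cat_ <- data.table::as.data.table(catalog)
  cat_ <- cat_[!is.na(tsd_length)]
  out <- cat_[, .(n = .N,
                  median_tsd = as.numeric(stats::median(tsd_length)),
                  q25 = stats::quantile(tsd_length, 0.25, names = FALSE),
                  q75 = stats::quantile(tsd_length, 0.75, names = FALSE)),
              by = te_family][n >= min_insertions]
  data.table::setorder(out, -n, te_family)
  out[]
}

#' Count insertions by family (and other grouping columns)
#'
#' @param catalog catalog table
#' @param group_by grouping columns (default `te_family`)
#' @param class_table optional data.table mapping `te_family` to
#'   `te_class`; unmapped families are counted under `"unknown"` with a
#'   warning
#' @return counts table sorted by decreasing count
#' @export
family_counts <- function(catalog, group_by = "te_family",
                          class_table = NULL) {
  cat_ <- data.table::as.data.table(catalog)
  if (nrow(cat_) == 0L) {
    return(data.table::data.table(te_family = character(0),
                                  n = integer(0)))
  }
  if (!is.null(class_table)) {
    ct <- data.table::as.data.table(class_table)
    cat_ <- merge(cat_, ct[, .(te_family, mapped_class = te_class)],
                  by = "te_family", all.x = TRUE)
    if (anyNA(cat_$mapped_class)) {
      warning("families missing from class table counted as unknown: ",
              paste(unique(cat_[is.na(mapped_class), te_family]),
                    collapse = ", "))
      cat_[is.na(mapped_class), mapped_class := "unknown"]
    }
    cat_[, te_class := mapped_class]
    cat_[, mapped_class := NULL]
  }
  out <- cat_[, .(n = .N), by = group_by]
  data.table::setorderv(out, c("n", group_by), c(-1L, rep(1L,
                                                          length(group_by))))
  out[]
}

#' Extract integration-site flanks and composition statistics
#'
#' For each call, the `flank` bases 5' of the TSD span and the `flank`
#' bases 3' of it are concatenated (the TSD itself is excluded unless
#' `include_tsd`). Calls too close to a contig end are skipped and
#' counted. Per-position base frequencies, AT fraction, and per-position
#' information content (2 - Shannon entropy, bits) are computed over the
#' extracted windows.
#'
#' @param calls table with `chrom`, `insertion_point` (1-based first
#'   duplicated base) and `tsd_length` (0/NA for point insertions)
#' @param reference named chromosome sequences
#' @param flank flank width on each side
#' @param include_tsd include the TSD sequence between the flanks
#' @param fasta_path optional path to write the flanks as FASTA (for
#'   external motif discovery)
#' @return list with `sequences` (per-call flank windows), `freq`
#'   (position x base frequency matrix), `at_fraction`, `info_content`,
#'   `skipped`
#' @export
extract_flanks <- function(calls, reference, flank = 10L,
                           include_tsd = FALSE, fasta_path = NULL) {
  calls <- data.table::as.data.table(calls)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(calls))) {
    chr <- calls$chrom[i]
    L <- nchar(reference[[chr]])
    t <- calls$tsd_length[i]
    if (is.na(t)) t <- 0L
    s <- calls$insertion_point[i] - 1L      # 0-based TSD span start
    e <- s + t
    if (s - flank < 0L || e + flank > L) {
      skipped <- skipped + 1L
      next
    }
    up <- substr(reference[[chr]], s - flank + 1L, s)
    dn <- substr(reference[[chr]], e + 1L, e + flank)
    mid <- if (include_tsd && t > 0L)
      substr(reference[[chr]], s + 1L, e) else ""
    rows[[length(rows) + 1L]] <- data.table::data.table(
      id = sprintf("%s_%d", chr, calls$insertion_point[i]),
      chrom = chr, insertion_point = calls$insertion_point[i],
      upstream = up, downstream = dn, window = paste0(up, mid, dn))
  }
  seqs <- if (length(rows) > 0L) data.table::rbindlist(rows) else
    data.table::data.table(id = character(0), chrom = character(0),
                           insertion_point = integer(0),
                           upstream = character(0),
                           downstream = character(0),
                           window = character(0))
  if (!is.null(fasta_path)) {
    write_fasta(stats::setNames(seqs$window, seqs$id), fasta_path)
  }
  freq <- NULL; at_fraction <- NA_real_; info <- NULL
  if (nrow(seqs) > 0L && !include_tsd) {
    mat <- do.call(rbind, strsplit(seqs$window, "", fixed = TRUE))
    freq <- t(apply(mat, 2L, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      as.numeric(tab) / length(col)
    }))
    colnames(freq) <- c("A", "C", "G", "T")
    at_fraction <- mean(mat %in% c("A", "T"))
    info <- apply(freq, 1L, function(p) {
      p <- p[p > 0]
      2 + sum(p * log2(p))
    })
  } else if (nrow(seqs) > 0L) {
    at_fraction <- mean(unlist(strsplit(seqs$window, "")) %in% c("A", "T"))
  }
  list(sequences = seqs, freq = freq, at_fraction = at_fraction,
       info_content = info, skipped = skipped)
}

# calls table -> point GRanges at the insertion position
.calls_granges <- function(calls) {
  calls <- data.table::as.data.table(calls)
  GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$insertion_point, width = 1L))
}

#' Annotate calls with genic feature classes
#'
#' Each call is labeled with the most specific overlapped class among
#' exon (CDS), 5'UTR, 3'UTR, intron and intergenic, and associated with
#' any gene whose span lies within `window` bases.
#'
#' @param calls table with `chrom`, `insertion_point`
#' @param gene_models `GRanges` (e.g. from [rtracklayer::import()] of a
#'   GFF3) with a `type` column containing `gene`, `CDS`,
#'   `five_prime_UTR`, `three_prime_UTR` features and a gene identifier
#'   column (`ID` or `Name`)
#' @param window association window around gene spans
#' @return calls with `feature_class` and `genes` columns
#' @export
annotate_genic <- function(calls, gene_models, window = 500L) {
  calls <- data.table::copy(data.table::as.data.table(calls))
  gr <- .calls_granges(calls)
  type <- as.character(gene_models$type)
  if (!"gene" %in% type) stop("gene models contain no gene features")
  pick <- function(tt) gene_models[type %in% tt]
  cds <- pick(c("CDS"))
  utr5 <- pick(c("five_prime_UTR", "5UTR"))
  utr3 <- pick(c("three_prime_UTR", "3UTR"))
  genes <- pick("gene")
  ov <- function(subject) {
    GenomicRanges::countOverlaps(gr, subject, ignore.strand = TRUE) > 0L
  }
  in_cds <- ov(cds); in_u5 <- ov(utr5); in_u3 <- ov(utr3)
  in_gene <- ov(genes)
  calls[, feature_class := data.table::fcase(
    in_cds, "exon",
    in_u5, "5UTR",
    in_u3, "3UTR",
    in_gene, "intron",
    default = "intergenic")]
  gene_ids <- if (!is.null(genes$ID)) as.character(genes$ID) else
    as.character(genes$Name)
  if (length(gene_ids) == 0L || all(is.na(gene_ids))) {
    gene_ids <- sprintf("gene%d", seq_along(genes))
  }
  near <- GenomicRanges::findOverlaps(gr, genes, maxgap = window - 1L,
                                      ignore.strand = TRUE)
  assoc <- rep("", nrow(calls))
  if (length(near) > 0L) {
    sp <- split(gene_ids[S4Vectors::subjectHits(near)],
                S4Vectors::queryHits(near))
    for (qi in names(sp)) {
      assoc[as.integer(qi)] <- paste(sort(unique(sp[[qi]])),
                                     collapse = ",")
    }
  }
  calls[, genes := assoc]
  calls[]
}

#' Insertion-site enrichment over interval tracks
#'
#' For each track a 2x2 contingency table of call sites in/out of the
#' track versus background units in/out is tested with a two-sided Fisher
#' exact test; p-values are Benjamini-Hochberg adjusted across tracks.
#' Enrichment is the observed/expected fraction ratio `r`, reported
#' signed (`r` when `r >= 1`, otherwise `-1/r`). A row is significant
#' when the adjusted p-value is below `p_threshold` and the magnitude of
#' the signed enrichment exceeds `e_threshold`.
#'
#' Background units are, by default, random sites sampled uniformly
#' within the mappable background intervals (`n_background_per_call` per
#' call, seeded); `mode = "bases"` uses base-pair coverage of the
#' background instead.
#'
#' @param calls table with `chrom`, `insertion_point`
#' @param tracks named list of `GRanges` (e.g. from [read_bed()])
#' @param background `GRanges` of mappable genome intervals
#' @param mode `"sites"` or `"bases"` background accounting
#' @param n_background_per_call background sites sampled per call
#' @param seed seed for background sampling
#' @param alpha BH false-discovery level (adjustment parameter)
#' @param p_threshold adjusted-p significance cutoff
#' @param e_threshold signed-enrichment magnitude cutoff
#' @return data.table: one row per track with counts `a,b,c,d`,
#'   `odds_ratio`, `signed_enrichment`, `p_fisher`, `p_adjusted`,
#'   `significant`, `untestable`
#' @export
enrichment <- function(calls, tracks, background,
                       mode = c("sites", "bases"),
                       n_background_per_call = 100L, seed = 1L,
                       alpha = 0.05, p_threshold = 0.001,
                       e_threshold = 1.5) {
  mode <- match.arg(mode)
  gr <- .calls_granges(calls)
  n_calls <- length(gr)
  bg_red <- GenomicRanges::reduce(background)
  bg_width <- sum(GenomicRanges::width(bg_red))
  bg_sites <- NULL
  if (mode == "sites") {
    n_bg <- n_calls * n_background_per_call
    bg_sites <- with_seed(seed, .sample_background_sites(bg_red, n_bg))
  }
  # concatenate all tracks once; two overlap queries replace a per-track
  # pass (overlap pairs are deduplicated, so per-track reduction is only
  # needed for base-pair accounting)
  track_names <- names(tracks)
  tr_list <- if (mode == "bases")
    lapply(tracks, GenomicRanges::reduce) else tracks
  cat_tr <- suppressWarnings(do.call(c, unname(tr_list)))
  track_of <- factor(rep(track_names, lengths(tr_list)),
                     levels = track_names)
  count_in <- function(query) {
    hits <- GenomicRanges::findOverlaps(query, cat_tr,
                                        ignore.strand = TRUE)
    pair <- unique(data.table::data.table(
      q = S4Vectors::queryHits(hits),
      tr = track_of[S4Vectors::subjectHits(hits)]))
    tab <- table(pair$tr)
    as.integer(tab[track_names])
  }
  a_vec <- count_in(gr)
  untest_hits <- GenomicRanges::findOverlaps(cat_tr, bg_red,
                                             ignore.strand = TRUE)
  testable <- track_names %in%
    unique(track_of[S4Vectors::queryHits(untest_hits)])
  if (mode == "sites") {
    c_vec <- count_in(bg_sites)
    d_vec <- rep(length(bg_sites), length(tracks)) - c_vec
  } else {
    c_vec <- vapply(tr_list, function(tr) {
      sum(GenomicRanges::width(GenomicRanges::intersect(
        tr, bg_red, ignore.strand = TRUE)))
    }, numeric(1))
    d_vec <- bg_width - c_vec
  }
  rows <- lapply(seq_along(track_names), function(i) {
    a <- a_vec[i]; b <- n_calls - a
    cc <- c_vec[i]; dd <- d_vec[i]
    ft <- stats::fisher.test(matrix(c(a, b, cc, dd), nrow = 2L))
    expected <- if (cc + dd > 0L) cc / (cc + dd) else NA_real_
    observed <- if (a + b > 0L) a / (a + b) else NA_real_
    r <- if (!is.na(expected) && expected > 0) observed / expected else
      NA_real_
    signed <- if (is.na(r)) NA_real_ else if (r == 0) -Inf else
      if (r >= 1) r else -1 / r
    data.table::data.table(
      track = track_names[i], a = a, b = b, c = cc, d = dd,
      odds_ratio = unname(ft$estimate), signed_enrichment = signed,
      p_fisher = ft$p.value, untestable = !testable[i])
  })
  out <- data.table::rbindlist(rows)
  out[, p_adjusted := stats::p.adjust(p_fisher, method = "BH",
                                      n = .N)]
  out[, significant := !untestable & !is.na(signed_enrichment) &
        p_adjusted < p_threshold & abs(signed_enrichment) > e_threshold]
  out[]
}

# Uniform random positions within background intervals, weighted by width.
.sample_background_sites <- function(background, n) {
  bg <- GenomicRanges::reduce(background)
  w <- GenomicRanges::width(bg)
  iv <- sample.int(length(bg), n, replace = TRUE, prob = w / sum(w))
  off <- floor(stats::runif(n) * w[iv])
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(bg)[iv],
    ranges = IRanges::IRanges(start = GenomicRanges::start(bg)[iv] + off,
                              width = 1L))
}
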