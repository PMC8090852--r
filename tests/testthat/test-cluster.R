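# Clustering, junction/TSD inference, clip linkage and candidate
# emission.

# Hand-construct a tagged-read row with just the columns clustering uses.
make_tagged <- function(read_id, chrom, start, end, strand,
                        evidence_source, clip_side = NA_character_,
                        clip_left = "", clip_right = "",
                        te_family = "rover", mate = 1L) {
  data.table::data.table(
    read_id = read_id, mate = mate, flag = 0L, chrom = chrom,
    start = start, end = end, strand = strand, mapq = 60L, cigar = "",
    seq = "", clip_left = clip_left, clip_right = clip_right,
    is_proper = FALSE, is_dup = FALSE, is_mapped = TRUE,
    mate_chrom = "", mate_pos = 0L, tlen = 0L, tags = "",
    evidence_source = evidence_source, clip_side = clip_side,
    te_reference = te_family, te_family = te_family,
    te_aln_start = 0L, te_aln_end = 50L, te_query_start = 0L,
    te_query_end = 50L, te_orientation = "same", te_score = 50L,
    te_ambiguous = FALSE)
}

test_that("insert-size interval equals inverse-ECDF percentiles", {
  mk <- function(tlens) {
    data.table::data.table(is_proper = TRUE, is_dup = FALSE,
                           tlen = as.integer(tlens))
  }
  expect_equal(estimate_insert_interval(mk(rep(250, 50))),
               list(low = 250, high = 250))

  set.seed(7)
  x <- as.integer(round(rnorm(1000, 300, 30)))
  got <- estimate_insert_interval(mk(x))
  # sort-and-index oracle (inverse ECDF): the ceil(p*n)-th order statistic
  xs <- sort(x)
  expect_equal(got$low, xs[ceiling(0.025 * length(xs))])
  expect_equal(got$high, xs[ceiling(0.975 * length(xs))])

  expect_error(estimate_insert_interval(mk(integer(0))), "proper pairs")
})

test_that("insert interval is identical from a SAM file and from memory", {
  sr <- toy_reads()
  in_mem <- estimate_insert_interval(sr$genome_aln)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sr$genome_aln[is_mapped == TRUE], sam, sr$seq_lengths)
  from_file <- estimate_insert_interval(parse_alignments(sam))
  expect_equal(from_file, in_mem)
})

test_that("a constructed locus forms one cluster with correct supports", {
  clipA <- strrep("ACGTT", 5)
  clipB <- strrep("GGCAT", 5)
  tg <- data.table::rbindlist(list(
    make_tagged(c("s1", "s2", "s3"), "chr1", 905L, 1005L, "+", "self",
                clip_side = "5p", clip_right = clipA),
    make_tagged(c("s4", "s5", "s6"), "chr1", 1000L, 1100L, "-", "self",
                clip_side = "3p", clip_left = clipB),
    make_tagged(c("m1", "m2"), "chr1", 850L, 950L, "+", "mate"),
    make_tagged(c("m3", "m4"), "chr1", 1050L, 1150L, "-", "mate")))
  fc <- find_clusters(tg, list(low = 200, high = 400))
  expect_equal(nrow(fc$clusters), 1L)
  expect_equal(fc$clusters$split_support, 6L)
  expect_equal(fc$clusters$mate_support, 4L)
  expect_equal(fc$clusters$junction_5p, 1005)
  expect_equal(fc$clusters$junction_3p, 1000)
  expect_equal(fc$clusters$clip_5p, clipA)
  expect_equal(fc$clusters$clip_3p, clipB)
})

test_that("clustering equals exhaustive single-linkage on real evidence", {
  tagged <- toy_tagged()
  fc <- find_clusters(tagged, list(low = 280, high = 420))
  expect_equal(nrow(fc$clusters), 2L)   # two implants, 18 kb apart

  # brute-force oracle: full pairwise compatibility graph -> components
  u <- teclone:::.cluster_units(tagged)
  n <- nrow(u)
  expect_lte(n, 200L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (u$chrom[i] != u$chrom[j]) next
      if (abs(u$anchor[i] - u$anchor[j]) > 420) next
      conflict <- FALSE
      if (u$is_split[i] && u$is_split[j] && u$side[i] == u$side[j]) {
        cmp <- clips_compatible(
          u$clip_seq[i], u$clip_seq[j],
          side = if (u$side[i] == "5p") "right" else "left")
        conflict <- isFALSE(cmp)
      }
      adj[i, j] <- !conflict
    }
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  oracle_part <- split(seq_len(n), comp$membership)
  got_part <- split(seq_len(n), fc$members$cluster_id[
    match(paste(u$read_id, u$mate),
          paste(fc$members$read_id, fc$members$mate))])
  normalize <- function(p) unname(lapply(p, sort))
  expect_setequal(normalize(got_part), normalize(oracle_part))
})

test_that("every tagged read lands in exactly one cluster", {
  tagged <- toy_tagged()
  fc <- find_clusters(tagged, list(low = 280, high = 420))
  keys <- fc$members[, paste(read_id, mate)]
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(!is.na(fc$members$cluster_id)))
  expect_equal(sum(fc$clusters$n_reads), nrow(fc$members))
})

test_that("adding a supporting read never shrinks a cluster", {
  clip <- strrep("ACGTT", 5)
  base <- data.table::rbindlist(list(
    make_tagged(c("s1", "s2"), "chr1", 905L, 1005L, "+", "self",
                clip_side = "5p", clip_right = clip),
    make_tagged("m1", "chr1", 850L, 950L, "+", "mate")))
  extra <- make_tagged("s9", "chr1", 910L, 1005L, "+", "self",
                       clip_side = "5p", clip_right = clip)
  before <- find_clusters(base, list(low = 200, high = 400))$clusters
  after <- find_clusters(rbind(base, extra),
                         list(low = 200, high = 400))$clusters
  expect_gte(nrow(after), nrow(before))
  expect_gte(after$split_support[1], before$split_support[1])
  expect_gte(after$mate_support[1], before$mate_support[1])
})

test_that("TSD calling follows the junction-order rule and bounds", {
  ref <- list(chr1 = paste(rep("ACGTG", 400), collapse = ""))
  cl <- data.table::data.table(
    cluster_id = 1:3, chrom = "chr1",
    start = 900L, end = 1100L, n_reads = 10L, split_support = 6L,
    mate_support = 4L,
    junction_5p = c(1005, 1000, 1061),
    junction_3p = c(1000, 1005, 1000),
    midpoint = NA_real_, clip_5p = NA_character_,
    clip_3p = NA_character_, te_family = "rover", family_votes = "",
    ambiguity = 0)
  got <- call_tsd(cl, ref, max_tsd = 60L)
  expect_equal(got$tsd_length[1], 5L)
  expect_equal(got$tsd_seq[1], substr(ref$chr1, 1001, 1005))
  expect_true(is.na(got$tsd_seq[2]))   # junctions in non-duplicating order
  expect_true(is.na(got$tsd_seq[3]))   # p1 - p2 = max_tsd + 1
})

test_that("TSDs called on gold data equal the implanted duplications", {
  res <- toy_calls()
  m <- toy_sim()$manifest
  got <- merge(res$candidates, m,
               by = c("chrom", "insertion_point", "te_family"))
  expect_equal(nrow(got), nrow(m))
  expect_equal(got$tsd_seq.x, got$tsd_seq.y)
})

test_that("soft-clip linkage counts matching clips at the junction", {
  clip <- strrep("ACGTT", 4)
  near_clip <- paste0(substr(clip, 1, 19), "A")   # one mismatch at the end
  idx <- data.table::data.table(
    chrom = "chr1", pos = 1005L, side = "5p",
    seq = c(clip, clip, clip, clip, near_clip))
  cl <- data.table::data.table(
    cluster_id = 1L, chrom = "chr1", start = 900L, end = 1100L,
    n_reads = 4L, split_support = 4L, mate_support = 0L,
    junction_5p = 1005, junction_3p = NA_real_, midpoint = NA_real_,
    clip_5p = clip, clip_3p = NA_character_, te_family = "rover",
    family_votes = "", ambiguity = 0)
  got <- link_softclips(cl, idx)
  expect_equal(got$linkage_5p, 5L)   # 4 exact + 1 at 95% identity
  expect_equal(got$linkage_3p, 0L)
  empty <- link_softclips(cl, idx[0])
  expect_equal(empty$linkage_5p, 0L)
})

test_that("candidate emission assigns majority family and conserves reads", {
  fc <- find_clusters(data.table::rbindlist(list(
    make_tagged(sprintf("r%d", 1:7), "chr1", 905L, 1005L, "+", "self",
                clip_side = "5p", clip_right = strrep("ACGTT", 5),
                te_family = "rover"),
    make_tagged("c1", "chr1", 910L, 1005L, "+", "mate",
                te_family = "copia"))), list(low = 200, high = 400))
  out <- emit_candidates(fc$clusters[, `:=`(tsd_seq = NA_character_,
                                            tsd_length = NA_integer_,
                                            tsd_start = NA_integer_,
                                            tsd_end = NA_integer_)],
                         fc$members)
  expect_equal(out$candidates$te_family, "rover")
  expect_equal(out$candidates$ambiguity, 1 / 8)
  expect_equal(nrow(out$evidence), 8L)

  empty <- emit_candidates(teclone:::.empty_cluster_table(),
                           teclone:::.cluster_units(toy_tagged()[0]))
  expect_equal(nrow(empty$candidates), 0L)
  expect_equal(nrow(empty$evidence), 0L)
})
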