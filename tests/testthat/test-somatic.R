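# Cross-sample confirmation: support prefilter, panel-of-normals
# subtraction, germline classification, per-family panel mode.

# Minimal candidate row for filter tests.
make_cand <- function(sample_id, chrom, pos, family = "rover",
                      tsd = "ACGTA", split = 3L, mate = 4L,
                      clip5 = NA_character_, clip3 = NA_character_) {
  data.table::data.table(
    sample_id = sample_id, candidate_id = sprintf("c_%s_%d", chrom, pos),
    chrom = chrom, insertion_point = as.integer(pos), te_family = family,
    tsd_seq = tsd, tsd_length = ifelse(is.na(tsd), NA_integer_,
                                       nchar(tsd)),
    gff_start = as.integer(pos), gff_end = as.integer(pos),
    split_support = split, mate_support = mate,
    clip_5p = clip5, clip_3p = clip3, ambiguity = 0, cluster_id = 1L)
}

test_that("support prefilter requires both evidence types", {
  cand <- data.table::rbindlist(list(
    make_cand("s", "chr1", 100, split = 3L, mate = 0L),
    make_cand("s", "chr1", 200, split = 1L, mate = 1L),
    make_cand("s", "chr1", 300, split = 0L, mate = 5L)))
  kept <- prefilter_support(cand)
  expect_equal(kept$insertion_point, 200L)

  set.seed(41)
  rnd <- data.table::rbindlist(lapply(1:50, function(i) {
    make_cand("s", "chr1", i * 10, split = sample(0:3, 1),
              mate = sample(0:3, 1))
  }))
  expect_equal(prefilter_support(rnd),
               rnd[rnd$split_support >= 1 & rnd$mate_support >= 1])
})

test_that("panel matches and missing TSDs exclude candidates", {
  gut <- data.table::rbindlist(list(
    make_cand("gut1", "chr1", 1000),                      # in panel
    make_cand("gut1", "chr1", 5000, tsd = NA_character_), # no TSD
    make_cand("gut1", "chr1", 9000)))                     # somatic
  panel <- make_cand("head1", "chr1", 1010)
  som <- confirm_somatic(gut, panel)
  expect_equal(som$insertion_point, 9000L)
})

test_that("an empty panel warns and proceeds panel-free", {
  gut <- make_cand("gut1", "chr1", 1000)
  expect_warning(som <- confirm_somatic(gut, gut[0]), "panel")
  expect_equal(nrow(som), 1L)
})

test_that("somatic set equals an exhaustive pairwise key comparison", {
  set.seed(43)
  mk_set <- function(sid, n) {
    data.table::rbindlist(lapply(seq_len(n), function(i) {
      make_cand(sid, sample(c("chr1", "chr2"), 1),
                sample.int(100000L, 1),
                family = sample(c("rover", "copia"), 1))
    }))
  }
  cases <- mk_set("gut1", 50)
  panel <- mk_set("head1", 50)
  # make some case candidates deliberate panel matches (within slop)
  for (i in sample.int(50, 12)) {
    j <- sample.int(50, 1)
    data.table::set(cases, i, "chrom", panel$chrom[j])
    data.table::set(cases, i, "insertion_point",
                    panel$insertion_point[j] + sample(-50:50, 1))
    data.table::set(cases, i, "te_family", panel$te_family[j])
  }
  som <- suppressWarnings(confirm_somatic(cases, panel))
  # O(n^2) oracle: same TSD requirement, position/family key
  keep <- vapply(seq_len(nrow(cases)), function(i) {
    a <- cases[i]
    if (is.na(a$tsd_seq)) return(FALSE)
    !any(panel$chrom == a$chrom & panel$te_family == a$te_family &
           abs(panel$insertion_point - a$insertion_point) <= 50)
  }, logical(1))
  expect_setequal(som$candidate_id, cases$candidate_id[keep])
})

test_that("role swap inverts the exclusion direction, not the keys", {
  gut <- data.table::rbindlist(list(make_cand("gut1", "chr1", 1000),
                                    make_cand("gut1", "chr1", 9000)))
  head_ <- data.table::rbindlist(list(make_cand("head1", "chr1", 1000),
                                      make_cand("head1", "chr1", 4000)))
  som_gut <- confirm_somatic(gut, head_)
  som_head <- confirm_somatic(head_, gut)
  expect_equal(som_gut$insertion_point, 9000L)
  expect_equal(som_head$insertion_point, 4000L)
})

test_that("filters commute on TSD-valid inputs and never add calls", {
  gut <- data.table::rbindlist(list(
    make_cand("gut1", "chr1", 1000, split = 0L),
    make_cand("gut1", "chr1", 5000),
    make_cand("gut1", "chr1", 9000)))
  panel <- make_cand("head1", "chr1", 5000)
  a <- suppressWarnings(confirm_somatic(prefilter_support(gut), panel))
  b <- prefilter_support(suppressWarnings(confirm_somatic(gut, panel)))
  expect_setequal(a$candidate_id, b$candidate_id)
  expect_true(all(a$candidate_id %in% gut$candidate_id))
})

test_that("germline classification follows tissue and coverage rules", {
  manifest <- data.table::data.table(
    sample_id = c("g12", "h12", "g13", "h13"),
    individual_id = c("fly12", "fly12", "fly13", "fly13"),
    tissue = c("gut", "head", "gut", "head"),
    genotype = "genoA", role = c("case", "control", "case", "control"))
  cands <- data.table::rbindlist(list(
    make_cand("g12", "chr1", 1000), make_cand("h12", "chr1", 1000),
    make_cand("g12", "chr1", 8000)))
  sites <- classify_germline(cands, manifest)
  germ <- sites[insertion_point == 1000L]
  expect_equal(germ$class, "germline_private")
  expect_equal(germ$n_individuals, 1L)

  # low-coverage germline sites are discarded
  cov_tab <- data.table::data.table(chrom = "chr1", position = 1000L,
                                    median_coverage = 9)
  sites_cov <- classify_germline(cands, manifest, site_coverage = cov_tab)
  expect_false(1000L %in% sites_cov[grepl("germline", class),
                                    insertion_point])
})

test_that("shared/private split matches a counting oracle over individuals", {
  n_ind <- 8L
  manifest <- data.table::rbindlist(lapply(seq_len(n_ind), function(i) {
    data.table::data.table(
      sample_id = c(sprintf("g%02d", i), sprintf("h%02d", i)),
      individual_id = sprintf("fly%02d", i),
      tissue = c("gut", "head"), genotype = "genoA",
      role = c("case", "control"))
  }))
  # one site in all individuals (both tissues), one site in exactly one
  shared <- data.table::rbindlist(lapply(seq_len(n_ind), function(i) {
    rbind(make_cand(sprintf("g%02d", i), "chr1", 2000),
          make_cand(sprintf("h%02d", i), "chr1", 2000))
  }))
  private <- rbind(make_cand("g03", "chr2", 7000),
                   make_cand("h03", "chr2", 7000))
  sites <- classify_germline(rbind(shared, private), manifest)
  expect_equal(sites[chrom == "chr1", class], "germline_shared")
  expect_equal(sites[chrom == "chr2", class], "germline_private")
  expect_equal(sites[chrom == "chr1", n_individuals], n_ind)
})

test_that("individuals lacking a second tissue yield ambiguous sites", {
  manifest <- data.table::data.table(
    sample_id = "g01", individual_id = "fly01", tissue = "gut",
    genotype = "genoA", role = "case")
  sites <- classify_germline(make_cand("g01", "chr1", 1000), manifest)
  expect_equal(sites$class, "ambiguous")
})

test_that("per-family mode keeps family-private calls and partitions", {
  cands <- data.table::rbindlist(list(
    make_cand("off1", "chr1", 1000, family = "FB4"),     # private to FB4
    make_cand("off1", "chr1", 5000, family = "rover"),   # rover locus
    make_cand("off1", "chr1", 5010, family = "copia")))  # same locus!
  fb <- per_family_germline_mode(cands, "FB4")
  expect_equal(fb$te_family, "FB4")
  # the rover/copia calls share a locus, so each is in the other's panel
  expect_equal(nrow(per_family_germline_mode(cands, "rover")), 0L)
  expect_equal(nrow(per_family_germline_mode(cands, "copia")), 0L)
  expect_error(per_family_germline_mode(cands, "nosuch"), "unknown")

  # partition property: retained calls across all families are disjoint
  all_ret <- data.table::rbindlist(lapply(unique(cands$te_family),
                                          function(f) {
    per_family_germline_mode(cands, f)
  }), fill = TRUE)
  expect_equal(anyDuplicated(all_ret$candidate_id), 0L)
})
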