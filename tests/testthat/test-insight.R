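# Downstream statistics: allele frequency and timing, TSD/family
# summaries, flanks, genic annotation, enrichment testing.

test_that("allele frequency arithmetic and error handling", {
  expect_equal(allele_frequency(0L, 12L)$allele_frequency, 0)
  expect_equal(allele_frequency(5L, 15L)$allele_frequency, 0.25)
  expect_true(is.na(allele_frequency(0L, 0L)$allele_frequency))
  expect_error(allele_frequency(-1L, 3L), "negative")
})

test_that("binomial sampling recovers the true allele frequency", {
  set.seed(3)
  reps <- 1000L; depth <- 60L; af <- 0.3
  sup <- rbinom(reps, depth, af)
  est <- allele_frequency(sup, depth - sup)$allele_frequency
  se_mean <- sqrt(af * (1 - af) / depth) / sqrt(reps)
  expect_lt(abs(mean(est) - af), 3 * se_mean)
})

test_that("cell fraction doubles autosomal AF and caps at 1", {
  expect_equal(cell_fraction(0.25, "chr2L", "male"), 0.5)
  expect_equal(cell_fraction(0.25, "chrX", "male"), 0.25)
  expect_equal(cell_fraction(0.6, "chr3R", "male"), 1.0)
  expect_error(cell_fraction(0.2, "chrZZ", "male"), "unknown")
})

test_that("timing classification against the clonal event", {
  expect_equal(classify_timing(0.8, 0.6), "pre_clonal")
  expect_equal(classify_timing(0.1, 0.6), "post_clonal")
  expect_error(classify_timing(0.5, NA), "missing")
  set.seed(5)
  ins <- runif(200); clonal <- runif(200)
  got <- classify_timing(ins, clonal)
  expect_equal(sum(got == "pre_clonal"), sum(ins >= clonal))
})

test_that("TSD summaries match a sort-based oracle per family", {
  cat_ <- toy_catalog()
  got <- tsd_summary(cat_, min_insertions = 3L)
  rover <- sort(cat_[te_family == "rover", tsd_length])
  expect_equal(got[te_family == "rover", median_tsd],
               median(rover))
  expect_equal(got[te_family == "rover", n], length(rover))
  # families below the threshold are absent
  expect_false("I-element" %in% got$te_family)
  expect_false("blood" %in% tsd_summary(cat_, 6L)$te_family)
})

test_that("family counts equal a tally oracle and map classes", {
  cat_ <- toy_catalog()
  got <- family_counts(cat_)
  oracle <- table(cat_$te_family)
  for (f in names(oracle)) {
    expect_equal(got[te_family == f, n], unname(oracle[f]))
  }
  expect_equal(nrow(family_counts(cat_[0])), 0L)

  ct <- te_library_families()[, .(te_family, te_class)]
  by_class <- family_counts(cat_, group_by = "te_class",
                            class_table = ct)
  expect_equal(by_class[te_class == "LTR", n], 11L)
  expect_warning(
    family_counts(rbind(cat_, data.table::copy(cat_[1])[,
      te_family := "mystery"]), class_table = ct), "unknown")
})

test_that("flank windows are exact substrings with boundary skipping", {
  ref <- list(c1 = paste(sample(c("A", "C", "G", "T"), 30,
                                replace = TRUE), collapse = ""))
  calls <- data.table::data.table(chrom = "c1",
                                  insertion_point = c(11L, 3L),
                                  tsd_length = c(0L, 0L))
  fl <- extract_flanks(calls, ref, flank = 10L)
  expect_equal(fl$skipped, 1L)   # the call 2 bases from the contig start
  expect_equal(nchar(fl$sequences$window), 20L)
  expect_equal(fl$sequences$window,
               paste0(substr(ref$c1, 1, 10), substr(ref$c1, 11, 20)))
})

test_that("flanks at AT-rich implant sites exceed genome AT content", {
  g <- build_reference(61L, c(c1 = 60000L), gc_fraction = 0.42)
  # choose implant sites at the most AT-rich windows
  v <- strsplit(g[["c1"]], "")[[1]] %in% c("A", "T")
  win <- stats::filter(as.numeric(v), rep(1, 20), sides = 2)
  pos <- order(win, decreasing = TRUE)
  picked <- integer(0)
  for (p in pos) {
    if (p < 2000 || p > 58000) next
    if (length(picked) > 0 && min(abs(picked - p)) < 100) next
    picked <- c(picked, p)
    if (length(picked) == 15L) break
  }
  calls <- data.table::data.table(chrom = "c1",
                                  insertion_point = as.integer(picked),
                                  tsd_length = 0L)
  fa <- withr::local_tempfile(fileext = ".fa")
  fl <- extract_flanks(calls, g, fasta_path = fa)
  expect_gt(fl$at_fraction, 0.58)
  expect_equal(length(read_fasta(fa)), nrow(calls) )
  expect_equal(nrow(fl$sequences), nrow(calls) - fl$skipped)
})

test_that("genic annotation resolves feature precedence and windows", {
  gm <- GenomicRanges::GRanges(
    "c1",
    IRanges::IRanges(start = c(1000, 1000, 1000, 1450, 1901),
                     end = c(2000, 1200, 1400, 1900, 2000)),
    type = c("gene", "five_prime_UTR", "CDS", "CDS",
             "three_prime_UTR"))
  gm$ID <- c("geneA", NA, NA, NA, NA)
  calls <- data.table::data.table(
    chrom = "c1",
    insertion_point = c(1100L, 1420L, 1500L, 1950L, 501L, 499L, 5000L))
  got <- annotate_genic(calls, gm, window = 500L)
  expect_equal(got$feature_class,
               c("exon", "intron", "exon", "3UTR", "intergenic",
                 "intergenic", "intergenic"))
  # association window: 499 bases upstream in, 501 out
  expect_equal(got$genes[5], "geneA")   # at 501, distance 499
  expect_equal(got$genes[6], "")        # at 499, distance 501
  expect_equal(got$genes[7], "")

  # brute-force scan oracle on random calls
  set.seed(65)
  rnd <- data.table::data.table(chrom = "c1",
                                insertion_point = sample.int(6000L, 40L))
  got_rnd <- annotate_genic(rnd, gm, window = 500L)
  oracle <- vapply(rnd$insertion_point, function(p) {
    inside <- function(i) p >= GenomicRanges::start(gm)[i] &&
      p <= GenomicRanges::end(gm)[i]
    types <- as.character(gm$type)
    if (any(vapply(which(types == "CDS"), inside, TRUE))) "exon"
    else if (any(vapply(which(types == "five_prime_UTR"), inside, TRUE)))
      "5UTR"
    else if (any(vapply(which(types == "three_prime_UTR"), inside, TRUE)))
      "3UTR"
    else if (any(vapply(which(types == "gene"), inside, TRUE))) "intron"
    else "intergenic"
  }, character(1))
  expect_equal(got_rnd$feature_class, oracle)
})

test_that("Fisher p-values equal hypergeometric enumeration", {
  # helper reproducing the 2x2 two-sided Fisher p by explicit enumeration
  fisher_enum <- function(a, b, c, d) {
    m <- a + c; n_ <- b + d; k <- a + b
    support <- max(0, k - n_):min(k, m)
    probs <- vapply(support, function(x) {
      exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
    }, numeric(1))
    p_obs <- probs[support == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(c(8, 2, 100, 900), c(3, 17, 40, 140), c(0, 10, 5, 85),
                c(12, 3, 30, 200))
  for (cs in cases) {
    got <- fisher.test(matrix(cs, 2))$p.value
    expect_equal(got, fisher_enum(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("enrichment rows: saturation, significance rule, BH", {
  set.seed(71)
  bg <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 100000))
  calls <- data.table::data.table(
    chrom = "c1", insertion_point = sample.int(100000L, 50L))
  full_track <- list(all = bg)
  row <- enrichment(calls, full_track, bg, seed = 5L)
  expect_equal(row$signed_enrichment, 1.0)
  expect_equal(row$p_fisher, 1.0)
  expect_false(row$significant)

  # an enriched track: all calls inside a 1 kb window
  calls2 <- data.table::data.table(
    chrom = "c1", insertion_point = sample(5000:6000, 50L,
                                           replace = TRUE))
  tracks <- list(hot = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(5000, 6000)),
    cold = GenomicRanges::GRanges("c1", IRanges::IRanges(50000, 51000)))
  rows <- enrichment(calls2, tracks, bg, seed = 6L)
  expect_true(rows[track == "hot", significant])
  expect_lt(rows[track == "cold", signed_enrichment], 0)

  # BH adjustment matches the reference step-up and preserves order
  set.seed(73)
  p <- runif(20)^2
  manual_bh <- function(p) {
    n <- length(p); o <- order(p); ro <- order(o)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(1, q)[ro]
  }
  expect_equal(p.adjust(p, "BH"), manual_bh(p))
  expect_equal(order(p.adjust(p, "BH")[order(p)]), seq_along(p))
})

test_that("supporting/opposing pair counts give unbiased AF", {
  res <- toy_calls()
  sr <- toy_reads()
  af <- estimate_af(res$candidates, res$members, sr$genome_aln)
  expect_equal(nrow(af), 2L)
  # heterozygous at full cell fraction: AF approximately 0.5; binomial
  # tolerance at the junction depth
  for (i in seq_len(nrow(af))) {
    n <- af$support_pairs[i] + af$opposing_pairs[i]
    expect_lt(abs(af$allele_frequency[i] - 0.5),
              3 * sqrt(0.25 / n) + 0.02)
  }
})
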