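# Shared fixtures, built in code and cached across test files within one
# run. All seeds fixed.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_genome <- function() cached("toy_genome", {
  build_reference(1L, c(chr1 = 50000L), 0.42)
})

toy_library <- function() cached("toy_library", build_te_library(2L))

# Two heterozygous implants at full cell fraction, 50x coverage.
toy_sim <- function() cached("toy_sim", {
  g <- toy_genome()
  lib <- toy_library()
  specs <- data.frame(
    te_family = c("rover", "copia"), target_chrom = "chr1",
    target_pos = c(12000L, 30000L), strand = c("+", "-"),
    tsd_length = c(5L, 8L), truncation_5p = c(0L, 13L),
    cell_fraction = 1.0, zygosity = "heterozygous")
  implant(g, lib, specs)
})

toy_reads <- function() cached("toy_reads", {
  simulate_short_reads(toy_sim(), coverage = 50, seed = 3L)
})

toy_tagged <- function() cached("toy_tagged", {
  sr <- toy_reads()
  tag_reads(sr$genome_aln, sr$te_aln)
})

toy_calls <- function() cached("toy_calls", {
  sr <- toy_reads()
  call_insertions(sr$genome_aln, sr$te_aln, toy_sim()$genome)
})

# Minimal hand-written SAM text for parser tests.
write_test_sam <- function(records, path, seq_lengths = c(chr1 = 1000L)) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  writeLines(c(hdr, records), path)
  path
}

# A small catalog table with known contents.
toy_catalog <- function() {
  data.table::data.table(
    sample_id = c("P1", "P1", "P2", "P2", "P2", "P3", "P3", "P3", "P3",
                  "P3", "P3", "P4"),
    genotype = c(rep("genoA", 11), "genoB"),
    tissue = "gut",
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr1", "chr1", "chr1",
              "chr2", "chr2", "chr1", "chr2", "chr1"),
    position = c(100L, 500L, 900L, 1300L, 1700L, 2100L, 2500L, 2900L,
                 3300L, 3700L, 4100L, 4500L),
    te_family = c("rover", "rover", "rover", "rover", "rover", "rover",
                  "copia", "copia", "copia", "blood", "blood",
                  "I-element"),
    te_class = c(rep("LTR", 11), "LINE-like"),
    tsd_sequence = NA_character_,
    tsd_length = c(4L, 5L, 5L, 6L, 5L, 7L, 8L, 9L, 8L, 3L, 4L, 12L),
    support_split = 2L, support_mate = 3L,
    allele_frequency = 0.4)
}
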