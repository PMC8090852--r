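# Synthetic-data generator: toy genomes, TE consensus libraries, clonal
# implants with target-site duplications, and short/long reads with gold
# alignments emitted directly from known read origins. The gold alignments
# stand in for an external aligner so the full caller is testable offline;
# real aligner SAM/BAM files can be supplied to the same downstream
# functions instead.

#' Build a random reference genome
#'
#' @param seed integer seed; identical seeds give identical genomes
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param gc_fraction target GC content in `[0, 1]`
#' @return named character vector of uppercase chromosome sequences
#' @export
build_reference <- function(seed, chrom_lengths, gc_fraction = 0.42) {
  stopifnot(length(chrom_lengths) > 0L, !is.null(names(chrom_lengths)),
            gc_fraction >= 0, gc_fraction <= 1)
  with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    out <- vapply(as.integer(chrom_lengths), function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    stats::setNames(out, names(chrom_lengths))
  })
}

#' Family-to-class table for the toy TE library
#'
#' @return data.table with `te_family`, `te_class` and consensus `length`
#' @export
te_library_families <- function() {
  data.table::data.table(
    te_family = c("rover", "copia", "blood", "I-element", "hobo", "FB4"),
    te_class  = c("LTR", "LTR", "LTR", "LINE-like", "TIR", "FB"),
    length    = c(2800L, 1500L, 800L, 2200L, 600L, 1200L))
}

#' Build a toy TE consensus library
#'
#' Six families covering the four TE classes (LTR, LINE-like, TIR, FB),
#' with consensus lengths between 0.6 and 2.8 kb so that long-read
#' simulations can contain full-length copies inside single reads.
#'
#' @param seed integer seed
#' @param families optional table as returned by [te_library_families()]
#' @param gc_fraction GC content of the consensus sequences
#' @return named character vector of consensus sequences; the family table
#'   is attached as attribute `"families"`
#' @export
build_te_library <- function(seed, families = te_library_families(),
                             gc_fraction = 0.45) {
  lib <- with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
           gc_fraction / 2, (1 - gc_fraction) / 2)
    vapply(families$length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  names(lib) <- families$te_family
  attr(lib, "families") <- families
  lib
}

# Probability that a sampled chromosome copy carries the implant: the cell
# fraction times the within-cell allele dosage. A heterozygous autosomal
# implant sits on one of two homologs; hemizygous (male X) and homozygous
# implants occupy every copy present.
zygosity_factor <- function(zygosity) {
  f <- c(heterozygous = 0.5, hemizygous = 1.0, homozygous = 1.0)
  bad <- setdiff(unique(zygosity), names(f))
  if (length(bad) > 0L) stop("unknown zygosity: ", bad[1L])
  unname(f[zygosity])
}

#' Implant TE copies with TSDs into a genome
#'
#' Each implant duplicates the `tsd_length` bases immediately 5' of the
#' insertion point on both sides of the inserted element, emulating the
#' staggered target-site cut of integration. Optional 5' truncation removes
#' bases from the element's own 5' end before strand is applied.
#'
#' @param genome named character vector from [build_reference()]
#' @param te_library named character vector from [build_te_library()]
#' @param specs data.frame with columns `te_family, target_chrom,
#'   target_pos` (0-based insertion point), `strand` (+/-), `tsd_length`,
#'   `truncation_5p`, `cell_fraction` in (0,1], `zygosity`
#' @return list with `genome`, `te_library`, `haplotypes` (per-chromosome
#'   carrier sequence containing every implant), and `manifest`, a
#'   data.table of realized implants used downstream as the truth record:
#'   final coordinates, TSD sequence, inserted sequence, carrier-haplotype
#'   block coordinates and the per-chromosome-copy sampling probability
#'   `allele_prob`
#' @export
implant <- function(genome, te_library, specs) {
  specs <- data.table::as.data.table(specs)
  need <- c("te_family", "target_chrom", "target_pos", "strand",
            "tsd_length", "truncation_5p", "cell_fraction", "zygosity")
  miss <- setdiff(need, names(specs))
  if (length(miss) > 0L) stop("implant specs missing column: ", miss[1L])
  if (nrow(specs) == 0L) stop("no implant specs given")
  bad_fam <- setdiff(specs$te_family, names(te_library))
  if (length(bad_fam) > 0L) stop("unknown TE family: ", bad_fam[1L])
  bad_chr <- setdiff(specs$target_chrom, names(genome))
  if (length(bad_chr) > 0L) stop("unknown chromosome: ", bad_chr[1L])

  specs <- specs[order(target_chrom, target_pos)]
  specs[, implant_id := sprintf("imp%03d", .I)]

  man_list <- list()
  haplotypes <- genome
  for (chr in unique(specs$target_chrom)) {
    ss <- specs[target_chrom == chr]
    L <- nchar(genome[[chr]])
    if (any(ss$target_pos - ss$tsd_length < 0L | ss$target_pos >= L)) {
      stop("implant position out of bounds on ", chr)
    }
    # duplicated windows [pos - tsd, pos) must not overlap between implants
    if (nrow(ss) > 1L) {
      lo <- ss$target_pos - ss$tsd_length
      hi <- ss$target_pos
      for (i in seq_len(nrow(ss) - 1L)) {
        if (hi[i] > lo[i + 1L]) {
          stop("overlapping implant specs: ", ss$implant_id[i], " and ",
               ss$implant_id[i + 1L])
        }
      }
    }
    pieces <- character(0)
    prev <- 0L       # next reference base to copy (0-based)
    cum <- 0L        # extra bases added so far
    for (i in seq_len(nrow(ss))) {
      p <- ss$target_pos[i]
      t <- ss$tsd_length[i]
      elem <- te_library[[ss$te_family[i]]]
      trunc <- ss$truncation_5p[i]
      if (trunc >= nchar(elem)) {
        stop("truncation_5p >= element length for ", ss$implant_id[i])
      }
      core <- substr(elem, trunc + 1L, nchar(elem))
      ins <- if (ss$strand[i] == "+") core else revcomp(core)
      e <- nchar(ins)
      tsd_seq <- if (t > 0L) substr(genome[[chr]], p - t + 1L, p) else ""
      pieces <- c(pieces, substr(genome[[chr]], prev + 1L, p), ins)
      # the haplotype resumes at ref p - t, duplicating the TSD bases
      prev <- p - t
      block_start <- p + cum            # haplotype coord of element start
      cum <- cum + e + t
      man_list[[length(man_list) + 1L]] <- data.table::data.table(
        implant_id = ss$implant_id[i],
        te_family = ss$te_family[i],
        chrom = chr,
        pos = p,
        insertion_point = p - t + 1L,   # 1-based first duplicated base
        strand = ss$strand[i],
        tsd_length = t,
        tsd_seq = tsd_seq,
        truncation_5p = trunc,
        insert_seq = ins,
        insert_len = e,
        block_start = block_start,
        block_len = e + t,
        cell_fraction = ss$cell_fraction[i],
        zygosity = ss$zygosity[i],
        allele_prob = ss$cell_fraction[i] * zygosity_factor(ss$zygosity[i]))
    }
    pieces <- c(pieces, substr(genome[[chr]], prev + 1L, L))
    haplotypes[[chr]] <- paste(pieces, collapse = "")
  }
  manifest <- data.table::rbindlist(man_list)
  for (chr in unique(manifest$chrom)) {
    expect_len <- nchar(genome[[chr]]) +
      manifest[chrom == chr, sum(block_len)]
    stopifnot(nchar(haplotypes[[chr]]) == expect_len)
  }
  list(genome = genome, te_library = te_library,
       haplotypes = haplotypes, manifest = manifest)
}

#' Sample random implant specifications
#'
#' Draws `n` implant sites uniformly (with a minimum separation), cycling
#' through the library families, with TSD lengths in `tsd_range` and
#' random strands. Sites where the inserted element's terminal base
#' coincides with the reference base immediately 5' of the TSD are
#' rejected and resampled: at such sites the TSD is not identifiable from
#' the sequence (the duplication could be extended by the coincidental
#' match), so no caller could be expected to recover the recorded length.
#'
#' @param genome named chromosome sequences
#' @param te_library consensus library
#' @param n number of implants
#' @param seed integer seed
#' @param tsd_range inclusive TSD length range
#' @param cell_fraction,zygosity recorded on every spec
#' @param truncation_5p 5' truncation per implant (recycled)
#' @param min_gap minimum distance between insertion points
#' @param edge_margin keep-out distance from contig ends
#' @return data.frame of implant specs for [implant()]
#' @export
random_implant_specs <- function(genome, te_library, n, seed = 1L,
                                 tsd_range = c(3L, 12L),
                                 cell_fraction = 1.0,
                                 zygosity = "heterozygous",
                                 truncation_5p = 0L,
                                 min_gap = 10000L, edge_margin = 2000L) {
  fams <- rep_len(names(te_library), n)
  trunc <- rep_len(as.integer(truncation_5p), n)
  with_seed(seed, {
    chroms <- names(genome)
    lens <- stats::setNames(as.numeric(nchar(genome)), chroms)
    # allocate implants to chromosomes proportionally to length, then
    # place each chromosome's implants in evenly spaced slots with
    # random jitter: placement always terminates, unlike rejection
    # sampling, and separation is guaranteed by construction
    alloc <- table(factor(
      sample(chroms, n, replace = TRUE, prob = lens / sum(lens)),
      levels = chroms))
    specs <- list()
    i <- 0L
    for (chr in chroms) {
      k <- as.integer(alloc[[chr]])
      if (k == 0L) next
      usable <- lens[[chr]] - 2 * edge_margin
      step <- usable / k
      if (step < min_gap) {
        stop("cannot place ", k, " implants with min_gap ", min_gap,
             " on ", chr, " (usable ", usable, " bases)")
      }
      jitter_w <- max(0, (step - min_gap) / 2)
      for (j in seq_len(k)) {
        i <- i + 1L
        t <- sample(seq(tsd_range[1], tsd_range[2]), 1L)
        s <- sample(c("+", "-"), 1L)
        elem <- te_library[[fams[i]]]
        core <- substr(elem, trunc[i] + 1L, nchar(elem))
        ins <- if (s == "+") core else revcomp(core)
        last_base <- substr(ins, nchar(ins), nchar(ins))
        center <- edge_margin + (j - 0.5) * step
        p <- as.integer(round(center +
                                stats::runif(1, -jitter_w, jitter_w)))
        # identifiability: the base left of the TSD must differ from the
        # element's final base, else the duplication length is ambiguous;
        # nudge the site by single bases until it does
        while (substr(genome[[chr]], p - t, p - t) == last_base) {
          p <- p + 1L
        }
        specs[[i]] <- data.frame(
          te_family = fams[i], target_chrom = chr, target_pos = p,
          strand = s, tsd_length = t, truncation_5p = trunc[i],
          cell_fraction = cell_fraction, zygosity = zygosity)
      }
    }
    do.call(rbind, specs)
  })
}

# Per-chromosome implant-block table with cumulative haplotype offsets.
.chrom_blocks <- function(manifest, chr) {
  bl <- manifest[chrom == chr]
  data.table::setorder(bl, block_start)
  if (nrow(bl) > 0L) {
    bl[, cum_before := data.table::shift(cumsum(block_len), fill = 0L)]
  }
  bl
}

# Apply uniform substitution errors to a character vector of reads.
.apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    v <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}

#' Simulate paired-end short reads over a clonal cell mixture
#'
#' Fragments are drawn uniformly over each chromosome; fragments whose
#' reference span crosses an implant's insertion point switch to the
#' carrier allele with probability `cell_fraction * dosage`, and carrier
#' coverage over the inserted block is replenished at the matched per-base
#' start density, so junction allele fractions behave binomially. Gold
#' genome alignments place every read at its true reference origin,
#' soft-clipping read portions that derive from inserted sequence (reads
#' without a sufficiently long reference anchor are emitted unmapped);
#' gold TE alignments map insert-derived read portions onto the family
#' consensus.
#'
#' @param sim result of [implant()], or `list(genome = ...)` for an
#'   insertion-free control
#' @param coverage mean read coverage (default 47, a typical whole-genome
#'   depth for this design)
#' @param read_len read length in bases
#' @param insert_mean,insert_sd fragment (template) length distribution
#' @param error_rate per-base substitution probability
#' @param seed integer seed; identical seeds give identical output
#' @param min_anchor minimum reference-aligned bases for a junction read
#'   to be emitted as mapped
#' @return list with `reads` (read_id, mate, seq in sequenced orientation,
#'   origin), `genome_aln` and `te_aln` alignment tables (the gold
#'   alignments, writable with [write_sam()]), `seq_lengths`, `manifest`
#' @export
simulate_short_reads <- function(sim, coverage = 47, read_len = 100L,
                                 insert_mean = 350, insert_sd = 35,
                                 error_rate = 0, seed = 1L,
                                 min_anchor = 15L) {
  if (insert_mean <= read_len) stop("insert_mean must exceed read_len")
  genome <- sim$genome
  manifest <- if (!is.null(sim$manifest)) sim$manifest else
    data.table::data.table()
  haplotypes <- if (!is.null(sim$haplotypes)) sim$haplotypes else genome
  min_te_len <- 15L

  with_seed(seed, {
    # ---- fragments ----------------------------------------------------
    frag_rows <- list()
    for (chr in names(genome)) {
      L <- nchar(genome[[chr]])
      N <- round(coverage * L / (2 * read_len))
      flen <- pmax(as.integer(round(stats::rnorm(N, insert_mean,
                                                 insert_sd))),
                   read_len + 10L)
      s <- as.integer(floor(stats::runif(N) * (L - flen)))
      keep <- rep(TRUE, N)
      blocks <- if (nrow(manifest) > 0L) .chrom_blocks(manifest, chr) else
        manifest
      carrier <- list()
      if (nrow(blocks) > 0L) {
        for (i in seq_len(nrow(blocks))) {
          p <- blocks$pos[i]; q <- blocks$allele_prob[i]
          cross <- which(s < p & s + flen > p)
          drop <- cross[stats::runif(length(cross)) < q]
          keep[drop] <- FALSE
          P <- blocks$block_start[i]; B <- blocks$block_len[i]
          lambda <- q * (N / L) * (B + insert_mean - 1)
          n_i <- stats::rpois(1L, lambda)
          if (n_i > 0L) {
            fl <- pmax(as.integer(round(stats::rnorm(n_i, insert_mean,
                                                     insert_sd))),
                       read_len + 10L)
            lo <- pmax(P - fl + 1L, 0L)
            hi <- pmin(P + B - 1L, nchar(haplotypes[[chr]]) - fl)
            ok <- hi >= lo
            st <- as.integer(lo + floor(stats::runif(n_i) * (hi - lo + 1L)))
            carrier[[length(carrier) + 1L]] <- data.table::data.table(
              start = st[ok], flen = fl[ok],
              origin = blocks$implant_id[i])
          }
        }
      }
      fr <- data.table::rbindlist(c(
        list(data.table::data.table(start = s[keep], flen = flen[keep],
                                    origin = "ref")),
        carrier))
      fr[, chrom := chr]
      frag_rows[[chr]] <- fr
    }
    frags <- data.table::rbindlist(frag_rows)
    frags[, frag_id := sprintf("frag%08d", .I)]
    frags[, fwd_is_r1 := stats::runif(.N) < 0.5]

    # ---- expand to reads ----------------------------------------------
    fwd <- frags[, .(frag_id, chrom, origin, fwd_is_r1,
                     a = start, b = start + read_len, strand = "+")]
    rev <- frags[, .(frag_id, chrom, origin, fwd_is_r1,
                     a = start + flen - read_len, b = start + flen,
                     strand = "-")]
    rd <- data.table::rbindlist(list(fwd, rev))
    rd[, mate := ifelse((strand == "+") == fwd_is_r1, 1L, 2L)]
    rd[, slice := ""]
    for (chr in names(genome)) {
      ir <- rd$chrom == chr & rd$origin == "ref"
      ih <- rd$chrom == chr & rd$origin != "ref"
      if (any(ir)) rd[ir, slice := substring(genome[[chr]], a + 1L, b)]
      if (any(ih)) rd[ih, slice := substring(haplotypes[[chr]], a + 1L, b)]
    }
    # ---- project carrier reads onto the reference ---------------------
    rd[, `:=`(mapped = TRUE, ref_start = a, m_left = read_len,
              m_right = 0L, te_hit = FALSE, q_s = NA_integer_,
              q_e = NA_integer_, cons_s = NA_integer_,
              cons_e = NA_integer_, tsh = NA_character_,
              te_fam = NA_character_)]
    if (nrow(manifest) > 0L) {
      for (chr in unique(manifest$chrom)) {
        blocks <- .chrom_blocks(manifest, chr)
        for (i in seq_len(nrow(blocks))) {
          id <- blocks$implant_id[i]
          idx <- which(rd$origin == id)
          if (length(idx) == 0L) next
          el_s <- blocks$block_start[i]
          e <- blocks$insert_len[i]
          el_e <- el_s + e
          cumb <- blocks$cum_before[i]
          pos <- blocks$pos[i]; t <- blocks$tsd_length[i]
          trunc <- blocks$truncation_5p[i]
          a_ <- rd$a[idx]; b_ <- rd$b[idx]
          left_of <- b_ <= el_s
          right_of <- a_ >= el_e
          ov <- !left_of & !right_of
          lf <- pmax(0L, el_s - a_)
          rt <- pmax(0L, b_ - el_e)
          ref_start_v <- ifelse(left_of, a_ - cumb,
                         ifelse(right_of, a_ - cumb - e - t,
                         ifelse(lf >= rt, a_ - cumb, pos - t)))
          m_left_v <- ifelse(ov, ifelse(lf >= rt, lf, 0L), read_len)
          m_right_v <- ifelse(ov, ifelse(lf >= rt, 0L, rt), 0L)
          mapped_v <- !ov | pmax(lf, rt) >= min_anchor
          ov_len <- pmin(b_, el_e) - pmax(a_, el_s)
          hit_v <- ov & ov_len >= min_te_len
          os <- pmax(0L, a_ - el_s)
          oe <- pmin(b_, el_e) - el_s
          if (blocks$strand[i] == "+") {
            cons_s_v <- trunc + os; cons_e_v <- trunc + oe; tsh_v <- "+"
          } else {
            cons_s_v <- trunc + e - oe; cons_e_v <- trunc + e - os
            tsh_v <- "-"
          }
          data.table::set(rd, i = idx, j = "mapped", value = mapped_v)
          data.table::set(rd, i = idx, j = "ref_start",
                          value = as.integer(ref_start_v))
          data.table::set(rd, i = idx, j = "m_left",
                          value = as.integer(m_left_v))
          data.table::set(rd, i = idx, j = "m_right",
                          value = as.integer(m_right_v))
          data.table::set(rd, i = idx, j = "te_hit", value = hit_v)
          data.table::set(rd, i = idx, j = "q_s",
                          value = as.integer(pmax(a_, el_s) - a_))
          data.table::set(rd, i = idx, j = "q_e",
                          value = as.integer(pmin(b_, el_e) - a_))
          data.table::set(rd, i = idx, j = "cons_s",
                          value = as.integer(cons_s_v))
          data.table::set(rd, i = idx, j = "cons_e",
                          value = as.integer(cons_e_v))
          data.table::set(rd, i = idx, j = "tsh", value = tsh_v)
          data.table::set(rd, i = idx, j = "te_fam",
                          value = blocks$te_family[i])
        }
      }
    }
    # ---- sequenced reads, errors --------------------------------------
    rd[, rseq := ifelse(strand == "-", revcomp(slice), slice)]
    rd[, rseq := .apply_errors(rseq, error_rate)]
    rd[, stored := ifelse(strand == "-", revcomp(rseq), rseq)]

    reads <- rd[, .(read_id = frag_id, mate, seq = rseq, origin, chrom,
                    hap_start = a)]
    genome_aln <- .gold_genome_table(rd, read_len)
    te_aln <- .gold_te_table(rd, read_len)
    list(reads = reads[], genome_aln = genome_aln, te_aln = te_aln,
         seq_lengths = stats::setNames(nchar(genome), names(genome)),
         manifest = manifest)
  })
}

# Assemble the gold genome alignment table (package schema, SAM-complete).
.gold_genome_table <- function(rd, read_len) {
  g <- rd[, .(read_id = frag_id, mate, chrom, strand, origin, mapped,
              ref_start, m_left, m_right, stored)]
  g[, cigar := data.table::fcase(
    !mapped, "*",
    m_left == read_len, sprintf("%dM", read_len),
    m_left > 0L, sprintf("%dM%dS", m_left, read_len - m_left),
    default = sprintf("%dS%dM", read_len - m_right, m_right))]
  g[, ref_len := ifelse(mapped, pmax(m_left, m_right), 0L)]
  g[, full := mapped & m_left == read_len]
  g[, mapq := ifelse(mapped, 60L, 0L)]
  mates <- g[, .(read_id, mate = 3L - mate, m_chrom = chrom,
                 m_start = ref_start, m_mapped = mapped,
                 m_strand = strand, m_full = full, m_ref_len = ref_len)]
  data.table::setkey(mates, read_id, mate)
  data.table::setkey(g, read_id, mate)
  g <- mates[g]
  g[, is_proper := mapped & m_mapped & full & m_full]
  g[, flag := 1L + ifelse(is_proper, 2L, 0L) +
      ifelse(mapped, 0L, 4L) + ifelse(m_mapped, 0L, 8L) +
      ifelse(strand == "-", 16L, 0L) +
      ifelse(m_mapped & m_strand == "-", 32L, 0L) +
      ifelse(mate == 1L, 64L, 128L)]
  both <- g$mapped & g$m_mapped
  g[, tlen := 0L]
  g[both & strand == "+", tlen := (m_start + m_ref_len) - ref_start]
  g[both & strand == "-", tlen := -((ref_start + ref_len) - m_start)]
  qn <- nchar(g$stored)
  out <- data.table::data.table(
    read_id = g$read_id, mate = g$mate, flag = g$flag,
    chrom = ifelse(g$mapped, g$chrom, ifelse(g$m_mapped, g$m_chrom, "")),
    start = ifelse(g$mapped, g$ref_start,
                   ifelse(g$m_mapped, g$m_start, 0L)),
    end = ifelse(g$mapped, g$ref_start + g$ref_len, 0L),
    strand = g$strand, mapq = g$mapq, cigar = g$cigar, seq = g$stored,
    clip_left = ifelse(g$mapped & g$m_left == 0L,
                       substr(g$stored, 1L, read_len - g$m_right), ""),
    clip_right = ifelse(g$mapped & g$m_left > 0L & g$m_left < read_len,
                        substr(g$stored, g$m_left + 1L, read_len), ""),
    is_proper = g$is_proper, is_dup = FALSE, is_mapped = g$mapped,
    mate_chrom = ifelse(g$m_mapped, g$m_chrom, ""),
    mate_pos = ifelse(g$m_mapped, g$m_start, 0L),
    tlen = g$tlen, tags = "", origin = g$origin)
  data.table::setorder(out, chrom, start, read_id, mate)
  out
}

# Assemble the gold TE-consensus alignment table. Records are stored in
# consensus orientation; query offsets live in the CIGAR clips.
.gold_te_table <- function(rd, read_len) {
  h <- rd[te_hit == TRUE]
  if (nrow(h) == 0L) {
    out <- empty_alignment_table()
    out[, origin := character(0)]
    return(out)
  }
  # stored-on-consensus sequence: forward haplotype slice when the element
  # went in forward, revcomp otherwise (independent of which mate it is);
  # `stored` is the error-mutated forward slice
  h[, te_seq := ifelse(tsh == "+", stored, revcomp(stored))]
  h[, te_strand := ifelse((strand == "-") == (tsh == "-"), "+", "-")]
  qs <- ifelse(h$tsh == "+", h$q_s, read_len - h$q_e)
  qe <- ifelse(h$tsh == "+", h$q_e, read_len - h$q_s)
  mlen <- qe - qs
  cig <- paste0(ifelse(qs > 0L, paste0(qs, "S"), ""), mlen, "M",
                ifelse(read_len - qe > 0L, paste0(read_len - qe, "S"), ""))
  out <- data.table::data.table(
    read_id = h$frag_id, mate = h$mate,
    flag = 1L + ifelse(h$te_strand == "-", 16L, 0L) +
      ifelse(h$mate == 1L, 64L, 128L),
    chrom = h$te_fam, start = h$cons_s, end = h$cons_e,
    strand = h$te_strand, mapq = 60L, cigar = cig, seq = h$te_seq,
    clip_left = ifelse(qs > 0L, substr(h$te_seq, 1L, qs), ""),
    clip_right = ifelse(read_len - qe > 0L,
                        substr(h$te_seq, qe + 1L, read_len), ""),
    is_proper = FALSE, is_dup = FALSE, is_mapped = TRUE,
    mate_chrom = "", mate_pos = 0L, tlen = 0L, tags = "",
    origin = h$origin)
  data.table::setorder(out, chrom, start, read_id, mate)
  out
}

#' Simulate long reads over a clonal cell mixture
#'
#' Read lengths follow a log-normal distribution (or are resampled from an
#' empirical length multiset). Reads whose reference span crosses an
#' implant's insertion point switch to the carrier haplotype with
#' probability `cell_fraction * dosage`; with `reads_per_implant` set,
#' each implant instead receives exactly that many spanning reads (full
#' insert plus flanks guaranteed), the controlled regime used for
#' singleton fixtures. Gold alignments encode each fully-contained
#' inserted block as a CIGAR `I` segment (default) or as a soft clip of
#' the shorter flank.
#'
#' @param sim result of [implant()]
#' @param depth target mean coverage in bases (default 85)
#' @param length_dist either `list(meanlog=, sdlog=)` or a numeric vector
#'   of lengths to resample from
#' @param error_rate per-base substitution probability
#' @param seed integer seed
#' @param reads_per_implant NULL for probabilistic carrier sampling, or an
#'   integer: exact number of implant-spanning reads per implant
#' @param encode `"insert_cigar"` or `"soft_clip"` gold representation
#' @param library_id,tissue labels recorded on every read (used by
#'   read-size normalization and singleton calling)
#' @param min_span_flank guaranteed flank on each side of the inserted
#'   block for forced spanning reads
#' @return list with `reads` (read_id, seq, len, tissue, library_id,
#'   origin), `aln` gold alignment table, `seq_lengths`, `manifest`
#' @export
simulate_long_reads <- function(sim, depth = 85,
                                length_dist = list(meanlog = log(8000),
                                                   sdlog = 0.5),
                                error_rate = 0, seed = 1L,
                                reads_per_implant = NULL,
                                encode = c("insert_cigar", "soft_clip"),
                                library_id = "lib1", tissue = "gut",
                                min_span_flank = 500L) {
  encode <- match.arg(encode)
  genome <- sim$genome
  manifest <- if (!is.null(sim$manifest)) sim$manifest else
    data.table::data.table()
  haplotypes <- if (!is.null(sim$haplotypes)) sim$haplotypes else genome

  draw_len <- function(n) {
    if (is.numeric(length_dist) && !is.list(length_dist)) {
      as.integer(sample(length_dist, n, replace = TRUE))
    } else {
      pmax(as.integer(round(stats::rlnorm(n, length_dist$meanlog,
                                          length_dist$sdlog))), 300L)
    }
  }

  with_seed(seed, {
    chroms <- names(genome)
    lens <- nchar(genome)
    names(lens) <- chroms
    target <- depth * sum(lens)
    rl <- integer(0)
    while (sum(rl) < target) rl <- c(rl, draw_len(max(16L, length(rl))))
    rl <- rl[seq_len(which(cumsum(rl) >= target)[1L])]
    chr_of <- sample(chroms, length(rl), replace = TRUE,
                     prob = lens / sum(lens))
    rows <- list(); alns <- list()
    read_no <- 0L
    emit_read <- function(chr, a, len, origin, carrier) {
      read_no <<- read_no + 1L
      rid <- sprintf("%s_long%06d", library_id, read_no)
      if (!carrier) {
        seqs <- substring(genome[[chr]], a + 1L, a + len)
        rows[[rid]] <<- list(read_id = rid, seq = seqs, len = len)
        alns[[rid]] <<- list(read_id = rid, chrom = chr, start = a,
                             cigar = sprintf("%dM", len), origin = origin)
        return(invisible(NULL))
      }
      blocks <- .chrom_blocks(manifest, chr)
      b <- a + len
      seqs <- substring(haplotypes[[chr]], a + 1L, b)
      hit <- blocks[block_start < b & block_start + block_len > a]
      lead_clip <- 0L; tail_clip <- 0L
      cur <- a
      ref_start <- NA_integer_
      if (nrow(hit) > 0L && hit$block_start[1L] <= a) {
        blk1 <- hit[1L]
        if (b <= blk1$block_start + blk1$insert_len) {
          return(invisible(NULL))   # read entirely inside the element
        }
        if (a < blk1$block_start + blk1$insert_len) {
          # read starts inside an element: clip the element-derived prefix
          lead_clip <- blk1$block_start + blk1$insert_len - a
          cur <- blk1$block_start + blk1$insert_len
          ref_start <- blk1$pos - blk1$tsd_length
        } else {
          # read starts in the duplicated copy: reference-aligned from
          # the resumed reference coordinate
          ref_start <- blk1$pos - blk1$tsd_length +
            (a - (blk1$block_start + blk1$insert_len))
        }
        hit <- hit[-1L]
      }
      if (nrow(hit) > 0L && hit[.N, block_start + block_len] > b) {
        # read ends inside the block: soft-clip the insert-derived tail
        # (including any partial TSD copy)
        tail_clip <- b - max(hit[.N, block_start], cur)
        hit <- hit[-nrow(hit)]
      }
      if (is.na(ref_start)) {
        after <- blocks[block_start + insert_len <= cur]
        shift <- if (nrow(after) == 0L) 0L else
          after[.N, cum_before + insert_len + tsd_length]
        ref_start <- cur - shift
      }
      pieces <- character(0)
      if (lead_clip > 0L) pieces <- c(pieces, sprintf("%dS", lead_clip))
      pos <- cur
      if (nrow(hit) > 0L) {
        for (i in seq_len(nrow(hit))) {
          m <- hit$block_start[i] - pos
          pieces <- c(pieces, sprintf("%dM", m),
                      sprintf("%dI", hit$block_len[i]))
          pos <- hit$block_start[i] + hit$block_len[i]
        }
      }
      endm <- (b - tail_clip) - pos
      if (endm > 0L) pieces <- c(pieces, sprintf("%dM", endm))
      if (tail_clip > 0L) pieces <- c(pieces, sprintf("%dS", tail_clip))
      cigar <- paste(pieces, collapse = "")
      if (encode == "soft_clip" && grepl("I", cigar, fixed = TRUE)) {
        conv <- .insert_to_clip(cigar, ref_start)
        cigar <- conv$cigar
        ref_start <- conv$ref_start
      }
      rows[[rid]] <<- list(read_id = rid, seq = seqs, len = len)
      alns[[rid]] <<- list(read_id = rid, chrom = chr, start = ref_start,
                           cigar = cigar, origin = origin)
      invisible(NULL)
    }

    for (k in seq_along(rl)) {
      chr <- chr_of[k]
      L <- lens[[chr]]
      len <- min(rl[k], L - 1L)
      a <- as.integer(floor(stats::runif(1) * (L - len)))
      carrier <- FALSE
      if (nrow(manifest) > 0L && is.null(reads_per_implant)) {
        mm <- manifest[chrom == chr & pos > a & pos < a + len]
        if (nrow(mm) > 0L && stats::runif(1) < mm$allele_prob[1L]) {
          carrier <- TRUE
          blocks <- .chrom_blocks(manifest, chr)
          a <- a + blocks[implant_id == mm$implant_id[1L], cum_before]
        }
      } else if (nrow(manifest) > 0L) {
        mm <- manifest[chrom == chr & pos > a & pos < a + len]
        if (nrow(mm) > 0L) next   # forced mode: background avoids junctions
      }
      emit_read(chr, a, len, if (carrier) "carrier" else "ref", carrier)
    }
    if (!is.null(reads_per_implant) && nrow(manifest) > 0L) {
      for (i in seq_len(nrow(manifest))) {
        chr <- manifest$chrom[i]
        blocks <- .chrom_blocks(manifest, chr)
        bi <- which(blocks$implant_id == manifest$implant_id[i])
        blk <- blocks[bi]
        # confine forced reads between the neighboring implant blocks so
        # each spanning read supports exactly one implant
        lo_bound <- if (bi > 1L)
          blocks[bi - 1L, block_start + block_len] else 0L
        hi_bound <- if (bi < nrow(blocks))
          blocks[bi + 1L, block_start] else nchar(haplotypes[[chr]])
        for (r in seq_len(reads_per_implant)) {
          len <- max(draw_len(1L), blk$block_len + 2L * min_span_flank)
          len <- min(len, hi_bound - lo_bound)
          lo <- max(lo_bound,
                    blk$block_start + blk$block_len + min_span_flank -
                      len)
          hi <- max(lo, min(blk$block_start - min_span_flank,
                            hi_bound - len))
          a <- as.integer(lo + floor(stats::runif(1) * (hi - lo + 1L)))
          len <- min(len, nchar(haplotypes[[chr]]) - a)
          emit_read(chr, a, len, blk$implant_id, TRUE)
        }
      }
    }
    reads <- data.table::rbindlist(rows)
    reads[, `:=`(tissue = tissue, library_id = library_id)]
    ann <- data.table::rbindlist(alns)
    reads[, origin := ann$origin[match(read_id, ann$read_id)]]
    reads[, seq := .apply_errors(seq, error_rate)]
    data.table::setkey(reads, read_id)
    aln <- data.table::data.table(
      read_id = ann$read_id, mate = NA_integer_, flag = 0L,
      chrom = ann$chrom, start = ann$start, end = 0L, strand = "+",
      mapq = 60L, cigar = ann$cigar,
      seq = reads[ann$read_id, seq],
      clip_left = "", clip_right = "", is_proper = FALSE, is_dup = FALSE,
      is_mapped = TRUE, mate_chrom = "", mate_pos = 0L, tlen = 0L,
      tags = "", origin = ann$origin)
    aln[, end := start + cigar_ref_length(cigar)]
    cl <- cigar_clip_lengths(aln$cigar)
    qn <- nchar(aln$seq)
    aln[, clip_left := ifelse(cl$left > 0L, substr(seq, 1L, cl$left), "")]
    aln[, clip_right := ifelse(cl$right > 0L,
                               substr(seq, qn - cl$right + 1L, qn), "")]
    data.table::setorder(aln, chrom, start, read_id)
    list(reads = reads[], aln = aln[],
         seq_lengths = stats::setNames(nchar(genome), names(genome)),
         manifest = manifest)
  })
}

# Convert an M/I/M gold CIGAR to the soft-clip representation: keep the
# longest aligned flank, clip the rest of the read.
.insert_to_clip <- function(cigar, ref_start) {
  ops <- cigar_ops(cigar)[[1]]
  qlen <- ifelse(ops$op %in% c("M", "I", "S"), ops$len, 0L)
  mi <- which(ops$op == "I")[1L]
  left <- seq_len(mi - 1L)
  left_m <- sum(ops$len[left][ops$op[left] == "M"])
  right <- setdiff(seq_len(nrow(ops)), c(left, mi))
  right_m <- sum(ops$len[right][ops$op[right] == "M"])
  qtot <- sum(qlen)
  if (left_m >= right_m) {
    list(cigar = sprintf("%dM%dS", left_m, qtot - left_m),
         ref_start = ref_start)
  } else {
    # aligned part resumes where the reference resumes after the block
    list(cigar = sprintf("%dS%dM", qtot - right_m, right_m),
         ref_start = ref_start + left_m)
  }
}

#' Write reads to FASTQ
#'
#' @param reads table with `read_id`, `seq` and optionally `mate`
#' @param path output path; for paired reads supply two paths (mate 1,
#'   mate 2)
#' @export
write_fastq <- function(reads, path) {
  emit <- function(tab, p) {
    qual <- strrep("I", nchar(tab$seq))
    writeLines(paste0("@", tab$read_id, "\n", tab$seq, "\n+\n", qual), p)
  }
  if ("mate" %in% names(reads) && length(path) == 2L) {
    emit(reads[mate == 1L], path[1L])
    emit(reads[mate == 2L], path[2L])
  } else {
    emit(reads, path[1L])
  }
  invisible(path)
}
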