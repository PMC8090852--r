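# Cross-sample confirmation of insertion candidates: support prefilter,
# panel-of-normals subtraction, TSD requirement, and germline
# classification across the tissues of each individual.

#' Require both split-read and mate-pair support
#'
#' @param candidates candidate table
#' @return the subset with `split_support >= 1` and `mate_support >= 1`
#' @export
prefilter_support <- function(candidates) {
  data.table::as.data.table(candidates)[split_support >= 1L &
                                          mate_support >= 1L]
}

# Does candidate row `a` link to candidate row `b`? Linked when they sit
# on the same chromosome within `slop` bases, share the TE family, and
# their junction clips are not incompatible (either side's clips matching
# under the anchored-identity rule, or no informative clip to compare).
.keys_link <- function(a, b, slop, min_clip = 10L, min_identity = 0.9) {
  if (a$chrom != b$chrom) return(FALSE)
  if (a$te_family != b$te_family) return(FALSE)
  if (abs(a$insertion_point - b$insertion_point) > slop) return(FALSE)
  cmp5 <- if (!is.na(a$clip_5p) && !is.na(b$clip_5p)) {
    clips_compatible(a$clip_5p, b$clip_5p, side = "right",
                     min_len = min_clip, min_identity = min_identity)
  } else NA
  cmp3 <- if (!is.na(a$clip_3p) && !is.na(b$clip_3p)) {
    clips_compatible(a$clip_3p, b$clip_3p, side = "left",
                     min_len = min_clip, min_identity = min_identity)
  } else NA
  if (isTRUE(cmp5) || isTRUE(cmp3)) return(TRUE)
  if (isFALSE(cmp5) || isFALSE(cmp3)) return(FALSE)
  TRUE   # position + family match, no informative clips to contradict
}

# All rows of `pool` linked to candidate `a` (indices into pool).
.linked_rows <- function(a, pool, slop, min_clip = 10L,
                         min_identity = 0.9) {
  if (nrow(pool) == 0L) return(integer(0))
  near <- which(pool$chrom == a$chrom &
                  pool$te_family == a$te_family &
                  abs(pool$insertion_point - a$insertion_point) <= slop)
  near[vapply(near, function(j) {
    .keys_link(a, pool[j], slop, min_clip, min_identity)
  }, logical(1))]
}

#' Confirm somatic insertions against a panel of normals
#'
#' A case candidate is somatic when no panel candidate links to it (same
#' chromosome and family, positions within `slop`, clip sequences not
#' conflicting) and, by default, when it carries a valid TSD. Calls are
#' annotated with the other case samples sharing the link key and with a
#' `needs_review` flag when junction estimates of linked case calls
#' disagree by more than `slop/2` (replacing manual screenshot review with
#' a machine-readable flag).
#'
#' @param candidates_by_sample named list of candidate tables (case
#'   samples), or a single table with a `sample_id` column
#' @param panel candidate table pooled across all panel-of-normals
#'   samples (typically every control-tissue sample; empty panel allowed
#'   with a warning)
#' @param slop maximum junction distance for cross-sample linking
#' @param require_tsd require a valid TSD on somatic calls
#' @param min_clip,min_identity clip matching rule
#' @return single table of somatic calls with `sample_id`,
#'   `shared_with` (comma-separated other case samples) and
#'   `needs_review`
#' @export
confirm_somatic <- function(candidates_by_sample, panel, slop = 50L,
                            require_tsd = TRUE, min_clip = 10L,
                            min_identity = 0.9) {
  cands <- .bind_samples(candidates_by_sample)
  panel <- data.table::as.data.table(panel)
  if (nrow(panel) == 0L) {
    warning("empty panel of normals: running panel-free")
  }
  if (nrow(cands) == 0L) return(cands)
  keep <- logical(nrow(cands))
  shared <- character(nrow(cands))
  review <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    a <- cands[i]
    if (require_tsd && (is.na(a$tsd_seq) || a$tsd_seq == "")) next
    if (length(.linked_rows(a, panel, slop, min_clip,
                            min_identity)) > 0L) next
    keep[i] <- TRUE
    others <- cands[sample_id != a$sample_id]
    li <- .linked_rows(a, others, slop, min_clip, min_identity)
    if (length(li) > 0L) {
      shared[i] <- paste(sort(unique(others$sample_id[li])),
                         collapse = ",")
      review[i] <- any(abs(others$insertion_point[li] -
                             a$insertion_point) > slop / 2)
    }
  }
  out <- cands[keep]
  out[, shared_with := shared[keep]]
  out[, needs_review := review[keep]]
  data.table::setorder(out, sample_id, chrom, insertion_point)
  out[]
}

.bind_samples <- function(candidates_by_sample) {
  if (data.table::is.data.table(candidates_by_sample) ||
      is.data.frame(candidates_by_sample)) {
    out <- data.table::as.data.table(candidates_by_sample)
    if (!"sample_id" %in% names(out)) {
      stop("candidate table must carry a sample_id column")
    }
    return(data.table::copy(out))
  }
  data.table::rbindlist(
    lapply(names(candidates_by_sample), function(s) {
      x <- data.table::as.data.table(candidates_by_sample[[s]])
      x[, sample_id := s]
      x
    }), use.names = TRUE)
}

#' Classify candidate sites as germline across tissues
#'
#' A site with a TSD-valid call evidenced in both tissues of at least one
#' individual is germline. Germline sites whose median coverage across
#' samples falls below `min_coverage` are discarded. Sites present in all
#' individuals of the manifest are `germline_shared`; in exactly one,
#' `germline_private`; in an intermediate number, `germline_multi`.
#' Individuals lacking a second tissue yield `ambiguous` sites.
#'
#' @param candidates candidate table with `sample_id` (all tissues)
#' @param manifest sample manifest: `sample_id`, `individual_id`,
#'   `tissue`, `genotype`, `role`
#' @param site_coverage optional function `(chrom, position) ->` numeric
#'   vector of per-sample coverages, or a table with `chrom`, `position`,
#'   `median_coverage`; NULL skips the coverage filter
#' @param slop,min_clip,min_identity linking rule (as [confirm_somatic()])
#' @param min_coverage minimum median coverage for a germline site
#' @return site-level table with `class` in `germline_shared`,
#'   `germline_private`, `germline_multi`, `ambiguous`,
#'   plus `n_individuals` and the representative site coordinates
#' @export
classify_germline <- function(candidates, manifest, site_coverage = NULL,
                              slop = 50L, min_coverage = 10,
                              min_clip = 10L, min_identity = 0.9) {
  cands <- .bind_samples(candidates)
  manifest <- data.table::as.data.table(manifest)
  if (nrow(cands) == 0L) {
    return(data.table::data.table(
      site_id = character(0), chrom = character(0),
      insertion_point = integer(0), te_family = character(0),
      n_individuals = integer(0), class = character(0)))
  }
  cands <- merge(cands, manifest[, .(sample_id, individual_id, tissue)],
                 by = "sample_id", all.x = TRUE)
  cands <- cands[!is.na(tsd_seq) & tsd_seq != ""]
  # group candidates into sites by single-linkage on the link key
  cands[, site := NA_integer_]
  data.table::setorder(cands, chrom, insertion_point, te_family,
                       sample_id)
  site_no <- 0L
  for (i in seq_len(nrow(cands))) {
    if (!is.na(cands$site[i])) next
    site_no <- site_no + 1L
    queue <- i
    data.table::set(cands, i = i, j = "site", value = site_no)
    while (length(queue) > 0L) {
      a <- cands[queue[1L]]
      queue <- queue[-1L]
      open <- which(is.na(cands$site))
      li <- open[vapply(open, function(j) {
        .keys_link(a, cands[j], slop, min_clip, min_identity)
      }, logical(1))]
      if (length(li) > 0L) {
        data.table::set(cands, i = li, j = "site", value = site_no)
        queue <- c(queue, li)
      }
    }
  }
  n_indiv_total <- length(unique(manifest$individual_id))
  two_tissue <- manifest[, .(n_tissue = length(unique(tissue))),
                         by = individual_id]
  sites <- cands[, {
    ind <- unique(individual_id)
    both <- vapply(ind, function(iv) {
      length(unique(tissue[individual_id == iv])) >= 2L
    }, logical(1))
    incomplete <- vapply(ind, function(iv) {
      two_tissue[individual_id == iv, n_tissue] < 2L
    }, logical(1))
    cls <- if (!any(both)) {
      if (any(incomplete)) "ambiguous" else "not_germline"
    } else if (length(ind) == n_indiv_total) "germline_shared"
    else if (length(ind) == 1L) "germline_private"
    else "germline_multi"
    list(chrom = chrom[1L],
         insertion_point = as.integer(stats::median(insertion_point)),
         te_family = te_family[1L],
         n_individuals = length(ind), class = cls)
  }, by = site]
  sites[, site_id := sprintf("site_%s_%d", chrom, insertion_point)]
  # coverage filter on germline sites
  if (!is.null(site_coverage)) {
    med <- if (is.function(site_coverage)) {
      vapply(seq_len(nrow(sites)), function(i) {
        stats::median(site_coverage(sites$chrom[i],
                                    sites$insertion_point[i]))
      }, numeric(1))
    } else {
      cov <- data.table::as.data.table(site_coverage)
      vapply(seq_len(nrow(sites)), function(i) {
        hit <- cov[chrom == sites$chrom[i] &
                     abs(position - sites$insertion_point[i]) <= slop]
        if (nrow(hit) == 0L) NA_real_ else hit$median_coverage[1L]
      }, numeric(1))
    }
    drop <- grepl("^germline", sites$class) & !is.na(med) &
      med < min_coverage
    sites <- sites[!drop]
  }
  data.table::setcolorder(sites, c("site_id", "chrom", "insertion_point",
                                   "te_family", "n_individuals", "class"))
  sites[, site := NULL]
  data.table::setorder(sites, chrom, insertion_point)
  sites[]
}

#' Family-private inherited calls (per-family panel mode)
#'
#' Re-runs [confirm_somatic()] with the panel set to the calls of every
#' family other than `family`: retained calls are private to the family
#' under analysis. Used to surface de novo inherited insertions of one
#' family against the background of all others.
#'
#' @param candidates candidate table with `sample_id`
#' @param family the TE family under analysis
#' @param slop,require_tsd,min_clip,min_identity as [confirm_somatic()]
#' @return somatic-call table restricted to `family`
#' @export
per_family_germline_mode <- function(candidates, family, slop = 50L,
                                     require_tsd = TRUE, min_clip = 10L,
                                     min_identity = 0.9) {
  cands <- .bind_samples(candidates)
  if (!family %in% cands$te_family) {
    stop("unknown family name: ", family)
  }
  focal <- cands[te_family == family]
  panel <- cands[te_family != family]
  # the family differs by construction, so panel linking must ignore it:
  # neutralize the family key on a panel copy
  panel2 <- data.table::copy(panel)
  panel2[, te_family := family]
  suppressWarnings(
    confirm_somatic(focal, panel2, slop = slop, require_tsd = require_tsd,
                    min_clip = min_clip, min_identity = min_identity))
}
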