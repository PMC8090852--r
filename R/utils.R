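# Shared low-level helpers: seeding, sequence manipulation, and the
# clip-sequence compatibility rule used by both the short-read caller and
# the cross-sample somatic filter.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over `{A,C,G,T,N}` (case kept upper)
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x))))
}

# Most frequent value; ties broken by the smallest value for determinism.
modal_value <- function(x) {
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  best <- names(tab)[tab == max(tab)]
  v <- sort(best)[1L]
  if (is.numeric(x)) as.numeric(v) else v
}

#' Clip-sequence compatibility
#'
#' Two soft-clipped sequences observed on the same side of a junction are
#' regarded as deriving from the same insertion when the shorter one is at
#' least `min_len` bases long and matches the other with at least
#' `min_identity` identity over its length, anchored at the junction end
#' (the end that abuts the aligned portion of the read). Left-side clips
#' (clip precedes the aligned block) are anchored at their 3' end; right
#' side clips at their 5' end.
#'
#' @param a,b clip sequences (character scalars)
#' @param side "left" or "right": which side of the aligned block the clip
#'   sits on
#' @param min_len minimum length of the shorter clip for a verdict
#' @param min_identity minimum anchored identity
#' @return TRUE when compatible, FALSE when the clips conflict, NA when the
#'   shorter clip is below `min_len` (no evidence either way)
#' @export
clips_compatible <- function(a, b, side = c("right", "left"),
                             min_len = 10L, min_identity = 0.9) {
  side <- match.arg(side)
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  if (n < min_len) return(NA)
  if (side == "right") {
    sa <- substr(a, 1L, n); sb <- substr(b, 1L, n)
  } else {
    sa <- substr(a, la - n + 1L, la); sb <- substr(b, lb - n + 1L, lb)
  }
  va <- strsplit(sa, "", fixed = TRUE)[[1]]
  vb <- strsplit(sb, "", fixed = TRUE)[[1]]
  mean(va == vb) >= min_identity
}

# Anchored identity between two same-length strings (helper for TSD checks).
string_identity <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("string_identity: unequal lengths")
  mean(va == vb)
}
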