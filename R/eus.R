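#' Filter colonies (reads) on masked-base content
#'
#' Retains reads that pass the extended-unidirectional filter: strictly
#' fewer than `max_head_n_frac` Ns among the most-5' `head_len` bases AND
#' strictly fewer than `max_total_n_frac` Ns overall. Reads are expected to
#' have been quality-masked first ([mask_low_quality()]). Reads shorter than
#' `head_len` are excluded and counted in the rejects report.
#'
#' @param reads Tibble of (masked) quality reads.
#' @param head_len Length of the 5' head window (default 20).
#' @param max_head_n_frac Maximum N fraction in the head, exclusive
#'   (default 0.05).
#' @param max_total_n_frac Maximum overall N fraction, exclusive
#'   (default 0.01).
#' @return The passing reads, with a `rejects` attribute: a named integer
#'   vector counting reads rejected as `too_short`, `head_n` or `total_n`.
#' @export
filter_colonies <- function(reads, head_len = 20, max_head_n_frac = 0.05,
                            max_total_n_frac = 0.01) {
  len <- nchar(reads$bases)
  too_short <- len < head_len
  head_n <- vapply(substr(reads$bases, 1, head_len),
                   function(s) sum(strsplit(s, "", fixed = TRUE)[[1]] == "N"),
                   integer(1), USE.NAMES = FALSE)
  total_n <- nchar(reads$bases) -
    nchar(gsub("N", "", reads$bases, fixed = TRUE))
  head_ok <- head_n / head_len < max_head_n_frac
  total_ok <- total_n / len < max_total_n_frac
  pass <- !too_short & head_ok & total_ok
  rejects <- c(
    too_short = sum(too_short),
    head_n = sum(!too_short & !head_ok),
    total_n = sum(!too_short & head_ok & !total_ok)
  )
  out <- reads[pass, , drop = FALSE]
  attr(out, "rejects") <- rejects
  out
}

# Hamming-style prefix match: read N counts as mismatch.
prefix_mismatches <- function(bases, primer) {
  plen <- nchar(primer)
  pref <- substr(bases, 1, plen)
  pm <- strsplit(primer, "", fixed = TRUE)[[1]]
  vapply(strsplit(pref, "", fixed = TRUE), function(ch) {
    if (length(ch) < plen) return(plen)
    sum(ch != pm)
  }, integer(1))
}

#' Assign read direction from primer prefixes
#'
#' A read is `forward` if its prefix matches the forward primer within
#' `max_mismatch` substitutions, `reverse` if it matches the reverse primer,
#' and `unknown` otherwise. An `N` on the read counts as a mismatch. A read
#' matching both primers indicates degenerate primer design and raises an
#' error.
#'
#' @param reads Tibble of quality reads.
#' @param forward_primer,reverse_primer Primer sequences as synthesized
#'   (5'->3').
#' @param max_mismatch Allowed substitutions in the primer prefix
#'   (default 0).
#' @return The reads tibble with the `direction` column filled in.
#' @export
assign_direction <- function(reads, forward_primer, reverse_primer,
                             max_mismatch = 0) {
  forward_primer <- normalize_bases(forward_primer)
  reverse_primer <- normalize_bases(reverse_primer)
  fwd_ok <- prefix_mismatches(reads$bases, forward_primer) <= max_mismatch
  rev_ok <- prefix_mismatches(reads$bases, reverse_primer) <= max_mismatch
  both <- fwd_ok & rev_ok
  if (any(both)) {
    abort(sprintf(
      "read '%s' matches both primers: primer design degenerate",
      reads$read_id[which(both)[1]]
    ))
  }
  reads$direction <- ifelse(fwd_ok, "forward",
                            ifelse(rev_ok, "reverse", "unknown"))
  reads
}

# Stack reads anchored at position 0 into a 5 x L count matrix.
stack_counts <- function(bases, L = max(nchar(bases))) {
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(BASE_ROWS, NULL))
  for (b in bases) {
    ch <- strsplit(b, "", fixed = TRUE)[[1]]
    idx <- match(ch, BASE_ROWS)
    for (k in 1:5) {
      at <- which(idx == k)
      counts[k, at] <- counts[k, at] + 1L
    }
  }
  counts
}

#' Build a directional consensus from anchored reads
#'
#' Stacks same-direction reads at the primer terminus (all reads share
#' position 1 = first base) and counts non-N bases per position. The
#' consensus is the modal base (alphabetical tie-break, flagged); the
#' profile is truncated at the last position whose non-N coverage reaches
#' `min_coverage`.
#'
#' @param reads Tibble of quality reads, all of one direction.
#' @param min_coverage Minimum non-N depth for a position to be reported
#'   (default 100, the full-scale run criterion; toy data needs lower
#'   values).
#' @return A consensus profile tibble.
#' @export
build_directional_consensus <- function(reads, min_coverage = 100) {
  if (nrow(reads) == 0) abort("no reads supplied to consensus builder")
  counts <- stack_counts(reads$bases)
  coverage <- colSums(counts[1:4, , drop = FALSE])
  keep <- which(coverage >= min_coverage)
  if (length(keep) == 0) {
    return(profile_from_counts(counts[, 0, drop = FALSE],
                               n_reads_used = nrow(reads)))
  }
  counts <- counts[, seq_len(max(keep)), drop = FALSE]
  profile_from_counts(counts, n_reads_used = nrow(reads))
}

# Reverse-complement a count matrix: reverse the position order and swap
# the A/T and C/G rows. N counts stay N.
revcomp_counts <- function(counts) {
  counts[c("T", "G", "C", "A", "N"), rev(seq_len(ncol(counts))),
         drop = FALSE] -> out
  rownames(out) <- BASE_ROWS
  out
}

#' Merge forward and reverse consensus profiles
#'
#' The reverse profile is reverse-complemented onto the forward coordinate
#' system, then the longest suffix-of-forward / prefix-of-reverse overlap
#' with per-base consensus identity of at least `min_overlap_identity` and
#' length at least `min_overlap` is selected. Inside the overlap the two
#' profiles' base counts are summed position-wise (re-analysis summing base
#' calls in both reads) and the consensus and agreement are recomputed from
#' the summed counts.
#'
#' @param fwd,rev Consensus profile tibbles for the forward and reverse
#'   read sets (`rev` in its own, un-complemented coordinates).
#' @param min_overlap Minimum acceptable overlap length in bases
#'   (default 10).
#' @param min_overlap_identity Minimum consensus identity across the
#'   overlap (default 0.9).
#' @return A list of class `merge_result` with elements `profile` (merged
#'   consensus profile), `overlap_length`, `forward_span` and
#'   `reverse_span` (1-based inclusive intervals on the merged
#'   coordinates).
#' @export
merge_consensus <- function(fwd, rev, min_overlap = 10,
                            min_overlap_identity = 0.9) {
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    abort("cannot merge: empty consensus profile")
  }
  fc <- profile_counts(fwd)
  rc <- revcomp_counts(profile_counts(rev))
  f_cons <- fwd$consensus
  r_cons <- profile_from_counts(rc)$consensus
  nf <- length(f_cons)
  nr <- length(r_cons)
  overlap <- NA_integer_
  for (L in seq.int(min(nf, nr), 1L)) {
    if (L < min_overlap) break
    fs <- f_cons[(nf - L + 1):nf]
    rs <- r_cons[1:L]
    informative <- fs != "N" & rs != "N"
    if (!any(informative)) next
    ident <- sum(fs[informative] == rs[informative]) / sum(informative)
    if (ident >= min_overlap_identity) {
      overlap <- L
      break
    }
  }
  if (is.na(overlap)) {
    abort(sprintf(
      "merge failure: no overlap of >= %d bases with identity >= %.2f",
      min_overlap, min_overlap_identity
    ), class = "barcodekit_merge_failure")
  }
  merged_len <- nf + nr - overlap
  counts <- matrix(0L, nrow = 5, ncol = merged_len,
                   dimnames = list(BASE_ROWS, NULL))
  counts[, 1:nf] <- fc
  counts[, (nf - overlap + 1):merged_len] <-
    counts[, (nf - overlap + 1):merged_len] + rc
  profile <- profile_from_counts(
    counts,
    n_reads_used = sum(n_reads_used(fwd), n_reads_used(rev), na.rm = TRUE)
  )
  structure(list(
    profile = profile,
    overlap_length = as.integer(overlap),
    forward_span = c(1L, nf),
    reverse_span = c(nf - overlap + 1L, merged_len)
  ), class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf(
    "<merge_result> merged length %d, overlap %d bases (fwd %d-%d, rev %d-%d)\n",
    nrow(x$profile), x$overlap_length,
    x$forward_span[1], x$forward_span[2],
    x$reverse_span[1], x$reverse_span[2]
  ))
  invisible(x)
}

#' Extended unidirectional consensus assembly
#'
#' End-to-end pipeline for one demultiplexed sample: quality masking,
#' colony filtering, direction assignment from the primer prefixes,
#' independent base-by-base consensus building in the forward and reverse
#' directions, and a reverse-complement merge that sums base calls inside
#' the overlap. Designed for extended unidirectional amplicon runs where
#' forward and reverse reads each cover most of the barcode and meet in a
#' central overlap.
#'
#' @param reads Tibble of quality reads (raw; masking is applied here).
#' @param forward_primer,reverse_primer Primer sequences (5'->3').
#' @param q_min Quality masking threshold (default 30).
#' @param min_coverage Minimum per-position depth for the directional
#'   consensus (default 100).
#' @param min_overlap,min_overlap_identity Merge acceptance parameters
#'   (defaults 10 bases, 0.9 identity).
#' @param max_mismatch Primer prefix mismatches tolerated in direction
#'   assignment (default 0).
#' @return A list of class `eus_assembly`: `profile` (merged consensus
#'   profile), `consensus` (string), `overlap_length`, `forward_span`,
#'   `reverse_span`, and `stage_counts` (named integer vector of reads
#'   surviving each stage).
#' @export
eus_assemble <- function(reads, forward_primer, reverse_primer,
                         q_min = 30, min_coverage = 100,
                         min_overlap = 10, min_overlap_identity = 0.9,
                         max_mismatch = 0) {
  n_in <- nrow(reads)
  masked <- mask_low_quality(reads, q_min = q_min)
  passed <- filter_colonies(masked)
  directed <- assign_direction(passed, forward_primer, reverse_primer,
                               max_mismatch = max_mismatch)
  fwd_reads <- dplyr::filter(directed, .data$direction == "forward")
  rev_reads <- dplyr::filter(directed, .data$direction == "reverse")
  stage_counts <- c(
    input = n_in,
    passed_filter = nrow(passed),
    forward = nrow(fwd_reads),
    reverse = nrow(rev_reads)
  )
  if (nrow(fwd_reads) == 0) {
    abort("insufficient coverage: no forward-direction reads",
          class = "barcodekit_coverage_failure")
  }
  if (nrow(rev_reads) == 0) {
    abort("insufficient coverage: no reverse-direction reads",
          class = "barcodekit_coverage_failure")
  }
  fwd <- build_directional_consensus(fwd_reads, min_coverage = min_coverage)
  rev <- build_directional_consensus(rev_reads, min_coverage = min_coverage)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    abort(sprintf(
      "insufficient coverage: no position reaches %d-fold depth",
      min_coverage
    ), class = "barcodekit_coverage_failure")
  }
  merged <- merge_consensus(fwd, rev, min_overlap = min_overlap,
                            min_overlap_identity = min_overlap_identity)
  structure(list(
    profile = merged$profile,
    consensus = consensus_string(merged$profile),
    overlap_length = merged$overlap_length,
    forward_span = merged$forward_span,
    reverse_span = merged$reverse_span,
    stage_counts = stage_counts
  ), class = "eus_assembly")
}

#' @export
print.eus_assembly <- function(x, ...) {
  cat(sprintf(
    "<eus_assembly> %d bp merged barcode, overlap %d bases\n",
    nchar(x$consensus), x$overlap_length
  ))
  cat("stage counts:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eus_assembly <- function(x, ...) {
  as_tibble(x$profile)
}

#' @export
glance.eus_assembly <- function(x, ...) {
  tibble(
    length = nchar(x$consensus),
    overlap_length = x$overlap_length,
    n_reads_input = unname(x$stage_counts["input"]),
    n_reads_passed = unname(x$stage_counts["passed_filter"]),
    min_agreement = min(x$profile$agreement, na.rm = TRUE),
    mean_agreement = mean(x$profile$agreement, na.rm = TRUE)
  )
}
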