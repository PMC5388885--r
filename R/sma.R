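#' Prepare reads for micro-assembly: mask, then double
#'
#' Applies quality masking (bases below `q_min` become `N`) and then doubles
#' the read set by appending the reverse complement of every masked read
#' (qualities reversed). Both orientations of a fragmented amplicon read are
#' thereby available to the assembler; a `source_id` column records which
#' original read each copy came from so usage statistics can count source
#' reads once.
#'
#' @param reads Tibble of quality reads.
#' @param q_min Quality masking threshold (default 30).
#' @return A tibble of 2x the input rows with columns of [quality_reads()]
#'   plus `source_id`; reverse-complement copies carry the read id suffix
#'   `"/rc"`.
#' @export
prepare_reads <- function(reads, q_min = 30) {
  masked <- mask_low_quality(reads, q_min = q_min)
  if (nrow(masked) == 0) {
    out <- masked
    out$source_id <- character(0)
    return(out)
  }
  rc <- masked
  rc$read_id <- paste0(masked$read_id, "/rc")
  rc$bases <- reverse_complement(masked$bases)
  rc$quals <- lapply(masked$quals, rev)
  out <- dplyr::bind_rows(
    dplyr::mutate(masked, source_id = .data$read_id),
    dplyr::mutate(rc, source_id = masked$read_id)
  )
  # interleave: each read immediately followed by its reverse complement
  n <- nrow(masked)
  out[rep(seq_len(n), each = 2) + rep(c(0L, n), times = n), , drop = FALSE]
}

# Grow a 5 x L count matrix to at least `ncol_needed` columns.
grow_counts <- function(counts, ncol_needed) {
  if (ncol(counts) >= ncol_needed) return(counts)
  extra <- max(ncol_needed - ncol(counts), ncol(counts))
  cbind(counts, matrix(0L, nrow = 5, ncol = extra,
                       dimnames = list(BASE_ROWS, NULL)))
}

# Add one read's bases (char vector) to the counts starting at 1-based
# column `start`; returns the updated matrix. Caller grows the matrix.
add_read_counts <- function(counts, ch, start) {
  cols <- start + seq_along(ch) - 1L
  idx <- match(ch, BASE_ROWS)
  for (k in 1:5) {
    at <- cols[idx == k]
    counts[k, at] <- counts[k, at] + 1L
  }
  counts
}

# Recompute the modal-base consensus (alphabetical tie-break) for the given
# 1-based columns of a count matrix; N only when coverage is zero.
consensus_at <- function(counts, cols) {
  sub <- counts[1:4, cols, drop = FALSE]
  idx <- max.col(t(sub), ties.method = "first")
  out <- BASE_ROWS[idx]
  out[colSums(sub) == 0] <- "N"
  out
}

#' Seed a micro-assembly at the forward primer
#'
#' Stacks every read whose prefix equals the forward primer exactly (an `N`
#' on the read counts as a mismatch) at position 1 and accumulates
#' per-position base counts; those reads are marked merged. The consensus
#' is the modal base per position with alphabetical tie-break.
#'
#' @param reads Doubled read tibble from [prepare_reads()] (a plain
#'   [quality_reads()] tibble is also accepted).
#' @param forward_primer Forward primer sequence (5'->3').
#' @param window Upstream match window used during extension (default 20);
#'   stored in the state.
#' @param max_length Hard cap on assembly length, guarding against runaway
#'   extension from chimeric input (default 5000).
#' @return An `assembly_state` object; see [extend_assembly()].
#' @export
seed_assembly <- function(reads, forward_primer, window = 20,
                          max_length = 5000) {
  forward_primer <- normalize_bases(forward_primer)
  if (!nzchar(forward_primer)) abort("forward primer must be non-empty")
  seeded <- prefix_mismatches(reads$bases, forward_primer) == 0
  if (!any(seeded)) {
    abort("seed failure: no read starts with the forward primer",
          class = "barcodekit_seed_failure")
  }
  split_bases <- strsplit(reads$bases, "", fixed = TRUE)
  lens <- lengths(split_bases)
  L0 <- max(lens[seeded])
  counts <- matrix(0L, nrow = 5, ncol = L0,
                   dimnames = list(BASE_ROWS, NULL))
  for (i in which(seeded)) {
    counts <- add_read_counts(counts, split_bases[[i]], 1L)
  }
  consensus <- consensus_at(counts, seq_len(L0))
  # prefix index over reads long enough to ever match a full window:
  # N-free prefixes go into a hashed exact-match table; prefixes containing
  # N (wildcard) are kept in a matrix for per-position scanning
  eligible <- which(lens >= window)
  prefix_str <- vapply(split_bases[eligible], function(ch) {
    paste(ch[1:window], collapse = "")
  }, character(1))
  has_n <- grepl("N", prefix_str, fixed = TRUE)
  exact_index <- new.env(parent = emptyenv())
  for (j in which(!has_n)) {
    key <- prefix_str[j]
    exact_index[[key]] <- c(exact_index[[key]], eligible[j])
  }
  wild <- eligible[has_n]
  prefixes <- if (length(wild) > 0) {
    do.call(rbind, lapply(split_bases[wild], function(ch) ch[1:window]))
  } else {
    matrix(character(), nrow = 0, ncol = window)
  }
  structure(list(
    counts = counts,
    length = L0,
    consensus = consensus,
    window = as.integer(window),
    max_length = as.integer(max_length),
    merged = seeded,
    read_ids = reads$read_id,
    source_id = if ("source_id" %in% names(reads)) reads$source_id
                else reads$read_id,
    split_bases = split_bases,
    read_lens = lens,
    eligible = eligible,
    exact_index = exact_index,
    wild = wild,
    prefixes = prefixes
  ), class = "assembly_state")
}

#' @export
print.assembly_state <- function(x, ...) {
  cat(sprintf(
    "<assembly_state> %d bp assembled, %d/%d reads merged (window %d)\n",
    x$length, sum(x$merged), length(x$merged), x$window
  ))
  invisible(x)
}

#' Extend a seeded micro-assembly to the full barcode
#'
#' Iterates a cursor along the growing assembly. At each position the
#' consensus of the `window` bases immediately upstream is computed from the
#' live counts, and every hitherto unmerged read whose first `window` bases
#' equal that consensus w-mer (an `N` on the read matches any base) is
#' recruited: its bases are added to the counts starting at the window
#' start, extending the assembly when the read runs past the current end.
#' Sweeps repeat until a complete pass recruits no read. Assemblies that
#' stop short of the full barcode are reported as-is, not raised.
#'
#' @param state Seeded `assembly_state` from [seed_assembly()].
#' @param window Upstream match window in bases (default: value stored at
#'   seeding).
#' @return The updated `assembly_state`.
#' @export
extend_assembly <- function(state, window = state$window) {
  w <- as.integer(window)
  repeat {
    recruited_this_pass <- 0L
    p <- w
    while (p <= state$length) {
      if (!any(!state$merged[state$eligible])) break
      wmer <- state$consensus[(p - w + 1L):p]
      key <- paste(wmer, collapse = "")
      exact_hits <- state$exact_index[[key]]
      exact_hits <- exact_hits[!state$merged[exact_hits]]
      wild_open <- !state$merged[state$wild]
      wild_hits <- integer(0)
      if (any(wild_open)) {
        pref <- state$prefixes[wild_open, , drop = FALSE]
        hit <- rowSums(pref == matrix(wmer, nrow(pref), w, byrow = TRUE) |
                         pref == "N") == w
        wild_hits <- state$wild[wild_open][hit]
      }
      recruits <- c(exact_hits, wild_hits)
      if (length(recruits) > 0) {
        start <- p - w + 1L
        for (i in recruits) {
          ch <- state$split_bases[[i]]
          end <- start + length(ch) - 1L
          if (end > state$max_length) {
            ch <- ch[seq_len(state$max_length - start + 1L)]
            end <- state$max_length
          }
          state$counts <- grow_counts(state$counts, end)
          state$counts <- add_read_counts(state$counts, ch, start)
          state$length <- max(state$length, end)
          state$merged[i] <- TRUE
        }
        touched <- start:state$length
        state$consensus[touched] <- consensus_at(state$counts, touched)
        recruited_this_pass <- recruited_this_pass + length(recruits)
      }
      p <- p + 1L
    }
    if (recruited_this_pass == 0L) break
  }
  state
}

# Materialize the profile tibble from an assembly state.
state_profile <- function(state) {
  profile_from_counts(
    state$counts[, seq_len(state$length), drop = FALSE],
    n_reads_used = sum(state$merged)
  )
}

#' Trim primers from an assembled profile
#'
#' Locates the forward primer at the profile start and the reverse
#' complement of the reverse primer at the profile end (each within
#' `max_mismatch` substitutions of the consensus) and excises both;
#' positions are renumbered from 1.
#'
#' @param profile A consensus profile tibble.
#' @param forward_primer,reverse_primer Primer sequences as synthesized
#'   (5'->3').
#' @param max_mismatch Substitutions tolerated in each primer copy
#'   (default 0).
#' @return The trimmed consensus profile. On failure a condition of class
#'   `barcodekit_trim_failure` is signalled whose `profile` field carries
#'   the untrimmed profile.
#' @export
trim_primers <- function(profile, forward_primer, reverse_primer,
                         max_mismatch = 0) {
  fp <- strsplit(normalize_bases(forward_primer), "", fixed = TRUE)[[1]]
  rp <- strsplit(reverse_complement(normalize_bases(reverse_primer)), "",
                 fixed = TRUE)[[1]]
  L <- nrow(profile)
  cons <- profile$consensus
  fail <- function(which_end) {
    rlang::abort(
      sprintf("trim failure: %s primer not found at the %s of the assembly",
              ifelse(which_end == "start", "forward", "reverse"), which_end),
      class = "barcodekit_trim_failure", profile = profile
    )
  }
  if (L < length(fp) + length(rp)) fail("start")
  if (sum(cons[seq_along(fp)] != fp) > max_mismatch) fail("start")
  tail_idx <- (L - length(rp) + 1L):L
  if (sum(cons[tail_idx] != rp) > max_mismatch) fail("end")
  keep <- (length(fp) + 1L):(L - length(rp))
  counts <- profile_counts(profile)[, keep, drop = FALSE]
  profile_from_counts(counts, n_reads_used = n_reads_used(profile))
}

#' Sonication micro-assembly of a long barcode from fragmented reads
#'
#' End-to-end pipeline for one demultiplexed sample: quality masking and
#' read doubling ([prepare_reads()]), primer seeding ([seed_assembly()]),
#' iterative upstream-window extension to convergence
#' ([extend_assembly()]), and primer trimming ([trim_primers()]). Designed
#' for sonicated amplicon fragments whose joint tiling spans a barcode much
#' longer than any single read.
#'
#' @param reads Tibble of quality reads (raw; masking applied here).
#' @param forward_primer,reverse_primer Primer sequences (5'->3').
#' @param q_min Quality masking threshold (default 30).
#' @param window Upstream match window in bases (default 20).
#' @param max_length Hard cap on assembly length (default 5000).
#' @param max_trim_mismatch Substitutions tolerated when locating each
#'   primer for trimming (default 0).
#' @return A list of class `sma_assembly`: `profile` (trimmed consensus
#'   profile), `consensus` (string), `untrimmed_length`, and `usage`
#'   (reads in, source reads recruited — a read and its added reverse
#'   complement count as one source read, recruited if either copy merged —
#'   and the fraction used).
#' @export
sma_assemble <- function(reads, forward_primer, reverse_primer,
                         q_min = 30, window = 20, max_length = 5000,
                         max_trim_mismatch = 0) {
  doubled <- prepare_reads(reads, q_min = q_min)
  state <- seed_assembly(doubled, forward_primer, window = window,
                         max_length = max_length)
  state <- extend_assembly(state)
  untrimmed <- state_profile(state)
  profile <- trim_primers(untrimmed, forward_primer, reverse_primer,
                          max_mismatch = max_trim_mismatch)
  used_sources <- unique(state$source_id[state$merged])
  n_sources <- length(unique(state$source_id))
  usage <- list(
    reads_in = nrow(reads),
    reads_doubled = nrow(doubled),
    source_reads_recruited = length(used_sources),
    fraction_used = if (n_sources > 0) length(used_sources) / n_sources
                    else NA_real_
  )
  structure(list(
    profile = profile,
    consensus = consensus_string(profile),
    untrimmed_length = nrow(untrimmed),
    usage = usage
  ), class = "sma_assembly")
}

#' @export
print.sma_assembly <- function(x, ...) {
  cat(sprintf(
    "<sma_assembly> %d bp trimmed barcode (%d untrimmed); %d/%d source reads used (%.1f%%)\n",
    nchar(x$consensus), x$untrimmed_length,
    x$usage$source_reads_recruited, x$usage$reads_in,
    100 * x$usage$fraction_used
  ))
  invisible(x)
}

#' @export
tidy.sma_assembly <- function(x, ...) {
  as_tibble(x$profile)
}

#' @export
glance.sma_assembly <- function(x, ...) {
  tibble(
    length = nchar(x$consensus),
    untrimmed_length = x$untrimmed_length,
    n_reads_input = x$usage$reads_in,
    source_reads_recruited = x$usage$source_reads_recruited,
    fraction_used = x$usage$fraction_used,
    min_agreement = min(x$profile$agreement, na.rm = TRUE),
    mean_agreement = mean(x$profile$agreement, na.rm = TRUE)
  )
}
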