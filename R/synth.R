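random_sequence <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

# Mutate each site with probability p to a uniformly chosen different base.
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(ch, collapse = "")
}

#' Simulate a comprehensive reference barcode database
#'
#' Generates a ground-truth CRB with controlled structure: a uniform random
#' root sequence per locus; each species mutates every site independently
#' with probability `d_inter` (interspecific divergence); with probability
#' `p_share` a species instead copies a previously generated species'
#' barcodes verbatim, planting deliberately non-diagnostic shared barcodes
#' whose ground truth is exact by construction; each species then emits
#' `variants_per_species` specimens whose sequences mutate the species
#' barcode at rate `d_intra` (intraspecific variation). Species are named
#' `"Genus<g> species<i>"` with genera of up to three species so
#' genus-level analyses are exercised.
#'
#' @param n_species Number of species (default 50).
#' @param variants_per_species Specimens per species (default 2).
#' @param locus_length Named integer vector of locus lengths (default
#'   `c(rbcL = 600, matK = 800)`).
#' @param d_inter Per-site interspecific substitution probability
#'   (default 0.02).
#' @param d_intra Per-site intraspecific substitution probability
#'   (default 0.002).
#' @param p_share Probability a species duplicates an earlier species'
#'   barcodes (default 0.05).
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list: `crb` (a `crb_database`), `records` (its base-locus
#'   records) and `truth` — a tibble listing, per locus, every set of
#'   species sharing an identical species-level barcode.
#' @export
simulate_crb <- function(n_species = 50, variants_per_species = 2,
                         locus_length = c(rbcL = 600, matK = 800),
                         d_inter = 0.02, d_intra = 0.002,
                         p_share = 0.05, seed = 1) {
  stopifnot(n_species >= 1, variants_per_species >= 1,
            all(locus_length > 0),
            d_inter >= 0, d_inter <= 1, d_intra >= 0, d_intra <= 1,
            p_share >= 0, p_share <= 1)
  loci <- names(locus_length)
  if (is.null(loci)) abort("locus_length must be a named vector")
  withr::with_seed(seed, {
    roots <- lapply(locus_length, random_sequence)
    # species-level barcodes; copy_of[i] > 0 marks a verbatim duplicate
    copy_of <- integer(n_species)
    species_seqs <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      if (i > 1 && stats::runif(1) < p_share) {
        donor <- sample.int(i - 1, 1)
        copy_of[i] <- donor
        species_seqs[[i]] <- species_seqs[[donor]]
      } else {
        species_seqs[[i]] <- lapply(roots, mutate_sequence, p = d_inter)
      }
    }
    species_names <- sprintf("Genus%03d species%03d",
                             ceiling(seq_len(n_species) / 3),
                             seq_len(n_species))
    rows <- list()
    for (i in seq_len(n_species)) {
      for (v in seq_len(variants_per_species)) {
        for (loc in loci) {
          base_seq <- species_seqs[[i]][[loc]]
          seq_v <- if (v == 1) base_seq else
            mutate_sequence(base_seq, d_intra)
          rows[[length(rows) + 1]] <- tibble(
            species = species_names[i],
            specimen_id = sprintf("sp%03d_v%d", i, v),
            locus = loc,
            sequence = seq_v
          )
        }
      }
    }
    records <- dplyr::bind_rows(rows)
    records <- barcode_records(records$species, records$specimen_id,
                               records$locus, records$sequence)
    # ground truth: species sharing an identical species-level barcode
    truth <- purrr::map_dfr(loci, function(loc) {
      seqs <- vapply(species_seqs, function(s) s[[loc]], character(1))
      groups <- split(species_names, seqs)
      shared <- groups[lengths(groups) > 1]
      if (length(shared) == 0) {
        return(tibble(locus = character(), species_set = list(),
                      n_species = integer()))
      }
      tibble(locus = loc,
             species_set = unname(shared),
             n_species = lengths(shared))
    })
    list(crb = build_crb(records), records = records, truth = truth)
  })
}

# Position-dependent substitution: error prob interpolates linearly from
# `rate5` at the first base to `rate3` at the last.
apply_read_errors <- function(ch, rate5, rate3) {
  L <- length(ch)
  p <- if (L == 1) rate5 else rate5 + (rate3 - rate5) * (0:(L - 1)) / (L - 1)
  hit <- which(stats::runif(L) < p)
  if (length(hit) > 0) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  ch
}

# Two-valued quality model: Q38 baseline, a random `p_lowq` fraction of
# bases dropped to Q2 (below any masking threshold in use).
draw_quals <- function(L, p_lowq, q_hi = 38L, q_lo = 2L) {
  q <- rep(q_hi, L)
  low <- stats::runif(L) < p_lowq
  q[low] <- q_lo
  q
}

#' Simulate extended unidirectional sequencing reads
#'
#' Emulates an extended unidirectional amplicon run: forward reads copy the
#' template 5' prefix and reverse reads the 5' prefix of the reverse
#' complement, so the two read sets meet in a central overlap when
#' `2 * read_length` exceeds the template length. Per-base substitution
#' probability interpolates linearly from `error_rate_5prime` at the primer
#' end to `error_rate_3prime` at the far end of the read; a `p_lowq`
#' fraction of bases is emitted below the Q30 masking threshold.
#'
#' @param template Amplicon sequence including both primers.
#' @param n_reads Total reads (default 600).
#' @param read_length Read length in bases (default 600); capped at the
#'   template length.
#' @param error_rate_5prime,error_rate_3prime Substitution probabilities at
#'   the two ends of a read (defaults 0.01 and 0.03, the error profile of
#'   extended unidirectional runs: lowest proximal to the primer, highest
#'   at the far end).
#' @param p_lowq Probability a base is emitted below Q30 (default 0.005;
#'   low by design — the downstream colony filter rejects any read with 1%
#'   or more masked bases, and an extended unidirectional run is useful
#'   only when a workable minority of colonies survives that filter).
#' @param orientation_mix Fraction of reads that are forward (default 0.5).
#' @param seed Integer seed.
#' @return A [quality_reads()] tibble with `direction` filled in
#'   (`round(n_reads * orientation_mix)` forward reads, the rest reverse).
#' @export
simulate_eus_reads <- function(template, n_reads = 600, read_length = 600,
                               error_rate_5prime = 0.01,
                               error_rate_3prime = 0.03,
                               p_lowq = 0.005, orientation_mix = 0.5,
                               seed = 1) {
  template <- normalize_bases(template)
  read_length <- min(read_length, nchar(template))
  n_fwd <- round(n_reads * orientation_mix)
  withr::with_seed(seed, {
    fwd_tpl <- strsplit(substr(template, 1, read_length), "",
                        fixed = TRUE)[[1]]
    rev_tpl <- strsplit(substr(reverse_complement(template), 1,
                               read_length), "", fixed = TRUE)[[1]]
    make <- function(i, tpl, tag) {
      ch <- apply_read_errors(tpl, error_rate_5prime, error_rate_3prime)
      list(id = sprintf("%s_%05d", tag, i),
           bases = paste(ch, collapse = ""),
           quals = draw_quals(length(ch), p_lowq))
    }
    fwd <- lapply(seq_len(n_fwd), make, tpl = fwd_tpl, tag = "fwd")
    rev <- lapply(seq_len(n_reads - n_fwd), make, tpl = rev_tpl,
                  tag = "rev")
    all <- c(fwd, rev)
    quality_reads(
      read_id = vapply(all, `[[`, character(1), "id"),
      bases = vapply(all, `[[`, character(1), "bases"),
      quals = lapply(all, `[[`, "quals"),
      direction = rep(c("forward", "reverse"),
                      c(n_fwd, n_reads - n_fwd))
    )
  })
}

#' Simulate sonicated amplicon fragment reads
#'
#' Emulates acoustic fragmentation of a long amplicon: fragment length is
#' Normal(`fragment_mean`, `fragment_sd`) clipped to `[min_fragment,
#' template length]`; with probability `p_end` the fragment is anchored at
#' an amplicon terminus (every sheared molecule contributes two terminal
#' fragments, so amplicon ends are over-represented relative to interior
#' breakpoints — the micro-assembler's primer seeding depends on them),
#' otherwise its start is uniform over the positions where the fragment
#' fits; each fragment is read from one end (up to `read_length` bases)
#' and its orientation flipped with probability 0.5. Substitutions occur at
#' a flat `error_rate`; a `p_lowq` fraction of bases is emitted below Q30.
#'
#' @param template Amplicon sequence including both primers.
#' @param n_reads Number of reads (default 2000).
#' @param fragment_mean,fragment_sd Fragment length distribution
#'   (defaults 280 and 60).
#' @param read_length Maximum read length (default 300).
#' @param min_fragment Minimum fragment length (default 21, one more than
#'   the default assembly window).
#' @param p_end Probability a fragment is anchored at an amplicon terminus,
#'   split evenly between the two ends (default 0.2).
#' @param error_rate Flat per-base substitution probability (default 0.01).
#' @param p_lowq Probability a base is emitted below Q30 (default 0.05).
#' @param seed Integer seed.
#' @return A [quality_reads()] tibble (direction `"unknown"`; the
#'   assembler doubles reads rather than relying on orientation tags).
#' @export
simulate_sma_reads <- function(template, n_reads = 2000,
                               fragment_mean = 280, fragment_sd = 60,
                               read_length = 300, min_fragment = 21,
                               p_end = 0.2,
                               error_rate = 0.01, p_lowq = 0.05,
                               seed = 1) {
  template <- normalize_bases(template)
  tlen <- nchar(template)
  if (fragment_mean > tlen) abort("fragment_mean exceeds template length")
  withr::with_seed(seed, {
    tpl <- strsplit(template, "", fixed = TRUE)[[1]]
    reads <- lapply(seq_len(n_reads), function(i) {
      len <- round(stats::rnorm(1, fragment_mean, fragment_sd))
      len <- max(min_fragment, min(len, tlen))
      u <- stats::runif(1)
      if (u < p_end / 2) {
        start <- 1L
      } else if (u < p_end) {
        start <- tlen - len + 1L
      } else {
        start <- sample.int(tlen - len + 1L, 1)
      }
      end <- start + len - 1L
      frag <- tpl[start:end]
      if (stats::runif(1) < 0.5) frag <- revcomp_chars(frag)
      frag <- frag[seq_len(min(length(frag), read_length))]
      frag <- apply_read_errors(frag, error_rate, error_rate)
      list(id = sprintf("frag_%05d", i),
           bases = paste(frag, collapse = ""),
           quals = draw_quals(length(frag), p_lowq))
    })
    quality_reads(
      read_id = vapply(reads, `[[`, character(1), "id"),
      bases = vapply(reads, `[[`, character(1), "bases"),
      quals = lapply(reads, `[[`, "quals")
    )
  })
}

#' Error-free fragments tiling a template
#'
#' Deterministic tiling fragments (every `step` bases, fixed length) over a
#' template — the simplest input on which the micro-assembler must
#' reconstruct the template exactly. Qualities are uniformly high.
#'
#' @param template Sequence to tile.
#' @param fragment_length Fragment length (default 100).
#' @param step Tiling step (default 5).
#' @return A [quality_reads()] tibble.
#' @export
tile_template <- function(template, fragment_length = 100, step = 5) {
  template <- normalize_bases(template)
  tlen <- nchar(template)
  starts <- unique(c(seq(1, max(1, tlen - fragment_length + 1), by = step),
                     tlen - fragment_length + 1))
  starts <- starts[starts >= 1]
  bases <- substring(template, starts,
                     pmin(starts + fragment_length - 1, tlen))
  quality_reads(
    read_id = sprintf("tile_%05d", seq_along(starts)),
    bases = bases,
    quals = lapply(nchar(bases), function(L) rep(38L, L))
  )
}
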