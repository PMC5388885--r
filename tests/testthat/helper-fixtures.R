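# Shared fixtures and independent oracles, all built in code.

# Reads with uniformly high quality from plain base strings.
reads_from_strings <- function(bases, q = 38L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(bases))
  quality_reads(ids, bases, lapply(nchar(bases), function(L) rep(q, L)))
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# A template with known primers at both termini: the forward primer is the
# first `plen` bases, the reverse primer is the reverse complement of the
# last `plen` bases (as synthesized, 5'->3').
make_amplicon <- function(length, plen = 20, seed = 1) {
  template <- random_dna(length, seed = seed)
  list(
    template = template,
    forward_primer = substr(template, 1, plen),
    reverse_primer = reverse_complement(
      substr(template, length - plen + 1, length)
    ),
    core = substr(template, plen + 1, length - plen)
  )
}

# Three-species toy CRB from the exact-match worked example:
# species A and B share barcode X, species C carries Y.
toy_shared_crb <- function() {
  build_crb(barcode_records(
    species = c("Alpha one", "Beta two", "Gamma three"),
    specimen_id = c("a1", "b1", "c1"),
    locus = "rbcL",
    sequence = c("ACGTACGTAC", "ACGTACGTAC", "TTTTCCCCGG")
  ))
}

# An irb_sample restricted to the given specimen ids (bypasses random
# sampling for hand-enumerable scenarios).
irb_of <- function(crb, specimen_ids) {
  structure(list(
    records = crb$records[crb$records$specimen_id %in% specimen_ids, ,
                          drop = FALSE],
    specimen_ids = specimen_ids,
    n_species = length(unique(
      crb$records$species[crb$records$specimen_id %in% specimen_ids]
    )),
    replicate_id = NA_integer_, seed = NULL
  ), class = "irb_sample")
}

# An ess_query_set from explicit specimen draws.
ess_of <- function(crb, specimen_ids) {
  frame <- crb$records[match(specimen_ids, crb$records$specimen_id), ,
                       drop = FALSE]
  structure(list(
    specimen_ids = specimen_ids,
    true_species = frame$species,
    n_species = length(unique(frame$species)),
    seed = NULL
  ), class = "ess_query_set")
}

# Independent brute-force classification oracle: nested loops over records,
# no grouping machinery shared with the implementation.
oracle_classify <- function(irb_records, crb_records, locus) {
  irb <- irb_records[irb_records$locus == locus, , drop = FALSE]
  crb <- crb_records[crb_records$locus == locus, , drop = FALSE]
  seqs <- unique(irb$sequence)
  perceived <- ambiguous <- false <- 0L
  for (s in seqs) {
    irb_sp <- unique(irb$species[irb$sequence == s])
    crb_sp <- unique(crb$species[crb$sequence == s])
    if (length(irb_sp) == 1L) {
      perceived <- perceived + 1L
      if (length(crb_sp) > 1L) false <- false + 1L
    } else {
      ambiguous <- ambiguous + 1L
    }
  }
  c(pct_perceived = 100 * perceived / length(seqs),
    pct_ambiguous = 100 * ambiguous / length(seqs),
    pct_false = 100 * false / length(seqs))
}

# Brute-force longest qualifying suffix/prefix overlap between two
# consensus strings (enumerates every length, longest first).
oracle_overlap <- function(fwd, rev_rc, min_overlap, min_identity) {
  nf <- nchar(fwd)
  nr <- nchar(rev_rc)
  for (L in rev(seq_len(min(nf, nr)))) {
    if (L < min_overlap) break
    a <- strsplit(substr(fwd, nf - L + 1, nf), "")[[1]]
    b <- strsplit(substr(rev_rc, 1, L), "")[[1]]
    ok <- a != "N" & b != "N"
    if (any(ok) && sum(a[ok] == b[ok]) / sum(ok) >= min_identity) {
      return(L)
    }
  }
  NA_integer_
}

# Brute-force percent identity for equal-length sequences, N columns
# excluded from numerator and denominator.
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  ok <- x != "N" & y != "N"
  100 * sum(x[ok] == y[ok]) / sum(ok)
}
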