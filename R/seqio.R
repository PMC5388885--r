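#' @importFrom rlang .data abort
#' @importFrom tibble tibble as_tibble
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Normalize nucleotide sequences to the {A,C,G,T,N} alphabet
#'
#' Uppercases the input and replaces every character outside `A`, `C`, `G`,
#' `T` with `N`. Both assemblers and the reference-database model are defined
#' only over this alphabet, so lowercase input and IUPAC ambiguity codes are
#' collapsed to `N` on entry.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_bases(c("acgu", "ACGT", "AR-T"))
normalize_bases <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Construct a tibble of quality reads
#'
#' The tabular unit of both assemblers: one row per sequencer read, holding
#' the read identifier, the base string, a list-column of per-base integer
#' Phred scores, and a direction tag (`"forward"`, `"reverse"` or
#' `"unknown"`).
#'
#' @param read_id Character vector of read identifiers.
#' @param bases Character vector of base strings (normalized to
#'   `{A,C,G,T,N}`).
#' @param quals List of integer vectors, one per read, same length as its
#'   base string.
#' @param direction Character vector of direction tags; recycled if length 1.
#' @return A tibble with columns `read_id`, `bases`, `quals`, `direction`.
#' @export
quality_reads <- function(read_id, bases, quals,
                          direction = "unknown") {
  bases <- normalize_bases(bases)
  quals <- lapply(quals, as.integer)
  bad <- which(nchar(bases) != lengths(quals))
  if (length(bad) > 0) {
    abort(sprintf(
      "bases/quals length mismatch for read '%s' (%d bases, %d qualities)",
      read_id[bad[1]], nchar(bases[bad[1]]), lengths(quals)[bad[1]]
    ))
  }
  if (!all(direction %in% c("forward", "reverse", "unknown"))) {
    abort("direction must be one of 'forward', 'reverse', 'unknown'")
  }
  tibble(
    read_id = as.character(read_id),
    bases = bases,
    quals = quals,
    direction = rep_len(direction, length(bases))
  )
}

#' Read a FASTQ file into a tibble of quality reads
#'
#' Parses 4-line FASTQ records with Phred+33 quality encoding (the Sanger /
#' modern Illumina convention). Bases are uppercased and any character
#' outside `{A,C,G,T,N}` is replaced by `N`.
#'
#' @param path Path to a FASTQ file.
#' @param offset Quality encoding offset (default 33, Phred+33).
#' @return A tibble as produced by [quality_reads()].
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    return(quality_reads(character(), character(), list()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf(
      "malformed FASTQ: %d lines is not a multiple of 4", length(lines)
    ))
  }
  ids_raw <- lines[seq(1, length(lines), by = 4)]
  bases <- lines[seq(2, length(lines), by = 4)]
  quals_raw <- lines[seq(4, length(lines), by = 4)]
  if (any(substr(ids_raw, 1, 1) != "@")) {
    first <- which(substr(ids_raw, 1, 1) != "@")[1]
    abort(sprintf("malformed FASTQ header at record %d: %s", first,
                  ids_raw[first]))
  }
  ids <- sub("^@", "", ids_raw)
  ids <- sub("\\s.*$", "", ids)
  bad <- which(nchar(bases) != nchar(quals_raw))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FASTQ record '%s': %d bases but %d quality characters",
      ids[bad[1]], nchar(bases[bad[1]]), nchar(quals_raw[bad[1]])
    ))
  }
  quals <- lapply(quals_raw, function(q) utf8ToInt(q) - as.integer(offset))
  quality_reads(ids, bases, quals)
}

#' Write quality reads to a FASTQ file
#'
#' @param reads Tibble of quality reads ([quality_reads()]).
#' @param path Output path.
#' @param offset Quality encoding offset (default 33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, offset = 33L) {
  qual_str <- vapply(
    reads$quals,
    function(q) intToUtf8(as.integer(q) + as.integer(offset)),
    character(1)
  )
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases,
                           "+", qual_str))
  writeLines(lines, path)
  invisible(path)
}

#' Mask low-quality bases with N
#'
#' Replaces every base whose Phred quality is strictly below `q_min` with
#' `N`. Qualities are left unchanged and read length is preserved. The
#' default threshold of 30 (one error per 1,000 bases) is applied before
#' both assembly pipelines; bases at exactly Q30 are kept.
#'
#' @param reads Tibble of quality reads.
#' @param q_min Minimum quality to keep a base call (default 30).
#' @return The reads tibble with masked base strings.
#' @export
mask_low_quality <- function(reads, q_min = 30) {
  masked <- mapply(function(b, q) {
    low <- q < q_min
    if (!any(low)) return(b)
    ch <- strsplit(b, "", fixed = TRUE)[[1]]
    ch[low] <- "N"
    paste(ch, collapse = "")
  }, reads$bases, reads$quals, USE.NAMES = FALSE)
  reads$bases <- masked
  reads
}

#' Reverse complement of DNA sequences
#'
#' Standard reverse complement over `{A,C,G,T,N}`; `N` maps to `N`.
#' Delegates to [Biostrings::reverseComplement()].
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AACN")
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character())
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))
  )
  unname(out)
}

# fast path used in inner loops: reverse complement on a character vector
# of single bases (already split)
revcomp_chars <- function(ch) {
  rev(chartr("ACGT", "TGCA", ch))
}

#' Construct a tibble of labelled barcode records
#'
#' The unit of the reference-database model: a species label, specimen
#' identifier, locus name and barcode sequence. The genus is derived as the
#' first whitespace-delimited token of the species label.
#'
#' @param species Character vector of species labels (non-empty).
#' @param specimen_id Character vector of specimen identifiers.
#' @param locus Character vector of locus names (e.g. `"rbcL"`).
#' @param sequence Character vector of barcode sequences (normalized).
#' @return A tibble with columns `species`, `specimen_id`, `locus`,
#'   `sequence`, `genus`.
#' @export
barcode_records <- function(species, specimen_id, locus, sequence) {
  species <- as.character(species)
  sequence <- normalize_bases(sequence)
  if (any(!nzchar(species))) abort("species labels must be non-empty")
  if (any(!nzchar(sequence))) abort("barcode sequences must be non-empty")
  tibble(
    species = species,
    specimen_id = as.character(specimen_id),
    locus = as.character(locus),
    sequence = sequence,
    genus = vapply(strsplit(species, "\\s+"), `[[`, character(1), 1)
  )
}

#' Read labelled barcode records from FASTA
#'
#' Headers use the dialect `>species|specimen_id|locus`; the species label
#' may contain spaces. Sequences are normalized to `{A,C,G,T,N}`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of barcode records ([barcode_records()]).
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    return(barcode_records(character(), character(), character(),
                           character())[0, ])
  }
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(sprintf(
      "FASTA header not in 'species|specimen_id|locus' form: '%s'",
      headers[bad[1]]
    ))
  }
  barcode_records(
    species = vapply(parts, `[[`, character(1), 1),
    specimen_id = vapply(parts, `[[`, character(1), 2),
    locus = vapply(parts, `[[`, character(1), 3),
    sequence = as.character(seqs)
  )
}

#' Write labelled barcode records to FASTA
#'
#' @param records Tibble of barcode records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- paste(records$species, records$specimen_id, records$locus,
                       sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
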