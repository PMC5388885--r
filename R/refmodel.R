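#' Build a comprehensive reference barcode (CRB) database
#'
#' Assembles labelled barcode records into the ground-truth database of the
#' completeness model: the complete set of barcodes and species names that
#' exist in a hypothetical region. Species may carry several records
#' (intraspecific variants). When a specimen carries every locus present in
#' the database, a combined locus (loci concatenated, named e.g.
#' `"rbcL+matK"`) is materialized for it.
#'
#' @param records Tibble of barcode records ([barcode_records()]).
#' @return An object of class `crb_database`: a list with `records` (the
#'   input plus combined-locus rows), `loci`, `species` and a per-locus
#'   `barcode_index` mapping each distinct sequence to the species carrying
#'   it.
#' @export
build_crb <- function(records) {
  if (nrow(records) == 0) abort("CRB requires at least one record")
  dup <- duplicated(records[, c("specimen_id", "locus")])
  if (any(dup)) {
    abort(sprintf(
      "duplicate (specimen, locus) pair: %s / %s",
      records$specimen_id[dup][1], records$locus[dup][1]
    ))
  }
  base_loci <- unique(records$locus)
  # canonical plant-barcode order first, anything else in appearance order
  ord <- c(intersect(c("rbcL", "matK"), base_loci),
           setdiff(base_loci, c("rbcL", "matK")))
  if (length(ord) >= 2) {
    combined_name <- paste(ord, collapse = "+")
    wide <- tidyr::pivot_wider(
      records[, c("species", "specimen_id", "locus", "sequence")],
      names_from = "locus", values_from = "sequence"
    )
    complete <- stats::complete.cases(wide[, ord])
    if (any(complete)) {
      w <- wide[complete, , drop = FALSE]
      combined <- barcode_records(
        species = w$species,
        specimen_id = w$specimen_id,
        locus = combined_name,
        sequence = do.call(paste0, w[, ord])
      )
      records <- dplyr::bind_rows(records, combined)
    }
  }
  barcode_index <- lapply(split(records, records$locus), function(df) {
    dplyr::summarise(dplyr::group_by(df, .data$sequence),
      n_species = dplyr::n_distinct(.data$species),
      species = list(unique(.data$species)),
      .groups = "drop"
    )
  })
  structure(list(
    records = records,
    loci = unique(records$locus),
    species = unique(records$species),
    barcode_index = barcode_index
  ), class = "crb_database")
}

#' @export
print.crb_database <- function(x, ...) {
  cat(sprintf(
    "<crb_database> %d records, %d species, loci: %s\n",
    nrow(x$records), length(x$species), paste(x$loci, collapse = ", ")
  ))
  invisible(x)
}

# Distinct specimens with their species label (sampling frame for IRB/ESS).
crb_specimens <- function(crb) {
  dplyr::distinct(crb$records[, c("specimen_id", "species")])
}

# Draw specimen indices uniformly with replacement until the distinct
# species count reaches n_species; returns the minimal prefix of draws.
draw_until_n_species <- function(species_of_specimen, n_species) {
  n_spec <- length(species_of_specimen)
  draws <- integer(0)
  repeat {
    draws <- c(draws, sample.int(n_spec, size = max(4L * n_species, 32L),
                                 replace = TRUE))
    sp <- species_of_specimen[draws]
    n_distinct_cum <- cumsum(!duplicated(sp))
    hit <- which(n_distinct_cum == n_species)
    if (length(hit) > 0) return(draws[seq_len(hit[1])])
    if (length(draws) > 1e7) abort("IRB sampling failed to converge")
  }
}

#' Sample an incomplete reference barcode (IRB) set
#'
#' Draws individuals (specimens) uniformly with replacement from the CRB
#' until the set contains `n_species` distinct species; duplicate draws of
#' the same specimen collapse to one stored record. This mimics the
#' unpredictable pattern by which species are assimilated into a growing
#' reference database.
#'
#' @param crb A `crb_database`.
#' @param n_species Target number of distinct species (the model's
#'   `N_s`).
#' @param seed Optional integer seed; a fixed seed makes the sample
#'   reproducible.
#' @param replicate_id Optional replicate label carried in the result.
#' @return An object of class `irb_sample`: list with `records` (subset of
#'   CRB records), `specimen_ids`, `n_species`, `replicate_id`, `seed`.
#' @export
sample_irb <- function(crb, n_species, seed = NULL, replicate_id = NA_integer_) {
  frame <- crb_specimens(crb)
  n_avail <- dplyr::n_distinct(frame$species)
  if (n_species < 1 || n_species > n_avail) {
    abort(sprintf("n_species must be in [1, %d], got %s", n_avail,
                  n_species))
  }
  draw <- function() draw_until_n_species(frame$species, n_species)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  specimen_ids <- unique(frame$specimen_id[idx])
  structure(list(
    records = crb$records[crb$records$specimen_id %in% specimen_ids, ,
                          drop = FALSE],
    specimen_ids = specimen_ids,
    n_species = as.integer(n_species),
    replicate_id = replicate_id,
    seed = seed
  ), class = "irb_sample")
}

#' @export
print.irb_sample <- function(x, ...) {
  cat(sprintf("<irb_sample> N_s = %d (%d specimens, %d records)\n",
              x$n_species, length(x$specimen_ids), nrow(x$records)))
  invisible(x)
}

#' Classify IRB barcodes as perceived, ambiguous or false species-unique
#'
#' Over the distinct barcode sequences of one locus in an IRB: a barcode is
#' *perceived species-unique* when it carries exactly one species name in
#' the IRB, *ambiguous* when shared by more than one IRB species, and
#' *false species-unique* when perceived in the IRB but carried by several
#' species in the CRB — the misclassification that inflates a growing
#' database's apparent diagnostic power.
#'
#' @param irb An `irb_sample`.
#' @param crb The `crb_database` the IRB was drawn from.
#' @param locus Locus name present in both.
#' @param per_record Count records instead of distinct sequences when
#'   computing percentages (default `FALSE`: duplicates carry no extra
#'   diagnostic information).
#' @return One-row tibble: `locus`, `n_barcodes`, `pct_perceived`,
#'   `pct_ambiguous`, `pct_false`.
#' @export
classify_barcodes <- function(irb, crb, locus, per_record = FALSE) {
  recs <- irb$records[irb$records$locus == locus, , drop = FALSE]
  if (nrow(recs) == 0) abort(sprintf("IRB has no records for locus %s", locus))
  cidx <- crb$barcode_index[[locus]]
  if (is.null(cidx)) abort(sprintf("locus %s absent from CRB", locus))
  grouped <- dplyr::summarise(dplyr::group_by(recs, .data$sequence),
    n_irb_species = dplyr::n_distinct(.data$species),
    n_records = dplyr::n(),
    .groups = "drop"
  )
  grouped$n_crb_species <-
    cidx$n_species[match(grouped$sequence, cidx$sequence)]
  weight <- if (per_record) grouped$n_records else rep(1L, nrow(grouped))
  total <- sum(weight)
  perceived <- grouped$n_irb_species == 1
  false_u <- perceived & grouped$n_crb_species > 1
  tibble(
    locus = locus,
    n_barcodes = nrow(grouped),
    pct_perceived = 100 * sum(weight[perceived]) / total,
    pct_ambiguous = 100 * sum(weight[!perceived]) / total,
    pct_false = 100 * sum(weight[false_u]) / total
  )
}

#' Sample an ecological study set (ESS)
#'
#' Draws simulated field specimens from the CRB with replacement until
#' `n_species` distinct species are represented. Unlike [sample_irb()],
#' duplicate draws are retained as separate query samples — they are
#' independent field collections — and each keeps its true species label.
#'
#' @inheritParams sample_irb
#' @return An object of class `ess_query_set`: list with `specimen_ids`
#'   (in draw order, with repeats), `true_species`, `n_species`, `seed`.
#' @export
sample_ess <- function(crb, n_species, seed = NULL) {
  frame <- crb_specimens(crb)
  n_avail <- dplyr::n_distinct(frame$species)
  if (n_species < 1 || n_species > n_avail) {
    abort(sprintf("n_species must be in [1, %d], got %s", n_avail,
                  n_species))
  }
  draw <- function() draw_until_n_species(frame$species, n_species)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(list(
    specimen_ids = frame$specimen_id[idx],
    true_species = frame$species[idx],
    n_species = as.integer(n_species),
    seed = seed
  ), class = "ess_query_set")
}

#' @export
print.ess_query_set <- function(x, ...) {
  cat(sprintf("<ess_query_set> %d samples spanning %d species\n",
              length(x$specimen_ids), x$n_species))
  invisible(x)
}

# Percent identity between one query and a set of references.
# Equal lengths: matching positions / columns, excluding any column where
# either side is N. Unequal lengths: global alignment identity
# (matches / alignment columns) via Biostrings.
identity_to_refs <- function(query, refs) {
  out <- numeric(length(refs))
  qlen <- nchar(query)
  same <- nchar(refs) == qlen
  if (any(same)) {
    qc <- strsplit(query, "", fixed = TRUE)[[1]]
    rm_ <- do.call(rbind, strsplit(refs[same], "", fixed = TRUE))
    valid <- t(rm_) != "N" & qc != "N"
    hits <- t(rm_) == qc & valid
    denom <- colSums(valid)
    out[same] <- ifelse(denom > 0, 100 * colSums(hits) / denom, 0)
  }
  if (any(!same)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(refs[!same]),
      Biostrings::DNAString(query),
      type = "global"
    )
    out[!same] <- Biostrings::pid(aln, type = "PID1")
  }
  out
}

# For every query, the set of species owning >= 1 reference barcode that
# matches it (exact equality, or identity >= threshold). `ref` is a tibble
# with columns sequence and species (list-column). Returns integer counts
# of candidate species per query.
candidate_species_counts <- function(queries, ref, threshold = NULL) {
  vapply(queries, function(q) {
    if (is.null(threshold)) {
      hit <- ref$sequence == q
    } else {
      hit <- identity_to_refs(q, ref$sequence) >= threshold
    }
    if (!any(hit)) return(0L)
    length(unique(unlist(ref$species[hit])))
  }, integer(1), USE.NAMES = FALSE)
}

# Shared worker: summarize identification outcomes given candidate counts
# against the IRB and against the CRB (truth).
identification_summary <- function(n_irb, n_crb, threshold_label) {
  n <- length(n_irb)
  perceived <- n_irb == 1
  ambiguous <- n_irb > 1
  unknown <- n_irb == 0
  true_id <- perceived & n_crb == 1
  false_id <- perceived & n_crb > 1
  tibble(
    threshold = threshold_label,
    n_queries = n,
    pct_perceived = 100 * sum(perceived) / n,
    pct_ambiguous = 100 * sum(ambiguous) / n,
    pct_unknown = 100 * sum(unknown) / n,
    pct_true = 100 * sum(true_id) / n,
    pct_false = 100 * sum(false_id) / n
  )
}

# Distinct (sequence -> species list) reference table for a locus.
locus_ref_table <- function(records, locus) {
  recs <- records[records$locus == locus, , drop = FALSE]
  dplyr::summarise(dplyr::group_by(recs, .data$sequence),
    species = list(unique(.data$species)), .groups = "drop"
  )
}

# Query sequences for an ESS at one locus (drops samples lacking the locus,
# e.g. specimens excluded from a combined locus).
ess_queries <- function(ess, crb, locus) {
  recs <- crb$records[crb$records$locus == locus, , drop = FALSE]
  seqs <- recs$sequence[match(ess$specimen_ids, recs$specimen_id)]
  seqs[!is.na(seqs)]
}

#' Identify ESS specimens against an IRB
#'
#' Attempts to identify each simulated field specimen by matching its
#' barcode against the reference barcodes of an incomplete database. A
#' query matching barcodes of exactly one IRB species is a *perceived*
#' identification; matching more than one species is *ambiguous*; matching
#' none is *unknown*. Truth is assessed by re-running the same matching
#' against the full CRB: a perceived identification whose CRB candidate set
#' contains more than one species is *false* (a false positive), otherwise
#' *true*.
#'
#' @param ess An `ess_query_set`.
#' @param irb An `irb_sample`.
#' @param crb The `crb_database` both were drawn from.
#' @param locus Locus to match on.
#' @param mode `"exact"` (sequence equality) or `"threshold"` (percent
#'   identity at least `threshold`).
#' @param threshold Percent identity cut-off in `[90, 100]` when
#'   `mode = "threshold"`.
#' @return One-row tibble: `threshold` (`"exact"` or the percentage),
#'   `n_queries`, `pct_perceived`, `pct_ambiguous`, `pct_unknown`,
#'   `pct_true`, `pct_false`.
#' @export
identify_specimens <- function(ess, irb, crb, locus,
                               mode = c("exact", "threshold"),
                               threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    if (is.null(threshold) || threshold < 90 || threshold > 100) {
      abort("threshold mode requires a percent identity in [90, 100]")
    }
  } else {
    threshold <- NULL
  }
  queries <- ess_queries(ess, crb, locus)
  irb_ref <- locus_ref_table(irb$records, locus)
  crb_ref <- locus_ref_table(crb$records, locus)
  n_irb <- candidate_species_counts(queries, irb_ref, threshold)
  n_crb <- candidate_species_counts(queries, crb_ref, threshold)
  identification_summary(
    n_irb, n_crb,
    if (is.null(threshold)) "exact" else as.character(threshold)
  )
}

#' Scan similarity thresholds for the optimal cut-off
#'
#' Runs threshold identification across a grid of percent-identity
#' cut-offs and reports the optimal threshold `O_t`: the grid value
#' maximizing the objective, with ties broken toward the highest (most
#' stringent) threshold.
#'
#' @inheritParams identify_specimens
#' @param grid Numeric vector of percent-identity thresholds (default
#'   97 to 99.9 by 0.1).
#' @param objective `"true"` (maximize the true-identification rate,
#'   default) or `"true_minus_false"`.
#' @return Object of class `threshold_scan`: list with `summaries` (one
#'   row per threshold) and `o_t`.
#' @export
scan_thresholds <- function(ess, irb, crb, locus,
                            grid = seq(97, 99.9, by = 0.1),
                            objective = c("true", "true_minus_false")) {
  objective <- match.arg(objective)
  if (length(grid) == 0) abort("threshold grid must be non-empty")
  queries <- ess_queries(ess, crb, locus)
  irb_ref <- locus_ref_table(irb$records, locus)
  crb_ref <- locus_ref_table(crb$records, locus)
  # identity matrices computed once; each threshold is then a cheap cut
  id_irb <- vapply(queries, identity_to_refs, numeric(nrow(irb_ref)),
                   refs = irb_ref$sequence)
  id_crb <- vapply(queries, identity_to_refs, numeric(nrow(crb_ref)),
                   refs = crb_ref$sequence)
  id_irb <- matrix(id_irb, nrow = nrow(irb_ref))
  id_crb <- matrix(id_crb, nrow = nrow(crb_ref))
  count_at <- function(idm, ref, t) {
    vapply(seq_len(ncol(idm)), function(j) {
      hit <- idm[, j] >= t
      if (!any(hit)) return(0L)
      length(unique(unlist(ref$species[hit])))
    }, integer(1))
  }
  summaries <- purrr::map_dfr(grid, function(t) {
    identification_summary(
      count_at(id_irb, irb_ref, t),
      count_at(id_crb, crb_ref, t),
      as.character(t)
    )
  })
  summaries$threshold <- grid
  score <- if (objective == "true") summaries$pct_true
           else summaries$pct_true - summaries$pct_false
  best <- max(score)
  o_t <- max(grid[score == best])
  structure(list(summaries = summaries, o_t = o_t, objective = objective),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %d thresholds, O_t = %.1f%% (objective: %s)\n",
              nrow(x$summaries), x$o_t, x$objective))
  invisible(x)
}

#' @export
tidy.threshold_scan <- function(x, ...) {
  x$summaries
}

#' @export
glance.threshold_scan <- function(x, ...) {
  best <- x$summaries[x$summaries$threshold == x$o_t, , drop = FALSE]
  tibble(o_t = x$o_t, objective = x$objective,
         pct_true_at_o_t = best$pct_true,
         pct_false_at_o_t = best$pct_false)
}

#' Plot a threshold scan
#'
#' @param object A `threshold_scan`.
#' @param ... Unused.
#' @return A ggplot of outcome percentages against threshold, with `O_t`
#'   marked.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summaries,
    dplyr::all_of(c("pct_true", "pct_false", "pct_ambiguous",
                    "pct_unknown")),
    names_to = "outcome", values_to = "pct"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$pct,
                                     colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$o_t, linetype = "dashed") +
    ggplot2::labs(x = "similarity threshold (%)", y = "queries (%)",
                  title = sprintf("Threshold scan (O_t = %.1f%%)",
                                  object$o_t))
}

#' IRB-size experiment: classification across database completeness
#'
#' For each IRB size in `n_grid`, samples `replicates` independent IRBs and
#' classifies their barcodes, reporting the mean and standard deviation of
#' each category percentage. This traces how perceived, ambiguous and false
#' species-unique fractions change as a reference database grows toward
#' completeness. Replicate `r` at every size uses seed `seed + r`, so
#' replicates are independent and sizes share common random numbers.
#'
#' @param crb A `crb_database`.
#' @param locus Locus to classify.
#' @param n_grid Integer vector of IRB sizes (distinct species counts).
#' @param replicates IRB replicates per size (default 200).
#' @param seed Base integer seed.
#' @param genus_level Re-label records by genus before classification
#'   (default `FALSE`).
#' @param per_record Passed to [classify_barcodes()].
#' @return A tibble with one row per IRB size: means and standard
#'   deviations of the category percentages.
#' @export
run_irb_size_experiment <- function(crb, locus, n_grid, replicates = 200,
                                    seed = 1, genus_level = FALSE,
                                    per_record = FALSE) {
  if (genus_level) {
    base_loci <- setdiff(crb$loci, grep("+", crb$loci, value = TRUE,
                                        fixed = TRUE))
    recs <- crb$records[crb$records$locus %in% base_loci, , drop = FALSE]
    recs$species <- recs$genus
    crb <- build_crb(barcode_records(recs$species, recs$specimen_id,
                                     recs$locus, recs$sequence))
  }
  purrr::map_dfr(n_grid, function(n) {
    per_rep <- purrr::map_dfr(seq_len(replicates), function(r) {
      irb <- sample_irb(crb, n, seed = seed + r, replicate_id = r)
      classify_barcodes(irb, crb, locus, per_record = per_record)
    })
    tibble(
      n_species = n,
      locus = locus,
      replicates = replicates,
      mean_n_barcodes = mean(per_rep$n_barcodes),
      mean_pct_perceived = mean(per_rep$pct_perceived),
      sd_pct_perceived = stats::sd(per_rep$pct_perceived),
      mean_pct_ambiguous = mean(per_rep$pct_ambiguous),
      sd_pct_ambiguous = stats::sd(per_rep$pct_ambiguous),
      mean_pct_false = mean(per_rep$pct_false),
      sd_pct_false = stats::sd(per_rep$pct_false)
    )
  })
}

#' Plot IRB-size classification trajectories
#'
#' @param experiment Tibble from [run_irb_size_experiment()].
#' @return A ggplot of mean category percentages against IRB size.
#' @export
plot_irb_trajectories <- function(experiment) {
  long <- tidyr::pivot_longer(
    experiment,
    dplyr::all_of(c("mean_pct_perceived", "mean_pct_ambiguous",
                    "mean_pct_false")),
    names_to = "category", values_to = "pct"
  )
  long$category <- sub("mean_pct_", "", long$category)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_species, y = .data$pct,
                                     colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(N[s] ~ "(species in IRB)"),
                  y = "barcodes (%)",
                  title = "Barcode classification across IRB sizes")
}
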