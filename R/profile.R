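#' @importFrom stats setNames
NULL

BASE_ROWS <- c("A", "C", "G", "T", "N")

# Build a consensus profile tibble from a 5 x L count matrix.
#
# Internal constructor. Rows of `counts` are A, C, G, T, N; columns are
# positions. Coverage at a position is the non-N depth; the consensus is the
# modal non-N base, ties broken alphabetically (A < C < G < T) and flagged;
# agreement is 100 * modal count / coverage. Positions with zero coverage
# get consensus "N" and agreement NA.
profile_from_counts <- function(counts, n_reads_used = NA_integer_) {
  stopifnot(is.matrix(counts), nrow(counts) == 5)
  L <- ncol(counts)
  if (L == 0) {
    prof <- tibble(
      position = integer(), A = integer(), C = integer(), G = integer(),
      T = integer(), N = integer(), coverage = integer(),
      consensus = character(), agreement = double(), tie = logical()
    )
  } else {
    acgt <- counts[1:4, , drop = FALSE]
    coverage <- colSums(acgt)
    top <- apply(acgt, 2, max)
    # max.col on the transpose gives the first (alphabetically smallest)
    # modal base; a tie exists when >1 base attains the maximum count
    idx <- max.col(t(acgt), ties.method = "first")
    tie <- colSums(acgt == rep(top, each = 4)) > 1 & top > 0
    consensus <- BASE_ROWS[idx]
    consensus[coverage == 0] <- "N"
    tie[coverage == 0] <- FALSE
    agreement <- ifelse(coverage > 0, 100 * top / coverage, NA_real_)
    prof <- tibble(
      position = seq_len(L),
      A = as.integer(counts[1, ]), C = as.integer(counts[2, ]),
      G = as.integer(counts[3, ]), T = as.integer(counts[4, ]),
      N = as.integer(counts[5, ]),
      coverage = as.integer(coverage),
      consensus = consensus,
      agreement = agreement,
      tie = tie
    )
  }
  structure(prof,
    class = c("consensus_profile", class(prof)),
    n_reads_used = as.integer(n_reads_used)
  )
}

# Recover the 5 x L count matrix from a profile tibble.
profile_counts <- function(profile) {
  m <- t(as.matrix(profile[, BASE_ROWS]))
  rownames(m) <- BASE_ROWS
  m
}

#' Consensus sequence of a profile
#'
#' @param profile A consensus profile tibble.
#' @return Single string: the per-position consensus calls concatenated.
#' @export
consensus_string <- function(profile) {
  paste(profile$consensus, collapse = "")
}

#' Number of reads used to build a profile
#'
#' @param profile A consensus profile tibble.
#' @return Integer count of recruited reads.
#' @export
n_reads_used <- function(profile) {
  attr(profile, "n_reads_used")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf(
    "<consensus_profile> %d positions, %s reads used, min agreement %s\n",
    nrow(x),
    ifelse(is.na(n_reads_used(x)), "?", n_reads_used(x)),
    ifelse(nrow(x) == 0, "-",
           formatC(suppressWarnings(min(x$agreement, na.rm = TRUE)),
                   digits = 4))
  ))
  NextMethod()
}

#' Write a per-base profile TSV
#'
#' Tab-separated table with 1-based positions, per-base counts, coverage,
#' consensus call, percent agreement and tie flag — the tabular twin of a
#' per-base assembly quality plot.
#'
#' @param profile A consensus profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-base coverage and consensus agreement
#'
#' @param object A consensus profile tibble.
#' @param ... Unused.
#' @return A ggplot object with coverage and agreement panels.
#' @export
autoplot.consensus_profile <- function(object, ...) {
  df <- tibble(
    position = rep(object$position, 2),
    value = c(object$coverage, object$agreement),
    metric = rep(c("coverage (reads)", "agreement (%)"),
                 each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Per-base assembly profile")
}
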