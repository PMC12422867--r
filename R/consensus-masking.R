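#' Masked consensus from a pileup under quality thresholds
#'
#' Builds a consensus sequence in which positions without trustworthy
#' evidence are replaced by the IUPAC unknown base `N`. A read base
#' contributes to the consensus only if its base quality and mapping quality
#' both reach the thresholds (strictly-below values fail, so a quality equal
#' to the threshold passes). A position is masked when it has zero depth
#' (`no_depth`), when no read passes the thresholds (`low_bq` if any read
#' failed the base-quality threshold, else `low_mq`), or when the passing
#' reads leave a majority tie (`ambiguous` -- ambiguity must not fabricate a
#' base). Otherwise the consensus is the majority base among passing reads.
#'
#' @param pileup A [simulate_pileup()] `pileup` (or one read from TSV via
#'   [read_pileup_tsv()]).
#' @param bq_min Minimum base quality (default 20).
#' @param mq_min Minimum mapping quality (default 20).
#' @return A `masked_sequence`: list with `seq` (string over `A,C,G,T,N`),
#'   `mask_reason` (factor per position: `pass`, `low_bq`, `low_mq`,
#'   `no_depth`, `ambiguous`), and `region`. A position is `N` iff its
#'   reason is not `pass`.
#' @examples
#' p <- simulate_species_pair(100, divergence = 0, seed = 1)
#' ind <- simulate_cross(p, "P1", seed = 1)
#' pu <- simulate_pileup(ind, mean_depth = 10, error_rate = 0, seed = 2)
#' ms <- masked_consensus(pu)
#' coverage_fraction(ms)
#' @export
masked_consensus <- function(pileup, bq_min = 20, mq_min = 20) {
  stopifnot(inherits(pileup, "pileup"))
  if (bq_min < 0 || mq_min < 0) stop("quality thresholds must be >= 0")
  positions <- pileup$positions
  n <- length(positions)
  if (length(pileup$depth) != n)
    stop("pileup depth vector does not match its region length")
  reads <- pileup$reads

  cons <- rep("N", n)
  reason <- rep("no_depth", n)
  has_depth <- pileup$depth > 0
  reason[has_depth] <- "low_mq"  # provisional; refined below

  ok <- reads$bq >= bq_min & reads$mq >= mq_min
  # positions where some read failed the BQ threshold
  bq_fail_pos <- unique(reads$pos[reads$bq < bq_min])
  reason[has_depth & positions %in% bq_fail_pos] <- "low_bq"

  pr <- reads[ok, , drop = FALSE]
  if (nrow(pr)) {
    counts <- table(factor(pr$pos, levels = positions),
                    factor(pr$base, levels = .BASES))
    counts <- matrix(counts, nrow = n, ncol = 4L,
                     dimnames = list(NULL, .BASES))
    top <- apply(counts, 1L, max)
    n_top <- rowSums(counts == top & counts > 0)
    covered <- top > 0
    tie <- covered & n_top > 1
    maj <- covered & n_top == 1
    cons[maj] <- .BASES[max.col(counts[maj, , drop = FALSE])]
    reason[maj] <- "pass"
    reason[tie] <- "ambiguous"
  }
  structure(
    list(seq = c2s(cons),
         mask_reason = factor(reason, levels = c("pass", "low_bq", "low_mq",
                                                 "no_depth", "ambiguous")),
         region = pileup$region, sample_id = pileup$sample_id),
    class = "masked_sequence"
  )
}

#' Fraction of a masked sequence passing quality masking
#'
#' @param seq A `masked_sequence`.
#' @return `(number of unmasked positions) / length`, in `[0, 1]`.
#' @export
coverage_fraction <- function(seq) {
  stopifnot(inherits(seq, "masked_sequence"))
  if (!length(seq$mask_reason)) stop("empty masked sequence")
  mean(seq$mask_reason == "pass")
}

#' @export
print.masked_sequence <- function(x, ...) {
  cat("Masked consensus over [", x$region[1], ", ", x$region[2], "]: ",
      sprintf("%.2f%%", 100 * coverage_fraction(x)), " covered\n", sep = "")
  print(table(x$mask_reason))
  invisible(x)
}

#' Masked intervals of a masked sequence
#'
#' @param seq A `masked_sequence`.
#' @return Data frame of 1-based closed intervals (`start`, `end`, `reason`)
#'   covering every masked position; suitable for [write_bed()].
#' @export
masked_intervals <- function(seq) {
  stopifnot(inherits(seq, "masked_sequence"))
  pos <- seq$region[1]:seq$region[2]
  masked <- seq$mask_reason != "pass"
  if (!any(masked))
    return(data.frame(start = integer(0), end = integer(0),
                      reason = character(0)))
  r <- rle(paste0(masked, "|", seq$mask_reason))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- startsWith(r$values, "TRUE")
  data.frame(start = pos[starts[keep]], end = pos[ends[keep]],
             reason = sub("^TRUE\\|", "", r$values[keep]),
             stringsAsFactors = FALSE)
}
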