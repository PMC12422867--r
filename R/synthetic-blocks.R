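#' Simulate phased haplotype blocks for a diploid individual
#'
#' Emulates read-backed phasing output at modest coverage: the genome breaks
#' into many short phase blocks, each covering a run of the individual's
#' heterozygous sites. Block extents are drawn from a gamma distribution
#' (defaults mirror short phase blocks of a few hundred bp); the variant
#' positions of a block are the individual's het sites within its span, and
#' each block carries the two haplotype consensus sequences over the span.
#' Phasing does not preserve haplotype orientation across blocks, so each
#' block's haplotype order is randomized; within a block, switch errors
#' exchange the haplotypes from a variant onward with probability
#' `switch_error_rate` per variant interval.
#'
#' @param ind A `diploid_individual`.
#' @param mean_length,sd_length Mean and SD of the gamma block-length
#'   distribution (bp); both must be positive.
#' @param min_block_gap Sites skipped between consecutive blocks.
#' @param switch_error_rate Per-variant-interval probability of a phase
#'   switch, in `[0, 0.5]`.
#' @param min_variants_per_block Minimum het sites for a span to become a
#'   block (spans with fewer are discarded, as single-variant "blocks" carry
#'   no phase information).
#' @param scaffold Scaffold name recorded on each block.
#' @param seed Optional integer seed.
#' @return List of `phase_block` objects: `scaffold`, `start`, `end`
#'   (1-based closed; the span of the block's variants), `variant_positions`,
#'   `hap1_seq`, `hap2_seq`, and `truth` (per-variant source lineage of each
#'   block haplotype, from the simulator's ancestry tracts).
#' @examples
#' p <- simulate_species_pair(20000, divergence = 0.037, seed = 1)
#' f1 <- simulate_cross(p, "F1", seed = 2)
#' blocks <- simulate_phase_blocks(f1, seed = 3)
#' length(blocks)
#' @export
simulate_phase_blocks <- function(ind, mean_length = 339, sd_length = 118,
                                  min_block_gap = 10, switch_error_rate = 0,
                                  min_variants_per_block = 2,
                                  scaffold = "scaffold_1", seed = NULL) {
  stopifnot(inherits(ind, "diploid_individual"))
  if (mean_length <= 0 || sd_length <= 0)
    stop("block length distribution must have positive mean and SD")
  if (switch_error_rate < 0 || switch_error_rate > 0.5)
    stop("switch_error_rate must lie in [0, 0.5]")

  hets <- het_sites(ind)
  if (!length(hets)) return(list())
  h1 <- s2c(ind$hap1)
  h2 <- s2c(ind$hap2)
  shape <- (mean_length / sd_length)^2
  rate <- mean_length / sd_length^2

  d_het <- length(hets) / ind$L

  with_seed(seed, {
    blocks <- list()
    i <- 1L
    n_het <- length(hets)
    while (i <= n_het - min_variants_per_block + 1L) {
      len <- rgamma(1L, shape = shape, rate = rate)
      k <- max(min_variants_per_block, as.integer(round(len * d_het)))
      k <- min(k, n_het - i + 1L)
      vp <- hets[i:(i + k - 1L)]
      if (length(vp) >= min_variants_per_block) {
        span <- vp[1]:vp[length(vp)]
        b1 <- h1[span]
        b2 <- h2[span]
        t1 <- truth_source_at(ind$truth_tracts$hap1, span)
        t2 <- truth_source_at(ind$truth_tracts$hap2, span)
        # phase switch errors: exchange haplotypes from a variant onward
        if (switch_error_rate > 0 && length(vp) > 1) {
          for (j in 2:length(vp)) {
            if (runif(1) < switch_error_rate) {
              at <- (vp[j] - vp[1] + 1L):length(span)
              tmp <- b1[at]; b1[at] <- b2[at]; b2[at] <- tmp
              tmp <- t1[at]; t1[at] <- t2[at]; t2[at] <- tmp
            }
          }
        }
        # phasing orientation is arbitrary per block
        if (runif(1) < 0.5) {
          tmp <- b1; b1 <- b2; b2 <- tmp
          tmp <- t1; t1 <- t2; t2 <- tmp
        }
        rel <- vp - vp[1] + 1L
        blocks[[length(blocks) + 1L]] <- structure(
          list(scaffold = scaffold, start = vp[1], end = vp[length(vp)],
               variant_positions = vp,
               hap1_seq = c2s(b1), hap2_seq = c2s(b2),
               truth = list(hap1_source = t1[rel], hap2_source = t2[rel])),
          class = "phase_block")
        i <- i + length(vp)
      } else {
        i <- i + 1L
      }
      # skip het sites falling inside the inter-block gap
      if (i > 1L && i <= n_het) {
        gap_end <- hets[i - 1L] + as.integer(min_block_gap)
        while (i <= n_het && hets[i] <= gap_end) i <- i + 1L
      }
    }
    blocks
  })
}

#' Construct a phase block
#'
#' @param scaffold Scaffold name.
#' @param variant_positions Sorted 1-based positions of phased variants
#'   (at least one).
#' @param hap1_seq,hap2_seq Haplotype consensus strings over the block span
#'   (equal length, spanning `min(variant_positions)` to
#'   `max(variant_positions)`).
#' @param start,end Span of the block; defaults to the variant extent.
#' @return A `phase_block`.
#' @export
phase_block <- function(scaffold, variant_positions, hap1_seq, hap2_seq,
                        start = min(variant_positions),
                        end = max(variant_positions)) {
  variant_positions <- sort(as.integer(variant_positions))
  if (!length(variant_positions)) stop("a phase block needs >= 1 variant")
  if (nchar(hap1_seq) != nchar(hap2_seq))
    stop("haplotype sequences must have equal length")
  if (any(variant_positions < start | variant_positions > end))
    stop("variant positions must lie within the block span")
  structure(list(scaffold = scaffold, start = as.integer(start),
                 end = as.integer(end),
                 variant_positions = variant_positions,
                 hap1_seq = hap1_seq, hap2_seq = hap2_seq, truth = NULL),
            class = "phase_block")
}

#' Length of a phase block
#'
#' Blocks are delimited by their phased variants: length is
#' `last variant - first variant + 1` in bp.
#'
#' @param block A `phase_block`.
#' @return Integer length in bp.
#' @export
block_length <- function(block) {
  vp <- block$variant_positions
  as.integer(vp[length(vp)] - vp[1] + 1L)
}

#' @export
print.phase_block <- function(x, ...) {
  cat("Phase block ", x$scaffold, ":", x$start, "-", x$end, " (",
      length(x$variant_positions), " variants, ", block_length(x),
      " bp)\n", sep = "")
  invisible(x)
}
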