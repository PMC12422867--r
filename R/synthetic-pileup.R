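#' Simulate a per-position pileup for a diploid individual
#'
#' Draws a Poisson read depth at every position of a region, samples each
#' read's base from one of the two haplotypes at random, applies substitution
#' errors, and attaches base and mapping qualities drawn from truncated
#' normal distributions (rounded, clipped to 0--60). Downstream masking
#' only consumes qualities through a threshold, so any spread straddling
#' the threshold exercises the rule.
#'
#' @param ind A `diploid_individual` (or [as_mito_diploid()] wrapper).
#' @param region Integer `c(start, end)` (1-based closed); default whole
#'   sequence.
#' @param mean_depth Mean read depth (> 0).
#' @param error_rate Per-base substitution error probability in `[0, 1)`.
#' @param bq_mean,bq_sd Base-quality distribution parameters.
#' @param mq_mean,mq_sd Mapping-quality distribution parameters.
#' @param seed Optional integer seed.
#' @return A `pileup`: list with `region`, `positions`, `depth` (integer per
#'   position) and `reads`, a data frame of (`pos`, `base`, `bq`, `mq`) with
#'   one row per read base; `nrow(reads[reads$pos == p, ])` equals
#'   `depth[p]`.
#' @examples
#' p <- simulate_species_pair(200, divergence = 0.1, seed = 1)
#' f1 <- simulate_cross(p, "F1", seed = 2)
#' pu <- simulate_pileup(f1, mean_depth = 8, seed = 3)
#' mean(pu$depth)
#' @export
simulate_pileup <- function(ind, region = NULL, mean_depth = 8,
                            error_rate = 0.002,
                            bq_mean = 32, bq_sd = 8,
                            mq_mean = 42, mq_sd = 12, seed = NULL) {
  stopifnot(inherits(ind, "diploid_individual"))
  region <- as.integer(region %||% c(1L, nchar(ind$hap1)))
  if (length(region) != 2 || region[2] < region[1])
    stop("region must be a non-empty c(start, end)")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")

  with_seed(seed, {
    positions <- region[1]:region[2]
    n <- length(positions)
    depth <- rpois(n, mean_depth)
    total <- sum(depth)
    pos <- rep.int(positions, depth)
    h1 <- s2c(ind$hap1)[pos]
    h2 <- s2c(ind$hap2)[pos]
    from2 <- runif(total) < 0.5
    base <- ifelse(from2, h2, h1)
    err <- runif(total) < error_rate
    if (any(err)) base[err] <- other_bases(base[err])
    rq <- function(m, s) pmin(60L, pmax(0L, as.integer(round(rnorm(total, m, s)))))
    structure(
      list(region = region, positions = positions, depth = depth,
           reads = data.frame(pos = pos, base = base,
                              bq = rq(bq_mean, bq_sd), mq = rq(mq_mean, mq_sd),
                              stringsAsFactors = FALSE),
           sample_id = ind$sample_id),
      class = "pileup"
    )
  })
}

#' @export
print.pileup <- function(x, ...) {
  cat("Pileup over [", x$region[1], ", ", x$region[2], "] (",
      length(x$positions), " positions, mean depth ",
      round(mean(x$depth), 2), ")\n", sep = "")
  invisible(x)
}

#' Wrap an individual's mitochondrial sequence as a haploid pseudo-diploid
#'
#' The mitochondrion is maternally inherited and effectively haploid; for
#' pileup simulation and consensus calling it is represented as a diploid
#' whose two haplotypes are identical copies of the maternal mitochondrial
#' sequence.
#'
#' @param ind A `diploid_individual` carrying `mito_seq`.
#' @return A `diploid_individual` over the mitochondrial replicon.
#' @export
as_mito_diploid <- function(ind) {
  stopifnot(inherits(ind, "diploid_individual"))
  if (!length(ind$mito_seq)) stop("individual carries no mitochondrial sequence")
  L <- nchar(ind$mito_seq)
  structure(
    list(sample_id = paste0(ind$sample_id, "_mito"),
         pedigree_class = ind$pedigree_class,
         hap1 = ind$mito_seq, hap2 = ind$mito_seq,
         truth_tracts = list(
           hap1 = data.frame(start = 1L, end = L, source = ind$mito_source),
           hap2 = data.frame(start = 1L, end = L, source = ind$mito_source)),
         mito_source = ind$mito_source, mito_seq = ind$mito_seq,
         L = L, labels = ind$labels),
    class = "diploid_individual"
  )
}
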