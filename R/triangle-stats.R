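#' Discover ancestry-informative markers from parental genotypes
#'
#' Computes per-site allele frequencies in each parental group and keeps
#' biallelic sites whose allele frequency difference reaches `delta`
#' (closed threshold, so `delta = 1` admits exactly the sites fixed for
#' alternate alleles). With single diploid parents, frequencies take values
#' in {0, 0.5, 1} and `delta = 1` selects opposite homozygotes. Sites
#' observed with more than two alleles, or missing in every sample of
#' either group, are skipped and counted.
#'
#' @param genotypes_p1,genotypes_p2 Genotypes of the two parental groups:
#'   a character vector of `"X/Y"` strings for one sample, or a matrix with
#'   one row per sample and one column per site. Alleles outside `A,C,G,T`
#'   are treated as missing.
#' @param positions Site positions (default `1:L`).
#' @param delta Allele frequency difference threshold in `(0, 1]`
#'   (default 1.0).
#' @return An `aim_set`: data frame (`pos`, `allele_p1`, `allele_p2`,
#'   `delta`) with attributes `delta_threshold` and `n_skipped`.
#'   `allele_p1`/`allele_p2` are the alleles enriched in each group; they
#'   orient the hybrid index.
#' @examples
#' aims <- discover_aims(c("A/A", "A/T"), c("T/T", "T/T"))
#' aims$pos  # only the first site is fixed for alternate alleles
#' @export
discover_aims <- function(genotypes_p1, genotypes_p2, positions = NULL,
                          delta = 1.0) {
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  g1 <- .as_gt_matrix(genotypes_p1)
  g2 <- .as_gt_matrix(genotypes_p2)
  if (ncol(g1) != ncol(g2))
    stop("parental genotype sets cover different numbers of sites")
  if (!nrow(g1) || !nrow(g2)) stop("parental genotype sets must be non-empty")
  L <- ncol(g1)
  positions <- positions %||% seq_len(L)

  f1 <- .allele_freqs(g1)  # 4 x L matrices of per-base frequencies
  f2 <- .allele_freqs(g2)
  n_alleles <- colSums((f1 > 0) | (f2 > 0))
  callable <- !is.na(f1[1, ]) & !is.na(f2[1, ])
  biallelic <- callable & n_alleles <= 2
  d <- apply(abs(f1 - f2), 2L, max)
  keep <- which(biallelic & d >= delta - 1e-12)

  a1 <- .BASES[apply(f1 - f2, 2L, which.max)]
  a2 <- .BASES[apply(f2 - f1, 2L, which.max)]
  out <- data.frame(pos = positions[keep], allele_p1 = a1[keep],
                    allele_p2 = a2[keep], delta = d[keep],
                    stringsAsFactors = FALSE)
  structure(out, class = c("aim_set", "data.frame"),
            delta_threshold = delta,
            n_skipped = sum(!biallelic))
}

.as_gt_matrix <- function(g) {
  if (is.matrix(g)) g else matrix(g, nrow = 1L)
}

# per-base allele frequencies over non-missing alleles; NA column when a
# site is missing in every sample
.allele_freqs <- function(g) {
  a1 <- substr(g, 1L, 1L)
  a2 <- substr(g, 3L, 3L)
  al <- rbind(matrix(a1, nrow = nrow(g)), matrix(a2, nrow = nrow(g)))
  freq <- vapply(seq_len(ncol(al)), function(j) {
    x <- al[, j]
    x <- x[x %in% .BASES]
    if (!length(x)) return(rep(NA_real_, 4L))
    tabulate(match(x, .BASES), 4L) / length(x)
  }, numeric(4))
  rownames(freq) <- .BASES
  freq
}

# per-AIM allele classification of one sample's genotypes:
# returns data frame with usable flag, count of p2 alleles, het flag
.classify_aims <- function(sample_genotypes, aims) {
  g <- sample_genotypes[aims$pos]
  a1 <- substr(g, 1L, 1L)
  a2 <- substr(g, 3L, 3L)
  in1 <- a1 == aims$allele_p1 | a1 == aims$allele_p2
  in2 <- a2 == aims$allele_p1 | a2 == aims$allele_p2
  usable <- in1 & in2 & !is.na(g)
  data.frame(usable = usable,
             n_p2 = (a1 == aims$allele_p2) + (a2 == aims$allele_p2),
             het = (a1 == aims$allele_p1 & a2 == aims$allele_p2) |
                   (a1 == aims$allele_p2 & a2 == aims$allele_p1))
}

#' Hybrid index of a sample at a set of AIMs
#'
#' The hybrid index is the proportion of the sample's alleles across
#' genotyped AIMs that derive from the parent-2 class: 0 for a pure
#' parent 1, 1 for a pure parent 2, 0.5 for equal ancestry (an F1). AIMs
#' with missing or out-of-class alleles are excluded.
#'
#' @param sample_genotypes Character vector of `"X/Y"` genotypes indexed by
#'   position (covering `aims$pos`).
#' @param aims An [discover_aims()] `aim_set`.
#' @return Hybrid index in `[0, 1]`.
#' @export
hybrid_index <- function(sample_genotypes, aims) {
  cl <- .classify_aims(sample_genotypes, aims)
  n <- sum(cl$usable)
  if (n == 0) stop("sample is genotyped at zero AIMs")
  sum(cl$n_p2[cl$usable]) / (2 * n)
}

#' Interclass heterozygosity of a sample at a set of AIMs
#'
#' The proportion of genotyped AIMs at which the sample carries exactly one
#' allele from each parental class: 1.0 for a true F1, 0 for pure parents,
#' declining under backcrossing.
#'
#' @inheritParams hybrid_index
#' @return Interclass heterozygosity in `[0, 1]`.
#' @export
interclass_heterozygosity <- function(sample_genotypes, aims) {
  cl <- .classify_aims(sample_genotypes, aims)
  n <- sum(cl$usable)
  if (n == 0) stop("sample is genotyped at zero AIMs")
  sum(cl$het[cl$usable]) / n
}

#' Triangle statistics of one sample
#'
#' Bundles hybrid index, interclass heterozygosity and AIM usage for one
#' sample.
#'
#' @inheritParams hybrid_index
#' @param sample_id Sample identifier.
#' @return A `triangle_stats`: list with `sample_id`, `h`, `H`,
#'   `n_aims_used`, `n_aims_missing`.
#' @export
triangle_stats <- function(sample_genotypes, aims, sample_id = "sample") {
  cl <- .classify_aims(sample_genotypes, aims)
  n <- sum(cl$usable)
  if (n == 0) stop("sample is genotyped at zero AIMs")
  structure(
    list(sample_id = sample_id,
         h = sum(cl$n_p2[cl$usable]) / (2 * n),
         H = sum(cl$het[cl$usable]) / n,
         n_aims_used = n, n_aims_missing = sum(!cl$usable)),
    class = "triangle_stats"
  )
}

#' @export
print.triangle_stats <- function(x, ...) {
  cat(sprintf("%s: hybrid index h = %.4f, interclass heterozygosity H = %.4f (%d AIMs used, %d missing)\n",
              x$sample_id, x$h, x$H, x$n_aims_used, x$n_aims_missing))
  invisible(x)
}

#' Triangle-plot coordinates with feasibility flags
#'
#' Lays out (h, H) pairs in the triangle whose vertices are the pure
#' parents (0, 0) and (1, 0) and the F1 (0.5, 1): any real mixture
#' satisfies `H <= 2 * min(h, 1 - h)`.
#'
#' @param stats A `triangle_stats`, or a list of them.
#' @return A `triangle_df` data frame (`sample_id`, `h`, `H`,
#'   `n_aims_used`, `feasible`) with a `vertices` attribute; has a `plot()`
#'   method.
#' @export
triangle_coordinates <- function(stats) {
  if (inherits(stats, "triangle_stats")) stats <- list(stats)
  df <- do.call(rbind, lapply(stats, function(s)
    data.frame(sample_id = s$sample_id, h = s$h, H = s$H,
               n_aims_used = s$n_aims_used, stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(sample_id = character(0), h = numeric(0),
                     H = numeric(0), n_aims_used = integer(0))
  df$feasible <- df$H <= 2 * pmin(df$h, 1 - df$h) + 1e-9
  structure(df, class = c("triangle_df", "data.frame"),
            vertices = data.frame(label = c("P1", "P2", "F1"),
                                  h = c(0, 1, 0.5), H = c(0, 0, 1)))
}

#' @export
plot.triangle_df <- function(x, ...) {
  v <- attr(x, "vertices")
  plot(NA, xlim = c(0, 1), ylim = c(0, 1.05),
       xlab = "hybrid index (h)", ylab = "interclass heterozygosity (H)", ...)
  polygon(v$h[c(1, 3, 2)], v$H[c(1, 3, 2)], border = "grey40")
  points(x$h, x$H, pch = 19,
         col = ifelse(x$feasible, "darkorange", "red"))
  text(v$h, v$H + 0.03, v$label, col = "grey40")
  invisible(x)
}
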