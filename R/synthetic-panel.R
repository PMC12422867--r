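#' Simulate a pair of diverged parental lineages
#'
#' Generates two haploid reference sequences for two parental lineages (e.g.
#' the two candidate parent species of a putative hybrid) together with the
#' ground-truth table of fixed differences and within-lineage polymorphic
#' sites, plus a short maternally inherited mitochondrial replicon per
#' lineage. Each autosomal site is independently a fixed difference with
#' probability `divergence`, otherwise polymorphic within one lineage with
#' probability `polymorphism` (minor-allele frequency drawn uniformly on
#' `maf_range`), otherwise monomorphic and shared.
#'
#' @param L Number of autosomal sites (>= 1).
#' @param divergence Per-site probability of a fixed difference between the
#'   two lineages, in `[0, 1]`.
#' @param polymorphism Per-site probability of a within-lineage segregating
#'   site; `divergence + polymorphism` must not exceed 1.
#' @param seed Optional integer seed; runs are bit-reproducible under it.
#' @param labels Character vector of two lineage names.
#' @param maf_range Range of minor-allele frequencies for polymorphic sites.
#' @param mito_length Length of the mitochondrial replicon (0 to skip).
#' @param mito_divergence Per-site fixed-difference probability for the
#'   mitochondrial replicon; defaults to `divergence`.
#'
#' @return A `parental_panel`: list with `label_a`, `label_b`, `seq_a`,
#'   `seq_b` (base strings of length `L`), `fixed_sites` (sorted 1-based
#'   positions), `polymorphic_sites` (data frame `pos`, `lineage`, `minor`,
#'   `maf`), `L`, and mitochondrial sequences `mito_a`, `mito_b`.
#' @examples
#' p <- simulate_species_pair(1000, divergence = 0.05, seed = 1)
#' length(p$fixed_sites)
#' @export
simulate_species_pair <- function(L, divergence = 0.05, polymorphism = 0,
                                  seed = NULL,
                                  labels = c("lineage_A", "lineage_B"),
                                  maf_range = c(0.05, 0.5),
                                  mito_length = 500L,
                                  mito_divergence = divergence) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be a positive integer")
  for (p in c(divergence, polymorphism, mito_divergence))
    if (p < 0 || p > 1) stop("divergence/polymorphism rates must lie in [0, 1]")
  if (divergence + polymorphism > 1)
    stop("divergence + polymorphism must not exceed 1")
  stopifnot(length(labels) == 2, labels[1] != labels[2])

  with_seed(seed, {
    anc <- random_dna(L)
    u <- runif(L)
    fixed <- which(u < divergence)
    poly <- which(u >= divergence & u < divergence + polymorphism)
    seq_a <- seq_b <- anc
    if (length(fixed)) seq_b[fixed] <- other_bases(seq_a[fixed])
    poly_df <- data.frame(pos = integer(0), lineage = character(0),
                          minor = character(0), maf = numeric(0))
    if (length(poly)) {
      lin <- resample(labels, length(poly), replace = TRUE)
      major <- ifelse(lin == labels[1], seq_a[poly], seq_b[poly])
      poly_df <- data.frame(
        pos = poly,
        lineage = lin,
        minor = other_bases(major),
        maf = runif(length(poly), maf_range[1], maf_range[2]),
        stringsAsFactors = FALSE
      )
    }
    mito_a <- mito_b <- character(0)
    if (mito_length > 0) {
      ma <- random_dna(mito_length)
      mb <- ma
      mfix <- which(runif(mito_length) < mito_divergence)
      if (length(mfix)) mb[mfix] <- other_bases(ma[mfix])
      mito_a <- c2s(ma)
      mito_b <- c2s(mb)
    }
    structure(
      list(label_a = labels[1], label_b = labels[2],
           seq_a = c2s(seq_a), seq_b = c2s(seq_b),
           fixed_sites = fixed, polymorphic_sites = poly_df, L = L,
           mito_a = mito_a, mito_b = mito_b),
      class = "parental_panel"
    )
  })
}

#' @export
print.parental_panel <- function(x, ...) {
  cat("Parental panel:", x$label_a, "vs", x$label_b, "\n")
  cat("  sites:", x$L,
      "| fixed differences:", length(x$fixed_sites),
      "| polymorphic sites:", nrow(x$polymorphic_sites), "\n")
  if (length(x$mito_a))
    cat("  mitochondrial replicon:", nchar(x$mito_a), "bp\n")
  invisible(x)
}

#' Build a labelled candidate panel of homologous reference sequences
#'
#' A candidate panel maps lineage/species labels to reference sequences
#' homologous to the query coordinates; it is the database that phase-block
#' haplotypes are scored against. `candidate_panel()` accepts named sequences
#' directly, or a [simulate_species_pair()] panel (whose two lineage
#' sequences become the candidates), optionally with extra named sequences
#' such as outgroups appended.
#'
#' @param x A `parental_panel` or a named character vector of sequences.
#' @param ... Additional named sequences (e.g. an outgroup).
#' @return Named character vector of class `candidate_panel` (>= 2 entries,
#'   unique labels).
#' @export
candidate_panel <- function(x, ...) {
  extra <- unlist(list(...))
  if (inherits(x, "parental_panel")) {
    seqs <- setNames(c(x$seq_a, x$seq_b), c(x$label_a, x$label_b))
  } else {
    seqs <- unlist(x)
  }
  seqs <- c(seqs, extra)
  if (length(seqs) < 2) stop("a candidate panel needs at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == ""))
    stop("candidate sequences must carry unique non-empty labels")
  structure(seqs, class = "candidate_panel")
}
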