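#' Simulate a pedigreed diploid individual
#'
#' Builds a diploid from a parental panel under a simple pedigree model:
#' pure parents (`P1`, `P2`), an F1 (one intact haplotype per lineage), an
#' F2 (two recombined F1 gametes) or first backcrosses (`BC1P1`, `BC1P2`:
#' one pure gamete plus one recombined F1 gamete). Gametes from an F1 parent
#' recombine with a Poisson number of crossovers placed uniformly. Ancestry
#' truth tracts per haplotype and the maternal mitochondrial source are
#' recorded for parameter-recovery tests.
#'
#' @param panel A [simulate_species_pair()] `parental_panel`.
#' @param pedigree_class One of `"P1"`, `"P2"`, `"F1"`, `"F2"`, `"BC1P1"`,
#'   `"BC1P2"`.
#' @param recomb_rate Expected crossovers per recombined gamete.
#' @param maternal Lineage label of the mother; defaults to lineage A
#'   (for an F1 this fixes `mito_source` and makes `hap1` the maternal
#'   haplotype).
#' @param sample_id Sample identifier.
#' @param seed Optional integer seed.
#' @return A `diploid_individual`: `sample_id`, `pedigree_class`, `hap1`,
#'   `hap2` (base strings), `truth_tracts` (per-haplotype data frames of
#'   1-based closed intervals `start`, `end`, `source`), `mito_source`,
#'   `mito_seq`, `L` and the panel labels.
#' @examples
#' p <- simulate_species_pair(500, divergence = 0.1, seed = 1)
#' f1 <- simulate_cross(p, "F1", seed = 2)
#' f1$mito_source
#' @export
simulate_cross <- function(panel, pedigree_class = "F1", recomb_rate = 2,
                           maternal = NULL, sample_id = NULL, seed = NULL) {
  stopifnot(inherits(panel, "parental_panel"))
  classes <- c("P1", "P2", "F1", "F2", "BC1P1", "BC1P2")
  if (!pedigree_class %in% classes)
    stop("unknown pedigree class: ", pedigree_class,
         " (supported: ", paste(classes, collapse = ", "), ")")
  labs <- c(panel$label_a, panel$label_b)
  maternal <- maternal %||% labs[1]
  if (!maternal %in% labs) stop("maternal must be one of the panel labels")
  sample_id <- sample_id %||% paste0("sim_", pedigree_class)

  with_seed(seed, {
    paternal <- setdiff(labs, maternal)
    gametes <- switch(pedigree_class,
      P1 = list(.pure_gamete(panel, labs[1]), .pure_gamete(panel, labs[1])),
      P2 = list(.pure_gamete(panel, labs[2]), .pure_gamete(panel, labs[2])),
      F1 = list(.pure_gamete(panel, maternal), .pure_gamete(panel, paternal)),
      F2 = list(.f1_gamete(panel, recomb_rate), .f1_gamete(panel, recomb_rate)),
      BC1P1 = list(.pure_gamete(panel, labs[1]), .f1_gamete(panel, recomb_rate)),
      BC1P2 = list(.pure_gamete(panel, labs[2]), .f1_gamete(panel, recomb_rate))
    )
    mito_source <- switch(pedigree_class,
      P1 = labs[1], P2 = labs[2], maternal)
    mito_seq <- if (length(panel$mito_a)) {
      if (mito_source == labs[1]) panel$mito_a else panel$mito_b
    } else character(0)
    structure(
      list(sample_id = sample_id, pedigree_class = pedigree_class,
           hap1 = c2s(gametes[[1]]$seq), hap2 = c2s(gametes[[2]]$seq),
           truth_tracts = list(hap1 = gametes[[1]]$tracts,
                               hap2 = gametes[[2]]$tracts),
           mito_source = mito_source, mito_seq = mito_seq,
           L = panel$L, labels = labs),
      class = "diploid_individual"
    )
  })
}

# a gamete drawn from a pure parent of one lineage: lineage sequence with
# minor alleles sampled at that lineage's polymorphic sites
.pure_gamete <- function(panel, lineage) {
  seq <- s2c(if (lineage == panel$label_a) panel$seq_a else panel$seq_b)
  ps <- panel$polymorphic_sites
  ps <- ps[ps$lineage == lineage, , drop = FALSE]
  if (nrow(ps)) {
    carry <- runif(nrow(ps)) < ps$maf
    seq[ps$pos[carry]] <- ps$minor[carry]
  }
  list(seq = seq,
       tracts = data.frame(start = 1L, end = panel$L, source = lineage,
                           stringsAsFactors = FALSE))
}

# a gamete from an F1 parent: mosaic of the two lineages with Poisson
# crossovers at uniform positions
.f1_gamete <- function(panel, recomb_rate) {
  ga <- .pure_gamete(panel, panel$label_a)
  gb <- .pure_gamete(panel, panel$label_b)
  L <- panel$L
  ncx <- rpois(1L, recomb_rate)
  bp <- if (ncx > 0 && L > 1) sort(unique(resample(seq_len(L - 1L), min(ncx, L - 1L)))) else integer(0)
  starts <- c(1L, bp + 1L)
  ends <- c(bp, L)
  first <- resample(c(panel$label_a, panel$label_b), 1L)
  src <- rep(c(first, setdiff(c(panel$label_a, panel$label_b), first)),
             length.out = length(starts))
  seq <- ga$seq
  for (k in seq_along(starts)) {
    if (src[k] == panel$label_b) seq[starts[k]:ends[k]] <- gb$seq[starts[k]:ends[k]]
  }
  list(seq = seq,
       tracts = data.frame(start = starts, end = ends, source = src,
                           stringsAsFactors = FALSE))
}

#' @export
print.diploid_individual <- function(x, ...) {
  cat("Diploid individual", x$sample_id, "(", x$pedigree_class, ")\n")
  cat("  L =", x$L, "| het sites:", length(het_sites(x)),
      "| mito from:", x$mito_source, "\n")
  invisible(x)
}

#' Heterozygous site positions of a diploid individual
#'
#' @param ind A `diploid_individual`.
#' @return Sorted 1-based positions where the two haplotypes differ.
#' @export
het_sites <- function(ind) {
  stopifnot(inherits(ind, "diploid_individual"))
  which(s2c(ind$hap1) != s2c(ind$hap2))
}

#' Diploid genotypes of an individual
#'
#' @param ind A `diploid_individual`.
#' @param positions Positions to extract (default: all).
#' @return Character vector of unphased-style `"X/Y"` genotype strings in
#'   `hap1/hap2` order.
#' @export
genotypes <- function(ind, positions = NULL) {
  stopifnot(inherits(ind, "diploid_individual"))
  h1 <- s2c(ind$hap1)
  h2 <- s2c(ind$hap2)
  if (!is.null(positions)) {
    h1 <- h1[positions]
    h2 <- h2[positions]
  }
  paste(h1, h2, sep = "/")
}

#' Perturb genotypes with independent per-allele errors
#'
#' Each allele of each genotype is replaced, with probability `error_rate`,
#' by one of the three other bases uniformly. Used to study how genotyping
#' error shifts triangle statistics.
#'
#' @param gt Character vector of `"X/Y"` genotypes.
#' @param error_rate Per-allele substitution probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Perturbed genotype vector of the same length.
#' @export
apply_genotype_error <- function(gt, error_rate, seed = NULL) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  if (error_rate == 0) return(gt)
  with_seed(seed, {
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    for (al in c("a1", "a2")) {
      v <- get(al)
      hit <- runif(length(v)) < error_rate & v %in% .BASES
      if (any(hit)) v[hit] <- other_bases(v[hit])
      assign(al, v)
    }
    paste(a1, a2, sep = "/")
  })
}

# ancestry source of a haplotype at given positions, from truth tracts
truth_source_at <- function(tracts, positions) {
  idx <- findInterval(positions, tracts$start)
  tracts$source[idx]
}
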