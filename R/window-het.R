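#' Construct a diploid window
#'
#' A diploid window holds the two aligned haplotype sequences of one sample
#' over a genomic window (e.g. a conserved gene such as ACTB), the unit of
#' per-site heterozygosity calculation.
#'
#' @param hap1,hap2 Aligned haplotype strings of equal length over
#'   `A,C,G,T,N,-`.
#' @param sample_id Sample identifier.
#' @param scaffold,start Window location (informational).
#' @return A `diploid_window`.
#' @export
diploid_window <- function(hap1, hap2, sample_id = "sample",
                           scaffold = "window", start = 1L) {
  if (nchar(hap1) != nchar(hap2))
    stop("haplotypes must be aligned to a common length")
  if (!nchar(hap1)) stop("window must have length >= 1")
  structure(list(sample_id = sample_id, scaffold = scaffold,
                 start = as.integer(start), hap1 = hap1, hap2 = hap2),
            class = "diploid_window")
}

#' Per-site heterozygosity of a diploid window
#'
#' The fraction of comparable sites (both haplotypes called `A,C,G,T`;
#' masked `N` and gap columns excluded from numerator and denominator) at
#' which the two haplotypes differ.
#'
#' @param win A [diploid_window()].
#' @return Per-site heterozygosity in `[0, 1]`.
#' @examples
#' w <- diploid_window("ACGTAC", "ACGTGC")
#' per_site_heterozygosity(w)  # 1/6
#' @export
per_site_heterozygosity <- function(win) {
  stopifnot(inherits(win, "diploid_window"))
  c1 <- s2c(win$hap1)
  c2 <- s2c(win$hap2)
  comparable <- c1 %in% .BASES & c2 %in% .BASES
  if (!any(comparable)) stop("window has no comparable (non-N) sites")
  sum(c1 != c2 & comparable) / sum(comparable)
}

#' @export
print.diploid_window <- function(x, ...) {
  cat("Diploid window", x$sample_id, "(", nchar(x$hap1), "bp ):",
      "per-site heterozygosity", signif(per_site_heterozygosity(x), 4), "\n")
  invisible(x)
}

#' Build a synthetic hybrid window from two species' haplotypes
#'
#' Pairs one haplotype from each of two species into an artificial diploid
#' whose per-site heterozygosity estimates the cross-species divergence of
#' the window -- the heterozygosity a true F1 is expected to show there.
#' Equal-length haplotypes are paired on shared coordinates; otherwise the
#' two are aligned globally with free end gaps, and gap columns are
#' excluded by the heterozygosity denominator.
#'
#' @param hap_from_species_a,hap_from_species_b Haplotype strings from the
#'   two species over homologous windows.
#' @param sample_id Sample identifier for the synthetic diploid.
#' @param max_length_diff Maximum tolerated relative length difference
#'   before alignment is refused.
#' @return A [diploid_window()] holding the paired (aligned) haplotypes.
#' @export
make_synthetic_hybrid <- function(hap_from_species_a, hap_from_species_b,
                                  sample_id = "synthetic_hybrid",
                                  max_length_diff = 0.2) {
  la <- nchar(hap_from_species_a)
  lb <- nchar(hap_from_species_b)
  if (!la || !lb) stop("haplotypes must be non-empty")
  if (abs(la - lb) / max(la, lb) > max_length_diff)
    stop("haplotype lengths differ beyond the configured gap tolerance")
  if (la == lb) {
    return(diploid_window(hap_from_species_a, hap_from_species_b,
                          sample_id = sample_id))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(hap_from_species_a),
    Biostrings::DNAString(hap_from_species_b),
    type = "overlap", substitutionMatrix = .blast_matrix(),
    gapOpening = 5, gapExtension = 2)
  diploid_window(as.character(Biostrings::alignedPattern(aln)),
                 as.character(Biostrings::alignedSubject(aln)),
                 sample_id = sample_id)
}
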