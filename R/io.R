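#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (names become headers),
#'   a `parental_panel` (both lineage sequences), or a `masked_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "parental_panel"))
    seqs <- setNames(c(seqs$seq_a, seqs$seq_b), c(seqs$label_a, seqs$label_b))
  if (inherits(seqs, "masked_sequence"))
    seqs <- setNames(seqs$seq, seqs$sample_id %||% "consensus")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a pileup as TSV
#'
#' One row per read base (`pos`, `depth`, `base`, `bq`, `mq`); zero-depth
#' positions appear once with base `"."` and missing qualities.
#'
#' @param pileup A `pileup`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  stopifnot(inherits(pileup, "pileup"))
  depth_at <- setNames(pileup$depth, pileup$positions)
  reads <- pileup$reads
  out <- data.frame(pos = reads$pos,
                    depth = as.integer(depth_at[as.character(reads$pos)]),
                    base = reads$base, bq = reads$bq, mq = reads$mq)
  empty <- pileup$positions[pileup$depth == 0]
  if (length(empty))
    out <- rbind(out, data.frame(pos = empty, depth = 0L, base = ".",
                                 bq = NA_integer_, mq = NA_integer_))
  out <- out[order(out$pos), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup from TSV
#'
#' @param path TSV written by [write_pileup_tsv()].
#' @return A `pileup`.
#' @export
read_pileup_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  positions <- sort(unique(tab$pos))
  depth <- vapply(split(tab$depth, tab$pos), function(d) d[1], numeric(1))
  reads <- tab[tab$base != ".", c("pos", "base", "bq", "mq")]
  rownames(reads) <- NULL
  structure(
    list(region = range(positions), positions = positions,
         depth = as.integer(depth[as.character(positions)]), reads = reads,
         sample_id = NULL),
    class = "pileup"
  )
}

#' Write intervals as BED
#'
#' Converts the package's 1-based closed intervals to BED's 0-based
#' half-open convention.
#'
#' @param intervals Data frame with `start`, `end` (1-based closed) and
#'   optional `reason`/`name` column, or a list of `phase_block`s.
#' @param path Output file path.
#' @param chrom Chromosome/scaffold name used when `intervals` lacks one.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "scaffold_1") {
  if (length(intervals) && inherits(intervals[[1]], "phase_block")) {
    intervals <- data.frame(
      chrom = vapply(intervals, function(b) b$scaffold, ""),
      start = vapply(intervals, function(b) b$start, numeric(1)),
      end = vapply(intervals, function(b) b$end, numeric(1)),
      name = vapply(intervals, function(b)
        paste0("n", length(b$variant_positions)), "")
    )
  }
  if (is.null(intervals$chrom)) intervals$chrom <- chrom
  name <- intervals$name %||% intervals$reason %||% "."
  bed <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,  # to 0-based
                    end = as.integer(intervals$end), name = name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write diploid genotypes as a minimal VCF
#'
#' Emits phased genotypes of one or more individuals at the panel's
#' variable sites, with a `PS` (phase set) FORMAT tag when phase-block
#' membership is supplied. Coordinates are written 1-based per VCF.
#'
#' @param inds A `diploid_individual` or list of them.
#' @param panel The `parental_panel` the individuals were simulated from
#'   (provides REF = lineage-A allele and site list).
#' @param path Output file path.
#' @param blocks Optional list of `phase_block`s assigning `PS` tags (first
#'   individual only).
#' @param chrom Scaffold name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(inds, panel, path, blocks = NULL,
                      chrom = "scaffold_1") {
  if (inherits(inds, "diploid_individual")) inds <- list(inds)
  stopifnot(inherits(panel, "parental_panel"))
  pos <- sort(unique(c(panel$fixed_sites, panel$polymorphic_sites$pos,
                       unlist(lapply(inds, het_sites)))))
  ref <- s2c(panel$seq_a)[pos]
  ps <- rep(NA_integer_, length(pos))
  if (!is.null(blocks)) {
    for (b in blocks) {
      in_b <- pos %in% b$variant_positions
      ps[in_b] <- b$start
    }
  }
  gts <- lapply(inds, function(ind) {
    a1 <- s2c(ind$hap1)[pos]
    a2 <- s2c(ind$hap2)[pos]
    list(a1 = a1, a2 = a2)
  })
  alt <- vapply(seq_along(pos), function(i) {
    alleles <- unique(c(vapply(gts, function(g) g$a1[i], ""),
                        vapply(gts, function(g) g$a2[i], "")))
    alleles <- setdiff(alleles, ref[i])
    if (length(alleles)) paste(alleles, collapse = ",") else "."
  }, "")
  gt_str <- vapply(seq_along(pos), function(i) {
    alleles <- c(ref[i], strsplit(alt[i], ",", fixed = TRUE)[[1]])
    cols <- vapply(gts, function(g) {
      code <- paste0(match(g$a1[i], alleles) - 1L, "|",
                     match(g$a2[i], alleles) - 1L)
      if (!is.na(ps[i])) paste0(code, ":", ps[i]) else code
    }, "")
    paste(cols, collapse = "\t")
  }, "")
  fmt <- ifelse(is.na(ps), "GT", "GT:PS")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   vapply(inds, function(i) i$sample_id, "")),
                 collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, gt_str,
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a checklist table as CSV
#'
#' @param checklists A [checklist_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_checklists_csv <- function(checklists, path) {
  write.csv(as.data.frame(checklists), path, row.names = FALSE)
  invisible(path)
}

#' Read a checklist table from CSV
#'
#' @param path CSV with the [checklist_table()] columns.
#' @return A `checklist_table`.
#' @export
read_checklists_csv <- function(path) {
  checklist_table(read.csv(path, stringsAsFactors = FALSE))
}
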