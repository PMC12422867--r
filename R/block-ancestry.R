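#' Filter phase blocks by variant count and length
#'
#' Retains blocks with at least `min_variants` phased variant positions and
#' a span of at least `min_length` bp (block length is last variant - first
#' variant + 1). Order is preserved.
#'
#' @param blocks List of `phase_block` objects.
#' @param min_variants Minimum variant positions (default 10).
#' @param min_length Minimum block length in bp (default 100).
#' @return Filtered list of `phase_block` objects.
#' @export
filter_blocks <- function(blocks, min_variants = 10, min_length = 100) {
  if (min_variants < 0 || min_length < 0) stop("thresholds must be >= 0")
  keep <- vapply(blocks, function(b)
    length(b$variant_positions) >= min_variants &&
      block_length(b) >= min_length, logical(1))
  blocks[keep]
}

#' Summary moments of a set of phase blocks
#'
#' @param blocks List of `phase_block` objects (>= 2 for SDs).
#' @return List with `n`, `mean_variants`, `sd_variants`, `mean_length`,
#'   `sd_length` (sample SD, n-1 denominator).
#' @export
block_summary <- function(blocks) {
  if (!length(blocks)) stop("no blocks to summarize")
  nv <- vapply(blocks, function(b) length(b$variant_positions), numeric(1))
  len <- vapply(blocks, block_length, numeric(1))
  if (length(blocks) < 2)
    stop("block SDs are undefined for fewer than 2 blocks")
  list(n = length(blocks),
       mean_variants = mean(nv), sd_variants = sd(nv),
       mean_length = mean(len), sd_length = sd(len))
}

# substitution matrix mimicking default nucleotide BLAST ranking
.blast_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA")
    mat
  }
})

# local affine-gap alignment of queries against one subject (one batched
# call); returns matrix with score and identity rows, one column per query.
# identity = matches / alignment length (gap columns count against
# identity, BLAST's convention)
.align_scores <- function(queries, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .blast_matrix(),
    gapOpening = 5, gapExtension = 2)
  rbind(score = BiocGenerics::score(aln),
        identity = Biostrings::pid(aln, type = "PID1") / 100)
}

# score several queries against every candidate; list of per-query ranked
# hit data frames
.score_queries <- function(queries, panel, min_identity) {
  per_cand <- lapply(unclass(panel), function(s) .align_scores(queries, s))
  lapply(seq_along(queries), function(i) {
    hits <- data.frame(
      label = names(panel),
      score = vapply(per_cand, function(m) m["score", i], numeric(1)),
      identity = vapply(per_cand, function(m) m["identity", i], numeric(1)),
      stringsAsFactors = FALSE)
    hits$eligible <- hits$identity >= min_identity
    hits <- hits[order(-hits$score, hits$label), , drop = FALSE]
    rownames(hits) <- NULL
    hits
  })
}

.top_category <- function(hits) {
  el <- hits[hits$eligible, , drop = FALSE]
  if (!nrow(el)) return(list(category = "none", labels = character(0)))
  top <- el$score >= el$score[1] - 1e-9
  labels <- sort(el$label[top])
  list(category = paste(labels, collapse = "+"), labels = labels)
}

#' Score a query haplotype against a candidate panel
#'
#' Computes a local affine-gap alignment score and percent identity of the
#' query against every candidate sequence (match +2, mismatch -3, gap open
#' 5, gap extend 2 -- chosen to mimic default nucleotide BLAST ranking),
#' ranks candidates by score, and reports the top category. Candidates
#' whose identity falls below `min_identity` are excluded before ranking;
#' equal top scores among survivors yield a tie-set category.
#'
#' @param query Base string (may contain `N`; an all-`N` query is an error).
#' @param panel A [candidate_panel()].
#' @param min_identity Identity gate applied before ranking (default 0.97).
#' @return A `hit_report`: list with `hits` (data frame `label`, `score`,
#'   `identity`, `eligible`, ranked by score), `top_category` (a single
#'   label, a `"+"`-joined tie-set, or `"none"`), and `top_labels`.
#' @export
score_haplotype <- function(query, panel, min_identity = 0.97) {
  stopifnot(inherits(panel, "candidate_panel"))
  qc <- s2c(query)
  if (!length(qc) || all(qc == "N")) stop("query is empty or all-N")
  hits <- .score_queries(query, panel, min_identity)[[1]]
  top <- .top_category(hits)
  structure(list(hits = hits, top_category = top$category,
                 top_labels = top$labels),
            class = "hit_report")
}

#' @export
print.hit_report <- function(x, ...) {
  cat("Top hit:", x$top_category, "\n")
  print(x$hits)
  invisible(x)
}

#' Tally top hits of both haplotypes of every phase block
#'
#' Scores both haplotype consensus sequences of each (already filtered)
#' block against the homologous span of each candidate (block span plus
#' `margin` bp each side, for coordinate-matched candidates). Queries with
#' more than `max_n_frac` masked (`N`) bases are dropped and counted
#' separately. Categories are the single candidate labels, observed
#' tie-sets, and `"none"` (no candidate passed the identity gate).
#'
#' @param blocks List of `phase_block` objects (already filtered).
#' @param panel A [candidate_panel()] of sequences homologous to (and in
#'   the coordinates of) the blocks' scaffold.
#' @param min_identity Identity gate (default 0.97).
#' @param margin Context added around the block span when extracting the
#'   homologous candidate region (bp).
#' @param max_n_frac Maximum tolerated fraction of `N` in a query.
#' @return A `hit_tally`: list with `counts` (named integer vector per
#'   category), `n_blocks`, `n_queries` (scored queries), `n_dropped`, and
#'   `assignments` (data frame: `block`, `hap`, `category`, and truth
#'   columns when the blocks carry simulator truth).
#' @export
tally_top_hits <- function(blocks, panel, min_identity = 0.97, margin = 100,
                           max_n_frac = 0.5) {
  stopifnot(inherits(panel, "candidate_panel"))
  plen <- nchar(unclass(panel))
  rows <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    lo <- max(1L, b$start - as.integer(margin))
    hi <- b$end + as.integer(margin)
    sub <- vapply(seq_along(panel),
                  function(k) substr(panel[[k]], lo, min(hi, plen[k])), "")
    names(sub) <- names(panel)
    subpanel <- structure(sub, class = "candidate_panel")
    truth <- b$truth
    qs <- c(b$hap1_seq, b$hap2_seq)
    n_frac <- vapply(strsplit(qs, "", fixed = TRUE),
                     function(x) mean(x == "N"), numeric(1))
    drop <- n_frac > max_n_frac
    cats <- rep("dropped", 2L)
    if (any(!drop)) {
      scored <- .score_queries(qs[!drop], subpanel, min_identity)
      cats[!drop] <- vapply(scored,
                            function(h) .top_category(h)$category, "")
    }
    for (h in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = bi, hap = h, category = cats[h],
        truth = if (!is.null(truth))
          truth[[paste0("hap", h, "_source")]][1] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = integer(0), hap = integer(0),
               category = character(0), truth = character(0))
  scored <- assignments[assignments$category != "dropped", , drop = FALSE]
  counts <- table(scored$category)
  structure(
    list(counts = setNames(as.integer(counts), names(counts)),
         n_blocks = length(blocks), n_queries = nrow(scored),
         n_dropped = sum(assignments$category == "dropped"),
         assignments = assignments),
    class = "hit_tally"
  )
}

#' @export
print.hit_tally <- function(x, ...) {
  cat("Top-hit tally over", x$n_blocks, "blocks (", x$n_queries,
      "queries,", x$n_dropped, "dropped)\n")
  print(x$counts)
  invisible(x)
}

#' Merge tally categories into report groups
#'
#' Re-labels tally categories according to a grouping (e.g. folding two
#' congeneric candidates and their tie into one group); categories not
#' covered by any group are folded into `"other"`.
#'
#' @param tally A `hit_tally`.
#' @param groups Named list mapping group name to the category labels it
#'   absorbs.
#' @return Named integer vector of grouped counts (groups plus `"other"`).
#' @export
group_tally <- function(tally, groups) {
  stopifnot(inherits(tally, "hit_tally"))
  out <- setNames(integer(length(groups) + 1L), c(names(groups), "other"))
  for (cat_ in names(tally$counts)) {
    hit <- vapply(groups, function(g) cat_ %in% g, logical(1))
    g <- if (any(hit)) names(groups)[which(hit)[1]] else "other"
    out[g] <- out[g] + tally$counts[[cat_]]
  }
  out
}

#' Exact binomial test of the F1 phase-block balance expectation
#'
#' A true F1 should show roughly equal numbers of block haplotypes assigned
#' to each parental species. Tests the observed split of single-label top
#' hits between the two parents against 0.5 with a two-sided exact binomial
#' test.
#'
#' @param tally A `hit_tally`.
#' @param label_parent1,label_parent2 Candidate labels of the two parents.
#' @return List with `proportion` (parent-1 share), `counts`, and `p_value`.
#' @export
f1_balance_test <- function(tally, label_parent1, label_parent2) {
  stopifnot(inherits(tally, "hit_tally"))
  c1 <- tally$counts[label_parent1]
  c2 <- tally$counts[label_parent2]
  c1 <- if (is.na(c1)) 0L else as.integer(c1)
  c2 <- if (is.na(c2)) 0L else as.integer(c2)
  if (c1 + c2 == 0) stop("no queries assigned to either parent")
  bt <- binom.test(c1, c1 + c2, p = 0.5)
  list(proportion = c1 / (c1 + c2),
       counts = setNames(c(c1, c2), c(label_parent1, label_parent2)),
       p_value = bt$p.value)
}
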