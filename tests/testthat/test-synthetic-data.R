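test_that("species-pair simulator respects divergence and is seed-reproducible", {
  p <- simulate_species_pair(10000, divergence = 0.05, seed = 7)
  expected <- 10000 * 0.05
  band <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(length(p$fixed_sites) - expected), band)
  # fixed sites truly differ, and the truth table is disjoint
  a <- strsplit(p$seq_a, "")[[1]]
  b <- strsplit(p$seq_b, "")[[1]]
  expect_true(all(a[p$fixed_sites] != b[p$fixed_sites]))
  expect_length(intersect(p$fixed_sites, p$polymorphic_sites$pos), 0)

  p2 <- simulate_species_pair(10000, divergence = 0.05, seed = 7)
  expect_identical(p, p2)

  p0 <- simulate_species_pair(100, divergence = 0, polymorphism = 0.1,
                              seed = 1)
  expect_length(p0$fixed_sites, 0)
  expect_identical(p0$seq_a, p0$seq_b)

  p1 <- simulate_species_pair(100, divergence = 1, polymorphism = 0, seed = 1)
  expect_identical(p1$fixed_sites, 1:100)

  expect_error(simulate_species_pair(0), "positive")
  expect_error(simulate_species_pair(10, divergence = 1.5), "\\[0, 1\\]")
  expect_error(simulate_species_pair(10, divergence = 0.6,
                                     polymorphism = 0.6), "exceed")
})

test_that("crosses follow Mendelian expectations at fixed sites", {
  p <- simulate_species_pair(2000, divergence = 0.25, polymorphism = 0,
                             seed = 5)
  fx <- p$fixed_sites

  f1 <- simulate_cross(p, "F1", seed = 1)
  g <- genotypes(f1, fx)
  expect_true(all(substr(g, 1, 1) != substr(g, 3, 3)))
  expect_identical(f1$mito_source, p$label_a)
  # maternal designation controls mito source
  f1b <- simulate_cross(p, "F1", maternal = p$label_b, seed = 1)
  expect_identical(f1b$mito_source, p$label_b)

  pp <- simulate_cross(p, "P1", seed = 2)
  b_alleles <- strsplit(p$seq_b, "")[[1]][fx]
  gp <- genotypes(pp, fx)
  expect_false(any(substr(gp, 1, 1) == b_alleles |
                   substr(gp, 3, 3) == b_alleles))

  # truth tracts tile [1, L] without overlap
  f2 <- simulate_cross(p, "F2", recomb_rate = 3, seed = 3)
  for (tr in f2$truth_tracts) {
    expect_identical(tr$start[1], 1L)
    expect_identical(tr$end[nrow(tr)], p$L)
    if (nrow(tr) > 1)
      expect_identical(tr$start[-1], tr$end[-nrow(tr)] + 1L)
  }

  expect_error(simulate_cross(p, "BC9"), "unknown pedigree class")
})

test_that("backcross and F2 allele fractions match Monte-Carlo expectations", {
  p <- simulate_species_pair(2000, divergence = 0.25, polymorphism = 0,
                             seed = 5)
  fx <- p$fixed_sites
  b_alleles <- strsplit(p$seq_b, "")[[1]][fx]
  frac_b <- function(ind) {
    g <- genotypes(ind, fx)
    mean(c(substr(g, 1, 1) == b_alleles, substr(g, 3, 3) == b_alleles))
  }
  set.seed(99)
  bc <- replicate(80, frac_b(simulate_cross(p, "BC1P1")))
  f2 <- replicate(80, frac_b(simulate_cross(p, "F2")))
  expect_lt(abs(mean(bc) - 0.25), 3 * sd(bc) / sqrt(length(bc)) + 1e-12)
  expect_lt(abs(mean(f2) - 0.5), 3 * sd(f2) / sqrt(length(f2)) + 1e-12)
})

test_that("pileups follow the depth and error model", {
  p <- simulate_species_pair(1000, divergence = 0.1, polymorphism = 0,
                             seed = 8)
  f1 <- simulate_cross(p, "F1", seed = 9)

  pu <- simulate_pileup(f1, mean_depth = 30, error_rate = 0, seed = 10)
  het <- het_sites(f1)[1]
  obs <- unique(pu$reads$base[pu$reads$pos == het])
  h1 <- substr(f1$hap1, het, het)
  h2 <- substr(f1$hap2, het, het)
  expect_true(all(obs %in% c(h1, h2)))

  pu8 <- simulate_pileup(f1, mean_depth = 8, seed = 11)
  expect_lt(abs(mean(pu8$depth) - 8), 3 * sqrt(8 / 1000))
  expect_identical(as.integer(table(factor(pu8$reads$pos,
                                           levels = pu8$positions))),
                   pu8$depth)
  expect_true(all(pu8$reads$bq >= 0 & pu8$reads$bq <= 60))
  expect_true(all(pu8$reads$mq >= 0 & pu8$reads$mq <= 60))

  sparse <- simulate_pileup(f1, mean_depth = 0.1, seed = 12)
  p0 <- mean(sparse$depth == 0)
  expect_lt(abs(p0 - exp(-0.1)), 3 * sqrt(exp(-0.1) * (1 - exp(-0.1)) / 1000))

  expect_error(simulate_pileup(f1, region = c(5, 2)), "region")
  expect_error(simulate_pileup(f1, mean_depth = 0), "mean_depth")
})

test_that("phase blocks hit their length/variant targets and carry truth", {
  fx <- f1_block_fixture()
  blocks <- fx$blocks
  expect_gte(length(blocks), 500)
  nv <- vapply(blocks, function(b) length(b$variant_positions), numeric(1))
  len <- vapply(blocks, block_length, numeric(1))
  expect_lt(abs(mean(nv) - 12.5) / 12.5, 0.1)
  expect_lt(abs(mean(len) - 339) / 339, 0.1)

  # zero switch error on an F1: within a block each haplotype matches one
  # parental lineage at every variant site
  a <- strsplit(fx$panel$seq_a, "")[[1]]
  b <- strsplit(fx$panel$seq_b, "")[[1]]
  for (blk in blocks[1:25]) {
    rel <- blk$variant_positions - blk$start + 1L
    h1 <- strsplit(blk$hap1_seq, "")[[1]][rel]
    src <- blk$truth$hap1_source
    ref <- ifelse(src == fx$panel$label_a, a[blk$variant_positions],
                  b[blk$variant_positions])
    expect_identical(h1, ref)
    expect_length(unique(src), 1L)  # F1 haplotypes are single-lineage
  }

  # blocks are non-overlapping and ordered
  starts <- vapply(blocks, function(b) b$start, numeric(1))
  ends <- vapply(blocks, function(b) b$end, numeric(1))
  expect_true(all(starts[-1] > ends[-length(ends)]))

  # an individual with no heterozygous sites yields no blocks
  mono <- simulate_species_pair(5000, divergence = 0, polymorphism = 0,
                                seed = 1)
  pure <- simulate_cross(mono, "P1", seed = 2)
  expect_identical(simulate_phase_blocks(pure, seed = 3), list())

  expect_error(simulate_phase_blocks(fx$f1, mean_length = -5), "positive")
  expect_error(simulate_phase_blocks(fx$f1, switch_error_rate = 0.7),
               "switch_error_rate")
})

test_that("switch errors break within-block haplotype consistency", {
  fx <- f1_block_fixture()
  noisy <- simulate_phase_blocks(fx$f1, switch_error_rate = 0.2, seed = 77)
  # with heavy switching, many blocks mix the two lineages on one haplotype
  mixed <- vapply(noisy, function(b)
    length(unique(b$truth$hap1_source)) > 1, logical(1))
  expect_gt(mean(mixed), 0.5)
})

test_that("checklist simulator retains usable ground truth", {
  cl0 <- simulate_checklists(30, 3, cooccurrence_rate = 0,
                             vagrancy_rate = 0, seed = 21)
  co <- find_cooccurrences(cl0, "green_jay", "blue_jay")
  expect_identical(co$n_checklists, 0L)
  expect_identical(co$n_localities, 0L)

  cl1 <- simulate_checklists(20, 4, detection_rate = 1,
                             cooccurrence_rate = 0.5, vagrancy_rate = 0,
                             seed = 22)
  res <- attr(cl1, "residency")
  fl <- filter_localities(cl1, "green_jay")
  sm <- fl$locality_summary
  # every resident locality with any checklist detects at 100% -> criterion 2
  surveyed <- unique(cl1$locality_id)
  for (loc in intersect(res$locality_id[res$resident_a], surveyed))
    expect_true(sm$crit2[sm$locality_id == loc])

  # a vagrant record in a single year at a low-rate locality fails both
  # criteria and is removed
  cl2 <- simulate_checklists(40, 5, detection_rate = 0.8,
                             cooccurrence_rate = 0.1, vagrancy_rate = 0.02,
                             seed = 23)
  vg <- attr(cl2, "vagrant_records")
  expect_gt(nrow(vg), 0)
  fl2 <- filter_localities(cl2, "green_jay")
  vg_g <- vg$checklist_id[vg$species == "green_jay"]
  sm2 <- fl2$locality_summary
  for (id in vg_g) {
    loc <- cl2$locality_id[cl2$checklist_id == id]
    row <- sm2[sm2$locality_id == loc, ]
    if (!row$crit1 && !row$crit2)
      expect_false(id %in% fl2$retained$checklist_id)
  }

  expect_error(simulate_checklists(0, 3), "n_localities")
  expect_error(simulate_checklists(5, 3, vagrancy_rate = 2), "rates")
})
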