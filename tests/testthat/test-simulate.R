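test_that("synthetic_config validates its arguments", {
  expect_s3_class(synthetic_config(), "sepol_config")
  expect_error(synthetic_config(n_genes = 10,
                                group_counts = c(strong_up = 5, weak_up = 5,
                                                 strong_down = 5,
                                                 weak_down = 5)))
  expect_error(synthetic_config(group_counts = c(a = 1)))
  expect_error(synthetic_config(theta_range = c(0, 1.5)))
})

test_that("the planted AED boundary is the density crossing point", {
  cfg <- synthetic_config()
  b <- aed_mixture_boundary(cfg)
  expect_gt(b, cfg$weak_lfc_mean)
  expect_lt(b, cfg$strong_lfc_mean)
  ## the two component densities are equal there
  expect_equal(dnorm(b, cfg$weak_lfc_mean, cfg$weak_lfc_sd),
               dnorm(b, cfg$strong_lfc_mean, cfg$strong_lfc_sd),
               tolerance = 1e-3)
  ## independent check by grid search
  grid <- seq(cfg$weak_lfc_mean, cfg$strong_lfc_mean, by = 1e-4)
  gap <- abs(dnorm(grid, cfg$weak_lfc_mean, cfg$weak_lfc_sd) -
               dnorm(grid, cfg$strong_lfc_mean, cfg$strong_lfc_sd))
  expect_lt(abs(b - grid[which.min(gap)]), 1e-3)
})

test_that("generation is bit-identical under one seed, distinct otherwise", {
  cfg <- small_config()
  g1 <- generate_genome_and_genes(cfg, seed = 3)
  g2 <- generate_genome_and_genes(cfg, seed = 3)
  expect_identical(g1$manifest$se, g2$manifest$se)
  expect_identical(g1$manifest$genes, g2$manifest$genes)
  g3 <- generate_genome_and_genes(cfg, seed = 4)
  expect_false(identical(g1$manifest$se$start, g3$manifest$se$start))

  t1 <- generate_coverage_library(cfg, g1$manifest, "control", "H3K27ac",
                                  seed = 3)
  t2 <- generate_coverage_library(cfg, g1$manifest, "control", "H3K27ac",
                                  seed = 3)
  expect_identical(t1$coverage, t2$coverage)
  ## replicates and marks use distinct noise streams
  t3 <- generate_coverage_library(cfg, g1$manifest, "control", "H3K27ac",
                                  replicate = 2, seed = 3)
  expect_false(identical(t1$coverage, t3$coverage))

  e1 <- generate_expression_table(cfg, g1$manifest, seed = 3)
  e2 <- generate_expression_table(cfg, g1$manifest, seed = 3)
  expect_identical(e1, e2)
})

test_that("an over-subscribed genome raises a capacity error", {
  cfg <- synthetic_config(genome_length = 2e5, n_genes = 0, n_ses = 10,
                          n_typical = 0,
                          group_counts = c(strong_up = 0, weak_up = 0,
                                           strong_down = 0, weak_down = 0))
  expect_error(generate_genome_and_genes(cfg, seed = 1), "capacity")
})

test_that("the genome layout honors its spacing and labeling contracts", {
  study <- small_study(seed = 2)
  cfg <- study$genome$config
  man <- study$genome$manifest
  se <- manifest_se_granges(man)
  ## SE bodies are disjoint and pairwise separated well beyond the stitch
  ## distance (flank + safety margin between footprints)
  expect_equal(length(reduce(se)), length(se))
  se_sorted <- sort(se)
  gaps <- start(se_sorted)[-1] - end(se_sorted)[-length(se_sorted)]
  expect_true(all(gaps > 12500))
  ## group labels match the configured counts
  expect_equal(as.numeric(table(man$genes$group)[names(cfg$group_counts)]),
               as.numeric(cfg$group_counts))
  ## typical enhancers stay clear of SE footprints plus the safety margin
  enh <- GRanges(man$enhancers$chrom,
                 IRanges(man$enhancers$center, width = 1))
  expect_false(any(overlapsAny(enh, se + cfg$feature_min_gap)))
})

test_that("H3K27ac read mass matches the planted feature masses", {
  study <- small_study(seed = 2)
  cfg <- study$genome$config
  man <- study$genome$manifest
  total <- sum(as.numeric(study$tracks$H3K27ac_control_rep1$coverage$chrS))
  expected <- cfg$bg_chip * cfg$genome_length +
    nrow(man$se) * cfg$se_mass +
    sum(man$enhancers$mass) +
    nrow(man$genes) * cfg$prom_ac_mass
  expect_lt(abs(total - expected) / expected, 0.02)
})

test_that("SE polarization concentration drops across conditions", {
  ## one isolated SE, no other features, so dominant-constituent mass
  ## fractions can be read off the coverage directly
  cfg <- synthetic_config(genome_length = 3e5, n_genes = 0, n_ses = 1,
                          n_typical = 0, bg_chip = 0.01, se_mass = 2e5,
                          group_counts = c(strong_up = 0, weak_up = 0,
                                           strong_down = 0, weak_down = 0))
  g <- generate_genome_and_genes(cfg, seed = 6)
  se <- g$manifest$se
  ctr <- se$centers[[1]][se$dominant]
  win <- (ctr - 2 * cfg$sigma_constituent):(ctr + 2 * cfg$sigma_constituent)
  frac <- sapply(c("control", "force", "force_oeEZH2"), function(cd) {
    trk <- generate_coverage_library(cfg, g$manifest, cd, "H3K27ac",
                                     seed = 6)
    v <- as.numeric(trk$coverage$chrS)
    sum(v[win]) / sum(v)
  })
  expect_gt(frac["control"], frac["force"])
  expect_gt(frac["force"], frac["force_oeEZH2"])
})

test_that("the H3K27me3 block abuts the declared side of each SE", {
  study <- small_study(seed = 2)
  cfg <- study$genome$config
  me3 <- study$tracks$H3K27me3_control_rep1
  se <- manifest_se_granges(study$genome$manifest)
  o <- orient_ses(se, me3, flank_width = cfg$me3_flank_width)
  left_heavier <- o$left_flank_me3 > o$right_flank_me3
  expect_gte(mean(left_heavier == (se$me3_side == "left")), 0.95)
})

test_that("expression AED tracks the planted effect sizes", {
  study <- small_study(seed = 2)
  expr <- study$expression
  genes <- study$genome$manifest$genes
  aed <- compute_aed(rowMeans(expr[grep("^fpkm_ctrl", names(expr))]),
                     rowMeans(expr[grep("^fpkm_stress", names(expr))]))
  ## per-group mean AED close to the configured mixture means
  expect_equal(mean(aed[genes$group %in% c("weak_up", "weak_down")]),
               0.7, tolerance = 0.1)
  expect_equal(mean(aed[genes$group %in% c("strong_up", "strong_down")]),
               2.0, tolerance = 0.15)
  ## direction of the fold change matches the group label
  lfc <- log2(rowMeans(expr[grep("^fpkm_stress", names(expr))]) /
                rowMeans(expr[grep("^fpkm_ctrl", names(expr))]))
  up <- genes$group %in% c("weak_up", "strong_up")
  down <- genes$group %in% c("weak_down", "strong_down")
  expect_gte(mean(lfc[up] > 0), 0.95)
  expect_gte(mean(lfc[down] < 0), 0.95)
  expect_identical(expr$significant, genes$group != "unchanged")
})
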