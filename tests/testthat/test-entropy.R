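test_that("region entropy hits its extremes and the worked example", {
  ## uniform density over 1024 bases -> 10 bits (maximum, log2 L)
  u <- toy_track(rep(3, 1024))
  r <- region_entropy(u, GRanges("chr1", IRanges(1, 1024)), eps = 0)
  expect_equal(r$entropy, 10)
  expect_equal(r$entropy_norm, 1)
  ## all mass at one base -> 0 bits
  pt <- toy_track(c(0, 0, 7, 0, 0))
  r <- region_entropy(pt, GRanges("chr1", IRanges(1, 5)), eps = 0)
  expect_equal(r$entropy, 0)
  ## density (1, 1, 2): p = (1/4, 1/4, 1/2), H = 1.5 bits
  tr <- toy_track(c(1, 1, 2))
  r <- region_entropy(tr, GRanges("chr1", IRanges(1, 3)), eps = 0)
  expect_equal(r$entropy, 1.5)
})

test_that("all-zero regions are flagged when eps is zero", {
  z <- toy_track(rep(0, 10))
  expect_error(region_entropy(z, GRanges("chr1", IRanges(1, 10)), eps = 0),
               "undefined entropy")
  ## with a pseudocount the region scores as uniform
  r <- region_entropy(z, GRanges("chr1", IRanges(1, 8)), eps = 0.1)
  expect_equal(r$entropy, 3)
})

test_that("entropy bounds and scale invariance hold on random regions", {
  withr::with_seed(23, {
    for (i in 1:1000) {
      L <- sample(2:200, 1)
      d <- rpois(L, runif(1, 0.2, 5))
      if (sum(d) == 0) d[1] <- 1
      trk <- toy_track(d, library_size = 1e6)
      r <- region_entropy(trk, GRanges("chr1", IRanges(1, L)))
      expect_gte(r$entropy, 0)
      expect_lte(r$entropy, log2(L) + 1e-9)
      ## independent brute-force Shannon value at the same eps
      expect_equal(r$entropy, shannon_bits(d * 1e6 / 1e6, r$eps),
                   tolerance = 1e-9)
      ## library-size renormalization leaves H unchanged
      trk2 <- toy_track(d, library_size = 3.7e7)
      r2 <- region_entropy(trk2, GRanges("chr1", IRanges(1, L)))
      expect_equal(r2$entropy, r$entropy, tolerance = 1e-9)
    }
  })
})

test_that("entropy deltas compare fixed regions across libraries", {
  a <- toy_track(c(5, 5, 5, 5))          # uniform: H = 2
  b <- toy_track(c(0, 20, 0, 0))         # point mass: H = 0
  reg <- GRanges("chr1", IRanges(1, 4))
  d <- entropy_deltas(a, b, reg, eps = 0)
  expect_equal(d$deltas$delta, 2)
  ## a vs itself: all deltas zero
  expect_equal(entropy_deltas(a, a, reg, eps = 0)$deltas$delta, 0)
  ## spiked minus uniform is negative
  expect_lt(entropy_deltas(b, a, reg, eps = 0)$deltas$delta, 0)
  ## five-number summary names
  expect_named(d$summary, c("min", "q1", "median", "q3", "max"))
})

test_that("matched background regions preserve lengths and avoid exclusions", {
  withr::with_seed(5, {
    regs <- GRanges("chrS", IRanges(start = c(1000, 50000, 200000),
                                    width = c(500, 1500, 800)))
    names(regs) <- paste0("SE", 1:3)
    bg <- matched_background_regions(regs, c(chrS = 1e6), seed = 9)
    expect_equal(sort(width(bg)), sort(width(regs)))
    expect_false(any(overlapsAny(bg, regs)))
    ## deterministic under the seed
    bg2 <- matched_background_regions(regs, c(chrS = 1e6), seed = 9)
    expect_identical(as.data.frame(bg), as.data.frame(bg2))
    ## capacity error when the genome cannot host the lengths
    expect_error(
      matched_background_regions(GRanges("chrS", IRanges(1, 900)),
                                 c(chrS = 1000), seed = 1,
                                 max_tries = 50),
      "capacity")
  })
})

test_that("wilcoxon signed-rank matches exhaustive enumeration for n <= 12", {
  ## all-positive n = 5: W = 15, one-sided p = 1/32
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), "greater")
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 1 / 32)
  ## random cases with ties and zeros across every n <= 12
  withr::with_seed(31, {
    for (n in 2:12) {
      for (rep in 1:5) {
        d <- round(rnorm(n, 0.3), 1)      # rounding induces ties/zeros
        if (all(d == 0)) d[1] <- 0.5
        for (alt in c("two.sided", "greater", "less")) {
          expect_equal(wilcoxon_signed_rank(d, alt)$p_value,
                       wilcoxon_oracle(d, alt),
                       tolerance = 1e-12,
                       label = paste("n =", n, alt))
        }
      }
    }
  })
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")
})

test_that("wilcoxon normal approximation tracks the exact tail at n = 13", {
  withr::with_seed(37, {
    for (rep in 1:10) {
      d <- rnorm(13, 0.4)
      approx <- wilcoxon_signed_rank(d, "greater", exact_max = 12)$p_value
      exact <- wilcoxon_signed_rank(d, "greater", exact_max = 13)$p_value
      expect_lt(abs(approx - exact), 0.01)
    }
  })
})

test_that("wilcoxon agrees with stats::wilcox.test when conventions align", {
  withr::with_seed(41, {
    d <- rnorm(10, 0.5)                    # continuous: no ties, no zeros
    got <- wilcoxon_signed_rank(d, "two.sided")
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
    ## large-n normal approximation with continuity correction
    d <- rnorm(60, 0.2)
    got <- wilcoxon_signed_rank(d, "two.sided")
    ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  })
})

test_that("delta ecdf report shifts and orders as constructed", {
  withr::with_seed(43, {
    base <- rnorm(40, 0, 0.1)
    shifted <- base + 0.5
    rep <- delta_ecdf_report(list(background = base, force = shifted),
                             paired = TRUE)
    ## ecdf of the shifted set is the base ecdf translated by +0.5
    eb <- rep$ecdf[rep$ecdf$set == "background", ]
    ef <- rep$ecdf[rep$ecdf$set == "force", ]
    expect_equal(ef$delta, eb$delta + 0.5)
    expect_equal(ef$f, eb$f)
    ## the shifted set is significantly above zero and above background
    vz <- rep$vs_zero
    expect_lt(vz$p_value[vz$set == "force"], 1e-6)
    expect_lt(rep$vs_control$signed_rank_p, 1e-6)
  })
  expect_error(delta_ecdf_report(list(a = 1)), "2")
})

test_that("promoter entropy contrast is zero for identical tracks", {
  withr::with_seed(47, {
    d <- rpois(20000, 2)
    trk <- toy_track(d, chrom = "chrS")
    tss <- GRanges("chrS", IRanges(c(5000, 12000), width = 1),
                   strand = c("+", "-"))
    names(tss) <- c("g1", "g2")
    groups <- c(g1 = "weak_up", g2 = "weak_down")
    r <- promoter_entropy_contrast(trk, trk, trk, tss, groups,
                                   half_width = 1000)
    expect_equal(r$per_gene$dh_force, c(0, 0))
    expect_equal(r$per_gene$dh_force_oe, c(0, 0))
    expect_true(all(is.na(r$per_group$paired_p)))
  })
})

test_that("promoter entropy contrast matches hand-built single-gene case", {
  ## control: sharp promoter peak; force: same; force_oe: flattened
  L <- 4000
  ctrl <- rep(1, L); ctrl[1900:2100] <- 50
  oe <- rep(1, L); oe[1000:3000] <- 6
  t_ctrl <- toy_track(ctrl, chrom = "c"); t_oe <- toy_track(oe, chrom = "c")
  tss <- GRanges("c", IRanges(2000, width = 1)); names(tss) <- "g"
  r <- promoter_entropy_contrast(t_ctrl, t_ctrl, t_oe, tss,
                                 c(g = "weak_up"), half_width = 1500,
                                 eps = 0)
  win <- 501:3500
  h <- function(x) shannon_bits(x[win])
  expect_equal(r$per_gene$dh_force, 0)
  expect_equal(r$per_gene$dh_force_oe, h(oe) - h(ctrl), tolerance = 1e-9)
  expect_gt(r$per_gene$dh_force_oe, 0)
})
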