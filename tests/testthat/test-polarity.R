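test_that("orient_ses flips only SEs with the stronger right flank", {
  ## chromosome of 300 bases; SE body [101, 200]; flanks of width 100
  d <- c(rep(10, 100), rep(0, 100), rep(2, 100))
  me3 <- toy_track(d)
  ses <- GRanges("chr1", IRanges(101, 200))
  o <- orient_ses(ses, me3, flank_width = 100)
  expect_equal(o$left_flank_me3, 10)
  expect_equal(o$right_flank_me3, 2)
  expect_false(o$flipped)
  ## mirror image flips
  me3r <- toy_track(rev(d))
  or <- orient_ses(ses, me3r, flank_width = 100)
  expect_true(or$flipped)
  ## exact tie is not flipped
  ot <- orient_ses(ses, toy_track(rep(3, 300)), flank_width = 100)
  expect_false(ot$flipped)
})

test_that("edge-truncated and off-genome flanks are handled", {
  me3 <- toy_track(c(rep(5, 10), rep(0, 20)))
  ## SE starting at base 1: left flank entirely off-genome -> 0 + warning
  ses <- GRanges("chr1", IRanges(1, 10))
  expect_warning(o <- orient_ses(ses, me3, flank_width = 50), "edge")
  expect_equal(o$left_flank_me3, 0)
  ## right flank truncated to the on-genome bases [11, 30], all zero
  expect_equal(o$right_flank_me3, 0)
})

test_that("double orientation is the identity on flip flags", {
  study <- small_study(seed = 2)
  me3 <- study$tracks$H3K27me3_control_rep1
  truth <- manifest_se_granges(study$genome$manifest)
  o1 <- orient_ses(truth, me3)
  o2 <- orient_ses(o1, me3)
  expect_identical(o1$flipped, o2$flipped)
})

test_that("orientation recovers the planted H3K27me3 side", {
  study <- small_study(seed = 2)
  man <- study$genome$manifest
  truth <- manifest_se_granges(man)
  o <- orient_ses(truth, study$tracks$H3K27me3_control_rep1)
  ## planted me3 side: "left" blocks should not flip, "right" should
  want_flip <- man$se$me3_side == "right"
  expect_gte(mean(o$flipped == want_flip), 0.95)
})

test_that("binned SE matrix reproduces hand-computed block averages", {
  ## depth [0 x5, 2 x5] split into 2 body bins of 5 bases -> (0, 2)
  trk <- toy_track(c(rep(0, 5), rep(2, 5)), library_size = 1e6)
  ses <- GRanges("chr1", IRanges(1, 10))
  ses$flipped <- FALSE
  m <- binned_se_matrix(ses, trk, body_bins = 2, flank_bins = 0)
  expect_equal(unname(m$matrix[1, ]), c(0, 2))
  ## flipping reverses the row
  ses$flipped <- TRUE
  mf <- binned_se_matrix(ses, trk, body_bins = 2, flank_bins = 0)
  expect_equal(unname(mf$matrix[1, ]), c(2, 0))
  ## constant track -> constant row at the normalized density
  ct <- toy_track(rep(3, 1000), library_size = 2e6)
  cs <- GRanges("chr1", IRanges(101, 800)); cs$flipped <- FALSE
  mc <- binned_se_matrix(cs, ct, body_bins = 7, flank_bins = 2,
                         flank_width = 100)
  expect_equal(unname(mc$matrix[1, ]), rep(1.5, 11))
  expect_equal(sum(mc$is_body), 7)
})

test_that("proportional binning conserves total mass for awkward lengths", {
  withr::with_seed(79, {
    for (i in 1:20) {
      L <- sample(11:257, 1)
      d <- rpois(L, 3)
      trk <- toy_track(d, library_size = 1e6)
      ses <- GRanges("chr1", IRanges(1, L)); ses$flipped <- FALSE
      nb <- sample(2:10, 1)
      m <- binned_se_matrix(ses, trk, body_bins = nb, flank_bins = 0)
      ## sum of (bin mean x bin width) equals total normalized mass
      expect_equal(sum(m$matrix[1, ]) * (L / nb), sum(d),
                   tolerance = 1e-9)
    }
  })
})

test_that("center-aligned heatmap centers, flips, and length-sorts rows", {
  d <- rep(0, 1000); d[496:505] <- 8
  trk <- toy_track(d, library_size = 1e6)
  ses <- GRanges("chr1", IRanges(c(481, 301), c(520, 700)))
  names(ses) <- c("short", "long")
  ses$flipped <- c(FALSE, FALSE)
  mat <- center_aligned_heatmap(ses, trk, window = 40, flank_pad = 0,
                                log2_eps = 1)
  ## longest SE first
  expect_equal(rownames(mat), c("long", "short"))
  ## the short SE (centered on the signal block) shows it mid-row
  mid <- ncol(mat) %/% 2 + 1
  expect_equal(unname(mat["short", mid]), log2(8 + 1))
  expect_equal(unname(mat["short", 1]), log2(0 + 1))
  ## a flipped asymmetric row equals the reverse of its unflipped self
  d2 <- rep(0, 1000); d2[481:490] <- 4
  trk2 <- toy_track(d2, library_size = 1e6)
  su <- GRanges("chr1", IRanges(481, 520)); su$flipped <- FALSE
  sf <- su; sf$flipped <- TRUE
  mu <- center_aligned_heatmap(su, trk2, window = 40, log2_eps = 1)
  mv <- center_aligned_heatmap(sf, trk2, window = 40, log2_eps = 1)
  expect_equal(unname(mv[1, ]), rev(unname(mu[1, ])))
})

test_that("se_set_overlap counts shared and unique intervals", {
  A <- GRanges("chr1", IRanges(c(1, 201), c(100, 300)))
  B <- GRanges("chr1", IRanges(50, 150))
  r <- se_set_overlap(list(A = A, B = B))
  expect_equal(r$A$n, 2)
  expect_equal(r$A$shared, 1)
  expect_equal(r$A$unique, 1)
  expect_equal(r$B$shared, 1)
  expect_equal(r$B$unique, 0)
  expect_equal(as.numeric(r$A$classes[c("A", "A+B")]), c(1, 1))
  ## duplicates are removed with a warning
  expect_warning(r2 <- se_set_overlap(list(A = c(A, A[1]), B = B)),
                 "duplicate")
  expect_equal(r2$A$n, 2)
  ## three-way: shared means overlapping both other sets
  C <- GRanges("chr1", IRanges(90, 120))
  r3 <- se_set_overlap(list(A = A, B = B, C = C))
  expect_equal(r3$A$shared, 1)
  expect_equal(r3$C$shared, 1)
  expect_error(se_set_overlap(list(A = A)), "2")
})

test_that("unique + partially-shared + fully-shared partition each set", {
  withr::with_seed(83, {
    for (i in 1:10) {
      mk <- function() {
        n <- sample(3:15, 1)
        GRanges("chr1", IRanges(start = sample.int(2e4, n),
                                width = sample(50:500, n, TRUE)))
      }
      sets <- list(X = unique(mk()), Y = unique(mk()), Z = unique(mk()))
      r <- suppressWarnings(se_set_overlap(sets))
      for (nm in names(sets)) {
        cls <- r[[nm]]$classes
        expect_equal(sum(cls), r[[nm]]$n)
        expect_gte(r[[nm]]$n, r[[nm]]$unique + r[[nm]]$shared)
      }
    }
  })
})
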