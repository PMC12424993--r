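mm_from <- function(frac, coverage = 20L, spacing = 100L) {
  # frac: sites x sublines matrix of methylation fractions
  subl <- sprintf("M%d", seq_len(ncol(frac)))
  colnames(frac) <- subl
  nt <- matrix(coverage, nrow(frac), ncol(frac),
               dimnames = list(NULL, subl))
  methyl_matrix(data.frame(chrom = "chr1",
                           pos = spacing * seq_len(nrow(frac))),
                round(frac * coverage), nt)
}

test_that("smoothing is constant-invariant and identity on isolated sites", {
  mm <- mm_from(matrix(0.8, 50, 4))
  sm <- smooth_methylation(mm, dmr_params(smoothing_window = 500))
  expect_true(all(abs(sm$smoothed - 0.8) < 1e-12))
  # isolated sites (window smaller than spacing) keep the raw fraction
  frac <- matrix(runif(40), 10, 4)
  mm2 <- mm_from(frac, spacing = 5000L)
  sm2 <- smooth_methylation(mm2, dmr_params(smoothing_window = 100))
  expect_equal(unname(sm2$smoothed), unname(round(frac * 20) / 20),
               tolerance = 1e-12)
})

test_that("smoothing a step profile stays monotone across the step", {
  frac <- matrix(rep(c(rep(0, 25), rep(1, 25)), 2), ncol = 2)
  mm <- mm_from(frac)
  sm <- smooth_methylation(mm, dmr_params(smoothing_window = 600))
  expect_true(all(diff(sm$smoothed[, 1]) >= -1e-12))
})

test_that("low-coverage CpGs are excluded before smoothing", {
  subl <- c("M1", "M2", "M3", "M4")
  nt <- matrix(10L, 6, 4, dimnames = list(NULL, subl))
  nt[3, 2] <- 2L   # below min_cov in one subline
  nm <- matrix(5L, 6, 4, dimnames = list(NULL, subl))
  nm[3, 2] <- 1L
  mm <- methyl_matrix(data.frame(chrom = "chr1", pos = 1:6 * 100L), nm, nt)
  sm <- smooth_methylation(mm, dmr_params(min_cov = 3))
  expect_equal(nrow(sm$sites), 5L)
  expect_false(300L %in% sm$sites$pos)
})

test_that("t statistics are zero-centred, floored and anti-symmetric", {
  set.seed(4)
  frac <- matrix(runif(400, 0.4, 0.6), 100, 4)
  frac[1:20, 1:2] <- frac[1:20, 1:2] + 0.3
  mm <- mm_from(frac)
  sm <- smooth_methylation(mm, dmr_params(smoothing_window = 150))
  st <- cpg_t_statistics(sm, c("M1", "M2"), c("M3", "M4"))
  # anti-symmetry under group swap
  st_rev <- cpg_t_statistics(sm, c("M3", "M4"), c("M1", "M2"))
  expect_equal(st$t, -st_rev$t)
  expect_equal(st$mean_diff, -st_rev$mean_diff)
  # shifted block gets the top ranks
  expect_true(all(st$qrank[1:20] > 0.8))
  expect_error(cpg_t_statistics(sm, "M1", c("M2", "M3")), "at least 2")
  # identical groups: all t zero, ranks tie at 0.5
  mm0 <- mm_from(matrix(rep(runif(50, 0.3, 0.7), 4), ncol = 4))
  sm0 <- smooth_methylation(mm0, dmr_params(smoothing_window = 150))
  st0 <- cpg_t_statistics(sm0, c("M1", "M2"), c("M3", "M4"))
  expect_true(all(st0$t == 0))
  expect_true(all(abs(st0$qrank - 0.5) < 1e-9))
})

test_that("DMR calling needs run length, same side and effect size", {
  base <- data.frame(chrom = "chr1", pos = 100L * 1:40, t = 0,
                     qrank = 0.5, mean_diff = 0)
  qualify <- function(d, idx, diff = 0.3, side = 0.99) {
    d$qrank[idx] <- side
    d$mean_diff[idx] <- diff
    d
  }
  p <- dmr_params(min_cpgs = 10)
  # 10 consecutive qualifying CpGs with diff 0.3: one DMR
  d1 <- call_dmrs(qualify(base, 1:10), p)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$n_cpgs, 10L)
  expect_equal(d1$direction, "hyper")
  # 9 consecutive: none
  expect_equal(nrow(call_dmrs(qualify(base, 1:9), p)), 0L)
  # 12 consecutive with mean diff 0.15: none
  expect_equal(nrow(call_dmrs(qualify(base, 1:12, diff = 0.15), p)), 0L)
  # opposite sides split the run
  d2 <- qualify(qualify(base, 1:10), 11:20, diff = -0.3, side = 0.001)
  got <- call_dmrs(d2, p)
  expect_equal(nrow(got), 2L)
  expect_setequal(got$direction, c("hyper", "hypo"))
})

test_that("swapping case and control flips DMR direction, not intervals", {
  b <- small_bundle
  cl <- b$caterpillar$clades
  case <- cl[[2]]
  control <- setdiff(b$tree$tip.label, case)
  p <- dmr_params(min_cpgs = 5)
  d1 <- dmr_pipeline(b$methylation, case, control, p)
  d2 <- dmr_pipeline(b$methylation, control, case, p)
  expect_equal(d1[, c("chrom", "start", "end", "n_cpgs")],
               d2[, c("chrom", "start", "end", "n_cpgs")])
  expect_equal(d1$mean_diff, -d2$mean_diff)
  expect_true(all(d1$direction != d2$direction) || nrow(d1) == 0)
  expect_gt(nrow(d1), 0)  # planted branch-shift regions are detectable
})

test_that("degenerate parameters report every CpG beyond the cutoffs", {
  set.seed(5)
  frac <- matrix(runif(200, 0.2, 0.8), 50, 4)
  mm <- mm_from(frac)
  sm <- smooth_methylation(mm, dmr_params(smoothing_window = 10))
  st <- cpg_t_statistics(sm, c("M1", "M2"), c("M3", "M4"))
  p0 <- dmr_params(min_cpgs = 1, min_meandiff = 0)
  got <- call_dmrs(st, p0)
  expect_equal(sum(got$n_cpgs),
               sum(st$qrank < 0.025 | st$qrank > 0.975))
})

test_that("the permutation null enumerates assignments exhaustively", {
  mm <- simulate_exchangeable_methylation(n_sublines = 8, n_regions = 10,
                                          seed = 99)
  pt <- dmr_count_permutation_test(mm, case = mm$sublines[1:2],
                                   params = dmr_params(min_cpgs = 3),
                                   n_perm = 1000, seed = 1)
  expect_true(pt$exhaustive)
  expect_equal(length(pt$null_counts), choose(8, 2))
  expect_gte(pt$p, 1 / choose(8, 2))
  expect_error(
    dmr_count_permutation_test(mm, case = mm$sublines[1:7]),
    "case size")
})

test_that("caterpillar cuts produce the nested suffix case groups", {
  ord <- sprintf("L%d", 1:8)
  cuts <- caterpillar_cuts(ord)
  expect_equal(vapply(cuts, function(x) length(x$case), integer(1)),
               c(5L, 4L, 3L, 2L))
  expect_equal(cuts[[1]]$case, ord[4:8])
  expect_equal(cuts[[4]]$control, ord[1:6])
  expect_true(all(vapply(cuts, function(x)
    length(x$case) >= 2 && length(x$control) >= 2, logical(1))))
  expect_equal(length(caterpillar_cuts(sprintf("L%d", 1:4))), 1L)
  expect_error(caterpillar_cuts(sprintf("L%d", 1:3)), "at least 4")
})

test_that("overlapping DMR intervals from different cuts merge", {
  dmrs <- data.frame(chrom = "chr1", start = c(0L, 50L, 200L),
                     end = c(100L, 150L, 300L))
  m <- merge_dmr_intervals(dmrs)
  expect_equal(nrow(m), 2L)
  expect_equal(c(m$start, m$end), c(0L, 200L, 150L, 300L))
})
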