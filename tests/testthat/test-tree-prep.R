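# Builders for compact site-level fixtures: one row per subline.
site_calls <- function(pos, status, depth, alt_depth,
                       sublines = sprintf("S%d", seq_along(status))) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
             subline = sublines, status = status, depth = depth,
             alt_depth = alt_depth, stringsAsFactors = FALSE)
}

test_that("private and clonal sites are dropped as uninformative", {
  calls <- rbind(
    site_calls(100L, c("present", rep("absent", 4)), rep(30L, 5),
               c(15L, 0L, 0L, 0L, 0L)),
    site_calls(200L, rep("present", 5), rep(30L, 5), rep(15L, 5)),
    site_calls(300L, c("present", "present", "absent", "absent", "absent"),
               rep(30L, 5), c(15L, 15L, 0L, 0L, 0L)))
  gm <- prepare_tree_snvs(calls)
  expect_equal(nrow(gm$sites), 1L)
  expect_equal(gm$sites$pos, 300L)
  expect_equal(unname(gm$audit["uninformative"]), 2L)
})

test_that("low-coverage entries become missing at the inclusive cutoff", {
  calls <- rbind(
    site_calls(100L, c("present", "present", "present", "absent", "absent"),
               c(9L, 12L, 30L, 30L, 30L), c(4L, 6L, 15L, 0L, 0L)),
    site_calls(200L, c("present", "present", "absent", "absent", "absent"),
               rep(30L, 5), c(15L, 15L, 0L, 0L, 0L)))
  gm <- prepare_tree_snvs(calls)
  row1 <- which(gm$sites$pos == 100L)
  expect_equal(unname(gm$status[row1, "S1"]), "missing")   # depth 9 <= 10
  expect_equal(unname(gm$status[row1, "S2"]), "present")   # depth 12 > 10
})

test_that("VAF rule drops a site only when both mean and median are low", {
  mk <- function(pos, vafs) {
    site_calls(pos, c(rep("present", 3), "absent", "absent"), rep(30L, 5),
               c(as.integer(round(vafs * 30)), 0L, 0L))
  }
  calls <- rbind(mk(100L, c(0.5, 0.5, 0.1)),   # mean .367 >= 1/3, kept
                 mk(200L, c(0.3, 0.3, 0.3)),   # mean = median = .3, dropped
                 mk(300L, c(0.5, 0.5, 0.5)))
  gm <- prepare_tree_snvs(calls)
  expect_setequal(gm$sites$pos, c(100L, 300L))
  expect_equal(unname(gm$audit["low_vaf"]), 1L)
  # a left-skewed site (VAFs 1/30, 14/30, 14/30: mean .322 below 1/3,
  # median .467 above) separates the two readings
  skew <- site_calls(500L, c(rep("present", 3), "absent", "absent"),
                     rep(30L, 5), c(1L, 14L, 14L, 0L, 0L))
  expect_equal(nrow(prepare_tree_snvs(skew)$sites), 1L)
  expect_equal(nrow(prepare_tree_snvs(skew,
                                      filter_logic = "either")$sites), 0L)
})

test_that("alt support in half of the absent sublines drops the site", {
  calls <- rbind(
    site_calls(100L, c("present", "absent", "absent", "absent", "absent"),
               rep(30L, 5), c(15L, 2L, 1L, 0L, 0L)),
    site_calls(100L, "present", 30L, 15L, "S6"),
    site_calls(200L, c("present", "present", "absent", "absent", "absent"),
               rep(30L, 5), c(15L, 15L, 0L, 0L, 0L)),
    site_calls(200L, "absent", 30L, 0L, "S6"))
  gm <- prepare_tree_snvs(calls)
  # site 100: 2 of 4 absent sublines have alt reads -> dropped
  expect_equal(gm$sites$pos, 200L)
  expect_equal(unname(gm$audit["alt_in_absent"]), 1L)
})

test_that("loss-overlap filter agrees with a brute-force interval scan", {
  set.seed(11)
  n <- 400L
  pos <- sort(sample.int(100000L, n))
  calls <- do.call(rbind, lapply(seq_len(n), function(i) {
    site_calls(pos[i], c("present", "present", "absent"), rep(30L, 3),
               c(15L, 15L, 0L), sublines = c("S1", "S2", "S3"))
  }))
  losses <- data.frame(chrom = "chr1",
                       start = c(5000L, 30000L, 70000L),
                       end = c(10000L, 31000L, 90000L),
                       subline = "S3", stringsAsFactors = FALSE)
  gm <- prepare_tree_snvs(calls, losses)
  inside <- vapply(pos, function(p) {
    any(losses$start <= p - 1L & losses$end > p - 1L)
  }, logical(1))
  expect_setequal(gm$sites$pos, pos[!inside])
  expect_equal(unname(gm$audit["loss_overlap"]), sum(inside))
})

test_that("audit counts sum to input minus output sites", {
  b <- small_bundle
  gm <- prepare_tree_snvs(b$snv_full, b$losses)
  a <- gm$audit
  expect_equal(sum(a[c("loss_overlap", "uninformative",
                       "low_site_coverage", "low_vaf", "alt_in_absent")]),
               unname(a["input_sites"] - a["output_sites"]))
})

test_that("clean synthetic data loses sites only to informativeness", {
  cfg <- sim_config(seed = 19L, n_sublines = 10L, n_clades = 2L,
                    caterpillar_size = 6L, n_snvs = 200L, fn_rate = 0,
                    fp_rate = 0, n_cna_events = 0L, n_svs = 10L,
                    snv_depth = 40)
  b <- simulate_dataset(cfg)
  losses_in_snv_zone <- b$losses[b$losses$end < 0.6 * cfg$chrom_length, ]
  gm <- prepare_tree_snvs(b$snv_full, losses_in_snv_zone)
  expect_equal(unname(gm$audit["loss_overlap"]), 0L)
  expect_equal(unname(gm$audit["low_vaf"]), 0L)
  expect_equal(unname(gm$audit["alt_in_absent"]), 0L)
  expect_gt(gm$audit["uninformative"], 0L)
})

test_that("genotype matrix export round-trips and encodes 1/0/?", {
  calls <- rbind(
    site_calls(100L, c("present", "absent", "present"), c(30L, 30L, 5L),
               c(15L, 0L, 2L), sublines = c("S1", "S2", "S3")),
    site_calls(200L, c("present", "present", "absent"), rep(30L, 3),
               c(15L, 15L, 0L), sublines = c("S1", "S2", "S3")))
  gm <- prepare_tree_snvs(calls, params = site_filter_params(
    site_cov_min = 0L, vaf_min = 0.01))
  tf <- withr::local_tempfile(fileext = ".tsv")
  export_genotype_matrix(gm, tf)
  raw <- utils::read.delim(tf, colClasses = "character")
  expect_equal(raw$S3[raw$pos == "100"], "?")
  expect_equal(raw$S1[raw$pos == "100"], "1")
  expect_equal(raw$S2[raw$pos == "100"], "0")
  back <- read_genotype_matrix(tf)
  expect_equal(back$status, gm$status, ignore_attr = TRUE)
  expect_equal(back$sites$pos, gm$sites$pos)
})

test_that("empty input yields an empty matrix with a zeroed audit", {
  gm <- prepare_tree_snvs(NULL)
  expect_equal(nrow(gm$sites), 0L)
  expect_true(all(gm$audit == 0L))
})
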