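genes3 <- data.frame(
  gene = c("g1", "g2", "g3"), chrom = "chr1",
  start = c(1000L, 9500L, 20000L), end = c(2000L, 10500L, 21000L),
  label = c("ONC", "TSG", "ND"), stringsAsFactors = FALSE)

segs3 <- data.frame(
  chrom = "chr1", start = c(0L, 10000L, 19000L),
  end = c(10000L, 19000L, 22000L), copy_number = c(3L, 2L, 1L),
  subline = "S1", stringsAsFactors = FALSE)

test_that("gene status requires full containment in an altered segment", {
  st <- gene_cn_status(genes3, segs3)
  expect_equal(st$status[st$gene == "g1"], "gain")    # inside CN=3
  expect_equal(st$status[st$gene == "g2"], "neutral") # straddles boundary
  expect_equal(st$status[st$gene == "g3"], "loss")    # inside CN=1
  cn <- gene_absolute_cn(genes3, segs3)
  expect_equal(unname(cn["g1", "S1"]), 3)
  expect_true(is.na(cn["g2", "S1"]))
  expect_equal(unname(cn["g3", "S1"]), 1)
})

test_that("enrichment tests flag fully separated labels", {
  status <- data.frame(
    gene = sprintf("g%02d", 1:20),
    subline = "S1",
    status = rep(c("gain", "loss"), each = 10), stringsAsFactors = FALSE)
  labels <- stats::setNames(rep(c("ONC", "TSG"), each = 10), status$gene)
  r <- onc_tsg_enrichment_tests(status, labels)
  expect_lt(r$gain$p, 0.01)
  expect_lt(r$loss$p, 0.01)
  expect_equal(unname(r$gain$table[1, 1]), 10)   # all ONC gained-only
  expect_error(onc_tsg_enrichment_tests(status[0, ], labels), "empty")
})

test_that("label-independent status gives uniform chi-squared p values", {
  ps <- vapply(1:200, function(s) {
    set.seed(6000 + s)
    n <- 60
    status <- data.frame(gene = sprintf("g%02d", 1:n), subline = "S1",
                         status = sample(c("gain", "loss"), n, TRUE),
                         stringsAsFactors = FALSE)
    labels <- stats::setNames(sample(c("ONC", "TSG"), n, TRUE),
                              status$gene)
    suppressWarnings(onc_tsg_enrichment_tests(status, labels)$gain$p)
  }, numeric(1))
  # chi-squared p under independence: roughly uniform (discreteness aside)
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)
})

test_that("boundary orientation counts ONC-high pairs and is
           orientation-invariant", {
  genes <- data.frame(
    gene = c("a", "b", "c", "d"), chrom = "chr1",
    start = c(1000L, 11000L, 21000L, 31000L),
    end = c(2000L, 12000L, 22000L, 32000L),
    label = c("ONC", "TSG", "ONC", "TSG"), stringsAsFactors = FALSE)
  segs <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                     end = c(10000L, 40000L), copy_number = c(4L, 2L),
                     subline = "S1", stringsAsFactors = FALSE)
  r <- boundary_orientation_test(genes, segs, n_perm = 200, seed = 1)
  expect_equal(r$observed, 1L)   # a(ONC, CN4) | b(TSG, CN2)
  # reversing the genome flips coordinates but not the high/low sides
  flip <- genes
  flip$start <- 50000L - genes$end
  flip$end <- 50000L - genes$start
  fsegs <- segs
  fsegs$start <- 50000L - segs$end
  fsegs$end <- 50000L - segs$start
  r2 <- boundary_orientation_test(flip, fsegs, n_perm = 200, seed = 1)
  expect_equal(r2$observed, r$observed)
  # all pairs oriented ONC-high: observed equals the pair count and the
  # permutation p is small
  genes_all <- data.frame(
    gene = sprintf("g%d", 1:12), chrom = "chr1",
    start = (0:11) * 10000L + 1000L, end = (0:11) * 10000L + 2000L,
    label = rep(c("ONC", "TSG"), 6), stringsAsFactors = FALSE)
  segs_all <- data.frame(chrom = "chr1", start = (0:11) * 10000L,
                         end = (1:12) * 10000L,
                         copy_number = rep(c(4L, 2L), 6), subline = "S1",
                         stringsAsFactors = FALSE)
  # every one of the 11 consecutive pairs alternates ONC/TSG and CN 4/2
  # with the ONC gene on the CN=4 side
  r3 <- boundary_orientation_test(genes_all, segs_all, n_perm = 500,
                                  seed = 1)
  expect_equal(r3$observed, 11L)
  expect_lt(r3$p, 0.05)
  # no eligible pairs: p = 1 with a warning
  expect_warning(
    r4 <- boundary_orientation_test(genes_all[1, ], segs_all, n_perm = 10,
                                    seed = 1),
    "no adjacent")
  expect_equal(r4$p, 1)
})

test_that("single-pair permutation p matches exact enumeration", {
  genes <- data.frame(
    gene = c("a", "b", "c", "d"), chrom = "chr1",
    start = c(1000L, 11000L, 110000L, 120000L),
    end = c(2000L, 12000L, 111000L, 121000L),
    label = c("ONC", "TSG", "ND", "ND"), stringsAsFactors = FALSE)
  segs <- data.frame(chrom = "chr1", start = c(0L, 10000L),
                     end = c(10000L, 200000L), copy_number = c(4L, 2L),
                     subline = "S1", stringsAsFactors = FALSE)
  r <- boundary_orientation_test(genes, segs, n_perm = 4000, seed = 2)
  expect_equal(r$observed, 1L)
  # exact: of the 4!/2!/1!/1! = 12 label arrangements, count those with
  # ONC at gene a and TSG at gene b (the only differing-CN adjacency in
  # this layout is a|b; c|d never differ) -> 1/12
  expect_equal(r$p, 1 / 12, tolerance = 0.05)
})

test_that("copy-neutral LOH timing matches 2H/(C+H) in both scenarios", {
  expect_equal(cn_loh_timing(0, 100), 0)
  expect_equal(cn_loh_timing(100, 100), 1)
  expect_equal(cn_loh_timing(100, 255), 200 / 355)
  expect_equal(cn_loh_timing(100, 255, "nondisjunction_then_loh"),
               200 / 355)
  expect_error(cn_loh_timing(10, 0), "positive")
  expect_error(cn_loh_timing(10, 5), "exceeds")
  # scenario equivalence over random inputs
  set.seed(8)
  C <- sample.int(10000, 500)
  H <- vapply(C, function(x) sample.int(x, 1), integer(1))
  expect_equal(cn_loh_timing(H, C),
               cn_loh_timing(H, C, "nondisjunction_then_loh"))
})
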