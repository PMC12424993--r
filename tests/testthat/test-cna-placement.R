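test_that("gain/loss ranges are extracted against the diploid baseline", {
  segs <- data.frame(chrom = "chr1",
                     start = c(0L, 1000L, 2000L, 5000L),
                     end = c(1000L, 2000L, 3000L, 6000L),
                     copy_number = c(3L, 4L, 2L, 1L), subline = "S1",
                     stringsAsFactors = FALSE)
  r <- extract_cn_ranges(segs)
  gains <- r[r$direction == "gain", ]
  # adjacent CN=3 and CN=4 merge into one gain range
  expect_equal(nrow(gains), 1L)
  expect_equal(c(gains$start, gains$end), c(0L, 2000L))
  losses <- r[r$direction == "loss", ]
  expect_equal(c(losses$start, losses$end), c(5000L, 6000L))
  # CN=2 emits nothing
  expect_equal(nrow(extract_cn_ranges(
    data.frame(chrom = "chr1", start = 0L, end = 10L, copy_number = 2L,
               subline = "S1"))), 0L)
})

test_that("a shared range lands once on the clade branch, not on leaves", {
  segs <- data.frame(chrom = "chr1", start = 0L, end = 1000L,
                     copy_number = 3L, subline = c("A", "B"),
                     stringsAsFactors = FALSE)
  out <- place_cnas(extract_cn_ranges(segs), balanced4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$node_label, node_label(balanced4,
                                          mrca_node(balanced4, c("A", "B"))))
  expect_equal(out$sublines, "A,B")
  expect_equal(c(out$start, out$end), c(0L, 1000L))
})

test_that("phase 3 splits a private extension off a clade range", {
  # A carries [0,150), B carries [0,100): the shared [0,100) goes to the
  # clade branch, the remainder [100,150) stays private to A
  segs <- data.frame(chrom = "chr1", start = c(0L, 100L, 0L),
                     end = c(100L, 150L, 100L), copy_number = 3L,
                     subline = c("A", "A", "B"), stringsAsFactors = FALSE)
  out <- place_cnas(extract_cn_ranges(segs), balanced4)
  out <- out[order(out$start), ]
  expect_equal(nrow(out), 2L)
  clade <- out[out$n_sublines == 2, ]
  expect_equal(c(clade$start, clade$end), c(0L, 100L))
  priv <- out[out$n_sublines == 1, ]
  expect_equal(c(priv$start, priv$end), c(100L, 150L))
  expect_equal(priv$sublines, "A")
  expect_equal(priv$clonality, "private")
})

test_that("parallel events in different clades stay on different branches", {
  # overlapping gains with distinct breakpoints in two whole clades of a
  # 12-leaf tree: their union (8) misses the trunk threshold (10), so the
  # two events survive as separate branch ranges with their own
  # breakpoints
  tr12 <- validate_tree(ape::read.tree(
    text = paste0("(((A1,A2),(A3,A4)),(((B1,B2),(B3,B4)),",
                  "((C1,C2),(C3,C4))));")))
  segs <- data.frame(chrom = "chr1",
                     start = c(rep(0L, 4), rep(50L, 4)),
                     end = c(rep(100L, 4), rep(160L, 4)), copy_number = 3L,
                     subline = c(sprintf("A%d", 1:4), sprintf("C%d", 1:4)),
                     stringsAsFactors = FALSE)
  out <- place_cnas(extract_cn_ranges(segs), tr12)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$sublines, c("A1,A2,A3,A4", "C1,C2,C3,C4"))
  expect_setequal(out$node_label,
                  node_label(tr12, c(mrca_node(tr12, sprintf("A%d", 1:4)),
                                     mrca_node(tr12, sprintf("C%d", 1:4)))))
  # intervals keep their own breakpoints
  expect_setequal(paste(out$start, out$end), c("0 100", "50 160"))
})

test_that("gains and losses are processed as disjoint pools", {
  segs <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                     copy_number = c(3L, 1L), subline = c("A", "B"),
                     stringsAsFactors = FALSE)
  out <- place_cnas(extract_cn_ranges(segs), balanced4)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$direction, c("gain", "loss"))
  expect_true(all(out$n_sublines == 1L))  # never combined across direction
})

test_that("assigned spans are disjoint along any root-to-leaf path", {
  # a nested construction: clade-wide gain with a private extension
  segs <- data.frame(chrom = "chr1", start = c(0L, 100L, 0L),
                     end = c(100L, 150L, 100L), copy_number = 3L,
                     subline = c("A", "A", "B"), stringsAsFactors = FALSE)
  nested <- place_cnas(extract_cn_ranges(segs), balanced4)
  path_a <- c(1L, tree_ancestors(balanced4, 1L))
  ir <- IRanges::IRanges(nested$start[nested$node %in% path_a] + 1L,
                         nested$end[nested$node %in% path_a])
  expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
               sum(IRanges::width(ir)))
  b <- small_bundle
  out <- place_cnas(extract_cn_ranges(b$cnas), b$tree)
  expect_true(all(!is.na(out$node)))
  for (leaf in seq_along(b$tree$tip.label)) {
    path <- c(leaf, tree_ancestors(b$tree, leaf))
    on_path <- out[out$node %in% path, , drop = FALSE]
    for (dir in unique(on_path$direction)) {
      for (chr in unique(on_path$chrom)) {
        d <- on_path[on_path$direction == dir & on_path$chrom == chr, ]
        if (nrow(d) < 2) next
        ir <- IRanges::IRanges(d$start + 1L, d$end)
        expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                     sum(IRanges::width(ir)))
      }
    }
  }
})

test_that("planted CNA events are recovered on their true branches", {
  b <- small_bundle
  out <- place_cnas(extract_cn_ranges(b$cnas), b$tree)
  ev <- b$truth$cna_events
  for (i in seq_len(nrow(ev))) {
    hit <- out[out$node_label == ev$true_node_label[i] &
                 out$chrom == ev$chrom[i] &
                 out$start == ev$start[i] & out$end == ev$end[i], ]
    expect_equal(nrow(hit), 1L)
  }
})
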