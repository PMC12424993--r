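make_placements <- function(ids, nodes, types = "SNV") {
  data.frame(variant_id = ids, type = types, chrom = "chr1",
             pos = seq_along(ids), node = nodes, node_label = "x",
             clonality = "subclonal", support = 1L, clade_size = 1L,
             regenotyped_sublines = "", stringsAsFactors = FALSE)
}

test_that("signature assignment sums subtree probabilities and breaks ties", {
  tr <- balanced4
  pl <- make_placements(c("m1", "m2", "m3"),
                        c(1L, mrca_node(tr, c("A", "B")), 2L))
  probs <- rbind(
    data.frame(mutation_id = "m1", subline = "A",
               signature = c("SBS7", "SBS5"), probability = c(0.9, 0.1)),
    # two sublines: (0.6,0.4) and (0.3,0.7) -> sums (0.9,1.1)
    data.frame(mutation_id = "m2", subline = c("A", "A", "B", "B"),
               signature = c("SBS7", "SBS5", "SBS7", "SBS5"),
               probability = c(0.6, 0.4, 0.3, 0.7)),
    # exact tie -> first name alphabetically
    data.frame(mutation_id = "m3", subline = "B",
               signature = c("SBSb", "SBSa"), probability = c(0.5, 0.5)))
  lab <- assign_branch_signatures(pl, probs, tr)
  expect_equal(lab$signature, c("SBS7", "SBS5", "SBSa"))
  # a mutation with no rows gets NA with a warning
  pl2 <- make_placements("m9", 1L)
  expect_warning(lab2 <- assign_branch_signatures(pl2, probs, tr),
                 "no signature")
  expect_true(is.na(lab2$signature))
})

test_that("branch activities aggregate sub-lettered signatures", {
  labels <- data.frame(variant_id = sprintf("m%d", 1:4), node = 5L,
                       signature = c("SBS7a", "SBS7b", "SBS5", "SBS5"),
                       stringsAsFactors = FALSE)
  act <- branch_activity(labels)
  expect_setequal(act$signature, c("SBS7", "SBS5"))
  expect_equal(act$activity[act$signature == "SBS7"], 0.5)
  expect_equal(act$activity[act$signature == "SBS5"], 0.5)
  expect_true(all(act$mutation_count == 4L))
  # activities sum to one per branch; aggregation keeps the count
  expect_equal(sum(act$activity), 1)
  # single signature -> activity 1
  one <- branch_activity(data.frame(variant_id = "m1", node = 5L,
                                    signature = "SBS1"))
  expect_equal(one$activity, 1)
  # no labelled mutations -> empty frame
  expect_equal(nrow(branch_activity(
    data.frame(variant_id = "m1", node = 5L,
               signature = NA_character_))), 0L)
})

test_that("cumulative dN/dS follows the site-normalized ratio", {
  expect_equal(cumulative_dnds(5, 5, 100, 100), 1)
  expect_equal(cumulative_dnds(6, 2, 100, 300), 1)   # (6/2) x (1/3)
  expect_equal(cumulative_dnds(0, 3, 100, 300), 0)
  expect_true(is.na(cumulative_dnds(3, 0, 100, 300)))
  # splitting a branch into two consecutive branches with the same pooled
  # cumulative counts leaves the value unchanged
  expect_equal(cumulative_dnds(4 + 2, 3 + 1, 100, 300),
               cumulative_dnds(6, 4, 100, 300))
})

test_that("cumulative branch counts are non-decreasing along root paths", {
  b <- small_bundle
  fit <- harmonize_tree(b$tree, snvs = b$snvs, svs = b$svs,
                        losses = b$losses)
  counts <- branch_counts(fit, annotations = b$annotations)
  for (leaf in seq_along(b$tree$tip.label)) {
    path <- rev(c(leaf, tree_ancestors(b$tree, leaf)))  # root .. leaf
    cum <- counts$cumulative_snv_count[path]
    expect_true(all(diff(cum) >= 0))
  }
  # per-branch counts sum to the number of placed variants
  expect_equal(sum(counts$snv_count),
               sum(!is.na(fit$placements$node) &
                     fit$placements$type == "SNV"))
})

test_that("branch SNV/SV correlation behaves at the extremes", {
  counts <- data.frame(snv_count = c(2L, 4L, 8L, 16L),
                       sv_count = c(4L, 8L, 16L, 32L))
  r <- branch_count_correlation(counts)
  expect_equal(r$r, 1)
  expect_error(branch_count_correlation(counts[1:2, ]), "at least")
  const <- data.frame(snv_count = c(3L, 3L, 3L), sv_count = c(1L, 2L, 3L))
  expect_true(is.na(branch_count_correlation(const)$r))
})

test_that("independent branch counts give CIs that cover zero", {
  covers <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    counts <- data.frame(snv_count = rpois(20, 10), sv_count = rpois(20, 5))
    if (sd(counts$snv_count) == 0 || sd(counts$sv_count) == 0) return(TRUE)
    ci <- stats::cor.test(counts$snv_count, counts$sv_count)$conf.int
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gte(mean(covers), 0.9)
})

test_that("group tests exclude degenerate groups and detect separation", {
  # identical values in two groups: adjusted p near 1
  r <- branch_group_tests(rep(c(1, 1), each = 5),
                          rep(c("internal", "terminal"), each = 5))
  expect_gt(r$pairs$p_adj, 0.99)
  # two groups 10 pooled SDs apart
  set.seed(1)
  vals <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  r2 <- branch_group_tests(vals, rep(c("a", "b"), each = 10))
  expect_lt(r2$pairs$p_adj, 0.001)
  # singleton group is dropped with a warning
  expect_warning(
    r3 <- branch_group_tests(c(vals, 5), c(rep(c("a", "b"), each = 10),
                                           "c")),
    "singleton")
  expect_false(any(grepl("c", r3$pairs$pair)))
  # NA labels are excluded entirely
  r4 <- branch_group_tests(c(vals, 5, 6), c(rep(c("a", "b"), each = 10),
                                            NA, NA))
  expect_equal(nrow(r4$pairs), 1L)
})

test_that("the tree-builder prior grid enumerates fp x fn x permutations", {
  g <- tree_search_grid()
  expect_equal(nrow(g), 8 * 7 * 100)
  g2 <- tree_search_grid(fp_priors = c(0.1, 0.01), fn_priors = 0.1,
                         n_row_permutations = 3)
  expect_equal(nrow(g2), 6L)
})
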