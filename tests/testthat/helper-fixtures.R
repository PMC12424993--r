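# Shared fixtures, built once per test run.

balanced4 <- validate_tree(ape::read.tree(text = "((A,B),(C,D));"))
caterpillar3 <- validate_tree(ape::read.tree(text = "((A,B),C);"))
example6 <- make_worked_example()

# A small but complete bundle reused across module tests.
small_bundle <- simulate_dataset(sim_config(
  seed = 7L, n_sublines = 14L, n_clades = 3L, caterpillar_size = 6L,
  n_snvs = 300L, n_svs = 30L, n_cna_events = 6L,
  n_meth_regions = 20L, n_branch_shift_regions = 4L,
  n_monotonic_regions = 4L, cpg_per_region = 15L))

# Random tree with unique labels, no branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  validate_tree(ape::rtree(n, tip.label = sprintf("t%d", seq_len(n)),
                           br = NULL))
}

# Brute-force placement oracle: deepest node whose leaf set contains the
# carriers and whose clade meets the support threshold.
brute_force_place <- function(carriers, tree, fn_rate) {
  nn <- length(tree$tip.label) + tree$Nnode
  best <- NA_integer_
  best_size <- Inf
  for (v in seq_len(nn)) {
    lv <- leaves_below(tree, v)
    if (all(carriers %in% lv) &&
        length(carriers) >= min_support(length(lv), fn_rate) &&
        length(lv) < best_size) {
      best <- v
      best_size <- length(lv)
    }
  }
  best
}
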