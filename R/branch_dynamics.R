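## Branch-level analytics over placements: counts, signature timing,
## cumulative dN/dS, and group tests.

#' Per-branch and cumulative variant counts
#'
#' Counts SNVs and SVs placed on each branch, plus cumulative counts from
#' the trunk through the branch inclusive. With an annotation table,
#' cumulative non-synonymous and synonymous counts are added.
#'
#' @param fit A `tree_harmonization` object, or a placements data.frame
#'   (then `tree` is required).
#' @param tree A `phylo` object when `fit` is a data.frame.
#' @param annotations Optional data.frame (`variant_id, consequence`) with
#'   consequence in `synonymous` / `nonsynonymous` / `other`.
#' @return A data.frame with one row per tree node.
#' @export
branch_counts <- function(fit, tree = NULL, annotations = NULL) {
  if (inherits(fit, "tree_harmonization")) {
    placements <- fit$placements
    tree <- fit$tree
  } else placements <- fit
  stopifnot(!is.null(tree))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  placed <- placements[!is.na(placements$node), , drop = FALSE]
  is_snv <- placed$type == "SNV"
  snv <- tabulate(placed$node[is_snv], nn)
  sv <- tabulate(placed$node[!is_snv], nn)
  nonsyn <- syn <- integer(nn)
  if (!is.null(annotations)) {
    cons <- annotations$consequence[match(placed$variant_id,
                                          annotations$variant_id)]
    nonsyn <- tabulate(placed$node[is_snv & !is.na(cons) &
                                     cons == "nonsynonymous"], nn)
    syn <- tabulate(placed$node[is_snv & !is.na(cons) &
                                  cons == "synonymous"], nn)
  }
  cum_snv <- cum_sv <- cum_nonsyn <- cum_syn <- integer(nn)
  for (v in level_order(tree)) {
    anc <- tree_ancestors(tree, v)
    up <- if (length(anc)) anc[1] else 0L
    cum_snv[v] <- snv[v] + if (up) cum_snv[up] else 0L
    cum_sv[v] <- sv[v] + if (up) cum_sv[up] else 0L
    cum_nonsyn[v] <- nonsyn[v] + if (up) cum_nonsyn[up] else 0L
    cum_syn[v] <- syn[v] + if (up) cum_syn[up] else 0L
  }
  data.frame(node = seq_len(nn),
             node_label = node_label(tree, seq_len(nn)),
             branch_class = classify_branch(tree, seq_len(nn)),
             snv_count = snv, sv_count = sv,
             cumulative_snv_count = cum_snv,
             cumulative_sv_count = cum_sv,
             nonsyn_count = cum_nonsyn, syn_count = cum_syn,
             stringsAsFactors = FALSE)
}

#' Assign each placed mutation its most probable mutational signature
#'
#' Per-mutation, per-subline signature probability vectors are summed over
#' the sublines in the subtree below the mutation's branch, and the
#' signature with the largest aggregated probability wins (ties broken by
#' signature name order).
#'
#' @param placements Placements data.frame (SNV rows are used).
#' @param probs Long data.frame (`mutation_id, subline, signature,
#'   probability`).
#' @param tree A `phylo` object.
#' @return A data.frame (`variant_id, node, signature`); mutations without
#'   any probability row get signature `NA` with a warning.
#' @export
assign_branch_signatures <- function(placements, probs, tree) {
  placed <- placements[!is.na(placements$node) & placements$type == "SNV", ,
                       drop = FALSE]
  sigs <- sort(unique(probs$signature))
  out <- data.frame(variant_id = placed$variant_id, node = placed$node,
                    signature = NA_character_, stringsAsFactors = FALSE)
  pr_by_mut <- split(probs, probs$mutation_id)
  n_missing <- 0L
  for (i in seq_len(nrow(placed))) {
    rows <- pr_by_mut[[placed$variant_id[i]]]
    if (!is.null(rows)) {
      below <- leaves_below(tree, placed$node[i])
      rows <- rows[rows$subline %in% below, , drop = FALSE]
    }
    if (is.null(rows) || nrow(rows) == 0L) { n_missing <- n_missing + 1L; next }
    agg <- vapply(split(rows$probability,
                        factor(rows$signature, levels = sigs)), sum,
                  numeric(1))
    out$signature[i] <- sigs[which.max(agg)]  # which.max: first on ties
  }
  if (n_missing) {
    warning(n_missing, " placed mutation(s) had no signature probabilities",
            call. = FALSE)
  }
  out
}

#' Default aggregation groups for sub-lettered signatures
#' @return Named character vector mapping member to group names.
#' @export
default_signature_groups <- function() {
  c(SBS7a = "SBS7", SBS7b = "SBS7", SBS7c = "SBS7", SBS7d = "SBS7",
    SBS17a = "SBS17", SBS17b = "SBS17")
}

#' Per-branch signature activities
#'
#' Activity of a signature at a branch is the proportion of mutations
#' placed on that branch whose label (after group aggregation, e.g.
#' SBS7a-d to SBS7) is the signature.
#'
#' @param labels Output of [assign_branch_signatures()].
#' @param aggregate_groups Named vector mapping member signature names to
#'   aggregated names (default [default_signature_groups()]).
#' @return A data.frame (`node, signature, activity, mutation_count`);
#'   branches with zero labelled mutations are omitted.
#' @export
branch_activity <- function(labels,
                            aggregate_groups = default_signature_groups()) {
  ok <- labels[!is.na(labels$signature), , drop = FALSE]
  grouped <- ifelse(ok$signature %in% names(aggregate_groups),
                    aggregate_groups[ok$signature], ok$signature)
  if (!nrow(ok)) {
    return(data.frame(node = integer(), signature = character(),
                      activity = numeric(), mutation_count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(ok$node, grouped)
  tot <- rowSums(tab)
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    nz <- tab[i, ] > 0
    data.frame(node = as.integer(rownames(tab)[i]),
               signature = colnames(tab)[nz],
               activity = as.numeric(tab[i, nz] / tot[i]),
               mutation_count = as.integer(tot[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cumulative dN/dS for a branch
#'
#' The ratio of cumulative non-synonymous to synonymous SNV counts from
#' the trunk through the branch, normalized by the genome-wide ratio of
#' synonymous to non-synonymous sites.
#'
#' @param nonsyn_count,syn_count Cumulative counts for the branch.
#' @param synonymous_sites,nonsynonymous_sites Site counts (both > 0).
#' @return The dN/dS value; `NA` when `syn_count` is zero.
#' @export
cumulative_dnds <- function(nonsyn_count, syn_count, synonymous_sites,
                            nonsynonymous_sites) {
  stopifnot(synonymous_sites > 0, nonsynonymous_sites > 0)
  ifelse(syn_count == 0, NA_real_,
         (nonsyn_count / syn_count) *
           (synonymous_sites / nonsynonymous_sites))
}

#' Correlation between per-branch SNV and SV counts
#'
#' @param counts A [branch_counts()] data.frame (rows with at least one
#'   variant are used).
#' @param min_branches Minimum branches required (default 3).
#' @return A list with `r`, `p`, `df`; `r` is `NA` when a count vector is
#'   constant.
#' @export
branch_count_correlation <- function(counts, min_branches = 3L) {
  use <- counts[counts$snv_count + counts$sv_count > 0, , drop = FALSE]
  if (nrow(use) < min_branches) {
    stop("need at least ", min_branches, " branches with variants",
         call. = FALSE)
  }
  if (stats::sd(use$snv_count) == 0 || stats::sd(use$sv_count) == 0) {
    return(list(r = NA_real_, p = NA_real_, df = nrow(use) - 2L))
  }
  ct <- stats::cor.test(use$snv_count, use$sv_count, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter))
}

#' ANOVA with Tukey HSD contrasts of branch values across groups
#'
#' Tests branch-level values (e.g. a signature's activity) across timing
#' classes (internal vs terminal) and across clade labels. Branches with
#' `NA` group labels, and groups with fewer than two branches, are
#' excluded from the corresponding contrasts.
#'
#' @param values Numeric vector, one value per branch.
#' @param groups Factor/character vector of group labels (NA allowed).
#' @return A list with `anova_p` and `pairs` (data.frame of Tukey-adjusted
#'   pairwise p values), or `NULL` with a warning when fewer than two
#'   usable groups remain.
#' @export
branch_group_tests <- function(values, groups) {
  ok <- !is.na(groups) & !is.na(values)
  values <- values[ok]
  groups <- as.character(groups[ok])
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= 2]
  drop <- setdiff(names(sizes), keep)
  if (length(drop)) {
    warning("excluding singleton group(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
  }
  use <- groups %in% keep
  if (length(keep) < 2) {
    warning("fewer than two usable groups; no test performed",
            call. = FALSE)
    return(NULL)
  }
  g <- factor(groups[use])
  fit <- stats::aov(values[use] ~ g)
  tk <- stats::TukeyHSD(fit)$g
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(anova_p = summary(fit)[[1]][["Pr(>F)"]][1], pairs = pairs)
}

#' Enumerate the tree-builder prior configuration grid
#'
#' The tree search is run over a grid of false-positive and
#' false-negative genotype-error priors, each repeated over random row
#' (subline) permutations of the genotype matrix; the maximum-likelihood
#' tree over the whole grid is kept. This helper enumerates that grid.
#'
#' @param fp_priors Vector of false-positive priors (default the 8 powers
#'   used for the study grid).
#' @param fn_priors Vector of false-negative priors (default 7 values
#'   0.05-0.2).
#' @param n_row_permutations Number of row permutations per prior pair
#'   (default 100).
#' @return A data.frame with one row per configuration
#'   (`fp, fn, permutation`).
#' @export
tree_search_grid <- function(fp_priors = c(1e-2, 5e-2, 1e-3, 1e-4, 1e-5,
                                           1e-6, 1e-7, 1e-8),
                             fn_priors = c(0.05, 0.075, 0.1, 0.125, 0.15,
                                           0.175, 0.2),
                             n_row_permutations = 100L) {
  expand.grid(fp = fp_priors, fn = fn_priors,
              permutation = seq_len(n_row_permutations),
              KEEP.OUT.ATTRS = FALSE)
}
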