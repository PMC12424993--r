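## Monotonic methylation trajectories: Mann-Kendall trend statistics over
## admissible leaf orderings, ordering equivalence classes, and the
## permutation test on the number of trend-associated genes.

#' Kendall's tau (tau-b) by concordant/discordant pair counting
#'
#' @param x,y Numeric vectors of equal length (at least 2). Ties are
#'   handled with the tau-b denominator correction.
#' @return The tau value (`NA` if either vector is constant).
#' @export
kendall_tau <- function(x, y = seq_along(x)) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  conc <- disc <- 0L
  tx <- ty <- 0L
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
    else if (dx == 0) tx <- tx + 1L
    else if (dy == 0) ty <- ty + 1L
    else if (dx == dy) conc <- conc + 1L
    else disc <- disc + 1L
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

#' Admissible orderings: base order plus sibling-slot swaps
#'
#' The tree structure fixes which ordering slots hold interchangeable
#' sibling leaves; each single swap and their combinations are admissible
#' (4 orderings for two sibling pairs).
#'
#' @param ordering Character vector: the base leaf order.
#' @param sibling_slots List of length-2 integer vectors of slot
#'   positions whose occupants may be swapped.
#' @return A list of orderings, the base order first.
#' @export
admissible_orderings <- function(ordering, sibling_slots = list()) {
  out <- list(ordering)
  for (slots in sibling_slots) {
    swapped <- lapply(out, function(o) {
      o[slots] <- o[rev(slots)]
      o
    })
    out <- c(out, swapped)
  }
  out
}

#' Maximum-magnitude Mann-Kendall trend over admissible orderings
#'
#' Computes Kendall's tau of the values against rank order for each
#' admissible ordering and records the tau of greatest absolute value.
#'
#' @param values Named numeric vector (names are sublines).
#' @param orderings List of orderings (character vectors over the names),
#'   e.g. from [admissible_orderings()].
#' @param tau_threshold Regions with `|tau|` at or above this are flagged
#'   (default 0.7, roughly a Pearson correlation of 0.9 under a
#'   bivariate-normal model; see [tau_to_pearson()]).
#' @return A list with `max_abs_tau`, `best_tau` (signed),
#'   `best_ordering`, `flagged`.
#' @export
mann_kendall_max_tau <- function(values, orderings,
                                 tau_threshold = 0.7) {
  stopifnot(length(values) >= 3, !is.null(names(values)))
  taus <- vapply(orderings, function(o) {
    kendall_tau(unname(values[o]))
  }, numeric(1))
  if (all(is.na(taus))) {
    return(list(max_abs_tau = NA_real_, best_tau = NA_real_,
                best_ordering = orderings[[1]], flagged = FALSE))
  }
  best <- which.max(abs(taus))
  list(max_abs_tau = abs(taus[best]), best_tau = taus[best],
       best_ordering = orderings[[best]],
       flagged = !is.na(taus[best]) && abs(taus[best]) >= tau_threshold)
}

#' Bivariate-normal conversion between Kendall's tau and Pearson's r
#'
#' Greiner's relation `r = sin(pi * tau / 2)`; a tau of 0.7 corresponds
#' to roughly r = 0.9.
#'
#' @param tau Kendall tau value(s) in `[-1, 1]`.
#' @return Pearson correlation value(s).
#' @export
tau_to_pearson <- function(tau) sin(pi * tau / 2)

ordering_transforms <- function(ordering, swap_pairs) {
  ## orbit of the order-8 (2^(k+1)) group generated by the label
  ## transpositions of each interchangeable pair and full reversal
  out <- list(ordering)
  for (pair in swap_pairs) {
    out <- c(out, lapply(out, function(o) {
      i <- match(pair, o)
      o[i] <- o[rev(i)]
      o
    }))
  }
  c(out, lapply(out, rev))
}

canonical_ordering_key <- function(ordering, swap_pairs) {
  min(vapply(ordering_transforms(ordering, swap_pairs),
             paste, character(1), collapse = "\r"))
}

#' Partition all leaf orderings into equivalence classes
#'
#' Two orderings are equivalent when one arises from the other by
#' exchanging the members of an interchangeable sibling pair and/or by
#' full reversal. With `k` swappable pairs each class has `2^(k+1)`
#' members; an 8-leaf linear clade with two pairs yields
#' `8!/8 = 7! = 5040` classes.
#'
#' @param leaves Character vector of leaves (at most 8 for exhaustive
#'   enumeration).
#' @param swap_pairs List of length-2 character vectors: the
#'   interchangeable sibling pairs.
#' @return A list with `n_orderings`, `n_classes`, `class_sizes` (table).
#' @export
ordering_equivalence_classes <- function(leaves, swap_pairs = list()) {
  n <- length(leaves)
  if (n > 8) stop("exhaustive enumeration supported up to 8 leaves",
                  call. = FALSE)
  perms <- all_permutations(n)
  keys <- vapply(seq_len(nrow(perms)), function(i) {
    canonical_ordering_key(leaves[perms[i, ]], swap_pairs)
  }, character(1))
  sizes <- table(keys)
  list(n_orderings = nrow(perms), n_classes = length(sizes),
       class_sizes = sizes)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Sample leaf orderings, at most one per equivalence class
#'
#' @param leaves Character vector of leaves.
#' @param swap_pairs Interchangeable sibling pairs (list of length-2
#'   character vectors).
#' @param n Number of orderings requested.
#' @param seed Integer seed.
#' @param exclude Optional ordering whose whole equivalence class is
#'   excluded (e.g. the observed ordering).
#' @return A list of orderings; fewer than `n` if the class space is
#'   exhausted (only possible for tiny clades).
#' @export
sample_orderings <- function(leaves, swap_pairs, n, seed = 1L,
                             exclude = NULL) {
  set.seed(seed)
  seen <- character(0)
  if (!is.null(exclude)) {
    seen <- canonical_ordering_key(exclude, swap_pairs)
  }
  out <- list()
  n_classes <- factorial(length(leaves)) / (2^(length(swap_pairs) + 1))
  budget <- if (!is.null(exclude)) n_classes - 1 else n_classes
  max_tries <- 200L * n
  tries <- 0L
  while (length(out) < min(n, budget) && tries < max_tries) {
    tries <- tries + 1L
    o <- sample(leaves)
    key <- canonical_ordering_key(o, swap_pairs)
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- o
    }
  }
  out
}

#' Permutation test on the number of genes with monotonic methylation
#'
#' For the observed clade ordering, a gene counts when any candidate
#' region overlapping its promoter/enhancer shows `|tau|` at or above the
#' threshold (maximised over sibling-slot swaps). The null re-runs the
#' same analysis on sampled orderings (at most one per equivalence class,
#' the observed class excluded); p is the fraction of null counts greater
#' than or equal to the observed count.
#'
#' @param region_values Numeric matrix, candidate regions x sublines
#'   (region mean smoothed methylation per subline); column names are the
#'   clade sublines.
#' @param region_genes Character vector (length `nrow(region_values)`),
#'   gene symbol per region or `NA` for regions without an associated
#'   gene.
#' @param base_ordering Character vector: the observed clade ordering.
#' @param swap_pairs List of interchangeable sibling label pairs.
#' @param tau_threshold Flagging threshold on `|tau|` (default 0.7).
#' @param n_perm Number of sampled orderings (default 1000).
#' @param seed Integer seed.
#' @return A list with `p`, `observed_genes`, `null_counts`, `seed`.
#' @export
trajectory_permutation_test <- function(region_values, region_genes,
                                        base_ordering, swap_pairs,
                                        tau_threshold = 0.7,
                                        n_perm = 1000L, seed = 1L) {
  stopifnot(nrow(region_values) == length(region_genes))
  slots <- lapply(swap_pairs, function(p) match(p, base_ordering))
  count_genes <- function(ordering) {
    ords <- admissible_orderings(ordering, slots)
    flagged <- vapply(seq_len(nrow(region_values)), function(r) {
      v <- region_values[r, ]
      mann_kendall_max_tau(v, ords, tau_threshold)$flagged
    }, logical(1))
    length(unique(stats::na.omit(region_genes[flagged])))
  }
  observed <- count_genes(base_ordering)
  perms <- sample_orderings(colnames(region_values), swap_pairs, n_perm,
                            seed = seed, exclude = base_ordering)
  null_counts <- vapply(perms, count_genes, numeric(1))
  list(p = mean(null_counts >= observed), observed_genes = observed,
       null_counts = null_counts, seed = seed)
}
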