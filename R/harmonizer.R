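#' Placement engine parameters
#'
#' @param fn_rate Assumed per-subline false-negative call rate used to
#'   derive clade-support thresholds (default 0.15).
#' @param fp_rate Assumed false-positive rate (default 1e-5). At the
#'   default the called carrier set is trusted and no leave-one-out search
#'   is performed.
#' @param reinclusion_cap Regenotyping is rejected when the ratio of
#'   loss-rescued sublines to originally called sublines reaches this cap
#'   (default 1, i.e. a reinclusion rate of 100 percent or more is rejected).
#' @param parsimony_guard If `TRUE` (default) a position is not
#'   regenotyped when another called SNV of the rescued subline falls
#'   inside the rescuing loss span (the loss is then assumed to sit on the
#'   other haplotype).
#' @param fp_leaveout Reserved switch for leave-one-out carrier search
#'   under high FP rates; off by default.
#' @return A list of class `placement_params`.
#' @export
placement_params <- function(fn_rate = 0.15, fp_rate = 1e-5,
                             reinclusion_cap = 1, parsimony_guard = TRUE,
                             fp_leaveout = FALSE) {
  stopifnot(fn_rate >= 0, fn_rate < 1, reinclusion_cap > 0)
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate,
                 reinclusion_cap = reinclusion_cap,
                 parsimony_guard = parsimony_guard,
                 fp_leaveout = fp_leaveout), class = "placement_params")
}

#' Minimum carrier support required to place a variant at a clade
#'
#' For clades of one or two leaves a variant needs the support of every
#' leaf. For larger clades the threshold is the largest integer `s` not
#' exceeding the clade size with `(clade_size - s) / clade_size >= fn_rate`
#' (never below 1), so the tolerated dropout approaches the assumed
#' false-negative rate from above.
#'
#' @param clade_size Integer clade size(s), at least 1.
#' @param fn_rate Assumed false-negative rate.
#' @return Integer vector of thresholds.
#' @seealso [effective_fn_rate()] for the implied per-clade dropout rate.
#' @export
min_support <- function(clade_size, fn_rate = 0.15) {
  stopifnot(all(clade_size >= 1))
  k <- as.numeric(clade_size)
  as.integer(ifelse(k <= 2, k, pmax(1, floor(k * (1 - fn_rate)))))
}

#' Effective false-negative rate implied by the support threshold
#' @inheritParams min_support
#' @return `(clade_size - min_support) / clade_size`.
#' @export
effective_fn_rate <- function(clade_size, fn_rate = 0.15) {
  (clade_size - min_support(clade_size, fn_rate)) / clade_size
}

## Precomputed tip-set index for the hot placement loops: logical matrix
## of nodes x tips, clade sizes, and a vectorized MRCA (deepest node whose
## tip set contains the carriers = smallest containing clade).
make_tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- phangorn::Descendants(tree, seq_len(nn), type = "tips")
  tipmat <- matrix(FALSE, nn, ntip)
  for (v in seq_len(nn)) tipmat[v, desc[[v]]] <- TRUE
  sizes <- rowSums(tipmat)
  list(tree = tree, ntip = ntip, tipmat = tipmat, sizes = sizes,
       labels = node_label(tree, seq_len(nn)))
}

index_mrca <- function(ix, tip_ids) {
  if (length(tip_ids) == 1L) return(tip_ids)
  ok <- which(rowSums(ix$tipmat[, tip_ids, drop = FALSE]) ==
                length(tip_ids))
  ok[which.min(ix$sizes[ok])]
}

index_place <- function(ix, tip_ids, params) {
  node <- index_mrca(ix, tip_ids)
  k <- ix$sizes[node]
  if (length(tip_ids) >= min_support(k, params$fn_rate)) {
    list(node = node, placed = TRUE, support = length(tip_ids),
         clade_size = k)
  } else {
    list(node = NA_integer_, placed = FALSE, support = length(tip_ids),
         clade_size = k)
  }
}

#' Place a single variant on the tree from its carrier set
#'
#' The most recent common ancestor of the carriers defines the candidate
#' clade; the variant is placed there when the carrier count reaches
#' [min_support()] of the clade size, otherwise it is unplaced.
#'
#' @param carriers Character vector of sublines in which the variant is
#'   called present (at least one).
#' @param tree A `phylo` object.
#' @param params A [placement_params()] object.
#' @return A list with `node` (id or `NA`), `node_label`, `clonality`,
#'   `support`, `clade_size`, `placed`.
#' @export
place_variant <- function(carriers, tree, params = placement_params()) {
  carriers <- unique(carriers)
  if (length(carriers) == 0) {
    stop("variant has no carrier sublines", call. = FALSE)
  }
  node <- mrca_node(tree, carriers)
  k <- length(leaves_below(tree, node))
  thr <- min_support(k, params$fn_rate)
  if (length(carriers) >= thr) {
    list(node = node, node_label = node_label(tree, node),
         clonality = unname(clonality_of(classify_branch(tree, node))),
         support = length(carriers), clade_size = k, placed = TRUE)
  } else {
    list(node = NA_integer_, node_label = NA_character_,
         clonality = "unplaced", support = length(carriers),
         clade_size = k, placed = FALSE)
  }
}

## Internal: evaluate regenotyping of one position.
## rescue_losses: data.frame rows of losses overlapping the position for
## sublines NOT in carriers; guard_conflict: logical, TRUE if any rescue
## span contains another called SNV of its subline.
regenotype_position <- function(carriers, rescue_sublines, guard_conflict,
                                tree, params) {
  base <- if (length(carriers)) place_variant(carriers, tree, params)
          else list(node = NA_integer_, node_label = NA_character_,
                    clonality = "unplaced", support = 0L,
                    clade_size = NA_integer_, placed = FALSE)
  base$regenotyped <- character(0)
  added <- setdiff(rescue_sublines, carriers)
  if (!length(added)) return(base)
  if (params$parsimony_guard && guard_conflict) return(base)
  if (length(carriers) == 0 ||
      length(added) / length(carriers) >= params$reinclusion_cap) {
    return(base)
  }
  candidate <- union(carriers, added)
  node <- mrca_node(tree, candidate)
  k <- length(leaves_below(tree, node))
  if (length(candidate) >= min_support(k, params$fn_rate)) {
    list(node = node, node_label = node_label(tree, node),
         clonality = unname(clonality_of(classify_branch(tree, node))),
         support = length(candidate), clade_size = k, placed = TRUE,
         regenotyped = added)
  } else base
}

#' Loss-aware regenotyping of a single variant
#'
#' Extends the carrier set with sublines whose loss regions overlap the
#' variant position, re-evaluates the MRCA and support threshold on the
#' candidate set, and accepts the rescue only when (a) the threshold is
#' met, (b) the parsimony guard passes (no other called SNV of a rescued
#' subline inside the rescuing loss span), and (c) the subline reinclusion
#' rate (added / originally called) is below the cap. On rejection the
#' original called set and its placement stand.
#'
#' @param variant A one-row data.frame (or list) with `chrom` and `pos`
#'   (1-based) identifying the position, plus `ref`/`alt` if other calls
#'   at the same position must be distinguished.
#' @param carriers Character vector of called-present sublines.
#' @param losses Loss-region data.frame (`chrom, start, end, subline`).
#' @param tree A `phylo` object.
#' @param params A [placement_params()] object.
#' @param other_calls Optional data.frame of all called-present SNVs
#'   (`chrom, pos, subline`) used by the parsimony guard; calls at the
#'   variant's own position are ignored.
#' @return As [place_variant()], plus `regenotyped` (character vector of
#'   rescued sublines, empty when the rescue was rejected).
#' @export
regenotype <- function(variant, carriers, losses, tree,
                       params = placement_params(), other_calls = NULL) {
  pos0 <- variant$pos - 1L
  ov <- losses$chrom == variant$chrom & losses$start <= pos0 &
    losses$end > pos0
  rescue <- losses[ov & !(losses$subline %in% carriers), , drop = FALSE]
  conflict <- FALSE
  if (nrow(rescue) && !is.null(other_calls) && nrow(other_calls)) {
    for (i in seq_len(nrow(rescue))) {
      hit <- other_calls$subline == rescue$subline[i] &
        other_calls$chrom == rescue$chrom[i] &
        other_calls$pos - 1L >= rescue$start[i] &
        other_calls$pos - 1L < rescue$end[i] &
        other_calls$pos != variant$pos
      if (any(hit)) { conflict <- TRUE; break }
    }
  }
  regenotype_position(carriers, unique(rescue$subline), conflict, tree,
                      params)
}

#' Place every SNV on the tree, with loss-aware regenotyping
#'
#' Groups calls by (chrom, pos, ref, alt) in genome order, places each
#' variant from its called carrier set and attempts regenotyping against
#' the loss set. Rescued sublines are reported per variant; the result
#' also carries a clonality summary.
#'
#' @param snvs Long data.frame of present calls (`chrom, pos, ref, alt,
#'   subline`; extra columns ignored).
#' @param losses Loss-region data.frame or `NULL` to skip regenotyping.
#' @param tree A `phylo` object.
#' @param params A [placement_params()] object.
#' @return A data.frame of placements (one row per unique variant) with
#'   attribute `"summary"` (named counts).
#' @export
place_all_snvs <- function(snvs, losses = NULL, tree,
                           params = placement_params()) {
  if (is.null(snvs) || nrow(snvs) == 0L) {
    out <- placement_frame()
    attr(out, "summary") <- placement_summary(out)
    return(out)
  }
  snvs <- snvs[snvs$status %in% c(NA, "present") |
                 is.null(snvs$status), , drop = FALSE]
  ord <- order(snvs$chrom, snvs$pos, snvs$alt)
  snvs <- snvs[ord, , drop = FALSE]
  key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt, sep = "\r")
  ukey <- unique(key)
  first <- match(ukey, key)
  vars <- snvs[first, c("chrom", "pos", "ref", "alt")]
  carriers_by <- split(snvs$subline, factor(key, levels = ukey))

  have_losses <- !is.null(losses) && nrow(losses) > 0L
  if (have_losses) {
    vgr <- GenomicRanges::GRanges(vars$chrom,
                                  IRanges::IRanges(vars$pos, width = 1L))
    lgr <- GenomicRanges::GRanges(
      losses$chrom, IRanges::IRanges(losses$start + 1L, losses$end))
    hits <- GenomicRanges::findOverlaps(vgr, lgr)
    loss_by_var <- split(S4Vectors::subjectHits(hits),
                         factor(S4Vectors::queryHits(hits),
                                levels = seq_len(nrow(vars))))
    ## per-subline present calls, for the parsimony guard
    cgr <- GenomicRanges::GRanges(snvs$chrom,
                                  IRanges::IRanges(snvs$pos, width = 1L))
    lc <- GenomicRanges::findOverlaps(lgr, cgr)
    conflict_calls <- split(S4Vectors::subjectHits(lc),
                            factor(S4Vectors::queryHits(lc),
                                   levels = seq_len(nrow(losses))))
  }

  ix <- make_tree_index(tree)
  nv <- nrow(vars)
  node <- rep(NA_integer_, nv)
  support <- clade_sz <- integer(nv)
  regen <- character(nv)
  for (i in seq_len(nv)) {
    carriers <- unique(carriers_by[[i]])
    cid <- match(carriers, tree$tip.label)
    res <- index_place(ix, cid, params)
    res$regenotyped <- character(0)
    if (have_losses) {
      li <- loss_by_var[[i]]
      rescue <- li[!(losses$subline[li] %in% carriers)]
      added <- unique(losses$subline[rescue])
      if (length(added) &&
          length(added) / length(carriers) < params$reinclusion_cap) {
        conflict <- FALSE
        if (params$parsimony_guard) {
          for (l in rescue) {
            calls <- conflict_calls[[l]]
            calls <- calls[snvs$subline[calls] == losses$subline[l] &
                             key[calls] != ukey[i]]
            if (length(calls)) { conflict <- TRUE; break }
          }
        }
        if (!conflict) {
          cand <- union(cid, match(added, tree$tip.label))
          res2 <- index_place(ix, cand, params)
          if (res2$placed) {
            res <- res2
            res$regenotyped <- added
          }
        }
      }
    }
    node[i] <- res$node
    support[i] <- res$support
    clade_sz[i] <- res$clade_size
    regen[i] <- paste(res$regenotyped, collapse = ",")
  }
  out <- data.frame(
    variant_id = sprintf("snv_%s_%d_%s_%s", vars$chrom, vars$pos,
                         vars$ref, vars$alt),
    type = "SNV", chrom = vars$chrom, pos = vars$pos, node = node,
    node_label = ifelse(is.na(node), NA_character_, ix$labels[node]),
    clonality = ifelse(is.na(node), "unplaced",
                       unname(clonality_of(
                         classify_branch(tree,
                                         ifelse(is.na(node), 1L, node))))),
    support = support, clade_size = clade_sz,
    regenotyped_sublines = regen, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- placement_summary(out)
  out
}

#' Place structural variants on the tree
#'
#' Identical clade-support thresholding to SNVs; no loss-aware rescue is
#' attempted.
#'
#' @param svs SV data.frame as from [read_sv_vcf()] (`variant_id, sv_type,
#'   chrom1, pos1, sublines`).
#' @param tree A `phylo` object.
#' @param params A [placement_params()] object.
#' @return A data.frame of placements with attribute `"summary"`.
#' @export
place_all_svs <- function(svs, tree, params = placement_params()) {
  if (is.null(svs) || nrow(svs) == 0L) {
    out <- placement_frame()
    attr(out, "summary") <- placement_summary(out)
    return(out)
  }
  ix <- make_tree_index(tree)
  nv <- nrow(svs)
  node <- rep(NA_integer_, nv)
  support <- clade_sz <- integer(nv)
  for (i in seq_len(nv)) {
    carriers <- strsplit(svs$sublines[i], ",", fixed = TRUE)[[1]]
    res <- index_place(ix, match(unique(carriers), tree$tip.label),
                       params)
    node[i] <- res$node
    support[i] <- res$support
    clade_sz[i] <- res$clade_size
  }
  out <- data.frame(
    variant_id = svs$variant_id, type = svs$sv_type, chrom = svs$chrom1,
    pos = svs$pos1, node = node,
    node_label = ifelse(is.na(node), NA_character_, ix$labels[node]),
    clonality = ifelse(is.na(node), "unplaced",
                       unname(clonality_of(
                         classify_branch(tree,
                                         ifelse(is.na(node), 1L, node))))),
    support = support, clade_size = clade_sz,
    regenotyped_sublines = "", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- placement_summary(out)
  out
}

placement_frame <- function() {
  data.frame(variant_id = character(), type = character(),
             chrom = character(), pos = integer(), node = integer(),
             node_label = character(), clonality = character(),
             support = integer(), clade_size = integer(),
             regenotyped_sublines = character(), stringsAsFactors = FALSE)
}

placement_summary <- function(placements) {
  lev <- c("clonal", "subclonal", "private", "unplaced")
  counts <- table(factor(placements$clonality, levels = lev))
  c(as.vector(counts), regenotyped =
      sum(nzchar(placements$regenotyped_sublines))) |>
    stats::setNames(c(lev, "regenotyped"))
}
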