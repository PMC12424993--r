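## CNA placement: three-phase overlap procedure over the tree.
## Gains (CN > 2) and losses (CN < 2) are extracted per subline relative to
## a diploid baseline and processed as disjoint pools.

#' Extract per-subline gain and loss ranges from copy-number segments
#'
#' Gains are segments with copy number above 2, losses below 2; adjacent
#' or overlapping same-direction ranges of one subline are merged.
#'
#' @param segments CNA segment data.frame (`chrom, start, end,
#'   copy_number, subline`), 0-based half-open.
#' @return A data.frame with `chrom, start, end, subline, direction`.
#' @export
extract_cn_ranges <- function(segments) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), subline = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (is.null(segments) || nrow(segments) == 0L) return(empty)
  segments$direction <- ifelse(segments$copy_number > 2, "gain",
                               ifelse(segments$copy_number < 2, "loss", NA))
  segments <- segments[!is.na(segments$direction), , drop = FALSE]
  if (!nrow(segments)) return(empty)
  parts <- split(segments,
                 list(segments$subline, segments$chrom, segments$direction),
                 drop = TRUE)
  out <- lapply(parts, function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(chrom = p$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), subline = p$subline[1],
               direction = p$direction[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$subline), , drop = FALSE]
}

## internal range record: list(start, end (half-open), sublines (char))
rng <- function(start, end, sublines) {
  list(start = start, end = end, sublines = sort(unique(sublines)))
}

rng_key <- function(r) {
  paste(r$start, r$end, paste(r$sublines, collapse = ","), sep = "|")
}

dedupe_rngs <- function(rs) {
  if (!length(rs)) return(rs)
  rs[!duplicated(vapply(rs, rng_key, character(1)))]
}

## merge mutually (strictly) overlapping ranges: union interval and
## union subline set, to transitive closure
merge_overlapping_rngs <- function(rs) {
  if (length(rs) <= 1) return(rs)
  rs <- rs[order(vapply(rs, `[[`, numeric(1), "start"))]
  out <- list(rs[[1]])
  for (r in rs[-1]) {
    last <- out[[length(out)]]
    if (r$start < last$end) {
      out[[length(out)]] <- rng(last$start, max(last$end, r$end),
                                c(last$sublines, r$sublines))
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

#' Place copy-number alteration ranges on the tree
#'
#' Three phases per direction and chromosome. Phase 1 (reverse level
#' order): overlapping ranges carried up from different child subtrees
#' spawn an overlap range — the intersection of the intervals, carried by
#' the union of the subline sets — at the meeting branch. Phase 2 (per
#' branch): ranges whose subline set meets the branch's [min_support()]
#' are kept, and mutually overlapping kept ranges are merged (union of
#' intervals and subline sets). Phase 3 (top-down level order): spans
#' already assigned to an ancestor are subtracted, splitting ranges where
#' needed; per-subline residue not claimed by any ancestor stays on the
#' terminal branch.
#'
#' @param ranges Per-subline ranges from [extract_cn_ranges()].
#' @param tree A `phylo` object.
#' @param params A [placement_params()] object.
#' @return A data.frame with `chrom, start, end, direction, node,
#'   node_label, clonality, sublines` (comma-joined), `n_sublines`.
#' @export
place_cnas <- function(ranges, tree, params = placement_params()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      node = integer(), node_label = character(),
                      clonality = character(), sublines = character(),
                      n_sublines = integer(), stringsAsFactors = FALSE)
  if (is.null(ranges) || nrow(ranges) == 0L) return(empty)
  out <- list()
  for (dir in unique(ranges$direction)) {
    for (chr in unique(ranges$chrom[ranges$direction == dir])) {
      sub <- ranges[ranges$direction == dir & ranges$chrom == chr, ,
                    drop = FALSE]
      out[[paste(dir, chr)]] <- place_cnas_one(sub, chr, dir, tree, params)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$node), , drop = FALSE]
}

place_cnas_one <- function(sub, chr, dir, tree, params) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  carry <- vector("list", nn)      # ranges carried up from each subtree
  placed <- vector("list", nn)     # phase-1 overlap ranges per branch
  leaf_ranges <- vector("list", nn)
  for (i in seq_len(ntip)) {
    li <- sub[sub$subline == tree$tip.label[i], , drop = FALSE]
    leaf_ranges[[i]] <- lapply(seq_len(nrow(li)), function(j)
      rng(li$start[j], li$end[j], li$subline[j]))
    carry[[i]] <- leaf_ranges[[i]]
  }
  ## phase 1: reverse level order, pair ranges across children
  for (v in level_order(tree, reverse = TRUE)) {
    if (v <= ntip) next
    kids <- tree_children(tree, v)
    new <- list()
    nk <- length(kids)
    if (nk >= 2) {
      for (a in seq_len(nk - 1)) for (b in seq((a + 1), nk)) {
        for (r1 in carry[[kids[a]]]) for (r2 in carry[[kids[b]]]) {
          s <- max(r1$start, r2$start); e <- min(r1$end, r2$end)
          if (s < e) new[[length(new) + 1L]] <-
              rng(s, e, c(r1$sublines, r2$sublines))
        }
      }
    }
    new <- dedupe_rngs(new)
    placed[[v]] <- new
    carry[[v]] <- dedupe_rngs(c(do.call(c, carry[kids]), new))
  }
  ## phase 2: threshold by clade size, then merge overlaps per branch
  kept <- vector("list", nn)
  for (v in seq.int(ntip + 1L, nn)) {
    if (!length(placed[[v]])) next
    k <- length(leaves_below(tree, v))
    thr <- min_support(k, params$fn_rate)
    ok <- Filter(function(r) length(r$sublines) >= thr, placed[[v]])
    kept[[v]] <- merge_overlapping_rngs(ok)
  }
  for (i in seq_len(ntip)) kept[[i]] <- leaf_ranges[[i]]
  ## phase 3: top-down, subtract spans assigned to ancestors
  assigned <- vector("list", nn)   # cumulative IRanges along the path
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  rows <- list()
  for (v in level_order(tree)) {
    inherited <- if (v == ntip + 1L) IRanges::IRanges()
                 else assigned[[parent[v]]]
    own <- IRanges::IRanges()
    for (r in kept[[v]]) {
      piece <- IRanges::setdiff(IRanges::IRanges(r$start + 1L, r$end),
                                inherited)
      if (length(piece)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, start = IRanges::start(piece) - 1L,
          end = IRanges::end(piece), direction = dir, node = v,
          node_label = node_label(tree, v),
          clonality = unname(clonality_of(classify_branch(tree, v))),
          sublines = paste(r$sublines, collapse = ","),
          n_sublines = length(r$sublines), stringsAsFactors = FALSE)
        own <- IRanges::union(own, piece)
      }
    }
    assigned[[v]] <- IRanges::union(inherited, own)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
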