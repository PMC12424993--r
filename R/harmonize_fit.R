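#' Harmonize somatic variant calls against a subline phylogeny
#'
#' The central entry point: places SNVs (with loss-aware regenotyping),
#' SVs and CNAs on the branches of the tree and returns a single object
#' carrying all placements and summaries.
#'
#' @param tree A `phylo` object (see [read_tree()]).
#' @param snvs Long data.frame of present SNV calls across sublines, or
#'   `NULL`.
#' @param svs SV data.frame (see [read_sv_vcf()]), or `NULL`.
#' @param cnas CNA segment data.frame (see [read_cna_tsv()]), or `NULL`.
#' @param losses Loss-region data.frame (see [read_loss_bed()]), or
#'   `NULL`.
#' @param params A [placement_params()] object.
#' @return An object of class `tree_harmonization` with elements
#'   `placements` (SNV+SV rows), `cna_ranges`, `tree`, `params` and
#'   `summary`.
#' @examples
#' ex <- make_worked_example()
#' fit <- harmonize_tree(ex$tree, snvs = ex$snvs, svs = ex$svs,
#'                       cnas = ex$cnas, losses = ex$losses)
#' summary(fit)
#' @export
harmonize_tree <- function(tree, snvs = NULL, svs = NULL, cnas = NULL,
                           losses = NULL, params = placement_params()) {
  tree <- validate_tree(tree)
  snv_pl <- place_all_snvs(snvs, losses, tree, params)
  sv_pl <- place_all_svs(svs, tree, params)
  cna_pl <- place_cnas(extract_cn_ranges(cnas), tree, params)
  placements <- rbind(snv_pl, sv_pl)
  structure(list(
    placements = placements,
    cna_ranges = cna_pl,
    tree = tree, params = params,
    summary = list(snv = attr(snv_pl, "summary"),
                   sv = attr(sv_pl, "summary"),
                   cna_ranges = nrow(cna_pl))),
    class = "tree_harmonization")
}

#' @export
print.tree_harmonization <- function(x, ...) {
  cat("Tree harmonization of", length(x$tree$tip.label), "sublines\n")
  pct <- function(s) {
    tot <- sum(s[c("clonal", "subclonal", "private", "unplaced")])
    placed <- tot - s[["unplaced"]]
    sprintf("%d variants, %.2f%% placed (%d clonal / %d subclonal / %d private; %d regenotyped)",
            tot, if (tot) 100 * placed / tot else 0,
            s[["clonal"]], s[["subclonal"]], s[["private"]],
            s[["regenotyped"]])
  }
  cat("  SNV:", pct(x$summary$snv), "\n")
  cat("  SV: ", pct(x$summary$sv), "\n")
  cat("  CNA: ", x$summary$cna_ranges, "branch-assigned ranges\n")
  invisible(x)
}

#' @export
summary.tree_harmonization <- function(object, ...) {
  counts <- branch_counts(object)
  print(object)
  cat("\nPer-branch counts (non-empty branches):\n")
  print(counts[counts$snv_count + counts$sv_count > 0, , drop = FALSE],
        row.names = FALSE)
  invisible(counts)
}

#' @export
plot.tree_harmonization <- function(x, ...) {
  ape::plot.phylo(x$tree, show.node.label = TRUE, ...)
  counts <- branch_counts(x)
  lab <- sprintf("%d/%d", counts$snv_count, counts$sv_count)
  ape::nodelabels(text = lab[counts$node > length(x$tree$tip.label)],
                  node = counts$node[counts$node > length(x$tree$tip.label)],
                  frame = "none", adj = c(0.5, 1.5), cex = 0.7)
  invisible(x)
}

#' Export placements as a TSV file
#' @param fit A `tree_harmonization` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(fit, path) {
  utils::write.table(fit$placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
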