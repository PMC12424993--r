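## Selection analyses over gene-level copy-number status: enrichment of
## oncogene gains and tumor-suppressor losses, orientation of ONC/TSG
## pairs at copy-number boundaries, and copy-neutral LOH timing.

#' Gene-level copy-number status per subline
#'
#' A gene is `gain` (`loss`) in a subline when its interval is entirely
#' contained in a segment with copy number above (below) 2; genes
#' straddling a segment boundary, or not covered by any altered segment,
#' are `neutral`.
#'
#' @param genes data.frame (`gene, chrom, start, end`), 0-based half-open,
#'   optionally with a `label` column.
#' @param segments CNA segment data.frame (`chrom, start, end,
#'   copy_number, subline`).
#' @return A data.frame (`gene, subline, status`), one row per gene per
#'   subline seen in `segments`.
#' @export
gene_cn_status <- function(genes, segments) {
  sublines <- sort(unique(segments$subline))
  out <- expand.grid(gene = genes$gene, subline = sublines,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$status <- "neutral"
  if (nrow(segments)) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L,
                                                   genes$end))
    alt <- segments[segments$copy_number != 2, , drop = FALSE]
    if (nrow(alt)) {
      sgr <- GenomicRanges::GRanges(alt$chrom,
                                    IRanges::IRanges(alt$start + 1L,
                                                     alt$end))
      hits <- GenomicRanges::findOverlaps(ggr, sgr, type = "within")
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      st <- ifelse(alt$copy_number[si] > 2, "gain", "loss")
      idx <- match(paste(genes$gene[qi], alt$subline[si], sep = "\r"),
                   paste(out$gene, out$subline, sep = "\r"))
      out$status[idx] <- st
    }
  }
  out
}

#' Absolute gene copy number per subline
#'
#' Copy number of the segment entirely containing the gene; baseline 2
#' when no segment covers it; `NA` when the gene straddles a boundary.
#'
#' @inheritParams gene_cn_status
#' @return A numeric matrix, genes x sublines.
#' @export
gene_absolute_cn <- function(genes, segments) {
  sublines <- sort(unique(segments$subline))
  cn <- matrix(2, nrow(genes), length(sublines),
               dimnames = list(genes$gene, sublines))
  if (!nrow(segments)) return(cn)
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L,
                                                 genes$end))
  sgr <- GenomicRanges::GRanges(segments$chrom,
                                IRanges::IRanges(segments$start + 1L,
                                                 segments$end))
  within <- GenomicRanges::findOverlaps(ggr, sgr, type = "within")
  any_ov <- GenomicRanges::findOverlaps(ggr, sgr)
  ## straddlers: overlap some segment but are not contained in it
  contained <- paste(S4Vectors::queryHits(within),
                     S4Vectors::subjectHits(within))
  part <- setdiff(paste(S4Vectors::queryHits(any_ov),
                        S4Vectors::subjectHits(any_ov)), contained)
  for (h in strsplit(part, " ")) {
    cn[as.integer(h[1]), segments$subline[as.integer(h[2])]] <- NA
  }
  qi <- S4Vectors::queryHits(within); si <- S4Vectors::subjectHits(within)
  cn[cbind(qi, match(segments$subline[si], sublines))] <-
    segments$copy_number[si]
  cn
}

#' Chi-squared enrichment tests of ONC gains and TSG losses
#'
#' Restricted to ONC/TSG-labelled genes impacted by a CNA in at least one
#' subline. Test 1 tabulates label against "gained-only" status (gained
#' in some subline, lost in none); test 2 against "lost-only" status.
#'
#' @param status Output of [gene_cn_status()].
#' @param labels Named character vector (gene -> `ONC`/`TSG`/`ND`).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list with elements `gain` and `loss`, each holding
#'   `statistic`, `p`, and the 2x2 `table`.
#' @export
onc_tsg_enrichment_tests <- function(status, labels, correct = FALSE) {
  if (is.null(status) || nrow(status) == 0L) {
    stop("empty gene copy-number status table", call. = FALSE)
  }
  gained <- tapply(status$status == "gain", status$gene, any)
  lost <- tapply(status$status == "loss", status$gene, any)
  genes <- names(gained)
  lab <- labels[genes]
  use <- lab %in% c("ONC", "TSG") & (gained | lost)
  if (!sum(use)) stop("no impacted ONC/TSG genes", call. = FALSE)
  one_test <- function(flag) {
    tab <- table(label = factor(lab[use], levels = c("ONC", "TSG")),
                 status = factor(flag[use], levels = c(TRUE, FALSE)))
    if (any(stats::chisq.test(tab, correct = correct)$expected < 1)) {
      warning("expected cell count below 1; interpret with care",
              call. = FALSE)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ct$statistic), p = ct$p.value, table = tab)
  }
  list(gain = one_test(gained & !lost), loss = one_test(lost & !gained))
}

#' Permutation test on ONC/TSG orientation at copy-number boundaries
#'
#' Adjacent gene pairs with one ONC and one TSG label whose absolute copy
#' numbers differ in some subline flank a copy-number boundary. The
#' observed statistic counts pairs (once per study) where the ONC gene
#' lies on the higher-copy side in at least one differing subline. The
#' null permutes the ONC/TSG/ND labels over all genes and recounts; p is
#' the fraction of permutations with a count greater than or equal to the
#' observed one.
#'
#' @param genes data.frame (`gene, chrom, start, end, label`).
#' @param segments CNA segment data.frame.
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @return A list with `observed`, `p`, `n_eligible_pairs`,
#'   `null_counts`.
#' @export
boundary_orientation_test <- function(genes, segments, n_perm = 5000L,
                                      seed = 1L) {
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  cn <- gene_absolute_cn(genes, segments)
  n <- nrow(genes)
  adj <- which(genes$chrom[-n] == genes$chrom[-1])  # i, i+1 adjacent
  if (!length(adj)) {
    warning("no adjacent gene pairs; p = 1", call. = FALSE)
    return(list(observed = 0L, p = 1, n_eligible_pairs = 0L,
                null_counts = integer(0)))
  }
  ## per adjacent pair: sublines where CNs differ, and who is higher
  a_higher <- b_higher <- rep(FALSE, length(adj))
  for (k in seq_along(adj)) {
    i <- adj[k]
    d <- cn[i, ] - cn[i + 1, ]
    d <- d[!is.na(d)]
    a_higher[k] <- any(d > 0)
    b_higher[k] <- any(d < 0)
  }
  count_for <- function(lab) {
    la <- lab[adj]; lb <- lab[adj + 1L]
    onctsg <- (la == "ONC" & lb == "TSG") | (la == "TSG" & lb == "ONC")
    onc_high <- (la == "ONC" & a_higher & lb == "TSG") |
      (lb == "ONC" & b_higher & la == "TSG")
    sum(onctsg & onc_high)
  }
  observed <- count_for(genes$label)
  eligible <- sum((a_higher | b_higher) &
                    ((genes$label[adj] == "ONC" &
                        genes$label[adj + 1L] == "TSG") |
                       (genes$label[adj] == "TSG" &
                          genes$label[adj + 1L] == "ONC")))
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    count_for(sample(genes$label))
  }, numeric(1))
  list(observed = observed, p = mean(null_counts >= observed),
       n_eligible_pairs = eligible, null_counts = null_counts)
}

#' Timing of a whole-chromosome copy-neutral LOH from clonal SNV counts
#'
#' With `H` observed homozygous clonal SNVs and `C` total observed clonal
#' SNVs on the chromosome, both scenarios — loss of heterozygosity
#' followed by duplication of the remaining haplotype, and mitotic
#' nondisjunction followed by LOH in the trisomic cell — bound the
#' fraction of trunk time elapsed before the duplication event by
#' `2H / (C + H)` (the unobserved SNVs on the lost copy are added to the
#' denominator; pre-event SNVs are at most twice the observed homozygous
#' count).
#'
#' @param homozygous_clonal `H`, observed homozygous clonal SNV count.
#' @param total_clonal `C`, all observed clonal SNVs on the chromosome
#'   (`H <= C`, `C > 0`).
#' @param scenario `"loh_then_duplication"` or
#'   `"nondisjunction_then_loh"`.
#' @return The timing fraction in `[0, 1]`.
#' @export
cn_loh_timing <- function(homozygous_clonal, total_clonal,
                          scenario = c("loh_then_duplication",
                                       "nondisjunction_then_loh")) {
  scenario <- match.arg(scenario)
  H <- homozygous_clonal; C <- total_clonal
  if (any(C <= 0)) stop("total_clonal must be positive", call. = FALSE)
  if (any(H > C)) stop("homozygous count exceeds total", call. = FALSE)
  if (scenario == "loh_then_duplication") {
    ## pre-duplication SNVs <= 2H; lost-copy SNVs add H to the total
    2 * H / (C + H)
  } else {
    ## pre-nondisjunction 2H; post-event heterozygous clonal SNVs C - H
    ## (already normalized to two copies of genomic content)
    2 * H / (2 * H + (C - H))
  }
}
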