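#' Parameters for the tree-input SNV filter cascade
#'
#' @param missing_cov_max Entries with depth at or below this are set to
#'   missing (default 10 reads, inclusive).
#' @param site_cov_min Sites whose mean/median depth across sublines is
#'   strictly below this are dropped (default 20 reads).
#' @param vaf_min Sites whose mean/median VAF over present sublines is
#'   strictly below this are dropped (default 1/3).
#' @param absent_alt_fraction Sites with alt-allele read support in at
#'   least this fraction of called-absent sublines are dropped (default
#'   0.5).
#' @return A list of class `site_filter_params`.
#' @export
site_filter_params <- function(missing_cov_max = 10L, site_cov_min = 20L,
                               vaf_min = 1 / 3, absent_alt_fraction = 0.5) {
  stopifnot(missing_cov_max >= 0, site_cov_min >= 0,
            vaf_min > 0, vaf_min < 1, absent_alt_fraction >= 0)
  structure(list(missing_cov_max = missing_cov_max,
                 site_cov_min = site_cov_min, vaf_min = vaf_min,
                 absent_alt_fraction = absent_alt_fraction),
            class = "site_filter_params")
}

#' Filter somatic SNVs into a phylogenetically informative genotype matrix
#'
#' Applies, in order: (1) drop sites overlapping a copy-number loss in any
#' subline; (2) drop private and clonal sites; (3) set entries with depth
#' \eqn{\le} `missing_cov_max` to missing; (4) drop sites with low
#' mean/median depth across sublines; (5) drop sites with low mean/median
#' VAF over present sublines (missing entries excluded); (6) drop sites
#' with alt-allele read support in at least half of the called-absent
#' sublines. A per-rule audit of removal counts is attached.
#'
#' `calls` should contain one row per (site, subline) with `status`
#' `"present"`/`"absent"` plus `depth` and `alt_depth`; combinations that
#' are missing from the table are treated as absent with zero depth.
#'
#' @param calls Long data.frame of calls across all sublines (columns
#'   `chrom, pos, ref, alt, subline, status, depth, alt_depth`).
#' @param loss_regions Loss-region data.frame (`chrom, start, end,
#'   subline`), 0-based half-open, or `NULL`.
#' @param params A [site_filter_params()] object.
#' @param filter_logic `"both"` (default): drop when both the mean and the
#'   median are below threshold in rules 4-5; `"either"`: drop when either
#'   is.
#' @param sublines Optional character vector fixing the subline set and
#'   column order.
#' @return An object of class `genotype_matrix`: list with `sites`
#'   (data.frame), `sublines`, `status`/`depth`/`alt_depth` matrices and
#'   an `audit` vector of per-rule removal counts.
#' @export
prepare_tree_snvs <- function(calls, loss_regions = NULL,
                              params = site_filter_params(),
                              filter_logic = c("both", "either"),
                              sublines = NULL) {
  filter_logic <- match.arg(filter_logic)
  if (is.null(sublines)) sublines <- sort(unique(calls$subline))
  audit <- c(loss_overlap = 0L, uninformative = 0L, low_site_coverage = 0L,
             low_vaf = 0L, alt_in_absent = 0L)
  if (is.null(calls) || nrow(calls) == 0L) {
    return(new_genotype_matrix(empty_sites(), sublines,
                               audit = c(input_sites = 0L, audit,
                                         output_sites = 0L)))
  }
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  ukey <- unique(key)
  sites <- calls[match(ukey, key), c("chrom", "pos", "ref", "alt")]
  rownames(sites) <- NULL
  si <- match(key, ukey)
  sj <- match(calls$subline, sublines)
  dim_ <- c(length(ukey), length(sublines))
  depth <- matrix(0L, dim_[1], dim_[2])
  alt_depth <- matrix(0L, dim_[1], dim_[2])
  present <- matrix(FALSE, dim_[1], dim_[2])
  idx <- cbind(si, sj)
  depth[idx] <- ifelse(is.na(calls$depth), 0L, calls$depth)
  alt_depth[idx] <- ifelse(is.na(calls$alt_depth), 0L, calls$alt_depth)
  present[idx] <- calls$status == "present"
  n_in <- nrow(sites)

  summ_below <- function(m, thr) {
    mn <- rowMeans(m)
    md <- apply(m, 1, stats::median)
    if (filter_logic == "both") (mn < thr) & (md < thr)
    else (mn < thr) | (md < thr)
  }

  ## rule 1: overlap with a loss region in >= 1 subline
  if (!is.null(loss_regions) && nrow(loss_regions)) {
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$pos, width = 1L))
    lr <- GenomicRanges::GRanges(
      loss_regions$chrom,
      IRanges::IRanges(loss_regions$start + 1L, loss_regions$end))
    drop1 <- GenomicRanges::countOverlaps(gr, lr) > 0
  } else drop1 <- rep(FALSE, nrow(sites))
  audit["loss_overlap"] <- sum(drop1)
  keep <- !drop1
  sites <- sites[keep, , drop = FALSE]
  depth <- depth[keep, , drop = FALSE]
  alt_depth <- alt_depth[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]

  ## rule 2: private or clonal sites are uninformative
  np <- rowSums(present)
  drop2 <- np <= 1L | np == length(sublines)
  audit["uninformative"] <- sum(drop2)
  sites <- sites[!drop2, , drop = FALSE]
  depth <- depth[!drop2, , drop = FALSE]
  alt_depth <- alt_depth[!drop2, , drop = FALSE]
  present <- present[!drop2, , drop = FALSE]

  ## rule 3: low-coverage entries become missing (inclusive threshold)
  missing <- depth <= params$missing_cov_max

  ## rule 4: sites with consistently low coverage (missing entries count)
  if (nrow(sites)) {
    drop4 <- summ_below(depth, params$site_cov_min)
  } else drop4 <- logical(0)
  audit["low_site_coverage"] <- sum(drop4)
  sites <- sites[!drop4, , drop = FALSE]
  depth <- depth[!drop4, , drop = FALSE]
  alt_depth <- alt_depth[!drop4, , drop = FALSE]
  present <- present[!drop4, , drop = FALSE]
  missing <- missing[!drop4, , drop = FALSE]

  ## rule 5: low VAF over present (non-missing) sublines
  if (nrow(sites)) {
    vaf <- ifelse(depth > 0, alt_depth / depth, NA_real_)
    vaf[!present | missing] <- NA_real_
    mn <- rowMeans(vaf, na.rm = TRUE)
    md <- apply(vaf, 1, stats::median, na.rm = TRUE)
    mn[is.nan(mn)] <- NA_real_
    low <- if (filter_logic == "both") (mn < params$vaf_min) &
             (md < params$vaf_min) else (mn < params$vaf_min) |
             (md < params$vaf_min)
    drop5 <- !is.na(low) & low
  } else drop5 <- logical(0)
  audit["low_vaf"] <- sum(drop5)
  sites <- sites[!drop5, , drop = FALSE]
  depth <- depth[!drop5, , drop = FALSE]
  alt_depth <- alt_depth[!drop5, , drop = FALSE]
  present <- present[!drop5, , drop = FALSE]
  missing <- missing[!drop5, , drop = FALSE]

  ## rule 6: alt support in too many called-absent sublines
  if (nrow(sites)) {
    absent <- !present
    supp <- absent & (alt_depth >= 1L)
    nab <- rowSums(absent)
    frac <- ifelse(nab > 0, rowSums(supp) / nab, 0)
    drop6 <- frac >= params$absent_alt_fraction & nab > 0
  } else drop6 <- logical(0)
  audit["alt_in_absent"] <- sum(drop6)
  sites <- sites[!drop6, , drop = FALSE]
  depth <- depth[!drop6, , drop = FALSE]
  alt_depth <- alt_depth[!drop6, , drop = FALSE]
  present <- present[!drop6, , drop = FALSE]
  missing <- missing[!drop6, , drop = FALSE]

  status <- matrix("absent", nrow(sites), length(sublines))
  status[present] <- "present"
  status[missing] <- "missing"
  new_genotype_matrix(sites, sublines, status, depth, alt_depth,
                      audit = c(input_sites = n_in, audit,
                                output_sites = nrow(sites)))
}

empty_sites <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

new_genotype_matrix <- function(sites, sublines, status = NULL, depth = NULL,
                                alt_depth = NULL, audit = NULL) {
  n <- nrow(sites)
  if (is.null(status)) status <- matrix(character(0), n, length(sublines))
  colnames(status) <- sublines
  if (!is.null(depth)) colnames(depth) <- sublines
  if (!is.null(alt_depth)) colnames(alt_depth) <- sublines
  structure(list(sites = sites, sublines = sublines, status = status,
                 depth = depth, alt_depth = alt_depth, audit = audit),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$sites), "sites x", length(x$sublines),
      "sublines\n")
  if (!is.null(x$audit)) {
    cat("Filter audit:\n")
    print(x$audit)
  }
  invisible(x)
}

#' Export a genotype matrix for the tree-search tool
#'
#' One row per site in deterministic (chrom, pos, alt) order, one column
#' per subline, entries 1/0/? for present/absent/missing, preceded by the
#' site key columns.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_genotype_matrix <- function(gm, path) {
  ord <- order(gm$sites$chrom, gm$sites$pos, gm$sites$alt)
  code <- matrix(c(present = "1", absent = "0",
                   missing = "?")[gm$status[ord, , drop = FALSE]],
                 nrow = length(ord))
  df <- cbind(gm$sites[ord, , drop = FALSE],
              as.data.frame(code, stringsAsFactors = FALSE))
  names(df) <- c("chrom", "pos", "ref", "alt", gm$sublines)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a genotype matrix written by [export_genotype_matrix()]
#' @param path TSV path.
#' @return A `genotype_matrix` (statuses only; depths are not stored).
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  sublines <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  sites <- data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                      ref = df$ref, alt = df$alt, stringsAsFactors = FALSE)
  status <- matrix(c(`1` = "present", `0` = "absent",
                     `?` = "missing")[as.matrix(df[, sublines,
                                                   drop = FALSE])],
                   nrow = nrow(df))
  new_genotype_matrix(sites, sublines, status)
}
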