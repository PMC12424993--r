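#' Construct a CpG-by-subline methylation count container
#'
#' @param sites data.frame with `chrom, pos` (1-based CpG positions),
#'   sorted by (chrom, pos).
#' @param n_mod Integer matrix of modified (methylated) read counts,
#'   sites x sublines, with subline column names.
#' @param n_total Integer matrix of total read counts, same shape.
#' @return An object of class `methyl_matrix`.
#' @export
methyl_matrix <- function(sites, n_mod, n_total) {
  stopifnot(nrow(sites) == nrow(n_mod), all(dim(n_mod) == dim(n_total)),
            !is.null(colnames(n_total)))
  if (any(n_mod > n_total) || any(n_mod < 0)) {
    stop("need 0 <= n_mod <= n_total", call. = FALSE)
  }
  o <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 n_mod = n_mod[o, , drop = FALSE],
                 n_total = n_total[o, , drop = FALSE],
                 sublines = colnames(n_total)),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("Methylation matrix:", nrow(x$sites), "CpG sites x",
      length(x$sublines), "sublines\n")
  invisible(x)
}

#' Read per-CpG methylation counts from a bedMethyl-like TSV
#'
#' Long format with header columns `chrom, pos, subline, n_mod, n_total`.
#'
#' @param path Path to the TSV.
#' @return A `methyl_matrix`.
#' @export
read_methyl_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "subline", "n_mod",
                                 "n_total"), "methylation")
  sublines <- sort(unique(df$subline))
  key <- paste(df$chrom, df$pos, sep = "\r")
  ukey <- unique(key)
  sites <- df[match(ukey, key), c("chrom", "pos")]
  rownames(sites) <- NULL
  idx <- cbind(match(key, ukey), match(df$subline, sublines))
  n_mod <- n_total <- matrix(0L, length(ukey), length(sublines),
                             dimnames = list(NULL, sublines))
  n_mod[idx] <- df$n_mod
  n_total[idx] <- df$n_total
  methyl_matrix(sites, n_mod, n_total)
}

#' Write a methyl_matrix to the long TSV format
#' @param mm A `methyl_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methyl_tsv <- function(mm, path) {
  long <- data.frame(
    chrom = rep(mm$sites$chrom, times = length(mm$sublines)),
    pos = rep(mm$sites$pos, times = length(mm$sublines)),
    subline = rep(mm$sublines, each = nrow(mm$sites)),
    n_mod = as.vector(mm$n_mod), n_total = as.vector(mm$n_total))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parameters for differential methylation calling
#'
#' @param min_cov Minimum total reads required in every subline for a CpG
#'   to enter the analysis (default 3).
#' @param min_cpgs Minimum consecutive qualifying CpGs in a DMR
#'   (default 10).
#' @param t_quantile_low,t_quantile_high Genome-wide empirical quantile
#'   cutoffs on the per-CpG statistic (defaults 0.025 / 0.975).
#' @param min_meandiff Minimum absolute mean smoothed difference over the
#'   run (default 0.2).
#' @param smoothing_window Half-width in bp of the smoothing window
#'   (default 1000).
#' @return A list of class `dmr_params`.
#' @export
dmr_params <- function(min_cov = 3L, min_cpgs = 10L,
                       t_quantile_low = 0.025, t_quantile_high = 0.975,
                       min_meandiff = 0.2, smoothing_window = 1000) {
  stopifnot(t_quantile_low > 0, t_quantile_high < 1,
            t_quantile_low < t_quantile_high, min_cpgs >= 1)
  structure(list(min_cov = min_cov, min_cpgs = min_cpgs,
                 t_quantile_low = t_quantile_low,
                 t_quantile_high = t_quantile_high,
                 min_meandiff = min_meandiff,
                 smoothing_window = smoothing_window),
            class = "dmr_params")
}

#' Smooth per-subline methylation fractions
#'
#' CpGs with coverage below `min_cov` in any subline are excluded, then
#' each subline's raw fractions are smoothed with a coverage-weighted
#' tricube kernel over CpGs within `smoothing_window` bp. Constant
#' profiles are left unchanged and isolated CpGs keep their raw fraction.
#'
#' @param mm A `methyl_matrix`.
#' @param params A [dmr_params()] object.
#' @return A list with `sites` (the retained CpGs) and `smoothed`
#'   (matrix of fractions in `[0, 1]`).
#' @export
smooth_methylation <- function(mm, params = dmr_params()) {
  keep <- apply(mm$n_total >= params$min_cov, 1, all)
  sites <- mm$sites[keep, , drop = FALSE]
  if (!nrow(sites)) {
    return(list(sites = sites,
                smoothed = matrix(numeric(0), 0, length(mm$sublines),
                                  dimnames = list(NULL, mm$sublines))))
  }
  n_mod <- mm$n_mod[keep, , drop = FALSE]
  n_total <- mm$n_total[keep, , drop = FALSE]
  frac <- n_mod / n_total
  h <- params$smoothing_window
  sm <- frac
  for (chr in unique(sites$chrom)) {
    ii <- which(sites$chrom == chr)
    pos <- sites$pos[ii]
    lo <- findInterval(pos - h, pos) + 1L   # first index with pos >= p-h
    hi <- findInterval(pos + h, pos)        # last index with pos <= p+h
    for (j in seq_along(ii)) {
      win <- ii[seq.int(lo[j], hi[j])]
      d <- abs(sites$pos[win] - pos[j]) / h
      w <- (1 - pmin(d, 1)^3)^3 * n_total[win, , drop = FALSE]
      sm[ii[j], ] <- colSums(w * frac[win, , drop = FALSE]) / colSums(w)
    }
  }
  list(sites = sites, smoothed = sm)
}

#' Per-CpG signal-to-noise statistics between two subline groups
#'
#' `t(i) = (mean_case - mean_control) / (pooled_sd + sd_floor)` on the
#' smoothed fractions, where `sd_floor` is the genome-wide 75th percentile
#' of the pooled standard deviation (a variance floor that stops
#' low-variance CpGs from dominating). The empirical quantile rank of each
#' statistic over all CpGs is returned as the corrected statistic.
#'
#' @param smooth Output of [smooth_methylation()].
#' @param case,control Character vectors of subline names (each of size
#'   at least 2).
#' @return A data.frame (`chrom, pos, t, qrank, mean_diff`).
#' @export
cpg_t_statistics <- function(smooth, case, control) {
  if (length(case) < 2 || length(control) < 2) {
    stop("case and control groups must both have at least 2 sublines",
         call. = FALSE)
  }
  sm <- smooth$smoothed
  stopifnot(all(c(case, control) %in% colnames(sm)))
  n1 <- length(case); n2 <- length(control)
  x1 <- sm[, case, drop = FALSE]; x2 <- sm[, control, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- (rowSums(x1 * x1) - n1 * m1 * m1) / (n1 - 1)
  v2 <- (rowSums(x2 * x2) - n2 * m2 * m2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  floor_ <- stats::quantile(pooled, 0.75, names = FALSE)
  t <- (m1 - m2) / (pooled + floor_)
  t[is.nan(t)] <- 0
  qrank <- rank(t, ties.method = "average") / (length(t) + 1)
  data.frame(chrom = smooth$sites$chrom, pos = smooth$sites$pos, t = t,
             qrank = qrank, mean_diff = m1 - m2, stringsAsFactors = FALSE)
}

#' Call differentially methylated regions from per-CpG statistics
#'
#' Maximal runs of consecutive CpGs (within a chromosome) whose quantile
#' rank falls beyond the same cutoff side, of length at least `min_cpgs`
#' and with absolute mean smoothed difference at least `min_meandiff`.
#'
#' @param stats Output of [cpg_t_statistics()].
#' @param params A [dmr_params()] object.
#' @return A data.frame (`chrom, start, end, n_cpgs, mean_diff,
#'   direction`) with 0-based half-open intervals spanning the CpGs;
#'   direction is `hyper`/`hypo` for the case group.
#' @export
call_dmrs <- function(stats, params = dmr_params()) {
  side <- ifelse(stats$qrank > params$t_quantile_high, 1L,
                 ifelse(stats$qrank < params$t_quantile_low, -1L, 0L))
  out <- list()
  for (chr in unique(stats$chrom)) {
    ii <- which(stats$chrom == chr)
    r <- rle(side[ii])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0L & r$lengths >= params$min_cpgs)) {
      run <- ii[seq.int(starts[k], ends[k])]
      md <- mean(stats$mean_diff[run])
      if (abs(md) >= params$min_meandiff) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = stats$pos[run[1]] - 1L,
          end = stats$pos[run[length(run)]], n_cpgs = length(run),
          mean_diff = md,
          direction = if (r$values[k] > 0) "hyper" else "hypo",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_diff = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Smooth, test and call DMRs between two subline groups
#'
#' @param mm A `methyl_matrix` (or a precomputed [smooth_methylation()]
#'   result via `smooth`).
#' @param case,control Character vectors of subline names.
#' @param params A [dmr_params()] object.
#' @param smooth Optional precomputed smoothing result (lets permutation
#'   tests reuse the label-independent smoothing).
#' @return The [call_dmrs()] data.frame.
#' @export
dmr_pipeline <- function(mm, case, control, params = dmr_params(),
                         smooth = NULL) {
  if (is.null(smooth)) smooth <- smooth_methylation(mm, params)
  call_dmrs(cpg_t_statistics(smooth, case, control), params)
}

#' Permutation test on the number of DMRs for a bipartition
#'
#' The null distribution is the DMR count over random case/control label
#' assignments of the same case size. When the number of distinct
#' assignments does not exceed `n_perm` they are enumerated exhaustively
#' (for 23 sublines and a case of 2 that is all 253 assignments);
#' otherwise `n_perm` distinct random assignments are drawn. The p value
#' is the literal fraction of null counts greater than or equal to the
#' observed count.
#'
#' @param mm A `methyl_matrix`.
#' @param case Character vector: the observed case group (size between 2
#'   and `n - 2`).
#' @param params A [dmr_params()] object.
#' @param n_perm Maximum number of assignments (default 1000).
#' @param seed Integer seed for the sampled mode.
#' @return A list with `p`, `observed`, `null_counts`, `exhaustive`.
#' @export
dmr_count_permutation_test <- function(mm, case, params = dmr_params(),
                                       n_perm = 1000L, seed = 1L) {
  sublines <- mm$sublines
  k <- length(case)
  if (k < 2 || k > length(sublines) - 2) {
    stop("case size must be between 2 and n_sublines - 2", call. = FALSE)
  }
  smooth <- smooth_methylation(mm, params)
  ## vectorized count path equivalent to call_dmrs(cpg_t_statistics(...))
  sm <- smooth$smoothed
  chrom_idx <- split(seq_len(nrow(sm)), smooth$sites$chrom)
  count_for <- function(cs) {
    ct <- setdiff(sublines, cs)
    n1 <- length(cs); n2 <- length(ct)
    x1 <- sm[, cs, drop = FALSE]; x2 <- sm[, ct, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- pmax((rowSums(x1 * x1) - n1 * m1 * m1) / (n1 - 1), 0)
    v2 <- pmax((rowSums(x2 * x2) - n2 * m2 * m2) / (n2 - 1), 0)
    pooled <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    t <- (m1 - m2) / (pooled + stats::quantile(pooled, 0.75,
                                               names = FALSE))
    t[is.nan(t)] <- 0
    qrank <- rank(t, ties.method = "average") / (length(t) + 1)
    side <- ifelse(qrank > params$t_quantile_high, 1L,
                   ifelse(qrank < params$t_quantile_low, -1L, 0L))
    diff <- m1 - m2
    count <- 0L
    for (ii in chrom_idx) {
      r <- rle(side[ii])
      ends <- cumsum(r$lengths)
      for (k in which(r$values != 0L & r$lengths >= params$min_cpgs)) {
        run <- ii[seq.int(ends[k] - r$lengths[k] + 1L, ends[k])]
        if (abs(mean(diff[run])) >= params$min_meandiff) {
          count <- count + 1L
        }
      }
    }
    count
  }
  observed <- count_for(case)
  n_assign <- choose(length(sublines), k)
  if (n_assign <= n_perm) {
    sets <- utils::combn(sublines, k, simplify = FALSE)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    seen <- character(0)
    sets <- list()
    while (length(sets) < n_perm) {
      cs <- sort(sample(sublines, k))
      key <- paste(cs, collapse = "\r")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        sets[[length(sets) + 1L]] <- cs
      }
    }
    exhaustive <- FALSE
  }
  null_counts <- vapply(sets, count_for, numeric(1))
  list(p = mean(null_counts >= observed), observed = observed,
       null_counts = null_counts, exhaustive = exhaustive)
}

#' Nested case groups along a linear (caterpillar) clade
#'
#' For a clade of `k` sublines ordered along the differentiation
#' trajectory, returns the suffix case groups of sizes `k - 3` down to 2
#' (a single 2-vs-2 cut for `k = 4`), each tested against the remainder of
#' the clade. Both sides of every cut have at least two sublines.
#'
#' @param ordering Character vector of at least 4 sublines in trajectory
#'   order.
#' @return A list of lists with elements `case` and `control`.
#' @export
caterpillar_cuts <- function(ordering) {
  k <- length(ordering)
  if (k < 4) stop("need a clade of at least 4 sublines", call. = FALSE)
  sizes <- if (k == 4) 2L else seq.int(k - 3L, 2L)
  lapply(sizes, function(s) {
    list(case = ordering[seq.int(k - s + 1L, k)],
         control = ordering[seq_len(k - s)])
  })
}

#' Merge overlapping intervals from several DMR sets
#'
#' @param dmrs A data.frame of DMR intervals (`chrom, start, end`), e.g.
#'   rbind of per-cut results.
#' @return A data.frame of merged candidate intervals.
#' @export
merge_dmr_intervals <- function(dmrs) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(dmrs, dmrs$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}
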