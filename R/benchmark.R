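## Pseudobulk truth sets from placed variants, and clonality-stratified
## precision/recall scoring of candidate call sets.

#' Define a pseudobulk mixture
#'
#' @param name Mixture name.
#' @param members Character vector of member sublines (non-empty).
#' @return A list of class `pseudobulk_spec`.
#' @export
pseudobulk_spec <- function(name, members) {
  stopifnot(length(members) >= 1, all(nzchar(members)))
  structure(list(name = name, members = unique(members)),
            class = "pseudobulk_spec")
}

#' Build the benchmarking truth set for a pseudobulk mixture
#'
#' Every placed variant carried by at least one member enters the truth
#' set; unplaced variants never do. A variant's carriers are the leaves
#' below its assigned branch minus sublines where it was regenotyped as
#' lost. Clonality in the mixture is `clonal` when all members carry it,
#' `private` when exactly one does, `subclonal` otherwise; the expected
#' VAF assumes heterozygous diploid loci: carriers / (2 x members).
#'
#' @param fit A `tree_harmonization` object (or a placements data.frame
#'   with a `tree` argument).
#' @param spec A [pseudobulk_spec()].
#' @param tree Required when `fit` is a data.frame.
#' @return A data.frame (`variant_id, type, chrom, pos, clonality,
#'   n_carriers, expected_vaf`).
#' @export
build_truth_set <- function(fit, spec, tree = NULL) {
  if (inherits(fit, "tree_harmonization")) {
    placements <- fit$placements
    tree <- fit$tree
  } else placements <- fit
  stopifnot(!is.null(tree))
  bad <- setdiff(spec$members, tree$tip.label)
  if (length(bad)) stop("unknown member subline(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  placed <- placements[!is.na(placements$node), , drop = FALSE]
  rows <- vector("list", nrow(placed))
  m <- length(spec$members)
  for (i in seq_len(nrow(placed))) {
    carriers <- leaves_below(tree, placed$node[i])
    lost <- strsplit(placed$regenotyped_sublines[i], ",", fixed = TRUE)[[1]]
    carriers <- setdiff(carriers, lost)
    inmix <- intersect(carriers, spec$members)
    if (!length(inmix)) next
    rows[[i]] <- data.frame(
      variant_id = placed$variant_id[i], type = placed$type[i],
      chrom = placed$chrom[i], pos = placed$pos[i],
      clonality = if (length(inmix) == m) "clonal"
                  else if (length(inmix) == 1L) "private" else "subclonal",
      n_carriers = length(inmix), expected_vaf = length(inmix) / (2 * m),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no placed variant is carried by any mixture member",
            call. = FALSE)
    out <- data.frame(variant_id = character(), type = character(),
                      chrom = character(), pos = integer(),
                      clonality = character(), n_carriers = integer(),
                      expected_vaf = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Score a candidate call set against a pseudobulk truth set
#'
#' SNVs match on exact (chrom, pos, ref, alt); SVs match on type with
#' breakend positions within `sv_tolerance` bp (insertions additionally
#' on length within `ins_length_tol`). Precision and recall are reported
#' overall and per truth-clonality stratum. False positives carry no
#' truth clonality and therefore count against the overall precision
#' only.
#'
#' @param candidate data.frame of candidate calls: SNV rows need
#'   `chrom, pos, ref, alt`; SV rows need `sv_type, chrom, pos` (and
#'   optionally `length`). A `type` column distinguishes `"SNV"` from SV
#'   types.
#' @param truth A [build_truth_set()] data.frame; SNV `variant_id`s
#'   encode (chrom, pos, ref, alt).
#' @param sv_tolerance Breakend tolerance in bp (default 50).
#' @param ins_length_tol Relative insertion length tolerance
#'   (default 0.2).
#' @return A data.frame (`stratum, tp, fp, fn, precision, recall`), with
#'   strata `overall, clonal, subclonal, private`.
#' @export
score_calls <- function(candidate, truth, sv_tolerance = 50,
                        ins_length_tol = 0.2) {
  if (is.null(candidate$type)) candidate$type <- "SNV"
  cand_snv <- candidate[candidate$type == "SNV", , drop = FALSE]
  cand_sv <- candidate[candidate$type != "SNV", , drop = FALSE]
  truth_snv <- truth[truth$type == "SNV", , drop = FALSE]
  truth_sv <- truth[truth$type != "SNV", , drop = FALSE]

  matched_truth <- rep(FALSE, nrow(truth))
  n_fp <- 0L
  ## SNVs: exact identity via the encoded variant_id
  if (nrow(cand_snv)) {
    bad <- is.na(cand_snv$pos) | is.na(cand_snv$chrom)
    if (any(bad)) {
      warning(sum(bad), " malformed candidate record(s) skipped",
              call. = FALSE)
      cand_snv <- cand_snv[!bad, , drop = FALSE]
    }
    key <- sprintf("snv_%s_%d_%s_%s", cand_snv$chrom, cand_snv$pos,
                   cand_snv$ref, cand_snv$alt)
    hit <- match(key, truth$variant_id)
    matched_truth[stats::na.omit(hit)] <- TRUE
    n_fp <- n_fp + sum(is.na(hit))
  }
  ## SVs: tolerance matching on type + position (+ insertion length)
  if (nrow(cand_sv)) {
    for (i in seq_len(nrow(cand_sv))) {
      ok <- which(!matched_truth & truth$type == cand_sv$type[i] &
                    truth$chrom == cand_sv$chrom[i] &
                    abs(truth$pos - cand_sv$pos[i]) <= sv_tolerance)
      if (length(ok) && cand_sv$type[i] == "INS" &&
          !is.null(cand_sv$length) && !is.null(truth$length)) {
        ok <- ok[abs(truth$length[ok] - cand_sv$length[i]) <=
                   ins_length_tol * pmax(truth$length[ok], 1)]
      }
      if (length(ok)) matched_truth[ok[1]] <- TRUE else n_fp <- n_fp + 1L
    }
  }
  strata <- c("overall", "clonal", "subclonal", "private")
  rows <- lapply(strata, function(s) {
    in_s <- if (s == "overall") rep(TRUE, nrow(truth))
            else truth$clonality == s
    tp <- sum(matched_truth & in_s)
    fn <- sum(!matched_truth & in_s)
    fp <- if (s == "overall") n_fp else 0L
    data.frame(stratum = s, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
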