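#' A tiny fixed dataset with hand-checkable placements
#'
#' Six sublines in two clades, `((A,(B,C)),(D,(E,F)))`, with eight SNVs,
#' a handful of SVs and one shared copy-number gain. Every placement can
#' be verified by hand against [min_support()] (clade of 3 needs 2
#' carriers; the full set of 6 needs 5):
#'
#' * `v1` called in all six sublines: clonal at the root.
#' * `v2` called in A,B,C: subclonal at the first clade.
#' * `v3` called in B,C: subclonal at the (B,C) cherry.
#' * `v4` called in D only: private.
#' * `v5` called in A,B with a deletion over its position in C: placed at
#'   the first clade; C is regenotyped as lost.
#' * `v6` called in A,B,D,E (support 4 < 5: unplaced on its own) with a
#'   deletion over its position in C: rescued to clonal with C lost.
#'   Removing C's deletion record leaves `v6` unplaced.
#' * `v7` called in D,E with a deletion over its position in F — but the
#'   deletion span also contains `v8`, called present in F, so the
#'   parsimony guard rejects the rescue and `v7` stays at the (D,(E,F))
#'   clade on its called support.
#' * `v8` called in F only: private.
#'
#' @return A list with `tree`, `snvs`, `svs`, `cnas`, `losses` and
#'   `expected` (a data.frame of the hand-derived placements).
#' @export
make_worked_example <- function() {
  tree <- validate_tree(ape::read.tree(
    text = "((A,(B,C)),(D,(E,F)));"))
  mk <- function(pos, sublines, ref = "A", alt = "T") {
    data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
               subline = sublines, status = "present", depth = 30L,
               alt_depth = 15L, vaf = 0.5, stringsAsFactors = FALSE)
  }
  snvs <- rbind(
    mk(1000, c("A", "B", "C", "D", "E", "F")),            # v1 clonal
    mk(2000, c("A", "B", "C")),                           # v2 subclonal
    mk(3000, c("B", "C")),                                # v3 cherry
    mk(4000, "D"),                                        # v4 private
    mk(5000, c("A", "B")),                                # v5 rescue C
    mk(6000, c("A", "B", "D", "E")),                      # v6 rescue C
    mk(7000, c("D", "E")),                                # v7 guard fires
    mk(7400, "F"))                                        # v8 inside del
  losses <- data.frame(
    chrom = "chr1",
    start = c(4900, 5900, 6900),
    end = c(5100, 6100, 7500),
    subline = c("C", "C", "F"),
    source = "sv_deletion", stringsAsFactors = FALSE)
  svs <- data.frame(
    variant_id = c("sv_001", "sv_002"),
    sv_type = c("DEL", "INS"),
    chrom1 = "chr2", pos1 = c(10000L, 50000L), chrom2 = "chr2",
    pos2 = c(30000L, 50000L), length = c(20000L, 300L),
    sublines = c("A,B,C,D,E,F", "A,B,C"), stringsAsFactors = FALSE)
  cnas <- data.frame(
    chrom = "chr3",
    start = c(1000L, 1000L, 1000L, 1000L),
    end = c(50000L, 50000L, 50000L, 80000L),
    copy_number = 3L,
    subline = c("D", "E", "F", "A"), stringsAsFactors = FALSE)
  expected <- data.frame(
    variant_id = c("snv_chr1_1000_A_T", "snv_chr1_2000_A_T",
                   "snv_chr1_3000_A_T", "snv_chr1_4000_A_T",
                   "snv_chr1_5000_A_T", "snv_chr1_6000_A_T",
                   "snv_chr1_7000_A_T", "snv_chr1_7400_A_T"),
    clonality = c("clonal", "subclonal", "subclonal", "private",
                  "subclonal", "clonal", "subclonal", "private"),
    regenotyped_sublines = c("", "", "", "", "C", "C", "", ""),
    stringsAsFactors = FALSE)
  list(tree = tree, snvs = snvs, svs = svs, cnas = cnas, losses = losses,
       expected = expected)
}
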