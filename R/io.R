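## Readers and writers for the external formats the package touches.
## Internal convention: 0-based half-open intervals everywhere; VCF is
## 1-based at the boundary, BED/TSV segment files are 0-based half-open.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    warning("empty ", what, " file: ", path, call. = FALSE)
    return(NULL)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file '", path, "' missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

parse_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) {
    if (!length(grep("^[^#]", lines))) return(NULL)  # headerless empty
    stop("VCF format error in '", path, "': no #CHROM header line",
         call. = FALSE)
  }
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  body <- lines[seq_along(lines) > hdr[1]]
  body <- body[!startsWith(body, "#")]
  if (!length(body)) return(NULL)
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != length(cols))) {
    stop("VCF format error in '", path, "': line ",
         which(n != length(cols))[1], " has ", n[n != length(cols)][1],
         " fields, expected ", length(cols), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  m
}

vcf_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read per-subline somatic SNV calls from a VCF file
#'
#' Expects a single-sample VCF v4.2 with `DP` (total depth) and `AD`
#' (ref,alt depths) in the FORMAT fields. Returns calls with status
#' `"present"`; 1-based `pos` is kept and the internal 0-based half-open
#' interval is exposed as `start`/`end`.
#'
#' @param path Path to the VCF.
#' @param subline Subline name to attach to the calls.
#' @return A data.frame with columns `chrom, pos, start, end, ref, alt,
#'   subline, status, depth, alt_depth, vaf`.
#' @export
read_snv_vcf <- function(path, subline) {
  m <- parse_vcf_lines(path)
  if (is.null(m)) {
    warning("no SNV records in '", path, "'", call. = FALSE)
    return(empty_snv_calls())
  }
  fmt <- strsplit(m[, "FORMAT"], ":", fixed = TRUE)
  sample_col <- ncol(m)
  vals <- strsplit(m[, sample_col], ":", fixed = TRUE)
  getf <- function(key) {
    mapply(function(f, v) {
      i <- match(key, f)
      if (is.na(i) || i > length(v)) NA_character_ else v[i]
    }, fmt, vals, USE.NAMES = FALSE)
  }
  depth <- suppressWarnings(as.integer(getf("DP")))
  ad <- getf("AD")
  alt_depth <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ",", fixed = TRUE),
                      function(x) if (length(x) >= 2) x[2] else NA_character_,
                      character(1))))
  pos <- as.integer(m[, "POS"])
  vaf <- ifelse(!is.na(depth) & depth > 0, alt_depth / depth, NA_real_)
  data.frame(
    chrom = m[, "CHROM"], pos = pos, start = pos - 1L, end = pos,
    ref = m[, "REF"], alt = m[, "ALT"], subline = subline,
    status = "present", depth = depth, alt_depth = alt_depth, vaf = vaf,
    stringsAsFactors = FALSE)
}

empty_snv_calls <- function() {
  data.frame(chrom = character(), pos = integer(), start = integer(),
             end = integer(), ref = character(), alt = character(),
             subline = character(), status = character(), depth = integer(),
             alt_depth = integer(), vaf = numeric(), stringsAsFactors = FALSE)
}

#' Read multi-sample structural variant calls from a VCF file
#'
#' Understands `SVTYPE`, `END` and `SVLEN` INFO keys plus symbolic ALT
#' alleles and BND mate notation (`N[chr:pos[` etc.). Carrier sublines are
#' the samples with a non-reference genotype.
#'
#' @param path Path to the (possibly multi-sample) VCF.
#' @return A data.frame with columns `variant_id, sv_type, chrom1, pos1,
#'   chrom2, pos2, length, sublines` (comma-joined carrier names).
#' @export
read_sv_vcf <- function(path) {
  m <- parse_vcf_lines(path)
  if (is.null(m)) {
    warning("no SV records in '", path, "'", call. = FALSE)
    return(empty_sv_calls())
  }
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  samples <- setdiff(colnames(m), fixed)
  info <- m[, "INFO"]
  svtype <- vcf_info_field(info, "SVTYPE")
  alt <- m[, "ALT"]
  svtype[is.na(svtype)] <- gsub("[<>]", "", alt[is.na(svtype)])
  endf <- suppressWarnings(as.integer(vcf_info_field(info, "END")))
  svlen <- suppressWarnings(as.integer(vcf_info_field(info, "SVLEN")))
  pos1 <- as.integer(m[, "POS"])
  chrom1 <- m[, "CHROM"]
  chrom2 <- chrom1
  pos2 <- endf
  bnd <- svtype == "BND"
  if (any(bnd)) {
    mate <- regmatches(alt[bnd], regexec("[][]([^:]+):([0-9]+)[][]", alt[bnd]))
    chrom2[bnd] <- vapply(mate, function(x) if (length(x) == 3) x[2]
                          else NA_character_, character(1))
    pos2[bnd] <- as.integer(vapply(mate, function(x) if (length(x) == 3) x[3]
                                   else NA_character_, character(1)))
  }
  carriers <- vapply(seq_len(nrow(m)), function(i) {
    gt <- sub(":.*$", "", m[i, samples])
    paste(samples[grepl("1", gt, fixed = TRUE)], collapse = ",")
  }, character(1))
  data.frame(
    variant_id = m[, "ID"], sv_type = svtype, chrom1 = chrom1, pos1 = pos1,
    chrom2 = chrom2, pos2 = pos2,
    length = ifelse(is.na(svlen), ifelse(is.na(pos2), NA_integer_,
                                         abs(pos2 - pos1)), abs(svlen)),
    sublines = carriers, stringsAsFactors = FALSE)
}

empty_sv_calls <- function() {
  data.frame(variant_id = character(), sv_type = character(),
             chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), length = integer(), sublines = character(),
             stringsAsFactors = FALSE)
}

#' Read integer copy-number segments from a TSV file
#'
#' Header columns `chrom, start, end, copy_number, subline`; coordinates
#' 0-based half-open. Segments of one subline must be non-overlapping per
#' chromosome.
#'
#' @param path Path to the TSV.
#' @return A data.frame of segments.
#' @export
read_cna_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "copy_number",
                                 "subline"), "CNA segment")
  if (is.null(df)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), copy_number = integer(),
                      subline = character(), stringsAsFactors = FALSE))
  }
  check_cna_segments(df)
  df
}

check_cna_segments <- function(df) {
  if (any(df$start >= df$end)) stop("CNA segment with start >= end",
                                    call. = FALSE)
  if (any(df$copy_number < 0)) stop("negative copy number", call. = FALSE)
  for (key in split(df, list(df$subline, df$chrom), drop = TRUE)) {
    o <- order(key$start)
    if (any(key$start[o][-1] < key$end[o][-nrow(key)])) {
      stop("overlapping CNA segments for subline ", key$subline[1],
           " on ", key$chrom[1], call. = FALSE)
    }
  }
  invisible(df)
}

#' Read loss regions (deletions and CN<=1 segments) from a BED file
#'
#' BED3+ with optional columns 4 (`subline`) and 5
#' (`source` in `sv_deletion`/`cn_loss`); 0-based half-open.
#'
#' @param path Path to the BED file.
#' @return A data.frame with columns `chrom, start, end, subline, source`.
#' @export
read_loss_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), subline = character(),
                      source = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    warning("empty loss BED file: ", path, call. = FALSE)
    return(empty)
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("loss BED needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    subline = if (ncol(df) >= 4) as.character(df[[4]])
                              else NA_character_,
                    source = if (ncol(df) >= 5) as.character(df[[5]])
                             else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("loss region with start >= end",
                                      call. = FALSE)
  out
}

#' Remove germline calls by variant identity and by region
#'
#' @param calls SNV call data.frame (as from [read_snv_vcf()]).
#' @param blacklist_variants data.frame with `chrom, pos, ref, alt`
#'   (1-based positions) of known germline variants, or `NULL`.
#' @param blacklist_regions data.frame with `chrom, start, end` (0-based
#'   half-open) of excluded regions, or `NULL`.
#' @return The filtered call data.frame.
#' @export
subtract_germline <- function(calls, blacklist_variants = NULL,
                              blacklist_regions = NULL) {
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(blacklist_variants) && nrow(blacklist_variants)) {
    key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
    bad <- paste(blacklist_variants$chrom, blacklist_variants$pos,
                 blacklist_variants$ref, blacklist_variants$alt, sep = "\r")
    keep <- keep & !(key %in% bad)
  }
  if (!is.null(blacklist_regions) && nrow(blacklist_regions) && nrow(calls)) {
    gr <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(calls$pos, width = 1L))
    bl <- GenomicRanges::GRanges(
      blacklist_regions$chrom,
      IRanges::IRanges(blacklist_regions$start + 1L, blacklist_regions$end))
    hit <- GenomicRanges::countOverlaps(gr, bl) > 0
    keep <- keep & !hit
  }
  calls[keep, , drop = FALSE]
}

## ---- writers (used by the synthetic generator and exports) ----

vcf_header <- function(samples, sv = FALSE) {
  c("##fileformat=VCFv4.2",
    if (sv) c('##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
              '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
              '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length">')
    else c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">'),
    if (sv) '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write per-subline SNV calls to a single-sample VCF
#' @param calls SNV call data.frame for one subline.
#' @param path Output path.
#' @param subline Sample name for the VCF column.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, path, subline) {
  hdr <- vcf_header(subline)
  rows <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          ".", "GT:DP:AD",
          sprintf("0/1:%d:%d,%d", calls$depth,
                  calls$depth - calls$alt_depth, calls$alt_depth),
          sep = "\t")
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write multi-sample SV calls to a VCF
#' @param svs SV data.frame as from [read_sv_vcf()].
#' @param sublines All sample names, in column order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, sublines, path) {
  hdr <- vcf_header(sublines, sv = TRUE)
  rows <- if (nrow(svs)) {
    vapply(seq_len(nrow(svs)), function(i) {
      s <- svs[i, ]
      carriers <- strsplit(s$sublines, ",", fixed = TRUE)[[1]]
      gts <- ifelse(sublines %in% carriers, "0/1", "0/0")
      if (s$sv_type == "BND") {
        alt <- sprintf("N[%s:%d[", s$chrom2, s$pos2)
        info <- "SVTYPE=BND"
      } else {
        alt <- sprintf("<%s>", s$sv_type)
        info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", s$sv_type, s$pos2,
                        s$length)
      }
      paste(c(s$chrom1, s$pos1, s$variant_id, "N", alt, ".", "PASS", info,
              "GT", gts), collapse = "\t")
    }, character(1))
  } else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write copy-number segments to TSV
#' @param segments CNA segment data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cna_tsv <- function(segments, path) {
  utils::write.table(
    segments[, c("chrom", "start", "end", "copy_number", "subline")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write loss regions to BED
#' @param losses Loss-region data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loss_bed <- function(losses, path) {
  utils::write.table(
    losses[, c("chrom", "start", "end", "subline", "source")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
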