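## Seeded generator of complete synthetic datasets with the statistical
## structure the placement engine and the downstream analyses assume:
## a clade-structured tree (one linear clade), branch-assigned SNVs/SVs
## with FN/FP noise (part of the FNs realized as overlapping deletions),
## copy-number events bounded by SV breakpoints (including parallel
## events), and CpG methylation with branch-shifted and monotonically
## drifting regions.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study design the package targets: 23 sublines in
#' 4 major clades, one of which (8 sublines) differentiates linearly; a
#' 15 percent variant-call false-negative rate with half of the dropouts caused
#' by overlapping deletions; a 1e-5 false-positive rate; heterozygous
#' diploid SNVs with VAF centred on 0.5.
#'
#' @param n_sublines Number of sublines (leaves).
#' @param n_clades Number of major clades (>= 2 for parallel CNAs).
#' @param caterpillar_size Size of the linear (caterpillar) clade.
#' @param n_snvs Total true somatic SNVs.
#' @param frac_clonal,frac_subclonal Fractions of SNVs placed at the
#'   trunk / at internal branches (the rest are private).
#' @param snv_depth Mean sequencing depth for simulated calls.
#' @param fn_rate Per-carrier false-negative probability (applied to
#'   variants whose true clade has at least 3 leaves; smaller clades
#'   demand full support, so a dropout there is unrecoverable by design).
#' @param frac_fn_deletion Fraction of FNs realized as a private
#'   overlapping deletion (recorded in the SV and loss sets).
#' @param fp_rate Per-(variant x subline) false-positive rate; FPs appear
#'   as private singleton calls.
#' @param n_svs Total true SVs.
#' @param n_cna_events Copy-number events (each bounded by an emitted SV).
#' @param parallel_fraction Fraction of CNA events organized as parallel
#'   pairs: same genomic region, distinct breakpoints, distinct clades.
#' @param n_meth_regions,cpg_per_region,cpg_spacing CpG region layout.
#' @param n_branch_shift_regions Regions whose mean shifts in one clade.
#' @param n_monotonic_regions Regions drifting linearly along the
#'   caterpillar order.
#' @param meth_effect Methylation effect size (fraction).
#' @param meth_coverage Mean read coverage per CpG.
#' @param meth_dispersion Beta-binomial dispersion (rho).
#' @param nonsyn_fraction,syn_fraction Fractions of SNVs annotated as
#'   non-synonymous / synonymous (rest `other`).
#' @param n_chroms,chrom_length Genome model.
#' @param seed Mandatory integer seed; a fixed seed reproduces the bundle
#'   exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sublines = 23L, n_clades = 4L,
                       caterpillar_size = 8L, n_snvs = 2000L,
                       frac_clonal = 0.08, frac_subclonal = 0.09,
                       snv_depth = 30, fn_rate = 0.15,
                       frac_fn_deletion = 0.5, fp_rate = 1e-5,
                       n_svs = 120L, n_cna_events = 10L,
                       parallel_fraction = 0.2, n_meth_regions = 40L,
                       cpg_per_region = 20L, cpg_spacing = 50L,
                       n_branch_shift_regions = 6L,
                       n_monotonic_regions = 6L, meth_effect = 0.3,
                       meth_coverage = 20, meth_dispersion = 0.02,
                       nonsyn_fraction = 0.4, syn_fraction = 0.2,
                       n_chroms = 5L, chrom_length = 10e6, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(n_clades >= 1, fn_rate >= 0, fn_rate < 1,
            frac_fn_deletion >= 0, frac_fn_deletion <= 1,
            caterpillar_size >= 4,
            n_sublines >= caterpillar_size + (n_clades - 1))
  if (parallel_fraction > 0 && n_clades < 2) {
    stop("parallel CNA events require at least 2 clades", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

## caterpillar clade with two interchangeable cherries, mirroring a
## linear differentiation pattern: (L1,((L2,L3),(L4,(...(Lk-1,Lk)))))
caterpillar_newick <- function(leaves) {
  k <- length(leaves)
  inner <- paste0("(", leaves[k - 1], ",", leaves[k], ")")
  for (i in rev(seq(4, k - 2))) inner <- paste0("(", leaves[i], ",", inner, ")")
  paste0("(", leaves[1], ",((", leaves[2], ",", leaves[3], "),", inner,
         "))")
}

random_clade_newick <- function(leaves) {
  if (length(leaves) == 1) return(leaves)
  if (length(leaves) == 2) return(paste0("(", leaves[1], ",", leaves[2],
                                         ")"))
  sub <- ape::rtree(length(leaves), tip.label = leaves, br = NULL)
  gsub(";$", "", ape::write.tree(sub))
}

#' Generate a complete synthetic dataset bundle
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_bundle`: list with `tree`,
#'   `caterpillar` (ordering + swap pairs), `snvs` (present calls),
#'   `snv_full` (all site x subline rows with depths, for the filter
#'   cascade), `svs`, `cnas`, `losses`, `methylation`,
#'   `signature_probs`, `annotations`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(2^30, 8)

  ## ---- tree ----
  set.seed(seeds[1])
  names_all <- sprintf("S%02d", seq_len(config$n_sublines))
  sizes <- c(config$caterpillar_size,
             rep(0L, max(0, config$n_clades - 1L)))
  if (config$n_clades > 1) {
    rest <- config$n_sublines - config$caterpillar_size
    base <- rest %/% (config$n_clades - 1L)
    sizes[-1] <- base
    extra <- rest - base * (config$n_clades - 1L)
    if (extra > 0) sizes[1 + seq_len(extra)] <- sizes[1 + seq_len(extra)] + 1L
  }
  idx <- split(names_all, rep(seq_along(sizes), sizes))
  cat_leaves <- idx[[1]]
  clade_nwk <- c(caterpillar_newick(cat_leaves),
                 vapply(idx[-1], random_clade_newick, character(1)))
  nwk <- clade_nwk[length(clade_nwk)]
  for (i in rev(seq_len(length(clade_nwk) - 1L))) {
    nwk <- paste0("(", clade_nwk[i], ",", nwk, ")")
  }
  tree <- validate_tree(ape::read.tree(text = paste0(nwk, ";")))
  caterpillar <- list(
    ordering = cat_leaves,
    swap_pairs = list(cat_leaves[2:3],
                      cat_leaves[(length(cat_leaves) - 1):
                                   length(cat_leaves)]),
    clades = idx)

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  internal_nodes <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  clade_size <- vapply(seq_len(ntip + tree$Nnode), function(v)
    length(leaves_below(tree, v)), integer(1))

  ## ---- genomic position lattice (keeps loss spans free of bystander
  ##      calls: no two SNVs closer than one lattice step) ----
  set.seed(seeds[2])
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  snv_zone <- floor(0.6 * config$chrom_length)
  n_needed <- config$n_snvs + 200L
  step <- max(1000, floor(snv_zone * config$n_chroms / (2 * n_needed)))
  slots <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(chrom = ch,
               pos = as.integer(seq(step, snv_zone - step, by = step)),
               stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_needed) stop("genome too small for n_snvs",
                                   call. = FALSE)
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]

  ## ---- true SNVs on branches ----
  n_clonal <- round(config$frac_clonal * config$n_snvs)
  n_sub <- round(config$frac_subclonal * config$n_snvs)
  n_priv <- config$n_snvs - n_clonal - n_sub
  branch <- c(rep(root, n_clonal),
              if (length(internal_nodes)) sample(internal_nodes, n_sub,
                                                 replace = TRUE),
              sample(seq_len(ntip), n_priv, replace = TRUE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_snvs, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  vars <- data.frame(
    variant_id = character(config$n_snvs),
    chrom = slots$chrom[seq_len(config$n_snvs)],
    pos = slots$pos[seq_len(config$n_snvs)], ref = ref, alt = alt,
    true_node = branch, true_node_label = node_label(tree, branch),
    clade_size = clade_size[branch], stringsAsFactors = FALSE)
  vars$variant_id <- sprintf("snv_%s_%d_%s_%s", vars$chrom, vars$pos,
                             vars$ref, vars$alt)

  ## ---- calls with FN/FP noise ----
  set.seed(seeds[3])
  call_rows <- vector("list", config$n_snvs)
  fn_truth <- vector("list", config$n_snvs)
  mask_dels <- list()
  half <- as.integer(step %/% 4)
  for (i in seq_len(config$n_snvs)) {
    carriers <- leaves_below(tree, vars$true_node[i])
    fn <- if (vars$clade_size[i] >= 3) {
      carriers[stats::runif(length(carriers)) < config$fn_rate]
    } else character(0)
    del_fn <- fn[stats::runif(length(fn)) < config$frac_fn_deletion]
    for (s in del_fn) {
      mask_dels[[length(mask_dels) + 1L]] <- data.frame(
        chrom = vars$chrom[i], start = vars$pos[i] - 1L - half,
        end = vars$pos[i] + half, subline = s, stringsAsFactors = FALSE)
    }
    called <- setdiff(carriers, fn)
    fn_truth[[i]] <- data.frame(
      variant_id = vars$variant_id[i],
      n_fn = length(fn), n_fn_deletion = length(del_fn),
      stringsAsFactors = FALSE)
    if (length(called)) {
      call_rows[[i]] <- data.frame(
        chrom = vars$chrom[i], pos = vars$pos[i], ref = vars$ref[i],
        alt = vars$alt[i], subline = called, stringsAsFactors = FALSE)
    }
  }
  snv_calls <- do.call(rbind, call_rows)
  ## false positives: private singleton calls at unused lattice positions
  n_fp <- stats::rbinom(1, config$n_snvs * ntip, config$fp_rate)
  fp_vars <- NULL
  if (n_fp > 0) {
    fp_slots <- slots[seq.int(config$n_snvs + 1L, config$n_snvs + n_fp), ,
                      drop = FALSE]
    fp_ref <- sample(bases, n_fp, replace = TRUE)
    fp_vars <- data.frame(
      chrom = fp_slots$chrom, pos = fp_slots$pos, ref = fp_ref,
      alt = vapply(fp_ref, function(r) sample(setdiff(bases, r), 1),
                   character(1)),
      subline = sample(names_all, n_fp, replace = TRUE),
      stringsAsFactors = FALSE)
    snv_calls <- rbind(snv_calls, fp_vars)
  }
  depth <- pmax(1L, stats::rpois(nrow(snv_calls), config$snv_depth))
  altd <- stats::rbinom(nrow(snv_calls), depth, 0.5)
  snv_calls$status <- "present"
  snv_calls$depth <- depth
  snv_calls$alt_depth <- pmax(1L, altd)
  snv_calls$vaf <- snv_calls$alt_depth / snv_calls$depth

  ## full site x subline table (absent rows carry background depths),
  ## used by the tree-construction filter cascade
  present_key <- paste(snv_calls$chrom, snv_calls$pos, snv_calls$subline,
                       sep = "\r")
  full <- expand.grid(vi = seq_len(config$n_snvs), subline = names_all,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- data.frame(chrom = vars$chrom[full$vi], pos = vars$pos[full$vi],
                     ref = vars$ref[full$vi], alt = vars$alt[full$vi],
                     subline = full$subline, stringsAsFactors = FALSE)
  fk <- paste(full$chrom, full$pos, full$subline, sep = "\r")
  m <- match(fk, present_key)
  full$status <- ifelse(is.na(m), "absent", "present")
  full$depth <- ifelse(is.na(m),
                       pmax(1L, stats::rpois(nrow(full),
                                             config$snv_depth)),
                       snv_calls$depth[m])
  full$alt_depth <- ifelse(is.na(m), 0L, snv_calls$alt_depth[m])

  ## ---- SVs ----
  set.seed(seeds[4])
  sv_zone <- c(floor(0.6 * config$chrom_length),
               floor(0.95 * config$chrom_length))
  sv_types <- sample(c("DEL", "INS", "DUP", "INV", "BND"), config$n_svs,
                     replace = TRUE, prob = c(0.4, 0.3, 0.12, 0.12, 0.06))
  sv_branch <- c(rep(root, round(0.08 * config$n_svs)),
                 if (length(internal_nodes))
                   sample(internal_nodes, round(0.09 * config$n_svs),
                          replace = TRUE))
  sv_branch <- c(sv_branch, sample(seq_len(ntip),
                                   config$n_svs - length(sv_branch),
                                   replace = TRUE))
  sv_rows <- lapply(seq_len(config$n_svs), function(i) {
    ch <- sample(chroms, 1)
    p1 <- sv_zone[1] + sample.int(sv_zone[2] - sv_zone[1] - 2e5, 1)
    type <- sv_types[i]
    len <- if (type == "INS") sample(50:1000, 1) else sample(1e4:1e5, 1)
    ch2 <- ch; p2 <- p1 + len
    if (type == "BND") { ch2 <- sample(setdiff(chroms, ch), 1)
      p2 <- sv_zone[1] + sample.int(sv_zone[2] - sv_zone[1], 1) }
    if (type == "INS") p2 <- p1
    data.frame(variant_id = sprintf("sv_%03d", i), sv_type = type,
               chrom1 = ch, pos1 = p1, chrom2 = ch2, pos2 = p2,
               length = len,
               sublines = paste(leaves_below(tree, sv_branch[i]),
                                collapse = ","),
               true_node = sv_branch[i],
               true_node_label = node_label(tree, sv_branch[i]),
               stringsAsFactors = FALSE)
  })
  svs <- do.call(rbind, sv_rows)

  ## ---- CNA events with SV-defined boundaries ----
  set.seed(seeds[5])
  n_par_pairs <- round(config$parallel_fraction * config$n_cna_events / 2)
  n_single <- config$n_cna_events - 2L * n_par_pairs
  cna_nodes_pool <- c(internal_nodes, seq_len(ntip))
  slot_w <- floor((sv_zone[2] - sv_zone[1]) /
                    max(1, ceiling(config$n_cna_events / config$n_chroms)))
  ev_slot <- 0L
  next_slot <- function() {
    ev_slot <<- ev_slot + 1L
    ch <- chroms[((ev_slot - 1L) %% config$n_chroms) + 1L]
    k <- (ev_slot - 1L) %/% config$n_chroms
    list(chrom = ch, lo = sv_zone[1] + k * slot_w,
         hi = sv_zone[1] + (k + 1L) * slot_w)
  }
  clade_mrcas <- vapply(idx, function(l) mrca_node(tree, l), integer(1))
  events <- list(); segs <- list(); cna_svs <- list()
  add_event <- function(node, chrom, start, end, dir, parallel_group) {
    id <- sprintf("cna_%03d", length(events) + 1L)
    cn <- if (dir == "gain") sample(3:5, 1) else sample(0:1, 1)
    carriers <- leaves_below(tree, node)
    events[[length(events) + 1L]] <<- data.frame(
      event_id = id, chrom = chrom, start = start, end = end,
      direction = dir, copy_number = cn, true_node = node,
      true_node_label = node_label(tree, node),
      parallel_group = parallel_group, stringsAsFactors = FALSE)
    segs[[length(segs) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, copy_number = cn,
      subline = carriers, stringsAsFactors = FALSE)
    cna_svs[[length(cna_svs) + 1L]] <<- data.frame(
      variant_id = paste0("sv_", id),
      sv_type = if (dir == "gain") "DUP" else "DEL", chrom1 = chrom,
      pos1 = start + 1L, chrom2 = chrom, pos2 = end, length = end - start,
      sublines = paste(carriers, collapse = ","), true_node = node,
      true_node_label = node_label(tree, node), stringsAsFactors = FALSE)
  }
  for (p in seq_len(n_par_pairs)) {
    sl <- next_slot()
    w <- floor(0.5 * (sl$hi - sl$lo))
    s1 <- sl$lo + 1000L; e1 <- s1 + w
    off <- sample(2000:10000, 1)
    s2 <- s1 + off; e2 <- min(e1 + off, sl$hi - 1000L)
    ## the pair spans the top-level split (clade 1 vs another clade) so
    ## the union of the two carrier sets only meets at the trunk, whose
    ## support threshold it cannot reach
    cl <- c(1L, sample(seq_along(clade_mrcas)[-1], 1))
    add_event(clade_mrcas[cl[1]], sl$chrom, s1, e1, "gain",
              sprintf("par_%d", p))
    add_event(clade_mrcas[cl[2]], sl$chrom, s2, e2, "gain",
              sprintf("par_%d", p))
  }
  for (q in seq_len(n_single)) {
    sl <- next_slot()
    w <- sample(floor(0.3 * slot_w):floor(0.8 * slot_w), 1)
    s <- sl$lo + 1000L
    dir <- if (stats::runif(1) < 0.7) "gain" else "loss"
    add_event(sample(cna_nodes_pool, 1), sl$chrom, s, s + w, dir, NA)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(), chrom = character(),
               start = integer(), end = integer(), direction = character(),
               copy_number = integer(), true_node = integer(),
               true_node_label = character(), parallel_group = character(),
               stringsAsFactors = FALSE)
  cnas <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               copy_number = integer(), subline = character(),
               stringsAsFactors = FALSE)
  svs <- rbind(svs, do.call(rbind, cna_svs))

  ## ---- loss regions: SV deletions + CN<=1 segments + masking dels ----
  del_losses <- do.call(rbind, c(list(NULL), lapply(
    which(svs$sv_type == "DEL"), function(i) {
      data.frame(chrom = svs$chrom1[i], start = svs$pos1[i] - 1L,
                 end = svs$pos2[i],
                 subline = strsplit(svs$sublines[i], ",")[[1]],
                 source = "sv_deletion", stringsAsFactors = FALSE)
    })))
  mask_df <- if (length(mask_dels)) do.call(rbind, mask_dels) else NULL
  if (!is.null(mask_df)) {
    mask_df$source <- "sv_deletion"
    svs <- rbind(svs, data.frame(
      variant_id = sprintf("sv_mask_%03d", seq_len(nrow(mask_df))),
      sv_type = "DEL", chrom1 = mask_df$chrom, pos1 = mask_df$start + 1L,
      chrom2 = mask_df$chrom, pos2 = mask_df$end,
      length = mask_df$end - mask_df$start, sublines = mask_df$subline,
      true_node = match(mask_df$subline, tree$tip.label),
      true_node_label = mask_df$subline, stringsAsFactors = FALSE))
  }
  cn_losses <- cnas[cnas$copy_number <= 1, , drop = FALSE]
  losses <- rbind(
    del_losses,
    if (!is.null(mask_df)) mask_df[, c("chrom", "start", "end", "subline",
                                       "source")],
    if (nrow(cn_losses)) data.frame(
      chrom = cn_losses$chrom, start = cn_losses$start,
      end = cn_losses$end, subline = cn_losses$subline,
      source = "cn_loss", stringsAsFactors = FALSE))

  ## ---- methylation ----
  set.seed(seeds[6])
  meth_zone <- floor(c(0.95, 1) * config$chrom_length)
  region_w <- config$cpg_per_region * config$cpg_spacing
  per_chrom <- ceiling(config$n_meth_regions / config$n_chroms)
  gap <- max(2000L,
             floor((meth_zone[2] - meth_zone[1] - per_chrom * region_w) /
                     max(1, per_chrom)))
  regions <- do.call(rbind, lapply(seq_len(config$n_meth_regions),
                                   function(r) {
    ch_i <- ((r - 1L) %% config$n_chroms) + 1L
    k <- (r - 1L) %/% config$n_chroms
    start <- meth_zone[1] + k * (region_w + gap)
    data.frame(region_id = sprintf("mr_%03d", r), chrom = chroms[ch_i],
               start = start, end = start + region_w,
               stringsAsFactors = FALSE)
  }))
  kinds <- c(rep("branch_shift", config$n_branch_shift_regions),
             rep("monotonic", config$n_monotonic_regions))
  regions$kind <- c(kinds, rep("background",
                               config$n_meth_regions - length(kinds)))
  regions$clade <- NA_integer_
  regions$direction <- 0
  base_mu <- stats::runif(config$n_meth_regions, 0.25, 0.75)
  regions$base_mu <- base_mu
  mu <- matrix(rep(base_mu, ntip), ncol = ntip,
               dimnames = list(NULL, names_all))
  for (r in which(regions$kind == "branch_shift")) {
    cl <- ((r - 1L) %% length(idx)) + 1L
    dir <- sample(c(-1, 1), 1)
    regions$clade[r] <- cl
    regions$direction[r] <- dir
    mu[r, idx[[cl]]] <- pmin(0.95, pmax(0.05, base_mu[r] +
                                          dir * config$meth_effect))
  }
  k_cat <- length(cat_leaves)
  for (r in which(regions$kind == "monotonic")) {
    dir <- sample(c(-1, 1), 1)
    regions$clade[r] <- 1L
    regions$direction[r] <- dir
    drift <- dir * config$meth_effect *
      ((seq_len(k_cat) - 1) / (k_cat - 1) - 0.5)
    mu[r, cat_leaves] <- pmin(0.95, pmax(0.05, base_mu[r] + drift))
  }
  sites <- do.call(rbind, lapply(seq_len(config$n_meth_regions),
                                 function(r) {
    data.frame(chrom = regions$chrom[r],
               pos = regions$start[r] +
                 config$cpg_spacing * seq_len(config$cpg_per_region),
               region = r, stringsAsFactors = FALSE)
  }))
  s0 <- (1 - config$meth_dispersion) / config$meth_dispersion
  n_total <- matrix(stats::rpois(nrow(sites) * ntip, config$meth_coverage),
                    nrow(sites), ntip, dimnames = list(NULL, names_all))
  p <- matrix(stats::rbeta(nrow(sites) * ntip,
                           mu[sites$region, ] * s0,
                           (1 - mu[sites$region, ]) * s0),
              nrow(sites), ntip)
  n_mod <- matrix(stats::rbinom(length(p), as.vector(n_total),
                                as.vector(p)),
                  nrow(sites), ntip, dimnames = list(NULL, names_all))
  methylation <- methyl_matrix(sites[, c("chrom", "pos")], n_mod, n_total)

  ## ---- signature probabilities and annotations ----
  set.seed(seeds[7])
  sig_names <- c("SBS1", "SBS5", "SBS7a", "SBS7b")
  trunk_w <- c(0.08, 0.12, 0.5, 0.3)    # UV-like signal at the trunk
  other_w <- c(0.45, 0.4, 0.08, 0.07)
  prob_rows <- lapply(seq_len(config$n_snvs), function(i) {
    carriers <- leaves_below(tree, vars$true_node[i])
    w <- if (vars$true_node[i] == root) trunk_w else other_w
    do.call(rbind, lapply(carriers, function(s) {
      a <- stats::rgamma(length(sig_names), shape = w * 30)
      data.frame(mutation_id = vars$variant_id[i], subline = s,
                 signature = sig_names, probability = a / sum(a),
                 stringsAsFactors = FALSE)
    }))
  })
  signature_probs <- do.call(rbind, prob_rows)
  cons <- sample(c("nonsynonymous", "synonymous", "other"), config$n_snvs,
                 replace = TRUE,
                 prob = c(config$nonsyn_fraction, config$syn_fraction,
                          1 - config$nonsyn_fraction -
                            config$syn_fraction))
  annotations <- data.frame(variant_id = vars$variant_id,
                            consequence = cons, stringsAsFactors = FALSE)

  structure(list(
    tree = tree, caterpillar = caterpillar, snvs = snv_calls,
    snv_full = full, svs = svs, cnas = cnas, losses = losses,
    methylation = methylation, signature_probs = signature_probs,
    annotations = annotations,
    truth = list(snvs = cbind(vars, do.call(rbind, fn_truth)[, -1]),
                 fp_snvs = fp_vars, cna_events = events,
                 meth_regions = regions),
    config = config), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic dataset:", length(x$tree$tip.label), "sublines,",
      nrow(x$truth$snvs), "true SNVs,", nrow(x$svs), "SV records,",
      nrow(x$truth$cna_events), "CNA events,",
      nrow(x$methylation$sites), "CpGs\n")
  invisible(x)
}

#' Write a synthetic bundle to a directory of standard-format files
#'
#' Emits `tree.nwk`, per-subline `snv/<subline>.vcf`, `sv.vcf`,
#' `cna.tsv`, `loss.bed`, `methylation.tsv`, `signature_probs.tsv`,
#' `annotations.tsv`, ground-truth TSVs under `truth/`, and a
#' `manifest.json` echoing the configuration.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "snv"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_tree(bundle$tree, file.path(dir, "tree.nwk"))
  for (s in bundle$tree$tip.label) {
    calls <- bundle$snvs[bundle$snvs$subline == s, , drop = FALSE]
    calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
    write_snv_vcf(calls, file.path(dir, "snv", paste0(s, ".vcf")), s)
  }
  write_sv_vcf(bundle$svs, bundle$tree$tip.label, file.path(dir, "sv.vcf"))
  write_cna_tsv(bundle$cnas, file.path(dir, "cna.tsv"))
  write_loss_bed(bundle$losses, file.path(dir, "loss.bed"))
  write_methyl_tsv(bundle$methylation, file.path(dir, "methylation.tsv"))
  utils::write.table(bundle$signature_probs,
                     file.path(dir, "signature_probs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$annotations,
                     file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$snvs, file.path(dir, "truth/snvs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$cna_events,
                     file.path(dir, "truth/cna_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- list.files(dir, recursive = TRUE)
  manifest <- list(config = unclass(bundle$config), files = files,
                   caterpillar = bundle$caterpillar[c("ordering")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with `tree`, `snvs`, `svs`, `cnas`, `losses`,
#'   `methylation`, `signature_probs`, `annotations`.
#' @export
read_bundle <- function(dir) {
  tree <- read_tree(file.path(dir, "tree.nwk"))
  snvs <- do.call(rbind, lapply(tree$tip.label, function(s) {
    read_snv_vcf(file.path(dir, "snv", paste0(s, ".vcf")), s)
  }))
  list(tree = tree, snvs = snvs,
       svs = read_sv_vcf(file.path(dir, "sv.vcf")),
       cnas = read_cna_tsv(file.path(dir, "cna.tsv")),
       losses = read_loss_bed(file.path(dir, "loss.bed")),
       methylation = read_methyl_tsv(file.path(dir, "methylation.tsv")),
       signature_probs = utils::read.delim(
         file.path(dir, "signature_probs.tsv"), stringsAsFactors = FALSE),
       annotations = utils::read.delim(
         file.path(dir, "annotations.tsv"), stringsAsFactors = FALSE))
}

#' Exchangeable-subline methylation data for calibration checks
#'
#' Generates a methylation matrix with per-subline regional offsets but no
#' group structure: sublines are exchangeable, so any case/control
#' bipartition is a draw from the null of the DMR-count permutation test.
#' Many regions keep the null DMR-count distribution dispersed, which is
#' what makes the literal-fraction p approximately uniform.
#'
#' @param n_sublines Number of sublines (default 12).
#' @param n_regions Number of CpG regions (default 150).
#' @param cpg_per_region CpGs per region (default 10).
#' @param spacing CpG spacing in bp (default 60).
#' @param region_sd Standard deviation of per-subline regional offsets
#'   (default 0.15).
#' @param coverage Mean read coverage (default 15).
#' @param seed Integer seed.
#' @return A `methyl_matrix`.
#' @export
simulate_exchangeable_methylation <- function(n_sublines = 12L,
                                              n_regions = 150L,
                                              cpg_per_region = 10L,
                                              spacing = 60L,
                                              region_sd = 0.15,
                                              coverage = 15, seed) {
  set.seed(seed)
  subl <- sprintf("M%02d", seq_len(n_sublines))
  sites <- data.frame(
    chrom = "chr1",
    pos = as.integer(outer(seq_len(cpg_per_region) * spacing,
                           (seq_len(n_regions) - 1L) * 5000L, "+")))
  mu0 <- rep(stats::runif(n_regions, 0.3, 0.7), each = cpg_per_region)
  off <- matrix(stats::rnorm(n_regions * n_sublines, 0, region_sd),
                n_regions)[rep(seq_len(n_regions),
                               each = cpg_per_region), ]
  mu <- pmin(0.95, pmax(0.05, mu0 + off))
  nt <- matrix(stats::rpois(length(mu), coverage), nrow(sites),
               n_sublines, dimnames = list(NULL, subl))
  nm <- matrix(stats::rbinom(length(mu), as.vector(nt), as.vector(mu)),
               nrow(sites), n_sublines, dimnames = list(NULL, subl))
  methyl_matrix(sites, nm, nt)
}

#' Gene labels independent of copy number, for calibration checks
#'
#' Generates a dense gene table with balanced ONC/TSG labels assigned
#' independently of per-subline copy-number profiles whose breakpoints
#' fall between genes; the observed labelling is then exchangeable with
#' permuted labellings in [boundary_orientation_test()].
#'
#' @param n_genes Number of genes (even; default 400).
#' @param n_sublines Number of sublines (default 8).
#' @param n_breakpoints Copy-number breakpoints per subline (default 40).
#' @param seed Integer seed.
#' @return A list with `genes` and `segments`.
#' @export
simulate_cn_label_null <- function(n_genes = 400L, n_sublines = 8L,
                                   n_breakpoints = 40L, seed) {
  set.seed(seed)
  W <- 100000L
  genes <- data.frame(
    gene = sprintf("g%03d", seq_len(n_genes)), chrom = "chr1",
    start = (seq_len(n_genes) - 1L) * W + 10000L,
    end = (seq_len(n_genes) - 1L) * W + 30000L,
    label = sample(rep(c("ONC", "TSG"), n_genes / 2)),
    stringsAsFactors = FALSE)
  segments <- do.call(rbind, lapply(seq_len(n_sublines), function(s) {
    bks <- sort(sample(seq_len(n_genes - 1L), n_breakpoints)) * W
    st <- c(0L, bks); en <- c(bks, n_genes * W)
    data.frame(chrom = "chr1", start = st, end = en,
               copy_number = sample(c(1, 2, 2, 3), length(st),
                                    replace = TRUE),
               subline = sprintf("S%d", s), stringsAsFactors = FALSE)
  }))
  list(genes = genes, segments = segments)
}
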