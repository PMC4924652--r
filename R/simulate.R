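## Synthetic mTSS-seq study generator.
##
## Generates a fully self-contained study -- genome, TSS annotation,
## DNA-encoded preference track, per-condition fragment sets, TF peaks,
## gene sets -- with planted, recoverable structure: four promoter
## architecture classes with nucleosome-depleted regions, 130-175 bp
## nucleosomal and <125 bp sub-nucleosomal fragment size modes,
## condition-specific redistribution of dyads toward the DNA-encoded
## preference track, 10-bp periodic A/T dinucleotide placement under
## dyads, and TF footprints with condition-specific binding multipliers.
## Identical (config, seed) produces byte-identical outputs.

#' Simulation configuration
#'
#' Defaults are the desk-scale stated world: 200 genes with 2 kb capture
#' windows, 2,000 nucleosomal fragments per gene with a ~152 bp size mode
#' (truncated to 120-200 bp), sub-nucleosomal footprints with a ~90 bp
#' mode (truncated to 50-124 bp), 20% of genes redistributed in the tumor
#' with full effect toward the DNA-encoded positions, occupancy
#' downweighted 0.6x downstream of the TSS in changed tumor genes, and
#' amplitude-1 period-10 A/T dinucleotide planting under dyads.
#'
#' @param n_genes number of genes.
#' @param window_flank half-width of the capture window around each TSS
#'   (bp).
#' @param chrom_count number of chromosomes genes are spread over.
#' @param nucleosome_len canonical protected length (bp), used for the
#'   dyad half-footprint (`len %/% 2` = 73) when planting sequence.
#' @param linker_len nominal linker length (bp), documentation of the
#'   ~200 bp repeat implied by the templates.
#' @param frag_count_per_gene nucleosomal fragments drawn per gene.
#' @param nuc_size_mode,nuc_size_sd nucleosomal fragment length mode/sd
#'   (bp); lengths truncated to [120, 200].
#' @param sub_size_mode,sub_size_sd sub-nucleosomal length mode/sd (bp);
#'   truncated to [50, 124].
#' @param sub_fraction_at_footprint expected footprint fragments per peak
#'   as a fraction of `frag_count_per_gene` (0.025 = 50 at defaults).
#' @param sub_background_per_gene diffuse sub-nucleosomal fragments per
#'   gene window (MNase debris not tied to a footprint).
#' @param redistribution_effect proportion in [0,1]: how far tumor dyads
#'   of changed genes move toward the model-preferred positions.
#' @param changed_gene_fraction proportion of genes planted as changed.
#' @param tumor_loss_weight multiplicative occupancy weight on dyads
#'   downstream of the TSS in changed tumor genes (default 0.6).
#' @param periodicity_period,periodicity_amplitude A/T dinucleotide
#'   planting period (bp) and amplitude in [0,1].
#' @param dyad_jitter_sd positional jitter of fragment midpoints around
#'   their dyad (bp).
#' @param alt_shift displacement (bp, downstream) of the model-preferred
#'   dyad layout of changed genes relative to the basal layout.
#' @param model_bump_sd Gaussian bump sd of the DNA-encoded preference
#'   track (bp).
#' @param chrom_len optional fixed chromosome length; an error is raised
#'   if the requested genes do not fit.
#' @param single_template optional template index (1-4): assign every
#'   gene this one architecture instead of the round-robin mix. Used for
#'   exchangeable-gene null calibrations, where per-gene correlation
#'   noise must not depend on profile shape.
#' @param seed master seed; all generator streams derive from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, window_flank = 1000L,
                       chrom_count = 2L, nucleosome_len = 147L,
                       linker_len = 53L, frag_count_per_gene = 2000L,
                       nuc_size_mode = 152, nuc_size_sd = 10,
                       sub_size_mode = 90, sub_size_sd = 15,
                       sub_fraction_at_footprint = 0.025,
                       sub_background_per_gene = 20L,
                       redistribution_effect = 1,
                       changed_gene_fraction = 0.2,
                       tumor_loss_weight = 0.6,
                       periodicity_period = 10L,
                       periodicity_amplitude = 1,
                       dyad_jitter_sd = 20,
                       alt_shift = 90L,
                       model_bump_sd = 30,
                       chrom_len = NULL,
                       single_template = NULL,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              window_flank = as.integer(window_flank),
              chrom_count = as.integer(chrom_count),
              nucleosome_len = as.integer(nucleosome_len),
              linker_len = as.integer(linker_len),
              frag_count_per_gene = as.integer(frag_count_per_gene),
              nuc_size_mode = nuc_size_mode, nuc_size_sd = nuc_size_sd,
              sub_size_mode = sub_size_mode, sub_size_sd = sub_size_sd,
              sub_fraction_at_footprint = sub_fraction_at_footprint,
              sub_background_per_gene = as.integer(sub_background_per_gene),
              redistribution_effect = redistribution_effect,
              changed_gene_fraction = changed_gene_fraction,
              tumor_loss_weight = tumor_loss_weight,
              periodicity_period = as.integer(periodicity_period),
              periodicity_amplitude = periodicity_amplitude,
              dyad_jitter_sd = dyad_jitter_sd,
              alt_shift = as.integer(alt_shift),
              model_bump_sd = model_bump_sd,
              chrom_len = if (is.null(chrom_len)) NULL else
                as.integer(chrom_len),
              single_template = if (is.null(single_template)) NULL else
                as.integer(single_template),
              seed = as.integer(seed))
  if (!is.null(single_template) &&
      (single_template < 1L || single_template > 4L))
    stop("sim_config: single_template must be in 1..4")
  counts <- c("n_genes", "window_flank", "chrom_count", "nucleosome_len",
              "frag_count_per_gene", "periodicity_period")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop("sim_config: ", f, " must be > 0")
  props <- c("sub_fraction_at_footprint", "redistribution_effect",
             "changed_gene_fraction", "tumor_loss_weight",
             "periodicity_amplitude")
  for (f in props)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must be in [0, 1]")
  if (cfg$nuc_size_mode <= cfg$sub_size_mode)
    stop("sim_config: nuc_size_mode must exceed sub_size_mode")
  structure(cfg, class = "sim_config")
}

#' The four planted promoter architecture templates
#'
#' Dyad offsets are relative to the TSS in the direction of
#' transcription. Templates 1 and 4 are both "strong +1 array" shapes
#' offset by ~30 bp (the most similar pair, so a k=3 clustering merges
#' them); template 3 carries two weight variants emphasizing the -1 or
#' the -2 nucleosome (so a k=5 clustering splits it); template 2 is a
#' wide-NDR distal arrangement. Pairwise template correlations stay
#' below 0.8.
#'
#' @return list of 4 templates, each with `cluster_id`, `dyad_offsets`,
#'   `dyad_weights` (first variant), `variants` (list of weight
#'   vectors), `ndr_span` (c(lo, hi), TSS-relative).
#' @export
architecture_templates <- function() {
  tpl <- list(
    list(cluster_id = 1L,
         dyad_offsets = c(-280L, 120L, 320L, 520L, 720L),
         variants = list(c(0.9, 1.0, 0.85, 0.7, 0.6)),
         ndr_span = c(-180L, 40L)),
    list(cluster_id = 2L,
         dyad_offsets = c(-650L, -450L, -250L, 250L, 450L, 650L),
         variants = list(c(0.7, 0.75, 0.8, 0.8, 0.75, 0.7)),
         ndr_span = c(-170L, 170L)),
    list(cluster_id = 3L,
         dyad_offsets = c(-320L, -120L, 250L, 450L),
         variants = list(c(0.55, 1.0, 0.3, 0.25),
                         c(1.0, 0.55, 0.3, 0.25)),
         ndr_span = c(-40L, 170L)),
    list(cluster_id = 4L,
         dyad_offsets = c(-260L, 150L, 350L, 550L, 750L),
         variants = list(c(0.8, 1.0, 0.9, 0.75, 0.65)),
         ndr_span = c(-180L, 70L)))
  for (t in tpl) validate_template(t)
  lapply(tpl, function(t) {
    t$dyad_weights <- t$variants[[1L]]
    t
  })
}

validate_template <- function(t, dyad_half = 73L) {
  if (length(t$dyad_offsets) == 0L) stop("template has no dyads")
  for (w in t$variants) {
    if (length(w) != length(t$dyad_offsets) || any(w < 0))
      stop("template weights must be non-negative, one per dyad")
    live <- t$dyad_offsets[w > 0]
    if (any(live + dyad_half >= t$ndr_span[1L] &
            live - dyad_half <= t$ndr_span[2L]))
      stop("NDR span overlaps a dyad footprint at positive weight")
  }
  invisible(t)
}

## gene layout (TSS-relative dyad offsets + weights) for one design row.
## role: "normal" = basal; "tumor" = displaced toward the model-preferred
## layout by redistribution_effect with downstream loss; "model" = the
## model-preferred layout itself.
gene_layout <- function(design_row, templates, cfg,
                        role = c("normal", "tumor", "model")) {
  role <- match.arg(role)
  t <- templates[[design_row$template]]
  w <- t$variants[[design_row$variant]]
  off <- t$dyad_offsets
  if (!design_row$changed || role == "normal")
    return(list(offsets = off, weights = w))
  alt <- off + cfg$alt_shift
  if (role == "model") return(list(offsets = alt, weights = w))
  shifted <- off + round(cfg$redistribution_effect * cfg$alt_shift)
  list(offsets = shifted,
       weights = w * ifelse(shifted > 0L, cfg$tumor_loss_weight, 1))
}

#' Generate the synthetic genome, TSS annotation and capture regions
#'
#' Genes are spaced so capture regions never overlap; each gene gets one
#' TSS with a seeded random strand, a template assignment (round-robin
#' over the four architectures, template 3 alternating its two
#' variants), and a seeded changed/unchanged label. Genome bases are
#' i.i.d. uniform A/C/G/T; periodic A/T planting under dyads is applied
#' separately by [plant_periodic_sequence()].
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `tss` (TSS table),
#'   `capture` (regions), `design` (per-gene truth: template, variant,
#'   changed), `chrom_sizes`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  flank <- cfg$window_flank
  spacing <- 2L * flank + 400L
  margin <- flank + 200L
  per_chrom <- diff(round(seq(0, cfg$n_genes,
                              length.out = cfg$chrom_count + 1L)))
  chrom_names <- sprintf("chr%d", seq_len(cfg$chrom_count))
  needed <- 2L * margin + (max(per_chrom) - 1L) * spacing
  chrom_len <- cfg$chrom_len %||% needed
  if (chrom_len < needed)
    stop(sprintf("chromosome length %d too short for %d genes (need %d)",
                 chrom_len, max(per_chrom), needed))
  tss_rows <- list()
  g <- 0L
  for (ci in seq_len(cfg$chrom_count)) {
    n <- per_chrom[ci]
    if (n == 0L) next
    pos <- margin + (seq_len(n) - 1L) * spacing
    tss_rows[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", g + seq_len(n)),
      chrom = chrom_names[ci], tss = pos, stringsAsFactors = FALSE)
    g <- g + n
  }
  tss <- do.call(rbind, tss_rows)
  tss$strand <- with_seed(sub_seed(cfg$seed, "strand"),
                          sample(c("+", "-"), nrow(tss), replace = TRUE))
  capture <- data.frame(chrom = tss$chrom,
                        start = pmax(tss$tss - flank, 0L),
                        end = pmin(tss$tss + flank, chrom_len),
                        stringsAsFactors = FALSE)
  genome <- with_seed(sub_seed(cfg$seed, "genome"), {
    seqs <- vapply(chrom_names, function(cn) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    }, "")
    Biostrings::DNAStringSet(seqs)
  })
  names(genome) <- chrom_names
  templates <- architecture_templates()
  design <- tss
  design$template <- if (is.null(cfg$single_template))
    rep_len(seq_along(templates), nrow(tss)) else
    rep(cfg$single_template, nrow(tss))
  design$variant <- 1L
  t3 <- which(design$template == 3L)
  design$variant[t3] <- rep_len(1:2, length(t3))
  n_changed <- round(cfg$changed_gene_fraction * nrow(tss))
  changed_idx <- with_seed(sub_seed(cfg$seed, "changed"),
                           sample(nrow(tss), n_changed))
  design$changed <- seq_len(nrow(tss)) %in% changed_idx
  list(genome = genome, tss = tss, capture = capture, design = design,
       templates = templates,
       chrom_sizes = setNames(rep(chrom_len, cfg$chrom_count),
                              chrom_names))
}

## absolute dyad positions of one layout for one gene
absolute_dyads <- function(design_row, layout) {
  if (design_row$strand == "+") design_row$tss + layout$offsets
  else design_row$tss - layout$offsets
}

#' Plant periodic A/T dinucleotide structure under dyads
#'
#' Within `dyad +/- halfwidth`, the probability of emitting an A or T at
#' distance d from the dyad is
#' `0.5 * (1 + amplitude * cos(2 * pi * d / period))`; bases outside
#' dyad footprints are untouched. Amplitude 0 redraws bases from the
#' background distribution (a null planting).
#'
#' @param genome a `DNAStringSet`.
#' @param dyads data.frame `chrom`, `pos` (0-based dyad positions).
#' @param period period in bp (default 10, the helical repeat).
#' @param amplitude modulation amplitude in [0, 1].
#' @param seed RNG seed.
#' @param halfwidth half-footprint in bp (default 73, i.e. 147/2).
#' @return the modified `DNAStringSet`.
#' @export
plant_periodic_sequence <- function(genome, dyads, period = 10L,
                                    amplitude = 1, seed = 1L,
                                    halfwidth = 73L) {
  stopifnot(amplitude >= 0, amplitude <= 1, period >= 2L)
  check_columns(dyads, c("chrom", "pos"))
  with_seed(as.integer(seed), {
    for (chrom in unique(dyads$chrom)) {
      if (!chrom %in% names(genome))
        stop("dyad on unknown chromosome ", chrom)
      centers <- dyads$pos[dyads$chrom == chrom]
      d <- rep(seq.int(-halfwidth, halfwidth), times = length(centers))
      gpos <- rep(centers, each = 2L * halfwidth + 1L) + d
      ok <- gpos >= 0L & gpos < Biostrings::width(genome[chrom])
      gpos <- gpos[ok]; d <- d[ok]
      ## overlapping footprints: the last-listed dyad wins
      keep <- !duplicated(gpos, fromLast = TRUE)
      gpos <- gpos[keep]; d <- d[keep]
      p_at <- pmin(pmax(0.5 * (1 + amplitude * cos(2 * pi * d / period)),
                        0), 1)
      is_at <- runif(length(gpos)) < p_at
      base <- ifelse(is_at,
                     ifelse(runif(length(gpos)) < 0.5, "A", "T"),
                     ifelse(runif(length(gpos)) < 0.5, "C", "G"))
      genome[[chrom]] <- Biostrings::replaceLetterAt(
        genome[[chrom]], at = gpos + 1L, letter = paste(base, collapse = ""))
    }
  })
  genome
}

#' DNA-encoded nucleosome-occupancy preference track
#'
#' A stand-in for a sequence-based occupancy model: per gene, a sum of
#' Gaussian bumps (sd `model_bump_sd`) at the model-preferred dyads
#' (basal dyads for unchanged genes, the displaced alternative layout
#' for changed genes), min-max scaled to [0, 1] per gene.
#'
#' @param annotation output of [generate_annotation()].
#' @param cfg the [sim_config()].
#' @return list with `matrix` (per-bp [signal_matrix()] of model scores
#'   over TSS +/- flank) and `bedgraph` (genome-coordinate track
#'   data.frame).
#' @export
generate_model_track <- function(annotation, cfg) {
  flank <- cfg$window_flank
  offsets <- seq.int(-flank, flank - 1L)
  design <- annotation$design
  values <- matrix(0, nrow = nrow(design), ncol = length(offsets),
                   dimnames = list(design$gene_id, NULL))
  for (i in seq_len(nrow(design))) {
    lay <- gene_layout(design[i, ], annotation$templates, cfg, "model")
    v <- numeric(length(offsets))
    for (j in seq_along(lay$offsets))
      v <- v + lay$weights[j] *
        exp(-((offsets - lay$offsets[j])^2) / (2 * cfg$model_bump_sd^2))
    rng <- range(v)
    if (rng[2L] == rng[1L]) stop("degenerate model window for gene ",
                                 design$gene_id[i])
    values[i, ] <- (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  mat <- signal_matrix(values, offsets, units = "model_score",
                       grid_step = 1L)
  bed <- lapply(seq_len(nrow(design)), function(i) {
    pos <- if (design$strand[i] == "+") design$tss[i] + offsets
           else design$tss[i] - offsets
    data.frame(chrom = design$chrom[i], start = pos, end = pos + 1L,
               score = round(values[i, ], 4L), stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, bed)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  rownames(bed) <- NULL
  list(matrix = mat, bedgraph = bed)
}

#' Generate TF peaks with planted binding multipliers
#'
#' Peaks are placed at each gene's NDR center (TF sites live in the
#' nucleosome-depleted region, which also plants the expected local
#' nucleosomal depletion at summits), with lengths drawn uniformly from
#' 150-400 bp and the summit at the peak center. Genes are distributed
#' round-robin over the factors; each factor carries planted
#' normal/tumor sub-nucleosomal intensity multipliers (e.g. tumor = 0.87
#' x normal plants a 13% binding decrease).
#'
#' @param annotation output of [generate_annotation()].
#' @param cfg the [sim_config()].
#' @param factors data.frame `factor`, `normal_mult`, `tumor_mult`; the
#'   default plants a 13% decrease for one factor and a 31% increase for
#'   the other.
#' @param seed RNG seed (default derived from `cfg$seed`).
#' @return peak data.frame `chrom`, `start`, `end`, `name`, `summit`,
#'   `factor`, `gene_id`, `normal_mult`, `tumor_mult`.
#' @export
generate_tf_peaks <- function(annotation, cfg,
                              factors = data.frame(
                                factor = c("TF_A", "TF_B"),
                                normal_mult = c(1, 1),
                                tumor_mult = c(0.87, 1.31),
                                stringsAsFactors = FALSE),
                              seed = sub_seed(cfg$seed, "peaks")) {
  design <- annotation$design
  fi <- rep_len(seq_len(nrow(factors)), nrow(design))
  lens <- with_seed(as.integer(seed),
                    sample(150:400, nrow(design), replace = TRUE))
  ndr_center <- vapply(seq_len(nrow(design)), function(i) {
    t <- annotation$templates[[design$template[i]]]
    as.integer(round(mean(t$ndr_span)))
  }, integer(1))
  center <- ifelse(design$strand == "+", design$tss + ndr_center,
                   design$tss - ndr_center)
  start <- center - lens %/% 2L
  peaks <- data.frame(
    chrom = design$chrom, start = start, end = start + lens,
    name = sprintf("%s_%s", factors$factor[fi], design$gene_id),
    summit = center,
    factor = factors$factor[fi],
    gene_id = design$gene_id,
    normal_mult = factors$normal_mult[fi],
    tumor_mult = factors$tumor_mult[fi],
    stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  peaks
}

#' Simulate one condition's fragment set
#'
#' Nucleosomal fragments: per gene, `frag_count_per_gene` draws of a dyad
#' (proportional to the condition-specific occupancy weights) with
#' Gaussian positional jitter, and a length ~ N(nuc mode, sd) truncated
#' to [120, 200]. In the tumor, dyads of changed genes are displaced
#' toward the model-preferred positions by
#' `redistribution_effect * alt_shift` and downweighted by
#' `tumor_loss_weight` downstream of the TSS. Sub-nucleosomal fragments
#' (length truncated to [50, 124]) arise at TF footprints with
#' Poisson counts scaled by the condition's planted multiplier, plus a
#' small diffuse background per gene. Fragments extending past the
#' chromosome are clipped and counted in `attr(x, "n_clipped")`.
#'
#' @param condition `"normal"` or `"tumor"`.
#' @param annotation output of [generate_annotation()].
#' @param cfg the [sim_config()].
#' @param peaks optional TF peaks from [generate_tf_peaks()]; when
#'   supplied, footprint fragments are added.
#' @param seed RNG seed (default derived from `cfg$seed` and the
#'   condition).
#' @return fragment data.frame with attributes `n_nucleosomal`,
#'   `n_footprint`, `n_background`, `n_clipped`, `total_fragments`.
#' @export
simulate_fragments <- function(condition = c("normal", "tumor"),
                               annotation, cfg, peaks = NULL,
                               seed = sub_seed(cfg$seed,
                                               paste0("frags_", condition))) {
  condition <- match.arg(condition)
  design <- annotation$design
  flank <- cfg$window_flank
  out <- with_seed(as.integer(seed), {
    chrom <- character(0); mid <- integer(0); len <- integer(0)
    ## nucleosomal fragments per gene
    per_gene <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      lay <- gene_layout(design[i, ], annotation$templates, cfg, condition)
      n <- cfg$frag_count_per_gene
      di <- sample.int(length(lay$offsets), n, replace = TRUE,
                       prob = lay$weights)
      rel <- lay$offsets[di] + as.integer(round(rnorm(n, 0, cfg$dyad_jitter_sd)))
      m <- if (design$strand[i] == "+") design$tss[i] + rel
           else design$tss[i] - rel
      per_gene[[i]] <- data.frame(
        chrom = design$chrom[i], mid = m,
        len = rtrunc_norm(n, cfg$nuc_size_mode, cfg$nuc_size_sd, 120L, 200L),
        stringsAsFactors = FALSE)
    }
    nuc <- do.call(rbind, per_gene)
    n_nuc <- nrow(nuc)
    ## diffuse sub-nucleosomal background per gene window
    n_bg_per <- cfg$sub_background_per_gene
    bg <- NULL
    if (n_bg_per > 0L) {
      n_bg <- n_bg_per * nrow(design)
      gidx <- rep(seq_len(nrow(design)), each = n_bg_per)
      bg <- data.frame(
        chrom = design$chrom[gidx],
        mid = design$tss[gidx] +
          sample.int(2L * flank, n_bg, replace = TRUE) - flank - 1L,
        len = rtrunc_norm(n_bg, cfg$sub_size_mode, cfg$sub_size_sd,
                          50L, 124L),
        stringsAsFactors = FALSE)
    }
    ## footprint sub-nucleosomal fragments at TF peaks
    fp <- NULL
    if (!is.null(peaks) && nrow(peaks) > 0L) {
      check_columns(peaks, c("chrom", "summit", "normal_mult", "tumor_mult"))
      mult <- if (condition == "normal") peaks$normal_mult
              else peaks$tumor_mult
      base <- cfg$sub_fraction_at_footprint * cfg$frag_count_per_gene
      n_fp <- rpois(nrow(peaks), base * mult)
      pidx <- rep(seq_len(nrow(peaks)), times = n_fp)
      if (length(pidx) > 0L)
        fp <- data.frame(
          chrom = peaks$chrom[pidx],
          mid = peaks$summit[pidx] +
            as.integer(round(rnorm(length(pidx), 0, 10))),
          len = rtrunc_norm(length(pidx), cfg$sub_size_mode,
                            cfg$sub_size_sd, 50L, 124L),
          stringsAsFactors = FALSE)
    }
    all <- rbind(nuc, bg, fp)
    list(all = all, n_nuc = n_nuc,
         n_bg = if (is.null(bg)) 0L else nrow(bg),
         n_fp = if (is.null(fp)) 0L else nrow(fp))
  })
  all <- out$all
  start <- all$mid - all$len %/% 2L
  end <- start + all$len
  ## clip at chromosome edges
  sizes <- annotation$chrom_sizes[all$chrom]
  clipped <- start < 0L | end > sizes
  start <- pmax(start, 0L)
  end <- pmin(end, as.integer(sizes))
  frags <- fragment_table(all$chrom, start, end)
  attr(frags, "n_nucleosomal") <- out$n_nuc
  attr(frags, "n_footprint") <- out$n_fp
  attr(frags, "n_background") <- out$n_bg
  attr(frags, "n_clipped") <- sum(clipped)
  attr(frags, "total_fragments") <- nrow(frags)
  attr(frags, "condition") <- condition
  frags
}

#' Simulate and write a complete synthetic study
#'
#' Generates annotation, genome with planted dyad periodicity, the
#' DNA-encoded model track, TF peaks, and per-patient normal/tumor
#' fragment sets, writing everything in standard formats next to a
#' machine-readable truth file (planted labels, effects, seeds).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param n_patients number of matched normal/tumor pairs (default 2).
#' @param factors TF factor table passed to [generate_tf_peaks()].
#' @return (invisibly) list with `paths`, plus the in-memory
#'   `annotation`, `model`, `peaks`, `fragments` (nested list
#'   patient -> condition) and `truth`.
#' @export
simulate_study <- function(cfg, dir, n_patients = 2L,
                           factors = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- generate_annotation(cfg)
  ## plant periodicity under every basal dyad
  dyads <- do.call(rbind, lapply(seq_len(nrow(ann$design)), function(i) {
    lay <- gene_layout(ann$design[i, ], ann$templates, cfg, "normal")
    data.frame(chrom = ann$design$chrom[i],
               pos = absolute_dyads(ann$design[i, ], lay),
               stringsAsFactors = FALSE)
  }))
  ann$genome <- plant_periodic_sequence(
    ann$genome, dyads, period = cfg$periodicity_period,
    amplitude = cfg$periodicity_amplitude,
    seed = sub_seed(cfg$seed, "plant"),
    halfwidth = cfg$nucleosome_len %/% 2L)
  model <- generate_model_track(ann, cfg)
  peaks <- if (is.null(factors)) generate_tf_peaks(ann, cfg)
           else generate_tf_peaks(ann, cfg, factors)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    tss = file.path(dir, "tss.bed"),
    capture = file.path(dir, "capture.bed"),
    model = file.path(dir, "model.bedGraph"),
    peaks = file.path(dir, "peaks.narrowPeak"),
    genesets = file.path(dir, "genesets.gmt"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(ann$genome, paths$genome)
  write_tss_bed(ann$tss, paths$tss)
  write_bed_regions(ann$capture, paths$capture)
  write_bedgraph(model$bedgraph, paths$model)
  write_narrowpeak(peaks, paths$peaks)
  sets <- c(list(changed = ann$design$gene_id[ann$design$changed]),
            setNames(lapply(1:4, function(k)
              ann$design$gene_id[ann$design$template == k]),
              sprintf("template_%d", 1:4)))
  write_gmt(sets, paths$genesets)
  fragments <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("patient%d", p)
    fragments[[pid]] <- list()
    for (cond in c("normal", "tumor")) {
      fr <- simulate_fragments(cond, ann, cfg, peaks,
                               seed = sub_seed(cfg$seed,
                                               paste0(pid, "_", cond)))
      fpath <- file.path(dir, sprintf("fragments_%s_%s.bed", pid, cond))
      write_fragments(fr, fpath)
      paths[[paste0("fragments_", pid, "_", cond)]] <- fpath
      fragments[[pid]][[cond]] <- fr
    }
  }
  truth <- list(
    config = unclass(cfg),
    n_patients = n_patients,
    genes = ann$design[, c("gene_id", "chrom", "tss", "strand",
                           "template", "variant", "changed")],
    factors = unique(peaks[, c("factor", "normal_mult", "tumor_mult")]),
    fragment_counts = lapply(fragments, function(pp)
      lapply(pp, function(fr)
        list(total = nrow(fr),
             nucleosomal = attr(fr, "n_nucleosomal"),
             footprint = attr(fr, "n_footprint"),
             background = attr(fr, "n_background"),
             clipped = attr(fr, "n_clipped")))))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(list(paths = paths, annotation = ann, model = model,
                 peaks = peaks, fragments = fragments, truth = truth))
}

#' Dyad-phased fragments for the periodicity analysis
#'
#' Builds a synthetic chromosome with `n` well-separated dyads, plants
#' the periodic A/T dinucleotide signal under each, and emits one
#' `length`-bp fragment exactly centered on each dyad (the idealized
#' nucleosome-protected fragment population used to verify the ~10 bp
#' helical repeat).
#'
#' @param n number of fragments/dyads.
#' @param length fragment length in bp (default 150).
#' @param period,amplitude planting parameters.
#' @param seed RNG seed.
#' @return list with `fragments` and `genome`.
#' @export
simulate_periodic_fragments <- function(n = 10000L, length = 150L,
                                        period = 10L, amplitude = 1,
                                        seed = 1L) {
  spacing <- as.integer(length + 100L)
  margin <- as.integer(length)
  chrom_len <- 2L * margin + (n - 1L) * spacing
  genome <- with_seed(sub_seed(seed, "periodic_genome"),
    Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
      collapse = "")))
  names(genome) <- "chrS"
  dyads <- data.frame(chrom = "chrS",
                      pos = margin + (seq_len(n) - 1L) * spacing)
  genome <- plant_periodic_sequence(genome, dyads, period = period,
                                    amplitude = amplitude,
                                    seed = sub_seed(seed, "periodic_plant"))
  start <- dyads$pos - length %/% 2L
  frags <- fragment_table("chrS", start, start + length)
  list(fragments = frags, genome = genome)
}
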