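## Seeded synthetic worlds with planted ground truth, emulating the structure
## of a two-replicate Cappable-seq + five time-point RNA-seq study on a single
## bacterial chromosome, at desk scale.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic world. Defaults state the emulated
#' study design: a single circular-in-principle (linear here) bacterial
#' chromosome, two Cappable-seq replicates, five developmental time points
#' (0/6/12/18/24 h), operons joined by intergenic gaps of at most 50 bp, and
#' planted promoter pile-ups far above the RRS threshold of 1.5. The
#' expression simulator uses 3 replicates and NB dispersion 0.05 so the
#' stand-in location test has power; planted effects are twice the class
#' threshold in fold space where the class geometry permits (strong_up
#' 8-fold = log2FC 3, down 4-fold down = log2FC -2) and midway between the
#' up and strong-up boundaries for the up class (log2FC 1.5, the only
#' placement from which the label is recoverable), in the proportions
#' 10:18:10:32 of the 70-gene focal catalog. Focal genes are embedded in a
#' genome-wide matrix of filler genes with a mostly-unchanged
#' developmental mix, the regime median-of-ratios normalization and BH
#' adjustment assume.
#'
#' @param seed integer seed; all generators are pure functions of the
#'   config.
#' @param chrom_length chromosome length in bp.
#' @param n_units number of transcription units.
#' @param operon_fraction fraction of units that are multi-gene operons.
#' @param operon_size_range genes per operon (uniform integer range).
#' @param gene_length_range gene length range in bp.
#' @param within_gap_range intra-operon intergenic distances (must stay
#'   within the 50 bp operon rule).
#' @param between_gap_range gaps between transcription units (must exceed
#'   50 bp).
#' @param tss_offset_range TSC-relative offsets for planted primary TSSs.
#' @param internal_promoter_fraction fraction of internal operon genes given
#'   a planted internal promoter.
#' @param tss_mean_reads mean read-start count per planted TSS (planted
#'   promoters carry most of the library so the absolute RRS >= 1.5
#'   threshold keeps its meaning at desk scale).
#' @param tss_dispersion NB dispersion of planted TSS counts.
#' @param tss_jitter maximal positional jitter of planted TSSs in bp.
#' @param noise_rate background read-start rate (reads/bp/strand).
#' @param multimap_fraction fraction of planted TSS reads emitted as k-way
#'   multimappers (a stress test for 1/k weighting, not a biological model).
#' @param multimap_k multimapper multiplicity.
#' @param n_replicates Cappable-seq replicates.
#' @param time_points developmental time points in hours.
#' @param expr_replicates RNA-seq replicates per time point.
#' @param nb_dispersion NB dispersion of the count matrix.
#' @param cluster_proportions named proportions of planted expression
#'   clusters.
#' @param cluster_effects named maximal log2FC per planted cluster.
#' @param n_filler_genes unannotated background genes added to the count
#'   matrix (the genome-wide context of the focal genes).
#' @param filler_proportions planted cluster mix of the filler genes.
#' @param baseline_mean_log mean of log(baseline expression).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       chrom_length = 200000L,
                       n_units = 30L,
                       operon_fraction = 0.4,
                       operon_size_range = c(2L, 4L),
                       gene_length_range = c(300L, 1500L),
                       within_gap_range = c(0L, 50L),
                       between_gap_range = c(150L, 600L),
                       tss_offset_range = c(-350L, -30L),
                       internal_promoter_fraction = 0.3,
                       tss_mean_reads = 3e4,
                       tss_dispersion = 0.1,
                       tss_jitter = 0L,
                       noise_rate = 0.02,
                       multimap_fraction = 0,
                       multimap_k = 2L,
                       n_replicates = 2L,
                       time_points = c(0, 6, 12, 18, 24),
                       expr_replicates = 3L,
                       nb_dispersion = 0.05,
                       cluster_proportions = c(strong_up = 10, up = 18,
                                               down = 10, unchanged = 32) / 70,
                       cluster_effects = c(strong_up = 3, up = 1.5,
                                           down = -2, unchanged = 0),
                       n_filler_genes = 400L,
                       filler_proportions = c(strong_up = 0.05, up = 0.10,
                                              down = 0.10, unchanged = 0.75),
                       baseline_mean_log = log(500)) {
  cfg <- as.list(environment())
  stopifnot(cfg$chrom_length > 0, cfg$n_units > 0,
            cfg$noise_rate >= 0, cfg$tss_mean_reads > 0,
            cfg$multimap_fraction >= 0, cfg$multimap_fraction <= 1,
            cfg$tss_jitter >= 0, 0 %in% cfg$time_points)
  class(cfg) <- "sim_config"
  cfg
}

.rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")

#' Generate a genome, annotation and operon truth
#'
#' Lays transcription units along a random chromosome: within-operon gaps
#' are drawn from `within_gap_range` (<= 50 bp, so the units are exactly the
#' operons recoverable by the distance rule) and between-unit gaps from
#' `between_gap_range` (> 50 bp). Strand is assigned per unit.
#'
#' @param config a [sim_config()].
#' @return list: `genome` ([Biostrings::DNAStringSet]), `annotation`
#'   ([new_annotation()]), `truth_operons` (data.frame gene_id, operon_id,
#'   n_genes, position_in_operon).
#' @export
gen_genome_annotation <- function(config) {
  .with_seed(config$seed, {
    chrom <- "chrSim"
    rows <- list()
    pos <- 600L  # headroom so upstream planted features stay on-chromosome
    gidx <- 0L
    for (u in seq_len(config$n_units)) {
      is_op <- runif(1) < config$operon_fraction
      n_genes <- if (is_op)
        sample(seq(config$operon_size_range[1], config$operon_size_range[2]), 1)
      else 1L
      strand <- sample(c("+", "-"), 1)
      for (k in seq_len(n_genes)) {
        len <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), 1)
        gidx <- gidx + 1L
        rows[[gidx]] <- data.frame(
          gene_id = sprintf("gene%03d", gidx), chrom = chrom,
          strand = strand, start = pos, end = pos + len - 1L,
          unit = u, stringsAsFactors = FALSE)
        pos <- pos + len  # pos now = end + 1, so adding d plants distance d
        if (k < n_genes)
          pos <- pos + sample(seq(config$within_gap_range[1],
                                  config$within_gap_range[2]), 1)
      }
      pos <- pos + sample(seq(config$between_gap_range[1],
                              config$between_gap_range[2]), 1)
    }
    genes <- do.call(rbind, rows)
    if (max(genes$end) + 600L > config$chrom_length)
      stop("planted genes overflow the chromosome; increase chrom_length")
    ann <- new_annotation(genes[, c("gene_id", "chrom", "strand", "start", "end")],
                          seqlengths = setNames(config$chrom_length, chrom))
    n_in_unit <- ave(genes$unit, genes$unit, FUN = length)
    ord <- ave(seq_len(nrow(genes)), genes$unit, FUN = seq_along)
    truth <- data.frame(
      gene_id = genes$gene_id,
      operon_id = sprintf("TU%04d", genes$unit),
      n_genes = as.integer(n_in_unit),
      position_in_operon = ifelse(genes$strand == "+", ord,
                                  n_in_unit - ord + 1L),
      stringsAsFactors = FALSE)
    genome <- Biostrings::DNAStringSet(setNames(.rdna(config$chrom_length), chrom))
    list(genome = genome, annotation = ann, truth_operons = truth)
  })
}

## Choose planted TSS sites: one per transcription unit upstream of the first
## gene (transcription order) plus internal promoters for a fraction of
## internal genes.
.plant_tss_sites <- function(config, world) {
  genes <- merge(world$annotation$genes, world$truth_operons, by = "gene_id")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  sites <- list()
  for (i in seq_len(nrow(genes))) {
    first <- genes$position_in_operon[i] == 1L
    internal <- !first &&
      runif(1) < config$internal_promoter_fraction
    if (!first && !internal) next
    offset <- sample(seq(config$tss_offset_range[1],
                         config$tss_offset_range[2]), 1)
    g <- genes[i, ]
    sites[[length(sites) + 1L]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      offset = as.integer(offset),
      pos = .offset_to_pos(offset, g$tsc, g$strand),
      mean_reads = exp(rnorm(1, log(config$tss_mean_reads), 0.3)),
      internal = !first, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, sites)
  truth$tss_truth_id <- sprintf("planted%03d", seq_len(nrow(truth)))
  truth
}

#' Generate Cappable-seq style 5'-end tracks with planted TSSs
#'
#' Plants one promoter TSS upstream of each transcription unit's first gene
#' and internal promoters for a fraction of internal genes, then draws
#' per-replicate read-start counts NB(mean, dispersion) at each site
#' (positionally jittered within +/- `tss_jitter`), adds uniform background
#' noise, and optionally re-emits a fraction of planted reads as k-way
#' multimappers with weight 1/k (plus k-1 decoy positions).
#'
#' @param config a [sim_config()].
#' @param world output of [gen_genome_annotation()].
#' @return list: `tracks` (list of [fiveprime_track()], one per replicate)
#'   and `truth` (planted sites: gene, offset, pre-jitter position, mean).
#' @export
gen_cappable_tracks <- function(config, world) {
  truth <- .with_seed(config$seed + 1L, .plant_tss_sites(config, world))
  L <- unname(world$annotation$seqlengths[1])
  chrom <- names(world$annotation$seqlengths)[1]
  tracks <- lapply(seq_len(config$n_replicates), function(r) {
    .with_seed(config$seed + 10L + r, {
      cnt <- rnbinom(nrow(truth), mu = truth$mean_reads,
                     size = 1 / config$tss_dispersion)
      jit <- if (config$tss_jitter > 0)
        sample(seq(-config$tss_jitter, config$tss_jitter), nrow(truth),
               replace = TRUE)
      else rep(0L, nrow(truth))
      pos <- pmin(pmax(truth$pos + jit, 1L), L)
      planted <- data.frame(chrom = truth$chrom, strand = truth$strand,
                            pos = pos, count = as.numeric(cnt))
      ## multimapper stress: move weight 1/k to decoys for a read fraction
      if (config$multimap_fraction > 0 && config$multimap_k > 1) {
        k <- config$multimap_k
        mm_reads <- round(planted$count * config$multimap_fraction)
        planted$count <- planted$count - mm_reads + mm_reads / k
        decoys <- data.frame(
          chrom = chrom,
          strand = sample(c("+", "-"), (k - 1) * nrow(planted), replace = TRUE),
          pos = sample.int(L, (k - 1) * nrow(planted), replace = TRUE),
          count = rep(mm_reads / k, k - 1))
        planted <- rbind(planted, decoys[decoys$count > 0, , drop = FALSE])
      }
      n_bg <- rpois(1, config$noise_rate * L * 2)
      bg <- if (n_bg > 0) data.frame(
        chrom = chrom,
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        pos = sample.int(L, n_bg, replace = TRUE),
        count = 1) else NULL
      fiveprime_track(rbind(planted[planted$count > 0, , drop = FALSE], bg),
                      replicate_id = sprintf("rep%d", r))
    })
  })
  list(tracks = tracks, truth = truth)
}

#' Generate an RNA-seq count matrix with planted expression clusters
#'
#' Each gene gets a baseline expression level and a planted cluster label;
#' cluster effects are applied as a log2FC ramp over the developmental time
#' points (half effect at 6 h, full effect from 12 h on). Counts are NB
#' draws around the time-profile means after applying drawn per-sample
#' library size factors, so normalization is genuinely exercised.
#'
#' @param config a [sim_config()].
#' @param world output of [gen_genome_annotation()].
#' @return list: `counts` (matrix), `metadata` (sample, time_h, replicate),
#'   `truth` (gene_id, cluster), `size_factors_true`.
#' @export
gen_count_matrix <- function(config, world) {
  .with_seed(config$seed + 100L, {
    focal <- world$annotation$genes$gene_id
    genes <- c(focal,
               if (config$n_filler_genes > 0)
                 sprintf("bg%04d", seq_len(config$n_filler_genes)))
    n <- length(genes)
    labels <- c(
      sample(names(config$cluster_proportions), length(focal),
             replace = TRUE, prob = config$cluster_proportions),
      if (config$n_filler_genes > 0)
        sample(names(config$filler_proportions), config$n_filler_genes,
               replace = TRUE, prob = config$filler_proportions))
    base <- pmax(exp(rnorm(n, config$baseline_mean_log, 0.8)), 60)
    times <- sort(config$time_points)
    ramp <- ifelse(times == 0, 0, ifelse(times <= 6, 0.5, 1))
    meta <- expand.grid(replicate = seq_len(config$expr_replicates),
                        time_h = times)
    meta$sample <- sprintf("t%02d_r%d", meta$time_h, meta$replicate)
    sf_true <- exp(runif(nrow(meta), log(0.5), log(2)))
    counts <- matrix(0L, n, nrow(meta),
                     dimnames = list(genes, meta$sample))
    for (j in seq_len(nrow(meta))) {
      fc <- config$cluster_effects[labels] * ramp[match(meta$time_h[j], times)]
      mu <- base * 2^fc * sf_true[j]
      counts[, j] <- rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    }
    list(counts = counts,
         metadata = meta[, c("sample", "time_h", "replicate")],
         truth = data.frame(gene_id = genes, cluster = labels,
                            stringsAsFactors = FALSE),
         size_factors_true = sf_true)
  })
}

#' Generate ChIP peak summits at chosen promoter offsets
#'
#' Places summits at requested TSC-relative offsets and derives the truth
#' criterion flags from the planted TSS truth with the two nomination
#' windows (summit offset within `tsc_window` of the TSC; summit within
#' `max_dist` of a planted TSS of the gene).
#'
#' @param config a [sim_config()].
#' @param world output of [gen_genome_annotation()].
#' @param tss_truth planted-TSS truth from [gen_cappable_tracks()].
#' @param placements data.frame (`gene_id`, `offset`); by default every
#'   third planted promoter gets a peak 30-180 bp upstream of its TSS and
#'   every tenth gene a far decoy peak.
#' @param tsc_window,max_dist the two nomination windows.
#' @return list: `peaks` (peak_id, chrom, summit), `truth` (per placement:
#'   gene_id, offset, criterion1, criterion2, nominated).
#' @export
gen_chip_peaks <- function(config, world, tss_truth, placements = NULL,
                           tsc_window = c(-400, 100), max_dist = 200) {
  .with_seed(config$seed + 200L, {
    genes <- world$annotation$genes
    if (is.null(placements)) {
      rows <- list()
      sel <- tss_truth[seq_len(nrow(tss_truth)) %% 3L == 0L, , drop = FALSE]
      for (i in seq_len(nrow(sel)))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sel$gene_id[i],
          offset = offset_shift(sel$offset[i], -sample(30:180, 1)),
          stringsAsFactors = FALSE)
      far <- genes$gene_id[seq_len(nrow(genes)) %% 10L == 0L]
      for (g in far)
        rows[[length(rows) + 1L]] <- data.frame(gene_id = g, offset = -450L)
      placements <- do.call(rbind, rows)
    }
    g <- genes[match(placements$gene_id, genes$gene_id), ]
    summit <- .offset_to_pos(placements$offset, g$tsc, g$strand)
    peaks <- data.frame(
      peak_id = sprintf("peak%03d", seq_len(nrow(placements))),
      chrom = g$chrom, summit = as.integer(summit),
      stringsAsFactors = FALSE)
    crit1 <- placements$offset >= tsc_window[1] &
      placements$offset <= tsc_window[2]
    crit2 <- vapply(seq_len(nrow(placements)), function(i) {
      tt <- tss_truth[tss_truth$gene_id == placements$gene_id[i], , drop = FALSE]
      if (nrow(tt) == 0) return(FALSE)
      any(abs(summit[i] - tt$pos) <= max_dist)
    }, TRUE)
    truth <- data.frame(peak_id = peaks$peak_id,
                        gene_id = placements$gene_id,
                        offset = placements$offset,
                        criterion1 = crit1, criterion2 = crit2,
                        nominated = crit1 & crit2,
                        stringsAsFactors = FALSE)
    list(peaks = peaks, truth = truth)
  })
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper running all generators in order.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `annotation`, `truth_operons`, `tracks`,
#'   `tss_truth`, `counts`, `metadata`, `cluster_truth`, `peaks`,
#'   `peak_truth`, and the `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  world <- gen_genome_annotation(config)
  capp <- gen_cappable_tracks(config, world)
  expr <- gen_count_matrix(config, world)
  chip <- gen_chip_peaks(config, world, capp$truth)
  list(genome = world$genome, annotation = world$annotation,
       truth_operons = world$truth_operons,
       tracks = capp$tracks, tss_truth = capp$truth,
       counts = expr$counts, metadata = expr$metadata,
       cluster_truth = expr$truth,
       peaks = chip$peaks, peak_truth = chip$truth,
       config = config)
}

#' The packaged promoter-anatomy fixture
#'
#' A deterministic miniature world hard-coding two worked promoter
#' scenarios on a 20 kb chromosome:
#' * a two-gene `+` strand operon whose first gene (`dmxB`-like) has four
#'   planted TSSs at -297/-213/-171/-135 relative to its TSC, a ChIP peak
#'   summit at -388, and a planted binding site centred at -409 (so the
#'   site sits 112/196/238/274 bp upstream of the four TSSs);
#' * a three-gene `-` strand operon whose last gene (`pmxA`-like) has
#'   internal promoters at -226/-131/-53 and a ChIP peak at -210, with the
#'   operon promoter at -63 upstream of the first gene.
#'
#' The binding-site consensus planted here is a synthetic stand-in (the
#' real MrpC consensus is defined externally and is a required user input
#' for real analyses).
#'
#' @param seed seed for the random genome background and count noise.
#' @return A world list as from [simulate_world()], plus `consensus` and
#'   `site_truth` (gene, planted centre offset).
#' @export
sim_paper_fixture <- function(seed = 1L) {
  consensus <- "TGTGACGTNNACGTCACA"  # synthetic palindromic stand-in, 18 nt
  .with_seed(seed, {
    chrom <- "chrFix"
    L <- 20000L
    genes <- data.frame(
      gene_id = c("dmxB_like", "dmxB_partner",
                  "pmxA_like", "pmxA_op_mid", "pmxA_op_first",
                  "bystander"),
      chrom = chrom,
      strand = c("+", "+", "-", "-", "-", "+"),
      start = c(3001L, 4230L, 7000L, 8230L, 9130L, 12000L),
      end = c(4200L, 5000L, 8200L, 9100L, 9900L, 13000L),
      stringsAsFactors = FALSE)
    ann <- new_annotation(genes, seqlengths = setNames(L, chrom))
    seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ## plant an exact consensus instance centred at -409 of the dmxB-like TSC
    site_center_offset <- -409L
    cw <- nchar(consensus)
    center_rel <- as.integer(ceiling(cw / 2) - 1L)
    dmxb <- gene_record(ann, "dmxB_like")
    site_center_pos <- tsc_offset_to_genomic(site_center_offset, dmxb)
    site_start <- site_center_pos - center_rel
    inst <- strsplit(gsub("N", "A", consensus), "")[[1]]
    seq_chars[site_start:(site_start + cw - 1L)] <- inst
    genome <- Biostrings::DNAStringSet(
      setNames(paste(seq_chars, collapse = ""), chrom))
    pmxa <- gene_record(ann, "pmxA_like")
    pfirst <- gene_record(ann, "pmxA_op_first")
    ## planted promoters carry most of the library (see sim_config) so the
    ## absolute RRS >= 1.5 threshold keeps its meaning: a singleton
    ## background read scores ~0.13 RRS here and is discarded
    tss_spec <- rbind(
      data.frame(gene_id = "dmxB_like", offset = c(-297L, -213L, -171L, -135L),
                 mean_reads = c(3e6, 1.5e6, 4e5, 6e5)),
      data.frame(gene_id = "pmxA_op_first", offset = -63L, mean_reads = 5e5),
      data.frame(gene_id = "pmxA_like", offset = c(-226L, -131L, -53L),
                 mean_reads = c(3e5, 2.5e5, 2e5)),
      data.frame(gene_id = "bystander", offset = -80L, mean_reads = 8e5))
    g <- ann$genes[match(tss_spec$gene_id, ann$genes$gene_id), ]
    truth <- data.frame(
      gene_id = tss_spec$gene_id, chrom = chrom, strand = g$strand,
      offset = tss_spec$offset,
      pos = as.integer(.offset_to_pos(tss_spec$offset, g$tsc, g$strand)),
      mean_reads = tss_spec$mean_reads,
      internal = tss_spec$gene_id == "pmxA_like",
      tss_truth_id = sprintf("planted%03d", seq_len(nrow(tss_spec))),
      stringsAsFactors = FALSE)
    tracks <- lapply(1:2, function(r) {
      cnt <- rnbinom(nrow(truth), mu = truth$mean_reads, size = 1 / 0.05)
      n_bg <- rpois(1, 0.02 * L * 2)
      bg <- data.frame(chrom = chrom,
                       strand = sample(c("+", "-"), n_bg, replace = TRUE),
                       pos = sample.int(L, n_bg, replace = TRUE), count = 1)
      fiveprime_track(
        rbind(data.frame(chrom = chrom, strand = truth$strand,
                         pos = truth$pos, count = as.numeric(cnt)), bg),
        replicate_id = sprintf("rep%d", r))
    })
    peak_spec <- data.frame(gene_id = c("dmxB_like", "pmxA_like"),
                            offset = c(-388L, -210L), stringsAsFactors = FALSE)
    pg <- ann$genes[match(peak_spec$gene_id, ann$genes$gene_id), ]
    peaks <- data.frame(
      peak_id = c("peak_dmxB", "peak_pmxA"), chrom = chrom,
      summit = as.integer(.offset_to_pos(peak_spec$offset, pg$tsc, pg$strand)),
      stringsAsFactors = FALSE)
    ## count matrix: dmxB-like & pmxA-like strong_up, partner up, mid/first
    ## unchanged, bystander down. The focal genes are embedded in a
    ## genome-wide matrix of filler genes whose planted labels follow the
    ## same cluster proportions as the main generator, as in real
    ## developmental data, so normalization and BH adjustment behave as
    ## they would genome wide.
    cfg <- sim_config(seed = seed)
    labels <- c(dmxB_like = "strong_up", dmxB_partner = "up",
                pmxA_like = "strong_up", pmxA_op_mid = "unchanged",
                pmxA_op_first = "unchanged", bystander = "down",
                setNames(sample(names(cfg$filler_proportions), 194,
                                replace = TRUE,
                                prob = cfg$filler_proportions),
                         sprintf("filler%03d", 1:194)))
    n_expr <- length(labels)
    base <- setNames(pmax(exp(rnorm(n_expr, cfg$baseline_mean_log, 0.5)), 60),
                     names(labels))
    times <- cfg$time_points
    ramp <- ifelse(times == 0, 0, ifelse(times <= 6, 0.5, 1))
    meta <- expand.grid(replicate = seq_len(cfg$expr_replicates),
                        time_h = times)
    meta$sample <- sprintf("t%02d_r%d", meta$time_h, meta$replicate)
    sf_true <- exp(runif(nrow(meta), log(0.5), log(2)))
    counts <- matrix(0L, n_expr, nrow(meta),
                     dimnames = list(names(labels), meta$sample))
    for (j in seq_len(nrow(meta))) {
      fc <- cfg$cluster_effects[labels] * ramp[match(meta$time_h[j], times)]
      mu <- base * 2^fc * sf_true[j]
      counts[, j] <- rnbinom(n_expr, mu = mu, size = 1 / cfg$nb_dispersion)
    }
    list(genome = genome, annotation = ann,
         truth_operons = data.frame(
           gene_id = genes$gene_id,
           operon_id = c("TU1", "TU1", "TU2", "TU2", "TU2", "TU3"),
           n_genes = c(2L, 2L, 3L, 3L, 3L, 1L),
           position_in_operon = c(1L, 2L, 3L, 2L, 1L, 1L),
           stringsAsFactors = FALSE),
         tracks = tracks, tss_truth = truth,
         counts = counts, metadata = meta[, c("sample", "time_h", "replicate")],
         cluster_truth = data.frame(gene_id = names(labels), cluster = labels,
                                    stringsAsFactors = FALSE),
         peaks = peaks,
         peak_truth = data.frame(peak_id = peaks$peak_id,
                                 gene_id = peak_spec$gene_id,
                                 offset = peak_spec$offset,
                                 nominated = c(TRUE, TRUE),
                                 stringsAsFactors = FALSE),
         consensus = consensus,
         site_truth = data.frame(gene_id = "dmxB_like",
                                 center_offset = site_center_offset,
                                 stringsAsFactors = FALSE),
         config = cfg)
  })
}

#' Write a synthetic world to disk in standard formats
#'
#' FASTA genome, GFF3 annotation, per-replicate strand-specific bedGraph
#' pairs, BED peak summits, counts and metadata TSVs, and truth tables as
#' TSV.
#'
#' @param world output of [simulate_world()] or [sim_paper_fixture()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(world$genome, file.path(dir, "genome.fasta"))
  g <- world$annotation$genes
  gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, locus_tag = g$gene_id)
  GenomeInfoDb::seqlengths(gr) <- world$annotation$seqlengths[
    GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")
  for (i in seq_along(world$tracks))
    write_fiveprime_bedgraph(world$tracks[[i]],
                             file.path(dir, sprintf("capp_rep%d", i)))
  pk <- world$peaks
  write.table(data.frame(pk$chrom, pk$summit - 1L, pk$summit, pk$peak_id,
                         0, "."),
              file.path(dir, "peaks.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(gene_id = rownames(world$counts), world$counts,
                         check.names = FALSE),
              file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(world$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in c("truth_operons", "tss_truth", "cluster_truth", "peak_truth"))
    if (!is.null(world[[nm]]))
      write.table(world[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
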