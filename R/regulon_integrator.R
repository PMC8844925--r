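#' Peak-summit offsets relative to gene TSCs (criterion 1)
#'
#' For every (peak, gene) pair on the same chromosome, computes the
#' TSC-relative offset of the peak summit and flags criterion 1: summit
#' offset inside `window` (default -400..+100, inclusive). Peaks are
#' summit coordinates only; the gene's strand defines the offset sign, and
#' peaks are strand-less so every gene is considered. Also reports, per
#' peak, the nearest TSC.
#'
#' @param peaks data.frame with columns `chrom`, `summit` (genomic bp),
#'   optionally `peak_id` and `score`.
#' @param annotation a [new_annotation()] object.
#' @param window inclusive offset window for criterion 1.
#' @return data.frame per (peak, gene): `peak_id`, `chrom`, `summit`,
#'   `gene_id`, `offset`, `criterion1`, `nearest_tsc` (TRUE for the gene
#'   whose TSC is closest to the summit).
#' @export
peak_to_tsc <- function(peaks, annotation, window = c(-400, 100)) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%s_%d", peaks$chrom, peaks$summit)
  genes <- annotation$genes
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    off <- .tsc_offset(peaks$summit[i], g$tsc, g$strand)
    dist <- abs(peaks$summit[i] - g$tsc)
    rows[[length(rows) + 1L]] <- data.frame(
      peak_id = peaks$peak_id[i], chrom = peaks$chrom[i],
      summit = peaks$summit[i], gene_id = g$gene_id,
      offset = as.integer(off),
      criterion1 = off >= window[1] & off <= window[2],
      nearest_tsc = dist == min(dist),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows) %||%
    data.frame(peak_id = character(), chrom = character(), summit = integer(),
               gene_id = character(), offset = integer(),
               criterion1 = logical(), nearest_tsc = logical())
  rownames(res) <- NULL
  res
}

#' Peak-summit distances to assigned TSSs (criterion 2)
#'
#' For every peak and every gene-assigned TSS on the same chromosome,
#' computes the absolute distance between the summit and the TSS max
#' position, and flags criterion 2 per (peak, gene): minimal distance to a
#' TSS assigned to that gene at most `max_dist` bp (default 200,
#' inclusive).
#'
#' @param peaks data.frame with `chrom`, `summit` (optional `peak_id`).
#' @param tss_table TSS-to-gene assignment table from [annotate_tss()].
#' @param max_dist maximal summit-TSS distance in bp.
#' @return data.frame per (peak, gene): `peak_id`, `gene_id`,
#'   `nearest_tss_id`, `distance` (NA if the gene has no assigned TSS),
#'   `criterion2`.
#' @export
peak_to_tss <- function(peaks, tss_table, max_dist = 200) {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%s_%d", peaks$chrom, peaks$summit)
  assigned <- tss_table[tss_table$assigned & !is.na(tss_table$gene_id), ,
                        drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    a <- assigned[assigned$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(a) == 0) next
    a$distance <- abs(peaks$summit[i] - a$max_position)
    for (gid in unique(a$gene_id)) {
      ag <- a[a$gene_id == gid, , drop = FALSE]
      j <- which.min(ag$distance)
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = peaks$peak_id[i], chrom = peaks$chrom[i],
        summit = peaks$summit[i], gene_id = gid,
        nearest_tss_id = ag$tss_id[j], distance = ag$distance[j],
        criterion2 = ag$distance[j] <= max_dist,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows) %||%
    data.frame(peak_id = character(), chrom = character(), summit = integer(),
               gene_id = character(), nearest_tss_id = character(),
               distance = integer(), criterion2 = logical())
  rownames(res) <- NULL
  res
}

#' Nominate candidate directly regulated genes and operons
#'
#' A gene is nominated when some single peak satisfies both criteria for it:
#' its summit lies in the TSC window (criterion 1) and within `max_dist` of
#' a TSS assigned to that gene (criterion 2). Operon-level calls aggregate
#' the first gene's and any internal-promoter gene's evidence. Output is
#' ranked by minimal peak-TSS distance.
#'
#' @param peak_tsc output of [peak_to_tsc()].
#' @param peak_tss output of [peak_to_tss()].
#' @param categories gene category table from [categorize_genes()];
#'   optional (`NULL` for gene-level calls only).
#' @return list with `genes` (per-gene CandidateCall data.frame with
#'   `criterion1`, `criterion2`, `nominated`, `best_peak_id`,
#'   `peak_offset`, `min_distance`) and `operons` (per-operon aggregation,
#'   NULL if `categories` is NULL).
#' @export
nominate_candidates <- function(peak_tsc, peak_tss, categories = NULL) {
  merged <- merge(peak_tsc, peak_tss[, c("peak_id", "gene_id",
                                         "nearest_tss_id", "distance",
                                         "criterion2")],
                  by = c("peak_id", "gene_id"), all.x = TRUE)
  merged$criterion2[is.na(merged$criterion2)] <- FALSE
  gene_ids <- unique(merged$gene_id)
  rows <- lapply(gene_ids, function(gid) {
    d <- merged[merged$gene_id == gid, , drop = FALSE]
    both <- d$criterion1 & d$criterion2
    if (any(both)) {
      dd <- d[both, , drop = FALSE]
      j <- which.min(dd$distance)
      best <- dd[j, ]
    } else {
      ord <- order(!d$criterion1, d$distance)
      best <- d[ord[1], ]
    }
    data.frame(gene_id = gid,
               criterion1 = best$criterion1,
               criterion2 = best$criterion2,
               nominated = best$criterion1 & best$criterion2,
               best_peak_id = best$peak_id,
               peak_offset = best$offset,
               nearest_tss_id = best$nearest_tss_id,
               min_distance = best$distance,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes <- genes[order(!genes$nominated, genes$min_distance), , drop = FALSE]
  rownames(genes) <- NULL
  operons <- NULL
  if (!is.null(categories)) {
    m <- merge(categories, genes, by = "gene_id", all.x = TRUE)
    m$nominated[is.na(m$nominated)] <- FALSE
    op_rows <- lapply(split(m, m$operon_id), function(d) {
      relevant <- d$category %in%
        c("standalone", "operon_first", "operon_internal_with_internal_promoter")
      nom <- any(d$nominated & relevant)
      data.frame(operon_id = d$operon_id[1],
                 n_genes = d$n_genes[1],
                 genes = paste(d$gene_id[order(d$position_in_operon)],
                               collapse = ","),
                 nominated = nom,
                 nominated_via = paste(d$gene_id[d$nominated & relevant],
                                       collapse = ","),
                 stringsAsFactors = FALSE)
    })
    operons <- do.call(rbind, op_rows)
    rownames(operons) <- NULL
  }
  list(genes = genes, operons = operons)
}

## IUPAC nucleotide classes
.iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Scan a promoter sequence for an IUPAC consensus binding site
#'
#' Slides the consensus along both strands of the sequence and reports
#' windows with at most `max_mismatches` mismatches. A mismatch is a window
#' base not contained in the IUPAC class at that consensus position (N
#' matches everything). The site centre is the left-of-centre base for
#' even-length consensi. If `from_offset` is given (the TSC-relative offset
#' of the sequence's first base, as produced by
#' [extract_promoter_sequence()]), centres are also reported as TSC-relative
#' offsets.
#'
#' @param promoter_seq character scalar, coding-strand orientation.
#' @param consensus IUPAC consensus string.
#' @param max_mismatches mismatch budget (default 0).
#' @param from_offset optional TSC-relative offset of base 1 of
#'   `promoter_seq`.
#' @return data.frame per hit: `start`, `end` (1-based in the sequence),
#'   `strand` (`+` = coding strand), `mismatches`, `matched_seq`,
#'   `center` (sequence position), and `center_offset` when `from_offset`
#'   is given.
#' @export
scan_consensus <- function(promoter_seq, consensus, max_mismatches = 0,
                           from_offset = NULL) {
  promoter_seq <- toupper(promoter_seq)
  consensus <- toupper(consensus)
  bad <- setdiff(strsplit(consensus, "")[[1]], names(.iupac))
  if (length(bad) > 0)
    stop("invalid IUPAC character(s) in consensus: ",
         paste(unique(bad), collapse = ", "))
  L <- nchar(consensus)
  n <- nchar(promoter_seq)
  if (L > n) stop("consensus longer than sequence")
  seq_chars <- strsplit(promoter_seq, "")[[1]]
  center_rel <- as.integer(ceiling(L / 2) - 1L)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else .revcomp_chr(consensus)
    pat_classes <- .iupac[strsplit(pat, "")[[1]]]
    for (s in seq_len(n - L + 1L)) {
      win <- seq_chars[s:(s + L - 1L)]
      mm <- sum(!mapply(function(b, cls) b %in% cls, win, pat_classes))
      if (mm <= max_mismatches) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s, end = s + L - 1L, strand = strand,
          mismatches = mm,
          matched_seq = paste(win, collapse = ""),
          center = s + center_rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, hits) %||%
    data.frame(start = integer(), end = integer(), strand = character(),
               mismatches = integer(), matched_seq = character(),
               center = integer())
  if (!is.null(from_offset) && nrow(res) > 0)
    res$center_offset <- offset_shift(from_offset, res$center - 1L)
  else if (!is.null(from_offset))
    res$center_offset <- integer(0)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Distances between a binding-site centre and TSSs in offset space
#'
#' The distance is `tss_offset - site_center_offset`, corrected for the
#' nonexistent offset 0 when the two offsets straddle the TSC (signs
#' differ), so that adjacent bases are always 1 bp apart. Positive values
#' mean the site lies upstream of the TSS.
#'
#' @param site_center TSC-relative offset of the site centre.
#' @param tss_offsets vector of TSC-relative TSS offsets.
#' @return data.frame: `site_center`, `tss_offset`, `distance`.
#' @export
site_tss_distances <- function(site_center, tss_offsets) {
  if (site_center == 0 || any(tss_offsets == 0))
    stop("offset 0 does not exist")
  raw <- tss_offsets - site_center
  straddle <- sign(tss_offsets) != sign(site_center)
  d <- ifelse(straddle & raw != 0, raw - sign(raw), raw)
  data.frame(site_center = site_center, tss_offset = tss_offsets,
             distance = as.integer(d))
}

#' Read ChIP peak summits from a BED file
#'
#' Single-base intervals are taken as summits; wider intervals collapse to
#' their midpoint with a warning.
#'
#' @param path BED file.
#' @return data.frame: `peak_id`, `chrom`, `summit`, `score`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  w <- BiocGenerics::width(gr)
  if (any(w > 1))
    warning(sum(w > 1), " peak interval(s) wider than 1 bp: using midpoints")
  summit <- as.integer(floor((BiocGenerics::start(gr) +
                                BiocGenerics::end(gr)) / 2))
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm)))
    nm <- sprintf("peak_%s_%d", as.character(GenomeInfoDb::seqnames(gr)), summit)
  data.frame(peak_id = nm,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             summit = summit,
             score = if (is.null(gr$score)) NA_real_ else gr$score,
             stringsAsFactors = FALSE)
}
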