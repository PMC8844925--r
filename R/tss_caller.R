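#' Construct a 5'-end read-start track
#'
#' A five-prime track stores, per (chromosome, strand, position), the
#' weighted number of reads whose first transcribed base maps there (Rns),
#' together with the library total Rt (total reads mapped to the genome;
#' fractional multi-mapper weights sum to one read each).
#'
#' @param counts data.frame with columns `chrom`, `strand`, `pos`, `count`
#'   (non-negative, fractional allowed). Rows with identical
#'   (chrom, strand, pos) are summed.
#' @param Rt total mapped reads; defaults to `sum(counts$count)`.
#' @param replicate_id optional replicate label.
#' @return Object of class `fiveprime_track`.
#' @export
fiveprime_track <- function(counts, Rt = NULL, replicate_id = NULL) {
  stopifnot(all(c("chrom", "strand", "pos", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("read-start counts must be >= 0")
  if (!all(counts$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  counts <- stats::aggregate(count ~ chrom + strand + pos, data = counts, FUN = sum)
  counts <- counts[counts$count > 0, , drop = FALSE]
  counts <- counts[order(counts$chrom, counts$strand, counts$pos), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts,
                 Rt = Rt %||% sum(counts$count),
                 replicate_id = replicate_id),
            class = "fiveprime_track")
}

#' @export
print.fiveprime_track <- function(x, ...) {
  cat(sprintf("fiveprime_track%s: %d positions, Rt = %g\n",
              if (is.null(x$replicate_id)) "" else paste0(" [", x$replicate_id, "]"),
              nrow(x$counts), x$Rt))
  invisible(x)
}

#' Count weighted 5'-end read starts from alignments
#'
#' Implements best-mapping filtering with fractional weights: for each read,
#' only the alignment(s) with the maximal alignment score (`AS` tag) are
#' kept, and each of the k equal-best alignments contributes weight 1/k at
#' the genomic position of the first transcribed base of the read (leftmost
#' aligned base on `+`, rightmost on `-`). Rt counts reads, not alignments:
#' every read with at least one best alignment contributes exactly 1 to Rt.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param replicate_id optional replicate label.
#' @return A [fiveprime_track()].
#' @export
count_read_starts <- function(path, replicate_id = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar"),
    tag = "AS",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(b$qname)
  if (n == 0)
    return(fiveprime_track(data.frame(chrom = character(), strand = character(),
                                      pos = integer(), count = numeric()),
                           Rt = 0, replicate_id = replicate_id))
  score <- b$tag$AS
  if (is.null(score) || all(is.na(score))) {
    warning("no AS alignment scores; keeping primary (non-secondary) alignments only")
    keep <- bitwAnd(b$flag, 256L) == 0L
  } else {
    score[is.na(score)] <- -Inf
    best <- tapply(score, b$qname, max)
    keep <- score == unname(best[b$qname])
  }
  qname <- b$qname[keep]
  strand <- as.character(b$strand)[keep]
  chrom <- as.character(b$rname)[keep]
  pos <- b$pos[keep]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
  fpos <- ifelse(strand == "+", pos, pos + width - 1L)
  k <- table(qname)
  w <- 1 / as.numeric(k[qname])
  counts <- stats::aggregate(
    count ~ chrom + strand + pos,
    data = data.frame(chrom = chrom, strand = strand, pos = fpos, count = w),
    FUN = sum)
  fiveprime_track(counts, Rt = length(unique(qname)),
                  replicate_id = replicate_id)
}

#' Write a five-prime track as a pair of strand-specific bedGraph files
#'
#' One bedGraph per strand (0-based half-open intervals, one base each).
#'
#' @param track a [fiveprime_track()].
#' @param prefix output prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @param seqlengths optional named chromosome lengths for the header.
#' @return Invisibly, the two file paths.
#' @export
write_fiveprime_bedgraph <- function(track, prefix, seqlengths = NULL) {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    cc <- track$counts[track$counts$strand == s, , drop = FALSE]
    path <- if (s == "+") paths[["plus"]] else paths[["minus"]]
    gr <- GenomicRanges::GRanges(cc$chrom,
                                 IRanges::IRanges(cc$pos, width = 1),
                                 score = cc$count)
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  invisible(paths)
}

#' Read a five-prime track from strand-specific bedGraph files
#'
#' Intervals wider than one base are expanded to per-base counts with the
#' interval's score at every base.
#'
#' @param plus,minus bedGraph files for the `+` and `-` strand.
#' @param Rt total mapped reads; defaults to the sum of all counts.
#' @param replicate_id optional replicate label.
#' @return A [fiveprime_track()].
#' @export
read_fiveprime_bedgraph <- function(plus, minus, Rt = NULL, replicate_id = NULL) {
  one <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0)
      return(data.frame(chrom = character(), strand = character(),
                        pos = integer(), count = numeric()))
    w <- BiocGenerics::width(gr)
    data.frame(
      chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), w),
      strand = strand,
      pos = unlist(lapply(seq_along(gr), function(i)
        seq.int(BiocGenerics::start(gr)[i], BiocGenerics::end(gr)[i]))),
      count = rep(gr$score, w))
  }
  fiveprime_track(rbind(one(plus, "+"), one(minus, "-")),
                  Rt = Rt, replicate_id = replicate_id)
}

#' Normalize a five-prime track to relative read scores (RRS)
#'
#' RRS = (Rns / Rt) x 1,000,000: the per-position weighted read-start count
#' scaled to reads-per-million of total mapped reads, so that the sum of RRS
#' over all positions is 1e6 when every mapped read is represented in the
#' track.
#'
#' @param track a [fiveprime_track()].
#' @return data.frame of class `rrs_track` with columns `chrom`, `strand`,
#'   `pos`, `rrs`; `Rt` and `replicate_id` are kept as attributes.
#' @export
compute_rrs <- function(track) {
  if (track$Rt <= 0) stop("Rt must be > 0 to compute RRS")
  out <- track$counts
  out$rrs <- out$count / track$Rt * 1e6
  out$count <- NULL
  attr(out, "Rt") <- track$Rt
  attr(out, "replicate_id") <- track$replicate_id
  class(out) <- c("rrs_track", "data.frame")
  out
}

#' Call TSS clusters from an RRS track
#'
#' Positions with RRS >= `threshold` are retained (strictly lower scores are
#' discarded), then, per chromosome and strand, retained positions at most
#' `cluster_gap` bases apart are merged transitively into one cluster
#' (single linkage, so flanking clusters chained within the gap collapse
#' into one large cluster). Each cluster's member with the highest RRS is
#' the major TSS ("max position"); ties go to the 5'-most member on the
#' transcript strand.
#'
#' @param rrs an RRS track from [compute_rrs()].
#' @param threshold lower RRS threshold (default 1.5).
#' @param cluster_gap maximal intra-cluster distance in bp (default 3).
#' @return data.frame of TSS calls: `tss_id`, `chrom`, `strand`,
#'   `cluster_start`, `cluster_end`, `max_position`, `max_rrs`, `n_members`,
#'   `replicate_id`, and a `members` list-column of per-member (pos, rrs).
#' @export
call_tss <- function(rrs, threshold = 1.5, cluster_gap = 3) {
  keep <- rrs[rrs$rrs >= threshold, , drop = FALSE]
  empty <- data.frame(tss_id = character(), chrom = character(),
                      strand = character(), cluster_start = integer(),
                      cluster_end = integer(), max_position = integer(),
                      max_rrs = numeric(), n_members = integer(),
                      replicate_id = character(), stringsAsFactors = FALSE)
  empty$members <- list()
  if (nrow(keep) == 0) return(empty)
  rep_id <- attr(rrs, "replicate_id") %||% NA_character_
  out <- list()
  for (key in split(seq_len(nrow(keep)),
                    paste(keep$chrom, keep$strand, sep = "\r"))) {
    d <- keep[key, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(d$pos) > cluster_gap)))
    for (g in split(seq_len(nrow(d)), grp)) {
      m <- d[g, , drop = FALSE]
      top <- m$pos[m$rrs == max(m$rrs)]
      maxpos <- if (m$strand[1] == "+") min(top) else max(top)
      out[[length(out) + 1L]] <- list(
        chrom = m$chrom[1], strand = m$strand[1],
        cluster_start = min(m$pos), cluster_end = max(m$pos),
        max_position = maxpos, max_rrs = max(m$rrs),
        n_members = nrow(m),
        members = data.frame(pos = m$pos, rrs = m$rrs))
    }
  }
  res <- data.frame(
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    cluster_start = vapply(out, `[[`, 0L, "cluster_start"),
    cluster_end = vapply(out, `[[`, 0L, "cluster_end"),
    max_position = vapply(out, `[[`, 0L, "max_position"),
    max_rrs = vapply(out, `[[`, 0, "max_rrs"),
    n_members = vapply(out, `[[`, 0L, "n_members"),
    stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$strand, res$max_position), , drop = FALSE]
  ord <- order(vapply(out, `[[`, "", "chrom"), vapply(out, `[[`, "", "strand"),
               vapply(out, `[[`, 0L, "max_position"))
  res$tss_id <- sprintf("TSS_%s_%s%d", res$chrom,
                        ifelse(res$strand == "+", "p", "m"), res$max_position)
  res$replicate_id <- rep_id
  res$members <- lapply(out, `[[`, "members")[ord]
  rownames(res) <- NULL
  res[, c("tss_id", "chrom", "strand", "cluster_start", "cluster_end",
          "max_position", "max_rrs", "n_members", "replicate_id", "members")]
}

#' Build a replicate consensus of TSS calls
#'
#' A consensus TSS is emitted where at least `min_replicates` replicates
#' (default: all) have clusters whose max positions are pairwise within
#' `tolerance` bp; its position is the max position of the replicate call
#' with the highest RRS. Calls without replicate support are retained and
#' flagged `reproducible = FALSE`.
#'
#' @param replicates list of TSS call tables from [call_tss()], one per
#'   replicate.
#' @param tolerance maximal pairwise max-position distance in bp (default 3,
#'   the cluster gap).
#' @param min_replicates replicates required for a reproducible call;
#'   default all supplied replicates.
#' @return data.frame of consensus calls with per-replicate max RRS columns
#'   (`rrs_rep1`, ...) and a `reproducible` flag.
#' @export
consensus_tss <- function(replicates, tolerance = 3, min_replicates = NULL) {
  n_rep <- length(replicates)
  if (n_rep < 2) {
    warning("fewer than 2 replicates: passing calls through unflagged")
    out <- replicates[[1]]
    out$reproducible <- FALSE
    return(out)
  }
  min_replicates <- min_replicates %||% n_rep
  all <- do.call(rbind, lapply(seq_len(n_rep), function(i) {
    d <- replicates[[i]][, c("tss_id", "chrom", "strand", "cluster_start",
                             "cluster_end", "max_position", "max_rrs")]
    d$rep <- i
    d
  }))
  out <- list()
  for (key in split(seq_len(nrow(all)),
                    paste(all$chrom, all$strand, sep = "\r"))) {
    d <- all[key, , drop = FALSE]
    d <- d[order(d$max_position), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(d$max_position) > tolerance)))
    for (g in split(seq_len(nrow(d)), grp)) {
      m <- d[g, , drop = FALSE]
      span_ok <- (max(m$max_position) - min(m$max_position)) <= tolerance
      reps_ok <- length(unique(m$rep)) >= min_replicates
      if (span_ok && reps_ok) {
        lead <- m[which.max(m$max_rrs), , drop = FALSE]
        rrs_by_rep <- rep(NA_real_, n_rep)
        for (r in unique(m$rep))
          rrs_by_rep[r] <- max(m$max_rrs[m$rep == r])
        row <- data.frame(
          chrom = lead$chrom, strand = lead$strand,
          cluster_start = min(m$cluster_start),
          cluster_end = max(m$cluster_end),
          max_position = lead$max_position, max_rrs = lead$max_rrs,
          n_replicates = length(unique(m$rep)), reproducible = TRUE,
          stringsAsFactors = FALSE)
        for (r in seq_len(n_rep)) row[[paste0("rrs_rep", r)]] <- rrs_by_rep[r]
        out[[length(out) + 1L]] <- row
      } else {
        for (i in seq_len(nrow(m))) {
          row <- data.frame(
            chrom = m$chrom[i], strand = m$strand[i],
            cluster_start = m$cluster_start[i], cluster_end = m$cluster_end[i],
            max_position = m$max_position[i], max_rrs = m$max_rrs[i],
            n_replicates = 1L, reproducible = FALSE, stringsAsFactors = FALSE)
          for (r in seq_len(n_rep))
            row[[paste0("rrs_rep", r)]] <-
              if (r == m$rep[i]) m$max_rrs[i] else NA_real_
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$strand, res$max_position), , drop = FALSE]
  res$tss_id <- sprintf("TSS_%s_%s%d", res$chrom,
                        ifelse(res$strand == "+", "p", "m"), res$max_position)
  rownames(res) <- NULL
  res[, c("tss_id", setdiff(names(res), "tss_id"))]
}

#' Assign TSS calls to genes by TSC-relative offset
#'
#' Each TSS is assigned to every same-strand gene for which the TSC-relative
#' offset of its max position falls inside `assign_window` (default -500 to
#' +100). TSSs with no gene in the window are reported with `gene_id = NA`.
#'
#' @param calls TSS call table ([call_tss()] or [consensus_tss()] output).
#' @param annotation a [new_annotation()] object.
#' @param assign_window length-2 offset window (inclusive).
#' @return data.frame with one row per (TSS, gene) assignment plus one row
#'   per unassigned TSS: `tss_id`, `chrom`, `strand`, `max_position`,
#'   `max_rrs`, `gene_id`, `offset`, `assigned` (and replicate RRS columns
#'   if present in `calls`).
#' @export
annotate_tss <- function(calls, annotation, assign_window = c(-500, 100)) {
  genes <- annotation$genes
  rrs_cols <- grep("^rrs_rep", names(calls), value = TRUE)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    g <- genes[genes$chrom == calls$chrom[i] &
                 genes$strand == calls$strand[i], , drop = FALSE]
    hit <- FALSE
    base <- calls[i, c("tss_id", "chrom", "strand", "max_position", "max_rrs",
                       rrs_cols), drop = FALSE]
    if (nrow(g) > 0) {
      off <- .tsc_offset(calls$max_position[i], g$tsc, g$strand)
      sel <- off >= assign_window[1] & off <= assign_window[2]
      if (any(sel)) {
        hit <- TRUE
        for (j in which(sel)) {
          row <- base
          row$gene_id <- g$gene_id[j]
          row$offset <- as.integer(off[j])
          row$assigned <- TRUE
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    if (!hit) {
      row <- base
      row$gene_id <- NA_character_
      row$offset <- NA_integer_
      row$assigned <- FALSE
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows) %||%
    data.frame(tss_id = character(), chrom = character(),
               strand = character(), max_position = integer(),
               max_rrs = numeric(), gene_id = character(),
               offset = integer(), assigned = logical(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export TSS calls as BED6
#'
#' Score is the max RRS times 100, rounded; name is the cluster id.
#'
#' @param calls TSS call table.
#' @param path output BED file.
#' @export
write_tss_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom,
                    start = calls$max_position - 1L,
                    end = calls$max_position,
                    name = calls$tss_id,
                    score = round(calls$max_rrs * 100),
                    strand = calls$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
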