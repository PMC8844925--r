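#' @importFrom stats median rnbinom rpois rnorm runif t.test setNames aggregate
#' @importFrom utils write.table read.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an annotation object
#'
#' An annotation is the package's central gene model: a table of genes with
#' strand and 1-based inclusive genomic coordinates, plus chromosome lengths.
#' Each gene exposes its translation start codon (TSC) position: the genomic
#' coordinate of the first base of the start codon, which is `start` for a
#' `+` strand gene and `end` for a `-` strand gene.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive). An optional `alias`
#'   column carries a secondary identifier.
#' @param seqlengths named integer vector of chromosome lengths. Defaults to
#'   the maximal gene end per chromosome.
#' @return An object of class `capr_annotation`: a list with elements
#'   `genes` (the validated gene table, sorted by chromosome and start, with
#'   a computed `tsc` column) and `seqlengths`.
#' @export
new_annotation <- function(genes, seqlengths = NULL) {
  required <- c("gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0)
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start > genes$end))
    stop("gene start must be <= end (1-based inclusive coordinates)")
  genes$tsc <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(seqlengths)) {
    seqlengths <- tapply(genes$end, genes$chrom, max)
    seqlengths <- setNames(as.integer(seqlengths), names(seqlengths))
  }
  structure(list(genes = genes, seqlengths = seqlengths),
            class = "capr_annotation")
}

#' @export
print.capr_annotation <- function(x, ...) {
  cat(sprintf("capr_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$seqlengths)))
  invisible(x)
}

#' Load a gene annotation from a GFF3 file
#'
#' Parses gene features from GFF3 (1-based inclusive coordinates, as the
#' format defines) into an annotation object. Features without a strand are
#' rejected with a warning; duplicate gene identifiers are an error.
#'
#' @param path GFF3 file.
#' @param feature_type feature types treated as genes (first type with any
#'   features wins; default tries `"gene"` then `"CDS"`).
#' @return A [new_annotation()] object.
#' @export
load_annotation <- function(path, feature_type = c("gene", "CDS")) {
  gff <- tryCatch(rtracklayer::import(path, format = "gff3"),
                  error = function(e) stop("malformed GFF3 '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  type <- as.character(gff$type)
  use <- character(0)
  for (ft in feature_type) {
    if (any(type == ft)) { use <- ft; break }
  }
  if (length(use) == 0)
    stop("no features of type ", paste(feature_type, collapse = "/"),
         " in ", path)
  gff <- gff[type == use]
  strand <- as.character(BiocGenerics::strand(gff))
  if (any(strand == "*")) {
    warning(sum(strand == "*"), " feature(s) without strand rejected")
    gff <- gff[strand != "*"]
    strand <- strand[strand != "*"]
  }
  mc <- S4Vectors::mcols(gff)
  pick <- function(cols) {
    out <- rep(NA_character_, length(gff))
    for (cl in cols) {
      if (cl %in% names(mc)) {
        v <- as.character(mc[[cl]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  ids <- pick(c("locus_tag", "ID", "gene_id", "Name"))
  if (anyNA(ids))
    stop("gene feature(s) without an identifier (locus_tag/ID/gene_id/Name)")
  alias <- pick(c("old_locus_tag", "Alias", "gene"))
  sl <- GenomeInfoDb::seqlengths(gff)
  if (all(is.na(sl))) sl <- NULL else sl <- sl[!is.na(sl)]
  new_annotation(
    data.frame(gene_id = ids,
               alias = alias,
               chrom = as.character(GenomeInfoDb::seqnames(gff)),
               strand = strand,
               start = BiocGenerics::start(gff),
               end = BiocGenerics::end(gff),
               stringsAsFactors = FALSE),
    seqlengths = sl)
}

#' Write an annotation's gene table to TSV
#' @param annotation a [new_annotation()] object.
#' @param path output file.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write.table(annotation$genes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Fetch one gene record
#' @param annotation a [new_annotation()] object.
#' @param gene_id gene identifier.
#' @return One-row data.frame.
#' @export
gene_record <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene_id: ", gene_id)
  g
}

## TSC-relative offsets: +1 is the first base of the start codon, -1 the base
## immediately upstream; there is no offset 0 (a deliberate discontinuity).

.tsc_offset <- function(pos, tsc, strand) {
  n <- max(length(pos), length(tsc), length(strand))
  pos <- rep_len(pos, n); tsc <- rep_len(tsc, n); strand <- rep_len(strand, n)
  ifelse(strand == "+",
         ifelse(pos >= tsc, pos - tsc + 1L, pos - tsc),
         ifelse(pos <= tsc, tsc - pos + 1L, tsc - pos))
}

.offset_to_pos <- function(offset, tsc, strand) {
  if (any(offset == 0)) stop("TSC-relative offset 0 does not exist")
  n <- max(length(offset), length(tsc), length(strand))
  offset <- rep_len(offset, n); tsc <- rep_len(tsc, n)
  strand <- rep_len(strand, n)
  ifelse(strand == "+",
         ifelse(offset > 0, tsc + offset - 1L, tsc + offset),
         ifelse(offset > 0, tsc - offset + 1L, tsc - offset))
}

#' Convert genomic positions to TSC-relative offsets
#'
#' Offsets are measured along the gene's coding strand relative to the first
#' base of its translation start codon (TSC): +1 is the TSC itself, -1 the
#' base immediately upstream; 0 is never produced.
#'
#' @param pos vector of genomic positions (1-based).
#' @param gene one-row gene record (from [gene_record()]) or any list with
#'   `tsc` and `strand`.
#' @return Integer vector of signed nonzero offsets.
#' @export
genomic_to_tsc_offset <- function(pos, gene) {
  as.integer(.tsc_offset(pos, gene$tsc[1], gene$strand[1]))
}

#' Convert TSC-relative offsets back to genomic positions
#'
#' Exact inverse of [genomic_to_tsc_offset()]. Offset 0 is an error.
#'
#' @param offset vector of signed nonzero offsets.
#' @inheritParams genomic_to_tsc_offset
#' @return Integer vector of genomic positions.
#' @export
tsc_offset_to_genomic <- function(offset, gene) {
  as.integer(.offset_to_pos(offset, gene$tsc[1], gene$strand[1]))
}

#' Shift a TSC-relative offset by k positions
#'
#' Moves `k` bases downstream (coding-strand direction) in offset space,
#' skipping the nonexistent offset 0.
#'
#' @param offset signed nonzero offset.
#' @param k integer shift (positive = downstream).
#' @return Shifted nonzero offset.
#' @export
offset_shift <- function(offset, k) {
  if (any(offset == 0)) stop("offset 0 does not exist")
  v <- offset + k
  v <- ifelse(offset < 0 & v >= 0, v + 1L, v)
  v <- ifelse(offset > 0 & v <= 0, v - 1L, v)
  as.integer(v)
}

#' Number of bases spanned by an offset interval
#'
#' @param from_offset,to_offset interval bounds in offset space,
#'   `from_offset` upstream of (smaller than) `to_offset`.
#' @return Integer width, accounting for the missing offset 0.
#' @export
offset_span <- function(from_offset, to_offset) {
  if (from_offset == 0 || to_offset == 0) stop("offset 0 does not exist")
  if (from_offset > to_offset) stop("from_offset must be <= to_offset")
  w <- to_offset - from_offset + 1L
  if (from_offset < 0 && to_offset > 0) w <- w - 1L
  as.integer(w)
}

#' Extract a promoter-region sequence in coding-strand orientation
#'
#' Returns the genomic sequence between two TSC-relative offsets, read 5' to
#' 3' on the gene's coding strand (reverse-complemented for `-` strand
#' genes).
#'
#' @param gene one-row gene record.
#' @param from_offset,to_offset offset interval (`from_offset` upstream).
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome, or a path
#'   to a FASTA file.
#' @return Character scalar; its length equals
#'   `offset_span(from_offset, to_offset)`.
#' @export
extract_promoter_sequence <- function(gene, from_offset, to_offset, genome) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  chrom <- gene$chrom[1]
  nm <- sub("\\s.*$", "", names(genome))
  idx <- match(chrom, nm)
  if (is.na(idx)) stop("chromosome ", chrom, " not in genome")
  p1 <- tsc_offset_to_genomic(from_offset, gene)
  p2 <- tsc_offset_to_genomic(to_offset, gene)
  lo <- min(p1, p2); hi <- max(p1, p2)
  if (lo < 1 || hi > length(genome[[idx]]))
    stop("region [", lo, ", ", hi, "] beyond chromosome ", chrom,
         " bounds (length ", length(genome[[idx]]), ")")
  s <- Biostrings::subseq(genome[[idx]], lo, hi)
  if (gene$strand[1] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
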