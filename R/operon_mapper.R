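#' Predict operons from intergenic distance
#'
#' Genes on the same strand of the same chromosome that are genomic
#' neighbours with an intergenic distance of at most `max_gap` bases are
#' chained transitively into one transcription unit. The intergenic distance
#' between adjacent genes is the number of bases strictly between them
#' (`next_start - prev_end - 1`), so touching genes give 0 and overlapping
#' genes give negative values (always joined: overlap is stronger evidence
#' of co-transcription). Every gene belongs to exactly one unit; units of a
#' single gene are singletons.
#'
#' @param annotation a [new_annotation()] object.
#' @param max_gap maximal intergenic distance in bp (default 50).
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tsc`, `operon_id`, `n_genes`, `position_in_operon`
#'   (transcription order: genomic order on `+`, reversed on `-`),
#'   `upstream_gap` (intergenic distance to the previous unit member in
#'   genomic order; NA for the first).
#' @export
predict_operons <- function(annotation, max_gap = 50) {
  genes <- annotation$genes
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  unit <- integer(nrow(genes))
  gap <- rep(NA_integer_, nrow(genes))
  uid <- 0L
  prev <- NULL
  for (i in seq_len(nrow(genes))) {
    join <- FALSE
    if (!is.null(prev) && genes$chrom[i] == genes$chrom[prev]) {
      d <- genes$start[i] - genes$end[prev] - 1L
      if (genes$strand[i] == genes$strand[prev] && d <= max_gap) {
        join <- TRUE
        gap[i] <- d
      }
    }
    if (!join) uid <- uid + 1L
    unit[i] <- uid
    prev <- i
  }
  genes$operon_id <- sprintf("TU%04d", unit)
  genes$n_genes <- as.integer(ave(unit, unit, FUN = length))
  ord_in_unit <- ave(seq_len(nrow(genes)), unit, FUN = seq_along)
  genes$position_in_operon <- ifelse(
    genes$strand == "+", ord_in_unit, genes$n_genes - ord_in_unit + 1L)
  genes$upstream_gap <- gap
  rownames(genes) <- NULL
  genes
}

#' Classify genes into the four transcription-unit categories
#'
#' Each gene is labelled `standalone` (not in a multi-gene operon),
#' `operon_first` (first gene in transcription order), `operon_internal`
#' (later gene, no own promoter evidence), or
#' `operon_internal_with_internal_promoter` (later gene with at least one
#' TSS assigned to it, i.e. an internal promoter). `has_tss` reports whether
#' any TSS was assigned to the gene at all.
#'
#' @param operons gene-level operon table from [predict_operons()].
#' @param tss_table TSS-to-gene assignment table from [annotate_tss()].
#' @return data.frame per gene: `gene_id`, `operon_id`, `n_genes`,
#'   `position_in_operon`, `category`, `has_tss`, `n_tss`, `tss_ids`
#'   (comma-separated), `operon_has_tss` (any member gene has a TSS).
#' @export
categorize_genes <- function(operons, tss_table) {
  assigned <- tss_table[tss_table$assigned & !is.na(tss_table$gene_id), ,
                        drop = FALSE]
  tss_by_gene <- split(assigned$tss_id, assigned$gene_id)
  n_tss <- vapply(operons$gene_id,
                  function(g) length(tss_by_gene[[g]] %||% character(0)), 0L)
  has_tss <- n_tss > 0
  category <- ifelse(
    operons$n_genes == 1L, "standalone",
    ifelse(operons$position_in_operon == 1L, "operon_first",
           ifelse(has_tss, "operon_internal_with_internal_promoter",
                  "operon_internal")))
  out <- data.frame(
    gene_id = operons$gene_id,
    chrom = operons$chrom,
    strand = operons$strand,
    operon_id = operons$operon_id,
    n_genes = operons$n_genes,
    position_in_operon = operons$position_in_operon,
    category = category,
    has_tss = has_tss,
    n_tss = as.integer(n_tss),
    tss_ids = vapply(operons$gene_id, function(g)
      paste(tss_by_gene[[g]] %||% character(0), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out$operon_has_tss <- ave(out$has_tss, out$operon_id,
                            FUN = function(x) any(x)) > 0
  rownames(out) <- NULL
  out
}

#' Write the gene category table to TSV
#' @param categories output of [categorize_genes()].
#' @param path output file.
#' @export
write_categories_tsv <- function(categories, path) {
  write.table(categories, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
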