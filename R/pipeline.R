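#' Pipeline parameters with their standard defaults
#'
#' Every knob of the pipeline in one place: RRS threshold 1.5, cluster gap
#' 3 nt, replicate tolerance 3 nt, operon gap 50 bp, TSS assignment window
#' -500..+100, nomination windows -400..+100 (TSC) and 200 bp (TSS),
#' log2FC thresholds 2 / 1 / -1, alpha 0.05, pseudocount 1.
#'
#' @param ... overrides for any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(threshold = 1.5, cluster_gap = 3, tolerance = 3,
            min_replicates = NULL, max_gap = 50,
            assign_window = c(-500, 100),
            tsc_window = c(-400, 100), max_dist = 200,
            fc_strong = 2, fc_up = 1, fc_down = -1, alpha = 0.05,
            pseudocount = 1, reference_time = 0,
            max_mismatches = 2)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0)
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline and emit the combined per-gene report
#'
#' Executes the stages in dependency order: five-prime tracks are
#' normalized to RRS and TSS-called per replicate, combined into a
#' replicate consensus, assigned to genes; operons are predicted and genes
#' categorized; the count matrix is normalized, profiled and classified;
#' ChIP peaks are evaluated against the two nomination criteria; and, when
#' a genome and consensus are supplied, nominated genes' promoter windows
#' are scanned for binding sites. The report joins everything per gene.
#'
#' @param inputs list with elements `annotation` ([new_annotation()] or
#'   GFF3 path), `tracks` (list of [fiveprime_track()], SAM/BAM paths, or
#'   `list(plus=, minus=)` bedGraph path pairs), and optionally `genome`
#'   (DNAStringSet or FASTA path), `peaks` (data.frame or BED path),
#'   `counts` (matrix or TSV path), `metadata` (data.frame or TSV path),
#'   `consensus` (IUPAC string).
#' @param params [pipeline_params()].
#' @param out optional output directory; report, stage tables and a JSON
#'   run manifest are written there. On failure partial outputs are
#'   removed.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list: `report` (one row per gene), `tss`, `tss_table`,
#'   `categories`, `profiles`, `clusters`, `candidates`, `sites`,
#'   `manifest`.
#' @export
run_all <- function(inputs, params = pipeline_params(), out = NULL,
                    seed = NULL) {
  written <- character(0)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    on.exit(if (length(written) > 0 && !is.null(attr(written, "failed")))
      unlink(written), add = TRUE)
  }
  input_files <- as.character(unlist(Filter(is.character,
                                            unlist(inputs, recursive = FALSE))))
  input_files <- input_files[file.exists(input_files)]

  ann <- .stage("annotation", {
    if (is.character(inputs$annotation)) load_annotation(inputs$annotation)
    else inputs$annotation
  })
  genome <- .stage("genome", {
    if (is.null(inputs$genome)) NULL
    else if (is.character(inputs$genome))
      Biostrings::readDNAStringSet(inputs$genome)
    else inputs$genome
  })

  tss_calls <- .stage("tss", {
    if (is.null(inputs$tracks)) stop("no five-prime tracks supplied")
    tracks <- lapply(seq_along(inputs$tracks), function(i) {
      tr <- inputs$tracks[[i]]
      if (inherits(tr, "fiveprime_track")) tr
      else if (is.list(tr) && !is.null(tr$plus))
        read_fiveprime_bedgraph(tr$plus, tr$minus,
                                replicate_id = sprintf("rep%d", i))
      else if (is.character(tr))
        count_read_starts(tr, replicate_id = sprintf("rep%d", i))
      else stop("unrecognized track input ", i)
    })
    lapply(tracks, function(tr)
      call_tss(compute_rrs(tr), threshold = params$threshold,
               cluster_gap = params$cluster_gap))
  })
  tss <- .stage("consensus", {
    if (length(tss_calls) >= 2)
      consensus_tss(tss_calls, tolerance = params$tolerance,
                    min_replicates = params$min_replicates)
    else {
      x <- tss_calls[[1]]
      x$reproducible <- NA
      x
    }
  })
  tss_table <- .stage("annotate_tss",
                      annotate_tss(tss, ann, assign_window = params$assign_window))
  operons <- .stage("operons", predict_operons(ann, max_gap = params$max_gap))
  categories <- .stage("categorize", categorize_genes(operons, tss_table))

  profiles <- clusters <- NULL
  if (!is.null(inputs$counts)) {
    profiles <- .stage("expression", {
      counts <- if (is.character(inputs$counts)) read_counts_tsv(inputs$counts)
      else as.matrix(inputs$counts)
      metadata <- if (is.character(inputs$metadata))
        read_metadata_tsv(inputs$metadata)
      else inputs$metadata
      if (is.null(metadata)) stop("counts given without metadata")
      sf <- size_factors(counts)
      expression_profiles(normalize_counts(counts, sf), metadata,
                          reference_time = params$reference_time,
                          pseudocount = params$pseudocount)
    })
    clusters <- .stage("classify",
                       classify_expression(profiles,
                                           fc_strong = params$fc_strong,
                                           fc_up = params$fc_up,
                                           fc_down = params$fc_down,
                                           alpha = params$alpha))
  }

  candidates <- sites <- NULL
  if (!is.null(inputs$peaks)) {
    candidates <- .stage("integrate", {
      peaks <- if (is.character(inputs$peaks)) read_peaks_bed(inputs$peaks)
      else as.data.frame(inputs$peaks)
      pt <- peak_to_tsc(peaks, ann, window = params$tsc_window)
      px <- peak_to_tss(peaks, tss_table, max_dist = params$max_dist)
      nominate_candidates(pt, px, categories)
    })
    if (!is.null(genome) && !is.null(inputs$consensus)) {
      sites <- .stage("scan_sites", {
        nominated <- candidates$genes$gene_id[candidates$genes$nominated]
        rows <- lapply(nominated, function(gid) {
          gene <- gene_record(ann, gid)
          from <- params$assign_window[1]
          to <- params$assign_window[2]
          ## clip the scan window to the chromosome
          lo <- tsc_offset_to_genomic(from, gene)
          hi <- tsc_offset_to_genomic(to, gene)
          len <- length(genome[[match(gene$chrom,
                                      sub("\\s.*$", "", names(genome)))]])
          if (min(lo, hi) < 1 || max(lo, hi) > len) return(NULL)
          hits <- scan_consensus(
            extract_promoter_sequence(gene, from, to, genome),
            inputs$consensus, max_mismatches = params$max_mismatches,
            from_offset = from)
          if (nrow(hits) == 0) return(NULL)
          hits$gene_id <- gid
          hits
        })
        do.call(rbind, rows)
      })
    }
  }

  report <- .stage("report", {
    r <- categories
    if (!is.null(clusters))
      r <- merge(r, clusters, by = "gene_id", all.x = TRUE)
    if (!is.null(candidates)) {
      r <- merge(r, candidates$genes[, c("gene_id", "criterion1", "criterion2",
                                         "nominated", "peak_offset",
                                         "min_distance")],
                 by = "gene_id", all.x = TRUE)
      r$nominated[is.na(r$nominated)] <- FALSE
    }
    if (!is.null(sites)) {
      ns <- table(sites$gene_id)
      r$n_site_hits <- as.integer(ns[r$gene_id])
      r$n_site_hits[is.na(r$n_site_hits)] <- 0L
    }
    r <- r[order(r$gene_id), , drop = FALSE]
    rownames(r) <- NULL
    r
  })

  manifest <- list(
    package = "capregulon",
    version = as.character(packageVersion("capregulon")),
    parameters = params,
    seed = seed,
    input_checksums = if (length(input_files) > 0)
      as.list(tools::md5sum(input_files)) else list())

  if (!is.null(out)) {
    wr <- function(d, f) {
      path <- file.path(out, f)
      cols <- !vapply(d, is.list, TRUE)
      write.table(d[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <<- c(written, path)
    }
    wr(tss, "tss_consensus.tsv")
    wr(tss_table, "tss_annotated.tsv")
    wr(categories, "operon_categories.tsv")
    if (!is.null(profiles)) wr(profiles, "expression_profiles.tsv")
    if (!is.null(clusters)) wr(clusters, "expression_clusters.tsv")
    if (!is.null(candidates)) {
      wr(candidates$genes, "candidates_genes.tsv")
      if (!is.null(candidates$operons)) wr(candidates$operons,
                                           "candidates_operons.tsv")
    }
    if (!is.null(sites)) wr(sites, "binding_sites.tsv")
    wr(report, "report.tsv")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    written <- c(written, file.path(out, "manifest.json"))
  }

  list(report = report, tss = tss, tss_table = tss_table,
       categories = categories, profiles = profiles, clusters = clusters,
       candidates = candidates, sites = sites, manifest = manifest)
}

#' Focal catalog of c-di-GMP-associated gene classes
#'
#' The published census of Myxococcus xanthus genes encoding
#' c-di-GMP-associated proteins, by domain class, that this pipeline's
#' report mirrors: 18 GGDEF, 2 EAL, 6 HD-GYP, 24 PilZ and 17 MshEN domain
#' proteins plus the 3 named receptors (CdbA, CdbB, Nla24), 70 genes in
#' all.
#'
#' @return data.frame with columns `class` and `n_genes`.
#' @export
cdg_gene_catalog <- function() {
  data.frame(
    class = c("GGDEF", "EAL", "HD-GYP", "PilZ", "MshEN", "named_receptor"),
    n_genes = c(18L, 2L, 6L, 24L, 17L, 3L),
    stringsAsFactors = FALSE)
}

#' Published developmental expression cluster sizes of the focal catalog
#'
#' The four-way classification of the 70-gene catalog reported for M.
#' xanthus development: 10 strongly upregulated (log2FC >= 2), 18
#' upregulated (log2FC >= 1), 10 downregulated (log2FC <= -1) and 32
#' unchanged.
#'
#' @return Named integer vector.
#' @export
cdg_cluster_sizes <- function() {
  c(strong_up = 10L, up = 18L, down = 10L, unchanged = 32L)
}
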