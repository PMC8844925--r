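# shared builders for small in-code fixtures

make_ann <- function(..., seqlen = NULL) {
  g <- data.frame(...)
  new_annotation(g, seqlengths = seqlen)
}

# a bare RRS track from vectors (one chromosome)
make_rrs <- function(pos, rrs, strand = "+", chrom = "chr", Rt = 1e6,
                     replicate_id = "rep1") {
  d <- data.frame(chrom = rep_len(chrom, length(pos)),
                  strand = rep_len(strand, length(pos)),
                  pos = as.integer(pos), rrs = rrs)
  attr(d, "Rt") <- Rt
  attr(d, "replicate_id") <- replicate_id
  class(d) <- c("rrs_track", "data.frame")
  d
}

# write a SAM file from a record list; each record is
# list(qname, flag, pos, cigar, as) on chromosome "chr" (length 100000)
write_sam <- function(records, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr\tLN:100000")
  body <- vapply(records, function(r) {
    seqlen <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar, perl = TRUE))[[1]]))
    paste(r$qname, r$flag, "chr", r$pos, 42, r$cigar, "*", 0, 0,
          paste(rep("A", seqlen), collapse = ""), "*",
          paste0("AS:i:", r$as), sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}

# brute-force single-linkage clustering oracle: transitive closure over all
# pairs at distance <= gap (independent of the linear-scan implementation)
oracle_cluster <- function(pos, gap) {
  n <- length(pos)
  if (n == 0) return(list())
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(pos[i] - pos[j]) <= gap && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(pos, comp), sort))
}

# mirror a genomic world through the reverse complement: positions flip to
# L - p + 1 and strands swap
flip_pos <- function(pos, L) L - pos + 1L
flip_strand <- function(s) ifelse(s == "+", "-", "+")

flip_annotation <- function(ann) {
  L <- unname(ann$seqlengths[1])
  g <- ann$genes
  new_annotation(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                            strand = flip_strand(g$strand),
                            start = flip_pos(g$end, L),
                            end = flip_pos(g$start, L)),
                 seqlengths = ann$seqlengths)
}

flip_track <- function(track, L) {
  cc <- track$counts
  fiveprime_track(data.frame(chrom = cc$chrom,
                             strand = flip_strand(cc$strand),
                             pos = flip_pos(cc$pos, L),
                             count = cc$count),
                  Rt = track$Rt, replicate_id = track$replicate_id)
}
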