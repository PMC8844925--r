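make_peak <- function(summit, chrom = "chr", id = NULL) {
  data.frame(peak_id = id %||% paste0("pk", summit), chrom = chrom,
             summit = summit)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("criterion 1 window is inclusive at -400 and +100", {
  ann <- make_ann(gene_id = "g", chrom = "chr", strand = "+",
                  start = 5000, end = 6000, seqlen = c(chr = 10000))
  off <- function(o) {
    g <- gene_record(ann, "g")
    pt <- peak_to_tsc(make_peak(tsc_offset_to_genomic(o, g)), ann)
    pt$criterion1[pt$gene_id == "g"]
  }
  expect_true(off(-388L))   # worked promoter case
  expect_true(off(-400L))
  expect_false(off(-401L))
  expect_true(off(100L))
  expect_false(off(101L))
})

test_that("criterion 2 distance is inclusive at 200 bp", {
  ann <- make_ann(gene_id = "g", chrom = "chr", strand = "+",
                  start = 5000, end = 6000, seqlen = c(chr = 10000))
  tss <- annotate_tss(call_tss(make_rrs(4703, 8)), ann)  # TSS at -297
  d <- function(summit) peak_to_tss(make_peak(summit), tss)
  expect_equal(d(4703)$distance, 0)
  expect_true(d(4703)$criterion2)
  expect_true(d(4703 + 200)$criterion2)
  expect_false(d(4703 + 201)$criterion2)
  expect_equal(d(4903)$distance, 200)
})

test_that("nomination requires one peak passing both criteria", {
  ann <- make_ann(gene_id = c("dmx", "partner"), chrom = "chr", strand = "+",
                  start = c(3001, 4230), end = c(4200, 5000),
                  seqlen = c(chr = 20000))
  tss <- annotate_tss(call_tss(make_rrs(2704, 9)), ann)  # -297 of dmx
  g <- gene_record(ann, "dmx")
  # peak at -388: both criteria pass, distance 91
  pk <- make_peak(tsc_offset_to_genomic(-388L, g))
  nom <- nominate_candidates(peak_to_tsc(pk, ann), peak_to_tss(pk, tss))
  row <- nom$genes[nom$genes$gene_id == "dmx", ]
  expect_true(row$nominated)
  expect_equal(row$peak_offset, -388L)
  expect_equal(row$min_distance, 91)
  expect_true(row$nominated == (row$criterion1 & row$criterion2))
  # peak at -450 near a TSS: criterion 1 fails -> not nominated
  tss2 <- annotate_tss(call_tss(make_rrs(2551, 9)), ann)  # -450
  pk2 <- make_peak(tsc_offset_to_genomic(-450L, g))
  nom2 <- nominate_candidates(peak_to_tsc(pk2, ann), peak_to_tss(pk2, tss2))
  expect_false(nom2$genes$nominated[nom2$genes$gene_id == "dmx"])
  # peak at -50 with nearest TSS 350 bp away: criterion 2 fails
  tss3 <- annotate_tss(call_tss(make_rrs(tsc_offset_to_genomic(-400L, g), 9)),
                       ann)
  pk3 <- make_peak(tsc_offset_to_genomic(-50L, g))
  nom3 <- nominate_candidates(peak_to_tsc(pk3, ann), peak_to_tss(pk3, tss3))
  expect_false(nom3$genes$nominated[nom3$genes$gene_id == "dmx"])
})

test_that("nomination is monotone in both windows", {
  set.seed(61)
  world <- simulate_world(sim_config(seed = 61, n_units = 10))
  tss <- annotate_tss(
    consensus_tss(lapply(world$tracks, function(t) call_tss(compute_rrs(t)))),
    world$annotation)
  nom_with <- function(w, d) {
    n <- nominate_candidates(peak_to_tsc(world$peaks, world$annotation,
                                         window = w),
                             peak_to_tss(world$peaks, tss, max_dist = d))
    n$genes$gene_id[n$genes$nominated]
  }
  base <- nom_with(c(-400, 100), 200)
  wider <- nom_with(c(-600, 200), 400)
  expect_true(all(base %in% wider))
})

test_that("IUPAC consensus scan matches the Biostrings oracle", {
  set.seed(71)
  consensus <- "TGTSANNWTCACA"
  for (i in 1:100) {
    n <- sample(50:2000, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    mm <- sample(0:3, 1)
    got <- scan_consensus(s, consensus, max_mismatches = mm)
    # oracle: IUPAC-aware Hamming distance from Biostrings, both strands
    subj <- Biostrings::DNAString(s)
    L <- nchar(consensus)
    starts <- seq_len(n - L + 1)
    for (strand in c("+", "-")) {
      pat <- Biostrings::DNAString(consensus)
      if (strand == "-") pat <- Biostrings::reverseComplement(pat)
      ed <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                        fixed = "subject")
      expect_equal(sort(got$start[got$strand == strand]),
                   sort(starts[ed <= mm]))
    }
  }
})

test_that("consensus scan reports mismatch counts, centres and offsets", {
  consensus <- "TGTGACGTNNACGTCACA"  # 18 nt, centre = 9th base
  site <- gsub("N", "T", consensus)
  flank_l <- "ACCA"
  seqs <- paste0(flank_l, site, "GGAT")
  hit <- scan_consensus(seqs, consensus, max_mismatches = 0,
                        from_offset = -26L)
  # exact (plus palindromic reverse) occurrence with 0 mismatches
  expect_true(all(hit$mismatches == 0))
  expect_equal(unique(hit$start), 5L)
  expect_equal(unique(hit$center), 5L + 8L)
  expect_equal(unique(hit$center_offset), -26L + 12L)
  # one substitution found with budget >= 1 only
  mut <- sub("TGTGA", "TGAGA", seqs)
  expect_equal(nrow(scan_consensus(mut, consensus, 0)), 0)
  h1 <- scan_consensus(mut, consensus, 2)
  expect_true(all(h1$mismatches >= 1))
  expect_error(scan_consensus(seqs, "TGXA", 0), "IUPAC")
})

test_that("site-TSS distance arithmetic handles the missing zero", {
  # worked promoter map: site centred at -409, four TSSs
  d <- site_tss_distances(-409L, c(-297L, -213L, -171L, -135L))
  expect_equal(d$distance, c(112L, 196L, 238L, 274L))
  expect_equal(site_tss_distances(-409L, -409L)$distance, 0L)
  expect_equal(site_tss_distances(-100L, -200L)$distance, -100L)
  # straddling the TSC: adjacent bases are 1 apart (-1 -> +1)
  expect_equal(site_tss_distances(-1L, 1L)$distance, 1L)
  expect_equal(site_tss_distances(-5L, 5L)$distance, 9L)
  # antisymmetry
  set.seed(81)
  for (i in 1:50) {
    a <- sample(c(-500:-1, 1:100), 1)
    b <- sample(c(-500:-1, 1:100), 1)
    expect_equal(site_tss_distances(a, b)$distance,
                 -site_tss_distances(b, a)$distance)
  }
})

test_that("peak offsets are strand symmetric", {
  set.seed(91)
  L <- 30000L
  ann <- make_ann(gene_id = c("gp", "gm"), chrom = "chr",
                  strand = c("+", "-"), start = c(10000, 20000),
                  end = c(11000, 21000), seqlen = c(chr = L))
  flip <- flip_annotation(ann)
  summits <- sample(1:L, 40)
  a <- peak_to_tsc(make_peak(summits), ann)
  b <- peak_to_tsc(make_peak(flip_pos(summits, L)), flip)
  key <- function(d) d[order(d$gene_id, d$summit), ]
  a <- a[order(a$gene_id, a$summit), ]
  b <- b[order(b$gene_id, -b$summit), ]
  expect_equal(b$offset, a$offset)
  expect_equal(b$criterion1, a$criterion1)
})
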