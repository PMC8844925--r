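test_that("best-mapping filter assigns fractional weights 1/k", {
  sam <- write_sam(list(
    list(qname = "r1", flag = 0, pos = 1000, cigar = "10M", as = 20),
    list(qname = "r2", flag = 0, pos = 2000, cigar = "10M", as = 20),
    list(qname = "r2", flag = 256, pos = 3000, cigar = "10M", as = 20),
    list(qname = "r3", flag = 0, pos = 4000, cigar = "10M", as = 20),
    list(qname = "r3", flag = 256, pos = 4100, cigar = "10M", as = 20),
    list(qname = "r3", flag = 256, pos = 4200, cigar = "10M", as = 20),
    list(qname = "r3", flag = 256, pos = 4300, cigar = "10M", as = 20),
    list(qname = "r4", flag = 0, pos = 5000, cigar = "10M", as = 20),
    list(qname = "r4", flag = 256, pos = 6000, cigar = "10M", as = 5)))
  tr <- count_read_starts(sam)
  cc <- tr$counts
  get <- function(p) cc$count[cc$pos == p]
  expect_equal(get(1000), 1)
  expect_equal(get(2000), 0.5)   # two equal-best: half a read each
  expect_equal(get(3000), 0.5)
  expect_equal(get(4000), 0.25)  # four equal-best: 1/k each
  expect_equal(get(4100), 0.25)
  expect_equal(get(5000), 1)     # sub-optimal alignment dropped
  expect_length(get(6000), 0)
  expect_equal(tr$Rt, 4)         # Rt counts reads, not alignments
  expect_equal(sum(cc$count), tr$Rt)  # weight conservation
})

test_that("5' end of a minus-strand alignment is its rightmost base", {
  sam <- write_sam(list(
    list(qname = "f", flag = 0, pos = 100, cigar = "20M", as = 10),
    list(qname = "r", flag = 16, pos = 100, cigar = "20M", as = 10),
    list(qname = "rd", flag = 16, pos = 300, cigar = "5M2D15M", as = 10)))
  cc <- count_read_starts(sam)$counts
  expect_equal(cc$pos[cc$strand == "+"], 100)
  # 20M minus: 100..119; 5M2D15M spans 22 reference bases: 300..321
  expect_setequal(cc$pos[cc$strand == "-"], c(119, 321))
})

test_that("RRS formula and conservation", {
  tr <- fiveprime_track(
    data.frame(chrom = "chr", strand = "+", pos = 100L, count = 15),
    Rt = 1e7)
  expect_equal(compute_rrs(tr)$rrs, 1.5)
  expect_error(compute_rrs(fiveprime_track(
    data.frame(chrom = "chr", strand = "+", pos = 1L, count = 0))), "Rt")
  # random track: sum RRS == 1e6 when every read is in the track
  set.seed(2)
  d <- data.frame(chrom = "chr", strand = sample(c("+", "-"), 300, TRUE),
                  pos = sample(1:5000, 300), count = rpois(300, 8) + 0.5)
  expect_equal(sum(compute_rrs(fiveprime_track(d))$rrs), 1e6)
})

test_that("threshold is >= 1.5: boundary retained, below discarded", {
  rrs <- make_rrs(c(10, 20, 30), c(1.5, 1.5 - 1e-9, 1.4))
  calls <- call_tss(rrs)
  expect_equal(calls$max_position, 10)
  expect_equal(nrow(call_tss(make_rrs(1:3, c(1.4, 1.2, 0.3)))), 0)
})

test_that("clustering merges within gap and picks max position", {
  calls <- call_tss(make_rrs(c(100, 101, 105), c(5, 2, 3)), cluster_gap = 3)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$max_position, c(100, 105))
  expect_equal(calls$cluster_start, c(100, 105))
  expect_equal(calls$cluster_end, c(101, 105))
  # flanking clusters chained through <=3 nt steps merge into one
  chain <- call_tss(make_rrs(c(10, 13, 16, 19), c(2, 9, 3, 4)))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$max_position, 13)
  expect_equal(chain$n_members, 4)
  # singleton
  single <- call_tss(make_rrs(50, 7.2))
  expect_equal(single$max_position, 50)
  expect_equal(single$max_rrs, 7.2)
})

test_that("max-position ties break to the 5'-most transcript-strand base", {
  tie_p <- call_tss(make_rrs(c(200, 202), c(4, 4), strand = "+"))
  expect_equal(tie_p$max_position, 200)
  tie_m <- call_tss(make_rrs(c(200, 202), c(4, 4), strand = "-"))
  expect_equal(tie_m$max_position, 202)
})

test_that("clustering equals the brute-force transitive-closure oracle", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    pos <- sort(sample(1:200, n))
    gap <- sample(1:5, 1)
    got <- call_tss(make_rrs(pos, runif(n, 1.5, 10)), threshold = 1.5,
                    cluster_gap = gap)
    want <- oracle_cluster(pos, gap)
    got_sets <- lapply(got$members, function(m) sort(m$pos))
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("consensus requires all replicates within tolerance", {
  r1 <- call_tss(make_rrs(c(500, 900), c(8, 3), replicate_id = "rep1"))
  r2 <- call_tss(make_rrs(502, 6, replicate_id = "rep2"))
  cons <- consensus_tss(list(r1, r2), tolerance = 3)
  rep_tss <- cons[cons$reproducible, ]
  expect_equal(nrow(rep_tss), 1)
  expect_equal(rep_tss$max_position, 500)  # rep1 has the higher RRS
  expect_equal(rep_tss$rrs_rep1, 8)
  expect_equal(rep_tss$rrs_rep2, 6)
  # the rep1-only call at 900 is retained but not reproducible
  solo <- cons[!cons$reproducible, ]
  expect_equal(solo$max_position, 900)
  # identical replicates are idempotent
  cons2 <- consensus_tss(list(r1, r1))
  expect_true(all(cons2$reproducible))
  expect_equal(cons2$max_position, r1$max_position)
  expect_equal(cons2$max_rrs, r1$max_rrs)
  expect_warning(consensus_tss(list(r1)), "replicates")
})

test_that("TSS assignment honours window and strand", {
  ann <- make_ann(gene_id = c("plusg", "minusg"), chrom = "chr",
                  strand = c("+", "-"), start = c(5000, 3500),
                  end = c(6000, 4400), seqlen = c(chr = 10000))
  # TSS 297 bp upstream of plusg TSC (5000): position 4703, + strand
  calls <- call_tss(make_rrs(c(4703, 4400), c(9, 5), strand = "+"))
  tab <- annotate_tss(calls, ann)
  hit <- tab[tab$max_position == 4703 & tab$assigned, ]
  expect_equal(hit$gene_id, "plusg")
  expect_equal(hit$offset, -297L)
  # equidistant from the divergent minus gene, but strand must match:
  # never assigned to minusg
  expect_false("minusg" %in% tab$gene_id)
  # a TSS at offset -600 is outside the default window
  far <- annotate_tss(call_tss(make_rrs(4400, 5, strand = "+")),
                      new_annotation(data.frame(
                        gene_id = "plusg", chrom = "chr", strand = "+",
                        start = 5000, end = 6000)))
  expect_false(any(far$assigned))
  expect_true(is.na(far$gene_id))
})

test_that("TSS calling is strand symmetric and deterministic", {
  world <- simulate_world(sim_config(seed = 3, n_units = 10))
  tr <- world$tracks[[1]]
  L <- unname(world$annotation$seqlengths[1])
  calls <- call_tss(compute_rrs(tr))
  flipped <- call_tss(compute_rrs(flip_track(tr, L)))
  expect_equal(nrow(flipped), nrow(calls))
  expect_setequal(flip_pos(flipped$max_position, L), calls$max_position)
  expect_equal(sort(flipped$max_rrs), sort(calls$max_rrs))
  # determinism: identical input -> identical output
  expect_identical(calls, call_tss(compute_rrs(tr)))
})

test_that("bedGraph round-trip preserves a track", {
  world <- simulate_world(sim_config(seed = 4, n_units = 6))
  tr <- world$tracks[[1]]
  prefix <- tempfile()
  write_fiveprime_bedgraph(tr, prefix)
  back <- read_fiveprime_bedgraph(paste0(prefix, ".plus.bedgraph"),
                                  paste0(prefix, ".minus.bedgraph"))
  expect_equal(back$counts$pos, tr$counts$pos)
  expect_equal(back$counts$count, tr$counts$count)
  expect_equal(back$Rt, tr$Rt)
})
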