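mk_dcs <- function(ref, locus, read_rows, ref_rows, starts) {
  win <- window_seq(ref, locus)
  data.table::data.table(ref_start = starts, ref_row = ref_rows,
                         read_row = read_rows,
                         umi = sprintf("U%03d", seq_along(starts)),
                         top_reads = 1L, bottom_reads = 1L,
                         locus_id = locus, window_start = win$start)
}

test_that("left normalisation makes repeated-context InDels canonical", {
  #        0123456789
  seq <- "GCAAATTTGC"
  # deleting any single A of the run normalises to the first A
  for (p in 2:4) {
    nv <- normalize_variant(p, "A", "", seq)
    expect_equal(nv$pos, 2L); expect_identical(nv$ref_allele, "A")
  }
  # insertion of T inside the T-run normalises to before the run
  nv <- normalize_variant(8L, "", "T", seq)
  expect_equal(nv$pos, 5L); expect_identical(nv$alt_allele, "T")
  # SNVs are untouched
  nv <- normalize_variant(4L, "T", "G", seq)
  expect_equal(nv$pos, 4L)
})

test_that("DCS identical to the reference yields no observations", {
  ref <- fixture_design()$reference
  win <- window_seq(ref, "L01")
  s <- substring(win$seq, 41, 160)
  dcs <- mk_dcs(ref, "L01", s, s, 40L)
  called <- call_dcs_variants(dcs, ref)
  expect_equal(nrow(called$observations), 0L)
  expect_equal(duplex_depth(called$depth, "L01", win$start + 100L), 1L)
})

test_that("a DCS missing CAGTT produces one left-normalised 5-bp deletion", {
  d <- fixture_design()
  ref <- d$reference
  win <- window_seq(ref, "L02")
  # window carries CAGTT at offset 94; build the deleted read row
  expect_identical(substring(win$seq, 95, 99), "CAGTT")
  read <- paste0(substring(win$seq, 41, 94), substring(win$seq, 100, 165))
  a <- glocal_align(read, win$seq)
  rr <- duplexr:::restore_ref_row(a$ref_start, a$ref_row, win$seq)
  dcs <- mk_dcs(ref, "L02", a$read_row, rr, a$ref_start)
  called <- call_dcs_variants(dcs, ref)
  obs <- called$observations
  expect_equal(nrow(obs), 1L)
  expect_identical(obs$kind, "deletion")
  expect_identical(obs$ref, "CAGTT")
  expect_equal(obs$pos, win$start + 94L)
  expect_equal(nchar(obs$ref) - nchar(obs$alt), 5L)
})

test_that("N columns never call and edge observations are guarded", {
  ref <- fixture_design()$reference
  win <- window_seq(ref, "L01")
  s <- substring(win$seq, 41, 160)
  masked <- `substr<-`(s, 60, 60, "N")
  flip <- function(x) chartr("ACGT", "TGCA", x)
  edge <- `substr<-`(s, 2, 2, flip(substring(s, 2, 2)))
  mid <- `substr<-`(s, 60, 60, flip(substring(s, 60, 60)))
  dcs <- mk_dcs(ref, "L01", c(masked, edge, mid), rep(s, 3), rep(40L, 3))
  called <- call_dcs_variants(dcs, ref, roi = NULL)
  expect_equal(nrow(called$observations), 1L)   # only the mid-span SNV
  expect_identical(called$observations$kind, "SNV")
  # the N column is excluded from depth at its position
  expect_equal(duplex_depth(called$depth, "L01",
                            win$start + 40L + 59L), 2L)
})

test_that("aggregation computes exact-mutation frequencies over non-N depth", {
  ref <- fixture_design()$reference
  win <- window_seq(ref, "L01")
  s <- substring(win$seq, 41, 160)
  alts <- setdiff(c("A", "C", "G", "T"), substring(s, 60, 60))
  mut <- `substr<-`(s, 60, 60, alts[1])
  mut2 <- `substr<-`(s, 60, 60, alts[2])
  rows <- c(rep(s, 7), rep(mut, 3))
  dcs <- mk_dcs(ref, "L01", rows, rep(s, 10), rep(40L, 10))
  calls <- aggregate_counts(call_dcs_variants(dcs, ref, roi = NULL))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$count, 3L)
  expect_equal(calls$depth, 10L)
  expect_equal(calls$frequency, 0.3)
  # two distinct alts at one position share the depth; frequencies sum <= 1
  dcs2 <- mk_dcs(ref, "L01", c(rep(s, 5), rep(mut, 3), rep(mut2, 2)),
                 rep(s, 10), rep(40L, 10))
  calls2 <- aggregate_counts(call_dcs_variants(dcs2, ref, roi = NULL))
  expect_equal(nrow(calls2), 2L)
  expect_true(all(calls2$depth == 10L))
  expect_lte(sum(calls2$frequency), 1)
})

test_that("pure-mutant simulation recovers frequency near 1", {
  d <- fixture_design()
  haps <- apply_edits(d$reference, d$edits)
  fr <- data.table::data.table(locus_id = "L02", hap = "CrtD5.a1", freq = 1)
  p <- sim_params()
  keep <- d$reference
  sim <- simulate_molecules(keep, haps, fr, p, n_per_locus = 150L, seed = 51)
  sim$molecules <- sim$molecules[sim$molecules$locus_id == "L02", ]
  em <- emit_fastq(sim, p, seed = 52)
  res <- process_sample(em$reads, keep, p)
  tr <- truth_variants(keep, d$edits)
  hit <- match_expected(res$calls, tr)
  del <- res$calls[which(hit == "CrtD5.a1"), ]
  expect_equal(nrow(del), 1L)
  # all duplexes carry the deletion (binomial at p=1 is degenerate)
  expect_equal(del$frequency, 1)
  expect_equal(nchar(del$ref), 5L)
})

test_that("replicate filter applies the two-rule acceptance logic", {
  base <- data.table::data.table(
    sample_id = "S", locus_id = "L01", contig = "c", pos = 10L,
    ref = "A", alt = "T", kind = "SNV", depth = 1000L)
  mk <- function(counts) lapply(seq_along(counts), function(i) {
    t <- data.table::copy(base)
    t$replicate <- i; t$count <- counts[i]
    t$frequency <- t$count / t$depth
    t[t$count > 0L, ]
  })
  run <- function(counts) replicate_filter(mk(counts))
  d1 <- run(c(2, 2, 2))
  expect_identical(d1$status, "accepted")
  expect_identical(d1$rule, "three_rep_min2")
  d2 <- run(c(5, 5, 0))
  expect_identical(d2$status, "accepted")
  expect_identical(d2$rule, "two_rep_min5")
  d3 <- run(c(4, 4, 0))
  expect_identical(d3$status, "rejected")
  d4 <- run(c(2, 2, 0))
  expect_identical(d4$status, "rejected")
  d5 <- run(c(1, 1, 1))
  expect_identical(d5$status, "rejected")

  # monotonicity: raising any threshold never adds passing variants
  set.seed(53)
  for (k in 1:30) {
    counts <- stats::rpois(3, 3)
    if (all(counts == 0)) counts[1] <- 1
    base_rules <- list(c(min_count = 2, min_reps = 3),
                       c(min_count = 5, min_reps = 2))
    harder <- list(c(min_count = 3, min_reps = 3),
                   c(min_count = 6, min_reps = 2))
    ok_base <- replicate_filter(mk(counts), base_rules)$status
    ok_hard <- replicate_filter(mk(counts), harder)$status
    expect_false(ok_base == "rejected" && ok_hard == "accepted",
                 info = paste(counts, collapse = ","))
  }
})

test_that("count x replicate heat-map data separates expected classes", {
  tabs <- lapply(1:3, function(i) data.table::data.table(
    sample_id = "S", replicate = i, locus_id = "L01", contig = "c",
    pos = c(10L, 20L), ref = "A", alt = "T", kind = "SNV",
    count = c(6L, 1L), depth = 100L, frequency = c(0.06, 0.01)))
  dec <- replicate_filter(tabs)
  hm <- count_replicate_heatmap(dec, expected = dec$pos == 10L)
  expect_equal(sum(hm$n), 2L)
  expect_setequal(hm$label, c("expected", "unexpected"))
})

test_that("PAM proximity equals a brute-force window enumeration", {
  expect_true(pam_proximity(5L, "AAAAAAGGAA"))     # adjacent NGG
  expect_false(pam_proximity(0L, "ATATATATATATAT"))
  set.seed(54)
  seq <- random_seq(500)
  pos <- sample(4:495, 300)
  got <- pam_proximity(pos, seq)
  want <- vapply(pos, function(p) oracle_pam(p, seq), logical(1))
  expect_identical(got, want)
})

test_that("VCF export anchors InDels and round-trips the call set", {
  d <- fixture_design()
  calls <- data.table::data.table(
    sample_id = "S", replicate = 1L, locus_id = c("L01", "L02", "L03"),
    contig = "sim_chr1",
    pos = c(894L, 2494L, 4094L),
    ref = c("C", "CAGTT", ""), alt = c("", "", "A"),
    kind = c("deletion", "deletion", "insertion"),
    count = c(3L, 5L, 7L), depth = 1000L,
    frequency = c(0.003, 0.005, 0.007))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, d$reference, path)
  txt <- readLines(path)
  rec <- strsplit(grep("^sim_chr1", txt, value = TRUE), "\t")
  # 1-based anchored representation: POS = 0-based pos, REF starts with
  # the anchor base
  expect_equal(as.integer(rec[[1]][2]), 894L)
  anchor <- substring(d$reference$contigs[[1]], 894, 894)
  expect_identical(rec[[1]][4], paste0(anchor, "C"))
  expect_identical(rec[[1]][5], anchor)
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_identical(back$ref, calls$ref)
  expect_identical(back$alt, calls$alt)
  expect_identical(back$kind, calls$kind)
  expect_equal(back$count, calls$count)
  expect_equal(back$frequency, calls$frequency, tolerance = 1e-6)
  # empty call set -> valid header-only VCF
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], d$reference, p2)
  expect_true(all(startsWith(readLines(p2), "#")))
  expect_equal(nrow(read_vcf(p2)), 0L)
})

test_that("emitted VCF parses with a standard VCF reader", {
  skip_if_not_installed("vcfR")
  d <- fixture_design()
  calls <- data.table::data.table(
    sample_id = "S", replicate = 1L, locus_id = "L01", contig = "sim_chr1",
    pos = 894L, ref = "C", alt = "", kind = "deletion",
    count = 3L, depth = 1000L, frequency = 0.003)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, d$reference, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), 1L)
  expect_equal(as.integer(v@fix[1, "POS"]), 894L)
  expect_equal(unname(vcfR::extract.info(v, "DC", as.numeric = TRUE)), 3)
})
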