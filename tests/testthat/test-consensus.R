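# build gapless member alignments for a family from read strings
mk_family <- function(reads, window, start = 0L) {
  lapply(reads, function(s) glocal_align(s, window, min_len = 1L))
}

# pin members to a fixed start (no re-placement of mutated reads)
mk_family_fixed <- function(reads, window, start) {
  lapply(reads, function(s) {
    structure(list(score = nchar(s), ref_start = start,
                   ref_row = substring(window, start + 1L,
                                       start + nchar(s)),
                   read_row = s, aligned = TRUE,
                   cigar = paste0(nchar(s), "M")),
              class = "duplex_alignment")
  })
}

test_that("exact grouping collects reads sharing (locus, UMI, tag)", {
  tagged <- data.table::data.table(
    id = as.character(1:12), umi = rep(c("AAAACCCCGGGG", "TTTTCCCCGGGG"),
                                       each = 6),
    strand_tag = rep(c("TT", "GG"), 6),
    locus_id = "L01", insert_r1 = "A", insert_r2 = "A",
    q1 = NA_character_, q2 = NA_character_, pass = TRUE,
    reason = NA_character_)
  g <- group_families(tagged, merge_umis = FALSE)
  expect_equal(length(unique(g$family_id)), 4L)
  expect_true(all(table(g$family_id) == 3L))
})

test_that("directional UMI merge absorbs small near-miss families", {
  # sizes 30 vs 1, Hamming distance 1 -> one family of 31
  umis <- c(rep("AAAACCCCGGGG", 30), "AAAACCCCGGGT")
  tagged <- data.table::data.table(
    id = as.character(seq_along(umis)), umi = umis, strand_tag = "TT",
    locus_id = "L01", insert_r1 = "A", insert_r2 = "A",
    q1 = NA_character_, q2 = NA_character_, pass = TRUE,
    reason = NA_character_)
  g <- group_families(tagged)
  expect_equal(length(unique(g$family_id)), 1L)
  expect_identical(unique(g$family_umi), "AAAACCCCGGGG")
  # a 2 vs 5 pair is below the 3x ratio: stays separate
  m <- umi_merge_map(c("AAAACCCCGGGG", "AAAACCCCGGGT"), c(5, 2))
  expect_identical(m, c("AAAACCCCGGGG", "AAAACCCCGGGT"))
  m2 <- umi_merge_map(c("AAAACCCCGGGG", "AAAACCCCGGGT"), c(6, 2))
  expect_identical(m2[2], "AAAACCCCGGGG")
})

test_that("zero-error simulation yields one family per captured strand", {
  s <- small_sample(n_per_locus = 120L, params = clean_params(), seed = 31)
  tg <- tag_reads(s$reads$r1, s$reads$r2, s$reads$q1, s$reads$q2,
                  s$reads$id, s$design$reference$primers, s$params)
  g <- group_families(tg$tagged)
  truth_strands <- nrow(unique(s$reads[, c("mol_id", "strand")]))
  expect_equal(length(unique(g$family_id)), truth_strands)
})

test_that("SSC plurality rule keeps the 0.6 boundary and masks below it", {
  set.seed(40)
  win <- random_seq(40)
  base <- substring(win, 5, 28)
  v <- function(s, at, b) `substr<-`(s, at, at, b)
  # 3-vs-2 column at exactly the 0.6 boundary keeps the majority base
  fam <- mk_family_fixed(c(base, base, base, v(base, 10, "T"),
                           v(base, 10, "T")), win, 4L)
  ssc <- build_ssc(fam)
  expect_equal(ssc$n_reads, 5L)
  cols <- ssc$columns
  expect_identical(cols$base[cols$ref_pos == 13], substring(base, 10, 10))
  # 2/2 split -> N
  fam2 <- mk_family_fixed(c(base, base, v(base, 10, "T"), v(base, 10, "T")),
                          win, 4L)
  expect_identical(build_ssc(fam2)$columns[ref_pos == 13]$base, "N")
  # unanimity: consensus equals the read
  fam3 <- mk_family(rep(base, 5), win)
  c3 <- build_ssc(fam3)$columns
  expect_identical(paste(c3$base, collapse = ""), base)
  # single-read family adopts the read
  c1 <- build_ssc(mk_family(base, win))$columns
  expect_identical(paste(c1$base, collapse = ""), base)
})

test_that("SSC equals the exhaustive per-column majority oracle", {
  set.seed(32)
  win <- random_seq(40)
  for (k in 1:40) {
    n_reads <- sample(2:6, 1)
    L <- sample(6:10, 1)
    start <- sample(1:20, 1)
    base <- substring(win, start, start + L - 1)
    reads <- vapply(seq_len(n_reads), function(i) {
      s <- base
      n_mut <- sample(0:2, 1)
      for (j in seq_len(n_mut)) {
        at <- sample(L, 1)
        substr(s, at, at) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }, "")
    ssc <- build_ssc(mk_family_fixed(reads, win, start - 1L))
    got <- paste(ssc$columns$base[ssc$columns$ins_offset == 0L],
                 collapse = "")
    expect_identical(got, oracle_consensus(reads), info = paste(reads,
                                                               collapse = " "))
  }
})

test_that("duplex merge masks discordance and is symmetric", {
  set.seed(41)
  win <- random_seq(32)
  s <- substring(win, 3, 22)
  ssc_a <- build_ssc(mk_family(s, win))
  expect_identical(
    paste(build_dcs(ssc_a, ssc_a)$columns$base, collapse = ""), s)
  # single discordant base -> N at that column
  s2 <- `substr<-`(s, 8, 8, if (substring(s, 8, 8) == "T") "G" else "T")
  ssc_b <- build_ssc(mk_family(s2, win))
  d1 <- build_dcs(ssc_a, ssc_b); d2 <- build_dcs(ssc_b, ssc_a)
  expect_identical(d1$columns$base, d2$columns$base)   # symmetry
  expect_identical(d1$columns$base[8], "N")
  expect_equal(sum(d1$columns$base == "N"), 1L)
  # spans intersect
  ssc_c <- build_ssc(mk_family(substring(win, 7, 26), win))
  d3 <- build_dcs(ssc_a, ssc_c)
  expect_equal(range(d3$columns$ref_pos), c(6, 21))
})

test_that("an insertion slot present on one strand only is masked out", {
  set.seed(42)
  win <- random_seq(32)
  s <- substring(win, 3, 22)
  with_ins <- paste0(substring(s, 1, 10), "A", substring(s, 11))
  ssc_plain <- build_ssc(mk_family(s, win))
  ssc_ins <- build_ssc(mk_family(with_ins, win))
  expect_true(any(ssc_ins$columns$ins_offset > 0L))
  d <- build_dcs(ssc_plain, ssc_ins)
  expect_false(any(d$columns$ins_offset > 0L))
  # both strands carrying the same insertion keep it
  d2 <- build_dcs(ssc_ins, ssc_ins)
  expect_true(any(d2$columns$ins_offset > 0L))
})

test_that("random SSC pairs merge symmetrically", {
  set.seed(33)
  win <- random_seq(60)
  for (k in 1:20) {
    mk <- function() {
      start <- sample(1:20, 1); L <- sample(15:30, 1)
      s <- substring(win, start, start + L - 1)
      if (runif(1) < 0.5) {
        at <- sample(5:10, 1)
        substr(s, at, at) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      build_ssc(mk_family(s, win))
    }
    a <- mk(); b <- mk()
    expect_identical(build_dcs(a, b)$columns, build_dcs(b, a)$columns)
  }
})

test_that("same-tag duplex pairing is a contract violation", {
  # pairing is by (locus, umi) with opposite tags; the batched pipeline
  # never pairs same-tag SSCs, and per-strand minimums are enforced
  set.seed(43)
  win <- random_seq(32)
  ssc <- build_ssc(mk_family(substring(win, 3, 22), win))
  expect_error(build_dcs(ssc, ssc, min_reads_per_strand = 2L),
               "min_reads_per_strand")
})

test_that("raising min_reads_per_strand never increases duplex count", {
  s <- small_sample(n_per_locus = 200L, seed = 34)
  tg <- tag_reads(s$reads$r1, s$reads$r2, s$reads$q1, s$reads$q2,
                  s$reads$id, s$design$reference$primers, s$params)
  g <- group_families(tg$tagged)
  n_prev <- Inf
  for (mrs in 1:4) {
    n <- nrow(consensus_sample(g, s$design$reference, s$params,
                               min_reads_per_strand = mrs)$dcs)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("single-strand damage never reaches the DCS; end-repair always does", {
  d <- fixture_design()
  p <- sim_params(end_repair_rate = 0.04, single_strand_rate = 0.04,
                  jackpot_rate = 0, seq_error = 0)
  sim <- simulate_molecules(d$reference, list(), NULL, p,
                            n_per_locus = 400L, seed = 35)
  em <- emit_fastq(sim, p, seed = 36)
  tg <- tag_reads(em$reads$r1, em$reads$r2, em$reads$q1, em$reads$q2,
                  em$reads$id, d$reference$primers, p)
  g <- group_families(tg$tagged)
  cons <- consensus_sample(g, d$reference, p)
  dcs <- cons$dcs
  mols <- sim$molecules
  led <- sim$ledger
  led <- led[led$rel >= 24, ]      # primer-covered bases never sequenced
  checked_er <- 0L; checked_ss <- 0L
  for (k in seq_len(nrow(led))) {
    mol <- mols[mols$mol_id == led$mol_id[k], ]
    i <- which(dcs$locus_id == mol$locus_id & dcs$umi == mol$umi)
    if (length(i) != 1L) next      # molecule not duplex-captured
    pos_rel <- mol$insert_start + led$rel[k] - dcs$window_start[i]
    char_at <- substring(dcs$read_row[i], pos_rel - dcs$ref_start[i] + 1L,
                         pos_rel - dcs$ref_start[i] + 1L)
    if (led$class[k] == "end_repair") {
      expect_identical(char_at, led$to_fwd[k])
      checked_er <- checked_er + 1L
    } else {
      expect_identical(char_at, "N")
      checked_ss <- checked_ss + 1L
    }
  }
  expect_gt(checked_er, 20L)
  expect_gt(checked_ss, 20L)
})
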