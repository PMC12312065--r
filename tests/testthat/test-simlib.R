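test_that("reference construction satisfies its invariants and is deterministic", {
  ref <- build_reference(seed = 1, n_loci = 4, window_len = 800)
  expect_equal(nrow(ref$windows), 4L)
  expect_equal(nrow(ref$primers), 4L)
  expect_true(validate_reference(ref))
  # windows lie inside the contig and each hosts its primer
  expect_true(all(ref$windows$end <= nchar(ref$contigs[[1]])))
  for (k in 1:4) {
    p <- ref$primers[k, ]; w <- ref$windows[k, ]
    expect_identical(substring(ref$contigs[[w$contig]], p$start + 1,
                               p$start + 24), p$sequence)
    expect_true(p$anchor >= w$start && p$anchor <= w$end)
  }
  ref2 <- build_reference(seed = 1, n_loci = 4, window_len = 800)
  expect_identical(ref, ref2)
  tmp <- tempfile()
  write_reference(ref, tmp)
  write_reference(ref2, paste0(tmp, "b"))
  expect_identical(readLines(paste0(tmp, ".fa")),
                   readLines(paste0(tmp, "b.fa")))
  expect_error(build_reference(seed = 1, n_loci = 4, window_len = 100),
               "too small")
})

test_that("reference FASTA/BED/TSV round trip", {
  ref <- fixture_design()$reference
  tmp <- tempfile()
  write_reference(ref, tmp)
  back <- read_reference(tmp)
  expect_identical(unname(back$contigs), unname(ref$contigs))
  expect_equal(as.data.frame(back$windows), as.data.frame(ref$windows))
  expect_equal(back$primers$sequence, ref$primers$sequence)
})

test_that("edits apply with correct length changes and guards", {
  d <- fixture_design()
  haps <- apply_edits(d$reference, d$edits)
  clen <- nchar(d$reference$contigs[[1]])
  # 5-bp deletion shortens the haplotype by 5
  expect_equal(nchar(haps[["CrtD5.a1"]]$contigs[[1]]), clen - 5L)
  # 1-bp insertion lengthens it by 1
  expect_equal(nchar(haps[["PsyIns1.a1"]]$contigs[[1]]), clen + 1L)
  # heterozygous line yields two haplotypes
  expect_equal(nchar(haps[["PsyHet.del"]]$contigs[[1]]), clen - 1L)
  expect_equal(nchar(haps[["PsyHet.ins"]]$contigs[[1]]), clen + 1L)
  # empty edit list: no haplotypes, reference untouched
  expect_length(apply_edits(d$reference, d$edits[0, ]), 0L)
  # ref_allele mismatch is caught (guards coordinate-convention bugs)
  bad <- data.table::copy(d$edits)
  bad$ref_allele[2] <- "AAAAA"
  expect_error(apply_edits(d$reference, bad), "mismatch")
  # downstream coordinates shift by the net indel length
  h <- haps[["CrtD5.a1"]]
  expect_equal(hap_coord(h, d$edits$start[2] + 100L),
               d$edits$start[2] + 95L)
})

test_that("mixture design converts mass to per-allele copy ratio by zygosity", {
  d <- fixture_design()
  mix <- design_mixture(d$edits, c(0.009, 0.001))
  hom <- mix$lines[mix$lines$line_id == "CrtD1" &
                   mix$lines$level == 0.009, ]
  expect_equal(hom$mass_fraction, 0.009)
  expect_equal(hom$per_allele_copy_ratio, 0.009)
  het <- mix$lines[mix$lines$line_id == "PsyHet" &
                   mix$lines$level == 0.001, ]
  expect_equal(het$mass_fraction, 0.002)      # double the mass
  expect_equal(het$per_allele_copy_ratio, 0.001)
  expect_error(design_mixture(d$edits, c(0, 0.1)), "levels")
  expect_error(design_mixture(d$edits, 0.5), "sum")
})

test_that("molecule haplotype sampling recovers the copy ratio", {
  d <- fixture_design()
  haps <- apply_edits(d$reference, d$edits)
  mix <- design_mixture(d$edits, 0.001)
  fr <- duplexr:::hap_frequencies(mix, d$edits, 0.001)
  p <- clean_params()
  sim <- simulate_molecules(d$reference, haps, fr, p,
                            n_per_locus = 10000L, seed = 3)
  m <- sim$molecules[sim$molecules$locus_id == "L01", ]
  x <- sum(m$hap == "CrtD1.a1")
  se <- sqrt(10000 * 0.001 * 0.999)
  expect_lt(abs(x - 10), 3 * se)
})

test_that("zero artefact rates give exact reverse-complement strands", {
  s <- small_sample(n_per_locus = 150L, params = clean_params())
  expect_equal(nrow(s$sim$ledger), 0L)
  expect_identical(revcomp(s$sim$molecules$bottom_seq),
                   s$sim$molecules$top_seq)
})

test_that("end-repair damage is double-stranded and adapter-proximal", {
  d <- fixture_design()
  p <- sim_params(end_repair_rate = 1, single_strand_rate = 0,
                  jackpot_rate = 0, seq_error = 0)
  sim <- simulate_molecules(d$reference, list(), NULL, p,
                            n_per_locus = 250L, seed = 5)
  led <- sim$ledger
  expect_equal(nrow(led), 1000L)             # one event per molecule
  expect_true(all(led$class == "end_repair"))
  expect_true(all(led$strand == "both"))
  m <- sim$molecules[match(led$mol_id, sim$molecules$mol_id), ]
  expect_true(all(led$rel >= m$insert_len - p$end_repair_window))
  expect_true(all(led$rel < m$insert_len))
  # change really is on both strands, complementarily
  for (k in sample(nrow(led), 25)) {
    rel <- led$rel[k]; il <- m$insert_len[k]
    top <- substring(m$top_seq[k], rel + 1, rel + 1)
    bot <- substring(m$bottom_seq[k], il - rel, il - rel)
    expect_identical(chartr("ACGT", "TGCA", top), bot)
  }
})

test_that("single-strand damage hits exactly one strand", {
  d <- fixture_design()
  p <- sim_params(end_repair_rate = 0, single_strand_rate = 1,
                  jackpot_rate = 0, seq_error = 0)
  sim <- simulate_molecules(d$reference, list(), NULL, p,
                            n_per_locus = 100L, seed = 6)
  led <- sim$ledger
  expect_true(all(led$class == "single_strand"))
  expect_true(all(led$strand %in% c("top", "bottom")))
  m <- sim$molecules[match(led$mol_id, sim$molecules$mol_id), ]
  for (k in sample(nrow(led), 25)) {
    rel <- led$rel[k]; il <- m$insert_len[k]
    top <- substring(m$top_seq[k], rel + 1, rel + 1)
    bot <- substring(m$bottom_seq[k], il - rel, il - rel)
    # damaged on one strand only: the two are NOT complementary there
    expect_false(identical(chartr("ACGT", "TGCA", top), bot))
  }
})

test_that("read emission has the documented structure", {
  d <- fixture_design()
  p <- clean_params(reads_per_strand_mean = 2, strand_capture = 1)
  sim <- simulate_molecules(d$reference, list(), NULL, p,
                            n_per_locus = 1L, seed = 7)
  sim$molecules <- sim$molecules[1, ]
  sim$molecules$umi <- "ACGTACGTACGT"
  em <- emit_fastq(sim, p, seed = 8)
  r <- em$reads
  # both strands captured; each read-1 carries the UMI then the tag
  expect_true(all(substring(r$r1, 1, 12) == "ACGTACGTACGT"))
  expect_setequal(unique(substring(r$r1, 13, 14)), c("TT", "GG"))
  expect_true(all(nchar(r$r1) == 150 & nchar(r$r2) == 150))
  # read 2 starts with the locus primer
  pr <- d$reference$primers$sequence[d$reference$primers$locus_id ==
                                     sim$molecules$locus_id]
  expect_true(all(substring(r$r2, 1, 24) == pr))
  # strand capture 0: no bottom-strand (GG) reads anywhere
  p0 <- clean_params(strand_capture = 0)
  sim0 <- simulate_molecules(d$reference, list(), NULL, p0,
                             n_per_locus = 50L, seed = 9)
  em0 <- emit_fastq(sim0, p0, seed = 10)
  expect_false(any(substring(em0$reads$r1, 13, 14) == "GG"))
})

test_that("mean reads per UMI matches the reads-per-strand law", {
  d <- fixture_design()
  # strand mean 1 + 4 = 5, both strands always captured -> 10 per UMI
  p <- clean_params(reads_per_strand_mean = 4, strand_capture = 1)
  sim <- simulate_molecules(d$reference, list(), NULL, p,
                            n_per_locus = 250L, seed = 11)
  em <- emit_fastq(sim, p, seed = 12)
  per_umi <- table(em$reads$mol_id)
  expect_lt(abs(mean(per_umi) - 10) / 10, 0.05)
})

test_that("emission is deterministic and FASTQ round-trips", {
  s1 <- small_sample(n_per_locus = 40L, seed = 13)
  s2 <- small_sample(n_per_locus = 40L, seed = 13)
  expect_identical(s1$reads, s2$reads)
  dir <- tempfile(); dir.create(dir)
  d <- fixture_design()
  em <- emit_fastq(s1$sim, s1$params, seed = 14,
                   out_prefix = file.path(dir, "x"))
  em2 <- emit_fastq(s1$sim, s1$params, seed = 14,
                    out_prefix = file.path(dir, "y"))
  f1 <- read_fastq(file.path(dir, "x_R1.fastq.gz"))
  g1 <- read_fastq(file.path(dir, "y_R1.fastq.gz"))
  expect_identical(f1, g1)
  expect_identical(f1$seq, em$reads$r1)
  expect_identical(f1$qual, em$reads$q1)
})

test_that("tag extraction round-trips error-free simulated reads losslessly", {
  s <- small_sample(n_per_locus = 150L, params = clean_params(), seed = 15)
  tg <- tag_reads(s$reads$r1, s$reads$r2, s$reads$q1, s$reads$q2,
                  s$reads$id, s$design$reference$primers, s$params)
  expect_equal(tg$report$passed, nrow(s$reads))    # 100 % recovery
  # recovered (UMI, tag, locus) match the simulator truth
  mols <- s$sim$molecules
  idx <- match(s$reads$mol_id, mols$mol_id)
  expect_identical(tg$tagged$umi, mols$umi[idx])
  expect_identical(tg$tagged$locus_id, mols$locus_id[idx])
  expect_identical(tg$tagged$strand_tag,
                   ifelse(s$reads$strand == "top", "TT", "GG"))
})
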