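#' Simulation parameters for the duplex library generator
#'
#' Defaults emulate a sheared (mean fragment 550 nt), SPE-enriched duplex
#' library sequenced 2 x 150 with about 10 reads per UMI: each captured
#' strand yields `1 + Poisson(4.5)` reads and the bottom strand of a
#' molecule is captured with probability 0.85.  Artefact classes:
#' \describe{
#'   \item{single_strand}{base damage on one strand only (rate per
#'     molecule); removed by duplex masking.}
#'   \item{end_repair}{oxidative/deamination damage (G->T or C->T on the
#'     damaged strand) copied to the complementary strand during end
#'     repair, placed within `end_repair_window` nt of the
#'     adapter-proximal fragment end; survives duplex masking.}
#'   \item{pcr_jackpot}{an early-cycle PCR error shared by a random
#'     fraction of one strand family's reads (rate per base-duplication
#'     opportunity, i.e. per template base per strand family).}
#' }
#'
#' @param fragment_mean,fragment_sd,fragment_min,fragment_max fragment
#'   length distribution (normal, clipped)
#' @param insert_min,insert_max amplicon insert range (primer 5' end to
#'   the adapter-proximal fragment end); the breakpoint is uniform
#' @param reads_per_strand_mean lambda of the Poisson part of the
#'   reads-per-strand distribution (reads = 1 + Poisson(lambda))
#' @param strand_capture probability that the bottom strand of a molecule
#'   is converted and sequenced
#' @param seq_error per-base sequencing error rate
#' @param jackpot_rate PCR jackpot probability per base-duplication
#'   opportunity
#' @param end_repair_rate per-molecule end-repair artefact probability
#' @param end_repair_window artefact distance from the adapter-proximal
#'   fragment end (nt)
#' @param single_strand_rate per-molecule single-strand damage probability
#' @param read_len read length (nt)
#' @param umi_len UMI length (nt)
#' @param base_quality constant Phred quality written to FASTQ
#' @param tag_top,tag_bottom 2-nt strand tags (the TT/GG labelling is an
#'   arbitrary but fixed pairing)
#' @return list of class `sim_params`
#' @export
sim_params <- function(fragment_mean = 550, fragment_sd = 40,
                       fragment_min = 400, fragment_max = 700,
                       insert_min = 150L, insert_max = 200L,
                       reads_per_strand_mean = 4.5,
                       strand_capture = 0.85,
                       seq_error = 1e-3,
                       jackpot_rate = 5e-5,
                       end_repair_rate = 3e-4,
                       end_repair_window = 30L,
                       single_strand_rate = 1e-3,
                       read_len = 150L, umi_len = 12L,
                       base_quality = 30L,
                       tag_top = "TT", tag_bottom = "GG") {
  p <- as.list(environment())
  probs <- c(p$strand_capture, p$seq_error, p$jackpot_rate,
             p$end_repair_rate, p$single_strand_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (p$insert_min < p$read_len)
    stopf("insert_min below read length is not supported")
  class(p) <- "sim_params"
  p
}

#' Simulate duplex molecules for one library
#'
#' Draws `n_per_locus` template molecules per target window.  Each
#' molecule picks a haplotype with probability equal to its per-allele
#' copy ratio, a fragment whose adapter-proximal end lies
#' `insert_min..insert_max` nt downstream of the SPE primer start
#' (uniform breakpoint), and a UMI i.i.d. uniform over 4^12.  Artefacts
#' are injected per `sim_params` and recorded in a ledger.  Only the
#' amplifiable segment (primer start to the adapter-proximal fragment
#' end) is tracked as sequence; damage inside the primer landing site is
#' not modelled because PCR replaces those bases with the primer oligo.
#'
#' @param ref a `duplex_reference`
#' @param haplotypes list from [apply_edits()] (may be empty)
#' @param hap_freq data.table (locus_id, hap, freq); loci absent from the
#'   table are all-background.  `NULL` means pure background.
#' @param params a `sim_params` object
#' @param n_per_locus molecules per target window (>= 1)
#' @param seed mandatory RNG seed
#' @return list(molecules, ledger): `molecules` has one row per molecule
#'   (mol_id, locus_id, hap, frag_start, frag_end, insert_start,
#'   insert_len, umi, top_seq, bottom_seq with bottom stored 5'->3');
#'   `ledger` has one row per artefact event (mol_id, class, strand, rel,
#'   change, read_fraction)
#' @export
simulate_molecules <- function(ref, haplotypes, hap_freq, params,
                               n_per_locus, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (n_per_locus < 1L) stopf("n_per_locus must be >= 1")
  set.seed(seed)
  loci <- ref$windows$locus_id
  mols <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    lid <- loci[i]
    pr <- ref$primers[ref$primers$locus_id == lid, ]
    w <- ref$windows[ref$windows$locus_id == lid, ]
    fr <- if (is.null(hap_freq)) NULL else hap_freq[hap_freq$locus_id == lid, ]
    if (is.null(fr) || nrow(fr) == 0L)
      fr <- data.table::data.table(locus_id = lid, hap = "background", freq = 1)
    if (abs(sum(fr$freq) - 1) > 1e-9) stopf("haplotype frequencies must sum to 1")
    hap <- fr$hap[sample.int(nrow(fr), n_per_locus, replace = TRUE,
                             prob = fr$freq)]
    insert_len <- sample(params$insert_min:params$insert_max, n_per_locus,
                         replace = TRUE)
    frag_len <- as.integer(round(pmin(params$fragment_max,
                                      pmax(params$fragment_min,
                                           stats::rnorm(n_per_locus,
                                                        params$fragment_mean,
                                                        params$fragment_sd)))))
    frag_len <- pmax(frag_len, insert_len)
    frag_end <- pr$start + insert_len   # adapter-proximal end (ref coords)
    mols[[i]] <- data.table::data.table(
      locus_id = lid, contig = w$contig, hap = hap,
      insert_start = pr$start, insert_len = insert_len,
      frag_start = frag_end - frag_len, frag_end = frag_end)
  }
  mols <- data.table::rbindlist(mols)
  n <- nrow(mols)
  mols$mol_id <- seq_len(n)
  mols$umi <- random_dna(n, params$umi_len)

  # template sequence of the amplifiable segment, per haplotype
  mols$top_seq <- ""
  for (h in unique(mols$hap)) {
    idx <- which(mols$hap == h)
    for (ct in unique(mols$contig[idx])) {
      jj <- idx[mols$contig[idx] == ct]
      contig <- if (h == "background") ref$contigs[[ct]] else
        haplotypes[[h]]$contigs[[ct]]
      s <- if (h == "background") mols$insert_start[jj] else
        hap_coord(haplotypes[[h]], mols$insert_start[jj])
      mols$top_seq[jj] <- substring(contig, s + 1L, s + mols$insert_len[jj])
    }
  }
  mols$bottom_seq <- revcomp(mols$top_seq)

  primer_len <- 24L
  ledger <- list()

  # end-repair damage: complementary change on BOTH strands near the
  # adapter-proximal end; the damaged base is a G or C on the damaged strand
  hit <- which(stats::rbinom(n, 1L, params$end_repair_rate) == 1L)
  if (length(hit)) {
    led <- lapply(hit, function(j) {
      ilen <- mols$insert_len[j]
      lo <- max(primer_len, ilen - params$end_repair_window)
      cand <- lo:(ilen - 1L)                      # 0-based rel positions
      strand <- sample(c("top", "bottom"), 1L)
      seq_fwd <- mols$top_seq[j]
      base_fwd <- substring(seq_fwd, cand + 1L, cand + 1L)
      base_on_strand <- if (strand == "top") base_fwd else comp_base(base_fwd)
      ok <- cand[base_on_strand %in% c("G", "C")]
      if (!length(ok)) return(NULL)
      rel <- if (length(ok) == 1L) ok else sample(ok, 1L)
      from <- substring(seq_fwd, rel + 1L, rel + 1L)
      from_strand <- if (strand == "top") from else comp_base(from)
      to_strand <- "T"                            # G->T or C->T on damaged strand
      to_fwd <- if (strand == "top") to_strand else comp_base(to_strand)
      data.table::data.table(mol_id = mols$mol_id[j], class = "end_repair",
                             strand = "both", rel = rel,
                             change = paste0(from_strand, ">", to_strand),
                             to_fwd = to_fwd, read_fraction = NA_real_)
    })
    ledger <- c(ledger, led)
  }

  # single-strand damage: one strand only, anywhere downstream of the primer
  hit <- which(stats::rbinom(n, 1L, params$single_strand_rate) == 1L)
  if (length(hit)) {
    rel <- primer_len + floor(runif(length(hit)) *
                              (mols$insert_len[hit] - primer_len))
    strand <- sample(c("top", "bottom"), length(hit), replace = TRUE)
    from_fwd <- substring(mols$top_seq[hit], rel + 1L, rel + 1L)
    to_fwd <- other_base(from_fwd)
    ledger <- c(ledger, list(data.table::data.table(
      mol_id = mols$mol_id[hit], class = "single_strand", strand = strand,
      rel = as.integer(rel), change = paste0(from_fwd, ">", to_fwd),
      to_fwd = to_fwd, read_fraction = NA_real_)))
  }

  # PCR jackpot: per strand family, probability rate * insert_len
  for (strand in c("top", "bottom")) {
    p_jack <- pmin(1, params$jackpot_rate * mols$insert_len)
    hit <- which(stats::rbinom(n, 1L, p_jack) == 1L)
    if (length(hit)) {
      rel <- primer_len + floor(runif(length(hit)) *
                                (mols$insert_len[hit] - primer_len))
      from_fwd <- substring(mols$top_seq[hit], rel + 1L, rel + 1L)
      to_fwd <- other_base(from_fwd)
      ledger <- c(ledger, list(data.table::data.table(
        mol_id = mols$mol_id[hit], class = "pcr_jackpot", strand = strand,
        rel = as.integer(rel), change = paste0(from_fwd, ">", to_fwd),
        to_fwd = to_fwd, read_fraction = runif(length(hit)))))
    }
  }

  ledger <- if (length(ledger)) data.table::rbindlist(ledger) else
    data.table::data.table(mol_id = integer(), class = character(),
                           strand = character(), rel = integer(),
                           change = character(), to_fwd = character(),
                           read_fraction = numeric())
  data.table::setorder(ledger, mol_id)

  # apply molecule-level damage (end_repair, single_strand) to the strands;
  # jackpots are PCR-stage events applied at read emission
  dmg <- ledger[ledger$class != "pcr_jackpot", ]
  if (nrow(dmg)) {
    for (k in seq_len(nrow(dmg))) {
      j <- dmg$mol_id[k]; rel <- dmg$rel[k]; to_fwd <- dmg$to_fwd[k]
      ilen <- mols$insert_len[j]
      if (dmg$strand[k] %in% c("top", "both"))
        substr(mols$top_seq[j], rel + 1L, rel + 1L) <- to_fwd
      if (dmg$strand[k] %in% c("bottom", "both"))    # bottom stored 5'->3'
        substr(mols$bottom_seq[j], ilen - rel, ilen - rel) <-
          comp_base(to_fwd)
    }
  }
  list(molecules = mols, ledger = ledger,
       primers = stats::setNames(ref$primers$sequence, ref$primers$locus_id))
}

#' Emit paired-end FASTQ reads from simulated molecules
#'
#' Read 1 is `[12-nt UMI][2-nt strand tag][genomic insert from the
#' adapter-proximal end inward]`; read 2 starts with the SPE primer oligo
#' and reads into the target.  The top strand of every molecule is
#' sequenced; the bottom strand only when captured (see
#' `strand_capture`).  Each captured strand yields `1 + Poisson` reads.
#' PCR jackpot changes are applied to a random subset of one strand
#' family's read pairs; sequencing errors are i.i.d. per base over the
#' full reads (UMI, tag and primer bases included).  Qualities are
#' constant (`base_quality`); error injection is independent of the
#' written qualities.
#'
#' @param sim result of [simulate_molecules()]
#' @param params a `sim_params` object
#' @param seed mandatory RNG seed
#' @param out_prefix if non-NULL, write `<prefix>_R1.fastq.gz`,
#'   `<prefix>_R2.fastq.gz` and truth tables
#'   `<prefix>.molecules.tsv` / `<prefix>.ledger.tsv`
#' @param sample_id sample label used in read names
#' @return list(reads, files): `reads` is a data.table (id, r1, r2, q1,
#'   q2, mol_id, strand)
#' @export
emit_fastq <- function(sim, params, seed, out_prefix = NULL,
                       sample_id = "S1") {
  if (missing(seed)) stopf("seed is mandatory")
  mols <- sim$molecules
  if (nrow(mols) == 0L) stopf("no molecules to emit")
  set.seed(seed)
  primer_len <- 24L
  rl <- params$read_len
  g1 <- rl - params$umi_len - 2L          # genomic bases in read 1

  fam <- data.table::rbindlist(list(
    data.table::data.table(mol_id = mols$mol_id, strand = "top"),
    data.table::data.table(
      mol_id = mols$mol_id[stats::rbinom(nrow(mols), 1L,
                                         params$strand_capture) == 1L],
      strand = "bottom")))
  fam$n_reads <- 1L + stats::rpois(nrow(fam), params$reads_per_strand_mean)

  idx <- match(fam$mol_id, mols$mol_id)
  template <- ifelse(fam$strand == "top", mols$top_seq[idx],
                     revcomp(mols$bottom_seq[idx]))  # forward orientation
  ilen <- mols$insert_len[idx]

  # jackpot changes mutate the strand family template for a read subset
  jp <- sim$ledger[sim$ledger$class == "pcr_jackpot", ]

  # expand families to reads
  fam$fam_row <- seq_len(nrow(fam))
  reads <- fam[rep(fam$fam_row, fam$n_reads),
               c("mol_id", "strand", "fam_row")]
  reads$read_no <- sequence(fam$n_reads)
  tpl <- template[reads$fam_row]
  tlen <- ilen[reads$fam_row]

  if (nrow(jp)) {
    key <- paste(reads$mol_id, reads$strand)
    for (k in seq_len(nrow(jp))) {
      rows <- which(key == paste(jp$mol_id[k], jp$strand[k]))
      if (!length(rows)) next
      pick <- rows[stats::rbinom(length(rows), 1L, jp$read_fraction[k]) == 1L]
      if (!length(pick)) next
      rel <- jp$rel[k]
      substr(tpl[pick], rel + 1L, rel + 1L) <- jp$to_fwd[k]
    }
  }

  # read 2: primer oligo (PCR replaces the landing site with the oligo
  # sequence) + template downstream of the primer site
  loc <- mols$locus_id[idx][reads$fam_row]
  r2 <- paste0(sim$primers[loc], substring(tpl, primer_len + 1L, rl))
  # read 1 genomic part: last g1 bases of the template, reverse complemented
  r1g <- revcomp(substring(tpl, tlen - g1 + 1L, tlen))
  umi <- mols$umi[idx][reads$fam_row]
  tag <- ifelse(reads$strand == "top", params$tag_top, params$tag_bottom)
  r1 <- paste0(umi, tag, r1g)

  # sequencing errors, uniform over read bases
  inject <- function(s) {
    nb <- length(s) * rl
    ne <- stats::rbinom(1L, nb, params$seq_error)
    if (ne == 0L) return(s)
    at <- sample.int(nb, ne, replace = TRUE)
    ridx <- ((at - 1L) %/% rl) + 1L
    pos <- ((at - 1L) %% rl) + 1L
    cur <- substring(s[ridx], pos, pos)
    cpp_substitute(s, ridx, pos, other_base(cur))
  }
  r1 <- inject(r1)
  r2 <- inject(r2)

  q <- strrep(intToUtf8(params$base_quality + 33L), rl)
  out <- data.table::data.table(
    id = sprintf("%s:%d:%s:%d", sample_id, reads$mol_id, reads$strand,
                 reads$read_no),
    r1 = r1, r2 = r2, q1 = q, q2 = q,
    mol_id = reads$mol_id, strand = reads$strand)

  files <- NULL
  if (!is.null(out_prefix)) {
    f1 <- paste0(out_prefix, "_R1.fastq.gz")
    f2 <- paste0(out_prefix, "_R2.fastq.gz")
    write_fastq(out$id, out$r1, out$q1, f1)
    write_fastq(out$id, out$r2, out$q2, f2)
    mt <- paste0(out_prefix, ".molecules.tsv")
    lt <- paste0(out_prefix, ".ledger.tsv")
    data.table::fwrite(mols[, c("mol_id", "locus_id", "hap", "frag_start",
                                "frag_end", "insert_start", "insert_len",
                                "umi")], mt, sep = "\t")
    data.table::fwrite(sim$ledger, lt, sep = "\t")
    files <- c(r1 = f1, r2 = f2, molecules = mt, ledger = lt)
  }
  list(reads = out, files = files)
}

#' Write a FASTQ file (gzipped when the path ends in .gz)
#' @param id,seq,qual equal-length character vectors
#' @param path output path
#' @export
write_fastq <- function(id, seq, qual, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  rec <- paste0("@", id, "\n", seq, "\n+\n", qual)
  writeLines(rec, con)
  invisible(path)
}

#' Read a FASTQ file into id/seq/qual vectors
#' @param path FASTQ path (.gz supported)
#' @return data.table(id, seq, qual)
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.table::data.table(id = sub("\\s.*$", "", names(x)),
                         seq = as.character(x),
                         qual = as.character(Biostrings::quality(x)))
}
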