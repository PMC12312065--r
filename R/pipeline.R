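#' Normalised truth variants for an edit table
#'
#' Converts `duplex_edits` rows into the same left-normalised
#' (contig, pos, ref, alt) tuples the caller produces, so spiked edits
#' can be matched exactly against called variants.
#'
#' @param ref a `duplex_reference`
#' @param edits a `duplex_edits` table
#' @return data.table (mutation, line_id, allele_id, locus_id, contig,
#'   pos, ref, alt, kind)
#' @export
truth_variants <- function(ref, edits) {
  out <- vector("list", nrow(edits))
  for (k in seq_len(nrow(edits))) {
    w <- ref$windows[ref$windows$locus_id == edits$locus_id[k], ]
    cs <- ref$contigs[[w$contig]]
    nv <- normalize_variant(edits$start[k], edits$ref_allele[k],
                            edits$alt_allele[k], cs)
    out[[k]] <- data.table::data.table(
      mutation = paste(edits$line_id[k], edits$allele_id[k], sep = "."),
      line_id = edits$line_id[k], allele_id = edits$allele_id[k],
      locus_id = edits$locus_id[k], contig = w$contig,
      pos = nv$pos, ref = nv$ref_allele, alt = nv$alt_allele,
      kind = edits$kind[k])
  }
  data.table::rbindlist(out)
}

#' Match called variants against truth edits
#' @param calls variant table from [aggregate_counts()]
#' @param truth table from [truth_variants()]
#' @return character vector: the matching mutation name per call row
#'   (NA for artefact-derived variants)
#' @export
match_expected <- function(calls, truth) {
  key <- paste(calls$contig, calls$pos, calls$ref, calls$alt)
  tkey <- paste(truth$contig, truth$pos, truth$ref, truth$alt)
  truth$mutation[match(key, tkey)]
}

#' Run the analysis pipeline on one sample's reads
#'
#' tag -> locus assignment -> QC -> UMI family grouping -> single-strand
#' and duplex consensus -> variant calling -> per-sample aggregation.
#'
#' @param reads data.table (id, r1, r2, q1, q2) as produced by
#'   [emit_fastq()] or read from FASTQ
#' @param ref a `duplex_reference`
#' @param params a `sim_params`
#' @param sample_id,replicate labels for the output table
#' @param min_mean_quality,min_insert_len,max_mismatch tagging thresholds
#' @param plurality,min_reads_per_strand,edge_guard consensus/calling
#'   parameters
#' @param roi region-of-interest table for variant calling (see
#'   [default_roi()]); NULL disables the restriction
#' @return list(calls, dcs, depth, reports)
#' @export
process_sample <- function(reads, ref, params = sim_params(),
                           sample_id = "S1", replicate = 1L,
                           min_mean_quality = 20, min_insert_len = 30L,
                           max_mismatch = 1L, plurality = 0.6,
                           min_reads_per_strand = 1L, edge_guard = 2L,
                           roi = default_roi(ref, params)) {
  tg <- tag_reads(reads$r1, reads$r2, reads$q1, reads$q2, reads$id,
                  ref$primers, params, min_mean_quality, min_insert_len,
                  max_mismatch)
  grouped <- group_families(tg$tagged)
  cons <- consensus_sample(grouped, ref, params, plurality,
                           min_reads_per_strand)
  called <- call_dcs_variants(cons$dcs, ref, edge_guard, roi)
  calls <- aggregate_counts(called, sample_id, replicate)
  list(calls = calls, dcs = cons$dcs, depth = called$depth,
       observations = called$observations,
       reports = list(tagging = tg$report, consensus = cons$stats))
}

#' Run a FASTQ pair through the pipeline
#' @param r1_path,r2_path FASTQ(.gz) paths
#' @inheritParams process_sample
#' @param ... passed to [process_sample()]
#' @return as [process_sample()]
#' @export
process_fastq <- function(r1_path, r2_path, ref, params = sim_params(), ...) {
  f1 <- read_fastq(r1_path); f2 <- read_fastq(r2_path)
  if (nrow(f1) != nrow(f2)) stopf("unpaired FASTQ files")
  reads <- data.table::data.table(id = f1$id, r1 = f1$seq, r2 = f2$seq,
                                  q1 = f1$qual, q2 = f2$qual)
  process_sample(reads, ref, params, ...)
}

#' Simulate and analyse a full spike-in titration
#'
#' For every level of the mixture design and every replicate, simulates a
#' duplex library (its own seed per sample), runs the pipeline, and
#' applies the replicate filter per level.  `duplex_depth` sets the
#' expected number of duplex-sequenced molecules per locus; the number of
#' simulated template molecules is `duplex_depth / strand_capture` since
#' only molecules captured on both strands form duplexes.
#'
#' @param design list(reference, edits) as from [ngt_design()]
#' @param levels per-allele copy ratios (0-1 scale)
#' @param replicates replicates per level
#' @param duplex_depth target duplex molecules per locus
#' @param params a `sim_params`
#' @param seed master seed; per-sample seeds derive from it
#'   deterministically
#' @param progress print per-sample progress
#' @return list(tables: calls per level/replicate, decisions per level,
#'   truth, summary: per (mutation, level, replicate) frequency incl.
#'   zeros for undetected, artefacts: all non-truth calls)
#' @export
run_titration <- function(design, levels = c(0.001, 0.005, 0.009, 0.10),
                          replicates = 3L, duplex_depth = 8000L,
                          params = sim_params(), seed = 1L,
                          progress = FALSE) {
  ref <- design$reference; edits <- design$edits
  mixture <- design_mixture(edits, levels, replicates)
  haps <- apply_edits(ref, edits)
  truth <- truth_variants(ref, edits)
  n_mol <- as.integer(round(duplex_depth / params$strand_capture))

  tables <- list(); decisions <- list()
  summary_rows <- list(); artefact_rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    fr <- hap_frequencies(mixture, edits, lev)
    lev_tables <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      sseed <- (seed * 1000L + li * 100L + r) %% .Machine$integer.max
      sid <- sprintf("L%g_R%d", lev * 100, r)
      sim <- simulate_molecules(ref, haps, fr, params, n_mol, seed = sseed)
      em <- emit_fastq(sim, params, seed = sseed + 1L, sample_id = sid)
      res <- process_sample(em$reads, ref, params, sample_id = sid,
                            replicate = r)
      lev_tables[[r]] <- res$calls
      if (progress)
        message(sprintf("level %g replicate %d: %d calls", lev, r,
                        nrow(res$calls)))
    }
    tables[[as.character(lev)]] <- lev_tables
    dec <- replicate_filter(lev_tables)
    dec$expected_mutation <- match_expected(dec, truth)
    decisions[[as.character(lev)]] <- dec

    # per-mutation replicate frequencies (0 when undetected)
    for (r in seq_len(replicates)) {
      tab <- lev_tables[[r]]
      hit <- match_expected(tab, truth)
      for (m in truth$mutation) {
        i <- which(hit == m)
        summary_rows[[length(summary_rows) + 1L]] <- data.table::data.table(
          mutation = m, level = lev, replicate = r,
          count = if (length(i)) tab$count[i] else 0L,
          depth = if (length(i)) tab$depth[i] else NA_integer_,
          frequency = if (length(i)) tab$frequency[i] else 0)
      }
      art <- tab[is.na(hit), ]
      if (nrow(art)) {
        art$level <- lev
        artefact_rows[[length(artefact_rows) + 1L]] <- art
      }
    }
  }
  list(tables = tables, decisions = decisions, truth = truth,
       summary = data.table::rbindlist(summary_rows),
       artefacts = if (length(artefact_rows))
         data.table::rbindlist(artefact_rows) else
         data.table::data.table())
}

#' Replicate-filter outcome for the expected edits
#'
#' @param titration result of [run_titration()]
#' @return data.table per (level, mutation): detected replicate count,
#'   filter status and whether the edit was detected in every replicate
#' @export
titration_detection <- function(titration) {
  out <- list()
  for (lev in names(titration$decisions)) {
    dec <- titration$decisions[[lev]]
    n_rep <- length(titration$tables[[lev]])
    for (m in titration$truth$mutation) {
      i <- which(dec$expected_mutation == m)
      out[[length(out) + 1L]] <- data.table::data.table(
        level = as.numeric(lev), mutation = m,
        n_replicates_detected = if (length(i))
          dec$n_replicates_detected[i] else 0L,
        status = if (length(i)) dec$status[i] else "undetected",
        rule = if (length(i)) dec$rule[i] else "rejected",
        in_all_replicates = if (length(i))
          dec$n_replicates_detected[i] == n_rep else FALSE)
    }
  }
  data.table::rbindlist(out)
}
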