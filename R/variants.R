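#' Left-normalise an InDel against the reference
#'
#' Shifts a pure insertion or deletion left while the flanking context
#' allows, making "the same exact mutation" well-defined as identity of
#' the normalised (pos, ref, alt) tuple.  SNVs are returned unchanged.
#'
#' @param pos 0-based contig/window coordinate (deletion: first removed
#'   base; insertion: the coordinate the bases are inserted before)
#' @param ref_allele,alt_allele allele strings (one empty for pure InDels)
#' @param seq the reference sequence the coordinates refer to
#' @return list(pos, ref_allele, alt_allele)
#' @export
normalize_variant <- function(pos, ref_allele, alt_allele, seq) {
  if (nchar(ref_allele) > 0L && nchar(alt_allele) > 0L)
    return(list(pos = pos, ref_allele = ref_allele, alt_allele = alt_allele))
  allele <- if (nchar(ref_allele)) ref_allele else alt_allele
  L <- nchar(allele)
  while (pos > 0L) {
    prev <- substring(seq, pos, pos)          # base at pos-1 (0-based)
    if (prev != substring(allele, L, L)) break
    allele <- paste0(prev, substring(allele, 1L, L - 1L))
    pos <- pos - 1L
  }
  if (nchar(ref_allele)) list(pos = pos, ref_allele = allele, alt_allele = "")
  else list(pos = pos, ref_allele = "", alt_allele = allele)
}

#' Call variant observations from duplex consensus sequences
#'
#' Every non-N duplex consensus column differing from the reference
#' yields one observation; runs of adjacent deleted columns merge into a
#' single deletion, insertion slots yield insertions, and InDels are
#' left-normalised.  Observations whose footprint lies within
#' `edge_guard` columns of the covered span are discarded (alignment
#' end-effect guard).
#'
#' Observations are restricted to each locus's region of interest (ROI)
#' when one is given: the segment every amplicon covers (downstream of
#' the SPE primer, within the read-2 footprint).  Outside it, duplex
#' depth decays with the fragment-breakpoint position and per-position
#' frequencies lose meaning.
#'
#' @param dcs data.table from [consensus_sample()] (window-relative
#'   padded alignments)
#' @param ref a `duplex_reference`
#' @param edge_guard span-edge exclusion in columns
#' @param roi optional data.table (locus_id, start, end), 0-based
#'   half-open contig coordinates; see [default_roi()]
#' @return list(observations, depth): `observations` has one row per
#'   (molecule, variant) with contig coordinates; `depth` holds per-DCS
#'   spans and N columns for non-N depth computation
#' @export
call_dcs_variants <- function(dcs, ref, edge_guard = 2L, roi = NULL) {
  obs_all <- list(); depth_all <- list()
  for (lid in unique(dcs$locus_id)) {
    sub <- dcs[dcs$locus_id == lid, ]
    win <- window_seq(ref, lid, flank = 0L)
    # only rows that can contain a call or an N need parsing
    plain <- substring(win$seq, sub$ref_start + 1L,
                       sub$ref_start + nchar(sub$ref_row)) == sub$read_row
    interesting <- which(!plain)
    spans <- data.table::data.table(
      locus_id = lid, contig = win$contig,
      start = sub$ref_start + win$start,
      end = sub$ref_start + nchar(gsub("-", "", sub$ref_row)) + win$start)
    ex <- cpp_extract_observations(sub$ref_start[interesting],
                                   sub$ref_row[interesting],
                                   sub$read_row[interesting],
                                   win$seq, edge_guard)
    spans$end[interesting] <- ex$span_end + win$start
    spans$start[interesting] <- ex$span_start + win$start
    obs <- data.table::as.data.table(ex$obs)
    if (nrow(obs)) {
      obs$dcs_row <- interesting[obs$idx]
      obs$umi <- sub$umi[obs$dcs_row]
      norm <- vector("list", nrow(obs))
      for (k in seq_len(nrow(obs)))
        norm[[k]] <- normalize_variant(obs$pos[k], obs$ref[k], obs$alt[k],
                                       win$seq)
      obs$pos <- vapply(norm, `[[`, 0L, "pos") + win$start
      obs$ref <- vapply(norm, `[[`, "", "ref_allele")
      obs$alt <- vapply(norm, `[[`, "", "alt_allele")
      obs$contig <- win$contig
      obs$locus_id <- lid
      if (!is.null(roi)) {
        i <- which(roi$locus_id == lid)
        if (length(i) == 1L) {
          span <- pmax(nchar(obs$ref), 1L)   # footprint length on the ref
          obs <- obs[obs$pos >= roi$start[i] &
                     obs$pos + span <= roi$end[i], ]
        }
      }
      obs_all[[lid]] <- obs[, c("locus_id", "contig", "pos", "ref", "alt",
                                "kind", "umi", "dcs_row")]
    }
    ncols <- data.table::as.data.table(ex$n_cols)
    if (nrow(ncols)) ncols$pos <- ncols$pos + win$start
    depth_all[[lid]] <- list(spans = spans, n_cols = ncols)
  }
  observations <- if (length(obs_all)) data.table::rbindlist(obs_all) else
    data.table::data.table(locus_id = character(), contig = character(),
                           pos = integer(), ref = character(),
                           alt = character(), kind = character(),
                           umi = character(), dcs_row = integer())
  list(observations = observations, depth = depth_all)
}

#' Default region of interest per locus
#'
#' The segment downstream of the SPE primer that every amplicon covers:
#' from the primer anchor to `read_len - primer_len` bases past it
#' (the read-2 footprint), clipped at the window end.  Every duplex
#' molecule of the locus covers this region in full, so per-position
#' duplex depth is flat across it.
#'
#' @param ref a `duplex_reference`
#' @param params a `sim_params` (read length)
#' @return data.table (locus_id, start, end), 0-based half-open contig
#'   coordinates
#' @export
default_roi <- function(ref, params = sim_params()) {
  p <- ref$primers
  plen <- nchar(p$sequence)
  out <- data.table::data.table(locus_id = p$locus_id, start = p$anchor,
                                end = p$anchor + params$read_len - plen)
  wend <- ref$windows$end[match(out$locus_id, ref$windows$locus_id)]
  out$end <- pmin(out$end, wend)
  out
}

#' Non-N duplex depth at given positions
#'
#' The depth counts duplex consensus sequences covering the position with
#' a non-N state (a masked column cannot support either allele, so it is
#' excluded from the denominator).
#'
#' @param depth the depth component from [call_dcs_variants()]
#' @param locus_id locus of interest
#' @param pos 0-based contig positions
#' @return integer vector of depths
#' @export
duplex_depth <- function(depth, locus_id, pos) {
  d <- depth[[locus_id]]
  if (is.null(d)) return(rep(0L, length(pos)))
  vapply(pos, function(p) {
    cov <- sum(d$spans$start <= p & d$spans$end > p)
    nn <- if (nrow(d$n_cols)) sum(d$n_cols$pos == p) else 0L
    cov - nn
  }, 0L)
}

#' Aggregate observations into a per-sample variant table
#'
#' Counts duplex molecules supporting each exact normalised mutation and
#' divides by the non-N duplex depth at the variant position: the
#' mutation frequency is the ratio of mutant duplex consensus sequences
#' carrying the same exact mutation to the total number of duplex
#' consensus sequences covering the site.
#'
#' @param called result of [call_dcs_variants()]
#' @param sample_id,replicate labels attached to the rows
#' @return data.table (sample_id, replicate, locus_id, contig, pos, ref,
#'   alt, kind, count, depth, frequency)
#' @export
aggregate_counts <- function(called, sample_id = "S1", replicate = 1L) {
  obs <- called$observations
  if (nrow(obs) == 0L)
    return(data.table::data.table(
      sample_id = character(), replicate = integer(), locus_id = character(),
      contig = character(), pos = integer(), ref = character(),
      alt = character(), kind = character(), count = integer(),
      depth = integer(), frequency = numeric()))
  tab <- obs[, list(count = .N),
             by = c("locus_id", "contig", "pos", "ref", "alt", "kind")]
  tab$depth <- 0L
  for (lid in unique(tab$locus_id)) {
    i <- which(tab$locus_id == lid)
    at <- ifelse(tab$kind[i] == "insertion", tab$pos[i], tab$pos[i])
    tab$depth[i] <- duplex_depth(called$depth, lid, at)
  }
  tab$frequency <- tab$count / pmax(tab$depth, 1L)
  tab$sample_id <- sample_id
  tab$replicate <- as.integer(replicate)
  data.table::setcolorder(tab, c("sample_id", "replicate", "locus_id",
                                 "contig", "pos", "ref", "alt", "kind",
                                 "count", "depth", "frequency"))
  data.table::setorder(tab, locus_id, pos)
  tab[]
}

#' Replicate-aware variant filter
#'
#' A variant is accepted when it is supported by at least `min_count`
#' duplex molecules in at least `min_reps` replicates for any configured
#' rule.  The defaults encode: at least two duplex consensus reads in
#' all three replicates, or at least five duplex counts in two
#' replicates; the boundary case of four counts in two replicates is
#' rejected.
#'
#' @param tables list of per-replicate variant tables from
#'   [aggregate_counts()]
#' @param rules list of c(min_count, min_reps) rules, tried in order
#' @return data.table with one row per distinct variant: per-replicate
#'   counts, `n_replicates_detected`, `rule` fired ("three_rep_min2",
#'   "two_rep_min5" with the default rules, or "rejected") and `status`
#' @export
replicate_filter <- function(tables,
                             rules = list(c(min_count = 2, min_reps = 3),
                                          c(min_count = 5, min_reps = 2))) {
  n_rep <- length(tables)
  if (n_rep < 2L) stopf("need at least 2 replicate tables")
  if (!(n_rep %in% c(2L, 3L)) &&
      identical(rules, list(c(min_count = 2, min_reps = 3),
                            c(min_count = 5, min_reps = 2))))
    stopf("default rules assume 2-3 replicates; configure rules explicitly")
  for (i in seq_along(tables)) tables[[i]]$replicate <- i
  all <- data.table::rbindlist(tables, use.names = TRUE)
  if (nrow(all) == 0L) stopf("no variants in any replicate")
  key_cols <- c("locus_id", "contig", "pos", "ref", "alt", "kind")
  wide <- data.table::dcast(all, as.formula(
    paste(paste(key_cols, collapse = " + "), "~ replicate")),
    value.var = "count", fill = 0L)
  for (i in seq_len(n_rep))   # replicates with zero variants drop out of dcast
    if (!as.character(i) %in% names(wide)) wide[[as.character(i)]] <- 0L
  cnt <- as.matrix(wide[, as.character(seq_len(n_rep)), with = FALSE])
  cnt[is.na(cnt)] <- 0L
  wide$counts <- apply(cnt, 1L, paste, collapse = ",")
  wide$n_replicates_detected <- rowSums(cnt > 0L)
  rule_name <- function(r)
    sprintf("%s_rep_min%d",
            c("one", "two", "three", "four", "five")[r["min_reps"]],
            r["min_count"])
  wide$rule <- "rejected"
  for (r in rev(rules)) {   # earlier rules take precedence in the label
    hit <- rowSums(cnt >= r["min_count"]) >= r["min_reps"]
    wide$rule[hit] <- rule_name(r)
  }
  wide$status <- ifelse(wide$rule == "rejected", "rejected", "accepted")
  max_count <- apply(cnt, 1L, max)
  wide$max_count <- max_count
  data.table::setorder(wide, locus_id, pos)
  wide[]
}

#' Duplex-count x replicate-count contingency table
#'
#' Bins every variant by its maximal per-replicate duplex count and the
#' number of replicates it was seen in; when a truth annotation is
#' provided the counts are split into expected/unexpected.
#'
#' @param decisions table from [replicate_filter()]
#' @param expected optional logical vector marking true (spiked) variants
#' @param count_bins upper edges of duplex-count bins
#' @return data.table (count_bin, n_replicates, label, n)
#' @export
count_replicate_heatmap <- function(decisions, expected = NULL,
                                    count_bins = c(1, 2, 3, 4, 5, 10, 100,
                                                   Inf)) {
  lab <- if (is.null(expected)) rep("all", nrow(decisions)) else
    ifelse(expected, "expected", "unexpected")
  bin <- cut(decisions$max_count, breaks = c(0, count_bins),
             labels = FALSE)
  dt <- data.table::data.table(count_bin = count_bins[bin],
                               n_replicates = decisions$n_replicates_detected,
                               label = lab)
  dt[, list(n = .N), by = c("count_bin", "n_replicates", "label")]
}

#' PAM proximity annotation
#'
#' Flags a variant when a Cas9 protospacer-adjacent motif (NGG on the
#' forward strand or CCN on the reverse) lies within `window` nucleotides
#' of the variant position; proximity of a PAM supports an
#' editing-derived origin for an unexpected mutation.
#'
#' @param pos 0-based variant position(s) on the contig
#' @param seq contig (or window) sequence the positions refer to
#' @param window maximal distance in nt between the motif and the variant
#' @return logical vector
#' @export
pam_proximity <- function(pos, seq, window = 3L) {
  n <- nchar(seq)
  vapply(pos, function(p) {
    for (q in max(0L, p - window - 2L):min(n - 3L, p + window + 2L)) {
      # motif interval [q, q+3); distance between intervals
      d <- max(0L, max(q - p, p - (q + 2L)))
      if (d > window) next
      tri <- substring(seq, q + 1L, q + 3L)
      if (substring(tri, 2L, 3L) == "GG" || substring(tri, 1L, 2L) == "CC")
        return(TRUE)
    }
    FALSE
  }, logical(1))
}
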