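#' Group tagged reads into UMI families
#'
#' Reads are grouped exactly by (locus, UMI, strand tag); then UMI
#' sequencing errors are absorbed by a directional merge: a family whose
#' UMI lies within Hamming distance 1 of a family at least `merge_ratio`
#' times larger at the same (locus, strand tag) is absorbed into it.
#' Without the merge, family counts inflate by roughly UMI length times
#' the per-base error rate.
#'
#' @param tagged data.table from [tag_reads()] (only passing reads are
#'   grouped)
#' @param merge_umis logical; apply the directional merge
#' @param merge_ratio minimal size ratio for absorption
#' @return the table with columns `family_umi` and `family_id` added
#'   (NA for non-passing reads)
#' @export
group_families <- function(tagged, merge_umis = TRUE, merge_ratio = 3) {
  tagged <- data.table::as.data.table(tagged)
  tagged$family_umi <- NA_character_
  live <- tagged$pass & !is.na(tagged$locus_id)
  if (!any(live)) { tagged$family_id <- NA_character_; return(tagged) }
  sub <- tagged[live, c("locus_id", "strand_tag", "umi")]
  sub$row <- which(live)
  grp <- sub[, list(count = .N), by = c("locus_id", "strand_tag", "umi")]
  grp$root <- grp$umi
  if (merge_umis) {
    parts <- split(seq_len(nrow(grp)),
                   paste(grp$locus_id, grp$strand_tag))
    for (rows in parts) {
      if (length(rows) < 2L) next
      map <- umi_merge_map(grp$umi[rows], grp$count[rows], merge_ratio)
      grp$root[rows] <- map
    }
  }
  key <- paste(sub$locus_id, sub$strand_tag, sub$umi)
  gkey <- paste(grp$locus_id, grp$strand_tag, grp$umi)
  tagged$family_umi[sub$row] <- grp$root[match(key, gkey)]
  tagged$family_id <- ifelse(is.na(tagged$family_umi), NA_character_,
                             paste(tagged$locus_id, tagged$family_umi,
                                   tagged$strand_tag, sep = ":"))
  tagged
}

#' Directional UMI merge map
#'
#' @param umis unique UMI strings
#' @param counts read counts per UMI
#' @param ratio absorption requires the parent to be >= ratio x larger
#' @return character vector: for each input UMI, the UMI of the family it
#'   is absorbed into (itself when not absorbed)
#' @export
umi_merge_map <- function(umis, counts, ratio = 3) {
  n <- length(umis)
  if (n < 2L) return(umis)
  L <- nchar(umis[1])
  # Hamming<=1 candidate pairs share one position-deleted key
  keys <- vector("list", L)
  for (i in seq_len(L))
    keys[[i]] <- data.table::data.table(
      delkey = paste0(i, ":", substring(umis, 1L, i - 1L),
                      substring(umis, i + 1L, L)),
      idx = seq_len(n))
  keys <- data.table::rbindlist(keys)
  pairs <- merge(keys, keys, by = "delkey", allow.cartesian = TRUE)
  pairs <- pairs[pairs$idx.x != pairs$idx.y,
                 c("idx.x", "idx.y")]
  pairs <- unique(pairs)
  parent <- seq_len(n)
  if (nrow(pairs)) {
    # children ascending by count, parents must be >= ratio x larger
    ord <- order(counts)
    cand <- split(pairs$idx.y, pairs$idx.x)
    for (child in ord) {
      nb <- cand[[as.character(child)]]
      if (is.null(nb)) next
      ok <- nb[counts[nb] >= ratio * counts[child]]
      if (!length(ok)) next
      parent[child] <- ok[which.max(counts[ok])]
    }
    # follow chains to the root
    for (i in seq_len(n)) {
      p <- i
      while (parent[p] != p) p <- parent[p]
      parent[i] <- p
    }
  }
  umis[parent]
}

# ---- column-map consensus (spec surface, used on modest family sizes) ----

member_columns <- function(alignment) {
  cols <- project(alignment)
  cols$span_lo <- min(cols$ref_pos)
  cols$span_hi <- max(cols$ref_pos)
  cols
}

#' Build a single-strand consensus from aligned family members
#'
#' Per-column plurality with a fixed fraction rule: the plurality state is
#' kept when its fraction of the covering members is at least
#' `plurality` (boundary included), otherwise the column becomes N.
#' Deletion columns ('-') and an insertion slot's "absent" state compete
#' exactly like bases; single-read families adopt the read's bases.
#'
#' @param alignments list of `duplex_alignment` for the family members
#' @param min_reads minimal member count (families below are rejected)
#' @param plurality plurality fraction threshold (default 0.6)
#' @return object of class `duplex_ssc`: list(columns, n_reads) with
#'   columns (ref_pos, ins_offset, base, depth)
#' @export
build_ssc <- function(alignments, min_reads = 1L, plurality = 0.6) {
  if (length(alignments) < min_reads)
    stopf("family has fewer than %d reads", min_reads)
  maps <- lapply(seq_along(alignments), function(i) {
    m <- member_columns(alignments[[i]]); m$member <- i; m
  })
  all <- data.table::rbindlist(maps)
  spans <- all[, list(lo = span_lo[1], hi = span_hi[1]), by = "member"]
  covers <- function(p) sum(spans$lo <= p & spans$hi >= p)

  out <- list()
  # reference columns
  refcols <- all[all$ins_offset == 0L, ]
  agg <- refcols[, list(n = .N), by = c("ref_pos", "base")]
  for (p in unique(agg$ref_pos)) {
    a <- agg[agg$ref_pos == p, ]
    depth <- sum(a$n)
    top <- a[which.max(a$n), ]
    base <- if (top$n / depth >= plurality) top$base else "N"
    out[[length(out) + 1L]] <- data.table::data.table(
      ref_pos = p, ins_offset = 0L, base = base, depth = depth)
  }
  # insertion slots: members covering the junction without the slot vote
  # for the "absent" state
  inscols <- all[all$ins_offset > 0L, ]
  if (nrow(inscols)) {
    slots <- unique(inscols[, c("ref_pos", "ins_offset")])
    for (k in seq_len(nrow(slots))) {
      p <- slots$ref_pos[k]; o <- slots$ins_offset[k]
      a <- inscols[inscols$ref_pos == p & inscols$ins_offset == o, ]
      depth <- sum(spans$lo <= p & spans$hi >= p + 1L)
      cnt <- table(a$base)
      absent <- depth - nrow(a)
      states <- c(as.list(cnt), list(`__absent__` = absent))
      best <- names(states)[which.max(unlist(states))]
      frac <- max(unlist(states)) / depth
      if (best == "__absent__" && frac >= plurality) next  # no column
      base <- if (frac >= plurality && best != "__absent__") best else "N"
      out[[length(out) + 1L]] <- data.table::data.table(
        ref_pos = p, ins_offset = o, base = base, depth = depth)
    }
  }
  cols <- data.table::rbindlist(out)
  data.table::setorder(cols, ref_pos, ins_offset)
  structure(list(columns = cols, n_reads = length(alignments)),
            class = "duplex_ssc")
}

#' Merge two opposite-strand consensus sequences into a duplex consensus
#'
#' Agreeing columns keep their base; any column where the strands differ
#' (including one being N, or an insertion slot present on one strand
#' only) is masked.  The covered span is the intersection of the two
#' single-strand spans.  Symmetric in its arguments.
#'
#' @param ssc_a,ssc_b `duplex_ssc` objects for the two strands of one
#'   molecule (same locus and UMI, opposite strand tags)
#' @param min_reads_per_strand duplexes with fewer reads on either strand
#'   are rejected
#' @return object of class `duplex_dcs`: list(columns, top_reads,
#'   bottom_reads); masked reference columns carry base N, masked
#'   insertion slots are absent
#' @export
build_dcs <- function(ssc_a, ssc_b, min_reads_per_strand = 1L) {
  if (ssc_a$n_reads < min_reads_per_strand ||
      ssc_b$n_reads < min_reads_per_strand)
    stopf("strand below min_reads_per_strand")
  ca <- ssc_a$columns; cb <- ssc_b$columns
  lo <- max(min(ca$ref_pos), min(cb$ref_pos))
  hi <- min(max(ca$ref_pos), max(cb$ref_pos))
  ca <- ca[ca$ref_pos >= lo & ca$ref_pos <= hi, ]
  cb <- cb[cb$ref_pos >= lo & cb$ref_pos <= hi, ]
  m <- merge(ca, cb, by = c("ref_pos", "ins_offset"), all = TRUE,
             suffixes = c("_a", "_b"))
  ref <- m[m$ins_offset == 0L, ]
  ref$base <- ifelse(!is.na(ref$base_a) & !is.na(ref$base_b) &
                     ref$base_a == ref$base_b & ref$base_a != "N",
                     ref$base_a, "N")
  ins <- m[m$ins_offset > 0L, ]
  if (nrow(ins)) {
    keep <- !is.na(ins$base_a) & !is.na(ins$base_b) &
            ins$base_a == ins$base_b & ins$base_a != "N"
    ins <- ins[keep, ]
    ins$base <- ins$base_a
  }
  cols <- rbind(ref[, c("ref_pos", "ins_offset", "base")],
                if (nrow(ins)) ins[, c("ref_pos", "ins_offset", "base")])
  data.table::setorder(cols, ref_pos, ins_offset)
  structure(list(columns = cols, top_reads = ssc_a$n_reads,
                 bottom_reads = ssc_b$n_reads),
            class = "duplex_dcs")
}

# ---- batched pipeline consensus ------------------------------------------

restore_ref_row <- function(start, ref_row, window) {
  # replace placeholder chars with reference bases, keeping '-' columns
  has_gap <- grepl("-", ref_row, fixed = TRUE)
  out <- character(length(ref_row))
  plain <- !has_gap
  out[plain] <- substring(window, start[plain] + 1L,
                          start[plain] + nchar(ref_row[plain]))
  for (k in which(has_gap)) {
    chars <- strsplit(ref_row[k], "")[[1]]
    p <- start[k]
    for (j in seq_along(chars)) {
      if (chars[j] != "-") {
        chars[j] <- substring(window, p + 1L, p + 1L)
        p <- p + 1L
      }
    }
    out[k] <- paste0(chars, collapse = "")
  }
  out
}

merge_padded_rows <- function(s1, r1ref, r1read, s2, r2ref, r2read, mode) {
  n <- length(s1)
  out <- data.table::data.table(ref_start = integer(n), ref_row = character(n),
                                read_row = character(n))
  for (k in seq_len(n)) {
    m <- cpp_merge_padded(s1[k], r1ref[k], r1read[k],
                          s2[k], r2ref[k], r2read[k], mode)
    out$ref_start[k] <- m$ref_start
    out$ref_row[k] <- m$ref_row
    out$read_row[k] <- m$read_row
  }
  out
}

#' Build per-sample duplex consensus sequences
#'
#' Batched composition of the consensus stage: per (locus, UMI, strand)
#' family, a per-mate plurality consensus is taken in read coordinates
#' (family members are PCR copies of one amplicon, so read columns line
#' up exactly), the two mate consensus strings are aligned to the target
#' window and merged into the single-strand consensus; opposite-strand
#' consensus pairs sharing (locus, UMI) are then merged into duplex
#' consensus sequences, masking discordant columns with N.
#'
#' @param tagged grouped read table from [group_families()]
#' @param ref a `duplex_reference`
#' @param params a `sim_params`
#' @param plurality SSC plurality fraction
#' @param min_reads_per_strand minimal reads per strand for a duplex
#' @param floor_frac alignment score floor (fraction of consensus length)
#' @return list(dcs, ssc_count, stats): `dcs` is a data.table (locus_id,
#'   umi, ref_start, ref_row, read_row, top_reads, bottom_reads) with
#'   rows in window-relative coordinates; `stats` is the stage report
#'   (families, SSCs, DCSs, mean reads per UMI, duplex depth per locus)
#' @export
consensus_sample <- function(tagged, ref, params = sim_params(),
                             plurality = 0.6, min_reads_per_strand = 1L,
                             floor_frac = 0.4) {
  live <- tagged[tagged$pass & !is.na(tagged$family_id), ]
  out <- list(); sscn <- 0L; fam_total <- 0L; unaligned <- 0L
  reads_per_umi <- numeric(0)
  for (lid in unique(live$locus_id)) {
    sub <- live[live$locus_id == lid, ]
    pr <- ref$primers[ref$primers$locus_id == lid, ]
    w <- ref$windows[ref$windows$locus_id == lid, ]
    win <- window_seq(ref, lid, flank = 0L)
    anchor_rel <- pr$anchor - win$start
    pstart_rel <- pr$start - win$start

    data.table::setorder(sub, family_id)
    gid <- match(sub$family_id, unique(sub$family_id))
    c2 <- cpp_consensus_by_group(sub$insert_r2, gid, plurality)
    c1 <- cpp_consensus_by_group(sub$insert_r1, gid, plurality)
    fam <- data.table::data.table(
      family_id = unique(sub$family_id)[c2$group],
      n_reads = c2$n_reads,
      cons_r2 = c2$consensus,
      cons_r1_fwd = revcomp(c1$consensus))
    fam_total <- fam_total + nrow(fam)
    # reads per UMI at molecule level: both strand families of one molecule
    # share the UMI from the duplex adapter
    umi_of <- data.table::tstrsplit(fam$family_id, ":", fixed = TRUE)[[2]]
    reads_per_umi <- c(reads_per_umi,
                       tapply(fam$n_reads, umi_of, sum))

    # align both mate consensus strings to the window
    a2 <- align_batch(fam$cons_r2, win$seq, expected_start = anchor_rel,
                      floor_frac = floor_frac)
    a1 <- align_batch(fam$cons_r1_fwd, win$seq, expected_start = NA_integer_,
                      region_lo = pstart_rel,
                      region_hi = pstart_rel + params$insert_max + 40L,
                      floor_frac = floor_frac)
    ok <- a1$aligned & a2$aligned
    unaligned <- unaligned + sum(!ok)
    fam <- fam[ok, ]; a1 <- a1[ok, ]; a2 <- a2[ok, ]
    if (nrow(fam) == 0L) next
    a1$ref_row <- restore_ref_row(a1$ref_start, a1$ref_row, win$seq)
    a2$ref_row <- restore_ref_row(a2$ref_start, a2$ref_row, win$seq)

    ssc <- mate_merge_fast(a2, a1, win$seq)
    ssc$family_id <- fam$family_id
    ssc$n_reads <- fam$n_reads
    sscn <- sscn + nrow(ssc)

    # duplex pairing on (umi): family_id is locus:umi:tag
    parts <- data.table::tstrsplit(ssc$family_id, ":", fixed = TRUE)
    ssc$umi <- parts[[2]]; ssc$tag <- parts[[3]]
    top <- ssc[ssc$tag == params$tag_top, ]
    bot <- ssc[ssc$tag == params$tag_bottom, ]
    m <- merge(top, bot, by = "umi", suffixes = c("_t", "_b"))
    if (nrow(m) == 0L) next
    m <- m[m$n_reads_t >= min_reads_per_strand &
           m$n_reads_b >= min_reads_per_strand, ]
    if (nrow(m) == 0L) next

    # duplex merge: fast path when both strands agree exactly
    same <- m$ref_start_t == m$ref_start_b & m$ref_row_t == m$ref_row_b &
            m$read_row_t == m$read_row_b
    dcs_fast <- data.table::data.table(
      ref_start = m$ref_start_t[same], ref_row = m$ref_row_t[same],
      read_row = m$read_row_t[same])
    dcs_slow <- merge_padded_rows(
      m$ref_start_t[!same], m$ref_row_t[!same], m$read_row_t[!same],
      m$ref_start_b[!same], m$ref_row_b[!same], m$read_row_b[!same],
      mode = 1L)
    if (nrow(dcs_slow))
      dcs_slow$ref_row <- restore_ref_row(dcs_slow$ref_start,
                                          dcs_slow$ref_row, win$seq)
    dcs <- rbind(
      cbind(dcs_fast, umi = m$umi[same], top_reads = m$n_reads_t[same],
            bottom_reads = m$n_reads_b[same]),
      cbind(dcs_slow, umi = m$umi[!same], top_reads = m$n_reads_t[!same],
            bottom_reads = m$n_reads_b[!same]))
    dcs$locus_id <- lid
    dcs$window_start <- win$start
    out[[lid]] <- dcs
  }
  dcs <- if (length(out)) data.table::rbindlist(out, use.names = TRUE) else
    data.table::data.table(ref_start = integer(), ref_row = character(),
                           read_row = character(), umi = character(),
                           top_reads = integer(), bottom_reads = integer(),
                           locus_id = character(), window_start = integer())
  depth_by_locus <- if (nrow(dcs)) table(dcs$locus_id) else table(character(0))
  stats <- list(families = fam_total, sscs = sscn, dcss = nrow(dcs),
                unaligned_consensus = unaligned,
                mean_reads_per_umi = if (length(reads_per_umi))
                  mean(reads_per_umi) else NA_real_,
                duplex_per_locus = as.list(depth_by_locus))
  list(dcs = dcs, stats = stats)
}

# vectorised mate merge for gapless agreeing alignments, C++ fallback
mate_merge_fast <- function(a2, a1, window) {
  n <- nrow(a2)
  gapless <- !grepl("-", a2$ref_row, fixed = TRUE) &
             !grepl("-", a2$read_row, fixed = TRUE) &
             !grepl("-", a1$ref_row, fixed = TRUE) &
             !grepl("-", a1$read_row, fixed = TRUE)
  lo1 <- a2$ref_start; hi1 <- lo1 + nchar(a2$read_row)
  lo2 <- a1$ref_start; hi2 <- lo2 + nchar(a1$read_row)
  olo <- pmax(lo1, lo2); ohi <- pmin(hi1, hi2)
  overlap_ok <- gapless & ohi > olo &
    substring(a2$read_row, olo - lo1 + 1L, ohi - lo1) ==
    substring(a1$read_row, olo - lo2 + 1L, ohi - lo2)

  out <- data.table::data.table(ref_start = pmin(lo1, lo2),
                                ref_row = character(n),
                                read_row = character(n))
  f <- overlap_ok
  if (any(f)) {
    left <- ifelse(lo1[f] <= lo2[f],
                   substring(a2$read_row[f], 1L, olo[f] - lo1[f]),
                   substring(a1$read_row[f], 1L, olo[f] - lo2[f]))
    mid <- substring(a2$read_row[f], olo[f] - lo1[f] + 1L, ohi[f] - lo1[f])
    right <- ifelse(hi1[f] >= hi2[f],
                    substring(a2$read_row[f], ohi[f] - lo1[f] + 1L),
                    substring(a1$read_row[f], ohi[f] - lo2[f] + 1L))
    out$read_row[f] <- paste0(left, mid, right)
    out$ref_row[f] <- substring(window, out$ref_start[f] + 1L,
                                out$ref_start[f] + nchar(out$read_row[f]))
  }
  if (any(!f)) {
    slow <- merge_padded_rows(a2$ref_start[!f], a2$ref_row[!f],
                              a2$read_row[!f], a1$ref_start[!f],
                              a1$ref_row[!f], a1$read_row[!f], mode = 0L)
    slow$ref_row <- restore_ref_row(slow$ref_start, slow$ref_row, window)
    out$ref_start[!f] <- slow$ref_start
    out$ref_row[!f] <- slow$ref_row
    out$read_row[!f] <- slow$read_row
  }
  out
}
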