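#' Default alignment scoring scheme
#' @return list(match, mismatch, gap_open, gap_extend)
#' @export
align_scoring <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                          gap_extend = -1L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Glocal alignment of an insert against a target window
#'
#' Gapped alignment that is global in the read (every insert base is
#' consumed) and local in the reference (free end positioning within the
#' window).  Affine gap costs: the first gapped base costs `gap_open`,
#' each further base `gap_extend`.  Ties are broken deterministically,
#' preferring the leftmost reference start and deletions before
#' insertions.  Alignments scoring below `floor_frac * nchar(insert)` are
#' reported unaligned.
#'
#' @param insert read sequence (>= 20 nt for meaningful placement)
#' @param window reference window sequence
#' @param scoring list from [align_scoring()]
#' @param floor_frac score floor as a fraction of the insert length
#' @param min_len minimal insert length accepted
#' @return object of class `duplex_alignment`: list(score, ref_start
#'   (0-based, window-relative), ref_row, read_row, cigar, aligned);
#'   `aligned = FALSE` when the score floor is not met
#' @export
glocal_align <- function(insert, window, scoring = align_scoring(),
                         floor_frac = 0.4, min_len = 20L) {
  if (nchar(insert) < min_len)
    stopf("insert shorter than %d nt", min_len)
  a <- cpp_glocal_align(insert, window, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  a$aligned <- a$score >= floor_frac * nchar(insert)
  a$cigar <- padded_to_cigar(a$ref_row, a$read_row)
  class(a) <- "duplex_alignment"
  a
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex_alignment: score %d, ref_start %d, cigar %s%s\n",
              x$score, x$ref_start, x$cigar,
              if (x$aligned) "" else " (below floor: unaligned)"))
  invisible(x)
}

padded_to_cigar <- function(ref_row, read_row) {
  rr <- strsplit(ref_row, "")[[1]]
  qr <- strsplit(read_row, "")[[1]]
  op <- ifelse(rr == "-", "I", ifelse(qr == "-", "D", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Project an alignment onto reference columns
#'
#' Yields the per-column read state: reference columns map to the read
#' base (or `-` for a deleted base), insertion columns are keyed by
#' (preceding reference position, offset).  The projection is reversible:
#' [reconstruct()] returns the original insert.
#'
#' @param alignment a `duplex_alignment`
#' @return data.table (ref_pos, ins_offset, base); `ins_offset` 0 for
#'   reference columns, 1.. for insertion slots after `ref_pos`
#' @export
project <- function(alignment) {
  rr <- strsplit(alignment$ref_row, "")[[1]]
  qr <- strsplit(alignment$read_row, "")[[1]]
  ref_pos <- integer(length(rr)); ins_off <- integer(length(rr))
  p <- alignment$ref_start - 1L; off <- 0L
  for (k in seq_along(rr)) {
    if (rr[k] == "-") { off <- off + 1L } else { p <- p + 1L; off <- 0L }
    ref_pos[k] <- p; ins_off[k] <- off
  }
  keep <- ref_pos >= alignment$ref_start  # drop leading insertions
  data.table::data.table(ref_pos = ref_pos[keep], ins_offset = ins_off[keep],
                         base = qr[keep])
}

#' Rebuild the read sequence from a projected column map
#' @param columns data.table from [project()]
#' @return the insert sequence
#' @export
reconstruct <- function(columns) {
  paste0(columns$base[columns$base != "-"], collapse = "")
}

#' Batch-align consensus strings to a window with an exact-match fast path
#'
#' Pipeline helper: unique (sequence, expected start) pairs are aligned
#' once.  A sequence identical to the reference substring at its expected
#' start becomes an all-match alignment without dynamic programming;
#' everything else goes through [glocal_align()] against a trimmed
#' sub-window (`slop` nt around the expected footprint), which preserves
#' optimal placement for amplicon-anchored inserts.
#'
#' @param seqs character vector of consensus sequences (may contain N)
#' @param window window sequence
#' @param expected_start expected 0-based window-relative start of each
#'   sequence (from the primer anchor geometry), or NA when the start is
#'   free (e.g. the adapter-side mate, whose start depends on the
#'   fragment breakpoint)
#' @param region_lo,region_hi 0-based half-open window-relative bounds
#'   the footprint must fall in (trims the dynamic program)
#' @param scoring,floor_frac as in [glocal_align()]
#' @param slop extra reference bases allowed on each side of an expected
#'   footprint
#' @return data.table (ref_start, ref_row, read_row, score, aligned), one
#'   row per input sequence
#' @export
align_batch <- function(seqs, window, expected_start = NA_integer_,
                        region_lo = 0L, region_hi = nchar(window),
                        scoring = align_scoring(), floor_frac = 0.4,
                        slop = 30L) {
  dt <- data.table::data.table(seq = seqs,
                               exp = as.integer(rep(expected_start,
                                                    length.out = length(seqs))))
  key <- paste(dt$seq, dt$exp)
  uk <- !duplicated(key)
  u <- dt[uk, ]
  n <- nrow(u)
  res <- data.table::data.table(ref_start = integer(n), ref_row = character(n),
                                read_row = character(n), score = integer(n),
                                aligned = logical(n))
  wlen <- nchar(window)
  region_lo <- max(0L, as.integer(region_lo))
  region_hi <- min(wlen, as.integer(region_hi))
  region <- substring(window, region_lo + 1L, region_hi)
  for (k in seq_len(n)) {
    s <- u$seq[k]; e <- u$exp[k]; L <- nchar(s)
    if (!is.na(e)) {                    # anchored: exact check at e
      if (e >= 0L && e + L <= wlen &&
          substring(window, e + 1L, e + L) == s) {
        res$ref_start[k] <- e; res$ref_row[k] <- s; res$read_row[k] <- s
        res$score[k] <- L; res$aligned[k] <- TRUE
        next
      }
      lo <- max(0L, e - slop); hi <- min(wlen, e + L + slop)
    } else {                            # free start: exact substring search
      at <- regexpr(s, region, fixed = TRUE)[1]
      if (at > 0L) {
        res$ref_start[k] <- region_lo + at - 1L
        res$ref_row[k] <- s; res$read_row[k] <- s
        res$score[k] <- L; res$aligned[k] <- TRUE
        next
      }
      lo <- region_lo; hi <- region_hi
    }
    sub <- substring(window, lo + 1L, hi)
    a <- glocal_align(s, sub, scoring, floor_frac)
    res$ref_start[k] <- a$ref_start + lo
    res$ref_row[k] <- a$ref_row; res$read_row[k] <- a$read_row
    res$score[k] <- a$score; res$aligned[k] <- a$aligned
  }
  res[match(key, key[uk]), ]
}
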