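#' Extract UMI and strand tag from read 1
#'
#' The first 12 nt of read 1 are the UMI, the next 2 nt the strand tag.
#' UMIs containing anything but A/C/G/T are rejected (a repaired UMI
#' would silently merge molecules) and the tag must match TT or GG
#' exactly: with only two tag bases, any mismatch tolerance would risk
#' merging the two strands, which is the single most damaging error for
#' duplex logic.
#'
#' @param r1,r2 character vectors of read sequences (read 1 / read 2)
#' @param q1,q2 matching quality strings (optional, may be NULL)
#' @param id read identifiers (optional)
#' @param params a `sim_params` (only umi_len and the tag labels are used)
#' @return data.table with one row per pair: id, umi, strand_tag, locus_id
#'   (NA until assigned), insert_r1, insert_r2, q1, q2, pass, reason
#' @export
extract_tags <- function(r1, r2, q1 = NULL, q2 = NULL, id = NULL,
                         params = sim_params()) {
  n <- length(r1)
  if (length(r2) != n) stopf("read 1 / read 2 length mismatch")
  if (is.null(id)) id <- as.character(seq_len(n))
  ul <- params$umi_len
  short <- nchar(r1) <= ul + 2L
  umi <- substring(r1, 1L, ul)
  tag <- substring(r1, ul + 1L, ul + 2L)
  out <- data.table::data.table(
    id = id, umi = umi, strand_tag = tag, locus_id = NA_character_,
    insert_r1 = substring(r1, ul + 3L), insert_r2 = r2,
    q1 = if (is.null(q1)) NA_character_ else substring(q1, ul + 3L),
    q2 = if (is.null(q2)) NA_character_ else q2,
    pass = TRUE, reason = NA_character_)
  bad_umi <- !grepl("^[ACGT]+$", umi)
  bad_tag <- !(tag %in% c(params$tag_top, params$tag_bottom))
  out$pass[short] <- FALSE; out$reason[short] <- "short_read1"
  out$pass[bad_umi & !short] <- FALSE
  out$reason[bad_umi & !short] <- "ambiguous_umi"
  sel <- bad_tag & !bad_umi & !short
  out$pass[sel] <- FALSE; out$reason[sel] <- "invalid_tag"
  out
}

#' Assign each read pair to a locus by its SPE primer
#'
#' A locus is assigned when read 2 begins with that locus's primer
#' sequence, anchored at position 0, allowing at most `max_mismatch`
#' mismatches (sequencing-error tolerance).  The primer bases are trimmed
#' from `insert_r2`.  Pairs matching no primer are rejected `off_target`;
#' pairs matching two primers equally well are rejected `ambiguous_primer`.
#'
#' @param tagged data.table from [extract_tags()]
#' @param primers data.table with columns locus_id, sequence (as in a
#'   `duplex_reference`)
#' @param max_mismatch mismatch tolerance in the primer region
#' @return the tagged table with locus_id filled in, primers trimmed, and
#'   rejects flagged
#' @export
assign_locus <- function(tagged, primers, max_mismatch = 1L) {
  if (nrow(primers) == 0L) stopf("primer set is empty")
  live <- which(tagged$pass)
  if (!length(live)) return(tagged)
  mm <- sapply(primers$sequence, function(p)
    cpp_prefix_mismatches(tagged$insert_r2[live], p))
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = length(live))
  mm[is.na(mm)] <- .Machine$integer.max
  best <- max.col(-mm, ties.method = "first")
  bestmm <- mm[cbind(seq_along(live), best)]
  nbest <- rowSums(mm == bestmm)
  ok <- bestmm <= max_mismatch & nbest == 1L
  amb <- bestmm <= max_mismatch & nbest > 1L
  tagged$locus_id[live[ok]] <- primers$locus_id[best[ok]]
  plen <- nchar(primers$sequence)[best[ok]]
  tagged$insert_r2[live[ok]] <- substring(tagged$insert_r2[live[ok]],
                                          plen + 1L)
  if (!all(is.na(tagged$q2)))
    tagged$q2[live[ok]] <- substring(tagged$q2[live[ok]], plen + 1L)
  tagged$pass[live[!ok]] <- FALSE
  tagged$reason[live[amb]] <- "ambiguous_primer"
  tagged$reason[live[!ok & !amb]] <- "off_target"
  tagged
}

#' Quality-control filter on tagged reads
#'
#' Flags pairs whose mean base quality falls below `min_mean_quality` on
#' either mate or whose genomic insert is shorter than `min_insert_len`.
#' Filtering order through the stage pipeline is extract -> locus -> QC.
#'
#' @param tagged data.table from [assign_locus()]
#' @param min_mean_quality minimum mean Phred quality per mate
#' @param min_insert_len minimum genomic insert length (nt)
#' @return the table with QC failures flagged (reasons `low_quality`,
#'   `short_insert`)
#' @export
qc_filter <- function(tagged, min_mean_quality = 20, min_insert_len = 30L) {
  live <- which(tagged$pass)
  if (!length(live)) return(tagged)
  shrt <- nchar(tagged$insert_r1[live]) < min_insert_len |
          nchar(tagged$insert_r2[live]) < min_insert_len
  lowq <- rep(FALSE, length(live))
  if (!all(is.na(tagged$q1))) {
    mq1 <- cpp_mean_phred(tagged$q1[live])
    mq2 <- cpp_mean_phred(tagged$q2[live])
    lowq <- mq1 < min_mean_quality | mq2 < min_mean_quality
  }
  tagged$pass[live[shrt | lowq]] <- FALSE
  tagged$reason[live[shrt]] <- "short_insert"
  tagged$reason[live[lowq & !shrt]] <- "low_quality"
  tagged
}

#' Tag, locus-assign and QC a set of read pairs
#'
#' Convenience driver running [extract_tags()], [assign_locus()] and
#' [qc_filter()] and accounting for every input pair exactly once.
#'
#' @param r1,r2,q1,q2,id read data as in [extract_tags()]
#' @param primers primer table (locus_id, sequence)
#' @param params a `sim_params`
#' @param min_mean_quality,min_insert_len QC thresholds
#' @param max_mismatch primer mismatch tolerance
#' @return list(tagged, report): `report` counts total, passed and every
#'   rejection reason
#' @export
tag_reads <- function(r1, r2, q1 = NULL, q2 = NULL, id = NULL, primers,
                      params = sim_params(), min_mean_quality = 20,
                      min_insert_len = 30L, max_mismatch = 1L) {
  tagged <- extract_tags(r1, r2, q1, q2, id, params)
  tagged <- assign_locus(tagged, primers, max_mismatch)
  tagged <- qc_filter(tagged, min_mean_quality, min_insert_len)
  reasons <- table(tagged$reason[!tagged$pass])
  report <- c(list(total = nrow(tagged), passed = sum(tagged$pass)),
              as.list(reasons))
  stopifnot(report$total == report$passed + sum(unlist(reasons)))
  list(tagged = tagged, report = report)
}

#' Tag a FASTQ pair from disk
#'
#' File-based wrapper around [tag_reads()].
#' @param r1_path,r2_path FASTQ(.gz) paths
#' @inheritParams tag_reads
#' @param out_prefix if non-NULL, write `<prefix>.tagged.tsv` and
#'   `<prefix>.tag_report.json`
#' @return as [tag_reads()]
#' @export
tag_fastq <- function(r1_path, r2_path, primers, params = sim_params(),
                      out_prefix = NULL, ...) {
  f1 <- read_fastq(r1_path); f2 <- read_fastq(r2_path)
  if (nrow(f1) != nrow(f2)) stopf("unpaired FASTQ files")
  res <- tag_reads(f1$seq, f2$seq, f1$qual, f2$qual, f1$id, primers,
                   params, ...)
  if (!is.null(out_prefix)) {
    data.table::fwrite(res$tagged, paste0(out_prefix, ".tagged.tsv"),
                       sep = "\t")
    writeLines(jsonlite::toJSON(res$report, auto_unbox = TRUE,
                                pretty = TRUE),
               paste0(out_prefix, ".tag_report.json"))
  }
  res
}
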