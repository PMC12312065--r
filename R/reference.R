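#' Build a synthetic reference with SPE-anchored target windows
#'
#' Generates a random contig carrying `n_loci` non-overlapping target
#' windows.  Each window embeds one 24-nt locus-specific single-primer-
#' extension (SPE) site on the forward strand; the primer's 3' end (the
#' "anchor") marks where locus-specific amplicons start reading into the
#' target.  Windows are separated by flanking sequence long enough to host
#' sheared fragments that extend beyond the window.
#'
#' All coordinates are 0-based, half-open.  Deterministic for a fixed
#' seed: the same call returns a byte-identical reference.
#'
#' @param seed integer RNG seed (mandatory)
#' @param n_loci number of target windows (>= 1)
#' @param window_len window length in nt (>= 200; large enough to host the
#'   24-nt primer plus the shortest amplicon insert)
#' @param primer_offset primer start relative to the window start
#' @param contig_name name of the generated contig
#' @return an object of class `duplex_reference`: list with `contigs`
#'   (named character vector), `windows` (data.table: locus_id, contig,
#'   start, end), `primers` (data.table: locus_id, name, sequence, strand,
#'   start, anchor)
#' @export
build_reference <- function(seed, n_loci, window_len = 800L,
                            primer_offset = 20L, contig_name = "sim_chr1") {
  if (missing(seed)) stopf("seed is mandatory")
  if (n_loci < 1L) stopf("n_loci must be >= 1")
  primer_len <- 24L
  min_insert <- 150L
  if (window_len < 200L || window_len < primer_offset + primer_len + min_insert - 24L)
    stopf("window_len %d too small to host primer and amplicon", window_len)
  set.seed(seed)
  pad <- 800L  # room for fragment ends upstream of the primer
  starts <- pad + (seq_len(n_loci) - 1L) * (pad + window_len)
  contig_len <- n_loci * (pad + window_len) + 200L

  repeat {
    contig <- random_dna(1L, contig_len)
    p_start <- starts + primer_offset
    primer_seq <- substring(contig, p_start + 1L, p_start + primer_len)
    # each primer sequence must occur exactly once in the reference
    hits <- vapply(primer_seq, function(p)
      sum(Biostrings::countPattern(p, Biostrings::DNAString(contig))), 0L)
    if (all(hits == 1L) && !anyDuplicated(primer_seq)) break
  }

  windows <- data.table::data.table(
    locus_id = sprintf("L%02d", seq_len(n_loci)),
    contig = contig_name, start = starts, end = starts + window_len)
  primers <- data.table::data.table(
    locus_id = windows$locus_id,
    name = sprintf("SPE_%02df", seq_len(n_loci)),
    sequence = primer_seq, strand = "+",
    start = p_start, anchor = p_start + primer_len)
  structure(list(contigs = stats::setNames(contig, contig_name),
                 windows = windows, primers = primers),
            class = "duplex_reference")
}

#' @export
print.duplex_reference <- function(x, ...) {
  cat(sprintf("duplex_reference: %d contig(s), %d target window(s)\n",
              length(x$contigs), nrow(x$windows)))
  print(x$windows)
  invisible(x)
}

#' Plant fixed motifs into a reference
#'
#' Overwrites reference bases so that downstream edits have a defined
#' local context (e.g. the exact bases a deletion removes).
#'
#' @param ref a `duplex_reference`
#' @param plant data.frame with columns `locus_id`, `offset`
#'   (0-based, window-relative) and `motif`
#' @return the modified `duplex_reference`
#' @export
plant_motifs <- function(ref, plant) {
  for (k in seq_len(nrow(plant))) {
    w <- ref$windows[ref$windows$locus_id == plant$locus_id[k], ]
    if (nrow(w) != 1L) stopf("unknown locus '%s'", plant$locus_id[k])
    at <- w$start + plant$offset[k]  # 0-based contig coord
    motif <- plant$motif[k]
    if (at + nchar(motif) > w$end) stopf("motif extends past window")
    contig <- ref$contigs[[w$contig]]
    substr(contig, at + 1L, at + nchar(motif)) <- motif
    ref$contigs[[w$contig]] <- contig
  }
  validate_reference(ref)
  ref
}

#' Validate reference invariants
#'
#' Checks that windows lie within their contig, each window hosts exactly
#' one SPE primer anchor, and every primer sequence occurs exactly once
#' across all contigs.
#' @param ref a `duplex_reference`
#' @return invisibly `TRUE`; stops on violation
#' @export
validate_reference <- function(ref) {
  w <- ref$windows; p <- ref$primers
  for (k in seq_len(nrow(w))) {
    clen <- nchar(ref$contigs[[w$contig[k]]])
    if (w$start[k] < 0L || w$end[k] > clen || w$start[k] >= w$end[k])
      stopf("window %s outside contig", w$locus_id[k])
    anch <- p[p$locus_id == w$locus_id[k], ]
    if (nrow(anch) != 1L || anch$anchor < w$start[k] || anch$anchor > w$end[k])
      stopf("window %s must contain exactly one SPE anchor", w$locus_id[k])
  }
  subj <- Biostrings::DNAStringSet(ref$contigs)
  for (k in seq_len(nrow(p))) {
    hits <- sum(Biostrings::vcountPattern(p$sequence[k], subj))
    if (hits != 1L) stopf("primer %s occurs %d times", p$name[k], hits)
  }
  invisible(TRUE)
}

#' Extract a window sequence (with optional flank)
#' @param ref a `duplex_reference`
#' @param locus_id locus identifier
#' @param flank extra bases on each side (clipped at contig ends)
#' @return list(seq, start) where `start` is the 0-based contig coordinate
#'   of the first returned base
#' @export
window_seq <- function(ref, locus_id, flank = 0L) {
  i <- which(ref$windows$locus_id == locus_id)
  w <- ref$windows[i, ]
  if (nrow(w) != 1L) stopf("unknown locus '%s'", locus_id)
  contig <- ref$contigs[[w$contig]]
  s <- max(0L, w$start - flank); e <- min(nchar(contig), w$end + flank)
  list(seq = substring(contig, s + 1L, e), start = s, contig = w$contig)
}

#' Write a reference to FASTA + BED + primer TSV
#' @param ref a `duplex_reference`
#' @param prefix path prefix; writes `<prefix>.fa`, `<prefix>.windows.bed`,
#'   `<prefix>.primers.tsv`
#' @return invisibly the written file paths
#' @export
write_reference <- function(ref, prefix) {
  fa <- paste0(prefix, ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), fa)
  bed <- paste0(prefix, ".windows.bed")
  data.table::fwrite(ref$windows[, c("contig", "start", "end", "locus_id")],
                     bed, sep = "\t", col.names = FALSE)
  ptsv <- paste0(prefix, ".primers.tsv")
  data.table::fwrite(ref$primers, ptsv, sep = "\t")
  invisible(c(fa, bed, ptsv))
}

#' Read a reference from FASTA + BED + primer TSV
#' @param prefix path prefix as used by [write_reference()]
#' @return a `duplex_reference`
#' @export
read_reference <- function(prefix) {
  seqs <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  contigs <- stats::setNames(as.character(seqs),
                             sub("\\s.*$", "", names(seqs)))
  bed <- data.table::fread(paste0(prefix, ".windows.bed"), header = FALSE,
                           col.names = c("contig", "start", "end", "locus_id"))
  primers <- data.table::fread(paste0(prefix, ".primers.tsv"))
  ref <- structure(list(contigs = contigs,
                        windows = bed[, c("locus_id", "contig", "start", "end")],
                        primers = primers),
                   class = "duplex_reference")
  validate_reference(ref)
  ref
}
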