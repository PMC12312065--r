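#' Write variant calls to a VCF 4.2 file
#'
#' InDels are written with the conventional 1-based anchor base: a
#' deletion of D at 0-based position p becomes POS = p, REF = anchor + D,
#' ALT = anchor; an insertion before 0-based position c becomes POS = c,
#' REF = anchor, ALT = anchor + inserted bases.  Duplex support travels
#' in INFO: DC (mutant duplex count), DP (non-N duplex depth), AF
#' (duplex frequency) and, when present, FILTSTAT (replicate-filter
#' status).
#'
#' @param calls variant table from [aggregate_counts()] (optionally with
#'   a `status` column merged in)
#' @param ref a `duplex_reference`
#' @param path output path
#' @return invisibly `path`
#' @export
write_vcf <- function(calls, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(ref$contigs),
                   nchar(ref$contigs)),
           "##INFO=<ID=DC,Number=1,Type=Integer,Description=\"Mutant duplex consensus count\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Non-N duplex consensus depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Duplex mutation frequency\">",
           "##INFO=<ID=FILTSTAT,Number=1,Type=String,Description=\"Replicate filter status\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(calls))
  for (k in seq_len(nrow(calls))) {
    contig <- calls$contig[k]; p <- calls$pos[k]
    refa <- calls$ref[k]; alta <- calls$alt[k]
    cs <- ref$contigs[[contig]]
    if (calls$kind[k] == "SNV") {
      pos1 <- p + 1L; vref <- refa; valt <- alta
    } else if (calls$kind[k] == "deletion") {
      anchor <- substring(cs, p, p)            # base at 0-based p-1
      pos1 <- p; vref <- paste0(anchor, refa); valt <- anchor
    } else {
      anchor <- substring(cs, p, p)
      pos1 <- p; vref <- anchor; valt <- paste0(anchor, alta)
    }
    info <- sprintf("DC=%d;DP=%d;AF=%.6g", calls$count[k], calls$depth[k],
                    calls$frequency[k])
    if (!is.null(calls$status))
      info <- paste0(info, ";FILTSTAT=", calls$status[k])
    rows[k] <- paste(contig, pos1, ".", vref, valt, ".", "PASS", info,
                     sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a duplexr VCF back into a variant table
#'
#' Inverse of [write_vcf()]: anchored InDel records are converted back to
#' 0-based, left-normalised (pos, ref, alt) with one allele empty.
#'
#' @param path VCF path
#' @return data.table (contig, pos, ref, alt, kind, count, depth,
#'   frequency)
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.table::data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  kind = character(), count = integer(),
                                  depth = integer(), frequency = numeric()))
  f <- data.table::fread(text = body, header = FALSE,
                         col.names = c("contig", "pos1", "id", "vref",
                                       "valt", "qual", "filter", "info"))
  get_info <- function(tag, mode = "integer") {
    v <- sub(sprintf(".*%s=([^;]+).*", tag), "\\1", f$info)
    if (mode == "integer") as.integer(v) else as.numeric(v)
  }
  out <- data.table::data.table(contig = f$contig, pos = f$pos1 - 1L,
                                ref = f$vref, alt = f$valt,
                                kind = "SNV",
                                count = get_info("DC"),
                                depth = get_info("DP"),
                                frequency = get_info("AF", "numeric"))
  del <- nchar(f$vref) > nchar(f$valt)
  ins <- nchar(f$valt) > nchar(f$vref)
  out$kind[del] <- "deletion"; out$kind[ins] <- "insertion"
  out$pos[del | ins] <- out$pos[del | ins] + 1L   # drop the anchor base
  out$ref[del] <- substring(f$vref[del], 2L); out$alt[del] <- ""
  out$ref[ins] <- ""; out$alt[ins] <- substring(f$valt[ins], 2L)
  out
}
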