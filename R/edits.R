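#' Construct an edit specification table
#'
#' One row per edited allele.  Coordinates are 0-based half-open on the
#' reference contig; a deletion spans the removed bases
#' (`end - start == nchar(ref_allele)`, empty `alt_allele`), an insertion
#' sits at a single coordinate (`start == end`, empty `ref_allele`), and an
#' SNV spans one base.  A heterozygous line may carry two rows (two edited
#' alleles) at the same site.
#'
#' @param line_id line identifier (one line may carry several alleles)
#' @param allele_id allele identifier within the line
#' @param locus_id target window the edit falls in
#' @param kind one of "SNV", "insertion", "deletion"
#' @param start,end 0-based half-open contig coordinates
#' @param ref_allele,alt_allele allele strings (empty as appropriate)
#' @param zygosity "homozygous" or "heterozygous"
#' @return data.table with one row per allele, class `duplex_edits`
#' @export
edit_spec <- function(line_id, allele_id, locus_id, kind, start, end,
                      ref_allele, alt_allele, zygosity) {
  e <- data.table::data.table(line_id = line_id, allele_id = allele_id,
                              locus_id = locus_id, kind = kind,
                              start = as.integer(start), end = as.integer(end),
                              ref_allele = ref_allele, alt_allele = alt_allele,
                              zygosity = zygosity)
  validate_edits(e)
  data.table::setattr(e, "class", c("duplex_edits", class(e)))
  e[]
}

validate_edits <- function(e) {
  if (!all(e$kind %in% c("SNV", "insertion", "deletion")))
    stopf("unknown edit kind")
  if (!all(e$zygosity %in% c("homozygous", "heterozygous")))
    stopf("unknown zygosity")
  del <- e$kind == "deletion"
  if (any(e$end[del] - e$start[del] != nchar(e$ref_allele[del])) ||
      any(nchar(e$alt_allele[del]) != 0L))
    stopf("deletion must span its removed bases and have empty alt")
  ins <- e$kind == "insertion"
  if (any(e$start[ins] != e$end[ins]) || any(nchar(e$ref_allele[ins]) != 0L) ||
      any(nchar(e$alt_allele[ins]) == 0L))
    stopf("insertion must have start == end, empty ref, non-empty alt")
  snv <- e$kind == "SNV"
  if (any(e$end[snv] - e$start[snv] != 1L) ||
      any(nchar(e$ref_allele[snv]) != 1L) || any(nchar(e$alt_allele[snv]) != 1L))
    stopf("SNV must span one base")
  invisible(TRUE)
}

#' Reference and edit set emulating the tomato NGT study design
#'
#' Builds a four-window synthetic reference and the matching four edited
#' lines: a homozygous 1-bp deletion (-C), a homozygous 5-bp deletion
#' (-CAGTT), a homozygous 1-bp insertion (+A), and a heterozygous line
#' carrying a 1-bp deletion (-A) on one allele and a 1-bp insertion (+C)
#' on the other, each line assigned its own target window.  The deleted
#' motifs are planted into the reference at a fixed offset downstream of
#' the SPE anchor so the edits are well-defined; flanking bases are forced
#' to differ from the run ends so left-normalisation leaves the
#' coordinates in place.
#'
#' @param seed RNG seed for the random reference backbone
#' @param window_len window length passed to [build_reference()]
#' @param edit_offset 0-based window-relative coordinate of the edit sites
#' @return list(reference = `duplex_reference`, edits = `duplex_edits`)
#' @export
ngt_design <- function(seed = 1L, window_len = 800L, edit_offset = 94L) {
  ref <- build_reference(seed, n_loci = 4L, window_len = window_len)
  plant <- data.frame(
    locus_id = c("L01", "L02", "L03", "L04"),
    offset = edit_offset - 1L,
    motif = c("TCG", "GCAGTTA", "TGC", "TAG"),
    stringsAsFactors = FALSE)
  ref <- plant_motifs(ref, plant)
  ws <- ref$windows$start[match(c("L01", "L02", "L03", "L04"),
                                ref$windows$locus_id)]
  at <- ws + edit_offset
  edits <- rbind(
    edit_spec("CrtD1", "a1", "L01", "deletion", at[1], at[1] + 1L, "C", "",
              "homozygous"),
    edit_spec("CrtD5", "a1", "L02", "deletion", at[2], at[2] + 5L, "CAGTT", "",
              "homozygous"),
    edit_spec("PsyIns1", "a1", "L03", "insertion", at[3], at[3], "", "A",
              "homozygous"),
    edit_spec("PsyHet", "del", "L04", "deletion", at[4], at[4] + 1L, "A", "",
              "heterozygous"),
    edit_spec("PsyHet", "ins", "L04", "insertion", at[4] + 1L, at[4] + 1L, "",
              "C", "heterozygous"))
  data.table::setattr(edits, "class", c("duplex_edits", "data.table",
                                        "data.frame"))
  list(reference = ref, edits = edits)
}

#' Apply edits to the reference, producing haplotype sequences
#'
#' Returns one haplotype per (line, allele): the contig sequences with
#' that allele's edits applied.  Coordinates downstream of an InDel shift
#' by its net length; `hap_coord()` on the returned object maps reference
#' coordinates into haplotype coordinates.
#'
#' @param ref a `duplex_reference`
#' @param edits a `duplex_edits` table (may be empty)
#' @return named list of haplotypes; each is
#'   list(name, line_id, allele_id, contigs, edits)
#' @export
apply_edits <- function(ref, edits) {
  if (nrow(edits) == 0L)
    return(list())
  validate_edits(edits)
  keys <- unique(edits[, c("line_id", "allele_id")])
  haps <- vector("list", nrow(keys))
  names(haps) <- paste(keys$line_id, keys$allele_id, sep = ".")
  for (k in seq_len(nrow(keys))) {
    sel <- edits[edits$line_id == keys$line_id[k] &
                 edits$allele_id == keys$allele_id[k], ]
    contigs <- ref$contigs
    # apply right-to-left so earlier coordinates stay valid
    sel <- sel[order(-sel$start), ]
    for (j in seq_len(nrow(sel))) {
      w <- ref$windows[ref$windows$locus_id == sel$locus_id[j], ]
      contig <- contigs[[w$contig]]
      s <- sel$start[j]; e <- sel$end[j]
      have <- substring(contig, s + 1L, e)
      if (!identical(have, sel$ref_allele[j]))
        stopf("ref_allele mismatch at %s:%d (expected '%s', found '%s')",
              w$contig, s, sel$ref_allele[j], have)
      contigs[[w$contig]] <- paste0(substring(contig, 1L, s),
                                    sel$alt_allele[j],
                                    substring(contig, e + 1L))
    }
    haps[[k]] <- list(name = names(haps)[k], line_id = keys$line_id[k],
                      allele_id = keys$allele_id[k], contigs = contigs,
                      edits = sel)
  }
  haps
}

#' Map a reference coordinate into haplotype coordinates
#'
#' Valid for positions not inside an edited interval: shifts the position
#' by the net indel length of all edits strictly upstream.
#' @param hap a haplotype from [apply_edits()]
#' @param pos 0-based reference coordinate(s)
#' @return 0-based haplotype coordinate(s)
#' @export
hap_coord <- function(hap, pos) {
  shift <- vapply(pos, function(p) {
    up <- hap$edits[hap$edits$end <= p, ]
    sum(nchar(up$alt_allele) - nchar(up$ref_allele))
  }, 0L)
  pos + shift
}

#' Write / read an edit table as TSV
#' @param edits a `duplex_edits` table
#' @param path file path
#' @export
write_edits <- function(edits, path) {
  data.table::fwrite(edits, path, sep = "\t")
  invisible(path)
}

#' @rdname write_edits
#' @export
read_edits <- function(path) {
  e <- data.table::fread(path, colClasses = list(
    character = c("ref_allele", "alt_allele")))
  e$ref_allele[is.na(e$ref_allele)] <- ""
  e$alt_allele[is.na(e$alt_allele)] <- ""
  validate_edits(e)
  data.table::setattr(e, "class", c("duplex_edits", "data.table", "data.frame"))
  e[]
}
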