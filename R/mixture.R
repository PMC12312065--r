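#' Design a spike-in mixture across levels
#'
#' Converts nominal spike levels (target per-allele copy-number ratios)
#' into DNA mass fractions per line.  For homozygous diploid material the
#' mass fraction equals the copy-number ratio; a heterozygous line carries
#' each edited allele on only half of its genome copies, so its DNA is
#' mixed at double the mass to reach the same per-allele copy ratio.
#' The wild-type background fills the remaining mass.
#'
#' @param edits a `duplex_edits` table (defines lines and zygosity)
#' @param levels numeric vector of per-allele copy ratios in (0, 1),
#'   e.g. `c(0.1, 0.5, 0.9, 10) / 100`
#' @param replicates number of library replicates per level
#' @param background id used for the wild-type background line
#' @return `duplex_mixture`: list with `lines` (per level x line:
#'   mass_fraction, per_allele_copy_ratio), `levels`, `replicates`,
#'   `background`
#' @export
design_mixture <- function(edits, levels, replicates = 3L,
                           background = "WT") {
  if (any(levels <= 0 | levels >= 1))
    stopf("levels must lie strictly inside (0, 1)")
  lines <- unique(edits[, c("line_id", "zygosity")])
  if (anyDuplicated(lines$line_id))
    stopf("a line cannot be both homozygous and heterozygous")
  grid <- data.table::CJ(level = levels, line_id = lines$line_id)
  grid <- merge(grid, lines, by = "line_id")
  grid$per_allele_copy_ratio <- grid$level
  grid$mass_fraction <- ifelse(grid$zygosity == "heterozygous",
                               2 * grid$level, grid$level)
  tot <- tapply(grid$mass_fraction, grid$level, sum)
  if (any(tot > 1))
    stopf("mass fractions sum to %.3f > 1 at level %s", max(tot),
          names(tot)[which.max(tot)])
  data.table::setorder(grid, level, line_id)
  structure(list(lines = grid, levels = sort(levels),
                 replicates = as.integer(replicates), background = background),
            class = "duplex_mixture")
}

#' @export
print.duplex_mixture <- function(x, ...) {
  cat(sprintf("duplex_mixture: %d level(s) x %d replicate(s), background '%s'\n",
              length(x$levels), x$replicates, x$background))
  print(x$lines)
  invisible(x)
}

#' Per-locus haplotype frequencies for one mixture level
#'
#' Each edited haplotype contributes molecules at its per-allele copy
#' ratio at its own locus; the remainder at each locus (including the
#' wild-type portion of the other lines' DNA) is background.
#'
#' @param mixture a `duplex_mixture`
#' @param edits the `duplex_edits` table used to build it
#' @param level one of the design levels
#' @return data.table (locus_id, hap, freq) where hap "background" closes
#'   each locus to frequency 1
#' @keywords internal
hap_frequencies <- function(mixture, edits, level) {
  keep <- which(abs(mixture$lines$level - level) < 1e-12)
  sel <- mixture$lines[keep, ]
  if (nrow(sel) == 0L) stopf("level %s not in design", format(level))
  al <- unique(edits[, c("line_id", "allele_id", "locus_id")])
  al <- merge(al, sel[, c("line_id", "per_allele_copy_ratio")], by = "line_id")
  al$hap <- paste(al$line_id, al$allele_id, sep = ".")
  out <- al[, c("locus_id", "hap", "per_allele_copy_ratio")]
  data.table::setnames(out, "per_allele_copy_ratio", "freq")
  bg <- out[, list(freq = 1 - sum(freq)), by = "locus_id"]
  bg$hap <- "background"
  rbind(out, bg[, c("locus_id", "hap", "freq")])
}
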