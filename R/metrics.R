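#' Precision (CV) and trueness (bias) per mutation and level
#'
#' For each (mutation, nominal level) group the replicate frequencies are
#' summarised as mean, sample SD (n-1 denominator), CV% = 100*SD/mean and
#' bias% = 100*(mean - level)/level, and flagged against the ENGL-style
#' acceptance criteria used in GMO analysis: precision passes when
#' CV <= 25% (relaxed to < 50% for levels below 0.2%), trueness passes
#' when |bias| <= 25%.
#'
#' @param calls data.table with columns `mutation`, `level` (nominal
#'   per-allele copy ratio, 0-1 scale), `replicate`, `frequency`
#' @param cv_limit,cv_limit_low,low_level,bias_limit criterion constants
#' @return data.table per (mutation, level): n, mean, sd, cv_pct,
#'   bias_pct, precision_pass, trueness_pass
#' @export
precision_trueness <- function(calls, cv_limit = 25, cv_limit_low = 50,
                               low_level = 0.002, bias_limit = 25) {
  need <- c("mutation", "level", "frequency")
  if (!all(need %in% names(calls))) stopf("calls must have %s",
                                          paste(need, collapse = ", "))
  rep <- calls[, list(n = .N, mean = mean(frequency),
                      sd = stats::sd(frequency)),
               by = c("mutation", "level")]
  if (any(rep$n < 2L)) stopf("need >= 2 replicates per (mutation, level)")
  rep$cv_pct <- 100 * rep$sd / rep$mean
  rep$bias_pct <- 100 * (rep$mean - rep$level) / rep$level
  rep$precision_pass <- ifelse(rep$level < low_level,
                               rep$cv_pct < cv_limit_low,
                               rep$cv_pct <= cv_limit)
  rep$trueness_pass <- abs(rep$bias_pct) <= bias_limit
  data.table::setorder(rep, mutation, level)
  rep[]
}

#' Quasi-binomial regression of mutation frequency on sample level
#'
#' Fits counts (mutant duplexes out of total duplexes) against the
#' nominal level with a binomial-family iteratively reweighted fit and a
#' moment (Pearson chi-square / residual df) dispersion estimate, on the
#' original untransformed 0-1 variables.  Linearity over the working
#' range shows as monotone fitted means.
#'
#' @param count mutant duplex counts
#' @param total total duplex depths
#' @param level nominal per-allele copy ratios (>= 2 distinct values)
#' @param link "logit" (default) or "identity" (sensitivity check)
#' @return object of class `duplex_fit`: list(model family, coefficients,
#'   dispersion, deviance, fitted, glm)
#' @export
fit_quasibinomial <- function(count, total, level, link = "logit") {
  if (length(unique(level)) < 2L) stopf("need >= 2 distinct levels")
  mustart <- pmin(pmax(count / total, 1e-8), 1 - 1e-8)
  fit <- stats::glm(cbind(count, total - count) ~ level,
                    family = stats::quasibinomial(link = link),
                    mustart = mustart)
  structure(list(family = "quasi_binomial",
                 coefficients = stats::coef(fit),
                 dispersion = summary(fit)$dispersion,
                 deviance = fit$deviance,
                 fitted = stats::fitted(fit), glm = fit),
            class = "duplex_fit")
}

#' Poisson regression with a fixed total-count offset
#'
#' Models mutant duplex counts with log-link Poisson regression, entering
#' the log of the total count as an offset with coefficient fixed at 1,
#' and reports per-factor likelihood-ratio chi-square tests (invariant to
#' parameterisation, unlike Wald tests).
#'
#' @param count non-negative integer response
#' @param factors data.frame of explanatory variables (factors or
#'   numeric)
#' @param offset_total positive totals entering as `offset(log(total))`
#' @return `duplex_fit` with `tests` (per-factor LRT chi-square and p),
#'   and `degenerate = TRUE` when some factor level has all-zero counts
#'   (no silent convergence claim is made in that case)
#' @export
fit_poisson_offset <- function(count, factors, offset_total) {
  if (any(count < 0) || any(count != round(count)))
    stopf("counts must be non-negative integers")
  if (any(offset_total <= 0)) stopf("offsets must be positive")
  df <- data.frame(count = count, factors, .off = log(offset_total))
  rhs <- paste(names(factors), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("count ~", rhs, "+ offset(.off)")),
                    family = stats::poisson(), data = df)
  degenerate <- FALSE
  for (nm in names(factors)) {
    v <- factors[[nm]]
    if (is.factor(v) || is.character(v)) {
      z <- tapply(count, v, sum)
      if (any(z == 0)) degenerate <- TRUE
    }
  }
  lrt <- stats::drop1(fit, test = "LRT")
  tests <- data.table::data.table(
    term = rownames(lrt)[-1L],
    chisq = lrt$LRT[-1L], df = lrt$Df[-1L],
    p_value = lrt$`Pr(>Chi)`[-1L])
  structure(list(family = "poisson_offset",
                 coefficients = stats::coef(fit),
                 dispersion = sum(stats::residuals(fit, "pearson")^2) /
                   fit$df.residual,
                 deviance = fit$deviance, tests = tests,
                 degenerate = degenerate, glm = fit),
            class = "duplex_fit")
}

#' @export
print.duplex_fit <- function(x, ...) {
  cat(sprintf("duplex_fit (%s): dispersion %.3f, deviance %.3f\n",
              x$family, x$dispersion, x$deviance))
  if (!is.null(x$tests)) print(x$tests)
  if (isTRUE(x$degenerate))
    cat("warning: degenerate design (all-zero counts for a factor level)\n")
  invisible(x)
}

#' Distance-from-UMI trend of artefact observations
#'
#' Bins unexpected-mutation observations by their distance from the UMI
#' on read 1 (the read adjacent to the UMI adapter; only read 1 is
#' considered), represents each bin by its midpoint (bin 1-20 by 10),
#' and fits a Poisson regression of bin count on midpoint.  A negative
#' distance coefficient reproduces the enrichment of end-repair
#' artefacts toward fragment ends.
#'
#' @param distance integer distances from the UMI (nt) of the artefact
#'   observations on read 1
#' @param bin_width bin width in nt (default 20: bins 1-20, 21-40, ...)
#' @param max_distance last bin edge (empty bins up to here enter the
#'   fit as zero counts)
#' @return list(bins = data.table(midpoint, count), coefficient,
#'   p_value, fit)
#' @export
distance_to_umi_trend <- function(distance, bin_width = 20L,
                                  max_distance = NULL) {
  if (!length(distance)) stopf("no observations")
  if (is.null(max_distance)) max_distance <- max(distance)
  n_bins <- max(1L, as.integer(ceiling(max_distance / bin_width)))
  bin <- pmax(1L, as.integer(ceiling(distance / bin_width)))  # 1..20 -> bin 1
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (seq_len(n_bins) - 1L) * bin_width + bin_width / 2  # 1-20 -> 10
  bins <- data.table::data.table(midpoint = mids, count = counts)
  if (n_bins < 2L)
    return(list(bins = bins, coefficient = NA_real_, p_value = NA_real_,
                fit = NULL))
  fit <- stats::glm(count ~ midpoint, family = stats::poisson(),
                    data = bins)
  sm <- summary(fit)$coefficients
  list(bins = bins, coefficient = unname(stats::coef(fit)["midpoint"]),
       p_value = unname(sm["midpoint", "Pr(>|z|)"]), fit = fit)
}

#' Down-sample a read-pair set without replacement
#'
#' Uniform sampling of intact pairs, deterministic per (seed, subsample
#' index); mirrors the down-sampling protocol used for minimal-coverage
#' titrations (several target sizes, several independent sampling
#' replicates per size).
#'
#' @param n_total total number of pairs available
#' @param n_pairs pairs to keep (<= n_total)
#' @param seed base RNG seed
#' @param subsample index of the independent sampling replicate
#' @return integer vector of kept pair indices (sorted)
#' @export
downsample_indices <- function(n_total, n_pairs, seed, subsample = 1L) {
  if (n_pairs > n_total) stopf("cannot sample %d of %d pairs", n_pairs,
                               n_total)
  set.seed(seed + 7919L * (subsample - 1L))
  sort(sample.int(n_total, n_pairs))
}

#' Down-sample a FASTQ pair to n read pairs
#'
#' @param r1_path,r2_path input FASTQ(.gz) paths
#' @param n_pairs pairs to keep
#' @param seed RNG seed
#' @param n_subsamples number of independent sampling replicates
#' @param out_prefix output prefix; writes
#'   `<prefix>.sub<k>_R1.fastq.gz` / `_R2.fastq.gz`
#' @return character matrix of written paths (subsample x mate)
#' @export
downsample_fastq <- function(r1_path, r2_path, n_pairs, seed,
                             n_subsamples = 3L, out_prefix) {
  f1 <- read_fastq(r1_path); f2 <- read_fastq(r2_path)
  if (nrow(f1) != nrow(f2)) stopf("unpaired FASTQ files")
  out <- matrix("", n_subsamples, 2L,
                dimnames = list(NULL, c("r1", "r2")))
  for (k in seq_len(n_subsamples)) {
    idx <- downsample_indices(nrow(f1), n_pairs, seed, k)
    p1 <- sprintf("%s.sub%d_R1.fastq.gz", out_prefix, k)
    p2 <- sprintf("%s.sub%d_R2.fastq.gz", out_prefix, k)
    write_fastq(f1$id[idx], f1$seq[idx], f1$qual[idx], p1)
    write_fastq(f2$id[idx], f2$seq[idx], f2$qual[idx], p2)
    out[k, ] <- c(p1, p2)
  }
  out
}
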