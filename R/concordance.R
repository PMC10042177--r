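#' Build a paired-patient table from a long TMB table
#'
#' Reshapes per-sample TMB results into one row per patient with `tmb_site1`
#' and `tmb_site2` columns for a chosen exome definition. Patients missing
#' either site are excluded and recorded in the attribute `"excluded"`.
#'
#' @param tab a TMB table with columns `sample_id` (patient identifier),
#'   `site` (`"site1"`/`"site2"`) and `tmb`; typically the output of
#'   [standardise_tmb_table()].
#' @param definition definition label to pair on (ignored when the table has
#'   no `definition` column).
#' @return Data.frame with `patient_id`, `tmb_site1`, `tmb_site2`.
#' @export
paired_patients <- function(tab, definition = NULL) {
  if (!is.null(definition) && "definition" %in% names(tab))
    tab <- tab[tab$definition == definition, , drop = FALSE]
  s1 <- tab[tab$site == "site1", c("sample_id", "tmb")]
  s2 <- tab[tab$site == "site2", c("sample_id", "tmb")]
  names(s1) <- c("patient_id", "tmb_site1")
  names(s2) <- c("patient_id", "tmb_site2")
  out <- merge(s1, s2, by = "patient_id")
  excluded <- setdiff(union(s1$patient_id, s2$patient_id), out$patient_id)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

concordance_stats <- function(v1, v2) {
  rho <- NA_real_; rho_p <- NA_real_
  sp <- tryCatch(spearman_test(v1, v2), error = function(e) NULL)
  if (!is.null(sp)) { rho <- sp$estimate; rho_p <- sp$p.value }
  wt <- wilcoxon_paired(v1, v2)
  list(spearman_rho = rho, spearman_p = rho_p,
       wilcoxon_stat = wt$statistic, wilcoxon_p = wt$p.value,
       wilcoxon_degenerate = wt$degenerate)
}

site_summaries <- function(v1, v2) {
  summ <- function(v) c(median = stats::median(v),
                        iqr = stats::IQR(v), sd = stats::sd(v))
  list(site1 = summ(v1), site2 = summ(v2))
}

new_concordance_report <- function(analyte, pairs, v1, v2, class1, class2) {
  st <- concordance_stats(v1, v2)
  per <- data.frame(patient_id = pairs$patient_id,
                    value_site1 = v1, value_site2 = v2,
                    stringsAsFactors = FALSE)
  if (!is.null(class1)) {
    per$class_site1 <- class1
    per$class_site2 <- class2
    per$concordant <- class1 == class2
    n_disc <- sum(!per$concordant)
  } else {
    n_disc <- NA_integer_
  }
  structure(list(analyte = analyte, n_pairs = nrow(per),
                 spearman_rho = st$spearman_rho, spearman_p = st$spearman_p,
                 wilcoxon_stat = st$wilcoxon_stat,
                 wilcoxon_p = st$wilcoxon_p,
                 wilcoxon_degenerate = st$wilcoxon_degenerate,
                 per_patient = per, n_discordant = n_disc,
                 medians = site_summaries(v1, v2),
                 alpha = 0.05),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Paired concordance (%s), %d pairs\n", x$analyte, x$n_pairs))
  cat(sprintf("  Spearman rho = %s (p = %s)\n",
              format(x$spearman_rho, digits = 3), format(x$spearman_p, digits = 3)))
  cat(sprintf("  Wilcoxon statistic = %s (p = %s)%s\n",
              format(x$wilcoxon_stat, digits = 3), format(x$wilcoxon_p, digits = 3),
              if (isTRUE(x$wilcoxon_degenerate)) " [degenerate: all differences zero]" else ""))
  m <- x$medians
  cat(sprintf("  medians: site1 %.2f (IQR %.2f, SD %.2f); site2 %.2f (IQR %.2f, SD %.2f)\n",
              m$site1["median"], m$site1["iqr"], m$site1["sd"],
              m$site2["median"], m$site2["iqr"], m$site2["sd"]))
  if (!is.na(x$n_discordant))
    cat(sprintf("  discordant pairs: %d / %d\n", x$n_discordant, x$n_pairs))
  invisible(x)
}

#' Paired-site TMB concordance
#'
#' Classifies each patient's two sites at the TMB cut-off (default 10
#' mutations per Mb); a pair is discordant when the high/low classes differ.
#' Also reports Spearman correlation and the paired Wilcoxon test over the
#' TMB values, and per-site medians with IQR and SD.
#'
#' @param pairs data.frame with `patient_id`, `tmb_site1`, `tmb_site2`
#'   (see [paired_patients()]).
#' @param cutoff TMB cut-off in mutations per Mb.
#' @param strict strict `>` at the cut-off boundary.
#' @return A `concordance_report`.
#' @export
paired_concordance <- function(pairs, cutoff = 10, strict = FALSE) {
  stopifnot(all(c("patient_id", "tmb_site1", "tmb_site2") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("tmb_site1", "tmb_site2")])
  pairs <- pairs[ok, , drop = FALSE]
  new_concordance_report("TMB", pairs, pairs$tmb_site1, pairs$tmb_site2,
                         classify_tmb(pairs$tmb_site1, cutoff, strict),
                         classify_tmb(pairs$tmb_site2, cutoff, strict))
}

#' KRAS mutant-allele-fraction concordance
#'
#' KRAS status is positive at a mutant-allele fraction of at least 0.2%
#' (0.002), the ddPCR assay's presence cut-off; concordance, Spearman and
#' Wilcoxon are reported over the MAF values.
#'
#' @param pairs data.frame with `patient_id`, `kras_maf_site1`,
#'   `kras_maf_site2` (fractions in `[0, 1]`).
#' @param cutoff positivity cut-off on the mutant-allele fraction.
#' @return A `concordance_report`.
#' @export
kras_concordance <- function(pairs, cutoff = 0.002) {
  stopifnot(all(c("patient_id", "kras_maf_site1", "kras_maf_site2") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("kras_maf_site1", "kras_maf_site2")])
  pairs <- pairs[ok, , drop = FALSE]
  cls <- function(v) ifelse(v >= cutoff, "positive", "negative")
  new_concordance_report("KRAS_MAF", pairs, pairs$kras_maf_site1,
                         pairs$kras_maf_site2,
                         cls(pairs$kras_maf_site1), cls(pairs$kras_maf_site2))
}

#' PD-L1 copy-number concordance
#'
#' Spearman and paired Wilcoxon over copy-number values; no status
#' classification is applied (no clinical copy-number cut-off is defined).
#'
#' @param pairs data.frame with `patient_id`, `pdl1_cn_site1`,
#'   `pdl1_cn_site2` (copy numbers, >= 0).
#' @return A `concordance_report`.
#' @export
pdl1_concordance <- function(pairs) {
  stopifnot(all(c("patient_id", "pdl1_cn_site1", "pdl1_cn_site2") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("pdl1_cn_site1", "pdl1_cn_site2")])
  pairs <- pairs[ok, , drop = FALSE]
  new_concordance_report("PDL1_CN", pairs, pairs$pdl1_cn_site1,
                         pairs$pdl1_cn_site2, NULL, NULL)
}

#' Mutant-allele fraction from ddPCR droplet counts
#'
#' Converts droplet digital PCR counts to a mutant-allele fraction. With
#' Poisson correction (the standard quantification) the per-channel target
#' concentration is `lambda = -ln(N_negative / N_total)` copies per droplet
#' and `maf = lambda_mut / (lambda_mut + lambda_wt)`. The `"raw"` method
#' uses positive-droplet fractions directly without correction.
#'
#' @param n_total total droplet count per well.
#' @param n_mut_positive droplets positive in the mutant channel.
#' @param n_wt_positive droplets positive in the wild-type channel.
#' @param method `"poisson"` (default) or `"raw"`.
#' @return Mutant-allele fraction(s) in `[0, 1]`.
#' @export
ddpcr_fractional_abundance <- function(n_total, n_mut_positive, n_wt_positive,
                                       method = c("poisson", "raw")) {
  method <- match.arg(method)
  if (any(n_mut_positive > n_total) || any(n_wt_positive > n_total))
    stop("positive droplet counts cannot exceed the total")
  if (any(n_mut_positive >= n_total & method == "poisson"))
    stop("saturated mutant channel: Poisson correction undefined")
  if (method == "poisson") {
    lam_mut <- -log((n_total - n_mut_positive) / n_total)
    lam_wt <- -log((n_total - n_wt_positive) / n_total)
    denom <- lam_mut + lam_wt
  } else {
    lam_mut <- n_mut_positive / n_total
    lam_wt <- n_wt_positive / n_total
    denom <- lam_mut + lam_wt
  }
  ifelse(denom > 0, lam_mut / denom, 0)
}

#' Copy number from TaqMan qPCR Ct values
#'
#' Relative quantification against a two-copy reference:
#' `CN = 2 * 2^(-ddCt)` where `ddCt = (Ct_target - Ct_reference) -
#' calibrator_dct`. A convenience beyond direct copy-number ingestion.
#'
#' @param ct_target Ct of the target assay.
#' @param ct_reference Ct of the two-copy reference assay in the same sample.
#' @param calibrator_dct delta-Ct of a known two-copy calibrator (default 0).
#' @return Estimated copy number(s).
#' @export
taqman_copy_number <- function(ct_target, ct_reference, calibrator_dct = 0) {
  ddct <- (ct_target - ct_reference) - calibrator_dct
  2 * 2^(-ddct)
}
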