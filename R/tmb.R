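#' Count calls falling in callable regions
#'
#' A call at 1-based VCF position `pos` is counted when the 0-based position
#' `pos - 1` lies within the merged region set (half-open semantics).
#'
#' @param calls a `variant_calls` data.frame.
#' @param regions a merged `region_set`.
#' @return Integer count of callable calls.
#' @export
count_callable <- function(calls, regions) {
  if (nrow(calls) == 0L) return(0L)
  sum(region_contains(regions, calls$chrom, calls$pos - 1))
}

#' Ratio-method TMB
#'
#' The tumour mutational burden as the ratio of callable mutations per
#' megabase of callable exome.
#'
#' @param mutation_count number of callable mutations.
#' @param callable_mb callable megabases; must be > 0.
#' @return Mutations per Mb (double).
#' @export
tmb_ratio <- function(mutation_count, callable_mb) {
  if (any(callable_mb <= 0))
    stop("callable_mb must be > 0: TMB is undefined over an empty callable region")
  mutation_count / callable_mb
}

#' z-score standardise TMB values
#'
#' Standardises scores across samples within one exome definition so that
#' scores from different definitions become comparable: `(x - mean) / sd`
#' with the sample (n-1) standard deviation. The output has mean 0 and sd 1.
#'
#' @param scores numeric vector of TMB values, one per sample, all computed
#'   under the same definition; needs `n >= 2` and non-zero spread.
#' @return Standardised scores.
#' @export
zscore_standardise <- function(scores) {
  if (length(scores) < 2L)
    stop("z-score standardisation needs at least 2 samples")
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0)
    stop("z-scores are undefined when all scores are identical (zero spread)")
  (scores - mean(scores)) / s
}

#' Classify TMB as high or low at a clinical cut-off
#'
#' The default cut-off is 10 mutations per Mb, the immunotherapy-response
#' threshold; `"high"` at `tmb >= cutoff` (set `strict = TRUE` for a strict
#' `>` boundary).
#'
#' @param tmb TMB value(s), mutations per Mb.
#' @param cutoff cut-off in mutations per Mb.
#' @param strict use strictly-greater-than at the boundary.
#' @return Character vector, `"high"` or `"low"`.
#' @export
classify_tmb <- function(tmb, cutoff = 10, strict = FALSE) {
  stopifnot(all(tmb >= 0))
  ifelse(if (strict) tmb > cutoff else tmb >= cutoff, "high", "low")
}

#' One TMB result row
#'
#' @param sample_id,site sample annotations (`site` conventionally
#'   `"site1"` for the primary and `"site2"` for the metastatic site).
#' @param definition region-set label used as denominator.
#' @param calls filtered `variant_calls`.
#' @param regions the merged, gap-subtracted `region_set` for that definition.
#' @return One-row data.frame: `sample_id`, `site`, `definition`,
#'   `mutation_count`, `callable_mb`, `tmb`.
#' @export
tmb_result <- function(sample_id, site, definition, calls, regions) {
  mb <- total_length_mb(regions)
  n <- count_callable(calls, regions)
  data.frame(sample_id = sample_id, site = site, definition = definition,
             mutation_count = n, callable_mb = mb, tmb = tmb_ratio(n, mb),
             stringsAsFactors = FALSE)
}

#' Panel-mode TMB for one sample
#'
#' Applies the panel filter, counts surviving calls inside the panel
#' footprint, and divides by the measured span of the supplied panel regions
#' (the nominal kit size is metadata, not the denominator).
#'
#' @param calls parsed and annotated `variant_calls`.
#' @param panel_regions the panel footprint as a `region_set`.
#' @param cfg a [filter_config()].
#' @param sample_id,site annotations for the result row.
#' @param cutoff high/low cut-off in mutations per Mb.
#' @return One-row TMB result data.frame with `tmb_class`.
#' @export
panel_tmb <- function(calls, panel_regions, cfg = filter_config(),
                      sample_id = NA_character_, site = NA_character_,
                      cutoff = 10) {
  kept <- panel_filter(calls, cfg)
  pr <- if (panel_regions$merged) panel_regions else merge_regions(panel_regions)
  res <- tmb_result(sample_id, site, panel_regions$label, kept, pr)
  res$tmb_class <- classify_tmb(res$tmb, cutoff = cutoff)
  attr(res, "tally") <- filter_tally(kept)
  res
}

#' Add per-definition z-scores and classes to a TMB table
#'
#' @param tab a TMB table (rows from [tmb_result()], long format over
#'   samples and definitions).
#' @param cutoff high/low cut-off in mutations per Mb.
#' @return The table with `zscore` and `tmb_class` columns; z-scores are
#'   computed across samples within each definition.
#' @export
standardise_tmb_table <- function(tab, cutoff = 10) {
  tab$zscore <- NA_real_
  for (def in unique(tab$definition)) {
    i <- tab$definition == def
    if (sum(i) >= 2L && stats::sd(tab$tmb[i]) > 0)
      tab$zscore[i] <- zscore_standardise(tab$tmb[i])
  }
  tab$tmb_class <- classify_tmb(tab$tmb, cutoff = cutoff)
  tab
}
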