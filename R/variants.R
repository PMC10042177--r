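#' Build a table of normalised variant calls
#'
#' Variant calls are held as a plain `data.frame` (class `variant_calls`) with
#' one row per (position, alt allele): `chrom`, `pos` (1-based, VCF
#' convention), `ref`, `alt`, `depth`, `alt_depth`, `vaf`, `var_class` (one of
#' `"SNV"`, `"indel"`, `"MNV"`), `consequence` (one of `"exonic"`,
#' `"splice_site"`, `"intronic"`, `"other"`), `known_snp` (membership in a
#' germline resource) and `pop_af` (maximum population allele frequency, `NA`
#' when unannotated).
#'
#' @param chrom,pos,ref,alt call coordinates and alleles (`pos` is 1-based).
#' @param depth total read depth; `alt_depth` alt-supporting reads.
#' @param alt_depth alt-supporting read count, `0 <= alt_depth <= depth`.
#' @param consequence functional consequence; defaults to `"exonic"`.
#' @param known_snp logical germline-resource membership (default `FALSE`).
#' @param pop_af maximum population allele frequency (default `NA`).
#' @param sample_id,site optional sample annotations carried through.
#' @return A `variant_calls` data.frame; `vaf` is `alt_depth/depth` (0 when
#'   `depth == 0`) and `var_class` is derived from allele lengths.
#' @export
variant_calls <- function(chrom, pos, ref, alt, depth, alt_depth,
                          consequence = "exonic", known_snp = FALSE,
                          pop_af = NA_real_, sample_id = NA_character_,
                          site = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    depth = rep_len(as.integer(depth), n),
    alt_depth = rep_len(as.integer(alt_depth), n),
    consequence = rep_len(as.character(consequence), n),
    known_snp = rep_len(as.logical(known_snp), n),
    pop_af = rep_len(as.numeric(pop_af), n),
    sample_id = rep_len(as.character(sample_id), n),
    site = rep_len(as.character(site), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (any(df$depth < 0L)) stop("depth must be >= 0")
    if (any(df$alt_depth < 0L | df$alt_depth > df$depth))
      stop("alt_depth must satisfy 0 <= alt_depth <= depth")
  }
  df$vaf <- ifelse(df$depth > 0L, df$alt_depth / df$depth, 0)
  df$var_class <- classify_alleles(df$ref, df$alt)
  df <- df[, c("chrom", "pos", "ref", "alt", "depth", "alt_depth", "vaf",
               "var_class", "consequence", "known_snp", "pop_af",
               "sample_id", "site")]
  class(df) <- c("variant_calls", "data.frame")
  df
}

classify_alleles <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("indel", length(ref))
  out[lr == la & lr == 1L] <- "SNV"
  out[lr == la & lr > 1L] <- "MNV"
  out
}

#' Filter configuration for the two filter regimes
#'
#' Defaults reproduce the published filter regimes: the whole-genome quality
#' filter removes calls with depth < 15 or VAF < 0.05 (so exactly-at-threshold
#' values are kept); the panel filter requires SNV class, an allowed
#' consequence, coverage >= 60x and allele frequency >= 5%; germline filtering
#' removes known-resource members and calls with population allele frequency
#' strictly greater than 1e-4.
#'
#' @param min_depth minimum read depth retained by the WGS quality filter.
#' @param min_vaf minimum variant allele fraction retained by the WGS filter.
#' @param panel_min_coverage minimum depth retained by the panel filter.
#' @param panel_min_af minimum VAF retained by the panel filter (limit of
#'   detection).
#' @param max_pop_af maximum population allele frequency tolerated before a
#'   call is treated as germline polymorphism.
#' @param exclude_indels drop indels/MNVs in panel mode.
#' @param allowed_consequences consequences counted in panel mode.
#' @param wgs_snv_only restrict the WGS quality filter to SNVs (default); set
#'   `FALSE` to admit indels/MNVs.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 15, min_vaf = 0.05,
                          panel_min_coverage = 60, panel_min_af = 0.05,
                          max_pop_af = 1e-4, exclude_indels = TRUE,
                          allowed_consequences = c("exonic", "splice_site", "intronic"),
                          wgs_snv_only = TRUE) {
  fr <- c(min_vaf = min_vaf, panel_min_af = panel_min_af, max_pop_af = max_pop_af)
  if (any(fr < 0 | fr > 1)) stop("fraction thresholds must lie in [0, 1]")
  if (min_depth < 0 || panel_min_coverage < 0) stop("read thresholds must be >= 0")
  structure(list(min_depth = min_depth, min_vaf = min_vaf,
                 panel_min_coverage = panel_min_coverage,
                 panel_min_af = panel_min_af, max_pop_af = max_pop_af,
                 exclude_indels = isTRUE(exclude_indels),
                 allowed_consequences = allowed_consequences,
                 wgs_snv_only = isTRUE(wgs_snv_only)),
            class = "filter_config")
}

#' Read a somatic VCF into normalised variant calls
#'
#' Parses a VCF 4.x file, splitting multi-allelic records into one call per
#' alternate allele. Depth and allele support are taken from the chosen
#' sample's `FORMAT` fields (`AD`/`DP`); when `DP` is absent the allelic
#' depths are summed. Records with no recoverable depth information are
#' emitted with `depth = 0` (they then fail every quality filter) and counted
#' in the parse report attached as attribute `"parse_report"`. Non-PASS
#' records (`FILTER` other than `PASS` or `.`) are dropped by default.
#' A `CONSEQ` INFO key, when present, supplies the functional consequence;
#' otherwise every call defaults to `"exonic"`.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param sample sample name to read; defaults to the sole sample in the file.
#' @param keep_filtered retain non-PASS records.
#' @return A `variant_calls` data.frame with attribute `"parse_report"`.
#' @export
read_vcf <- function(path, sample = NULL, keep_filtered = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    out <- variant_calls(character(), integer(), character(), character(),
                         integer(), integer())
    attr(out, "parse_report") <- list(n_records = 0L, n_calls = 0L,
                                      n_multiallelic = 0L, n_missing_depth = 0L,
                                      n_dropped_filter = 0L, depth_source = "none")
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n_records <- nrow(fix)

  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("no sample FORMAT columns in ", path, "; cannot recover depth/AD")
  samples <- colnames(gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) > 1L)
      stop("multiple samples in ", path, "; specify `sample`")
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    stop("sample '", sample, "' not found in ", path)
  }
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, sample]))
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]

  pass <- fix$FILTER %in% c("PASS", ".") | is.na(fix$FILTER)
  drop_n <- sum(!pass)
  if (!keep_filtered) {
    keep <- pass
  } else {
    keep <- rep(TRUE, n_records)
  }

  conseq <- extract_info_key(fix$INFO, "CONSEQ")
  conseq[is.na(conseq)] <- "exonic"

  rows <- list()
  n_multi <- 0L
  n_missing_depth <- 0L
  for (i in which(keep)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (length(alts) > 1L) n_multi <- n_multi + 1L
    ad_i <- if (is.na(ad[i])) NULL else
      suppressWarnings(as.numeric(strsplit(ad[i], ",", fixed = TRUE)[[1L]]))
    depth_i <- dp[i]
    if (is.na(depth_i) && !is.null(ad_i)) depth_i <- sum(ad_i, na.rm = TRUE)
    if (is.na(depth_i)) {
      depth_i <- 0
      n_missing_depth <- n_missing_depth + 1L
    }
    for (j in seq_along(alts)) {
      alt_d <- if (!is.null(ad_i) && length(ad_i) >= j + 1L && !is.na(ad_i[j + 1L]))
        ad_i[j + 1L] else 0
      alt_d <- min(alt_d, depth_i)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j], depth = as.integer(depth_i),
        alt_depth = as.integer(alt_d), consequence = conseq[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- variant_calls(character(), integer(), character(), character(),
                         integer(), integer())
  } else {
    df <- do.call(rbind, rows)
    out <- variant_calls(df$chrom, df$pos, df$ref, df$alt, df$depth,
                         df$alt_depth, consequence = df$consequence)
  }
  attr(out, "parse_report") <- list(
    n_records = n_records, n_calls = nrow(out), n_multiallelic = n_multi,
    n_missing_depth = n_missing_depth, n_dropped_filter = drop_n,
    depth_source = "FORMAT DP/AD")
  out
}

extract_info_key <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Annotate calls against a germline resource
#'
#' Sets `known_snp` by exact (chrom, pos, ref, alt) match against the
#' resource — allele identity is required, not mere positional overlap — and
#' `pop_af` to the maximum `AF` found across matching resource records.
#'
#' @param calls a `variant_calls` data.frame.
#' @param resource path to a germline-resource VCF with an `AF` INFO key, or a
#'   data.frame with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return `calls` with `known_snp` and `pop_af` populated.
#' @export
annotate_known <- function(calls, resource) {
  if (is.character(resource)) resource <- read_germline_resource(resource)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(resource)))
  if (nrow(calls) == 0L) return(calls)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  rk <- key(resource)
  raf <- tapply(resource$af, rk, max)
  ck <- key(calls)
  hit <- ck %in% names(raf)
  calls$known_snp <- hit
  calls$pop_af[hit] <- as.numeric(raf[ck[hit]])
  calls
}

read_germline_resource <- function(path) {
  if (!file.exists(path)) stop("germline resource not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), af = numeric()))
  af_raw <- extract_info_key(fix$INFO, "AF")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    afs <- if (is.na(af_raw[i])) rep(NA_real_, length(alts)) else
      suppressWarnings(as.numeric(strsplit(af_raw[i], ",", fixed = TRUE)[[1L]]))
    afs <- rep_len(afs, length(alts))
    data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
               ref = fix$REF[i], alt = alts, af = afs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$af[is.na(out$af)] <- 0
  out
}

apply_filter <- function(calls, predicates) {
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  for (nm in names(predicates)) {
    fails <- predicates[[nm]](calls)
    reason[is.na(reason) & fails] <- nm
  }
  kept <- calls[is.na(reason), , drop = FALSE]
  tally <- c(input = n, kept = nrow(kept),
             vapply(names(predicates),
                    function(nm) sum(reason == nm, na.rm = TRUE), integer(1)))
  attr(kept, "tally") <- tally
  attr(kept, "parse_report") <- attr(calls, "parse_report")
  class(kept) <- c("variant_calls", "data.frame")
  kept
}

#' Per-reason removal tally of a filter step
#'
#' Removal reasons are attributed to the first failing predicate in the
#' filter's documented order, so `kept + sum(reasons) == input`.
#'
#' @param calls the output of a filter operation.
#' @return Named integer vector of counts.
#' @export
filter_tally <- function(calls) attr(calls, "tally")

#' Whole-genome quality filter
#'
#' Removes poor-quality calls: depth below `min_depth` (default 15) or VAF
#' below `min_vaf` (default 0.05). Exactly-at-threshold calls are kept. By
#' default only SNVs are retained (switch with `wgs_snv_only` in
#' [filter_config()]). Removal reasons, in attribution order `class`,
#' `depth`, `vaf`, are tallied in attribute `"tally"`.
#'
#' @param calls a `variant_calls` data.frame.
#' @param cfg a [filter_config()].
#' @return Kept calls with attribute `"tally"`.
#' @export
wgs_quality_filter <- function(calls, cfg = filter_config()) {
  preds <- list(
    class = function(d) if (cfg$wgs_snv_only) d$var_class != "SNV" else rep(FALSE, nrow(d)),
    depth = function(d) d$depth < cfg$min_depth,
    vaf   = function(d) d$vaf < cfg$min_vaf
  )
  apply_filter(calls, preds)
}

#' Germline filter
#'
#' Removes calls flagged as known germline polymorphisms: `known_snp` is
#' `TRUE` or `pop_af` strictly exceeds `max_pop_af` (default 1e-4).
#' Unannotated calls (`pop_af` is `NA`) are kept.
#'
#' @inheritParams wgs_quality_filter
#' @return Kept calls with attribute `"tally"` (reasons `known_snp`,
#'   `pop_af`).
#' @export
germline_filter <- function(calls, cfg = filter_config()) {
  preds <- list(
    known_snp = function(d) d$known_snp %in% TRUE,
    pop_af    = function(d) !is.na(d$pop_af) & d$pop_af > cfg$max_pop_af
  )
  apply_filter(calls, preds)
}

#' Panel-mode filter
#'
#' Reproduces a targeted-panel mutational-load calling regime: somatic SNVs
#' only (indels and MNVs excluded), consequence within the allowed set
#' (exonic, splice-site and intronic by default), coverage >= 60x, allele
#' frequency >= 5% limit of detection, and germline exclusion at 1e-4 maximum
#' population allele frequency. Attribution order: `class`, `consequence`,
#' `coverage`, `af`, `known_snp`, `pop_af`.
#'
#' @inheritParams wgs_quality_filter
#' @return Kept calls with attribute `"tally"`.
#' @export
panel_filter <- function(calls, cfg = filter_config()) {
  preds <- list(
    class = function(d) if (cfg$exclude_indels) d$var_class != "SNV" else rep(FALSE, nrow(d)),
    consequence = function(d) !(d$consequence %in% cfg$allowed_consequences),
    coverage = function(d) d$depth < cfg$panel_min_coverage,
    af = function(d) d$vaf < cfg$panel_min_af,
    known_snp = function(d) d$known_snp %in% TRUE,
    pop_af = function(d) !is.na(d$pop_af) & d$pop_af > cfg$max_pop_af
  )
  apply_filter(calls, preds)
}

#' Write variant calls as a VCF 4.2 file
#'
#' Emits one record per call with `DP`/`AD` FORMAT fields for a single sample
#' and `CONSEQ` in INFO, sorted by (chrom, pos). This is the carrier format of
#' the synthetic-cohort generator and the re-emission path for filtered calls.
#'
#' @param calls a `variant_calls` data.frame.
#' @param path output path.
#' @param sample_name sample column name.
#' @param contigs optional named numeric vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "TUMOR", contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tmbpair",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=CONSEQ,Number=1,Type=String,Description=\"Functional consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name)
  )
  o <- order(calls$chrom, calls$pos, calls$alt)
  calls <- calls[o, , drop = FALSE]
  body <- if (nrow(calls) > 0L) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCONSEQ=%s\tGT:DP:AD\t0/1:%d:%d,%d",
            calls$chrom, calls$pos, calls$ref, calls$alt, calls$consequence,
            calls$depth, calls$depth - calls$alt_depth, calls$alt_depth)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_germline_resource_vcf <- function(resource, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tmbpair",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  o <- order(resource$chrom, resource$pos, resource$alt)
  resource <- resource[o, , drop = FALSE]
  body <- if (nrow(resource) > 0L) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
            resource$chrom, resource$pos, resource$ref, resource$alt,
            format(resource$af, scientific = FALSE, trim = TRUE, digits = 10))
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
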