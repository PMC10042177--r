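#' Build a run configuration
#'
#' Collects everything an end-to-end run needs: the analysis mode, the sample
#' sheet (one VCF per patient x site), region-definition BEDs, the assembly
#' gap BED, the germline resource, filter thresholds, the TMB cut-off and
#' statistics options. All thresholds default to the published filter
#' regimes, so a bare configuration reproduces them.
#'
#' @param mode `"wgs_ratio"` or `"panel"`.
#' @param samples data.frame with columns `patient_id`, `site`
#'   (`"site1"`/`"site2"`), `vcf` (path) and optionally `cellularity_pct`
#'   (QC metadata; samples below 20% are flagged but still computed).
#' @param regions named character vector/list of BED paths, one per
#'   definition (panel mode expects a single `"panel"` entry).
#' @param gap_bed optional BED of assembly gaps to subtract.
#' @param germline_resource optional germline-resource VCF (AF INFO key).
#' @param filter a [filter_config()].
#' @param cutoff TMB high/low cut-off, mutations per Mb.
#' @param comparison_definition definition used for paired concordance.
#' @param chr_prefix chromosome-name harmonisation applied to region sets:
#'   `"asis"`, `"strip"` or `"add"`.
#' @param droplets_tsv optional ddPCR droplet-count TSV (`patient_id`,
#'   `site`, `n_total`, `n_mut_positive`, `n_wt_positive`).
#' @param copy_number_tsv optional PD-L1 copy-number TSV (`patient_id`,
#'   `site`, `pdl1_cn`).
#' @param seed seed for any Monte-Carlo statistics.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("wgs_ratio", "panel"), samples, regions,
                       gap_bed = NULL, germline_resource = NULL,
                       filter = filter_config(), cutoff = 10,
                       comparison_definition = "canonical",
                       chr_prefix = "asis", droplets_tsv = NULL,
                       copy_number_tsv = NULL, seed = 1) {
  structure(list(mode = match.arg(mode), samples = samples,
                 regions = as.list(regions), gap_bed = gap_bed,
                 germline_resource = germline_resource, filter = filter,
                 cutoff = cutoff,
                 comparison_definition = comparison_definition,
                 chr_prefix = chr_prefix, droplets_tsv = droplets_tsv,
                 copy_number_tsv = copy_number_tsv, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()]; relative paths
#'   are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(patient_id = s$patient_id, site = s$site, vcf = resolve(s$vcf),
               cellularity_pct = if (is.null(s$cellularity_pct)) NA_real_
                                 else s$cellularity_pct,
               stringsAsFactors = FALSE)))
  fl <- if (is.null(y$filter)) filter_config() else do.call(filter_config, y$filter)
  run_config(mode = y$mode %||% "wgs_ratio", samples = samples,
             regions = lapply(y$regions, resolve),
             gap_bed = resolve(y$gap_bed),
             germline_resource = resolve(y$germline_resource), filter = fl,
             cutoff = y$cutoff %||% 10,
             comparison_definition = y$comparison_definition %||% "canonical",
             chr_prefix = y$chr_prefix %||% "asis",
             droplets_tsv = resolve(y$droplets_tsv),
             copy_number_tsv = resolve(y$copy_number_tsv),
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Collects every problem at once (missing files, duplicate patient/site
#' labels, more than two sites per patient, out-of-range thresholds) rather
#' than stopping at the first.
#'
#' @param cfg a `run_config`.
#' @return Data.frame with columns `field` and `message`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(cfg) {
  errs <- list()
  add <- function(field, message)
    errs[[length(errs) + 1L]] <<- data.frame(field = field, message = message,
                                             stringsAsFactors = FALSE)
  s <- cfg$samples
  if (is.null(s) || nrow(s) == 0L) add("samples", "no samples defined")
  else {
    key <- paste(s$patient_id, s$site)
    if (anyDuplicated(key)) add("samples", paste("duplicate (patient, site):",
                                paste(unique(key[duplicated(key)]), collapse = ", ")))
    nsites <- table(s$patient_id)
    if (any(nsites > 2L)) add("samples", paste("more than 2 sites for:",
                              paste(names(nsites)[nsites > 2L], collapse = ", ")))
    if (!all(s$site %in% c("site1", "site2")))
      add("samples", "site labels must be 'site1' or 'site2'")
    missing <- s$vcf[!file.exists(s$vcf)]
    for (m in missing) add("samples", paste("missing VCF:", m))
  }
  if (length(cfg$regions) == 0L) add("regions", "no region definitions")
  if (is.null(names(cfg$regions)) || any(!nzchar(names(cfg$regions))) ||
      anyDuplicated(names(cfg$regions)))
    add("regions", "region definitions must have unique non-empty labels")
  for (p in unlist(cfg$regions)) if (!file.exists(p))
    add("regions", paste("missing BED:", p))
  for (f in c("gap_bed", "germline_resource", "droplets_tsv", "copy_number_tsv"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      add(f, paste("missing file:", cfg[[f]]))
  if (cfg$cutoff < 0) add("cutoff", "cutoff must be >= 0")
  if (length(errs) == 0L)
    data.frame(field = character(), message = character())
  else do.call(rbind, errs)
}

load_definitions <- function(cfg) {
  defs <- lapply(names(cfg$regions), function(nm) {
    rs <- load_bed(cfg$regions[[nm]], label = nm)
    rs <- harmonise_chr(rs, cfg$chr_prefix)
    merge_regions(rs)
  })
  names(defs) <- names(cfg$regions)
  if (!is.null(cfg$gap_bed)) {
    gaps <- harmonise_chr(load_bed(cfg$gap_bed, label = "gaps"), cfg$chr_prefix)
    defs <- lapply(defs, function(d) subtract_regions(d, gaps))
  }
  defs
}

log_entry <- function(log, event, ...) {
  c(log, list(c(list(event = event), list(...))))
}

wgs_sample_rows <- function(calls, defs, fcfg, patient_id, site, log) {
  q <- wgs_quality_filter(calls, fcfg)
  g <- germline_filter(q, fcfg)
  log <- log_entry(log, "filter", patient_id = patient_id, site = site,
                   quality_tally = as.list(filter_tally(q)),
                   germline_tally = as.list(filter_tally(g)))
  rows <- do.call(rbind, lapply(names(defs), function(nm)
    tmb_result(patient_id, site, nm, g, defs[[nm]])))
  list(rows = rows, log = log)
}

cross_definition_correlation <- function(tab) {
  defs <- unique(tab$definition)
  if (length(defs) < 2L) return(NULL)
  wide <- stats::reshape(
    tab[, c("sample_id", "site", "definition", "tmb")],
    idvar = c("sample_id", "site"), timevar = "definition",
    direction = "wide")
  combs <- utils::combn(defs, 2)
  do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
    a <- wide[[paste0("tmb.", combs[1, k])]]
    b <- wide[[paste0("tmb.", combs[2, k])]]
    sp <- tryCatch(spearman_test(a, b), error = function(e) NULL)
    data.frame(definition1 = combs[1, k], definition2 = combs[2, k],
               spearman_rho = if (is.null(sp)) NA_real_ else sp$estimate,
               spearman_p = if (is.null(sp)) NA_real_ else sp$p.value,
               n = length(a), stringsAsFactors = FALSE)
  }))
}

finalise_run <- function(tab, cfg, log, extra = list()) {
  tab <- standardise_tmb_table(tab, cutoff = cfg$cutoff)
  if (!is.null(cfg$samples$cellularity_pct)) {
    key <- paste(cfg$samples$patient_id, cfg$samples$site)
    cell <- stats::setNames(cfg$samples$cellularity_pct, key)
    tab$cellularity_pct <- as.numeric(cell[paste(tab$sample_id, tab$site)])
    tab$low_cellularity <- !is.na(tab$cellularity_pct) & tab$cellularity_pct < 20
    for (k in unique(paste(tab$sample_id, tab$site)[tab$low_cellularity %in% TRUE]))
      log <- log_entry(log, "qc_flag", sample = k,
                       reason = "tumour cellularity below 20%")
  }
  pairs <- paired_patients(tab, cfg$comparison_definition)
  for (ex in attr(pairs, "excluded"))
    log <- log_entry(log, "pair_excluded", patient_id = ex,
                     reason = "missing site")
  conc <- paired_concordance(pairs, cutoff = cfg$cutoff)
  c(list(tmb_table = tab, concordance = conc,
         cross_definition = cross_definition_correlation(tab),
         log = log, config = cfg), extra)
}

#' Run the whole-genome Ratio-method analysis
#'
#' For every sample: parse the VCF, annotate against the germline resource,
#' apply the quality and germline filters, and compute TMB against each
#' merged, gap-subtracted region definition. Scores are z-standardised per
#' definition, classified at the cut-off, and the designated comparison
#' definition feeds the paired-site concordance analysis. Cross-definition
#' Spearman correlations are reported when several definitions are supplied.
#'
#' @param cfg a `run_config` with `mode = "wgs_ratio"`.
#' @return A `tmb_run` list: `tmb_table`, `concordance`,
#'   `cross_definition`, `log`, `config`.
#' @export
run_wgs <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), cfg$mode == "wgs_ratio")
  errs <- validate_config(cfg)
  if (nrow(errs) > 0L)
    stop("invalid run configuration:\n",
         paste(sprintf("  [%s] %s", errs$field, errs$message), collapse = "\n"))
  defs <- load_definitions(cfg)
  resource <- if (!is.null(cfg$germline_resource))
    read_germline_resource(cfg$germline_resource) else NULL
  log <- list()
  rows <- list()
  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples[i, ]
    calls <- read_vcf(s$vcf)
    log <- log_entry(log, "parse", patient_id = s$patient_id, site = s$site,
                     report = attr(calls, "parse_report"))
    if (!is.null(resource)) calls <- annotate_known(calls, resource)
    res <- wgs_sample_rows(calls, defs, cfg$filter, s$patient_id, s$site, log)
    rows[[i]] <- res$rows
    log <- res$log
  }
  out <- finalise_run(do.call(rbind, rows), cfg, log)
  class(out) <- "tmb_run"
  out
}

#' Run the panel-mode analysis
#'
#' Applies the panel filter, counts surviving calls in the panel footprint
#' and divides by its measured span. When assay tables are supplied, KRAS
#' mutant-allele fractions are derived from ddPCR droplet counts (Poisson
#' corrected) and PD-L1 copy numbers ingested directly, each with their own
#' paired concordance report.
#'
#' @param cfg a `run_config` with `mode = "panel"` and a `"panel"` region.
#' @return A `tmb_run` list; `kras` and `pdl1` elements hold the assay
#'   concordance reports when tables were supplied.
#' @export
run_panel <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"), cfg$mode == "panel")
  errs <- validate_config(cfg)
  if (nrow(errs) > 0L)
    stop("invalid run configuration:\n",
         paste(sprintf("  [%s] %s", errs$field, errs$message), collapse = "\n"))
  defs <- load_definitions(cfg)
  if (!"panel" %in% names(defs)) stop("panel mode needs a region labelled 'panel'")
  resource <- if (!is.null(cfg$germline_resource))
    read_germline_resource(cfg$germline_resource) else NULL
  log <- list()
  rows <- list()
  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples[i, ]
    calls <- read_vcf(s$vcf)
    log <- log_entry(log, "parse", patient_id = s$patient_id, site = s$site,
                     report = attr(calls, "parse_report"))
    if (!is.null(resource)) calls <- annotate_known(calls, resource)
    res <- panel_tmb(calls, defs$panel, cfg$filter, sample_id = s$patient_id,
                     site = s$site, cutoff = cfg$cutoff)
    log <- log_entry(log, "filter", patient_id = s$patient_id, site = s$site,
                     panel_tally = as.list(attr(res, "tally")))
    rows[[i]] <- res[, c("sample_id", "site", "definition", "mutation_count",
                         "callable_mb", "tmb")]
  }
  cfg$comparison_definition <- "panel"
  extra <- list()
  if (!is.null(cfg$droplets_tsv)) {
    dro <- utils::read.delim(cfg$droplets_tsv, stringsAsFactors = FALSE)
    dro$maf <- ddpcr_fractional_abundance(dro$n_total, dro$n_mut_positive,
                                          dro$n_wt_positive)
    w <- stats::reshape(dro[, c("patient_id", "site", "maf")],
                        idvar = "patient_id", timevar = "site",
                        direction = "wide")
    names(w) <- sub("^maf\\.", "kras_maf_", names(w))
    extra$kras <- kras_concordance(w)
  }
  if (!is.null(cfg$copy_number_tsv)) {
    cn <- utils::read.delim(cfg$copy_number_tsv, stringsAsFactors = FALSE)
    w <- stats::reshape(cn[, c("patient_id", "site", "pdl1_cn")],
                        idvar = "patient_id", timevar = "site",
                        direction = "wide")
    names(w) <- sub("^pdl1_cn\\.", "pdl1_cn_", names(w))
    extra$pdl1 <- pdl1_concordance(w)
  }
  out <- finalise_run(do.call(rbind, rows), cfg, log, extra)
  class(out) <- "tmb_run"
  out
}

#' Analyse an in-memory synthetic cohort
#'
#' Runs the same analysis as [run_wgs()]/[run_panel()] directly on a
#' [generate_cohort()] object, without writing or re-reading files. Used for
#' simulation studies where file round-trips would dominate runtime; the
#' file-based and in-memory paths share all filtering and scoring code.
#'
#' @param cohort a `synthetic_cohort`.
#' @param mode `"wgs_ratio"` or `"panel"`.
#' @param filter a [filter_config()].
#' @param cutoff TMB cut-off.
#' @param comparison_definition definition used for pairing (WGS mode).
#' @return A `tmb_run` list (no file-backed log entries).
#' @export
analyse_cohort <- function(cohort, mode = c("wgs_ratio", "panel"),
                           filter = filter_config(), cutoff = 10,
                           comparison_definition = "canonical") {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  gaps <- cohort$regions$gaps
  if (mode == "wgs_ratio") {
    defs <- lapply(cohort$regions[c("canonical", "crev2", "tcga")],
                   function(rs) subtract_regions(merge_regions(rs), gaps))
  } else {
    defs <- list(panel = subtract_regions(merge_regions(cohort$regions$panel), gaps))
  }
  log <- list()
  rows <- list()
  for (p in cohort$patients) {
    for (site in c("site1", "site2")) {
      calls <- annotate_known(p[[site]], cohort$resource)
      if (mode == "wgs_ratio") {
        res <- wgs_sample_rows(calls, defs, filter, p$patient_id, site, log)
        rows[[length(rows) + 1L]] <- res$rows
        log <- res$log
      } else {
        res <- panel_tmb(calls, defs$panel, filter, sample_id = p$patient_id,
                         site = site, cutoff = cutoff)
        rows[[length(rows) + 1L]] <-
          res[, c("sample_id", "site", "definition", "mutation_count",
                  "callable_mb", "tmb")]
      }
    }
  }
  cfg <- run_config(mode = mode, samples = cohort$truth$samples,
                    regions = list(), filter = filter, cutoff = cutoff,
                    comparison_definition = if (mode == "panel") "panel"
                                            else comparison_definition)
  extra <- list()
  if (mode == "panel") {
    dro <- cohort$truth$droplets
    dro$maf <- ddpcr_fractional_abundance(dro$n_total, dro$n_mut_positive,
                                          dro$n_wt_positive)
    w <- stats::reshape(dro[, c("patient_id", "site", "maf")],
                        idvar = "patient_id", timevar = "site",
                        direction = "wide")
    names(w) <- sub("^maf\\.", "kras_maf_", names(w))
    extra$kras <- kras_concordance(w)
    extra$pdl1 <- pdl1_concordance(cohort$truth$assay)
  }
  out <- finalise_run(do.call(rbind, rows), cfg, log, extra)
  class(out) <- "tmb_run"
  out
}

#' @export
print.tmb_run <- function(x, ...) {
  cat(sprintf("tmb_run (%s): %d result rows over %d definition(s)\n",
              x$config$mode, nrow(x$tmb_table),
              length(unique(x$tmb_table$definition))))
  print(x$concordance)
  invisible(x)
}

report_payload <- function(run) {
  conc_json <- function(cr) {
    if (is.null(cr)) return(NULL)
    list(analyte = cr$analyte, n_pairs = cr$n_pairs,
         spearman_rho = cr$spearman_rho, spearman_p = cr$spearman_p,
         wilcoxon_stat = cr$wilcoxon_stat, wilcoxon_p = cr$wilcoxon_p,
         wilcoxon_degenerate = cr$wilcoxon_degenerate,
         n_discordant = cr$n_discordant,
         medians = lapply(cr$medians, as.list),
         per_patient = cr$per_patient)
  }
  tab <- run$tmb_table
  tab$tmb_2dp <- round(tab$tmb, 2)   # display precision; full values retained
  list(mode = run$config$mode, cutoff = run$config$cutoff,
       comparison_definition = run$config$comparison_definition,
       tmb_table = tab,
       concordance = conc_json(run$concordance),
       cross_definition = run$cross_definition,
       kras = conc_json(run$kras), pdl1 = conc_json(run$pdl1))
}

#' Write a run report to disk
#'
#' Emits the result table as TSV, the full report as JSON, and the
#' structured log as JSON-lines. Output is deterministic for a given run.
#'
#' @param run a `tmb_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$tmb_table, file.path(dir, "tmb_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report_payload(run), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  lines <- vapply(run$log, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)),
    character(1))
  writeLines(lines, file.path(dir, "log.jsonl"))
  invisible(dir)
}
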