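#' Configuration for the synthetic paired-cohort generator
#'
#' Defines the study conditions emulated by the generator: a paired design
#' (two sampled sites per patient) over a toy genome, with trunk mutations
#' shared by both sites, site-private mutations, germline contaminants
#' carrying population allele frequencies, and sub-threshold artefacts that
#' the quality filters must remove. All rates are per megabase of callable
#' sequence.
#'
#' Defaults mirror a small paired lung-cancer cohort profiled at
#' whole-genome depth: 10 patients, a 20 Mb toy genome on two contigs, a
#' canonical exome covering half of it, nested CREv2-like (88% of canonical)
#' and TCGA-like (50% of CREv2-like) definitions matching the relative sizes
#' of the three real exome definitions, a panel footprint of 8.5% of the
#' genome (1.7 Mb nominal), trunk rate 8 mutations/Mb (the cohort-median
#' burden), small private rates, mean depth 60x, and a clonal-like VAF
#' distribution Beta(8, 15) (mean 0.35, SD 0.10).
#'
#' @param n_patients number of patients (each with two sites).
#' @param genome_length_bp toy genome span, split equally over `n_contigs`.
#' @param n_contigs number of toy contigs.
#' @param tile_bp tile width used to lay out region definitions.
#' @param exome_fraction fraction of the genome covered by the canonical
#'   definition.
#' @param crev2_fraction fraction of canonical kept in the CREv2-like set.
#' @param tcga_fraction fraction of the CREv2-like set kept in the TCGA-like
#'   set.
#' @param panel_fraction fraction of the genome covered by the panel
#'   footprint (subset of canonical).
#' @param gap_fraction fraction of the genome marked as assembly gap;
#'   gaps are drawn from canonical-but-not-panel tiles and from
#'   extra-exonic tiles in equal parts.
#' @param trunk_rate trunk (shared) SNV rate, mutations per callable Mb.
#' @param private_rate_site1,private_rate_site2 site-private SNV rates.
#' @param indel_rate trunk indel rate (exercises indel exclusion).
#' @param germline_rate germline contaminant rate per callable Mb; population
#'   AFs are drawn from a 70/30 mixture of common (AF ~ U(0.01, 0.5)) and
#'   rare (AF ~ U(2e-4, 0.01)) polymorphisms, all above the 1e-4 filter.
#' @param artefact_rate artefact rate per callable Mb, split 50/50 between
#'   depth-violating (depth < 15) and VAF-violating (VAF < 0.05) calls.
#' @param mean_depth mean sequencing depth (Poisson), e.g. 60 for WGS-like,
#'   500 for panel-like cohorts.
#' @param vaf_alpha,vaf_beta Beta parameters of the true clonal VAF.
#' @param kras_positive_fraction probability a patient is truly KRAS mutant.
#' @param seed root seed; per-patient substreams are derived by stable
#'   hashing of (seed, patient_id) so adding a patient never changes the
#'   data of earlier patients.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10, genome_length_bp = 2e7,
                          n_contigs = 2, tile_bp = 2000,
                          exome_fraction = 0.5, crev2_fraction = 0.88,
                          tcga_fraction = 0.5, panel_fraction = 0.085,
                          gap_fraction = 0.02,
                          trunk_rate = 8, private_rate_site1 = 0.5,
                          private_rate_site2 = 0.5, indel_rate = 0.5,
                          germline_rate = 2, artefact_rate = 2,
                          mean_depth = 60, vaf_alpha = 8, vaf_beta = 15,
                          kras_positive_fraction = 0.3, seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              genome_length_bp = genome_length_bp, n_contigs = as.integer(n_contigs),
              tile_bp = as.integer(tile_bp),
              exome_fraction = exome_fraction, crev2_fraction = crev2_fraction,
              tcga_fraction = tcga_fraction, panel_fraction = panel_fraction,
              gap_fraction = gap_fraction, trunk_rate = trunk_rate,
              private_rate_site1 = private_rate_site1,
              private_rate_site2 = private_rate_site2,
              indel_rate = indel_rate, germline_rate = germline_rate,
              artefact_rate = artefact_rate, mean_depth = mean_depth,
              vaf_alpha = vaf_alpha, vaf_beta = vaf_beta,
              kras_positive_fraction = kras_positive_fraction,
              seed = as.integer(seed))
  rates <- c(cfg$trunk_rate, cfg$private_rate_site1, cfg$private_rate_site2,
             cfg$indel_rate, cfg$germline_rate, cfg$artefact_rate)
  if (any(rates < 0)) stop("mutation rates must be >= 0")
  fr <- c(cfg$exome_fraction, cfg$crev2_fraction, cfg$tcga_fraction,
          cfg$panel_fraction)
  if (any(fr <= 0 | fr > 1)) stop("fractions must lie in (0, 1]")
  if (cfg$panel_fraction + cfg$gap_fraction > cfg$exome_fraction)
    stop("panel and gap fractions cannot exceed the exome fraction")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$kras_positive_fraction < 0 || cfg$kras_positive_fraction > 1)
    stop("kras_positive_fraction must lie in [0, 1]")
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic 31-bit substream seed from (seed, key); stable across platforms
substream_seed <- function(seed, key) {
  s <- paste0(seed, "::", key)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

contig_table <- function(cfg) {
  len <- cfg$genome_length_bp / cfg$n_contigs
  stats::setNames(rep(len, cfg$n_contigs),
                  paste0("syn", seq_len(cfg$n_contigs)))
}

tiles_to_region_set <- function(tiles, cfg, label) {
  contigs <- contig_table(cfg)
  tiles_per_contig <- as.integer(contigs[1] / cfg$tile_bp)
  tiles <- sort(tiles)
  ci <- (tiles - 1L) %/% tiles_per_contig + 1L
  ti <- (tiles - 1L) %% tiles_per_contig
  region_set(names(contigs)[ci], as.numeric(ti) * cfg$tile_bp,
             (as.numeric(ti) + 1) * cfg$tile_bp, label = label)
}

#' Generate the synthetic region definitions
#'
#' Lays out nested exome definitions on the toy genome by sampling fixed-width
#' tiles: TCGA-like is a subset of CREv2-like, itself a subset of canonical;
#' the panel footprint is a subset of canonical disjoint from the assembly
#' gaps. Deterministic given the config seed.
#'
#' @param cfg a [cohort_config()].
#' @return List with raw `region_set`s `canonical`, `crev2`, `tcga`,
#'   `panel`, `gaps`, the precomputed merged gap-subtracted `callable` set,
#'   the `contigs` length table, and exact `lengths_mb` bookkeeping.
#' @export
generate_regions <- function(cfg) {
  withr::with_seed(substream_seed(cfg$seed, "regions"), {
    contigs <- contig_table(cfg)
    tiles_per_contig <- as.integer(contigs[1] / cfg$tile_bp)
    n_tiles <- tiles_per_contig * cfg$n_contigs
    n_can <- round(cfg$exome_fraction * n_tiles)
    can <- sort(sample.int(n_tiles, n_can))
    crev2 <- sort(sample(can, round(cfg$crev2_fraction * n_can)))
    tcga <- sort(sample(crev2, round(cfg$tcga_fraction * length(crev2))))
    panel <- sort(sample(can, round(cfg$panel_fraction * n_tiles)))
    n_gap <- round(cfg$gap_fraction * n_tiles)
    gap_pool_in <- setdiff(can, panel)
    gap_pool_out <- setdiff(seq_len(n_tiles), can)
    gaps <- sort(c(sample(gap_pool_in, min(ceiling(n_gap / 2), length(gap_pool_in))),
                   sample(gap_pool_out, min(floor(n_gap / 2), length(gap_pool_out)))))
    sets <- list(canonical = tiles_to_region_set(can, cfg, "canonical"),
                 crev2 = tiles_to_region_set(crev2, cfg, "crev2"),
                 tcga = tiles_to_region_set(tcga, cfg, "tcga"),
                 panel = tiles_to_region_set(panel, cfg, "panel"),
                 gaps = tiles_to_region_set(gaps, cfg, "gaps"))
    callable <- subtract_regions(merge_regions(sets$canonical), sets$gaps)
    callable$label <- "callable"
    c(sets,
      list(callable = callable, contigs = contigs,
           lengths_mb = c(canonical = total_length_mb(merge_regions(sets$canonical)),
                          crev2 = total_length_mb(merge_regions(sets$crev2)),
                          tcga = total_length_mb(merge_regions(sets$tcga)),
                          panel = total_length_mb(merge_regions(sets$panel)),
                          gaps = total_length_mb(merge_regions(sets$gaps)),
                          callable = total_length_mb(callable))))
  })
}

# map 1-based offsets into the callable base-pair union to (chrom, pos)
offsets_to_positions <- function(offsets, gr) {
  w <- GenomicRanges::width(gr)
  cw <- cumsum(as.numeric(w))
  i <- pmax(findInterval(offsets, c(0, cw), left.open = TRUE), 1L) # region index
  within <- offsets - c(0, cw)[i] - 1
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[i],
             pos = GenomicRanges::start(gr)[i] + within,
             stringsAsFactors = FALSE)
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

observe_site <- function(n, cfg, vaf_true = NULL) {
  depth <- pmax(stats::rpois(n, cfg$mean_depth), 1L)
  if (is.null(vaf_true)) vaf_true <- stats::rbeta(n, cfg$vaf_alpha, cfg$vaf_beta)
  alt <- stats::rbinom(n, depth, vaf_true)
  list(depth = depth, alt = alt, vaf_true = vaf_true)
}

#' Generate one synthetic paired patient
#'
#' Plants trunk mutations (written to both sites), site-private mutations,
#' trunk indels, germline contaminants (both sites, heterozygous, annotated
#' with population AFs) and threshold-violating artefacts, all uniformly
#' placed at disjoint positions in the callable region. Each call is observed
#' with Poisson depth and binomial allele counts. Also draws the patient's
#' true KRAS status/MAF, ddPCR droplet counts, PD-L1 copy numbers and a
#' tumour-cellularity QC value per site.
#'
#' @param cfg a [cohort_config()].
#' @param regions output of [generate_regions()].
#' @param patient_id patient identifier (drives the RNG substream).
#' @return List with `variant_calls` data.frames `site1` and `site2` and a
#'   `truth` list (`somatic`, `germline`, `artefact`, `assay`, `droplets`,
#'   `samples`).
#' @export
generate_patient <- function(cfg, regions, patient_id) {
  withr::with_seed(substream_seed(cfg$seed, patient_id), {
    gr <- as_granges(regions$callable)
    mb <- total_length_mb(regions$callable)
    total_bp <- total_length_bp(regions$callable)

    n_trunk <- stats::rpois(1, cfg$trunk_rate * mb)
    n_p1 <- stats::rpois(1, cfg$private_rate_site1 * mb)
    n_p2 <- stats::rpois(1, cfg$private_rate_site2 * mb)
    n_indel <- stats::rpois(1, cfg$indel_rate * mb)
    n_germ <- stats::rpois(1, cfg$germline_rate * mb)
    n_art1 <- stats::rpois(1, cfg$artefact_rate * mb)
    n_art2 <- stats::rpois(1, cfg$artefact_rate * mb)
    n_all <- n_trunk + n_p1 + n_p2 + n_indel + n_germ + n_art1 + n_art2

    # disjoint positions for everything; hash sampling avoids allocating
    # the full base-pair population
    offs <- sample.int(as.integer(total_bp), n_all, useHash = TRUE)
    posmap <- offsets_to_positions(offs, gr)
    grp <- rep(c("trunk", "p1", "p2", "indel", "germ", "art1", "art2"),
               c(n_trunk, n_p1, n_p2, n_indel, n_germ, n_art1, n_art2))

    conseq_pool <- c("exonic", "splice_site", "intronic")
    conseq_prob <- c(0.8, 0.1, 0.1)

    mk_snv <- function(idx, origin) {
      n <- length(idx)
      al <- random_snv_alleles(n)
      data.frame(chrom = posmap$chrom[idx], pos = posmap$pos[idx],
                 ref = al$ref, alt = al$alt, var_class = rep_len("SNV", n),
                 origin = rep_len(origin, n),
                 consequence = sample(conseq_pool, n, replace = TRUE,
                                      prob = conseq_prob),
                 stringsAsFactors = FALSE)
    }
    trunk <- mk_snv(which(grp == "trunk"), "trunk")
    priv1 <- mk_snv(which(grp == "p1"), "private_site1")
    priv2 <- mk_snv(which(grp == "p2"), "private_site2")
    indel <- local({
      idx <- which(grp == "indel")
      n <- length(idx)
      base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      ext <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      data.frame(chrom = posmap$chrom[idx], pos = posmap$pos[idx],
                 ref = paste0(base, ext), alt = base,
                 var_class = rep_len("indel", n),
                 origin = rep_len("trunk_indel", n),
                 consequence = sample(conseq_pool, n, replace = TRUE,
                                      prob = conseq_prob),
                 stringsAsFactors = FALSE)
    })

    germ_idx <- which(grp == "germ")
    germ_al <- random_snv_alleles(length(germ_idx))
    common <- stats::runif(length(germ_idx)) < 0.7
    germ <- data.frame(chrom = posmap$chrom[germ_idx], pos = posmap$pos[germ_idx],
                       ref = germ_al$ref, alt = germ_al$alt,
                       af = ifelse(common, stats::runif(length(germ_idx), 0.01, 0.5),
                                   stats::runif(length(germ_idx), 2e-4, 0.01)),
                       stringsAsFactors = FALSE)

    mk_artefact <- function(idx) {
      n <- length(idx)
      al <- random_snv_alleles(n)
      lowdepth <- seq_len(n) <= ceiling(n / 2)
      depth <- integer(n); alt_d <- integer(n)
      depth[lowdepth] <- sample(3:14, sum(lowdepth), replace = TRUE)
      alt_d[lowdepth] <- stats::rbinom(sum(lowdepth), depth[lowdepth],
                                       stats::runif(sum(lowdepth), 0.1, 0.4))
      nh <- sum(!lowdepth)
      depth[!lowdepth] <- pmax(stats::rpois(nh, cfg$mean_depth), 15L)
      # alt count capped strictly below the 5% VAF threshold
      cap <- pmax(ceiling(depth[!lowdepth] * 0.05) - 1L, 0L)
      alt_d[!lowdepth] <- vapply(cap, function(k) sample.int(k + 1L, 1L) - 1L,
                                 integer(1))
      data.frame(chrom = posmap$chrom[idx], pos = posmap$pos[idx],
                 ref = al$ref, alt = al$alt, depth = depth, alt_depth = alt_d,
                 kind = ifelse(lowdepth, "low_depth", "low_vaf"),
                 stringsAsFactors = FALSE)
    }
    art1 <- mk_artefact(which(grp == "art1"))
    art2 <- mk_artefact(which(grp == "art2"))

    somatic_site <- function(site, label) {
      som <- rbind(trunk, if (label == "site1") priv1 else priv2, indel)
      obs <- observe_site(nrow(som), cfg)
      som$depth <- obs$depth; som$alt_depth <- obs$alt
      som$vaf_true <- obs$vaf_true
      som$site <- label
      som
    }
    som1 <- somatic_site(1, "site1")
    som2 <- somatic_site(2, "site2")

    germ_site <- function(label) {
      obs <- observe_site(nrow(germ), cfg, vaf_true = rep(0.5, nrow(germ)))
      data.frame(germ[, c("chrom", "pos", "ref", "alt", "af")],
                 depth = obs$depth, alt_depth = obs$alt,
                 site = rep_len(label, nrow(germ)), stringsAsFactors = FALSE)
    }
    g1 <- germ_site("site1"); g2 <- germ_site("site2")

    build_calls <- function(som, g, art, label) {
      df <- rbind(
        data.frame(chrom = som$chrom, pos = som$pos, ref = som$ref,
                   alt = som$alt, depth = som$depth, alt_depth = som$alt_depth,
                   consequence = som$consequence, stringsAsFactors = FALSE),
        data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
                   depth = g$depth, alt_depth = g$alt_depth,
                   consequence = rep_len("exonic", nrow(g)),
                   stringsAsFactors = FALSE),
        data.frame(chrom = art$chrom, pos = art$pos, ref = art$ref,
                   alt = art$alt, depth = art$depth, alt_depth = art$alt_depth,
                   consequence = rep_len("exonic", nrow(art)),
                   stringsAsFactors = FALSE))
      df <- df[order(df$chrom, df$pos), , drop = FALSE]
      variant_calls(df$chrom, df$pos, df$ref, df$alt, df$depth, df$alt_depth,
                    consequence = df$consequence, sample_id = patient_id,
                    site = label)
    }
    calls1 <- build_calls(som1, g1, art1, "site1")
    calls2 <- build_calls(som2, g2, art2, "site2")

    # assays: KRAS ddPCR droplets and PD-L1 copy number, correlated across sites
    kras_pos <- stats::runif(1) < cfg$kras_positive_fraction
    if (kras_pos) {
      maf1 <- stats::runif(1, 0.01, 0.35)
      maf2 <- stats::plogis(stats::qlogis(maf1) + stats::rnorm(1, 0, 0.3))
    } else {
      maf1 <- stats::runif(1, 0, 5e-4)
      maf2 <- stats::runif(1, 0, 5e-4)
    }
    n_total <- 15000L; lam_total <- 1.2
    droplet_row <- function(maf, label) {
      lam_mut <- maf * lam_total; lam_wt <- (1 - maf) * lam_total
      data.frame(patient_id = patient_id, site = label, n_total = n_total,
                 n_mut_positive = stats::rbinom(1, n_total, 1 - exp(-lam_mut)),
                 n_wt_positive = stats::rbinom(1, n_total, 1 - exp(-lam_wt)),
                 stringsAsFactors = FALSE)
    }
    droplets <- rbind(droplet_row(maf1, "site1"), droplet_row(maf2, "site2"))
    cn1 <- 2 * 2^stats::rnorm(1, 0, 0.4)
    cn2 <- cn1 * 2^stats::rnorm(1, 0, 0.2)

    with_id <- function(df, ...) {
      extra <- lapply(list(...), rep_len, nrow(df))
      cbind(data.frame(extra, stringsAsFactors = FALSE), df)
    }
    som_cols <- c("site", "chrom", "pos", "ref", "alt", "var_class", "origin",
                  "consequence", "vaf_true", "depth", "alt_depth")
    truth_somatic <- rbind(with_id(som1[, som_cols], patient_id = patient_id),
                           with_id(som2[, som_cols], patient_id = patient_id))
    truth_germline <- rbind(with_id(g1, patient_id = patient_id),
                            with_id(g2, patient_id = patient_id))
    truth_artefact <- rbind(
      with_id(art1, patient_id = patient_id, site = "site1"),
      with_id(art2, patient_id = patient_id, site = "site2"))
    truth_assay <- data.frame(
      patient_id = patient_id, kras_status = ifelse(kras_pos, "positive", "negative"),
      kras_maf_site1 = maf1, kras_maf_site2 = maf2,
      pdl1_cn_site1 = cn1, pdl1_cn_site2 = cn2, stringsAsFactors = FALSE)
    samples <- data.frame(
      patient_id = patient_id, site = c("site1", "site2"),
      cellularity_pct = round(stats::runif(2, 15, 95)),
      true_snv_density = c(cfg$trunk_rate + cfg$private_rate_site1,
                           cfg$trunk_rate + cfg$private_rate_site2),
      stringsAsFactors = FALSE)

    list(patient_id = patient_id, site1 = calls1, site2 = calls2,
         truth = list(somatic = truth_somatic, germline = truth_germline,
                      artefact = truth_artefact, assay = truth_assay,
                      droplets = droplets, samples = samples))
  })
}

#' Generate a full synthetic paired cohort
#'
#' Builds region definitions and all patients, assembling cohort-level truth
#' tables and the cohort-wide germline resource (the union of every planted
#' contaminant with its population AF). Per-patient RNG substreams make the
#' cohort reproducible from (config, seed) alone, and adding a patient never
#' changes earlier patients' data.
#'
#' @param cfg a [cohort_config()].
#' @return A `synthetic_cohort` list: `config`, `regions`, `patients`
#'   (named list of [generate_patient()] outputs), `truth` (cohort-level
#'   tables) and `resource` (germline resource data.frame).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  regions <- generate_regions(cfg)
  ids <- sprintf("P%02d", seq_len(cfg$n_patients))
  patients <- lapply(ids, function(id) generate_patient(cfg, regions, id))
  names(patients) <- ids
  bind <- function(field) do.call(rbind, lapply(patients, function(p) p$truth[[field]]))
  truth <- list(somatic = bind("somatic"), germline = bind("germline"),
                artefact = bind("artefact"), assay = bind("assay"),
                droplets = bind("droplets"), samples = bind("samples"),
                lengths_mb = regions$lengths_mb)
  rownames(truth$somatic) <- rownames(truth$germline) <-
    rownames(truth$artefact) <- rownames(truth$assay) <-
    rownames(truth$droplets) <- rownames(truth$samples) <- NULL
  res <- truth$germline[, c("chrom", "pos", "ref", "alt", "af")]
  key <- paste(res$chrom, res$pos, res$ref, res$alt, sep = ":")
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$chrom, res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(config = cfg, regions = regions, patients = patients,
                 truth = truth, resource = res),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients x 2 sites, callable %.3f Mb, seed %d\n",
              x$config$n_patients, x$truth$lengths_mb["callable"], x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-site VCF 4.2 files, BED3 region definitions, the germline
#' resource VCF, assay TSVs (droplet counts, copy numbers), truth TSVs, a
#' sample sheet and a JSON manifest with the config and per-file MD5
#' checksums. Refuses to write into a non-empty directory unless
#' `overwrite = TRUE`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("output directory not empty: ", dir, " (use overwrite = TRUE)")
  for (d in c("", "vcf", "regions", "assays", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  contigs <- cohort$regions$contigs
  for (p in cohort$patients) {
    write_vcf(p$site1, file.path(dir, "vcf", paste0(p$patient_id, "_site1.vcf")),
              sample_name = "TUMOR", contigs = contigs)
    write_vcf(p$site2, file.path(dir, "vcf", paste0(p$patient_id, "_site2.vcf")),
              sample_name = "TUMOR", contigs = contigs)
  }
  for (nm in c("canonical", "crev2", "tcga", "panel", "gaps"))
    write_bed(cohort$regions[[nm]], file.path(dir, "regions", paste0(nm, ".bed")))
  write_germline_resource_vcf(cohort$resource,
                              file.path(dir, "germline_resource.vcf"),
                              contigs = contigs)
  wtsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                                quote = FALSE, row.names = FALSE)
  wtsv(cohort$truth$droplets, file.path(dir, "assays", "droplets.tsv"))
  cn <- rbind(
    data.frame(patient_id = cohort$truth$assay$patient_id, site = "site1",
               pdl1_cn = cohort$truth$assay$pdl1_cn_site1),
    data.frame(patient_id = cohort$truth$assay$patient_id, site = "site2",
               pdl1_cn = cohort$truth$assay$pdl1_cn_site2))
  cn <- cn[order(cn$patient_id, cn$site), ]
  wtsv(cn, file.path(dir, "assays", "copy_number.tsv"))
  for (nm in c("somatic", "germline", "artefact", "assay", "samples"))
    wtsv(cohort$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")))
  wtsv(data.frame(name = names(cohort$truth$lengths_mb),
                  mb = as.numeric(cohort$truth$lengths_mb)),
       file.path(dir, "truth", "region_lengths.tsv"))
  sheet <- cohort$truth$samples
  sheet$vcf <- file.path("vcf", paste0(sheet$patient_id, "_", sheet$site, ".vcf"))
  wtsv(sheet, file.path(dir, "samples.tsv"))
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    config = unclass(cohort$config),
    files = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
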