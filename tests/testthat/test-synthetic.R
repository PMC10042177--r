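test_that("cohort configuration validates rates and fractions", {
  expect_error(cohort_config(trunk_rate = -1), "rates")
  expect_error(cohort_config(exome_fraction = 0), "fractions")
  expect_error(cohort_config(panel_fraction = 0.4, gap_fraction = 0.2,
                             exome_fraction = 0.5), "exceed")
  expect_error(cohort_config(n_patients = 0), "n_patients")
})

test_that("region definitions are nested and sized as configured", {
  cfg <- small_cohort_config(seed = 5)
  r <- generate_regions(cfg)
  within <- function(inner, outer) {
    d <- subtract_regions(merge_regions(inner), merge_regions(outer))
    total_length_bp(d) == 0
  }
  expect_true(within(r$tcga, r$crev2))
  expect_true(within(r$crev2, r$canonical))
  expect_true(within(r$panel, r$canonical))
  # panel is laid out clear of the assembly gaps
  ov <- GenomicRanges::intersect(as_granges(merge_regions(r$panel)),
                                 as_granges(merge_regions(r$gaps)))
  expect_equal(sum(GenomicRanges::width(ov)), 0L)
  expect_equal(r$lengths_mb[["canonical"]],
               cfg$exome_fraction * cfg$genome_length_bp / 1e6,
               tolerance = 0.01)
  expect_equal(r$lengths_mb[["callable"]],
               total_length_mb(r$callable))
})

test_that("cohorts are deterministic and patient substreams are stable", {
  cfg <- small_cohort_config(seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$patients$P01$site1, b$patients$P01$site1)

  bigger <- generate_cohort(cohort_config(n_patients = 5, genome_length_bp = 4e6,
                                          seed = 9))
  expect_identical(bigger$patients$P02, a$patients$P02)
})

test_that("trunk mutations are shared and private sets are disjoint", {
  co <- generate_cohort(small_cohort_config(seed = 13))
  tr <- co$truth$somatic
  for (pid in unique(tr$patient_id)) {
    p <- tr[tr$patient_id == pid, ]
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
    t1 <- key(p[p$site == "site1" & p$origin == "trunk", ])
    t2 <- key(p[p$site == "site2" & p$origin == "trunk", ])
    expect_setequal(t1, t2)
    p1 <- key(p[p$origin == "private_site1", ])
    p2 <- key(p[p$origin == "private_site2", ])
    expect_length(intersect(p1, p2), 0)
    expect_length(intersect(p1, t1), 0)
    expect_length(intersect(p2, t1), 0)
  }
})

test_that("every somatic VCF record is in the truth table and vice versa", {
  co <- generate_cohort(small_cohort_config(seed = 17))
  for (p in co$patients) {
    for (site in c("site1", "site2")) {
      calls <- p[[site]]
      tt <- co$truth
      som <- tt$somatic[tt$somatic$patient_id == p$patient_id &
                          tt$somatic$site == site, ]
      germ <- tt$germline[tt$germline$patient_id == p$patient_id &
                            tt$germline$site == site, ]
      art <- tt$artefact[tt$artefact$patient_id == p$patient_id &
                           tt$artefact$site == site, ]
      key <- function(d) sort(paste(d$chrom, d$pos, d$ref, d$alt))
      expect_identical(key(calls), key(rbind(som[, c("chrom", "pos", "ref", "alt")],
                                             germ[, c("chrom", "pos", "ref", "alt")],
                                             art[, c("chrom", "pos", "ref", "alt")])))
    }
  }
})

test_that("with no private mutations or artefacts both sites carry identical records", {
  cfg <- cohort_config(n_patients = 2, genome_length_bp = 4e6,
                       private_rate_site1 = 0, private_rate_site2 = 0,
                       artefact_rate = 0, seed = 21)
  co <- generate_cohort(cfg)
  for (p in co$patients) {
    key <- function(calls) sort(paste(calls$chrom, calls$pos, calls$ref, calls$alt))
    expect_identical(key(p$site1), key(p$site2))
  }
})

test_that("planted trunk counts match the Poisson expectation", {
  cfg <- cohort_config(n_patients = 1, genome_length_bp = 2e6, trunk_rate = 8,
                       seed = 25)
  regions <- generate_regions(cfg)
  mb <- total_length_mb(regions$callable)
  counts <- vapply(1:200, function(i) {
    p <- generate_patient(cfg, regions, sprintf("T%03d", i))
    sum(p$truth$somatic$origin == "trunk" & p$truth$somatic$site == "site1")
  }, numeric(1))
  expected <- cfg$trunk_rate * mb
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("planted artefacts always violate the quality thresholds", {
  co <- generate_cohort(small_cohort_config(seed = 29))
  art <- co$truth$artefact
  vaf <- art$alt_depth / art$depth
  expect_true(all(art$depth < 15 | vaf < 0.05))
  # and germline AFs all exceed the population-AF cut-off
  expect_true(all(co$truth$germline$af > 1e-4))
})

test_that("a written cohort round-trips losslessly and refuses dirty directories", {
  co <- generate_cohort(cohort_config(n_patients = 2, genome_length_bp = 4e6,
                                      seed = 33))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, overwrite = TRUE)
  expect_error(write_cohort(co, dir), "not empty")

  # VCF round-trip: parsed calls equal the in-memory calls
  for (p in co$patients) {
    back <- read_vcf(file.path(dir, "vcf", paste0(p$patient_id, "_site1.vcf")))
    expect_equal(attr(back, "parse_report")$n_missing_depth, 0L)
    o1 <- p$site1[order(p$site1$chrom, p$site1$pos, p$site1$alt), ]
    o2 <- back[order(back$chrom, back$pos, back$alt), ]
    expect_equal(o2$pos, o1$pos)
    expect_equal(o2$depth, o1$depth)
    expect_equal(o2$alt_depth, o1$alt_depth)
    expect_equal(o2$consequence, o1$consequence)
  }
  # BED round-trip preserves the merged region sets
  for (nm in c("canonical", "panel", "gaps")) {
    back <- merge_regions(load_bed(file.path(dir, "regions", paste0(nm, ".bed"))))
    expect_identical(as_granges(back),
                     as_granges(merge_regions(co$regions[[nm]])))
  }
  # germline resource round-trip
  res <- tmbpair:::read_germline_resource(file.path(dir, "germline_resource.vcf"))
  expect_equal(nrow(res), nrow(co$resource))
  expect_equal(sort(res$af), sort(co$resource$af), tolerance = 1e-8)
  # manifest checksums describe the files on disk
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  f <- names(man$files)[1]
  expect_equal(unname(tools::md5sum(file.path(dir, f))), man$files[[f]])
})

test_that("the filtered pipeline recovers exactly the planted somatic SNVs", {
  co <- generate_cohort(small_cohort_config(seed = 37, mean_depth = 500))
  for (p in co$patients[1:2]) {
    calls <- annotate_known(p$site1, co$resource)
    kept <- germline_filter(wgs_quality_filter(calls))
    truth <- co$truth$somatic
    planted <- truth[truth$patient_id == p$patient_id & truth$site == "site1" &
                       truth$var_class == "SNV", ]
    # at 500x every planted SNV clears depth/VAF thresholds with margin
    clears <- planted[planted$alt_depth / planted$depth >= 0.05 &
                        planted$depth >= 15, ]
    expect_setequal(paste(kept$chrom, kept$pos, kept$ref, kept$alt),
                    paste(clears$chrom, clears$pos, clears$ref, clears$alt))
  }
})

test_that("planted KRAS positives are recoverable from droplet counts", {
  co <- generate_cohort(cohort_config(n_patients = 10, genome_length_bp = 2e6,
                                      seed = 41))
  dro <- co$truth$droplets
  maf <- ddpcr_fractional_abundance(dro$n_total, dro$n_mut_positive,
                                    dro$n_wt_positive)
  status <- ifelse(maf[dro$site == "site1"] >= 0.002, "positive", "negative")
  expect_equal(status, co$truth$assay$kras_status)
})
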