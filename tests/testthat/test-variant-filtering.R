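make_call <- function(depth, alt_depth, ref = "A", alt = "T", pos = 100,
                      consequence = "exonic", known_snp = FALSE,
                      pop_af = NA_real_) {
  variant_calls("syn1", pos, ref, alt, depth, alt_depth,
                consequence = consequence, known_snp = known_snp,
                pop_af = pop_af)
}

test_that("variant_calls derives VAF and variant class and validates depths", {
  v <- make_call(50, 10)
  expect_equal(v$vaf, 0.2)
  expect_equal(v$var_class, "SNV")
  expect_equal(make_call(40, 4, ref = "AT", alt = "A")$var_class, "indel")
  expect_equal(make_call(40, 4, ref = "AT", alt = "GC")$var_class, "MNV")
  expect_equal(make_call(0, 0)$vaf, 0)
  expect_error(make_call(10, 11), "alt_depth")
  expect_error(variant_calls("syn1", 5, "A", "T", -1, 0), "depth")
})

test_that("read_vcf recovers DP/AD, splits multi-allelics and reports parsing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tT\t.\tPASS\tCONSEQ=splice_site\tGT:DP:AD\t0/1:50:40,10",
    "chr1\t200\t.\tG\tT,C\t.\tPASS\t.\tGT:DP:AD\t0/1:60:30,20,10",
    "chr1\t300\t.\tC\tA\t.\tlowqual\t.\tGT:DP:AD\t0/1:99:0,99",
    "chr1\t400\t.\tT\tG\t.\tPASS\t.\tGT\t0/1"), vcf)
  calls <- read_vcf(vcf)
  rep <- attr(calls, "parse_report")
  expect_equal(nrow(calls), 4L)            # multi-allelic split, non-PASS dropped
  expect_equal(calls$vaf[calls$pos == 100], 0.2)
  expect_equal(calls$consequence[calls$pos == 100], "splice_site")
  expect_equal(sum(calls$pos == 200), 2L)
  expect_equal(sort(calls$alt_depth[calls$pos == 200]), c(10L, 20L))
  expect_equal(calls$depth[calls$pos == 400], 0L)  # no depth info anywhere
  expect_equal(rep$n_missing_depth, 1L)
  expect_equal(rep$n_multiallelic, 1L)
  expect_equal(rep$n_dropped_filter, 1L)

  kept <- read_vcf(vcf, keep_filtered = TRUE)
  expect_equal(nrow(kept), 5L)
})

test_that("WGS quality filter applies >= threshold semantics", {
  cfg <- filter_config()
  expect_equal(nrow(wgs_quality_filter(make_call(14, 7), cfg)), 0L)   # depth < 15
  expect_equal(nrow(wgs_quality_filter(make_call(15, 7), cfg)), 1L)   # at threshold kept
  expect_equal(nrow(wgs_quality_filter(make_call(100, 4), cfg)), 0L)  # vaf 0.04 < 0.05
  expect_equal(nrow(wgs_quality_filter(make_call(100, 5), cfg)), 1L)  # vaf exactly 0.05
  expect_equal(nrow(wgs_quality_filter(make_call(100, 49, ref = "AT", alt = "A"), cfg)),
               0L)                                                    # SNV-only default
  loose <- filter_config(wgs_snv_only = FALSE)
  expect_equal(nrow(wgs_quality_filter(make_call(100, 49, ref = "AT", alt = "A"), loose)),
               1L)
})

test_that("germline filter removes known SNPs and high population AF only", {
  cfg <- filter_config()
  expect_equal(nrow(germline_filter(make_call(50, 25, pop_af = 0.001), cfg)), 0L)
  expect_equal(nrow(germline_filter(make_call(50, 25, pop_af = 1e-4), cfg)), 1L)  # at cut-off kept
  expect_equal(nrow(germline_filter(make_call(50, 25), cfg)), 1L)                 # unannotated kept
  expect_equal(nrow(germline_filter(make_call(50, 25, known_snp = TRUE), cfg)), 0L)
})

test_that("annotate_known matches on full allele identity", {
  res <- data.frame(chrom = "syn1", pos = 100L, ref = "A", alt = "T", af = 0.3)
  hit <- annotate_known(make_call(50, 10), res)
  expect_true(hit$known_snp)
  expect_equal(hit$pop_af, 0.3)
  miss_alt <- annotate_known(make_call(50, 10, alt = "G"), res)
  expect_false(miss_alt$known_snp)
  miss_pos <- annotate_known(make_call(50, 10, pos = 101), res)
  expect_false(miss_pos$known_snp)
})

test_that("panel filter enforces class, consequence, coverage and LOD rules", {
  cfg <- filter_config()
  expect_equal(nrow(panel_filter(make_call(500, 200, ref = "ATG", alt = "A"), cfg)),
               0L)                                                       # indel excluded
  expect_equal(nrow(panel_filter(make_call(59, 30), cfg)), 0L)           # < 60x
  expect_equal(nrow(panel_filter(make_call(60, 30), cfg)), 1L)
  expect_equal(nrow(panel_filter(make_call(100, 4), cfg)), 0L)           # < 5% LOD
  expect_equal(nrow(panel_filter(make_call(100, 30, consequence = "other"), cfg)),
               0L)
  expect_equal(nrow(panel_filter(make_call(100, 30, consequence = "intronic"), cfg)),
               1L)
  expect_equal(nrow(panel_filter(make_call(100, 30, pop_af = 0.01), cfg)), 0L)
})

test_that("filters equal the predicate oracle on randomised calls", {
  set.seed(404)
  cfg <- filter_config()
  for (i in 1:5) {
    calls <- random_calls(200)
    expect_identical(call_keys(wgs_quality_filter(calls, cfg)),
                     call_keys(calls[oracle_wgs_keep(calls, cfg), ]))
    expect_identical(call_keys(germline_filter(calls, cfg)),
                     call_keys(calls[oracle_germline_keep(calls, cfg), ]))
    expect_identical(call_keys(panel_filter(calls, cfg)),
                     call_keys(calls[oracle_panel_keep(calls, cfg), ]))
  }
})

test_that("filter order does not matter and tallies conserve counts", {
  set.seed(505)
  calls <- random_calls(300)
  cfg <- filter_config()
  ab <- germline_filter(wgs_quality_filter(calls, cfg), cfg)
  ba <- wgs_quality_filter(germline_filter(calls, cfg), cfg)
  expect_setequal(call_keys(ab), call_keys(ba))

  for (f in list(wgs_quality_filter, germline_filter, panel_filter)) {
    out <- f(calls, cfg)
    tl <- filter_tally(out)
    expect_equal(unname(tl["kept"] + sum(tl[setdiff(names(tl), c("input", "kept"))])),
                 unname(tl["input"]))
    expect_equal(unname(tl["input"]), nrow(calls))
    expect_equal(unname(tl["kept"]), nrow(out))
  }
})

test_that("raising any threshold never increases the kept set", {
  set.seed(606)
  calls <- random_calls(400)
  n_kept <- function(f, ...) nrow(f(calls, filter_config(...)))
  for (d in c(0, 10, 15, 30, 60, 100))
    expect_lte(n_kept(wgs_quality_filter, min_depth = d + 5),
               n_kept(wgs_quality_filter, min_depth = d))
  for (v in c(0, 0.02, 0.05, 0.2))
    expect_lte(n_kept(wgs_quality_filter, min_vaf = v + 0.05),
               n_kept(wgs_quality_filter, min_vaf = v))
  for (cv in c(0, 30, 60, 120))
    expect_lte(n_kept(panel_filter, panel_min_coverage = cv + 20),
               n_kept(panel_filter, panel_min_coverage = cv))
  for (a in c(0, 0.02, 0.05, 0.2))
    expect_lte(n_kept(panel_filter, panel_min_af = a + 0.05),
               n_kept(panel_filter, panel_min_af = a))
})

test_that("filtered calls round-trip through write_vcf/read_vcf", {
  set.seed(707)
  calls <- random_calls(50)
  calls <- calls[calls$depth > 0, ]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, vcf, contigs = c(syn1 = 1e5, syn2 = 1e5))
  back <- read_vcf(vcf)
  expect_setequal(call_keys(back), call_keys(calls))
  o1 <- calls[order(call_keys(calls)), ]
  o2 <- back[order(call_keys(back)), ]
  expect_equal(o2$depth, o1$depth)
  expect_equal(o2$alt_depth, o1$alt_depth)
  expect_equal(o2$consequence, o1$consequence)
})
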