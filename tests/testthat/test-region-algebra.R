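test_that("load_bed parses records in file order and validates coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t50\t150", "chr2\t0\t10"), bed)
  rs <- load_bed(bed)
  expect_equal(n_intervals(rs), 3L)
  expect_equal(total_length_bp(rs), 210)  # raw, un-merged: 100 + 100 + 10
  expect_false(rs$merged)

  empty <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), empty)
  e <- load_bed(empty)
  expect_equal(n_intervals(e), 0L)
  expect_equal(total_length_mb(e), 0)

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t100"), bad)
  expect_error(load_bed(bad), "line 2")

  short <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1 only-two-fields"), short)
  expect_error(load_bed(short), "line 2")

  tracked <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("browser position chr1", "track name=y", "# comment",
               "chr1\t10\t20"), tracked)
  expect_equal(n_intervals(load_bed(tracked)), 1L)
})

test_that("merge coalesces overlapping and book-ended intervals and is idempotent", {
  m1 <- merge_regions(region_set("chr1", c(0, 50), c(100, 150)))
  expect_equal(n_intervals(m1), 1L)
  expect_equal(total_length_bp(m1), 150)

  # book-ended intervals coalesce (bedtools merge default)
  m2 <- merge_regions(region_set("chr1", c(0, 100), c(100, 200)))
  expect_equal(n_intervals(m2), 1L)
  expect_equal(total_length_bp(m2), 200)

  set.seed(101)
  for (i in 1:10) {
    rs <- random_region_set(50, c(toy = 10000), max_width = 400)
    m <- merge_regions(rs)
    expect_identical(as_granges(merge_regions(m)), as_granges(m))
  }
})

test_that("subtract removes exactly the gap base pairs", {
  a <- merge_regions(region_set("chr1", 0, 100))
  g <- merge_regions(region_set("chr1", 40, 60))
  d <- subtract_regions(a, g)
  expect_equal(n_intervals(d), 2L)
  expect_equal(total_length_bp(d), 80)
  expect_equal(GenomicRanges::start(as_granges(d)), c(1L, 61L))

  expect_equal(total_length_bp(subtract_regions(a, a)), 0)
  expect_equal(total_length_bp(subtract_regions(a, region_set(character(), integer(), integer()))),
               100)
})

test_that("total_length_mb uses exactly 1e6 bp per Mb", {
  expect_equal(total_length_mb(region_set("chr1", 0, 1e6)), 1.0)
  expect_equal(total_length_mb(region_set(character(), integer(), integer())), 0)
})

test_that("region membership is half-open and false off-set", {
  rs <- merge_regions(region_set("chr1", 0, 100))
  expect_true(region_contains(rs, "chr1", 0))
  expect_true(region_contains(rs, "chr1", 99))
  expect_false(region_contains(rs, "chr1", 100))
  expect_false(region_contains(rs, "chrUnknown", 50))
})

test_that("merge/subtract/contains agree with mask and linear-scan oracles", {
  set.seed(202)
  lens <- c(toyA = 50000, toyB = 30000)
  for (i in 1:30) {
    a <- random_region_set(sample(5:120, 1), lens)
    b <- random_region_set(sample(5:120, 1), lens)
    ma <- region_mask(a, lens); mb <- region_mask(b, lens)
    am <- merge_regions(a)
    expect_equal(total_length_bp(am), mask_total(ma))
    d <- subtract_regions(a, b)
    diff_mask <- mapply(function(x, y) x & !y, ma, mb, SIMPLIFY = FALSE)
    expect_equal(total_length_bp(d), mask_total(diff_mask))
    # |A \ B| = |A| - |A intersect B|
    int_mask <- mapply(`&`, ma, mb, SIMPLIFY = FALSE)
    expect_equal(total_length_bp(d),
                 mask_total(ma) - mask_total(int_mask))
    qc <- sample(names(lens), 40, replace = TRUE)
    qp <- floor(runif(40, 0, lens[qc]))
    expect_identical(region_contains(am, qc, qp), linear_contains(a, qc, qp))
  }
})

test_that("BED writing round-trips through load_bed", {
  set.seed(303)
  rs <- merge_regions(random_region_set(40, c(chrZ = 20000)))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, bed)
  back <- merge_regions(load_bed(bed))
  expect_identical(as_granges(back), as_granges(rs))
})

test_that("chr-prefix harmonisation strips and adds the prefix explicitly", {
  rs <- region_set(c("chr1", "chr2"), c(0, 0), c(10, 10))
  stripped <- harmonise_chr(rs, "strip")
  expect_setequal(as.character(GenomicRanges::seqnames(as_granges(stripped))),
                  c("1", "2"))
  back <- harmonise_chr(stripped, "add")
  expect_setequal(as.character(GenomicRanges::seqnames(as_granges(back))),
                  c("chr1", "chr2"))
  expect_identical(harmonise_chr(rs, "asis"), rs)
})
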