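#' Construct a region set
#'
#' A `region_set` is an ordered collection of genomic intervals with a label
#' naming the definition it represents (e.g. `"canonical"`, `"crev2"`,
#' `"tcga"`, `"panel"`, `"gaps"`). Coordinates are supplied in BED convention
#' (0-based, half-open); internally the intervals are held as a
#' [GenomicRanges::GRanges] (1-based, closed), the standard container in the
#' Bioconductor ecosystem. Conversion happens only at construction and at
#' BED input/output, so both conventions are preserved bit-exactly.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts (bp).
#' @param end integer vector, 0-based exclusive ends (bp); must satisfy
#'   `start < end`.
#' @param label single string naming the definition.
#' @return An object of class `region_set`.
#' @examples
#' rs <- region_set("chr1", c(0, 50), c(100, 150), label = "toy")
#' total_length_bp(rs)
#' @export
region_set <- function(chrom, start, end, label = "regions") {
  stopifnot(length(start) == length(end))
  chrom <- rep_len(as.character(chrom), length(start))
  if (length(chrom) > 0L) {
    if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
    if (any(start < 0)) stop("interval starts must be >= 0")
    if (any(start >= end)) {
      bad <- which(start >= end)[1L]
      stop(sprintf("invalid interval %s:%d-%d (start must be < end)",
                   chrom[bad], start[bad], end[bad]))
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges   = IRanges::IRanges(start = as.numeric(start) + 1, end = as.numeric(end))
  )
  new_region_set(gr, label)
}

new_region_set <- function(gr, label, merged = FALSE) {
  structure(list(gr = gr, label = as.character(label)[1L], merged = isTRUE(merged)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d interval(s), %s bp (%.4f Mb)%s\n",
              x$label, length(x$gr), format(total_length_bp(x), big.mark = ","),
              total_length_mb(x), if (x$merged) ", merged" else ""))
  invisible(x)
}

#' Extract the underlying GRanges of a region set
#' @param regions a `region_set`.
#' @return A [GenomicRanges::GRanges].
#' @export
as_granges <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  regions$gr
}

#' Number of intervals in a region set
#' @param regions a `region_set`.
#' @export
n_intervals <- function(regions) length(as_granges(regions))

#' Read a BED file into a region set
#'
#' Reads BED3+ (tab-separated; `track`, `browser` and `#` comment lines are
#' skipped) and returns the records in file order, un-merged. Only the first
#' three columns are used.
#'
#' @param path path to a BED file.
#' @param label definition label; defaults to the file name without extension.
#' @return A `region_set` of raw (un-merged) intervals.
#' @export
load_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(new_region_set(GenomicRanges::GRanges(), label))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated fields",
                 bad, path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("malformed BED line %d in %s: coordinates are not integers",
                 bad, path))
  }
  if (any(start < 0) || any(start >= end)) {
    bad <- idx[which(start < 0 | start >= end)[1L]]
    stop(sprintf("invalid interval on BED line %d in %s: start must satisfy 0 <= start < end",
                 bad, path))
  }
  region_set(chrom, start, end, label = label)
}

#' Write a region set as BED3
#'
#' Intervals are written sorted by (chrom, start) in 0-based half-open
#' coordinates.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::sort(as_granges(regions), ignore.strand = TRUE)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0L) {
    writeLines(sprintf("%s\t%d\t%d", df$chrom, df$start, df$end), con)
  }
  invisible(path)
}

#' Merge a region set into disjoint sorted intervals
#'
#' Produces the minimal sorted set of disjoint intervals covering exactly the
#' same base pairs. Overlapping and book-ended intervals (one ending where the
#' next begins) coalesce, matching the default behaviour of `bedtools merge`.
#' Idempotent.
#'
#' @param regions a `region_set`.
#' @return A merged `region_set` with the same label.
#' @export
merge_regions <- function(regions) {
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_granges(regions), ignore.strand = TRUE),
                              ignore.strand = TRUE)
  new_region_set(gr, regions$label, merged = TRUE)
}

#' Subtract one region set from another
#'
#' Returns the base pairs present in `regions` and absent from `gaps`, as
#' merged intervals. Subtracting an empty set is the identity (up to merging).
#'
#' @param regions a `region_set` (e.g. an exome definition).
#' @param gaps a `region_set` to remove (e.g. assembly gaps).
#' @return A merged `region_set` labelled as `regions`.
#' @export
subtract_regions <- function(regions, gaps) {
  a <- as_granges(merge_regions(regions))
  b <- as_granges(merge_regions(gaps))
  out <- suppressWarnings(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
  new_region_set(out, regions$label, merged = TRUE)
}

#' Total length of a region set in base pairs
#' @param regions a `region_set`.
#' @export
total_length_bp <- function(regions) {
  sum(as.numeric(GenomicRanges::width(as_granges(regions))))
}

#' Total length of a region set in megabases
#'
#' One megabase is exactly 1e6 bp. For un-merged sets this is the raw sum of
#' interval lengths; merge first to obtain the size of the base-pair union.
#'
#' @param regions a `region_set`.
#' @return Length in Mb (double).
#' @export
total_length_mb <- function(regions) total_length_bp(regions) / 1e6

#' Test positions for membership in a region set
#'
#' @param regions a merged `region_set`.
#' @param chrom chromosome name(s).
#' @param pos_0based 0-based position(s); recycled against `chrom`.
#' @return Logical vector: `TRUE` where some interval satisfies
#'   `start <= pos < end` (half-open semantics).
#' @export
region_contains <- function(regions, chrom, pos_0based) {
  n <- max(length(chrom), length(pos_0based))
  chrom <- rep_len(as.character(chrom), n)
  pos1 <- rep_len(as.numeric(pos_0based), n) + 1  # to 1-based
  gr <- as_granges(regions)
  if (n == 0L || length(gr) == 0L) return(rep(FALSE, n))
  if (!regions$merged) gr <- GenomicRanges::reduce(
    GenomicRanges::sort(gr, ignore.strand = TRUE), ignore.strand = TRUE)
  grch <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  out <- logical(n)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ri <- which(grch == ch)
    if (length(ri) == 0L) next
    o <- order(st[ri])
    s <- st[ri][o]; e <- en[ri][o]
    j <- findInterval(pos1[qi], s)          # binary search: disjoint sorted
    out[qi] <- j >= 1L & pos1[qi] <= e[pmax(j, 1L)]
  }
  out
}

#' Harmonise chromosome-name dialects
#'
#' Chromosome names are otherwise compared verbatim; this utility optionally
#' strips or adds a `"chr"` prefix so that e.g. a `"1"`-style VCF can be
#' intersected with a `"chr1"`-style BED. No silent harmonisation is ever
#' applied elsewhere.
#'
#' @param regions a `region_set`.
#' @param action one of `"asis"`, `"strip"` (remove a leading `"chr"`), or
#'   `"add"` (prepend `"chr"` where absent).
#' @return A `region_set` with renamed seqlevels.
#' @export
harmonise_chr <- function(regions, action = c("asis", "strip", "add")) {
  action <- match.arg(action)
  if (action == "asis") return(regions)
  gr <- as_granges(regions)
  lv <- GenomeInfoDb::seqlevels(gr)
  new <- switch(action,
                strip = sub("^chr", "", lv),
                add   = ifelse(grepl("^chr", lv), lv, paste0("chr", lv)))
  GenomeInfoDb::seqlevels(gr) <- new
  new_region_set(gr, regions$label, merged = regions$merged)
}
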