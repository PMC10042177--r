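# Independent oracles used across the suite. These deliberately avoid the
# package's own interval/statistics code paths: regions are checked against
# per-base boolean masks, filters against direct predicate re-evaluation,
# and the exact tests against full enumeration.

# ---- interval oracles -------------------------------------------------------

# per-chromosome boolean occupancy mask of a region_set (0-based half-open)
region_mask <- function(rs, chrom_lengths) {
  gr <- as_granges(rs)
  masks <- lapply(names(chrom_lengths), function(ch) {
    m <- logical(chrom_lengths[[ch]])
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    for (i in which(sel)) {
      s <- GenomicRanges::start(gr)[i]      # 1-based
      e <- GenomicRanges::end(gr)[i]
      m[s:e] <- TRUE
    }
    m
  })
  names(masks) <- names(chrom_lengths)
  masks
}

mask_total <- function(masks) sum(vapply(masks, sum, numeric(1)))

random_region_set <- function(n, chrom_lengths, max_width = 500,
                              label = "rand") {
  ch <- sample(names(chrom_lengths), n, replace = TRUE)
  len <- chrom_lengths[ch]
  start <- floor(runif(n, 0, len - 1))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  end <- pmin(start + width, len)
  region_set(ch, start, end, label = label)
}

# linear-scan membership, no sorting or trees
linear_contains <- function(rs, chrom, pos0) {
  gr <- as_granges(rs)
  chs <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr) - 1  # back to 0-based
  en <- GenomicRanges::end(gr)        # exclusive
  vapply(seq_along(chrom), function(i)
    any(chs == chrom[i] & st <= pos0[i] & pos0[i] < en),
    logical(1))
}

# ---- random variant calls ---------------------------------------------------

random_calls <- function(n, chroms = c("syn1", "syn2"), max_pos = 1e5) {
  classes <- sample(c("SNV", "indel", "MNV"), n, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
  ref <- character(n); alt <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    if (classes[i] == "SNV") {
      ref[i] <- sample(bases, 1); alt[i] <- sample(setdiff(bases, ref[i]), 1)
    } else if (classes[i] == "MNV") {
      ref[i] <- paste(sample(bases, 2, TRUE), collapse = "")
      alt[i] <- paste(sample(bases, 2, TRUE), collapse = "")
      if (alt[i] == ref[i]) alt[i] <- chartr("ACGT", "TGCA", ref[i])
    } else {
      ref[i] <- paste(sample(bases, 3, TRUE), collapse = ""); alt[i] <- sample(bases, 1)
    }
  }
  depth <- sample(0:200, n, replace = TRUE)
  alt_depth <- vapply(depth, function(d) sample.int(d + 1L, 1L) - 1L, integer(1))
  calls <- variant_calls(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE),
    ref = ref, alt = alt, depth = depth, alt_depth = alt_depth,
    consequence = sample(c("exonic", "splice_site", "intronic", "other"),
                         n, replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1)))
  calls$known_snp <- runif(n) < 0.2
  calls$pop_af <- ifelse(runif(n) < 0.5, NA_real_, 10^runif(n, -6, -0.5))
  calls
}

# direct re-evaluation of filter predicates, independent of apply_filter()
oracle_wgs_keep <- function(calls, cfg) {
  (if (cfg$wgs_snv_only) calls$var_class == "SNV" else TRUE) &
    calls$depth >= cfg$min_depth & calls$vaf >= cfg$min_vaf
}
oracle_germline_keep <- function(calls, cfg) {
  !(calls$known_snp %in% TRUE) &
    !(!is.na(calls$pop_af) & calls$pop_af > cfg$max_pop_af)
}
oracle_panel_keep <- function(calls, cfg) {
  (if (cfg$exclude_indels) calls$var_class == "SNV" else TRUE) &
    calls$consequence %in% cfg$allowed_consequences &
    calls$depth >= cfg$panel_min_coverage &
    calls$vaf >= cfg$panel_min_af &
    oracle_germline_keep(calls, cfg)
}

call_keys <- function(calls) paste(calls$chrom, calls$pos, calls$ref, calls$alt)

# ---- enumeration oracles for the exact tests --------------------------------

# all permutations of 1..n, plain recursion (independent of the package)
enum_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in enum_perms(n - 1L)) {
    for (j in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = j - 1L)
    }
  }
  out
}

spearman_enum_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  hits <- 0L; total <- 0L
  for (p in enum_perms(n)) {
    total <- total + 1L
    if (abs(cor(rx, ry[p])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxon_enum_p <- function(x, y) {
  d <- (x - y); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}

# reorder/subset a region_set's intervals through the public constructor
rs_subset <- function(rs, idx, label = rs$label) {
  gr <- as_granges(rs)[idx]
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
             label = label)
}

small_cohort_config <- function(seed, ...) {
  cohort_config(n_patients = 3, genome_length_bp = 4e6, seed = seed, ...)
}
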