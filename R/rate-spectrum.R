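#' @include AllClasses.R
NULL

#' Count callable bases
#'
#' Number of positions in a sample's depth track covered by `lo` to `hi`
#' reads (inclusive) — the denominator n_bp of the mutation-rate estimator.
#'
#' @param depth a [DepthTrackSet-class].
#' @param sample sample id.
#' @param chrom chromosome name.
#' @param lo,hi inclusive depth bounds (default 10 and 200).
#' @return integer count of callable bases.
#' @export
countCallable <- function(depth, sample, chrom, lo = 10, hi = 200) {
  r <- depthTrack(depth, sample, chrom)
  sum(runLength(r)[runValue(r) >= lo & runValue(r) <= hi])
}

#' Reconcile replicate variant counts
#'
#' When the variant counts of the replicates of an isogenic line do not
#' match, the higher count is used.
#'
#' @param counts integer vector of per-replicate variant counts (>= 1 value).
#' @return the maximum count.
#' @export
reconcileReplicates <- function(counts) {
  if (length(counts) == 0L) stop("input error: no replicate counts")
  max(counts)
}

#' Per-base per-generation diploid mutation rate
#'
#' `u = n_var / (n_bp * g)`. Because an isogenized chromosome harvests half
#' of the genetic variation of a diploid individual, n_bp (not 2 n_bp) is
#' used, so u corresponds to the per-base rate in a diploid genome.
#'
#' @param n_var mutation count (both homozygous and heterozygous calls).
#' @param n_bp callable bases (covered by 10-200 reads).
#' @param g generations (integer >= 1).
#' @return the rate u.
#' @export
estimateRate <- function(n_var, n_bp, g) {
  if (any(n_bp <= 0)) stop("domain error: n_bp must be > 0")
  if (any(g < 1)) stop("domain error: g must be >= 1")
  n_var / (n_bp * g)
}

#' Aggregate per-line rate estimates
#'
#' @param u numeric vector of per-line rates.
#' @return list with `mean`, `se` (sample standard deviation / sqrt(n)),
#'   `sd` and `n_lines`.
#' @export
aggregateRates <- function(u) {
  n <- length(u)
  list(mean = mean(u), se = if (n > 1L) sd(u) / sqrt(n) else NA_real_,
       sd = if (n > 1L) sd(u) else NA_real_, n_lines = n)
}

#' Classify variants by mutation class
#'
#' SNPs are split into the deaminase signature (C>T or G>A) versus other
#' substitutions; length changes are insertions or deletions; equal-length
#' multi-base changes are MNPs.
#'
#' @param ref,alt allele strings.
#' @return character vector over `CtoT_GtoA`, `other_SNP`, `insertion`,
#'   `deletion`, `MNP`.
#' @export
classifyVariant <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  out <- character(length(ref))
  snp <- nr == 1L & na == 1L
  deam <- snp & ((ref == "C" & alt == "T") | (ref == "G" & alt == "A"))
  out[snp] <- "other_SNP"
  out[deam] <- "CtoT_GtoA"
  out[nr < na] <- "insertion"
  out[nr > na] <- "deletion"
  out[nr == na & nr > 1L] <- "MNP"
  out
}

#' Deaminase-signature fraction of a private variant set
#'
#' Fraction of C>T / G>A changes among SNPs and among all variants, both
#' reported (with one-decimal half-up percentages, matching the reporting
#' style of mutation-accumulation studies).
#'
#' @param pvs a [PrivateVariantSet-class] (or a data.frame with `ref`,
#'   `alt`).
#' @return list with counts (`n_deam`, `n_snp`, `n_total`), fractions
#'   (`frac_of_snps`, `frac_of_all`), percentages (`pct_of_snps`,
#'   `pct_of_all`) and `defined` (FALSE when the set is empty, in which case
#'   fractions are NA, not 0).
#' @export
spectrumFraction <- function(pvs) {
  df <- if (is(pvs, "PrivateVariantSet")) pvs@variants else pvs
  n_total <- nrow(df)
  if (n_total == 0L)
    return(list(n_deam = 0L, n_snp = 0L, n_total = 0L,
                frac_of_snps = NA_real_, frac_of_all = NA_real_,
                pct_of_snps = NA_real_, pct_of_all = NA_real_,
                defined = FALSE))
  cls <- classifyVariant(df$ref, df$alt)
  n_snp <- sum(cls %in% c("CtoT_GtoA", "other_SNP"))
  n_deam <- sum(cls == "CtoT_GtoA")
  list(n_deam = n_deam, n_snp = n_snp, n_total = n_total,
       frac_of_snps = if (n_snp > 0L) n_deam / n_snp else NA_real_,
       frac_of_all = n_deam / n_total,
       pct_of_snps = if (n_snp > 0L)
         roundHalfUp(100 * n_deam / n_snp, 1L) else NA_real_,
       pct_of_all = roundHalfUp(100 * n_deam / n_total, 1L),
       defined = TRUE)
}

#' Mutation-class spectrum summary
#'
#' @param pvs a [PrivateVariantSet-class].
#' @return named integer vector of counts over the five mutation classes
#'   (they partition the set).
#' @export
spectrumCounts <- function(pvs) {
  df <- if (is(pvs, "PrivateVariantSet")) pvs@variants else pvs
  cls <- factor(classifyVariant(df$ref, df$alt),
                levels = c("CtoT_GtoA", "other_SNP", "insertion",
                           "deletion", "MNP"))
  table(cls)
}

#' Fisher's exact contingency test with cross-product odds ratio
#'
#' For the 2x2 table with rows (mutagenized: deaminase-signature, other) and
#' (background: deaminase-signature, other), the odds ratio is the sample
#' cross-product estimator `(a d) / (b c)` — not the conditional MLE that
#' [stats::fisher.test()] reports — and the two-sided p-value is the exact
#' hypergeometric test.
#'
#' @param a,b,c_,d non-negative integer cell counts: `a`/`b` the focal row
#'   (signature / other), `c_`/`d` the background row.
#' @return list with `odds_ratio` (Inf or 0 when a zero cell makes the
#'   cross-product degenerate, with `zero_cell = TRUE`), `p_two_sided`, and
#'   `zero_cell`.
#' @export
contingencyTest <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  zero <- any(cells == 0)
  or <- (a * d) / (b * c_)   # 0/0 -> NaN, x/0 -> Inf
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2L,
                          byrow = TRUE))$p.value
  list(odds_ratio = or, p_two_sided = p, zero_cell = zero)
}

#' Occurrence statistics of a private variant set
#'
#' Occurrences are carrier entries summed over variants; the singleton
#' fraction is over variants (exactly one carrier); the heterozygous
#' fraction is over occurrences.
#'
#' @param pvs a [PrivateVariantSet-class].
#' @return list with `singleton_fraction`, `het_fraction`, `n_occurrences`,
#'   `n_variants`.
#' @export
occurrenceStats <- function(pvs) {
  df <- pvs@variants
  n_var <- nrow(df)
  cc <- lengths(df$carriers)
  n_occ <- sum(cc)
  zyg <- unlist(as.list(df$zygosity), use.names = FALSE)
  list(singleton_fraction = if (n_var) mean(cc == 1L) else NA_real_,
       het_fraction = if (n_occ) mean(zyg == "het") else NA_real_,
       n_occurrences = n_occ, n_variants = n_var)
}

#' Per-line mutation-rate estimates from a private variant set
#'
#' For every replicate group (isogenic line) whose samples pass the
#' mean-depth requirement, counts the private variants carried per
#' replicate, reconciles replicates by taking the higher count, divides by
#' the callable bases (10-200 reads) of the replicate attaining that count
#' and by the line's generation number, and aggregates across lines.
#'
#' @param pvs a [PrivateVariantSet-class] (mutagenized-private, typically).
#' @param depth a [DepthTrackSet-class].
#' @param manifest a [SampleManifest-class].
#' @param chrom chromosome analysed.
#' @param lo,hi callable-depth bounds.
#' @param min_mean_depth samples below this mean depth are excluded from the
#'   rate analysis (default 9).
#' @return data.frame with one row per line (`line_id`, `n_var`, `n_bp`,
#'   `g`, `u`) and attribute `aggregate` = [aggregateRates()] output.
#' @export
estimateLineRates <- function(pvs, depth, manifest, chrom, lo = 10, hi = 200,
                              min_mean_depth = 9) {
  groups <- replicateGroups(manifest)
  sm <- manifestSamples(manifest)
  df <- pvs@variants
  carr <- as.list(df$carriers)
  rows <- list()
  for (line in names(groups)) {
    reps <- groups[[line]]
    reps <- reps[!is.na(sm[reps, "mean_depth"]) &
                 sm[reps, "mean_depth"] >= min_mean_depth]
    reps <- intersect(reps, names(depth@tracks))
    if (length(reps) == 0L) next
    counts <- vapply(reps, function(s)
      sum(vapply(carr, function(cs) s %in% cs, TRUE)), 0L)
    n_var <- reconcileReplicates(counts)
    pick <- reps[which.max(counts)]
    n_bp <- countCallable(depth, pick, chrom, lo, hi)
    g <- sm[pick, "generations"]
    rows[[line]] <- data.frame(line_id = line, n_var = n_var, n_bp = n_bp,
                               g = g, u = estimateRate(n_var, n_bp, g))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(line_id = character(0), n_var = integer(0),
               n_bp = integer(0), g = integer(0), u = numeric(0))
  rownames(out) <- NULL
  attr(out, "aggregate") <- aggregateRates(out$u)
  out
}
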