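#' @include AllClasses.R
NULL

## log-odds matrix with 0.01 pseudocount when any cell is zero
.pwmLogOdds <- function(pwm) {
  m <- pwm@matrix
  if (any(m == 0)) m <- sweep(m + 0.01, 2L, colSums(m + 0.01), "/")
  log(m / pwm@background)
}

#' PWM score bounds and threshold
#'
#' `pwmMaxScore` is the maximal achievable log-odds score; `pwmThreshold`
#' resolves the motif's hit threshold (its `score_threshold` slot, or 60
#' percent of the maximal score when unset).
#'
#' @param pwm a [PWMotif-class].
#' @return numeric score.
#' @export
pwmMaxScore <- function(pwm) {
  sum(apply(.pwmLogOdds(pwm), 2L, max))
}

#' @rdname pwmMaxScore
#' @export
pwmThreshold <- function(pwm) {
  if (is.na(pwm@score_threshold)) 0.6 * pwmMaxScore(pwm)
  else pwm@score_threshold
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds scoring (`sum log(p_pos(base) / bg(base))`) of every window on
#' both strands; a window is a hit iff its score is at least the motif's
#' threshold. Windows containing N are skipped.
#'
#' @param sequence a DNA string (character or
#'   [Biostrings::DNAString]).
#' @param pwm a [PWMotif-class].
#' @param threshold log-odds threshold; default [pwmThreshold()].
#' @return data.frame with `start` (0-based), `end` (0-based exclusive),
#'   `strand`, `score`, sorted by start.
#' @export
pwmScan <- function(sequence, pwm, threshold = pwmThreshold(pwm)) {
  seq_chr <- as.character(sequence)
  code <- match(strsplit(toupper(seq_chr), "")[[1L]], BASES)
  w <- ncol(pwm@matrix)
  L <- length(code)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (L < w) return(empty)
  lo_plus <- .pwmLogOdds(pwm)
  lo_minus <- lo_plus[4:1, w:1, drop = FALSE]   # reverse-complement motif
  rownames(lo_minus) <- BASES
  scoreWith <- function(lo) {
    s <- numeric(L - w + 1L)
    for (j in seq_len(w)) s <- s + lo[code[j:(L - w + j)], j]
    s
  }
  sp <- scoreWith(lo_plus)
  sm <- scoreWith(lo_minus)
  hp <- which(!is.na(sp) & sp >= threshold)
  hm <- which(!is.na(sm) & sm >= threshold)
  out <- data.frame(start = c(hp, hm) - 1L,
                    end = c(hp, hm) - 1L + w,
                    strand = rep(c("+", "-"), c(length(hp), length(hm))),
                    score = c(sp[hp], sm[hm]))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Chain motif hits into clusters
#'
#' Hits are chained while the gap between consecutive hits (next start minus
#' previous end, half-open coordinates) is at most `max_gap`; chains with at
#' least `min_hits` hits become cluster intervals spanning the first hit's
#' start to the last hit's end.
#'
#' @param hits data.frame with `start`, `end` (0-based half-open), sorted by
#'   start (e.g. from [pwmScan()]).
#' @param max_gap maximum inter-hit gap in bp.
#' @param min_hits minimum hits per cluster.
#' @return data.frame with `start`, `end` (0-based half-open), `n_hits`.
#' @export
clusterHits <- function(hits, max_gap = 35, min_hits = 2L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_hits = integer(0))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  n <- nrow(hits)
  ## inter-hit gap: next hit's start minus previous hit's end (half-open)
  chain_id <- cumsum(c(1L, as.integer(
    hits$start[-1L] - hits$end[-n] > max_gap)))
  out <- do.call(rbind, lapply(split(seq_len(n), chain_id),
    function(i) data.frame(start = min(hits$start[i]),
                           end = max(hits$end[i]), n_hits = length(i))))
  out <- out[out$n_hits >= min_hits, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide motif-cluster track
#'
#' Scans every chromosome with the PWM and chains hits into clusters,
#' returning a 1-based GRanges track.
#'
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param pwm a [PWMotif-class].
#' @param max_gap,min_hits see [clusterHits()].
#' @param threshold see [pwmScan()].
#' @return GRanges of motif clusters.
#' @export
motifClusterTrack <- function(sequences, pwm, max_gap = 35, min_hits = 2L,
                              threshold = pwmThreshold(pwm)) {
  per_chrom <- lapply(names(sequences), function(ch) {
    cl <- clusterHits(pwmScan(sequences[[ch]], pwm, threshold = threshold),
                      max_gap = max_gap, min_hits = min_hits)
    if (nrow(cl) == 0L) return(GRanges())
    bedToGRanges(ch, cl$start, cl$end)
  })
  sort(suppressWarnings(do.call(c, per_chrom)))
}

#' Distance from positions to the nearest feature
#'
#' Distance is 0 when the position lies inside an interval, otherwise the
#' number of bases strictly between the position and the nearest interval on
#' the same chromosome; positions on chromosomes without intervals get
#' `Inf`.
#'
#' @param chrom,pos chromosome names and 1-based positions.
#' @param track a GRanges feature track (1-based internal convention; use
#'   [readBed()] for BED input).
#' @return numeric distances in bp.
#' @export
nearestFeatureDistance <- function(chrom, pos, track) {
  n <- length(pos)
  d <- rep(Inf, n)
  if (length(track) == 0L || n == 0L) return(d)
  q <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  ## positions may sit on chromosomes absent from the track (-> Inf); the
  ## seqlevel-mismatch warning is expected there
  hits <- suppressWarnings(distanceToNearest(q, track,
                                             ignore.strand = TRUE))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  d
}

#' Resampling-based proximity enrichment around feature tracks
#'
#' Tests whether focal variants lie within `window` bp of features more
#' often than background variants: per replicate, `n_sample` background
#' positions are drawn from the pool (without replacement when the pool is
#' large enough, otherwise with replacement, with a message), the 2x2 table
#' (within / beyond window, focal / background) is formed, the cross-product
#' odds ratio and two-sided Fisher p-value are computed, and p-values are
#' Benjamini-Hochberg adjusted across tracks within each replicate.
#'
#' @param focal data.frame with `chrom`, `pos` (1-based) of focal variants.
#' @param background_pool data.frame with `chrom`, `pos` of the background
#'   variant pool.
#' @param tracks named list of GRanges feature tracks.
#' @param window proximity threshold in bp ("within" means distance <=
#'   window).
#' @param n_sample background positions drawn per replicate.
#' @param n_reps number of resampling replicates.
#' @param seed integer RNG seed.
#' @return named list of [EnrichmentResult-class], one per track.
#' @export
proximityEnrichment <- function(focal, background_pool, tracks,
                                window = 100, n_sample = 10000L,
                                n_reps = 500L, seed = 1L) {
  if (nrow(focal) == 0L) stop("empty focal set")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list")
  n_pool <- nrow(background_pool)
  if (n_pool == 0L) stop("empty background pool")
  with_replacement <- n_pool < n_sample
  if (with_replacement)
    message("background pool smaller than n_sample; sampling with replacement")
  n_focal <- nrow(focal)
  within_focal <- lapply(tracks, function(tr)
    nearestFeatureDistance(focal$chrom, focal$pos, tr) <= window)
  within_pool <- lapply(tracks, function(tr)
    nearestFeatureDistance(background_pool$chrom, background_pool$pos,
                           tr) <= window)
  degenerate <- vapply(tracks, function(tr) length(tr) == 0L, TRUE)
  set.seed(as.integer(seed))
  idx <- replicate(n_reps,
                   sample.int(n_pool, n_sample, replace = with_replacement),
                   simplify = FALSE)
  p_raw <- matrix(NA_real_, n_reps, length(tracks),
                  dimnames = list(NULL, names(tracks)))
  tabs <- vector("list", length(tracks))
  names(tabs) <- names(tracks)
  for (tn in names(tracks)) {
    a <- sum(within_focal[[tn]])
    b <- n_focal - a
    cw <- vapply(idx, function(i) sum(within_pool[[tn]][i]), 0L)
    dw <- n_sample - cw
    or <- (as.numeric(a) * dw) / (as.numeric(b) * cw)
    p <- vapply(seq_len(n_reps), function(r)
      fisher.test(matrix(c(a, b, cw[r], dw[r]), 2L, byrow = TRUE))$p.value,
      0)
    p_raw[, tn] <- p
    tabs[[tn]] <- DataFrame(rep = seq_len(n_reps), focal_within = a,
                            focal_beyond = b, bg_within = cw,
                            bg_beyond = dw, odds_ratio = or, p_raw = p)
  }
  p_adj <- t(apply(p_raw, 1L, p.adjust, method = "BH"))
  if (length(tracks) == 1L) p_adj <- matrix(p_raw, ncol = 1L,
                                            dimnames = dimnames(p_raw))
  out <- lapply(names(tracks), function(tn) {
    df <- tabs[[tn]]
    df$p_adj <- p_adj[, tn]
    new("EnrichmentResult", track = tn, replicates = df,
        params = list(window = window, n_sample = n_sample,
                      n_reps = n_reps, seed = seed,
                      with_replacement = with_replacement,
                      degenerate = unname(degenerate[tn])))
  })
  names(out) <- names(tracks)
  out
}

#' Extract mutation-centred sequence windows as FASTA entries
#'
#' Each entry is `width` bp with the variant base at position
#' `ceiling(width / 2)` (1-based within the window); windows truncated at
#' chromosome ends are padded with N and flagged. Entry names encode
#' `chrom:pos`. Intended input are C>T / G>A SNPs (see [deaminaseSnps()]);
#' the FASTA is the input a de novo motif-discovery tool consumes.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based; SNPs).
#' @param sequences named [Biostrings::DNAStringSet] genome.
#' @param width window width in bp.
#' @return A [Biostrings::DNAStringSet] with `mcols()$padded`.
#' @export
extractWindows <- function(variants, sequences, width = 200L) {
  n <- nrow(variants)
  left <- ceiling(width / 2) - 1L
  right <- width - ceiling(width / 2)
  out <- character(n)
  padded <- logical(n)
  for (i in seq_len(n)) {
    ch <- variants$chrom[i]
    if (!ch %in% names(sequences))
      stop(sprintf("unknown chromosome '%s'", ch))
    L <- length(sequences[[ch]])
    p <- variants$pos[i]
    if (p < 1L || p > L)
      stop(sprintf("position %d beyond chromosome '%s' (length %d)",
                   p, ch, L))
    s <- p - left; e <- p + right
    pad_l <- max(0L, 1L - s); pad_r <- max(0L, e - L)
    core <- as.character(subseq(sequences[[ch]], max(1L, s), min(L, e)))
    out[i] <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
    padded[i] <- pad_l > 0L || pad_r > 0L
  }
  res <- DNAStringSet(out)
  names(res) <- paste0(variants$chrom, ":", variants$pos)
  S4Vectors::mcols(res)$padded <- padded
  res
}

#' Deaminase-signature SNPs of a private variant set
#'
#' @param pvs a [PrivateVariantSet-class].
#' @return data.frame with `chrom`, `pos`, `ref`, `alt` restricted to C>T /
#'   G>A SNPs.
#' @export
deaminaseSnps <- function(pvs) {
  df <- as.data.frame(pvs@variants[, c("chrom", "pos", "ref", "alt")])
  df[classifyVariant(df$ref, df$alt) == "CtoT_GtoA", , drop = FALSE]
}

#' Shared-variant policy between two mutagenesis analyses
#'
#' Variants found in both sets are kept in both analyses; the overlap
#' fraction (shared / union) is reported.
#'
#' @param set_a,set_b data.frames with `chrom`, `pos`, `ref`, `alt`.
#' @return list with `a`, `b` (the per-analysis variant lists, shared
#'   variants retained in both), `n_shared`, `overlap_fraction`.
#' @export
sharedVariantPolicy <- function(set_a, set_b) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  ka <- key(set_a); kb <- key(set_b)
  shared <- intersect(ka, kb)
  n_union <- length(union(ka, kb))
  list(a = set_a, b = set_b, n_shared = length(shared),
       overlap_fraction = if (n_union) length(shared) / n_union else 0)
}

#' Read PWMs in JASPAR-style text format
#'
#' Parses motifs of the form `>name` followed by four rows `A [ ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]` (brackets optional). Counts are
#' normalised to per-position probabilities.
#'
#' @param path file path.
#' @param background,score_threshold passed to [PWMotif()].
#' @return named list of [PWMotif-class].
#' @export
readJasparPwm <- function(path, background = c(A = .25, C = .25, G = .25,
                                               T = .25),
                          score_threshold = NA_real_) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop(sprintf("no motif headers in '%s'", path))
  out <- list()
  for (k in seq_along(starts)) {
    name <- sub("^>\\s*", "", lines[starts[k]])
    name <- strsplit(name, "\\s+")[[1L]][1L]
    block <- lines[(starts[k] + 1L):(if (k < length(starts))
      starts[k + 1L] - 1L else length(lines))]
    if (length(block) < 4L)
      stop(sprintf("motif '%s' lacks 4 base rows", name))
    m <- matrix(NA_real_, 4L, 0L, dimnames = list(BASES, NULL))
    rows <- lapply(BASES, function(b) {
      row <- block[grepl(paste0("^", b, "\\b"), block)][1L]
      if (is.na(row)) stop(sprintf("motif '%s' lacks row %s", name, b))
      nums <- regmatches(row, gregexpr("[0-9.eE+-]+", row))[[1L]]
      as.numeric(nums)
    })
    wlen <- unique(lengths(rows))
    if (length(wlen) != 1L)
      stop(sprintf("motif '%s' has ragged rows", name))
    m <- do.call(rbind, rows)
    rownames(m) <- BASES
    out[[name]] <- PWMotif(name, m, background = background,
                           score_threshold = score_threshold)
  }
  out
}
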