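#' @include AllClasses.R
NULL

#' QUAL prefilter
#'
#' Removes records with a site QUAL score below 10 (records with missing
#' QUAL carry `qual = 0` from [readJointVcf()] and are removed).
#'
#' @param jvt a [JointVariantTable-class].
#' @param min_qual retained iff `qual >= min_qual` (default 10).
#' @return the filtered [JointVariantTable-class].
#' @export
qualPrefilter <- function(jvt, min_qual = 10) {
  jvt[qualScore(jvt) >= min_qual, ]
}

#' Per-genotype quality filter
#'
#' A carrier genotype passes iff its sequencing depth is between 10 and 200
#' (inclusive) and, for heterozygous calls, at least 3 reads support each
#' allele (AO > 2 and RO > 2). Homozygous-alt calls need only the depth
#' bounds.
#'
#' @param gt integer genotype codes (1 het, 2 hom alt).
#' @param dp,ro,ao integer depth / allele observation counts.
#' @param dp_min,dp_max inclusive depth bounds.
#' @param min_obs het calls need `ao > min_obs` and `ro > min_obs`.
#' @return logical vector, pass/fail per call.
#' @export
genotypeFilter <- function(gt, dp, ro, ao, dp_min = 10, dp_max = 200,
                           min_obs = 2) {
  dp_ok <- !is.na(dp) & dp >= dp_min & dp <= dp_max
  het_ok <- gt != GT_HET |
    (!is.na(ao) & !is.na(ro) & ao > min_obs & ro > min_obs)
  dp_ok & het_ok
}

## carrier matrix: TRUE where the sample carries >= 1 alt allele
.carrierMatrix <- function(jvt) {
  gt <- genotypes(jvt)
  !is.na(gt) & gt >= GT_HET
}

.pvsFromIndex <- function(jvt, idx, carrier, target, chrom, target_samples,
                          gf, rescued) {
  carriers <- lapply(idx, function(i) {
    target_samples[carrier[i, target_samples]]
  })
  gt <- genotypes(jvt)
  zyg <- lapply(seq_along(idx), function(k) {
    ifelse(gt[idx[k], carriers[[k]]] == GT_HOM_ALT, "hom_alt", "het")
  })
  cpass <- lapply(seq_along(idx), function(k) {
    unname(gf[idx[k], carriers[[k]]])
  })
  df <- DataFrame(chrom = variantChrom(jvt)[idx],
                  pos = variantPos(jvt)[idx],
                  ref = refAllele(jvt)[idx],
                  alt = altAllele(jvt)[idx],
                  qual = qualScore(jvt)[idx],
                  carriers = CharacterList(carriers),
                  zygosity = CharacterList(zyg),
                  carrier_pass = LogicalList(cpass),
                  rescued = rescued)
  new("PrivateVariantSet", variants = df, target = target, chrom = chrom)
}

#' Select variants private to a designated sample set
#'
#' A variant is private to the target set iff at least one target-set sample
#' carries the alternative allele (het or hom alt, at ANY quality) and no
#' sample outside the target set within the full set carries it (again at
#' ANY quality, including calls that would fail later genotype filters).
#' Missing genotypes do not count as carrying. This strictness — privateness
#' is decided before any quality filtering — is deliberate: a low-quality
#' alt call outside the target set disqualifies the variant.
#'
#' @param jvt a [JointVariantTable-class] (typically QUAL-prefiltered and
#'   restricted to one chromosome).
#' @param manifest a [SampleManifest-class].
#' @param target `"mutagenized"` or `"background"`.
#' @param chrom chromosome whose sample sets apply.
#' @param exclude_samples samples removed from the analysis (dropped from
#'   all sets before the set logic).
#' @return A [PrivateVariantSet-class] (pre-filter: `carrier_pass` and
#'   `rescued` are filled by [runPrivatePipeline()]; here `carrier_pass` is
#'   the genotype-filter outcome and `rescued` is FALSE).
#' @export
selectPrivate <- function(jvt, manifest, target = c("mutagenized",
                                                    "background"),
                          chrom, exclude_samples = character(0)) {
  target <- match.arg(target)
  full <- setdiff(sampleSet(manifest, chrom, "full"), exclude_samples)
  tset <- setdiff(sampleSet(manifest, chrom, target), exclude_samples)
  if (length(tset) == 0L)
    stop(sprintf("configuration error: empty %s set for %s", target, chrom))
  full <- intersect(full, colnames(jvt))
  tset <- intersect(tset, colnames(jvt))
  others <- setdiff(full, tset)
  onchrom <- variantChrom(jvt) == chrom
  carrier <- .carrierMatrix(jvt)
  in_target <- rowSums(carrier[, tset, drop = FALSE]) > 0L
  in_others <- rowSums(carrier[, others, drop = FALSE]) > 0L
  idx <- which(onchrom & in_target & !in_others)
  gf <- genotypeFilter(genotypes(jvt), readDepth(jvt), refObs(jvt),
                       altObs(jvt))
  .pvsFromIndex(jvt, idx, carrier, target, chrom, tset, gf,
                rescued = rep(FALSE, length(idx)))
}

#' Replicate rescue
#'
#' A variant is rescued iff at least two samples of the same replicate group
#' carry the alternative allele; the rescue keeps the variant regardless of
#' sequencing depth or allele-observation filters.
#'
#' @param carriers character vector of carrier sample ids for one variant.
#' @param manifest a [SampleManifest-class].
#' @return logical: rescued or not.
#' @export
replicateRescue <- function(carriers, manifest) {
  if (length(carriers) < 2L) return(FALSE)
  lid <- manifestSamples(manifest)[carriers, "line_id"]
  lid <- lid[!is.na(lid)]
  length(lid) > 0L && max(table(lid)) >= 2L
}

## variant-level survival of the genotype-filter / rescue stage
.filterStage <- function(pvs, manifest) {
  df <- pvs@variants
  if (nrow(df) == 0L) return(pvs)
  rescued <- vapply(as.list(df$carriers), replicateRescue, TRUE,
                    manifest = manifest)
  any_pass <- vapply(as.list(df$carrier_pass), any, TRUE)
  df$rescued <- rescued
  keep <- any_pass | rescued
  initialize(pvs, variants = df[keep, , drop = FALSE])
}

#' Cross-set coverage filter
#'
#' A variant private to one set is retained iff the opposite designated set
#' has a non-missing genotype call at its site in at least `min_samples`
#' samples: a mutagenized-private variant must be covered in the background
#' samples, and vice versa, so the two sets are compared fairly.
#'
#' @param pvs a [PrivateVariantSet-class].
#' @param jvt the [JointVariantTable-class] the set was computed against.
#' @param manifest a [SampleManifest-class].
#' @param min_samples minimum non-missing samples in the complement set.
#' @param exclude_samples samples removed from the analysis.
#' @return the filtered [PrivateVariantSet-class].
#' @export
crossCoverageFilter <- function(pvs, jvt, manifest, min_samples = 2L,
                                exclude_samples = character(0)) {
  df <- pvs@variants
  if (nrow(df) == 0L) return(pvs)
  other <- if (pvs@target == "mutagenized") "background" else "mutagenized"
  oset <- setdiff(sampleSet(manifest, pvs@chrom, other), exclude_samples)
  oset <- intersect(oset, colnames(jvt))
  key_jvt <- paste(variantChrom(jvt), variantPos(jvt), refAllele(jvt),
                   altAllele(jvt))
  key_pvs <- paste(df$chrom, df$pos, df$ref, df$alt)
  idx <- match(key_pvs, key_jvt)
  nonmiss <- !is.na(genotypes(jvt)[, oset, drop = FALSE])
  covered <- rowSums(nonmiss[idx, , drop = FALSE]) >= min_samples
  initialize(pvs, variants = df[covered, , drop = FALSE])
}

#' Detect introgression blocks
#'
#' A sample is flagged when it carries at least `min_count` private variants
#' within any `window_kb`-kb sliding window on one chromosome — the
#' signature of a long foreign haplotype block rather than independent de
#' novo mutations. Flagged samples should be removed and privateness
#' recomputed.
#'
#' @param pvs_list list of [PrivateVariantSet-class] (both targets).
#' @param window_kb window size in kb.
#' @param min_count private-variant count that triggers the flag.
#' @return character vector of flagged sample ids.
#' @export
detectIntrogression <- function(pvs_list, window_kb = 100, min_count = 20) {
  if (is(pvs_list, "PrivateVariantSet")) pvs_list <- list(pvs_list)
  per_sample <- list()
  for (pvs in pvs_list) {
    df <- pvs@variants
    if (nrow(df) == 0L) next
    carr <- as.list(df$carriers)
    for (i in seq_len(nrow(df))) {
      for (s in carr[[i]]) {
        k <- paste0(s, "\r", df$chrom[i])
        per_sample[[k]] <- c(per_sample[[k]], df$pos[i])
      }
    }
  }
  w <- window_kb * 1000
  flagged <- character(0)
  for (k in names(per_sample)) {
    pos <- sort(per_sample[[k]])
    if (length(pos) < min_count) next
    ## max count over all windows [p_i, p_i + w)
    hi <- findInterval(pos + w - 1e-9, pos)
    if (max(hi - seq_along(pos) + 1L) >= min_count)
      flagged <- c(flagged, sub("\r.*$", "", k))
  }
  sort(unique(flagged))
}

#' Per-chromosome mean-depth sample exclusion
#'
#' Samples with a mean sequencing depth below the chromosome's threshold are
#' removed from variant counting: by default below 9x for chr2 and below 5x
#' for chr3 (samples between 5x and 9x are kept on chr3 but not on chr2).
#' Unknown chromosomes fall back to the global default threshold (5) with a
#' warning.
#'
#' @param manifest a [SampleManifest-class].
#' @param chrom chromosome name.
#' @param thresholds named list of per-chromosome minimum mean depths.
#' @param default_threshold fallback threshold.
#' @return character vector of retained sample ids.
#' @export
depthExclusion <- function(manifest, chrom,
                           thresholds = list(chr2 = 9, chr3 = 5),
                           default_threshold = 5) {
  if (chrom %in% names(thresholds)) {
    thr <- thresholds[[chrom]]
  } else {
    warning(sprintf("no depth threshold configured for '%s'; using default %g",
                    chrom, default_threshold))
    thr <- default_threshold
  }
  df <- manifestSamples(manifest)
  md <- df$mean_depth
  rownames(df)[!is.na(md) & md >= thr]
}

#' Homozygous-alternative reversion audit
#'
#' Counts sites at which every background-set sample is homozygous for the
#' alternative allele (no missing calls), and among those, sites where any
#' mutagenized sample is het or hom ref — i.e. apparent reversions toward
#' the reference allele, which de novo mutations matching the reference
#' would produce.
#'
#' @param jvt a [JointVariantTable-class].
#' @param manifest a [SampleManifest-class].
#' @param chrom chromosome name.
#' @return list with `n_hom_alt_background_sites` and `n_reverted`.
#' @export
reversionAudit <- function(jvt, manifest, chrom) {
  bg <- intersect(sampleSet(manifest, chrom, "background"), colnames(jvt))
  mut <- intersect(sampleSet(manifest, chrom, "mutagenized"), colnames(jvt))
  onchrom <- variantChrom(jvt) == chrom
  gt <- genotypes(jvt)
  bg_gt <- gt[, bg, drop = FALSE]
  all_hom <- rowSums(!is.na(bg_gt) & bg_gt == GT_HOM_ALT) == length(bg)
  fixed <- onchrom & all_hom
  mut_gt <- gt[, mut, drop = FALSE]
  reverted <- rowSums(!is.na(mut_gt) & mut_gt <= GT_HET) > 0L
  list(n_hom_alt_background_sites = sum(fixed),
       n_reverted = sum(fixed & reverted))
}

#' Removed fraction at the privateness stage
#'
#' The percentage of joint-call variants eliminated by requiring privateness
#' to either designated set, reported to one decimal (half-up rounding).
#'
#' @param n_total variants entering the privateness stage.
#' @param n_private_mut,n_private_bg private variants found per set.
#' @return percentage removed (numeric, one decimal).
#' @export
privatenessRemovedFraction <- function(n_total, n_private_mut,
                                       n_private_bg) {
  roundHalfUp(100 * (1 - (n_private_mut + n_private_bg) / n_total), 1L)
}

#' Removed fraction for a ledger stage
#'
#' @param ledger the stage ledger (data.frame) from [runPrivatePipeline()].
#' @param stage a stage name present in `ledger$stage`.
#' @return percentage of that stage's input removed, one decimal (half-up).
#' @export
removedFraction <- function(ledger, stage = "select_private") {
  i <- match(stage, ledger$stage)
  if (is.na(i)) stop(sprintf("no ledger stage '%s'", stage))
  kept <- ledger$n_mutagenized[i] + ledger$n_background[i]
  roundHalfUp(100 * (1 - kept / ledger$n_input[i]), 1L)
}

#' Run the full private-variant identification pipeline
#'
#' Stage order: QUAL prefilter on the joint call, privateness selection per
#' target set, per-carrier genotype filtering merged with replicate rescue,
#' cross-set coverage filtering, introgression detection with sample removal
#' and recomputation of privateness from scratch, and finally per-chromosome
#' mean-depth sample exclusion for counting. A stage ledger records counts
#' at every step, including variants newly qualifying after introgressed
#' samples are removed.
#'
#' @param jvt a [JointVariantTable-class] (the joint call).
#' @param manifest a [SampleManifest-class].
#' @param chrom chromosome to analyse.
#' @param qual_min QUAL prefilter threshold.
#' @param coverage_min_samples cross-coverage non-missing sample minimum.
#' @param introgression_window_kb,introgression_min_count see
#'   [detectIntrogression()].
#' @param depth_thresholds per-chromosome mean-depth exclusion thresholds.
#' @return list with `mutagenized` and `background`
#'   [PrivateVariantSet-class]s, `ledger` (data.frame: stage, n_input,
#'   n_mutagenized, n_background, n_added), and `removed_samples`
#'   (data.frame: sample, reason).
#' @export
runPrivatePipeline <- function(jvt, manifest, chrom, qual_min = 10,
                               coverage_min_samples = 2L,
                               introgression_window_kb = 100,
                               introgression_min_count = 20,
                               depth_thresholds = list(chr2 = 9, chr3 = 5)) {
  onchrom <- jvt[variantChrom(jvt) == chrom, ]
  n0 <- nVariants(onchrom)
  qv <- qualPrefilter(onchrom, min_qual = qual_min)
  n_qual <- nVariants(qv)
  runStages <- function(excluded) {
    out <- lapply(c("mutagenized", "background"), function(tg) {
      pvs <- selectPrivate(qv, manifest, tg, chrom,
                           exclude_samples = excluded)
      n_priv <- nrow(pvs@variants)
      pvs <- .filterStage(pvs, manifest)
      n_filt <- nrow(pvs@variants)
      pvs <- crossCoverageFilter(pvs, qv, manifest,
                                 min_samples = coverage_min_samples,
                                 exclude_samples = excluded)
      list(pvs = pvs, n_priv = n_priv, n_filt = n_filt,
           n_cov = nrow(pvs@variants))
    })
    names(out) <- c("mutagenized", "background")
    out
  }
  pass1 <- runStages(character(0))
  flagged <- detectIntrogression(list(pass1$mutagenized$pvs,
                                      pass1$background$pvs),
                                 window_kb = introgression_window_kb,
                                 min_count = introgression_min_count)
  pass2 <- if (length(flagged)) runStages(flagged) else pass1
  keyset <- function(pvs) paste(pvs@variants$chrom, pvs@variants$pos,
                                pvs@variants$ref, pvs@variants$alt)
  added <- vapply(c("mutagenized", "background"), function(tg) {
    sum(!keyset(pass2[[tg]]$pvs) %in% keyset(pass1[[tg]]$pvs))
  }, 0L)
  ## depth exclusion: drop carriers in excluded samples from counting
  retained <- depthExclusion(manifest, chrom, thresholds = depth_thresholds)
  dropLowDepth <- function(pvs) {
    df <- pvs@variants
    if (nrow(df) == 0L) return(pvs)
    keep_carrier <- lapply(as.list(df$carriers), function(cs) cs %in% retained)
    df$zygosity <- CharacterList(mapply(function(z, k) z[k],
                                        as.list(df$zygosity), keep_carrier,
                                        SIMPLIFY = FALSE))
    df$carrier_pass <- LogicalList(mapply(function(p, k) p[k],
                                          as.list(df$carrier_pass),
                                          keep_carrier, SIMPLIFY = FALSE))
    df$carriers <- CharacterList(mapply(function(cs, k) cs[k],
                                        as.list(df$carriers), keep_carrier,
                                        SIMPLIFY = FALSE))
    initialize(pvs, variants = df[lengths(df$carriers) > 0L, , drop = FALSE])
  }
  mut_final <- dropLowDepth(pass2$mutagenized$pvs)
  bg_final <- dropLowDepth(pass2$background$pvs)
  ledger <- data.frame(
    stage = c("input", "qual_prefilter", "select_private",
              "genotype_rescue", "cross_coverage",
              "introgression_recompute", "depth_exclusion"),
    n_input = c(n0, n0, n_qual, rep(n_qual, 4L)),
    n_mutagenized = c(NA, NA, pass1$mutagenized$n_priv,
                      pass1$mutagenized$n_filt, pass1$mutagenized$n_cov,
                      pass2$mutagenized$n_cov, nrow(mut_final@variants)),
    n_background = c(NA, NA, pass1$background$n_priv,
                     pass1$background$n_filt, pass1$background$n_cov,
                     pass2$background$n_cov, nrow(bg_final@variants)),
    n_added = c(NA, NA, NA, NA, NA, sum(added), NA),
    n_kept = c(n0, n_qual, NA, NA, NA, NA, NA))
  removed_samples <- if (length(flagged))
    data.frame(sample = flagged, reason = "introgression")
  else data.frame(sample = character(0), reason = character(0))
  excluded_depth <- setdiff(rownames(manifestSamples(manifest)), retained)
  if (length(excluded_depth))
    removed_samples <- rbind(removed_samples,
                             data.frame(sample = excluded_depth,
                                        reason = "mean_depth"))
  list(mutagenized = mut_final, background = bg_final, ledger = ledger,
       removed_samples = removed_samples)
}
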