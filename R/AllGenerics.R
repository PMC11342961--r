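#' @include AllClasses.R
NULL

#' Accessors for JointVariantTable
#'
#' `variantChrom`, `variantPos`, `refAllele`, `altAllele` and `qualScore`
#' return per-variant vectors; `genotypes`, `readDepth`, `refObs`, `altObs`
#' return the variants x samples integer matrices; `nVariants` the number of
#' records.
#'
#' @param x a [JointVariantTable-class].
#' @return vectors / matrices as described.
#' @name JointVariantTable-accessors
#' @aliases variantChrom variantPos refAllele altAllele qualScore genotypes
#'   readDepth refObs altObs nVariants
NULL

#' @rdname JointVariantTable-accessors
#' @export
setGeneric("variantChrom", function(x) standardGeneric("variantChrom"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("variantPos", function(x) standardGeneric("variantPos"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("qualScore", function(x) standardGeneric("qualScore"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("refObs", function(x) standardGeneric("refObs"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("altObs", function(x) standardGeneric("altObs"))
#' @rdname JointVariantTable-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

setMethod("variantChrom", "JointVariantTable",
          function(x) as.character(seqnames(rowRanges(x))))
setMethod("variantPos", "JointVariantTable",
          function(x) start(rowRanges(x)))
setMethod("refAllele", "JointVariantTable",
          function(x) S4Vectors::mcols(rowRanges(x))$ref)
setMethod("altAllele", "JointVariantTable",
          function(x) S4Vectors::mcols(rowRanges(x))$alt)
setMethod("qualScore", "JointVariantTable",
          function(x) S4Vectors::mcols(rowRanges(x))$qual)
setMethod("genotypes", "JointVariantTable", function(x) assay(x, "GT"))
setMethod("readDepth", "JointVariantTable", function(x) assay(x, "DP"))
setMethod("refObs", "JointVariantTable", function(x) assay(x, "RO"))
setMethod("altObs", "JointVariantTable", function(x) assay(x, "AO"))
setMethod("nVariants", "JointVariantTable", function(x) nrow(x))

setMethod("show", "JointVariantTable", function(object) {
  cat(sprintf("JointVariantTable: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  if (nrow(object) > 0L) {
    tab <- table(variantChrom(object))
    cat("  chromosomes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (ncol(object) > 0L)
    cat("  samples:", paste(utils::head(colnames(object), 6L),
                            collapse = ", "),
        if (ncol(object) > 6L) "..." else "", "\n")
})

#' Accessors for SampleManifest
#'
#' @param x a [SampleManifest-class].
#' @param chrom chromosome name.
#' @param which one of `"full"`, `"mutagenized"`, `"background"`.
#' @return `manifestSamples`: the per-sample DataFrame; `sampleSet`: character
#'   vector of sample ids; `replicateGroups`: named list line id -> sample
#'   ids (groups of size >= 1).
#' @name SampleManifest-accessors
#' @aliases manifestSamples sampleSet replicateGroups
NULL

#' @rdname SampleManifest-accessors
#' @export
setGeneric("manifestSamples", function(x) standardGeneric("manifestSamples"))
#' @rdname SampleManifest-accessors
#' @export
setGeneric("sampleSet",
           function(x, chrom, which = "full") standardGeneric("sampleSet"))
#' @rdname SampleManifest-accessors
#' @export
setGeneric("replicateGroups", function(x) standardGeneric("replicateGroups"))

setMethod("manifestSamples", "SampleManifest", function(x) x@samples)

setMethod("sampleSet", "SampleManifest", function(x, chrom, which = "full") {
  which <- match.arg(which, c("full", "mutagenized", "background"))
  if (!chrom %in% names(x@sets))
    stop(sprintf("no sample sets defined for chromosome '%s'", chrom))
  x@sets[[chrom]][[which]]
})

setMethod("replicateGroups", "SampleManifest", function(x) {
  lid <- x@samples$line_id
  ids <- rownames(x@samples)
  keep <- !is.na(lid)
  split(ids[keep], lid[keep])
})

setMethod("show", "SampleManifest", function(object) {
  cat(sprintf("SampleManifest: %d samples, %d replicate groups\n",
              nrow(object@samples), length(replicateGroups(object))))
  for (chrom in names(object@sets)) {
    s <- object@sets[[chrom]]
    cat(sprintf("  %s: full %d, mutagenized %d, background %d\n", chrom,
                length(s$full), length(s$mutagenized), length(s$background)))
  }
})

#' Accessors for PrivateVariantSet
#'
#' @param x a [PrivateVariantSet-class].
#' @return `privateVariants`: the variant DataFrame; `privateTarget`: the set
#'   label; `carrierCounts`: integer carriers per variant; `isSingleton`:
#'   logical, exactly one carrier.
#' @name PrivateVariantSet-accessors
#' @aliases privateVariants privateTarget carrierCounts isSingleton
NULL

#' @rdname PrivateVariantSet-accessors
#' @export
setGeneric("privateVariants", function(x) standardGeneric("privateVariants"))
#' @rdname PrivateVariantSet-accessors
#' @export
setGeneric("privateTarget", function(x) standardGeneric("privateTarget"))
#' @rdname PrivateVariantSet-accessors
#' @export
setGeneric("carrierCounts", function(x) standardGeneric("carrierCounts"))
#' @rdname PrivateVariantSet-accessors
#' @export
setGeneric("isSingleton", function(x) standardGeneric("isSingleton"))

setMethod("privateVariants", "PrivateVariantSet", function(x) x@variants)
setMethod("privateTarget", "PrivateVariantSet", function(x) x@target)
setMethod("carrierCounts", "PrivateVariantSet",
          function(x) lengths(x@variants$carriers))
setMethod("isSingleton", "PrivateVariantSet",
          function(x) lengths(x@variants$carriers) == 1L)

setMethod("show", "PrivateVariantSet", function(object) {
  cat(sprintf("PrivateVariantSet (%s, %s): %d variants, %d occurrences, %d rescued\n",
              object@target, object@chrom, nrow(object@variants),
              sum(lengths(object@variants$carriers)),
              sum(object@variants$rescued)))
})

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif '%s': width %d, max score %.2f, threshold %.2f\n",
              object@name, ncol(object@matrix), pwmMaxScore(object),
              pwmThreshold(object)))
})

setMethod("show", "SimGenome", function(object) {
  cat(sprintf("SimGenome: %d chromosome(s), %s bp total; %d motif sites, %d peaks\n",
              length(object@sequences),
              format(sum(Biostrings::width(object@sequences)), big.mark = ","),
              length(object@motif_sites), length(object@peak_sites)))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d de novo mutations, %d standing variants, %d samples, %d isogenic lines\n",
    nrow(object@denovo), nrow(object@standing), nrow(object@samples),
    length(unique(object@iso_carriage$line_id))))
})

setMethod("show", "DepthTrackSet", function(object) {
  cat(sprintf("DepthTrackSet: %d samples x %d chromosome(s)\n",
              length(object@tracks),
              length(unique(unlist(lapply(object@tracks, names))))))
})

setMethod("show", "EnrichmentResult", function(object) {
  or <- object@replicates$odds_ratio
  cat(sprintf(
    "EnrichmentResult '%s': %d replicates, median OR %.3g, median adjusted p %.3g\n",
    object@track, nrow(object@replicates),
    stats::median(or[is.finite(or)]),
    stats::median(object@replicates$p_adj)))
})

#' Depth track accessor
#'
#' @param x a [DepthTrackSet-class].
#' @param sample sample id.
#' @param chrom chromosome name.
#' @return the [S4Vectors::Rle] of per-base depth.
#' @export
setGeneric("depthTrack",
           function(x, sample, chrom) standardGeneric("depthTrack"))

setMethod("depthTrack", "DepthTrackSet", function(x, sample, chrom) {
  if (!sample %in% names(x@tracks))
    stop(sprintf("no depth track for sample '%s'", sample))
  tr <- x@tracks[[sample]]
  if (!chrom %in% names(tr))
    stop(sprintf("no depth track for chromosome '%s' in sample '%s'",
                 chrom, sample))
  tr[[chrom]]
})
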