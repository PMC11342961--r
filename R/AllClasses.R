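#' @import methods
#' @importFrom BiocGenerics start end width
#' @importFrom S4Vectors DataFrame Rle runValue runLength metadata metadata<-
#' @importFrom IRanges IRanges CharacterList LogicalList
#' @importFrom GenomicRanges GRanges findOverlaps distanceToNearest reduce
#' @importFrom GenomeInfoDb seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   subseq reverseComplement
#' @importFrom stats rpois rbinom rnbinom runif median sd fisher.test p.adjust
#' @importFrom utils head read.table write.table packageVersion
NULL

## Genotype codes used throughout the package: 0 = hom_ref, 1 = het,
## 2 = hom_alt, NA = missing. Stored as an integer assay so that set logic
## over samples is plain matrix arithmetic.
GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' JointVariantTable: a joint multi-sample variant call
#'
#' Container for decomposed biallelic variant records from a joint caller.
#' Rows are variants (1-based positions, single ALT allele per row after
#' multi-allelic decomposition), columns are samples. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment-class] with four integer
#' assays: `GT` (0 = hom ref, 1 = het, 2 = hom alt, NA = missing), `DP`
#' (total read depth), `RO` (reference-allele observations) and `AO`
#' (alternative-allele observations). Row metadata columns `ref`, `alt` and
#' `qual` carry the allele strings and the site QUAL score.
#'
#' @export
setClass("JointVariantTable", contains = "RangedSummarizedExperiment")

setValidity("JointVariantTable", function(object) {
  msg <- character()
  need <- c("GT", "DP", "RO", "AO")
  if (!all(need %in% names(assays(object))))
    msg <- c(msg, paste("assays must include", paste(need, collapse = ", ")))
  mc <- S4Vectors::mcols(rowRanges(object))
  for (f in c("ref", "alt", "qual"))
    if (!f %in% names(mc)) msg <- c(msg, paste("missing rowData field", f))
  if (length(msg)) return(msg)
  if (nrow(object) > 0L) {
    if (any(start(rowRanges(object)) < 1L)) msg <- c(msg, "pos must be >= 1")
    ok <- grepl("^[ACGT]+$", mc$ref) & grepl("^[ACGT]+$", mc$alt)
    if (!all(ok)) msg <- c(msg, "ref/alt must be non-empty strings over ACGT")
    gt <- assay(object, "GT")
    if (!all(gt[!is.na(gt)] %in% c(0L, 1L, 2L)))
      msg <- c(msg, "GT codes must be 0, 1, 2 or NA")
    for (a in c("DP", "RO", "AO")) {
      x <- assay(object, a)
      if (any(x[!is.na(x)] < 0L)) msg <- c(msg, paste(a, "must be >= 0"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a JointVariantTable
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles (one ALT per record).
#' @param qual numeric QUAL scores (missing QUAL should be encoded as 0).
#' @param GT integer matrix (variants x samples) of genotype codes
#'   (0 hom ref, 1 het, 2 hom alt, NA missing); column names are sample ids.
#' @param DP,RO,AO integer matrices of depth and allele observations,
#'   dimensioned like `GT`.
#' @return A [JointVariantTable-class].
#' @examples
#' jvt <- JointVariantTable(
#'   chrom = "chr3", pos = 100L, ref = "C", alt = "T", qual = 50,
#'   GT = matrix(1L, 1, 1, dimnames = list(NULL, "s1")),
#'   DP = matrix(20L, 1, 1), RO = matrix(10L, 1, 1), AO = matrix(10L, 1, 1))
#' nVariants(jvt)
#' @export
JointVariantTable <- function(chrom, pos, ref, alt, qual, GT, DP, RO, AO) {
  GT <- as.matrix(GT); mode(GT) <- "integer"
  DP <- as.matrix(DP); mode(DP) <- "integer"
  RO <- as.matrix(RO); mode(RO) <- "integer"
  AO <- as.matrix(AO); mode(AO) <- "integer"
  colnames(DP) <- colnames(RO) <- colnames(AO) <- colnames(GT)
  rr <- GRanges(chrom, IRanges(as.integer(pos), width = nchar(ref)))
  S4Vectors::mcols(rr) <- DataFrame(ref = as.character(ref),
                                    alt = as.character(alt),
                                    qual = as.numeric(qual))
  se <- SummarizedExperiment(
    assays = list(GT = GT, DP = DP, RO = RO, AO = AO),
    rowRanges = rr,
    colData = DataFrame(row.names = colnames(GT)))
  new("JointVariantTable", se)
}

#' Sample manifest: sample sets, replicate groups and per-sample metadata
#'
#' Describes the experimental design of a joint call: which samples form the
#' full / mutagenized / background sets on each chromosome, which samples are
#' replicates of the same isogenic line, and per-sample generation counts and
#' mean sequencing depths.
#'
#' @slot samples a [S4Vectors::DataFrame] with rownames = sample ids and
#'   columns `line_id` (replicate group; NA for unreplicated samples),
#'   `generations` (integer G), `mean_depth` (numeric, reads) and `role`
#'   (free-text tag, e.g. "isogenic_chr3").
#' @slot sets named list, one element per chromosome, each a list with
#'   character vectors `full`, `mutagenized`, `background`.
#' @export
setClass("SampleManifest",
  representation(samples = "DataFrame", sets = "list"))

setValidity("SampleManifest", function(object) {
  msg <- character()
  ids <- rownames(object@samples)
  for (chrom in names(object@sets)) {
    s <- object@sets[[chrom]]
    if (!all(c("full", "mutagenized", "background") %in% names(s))) {
      msg <- c(msg, sprintf("sets[[%s]] must define full/mutagenized/background", chrom))
      next
    }
    if (!all(unlist(s) %in% ids))
      msg <- c(msg, sprintf("sets[[%s]] references unknown samples", chrom))
    if (length(intersect(s$mutagenized, s$background)))
      msg <- c(msg, sprintf("mutagenized and background sets overlap on %s", chrom))
    if (!all(s$mutagenized %in% s$full) || !all(s$background %in% s$full))
      msg <- c(msg, sprintf("mutagenized/background must be subsets of full on %s", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleManifest
#'
#' @param sample_ids character vector of sample ids.
#' @param line_id replicate-group label per sample (NA = no replicate group).
#' @param generations integer generation count per sample.
#' @param mean_depth numeric mean sequencing depth per sample.
#' @param role character tag per sample.
#' @param sets named list chromosome -> list(full, mutagenized, background).
#' @return A [SampleManifest-class].
#' @export
SampleManifest <- function(sample_ids, line_id = NA_character_,
                           generations = 1L, mean_depth = NA_real_,
                           role = NA_character_, sets = list()) {
  n <- length(sample_ids)
  df <- DataFrame(line_id = rep_len(as.character(line_id), n),
                  generations = rep_len(as.integer(generations), n),
                  mean_depth = rep_len(as.numeric(mean_depth), n),
                  role = rep_len(as.character(role), n),
                  row.names = sample_ids)
  new("SampleManifest", samples = df, sets = sets)
}

#' Private variant set
#'
#' Variants private to one designated sample set (mutagenized or background)
#' after the de novo identification pipeline, with carrier lists, per-carrier
#' zygosity, per-carrier genotype-filter flags and the replicate-rescue flag.
#'
#' @slot variants a [S4Vectors::DataFrame] with columns `chrom`, `pos`,
#'   `ref`, `alt`, `qual`, `carriers` (CharacterList), `zygosity`
#'   (CharacterList, "het"/"hom_alt" parallel to carriers), `carrier_pass`
#'   (LogicalList, genotype filter outcome per carrier) and `rescued`
#'   (logical).
#' @slot target `"mutagenized"` or `"background"`.
#' @slot chrom chromosome the set was computed on.
#' @export
setClass("PrivateVariantSet",
  representation(variants = "DataFrame", target = "character",
                 chrom = "character"))

setValidity("PrivateVariantSet", function(object) {
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "qual", "carriers", "zygosity",
            "carrier_pass", "rescued")
  if (!all(need %in% names(object@variants)))
    msg <- c(msg, paste("variants must have columns",
                        paste(need, collapse = ", ")))
  if (!object@target %in% c("mutagenized", "background"))
    msg <- c(msg, "target must be 'mutagenized' or 'background'")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix for motif scanning
#'
#' @slot name motif name.
#' @slot matrix 4 x width numeric matrix of per-position base probabilities,
#'   rownames A, C, G, T; each column sums to 1.
#' @slot background named base frequencies used in the log-odds denominator.
#' @slot score_threshold log-odds threshold for calling a hit; `NA` means
#'   60 percent of the maximal achievable score.
#' @export
setClass("PWMotif",
  representation(name = "character", matrix = "matrix",
                 background = "numeric", score_threshold = "numeric"))

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    msg <- c(msg, "matrix rownames must be A, C, G, T")
  if (ncol(m) < 4L) msg <- c(msg, "matrix width must be >= 4")
  if (any(abs(colSums(m) - 1) > 1e-9))
    msg <- c(msg, "each matrix column must sum to 1 (+- 1e-9)")
  bg <- object@background
  if (!identical(names(bg), c("A", "C", "G", "T")) || abs(sum(bg) - 1) > 1e-9)
    msg <- c(msg, "background must be named A,C,G,T frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PWMotif
#'
#' @param name motif name.
#' @param matrix 4 x width matrix of probabilities or counts (rows A,C,G,T).
#'   Counts are normalised per column. Columns containing a zero receive a
#'   0.01 pseudocount before log-odds are formed.
#' @param background named numeric base frequencies (default uniform).
#' @param score_threshold log-odds hit threshold; default `NA` = 60 percent
#'   of the maximal achievable score.
#' @return A [PWMotif-class].
#' @export
PWMotif <- function(name, matrix, background = c(A = .25, C = .25,
                                                 G = .25, T = .25),
                    score_threshold = NA_real_) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  m <- sweep(m, 2L, colSums(m), "/")
  new("PWMotif", name = name, matrix = m,
      background = background[c("A", "C", "G", "T")],
      score_threshold = as.numeric(score_threshold))
}

#' Simulated genome with planted motif sites and regulatory intervals
#'
#' @slot sequences a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot motif_sites GRanges of planted motif matches (1-based).
#' @slot peak_sites GRanges of planted regulatory intervals, each containing
#'   at least one motif site.
#' @slot pwm the generating [PWMotif-class].
#' @export
setClass("SimGenome",
  representation(sequences = "DNAStringSet", motif_sites = "GRanges",
                 peak_sites = "GRanges", pwm = "PWMotif"))

#' Germline mutagenesis model parameters
#'
#' @slot base_rate per-base per-generation diploid mutation rate outside
#'   target windows.
#' @slot target_rate_multiplier fold elevation of the rate inside target
#'   windows (>= 1).
#' @slot target_window bp added on each side of a planted motif site to form
#'   the elevated-rate window.
#' @slot deamination_fraction probability that an induced mutation is a
#'   deamination event (C>T on the plus strand or G>A, i.e. C>T on the
#'   minus strand).
#' @slot generations integer number of generations G.
#' @slot het_fraction probability that a surviving de novo mutation is
#'   sampled heterozygous.
#' @export
setClass("MutagenesisModel",
  representation(base_rate = "numeric", target_rate_multiplier = "numeric",
                 target_window = "numeric", deamination_fraction = "numeric",
                 generations = "integer", het_fraction = "numeric"))

setValidity("MutagenesisModel", function(object) {
  msg <- character()
  if (object@base_rate <= 0) msg <- c(msg, "base_rate must be > 0")
  if (object@target_rate_multiplier < 1)
    msg <- c(msg, "target_rate_multiplier must be >= 1")
  if (object@deamination_fraction < 0 || object@deamination_fraction > 1)
    msg <- c(msg, "deamination_fraction must be in [0, 1]")
  if (object@het_fraction < 0 || object@het_fraction > 1)
    msg <- c(msg, "het_fraction must be in [0, 1]")
  if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MutagenesisModel
#'
#' Defaults anchor to the endogenous Drosophila per-base diploid rate
#' (8.4e-9 per base per generation) with a 50-fold elevation inside
#' 100-bp windows around planted motif sites, an 0.85 deamination fraction
#' and an 0.883 heterozygous fraction. Desk-scale simulations typically pass
#' a larger `base_rate` so expected counts on a small genome remain
#' informative.
#'
#' @param base_rate,target_rate_multiplier,target_window,deamination_fraction
#'   see slots.
#' @param generations,het_fraction see slots.
#' @return A [MutagenesisModel-class].
#' @export
mutagenesisModel <- function(base_rate = 8.4e-9, target_rate_multiplier = 50,
                             target_window = 100, deamination_fraction = 0.85,
                             generations = 10L, het_fraction = 0.883) {
  new("MutagenesisModel", base_rate = base_rate,
      target_rate_multiplier = target_rate_multiplier,
      target_window = as.numeric(target_window),
      deamination_fraction = deamination_fraction,
      generations = as.integer(generations), het_fraction = het_fraction)
}

#' Sequencing / genotyping noise model
#'
#' @slot mean_depth target mean coverage (reads).
#' @slot depth_dispersion negative-binomial overdispersion of per-bin depth
#'   (0 = constant depth).
#' @slot error_rate per-read miscall probability.
#' @slot missing_below DP threshold below which a genotype is emitted
#'   missing.
#' @slot artifact_fraction fraction of emitted records that are injected
#'   low-quality artifacts (QUAL < 10).
#' @slot depth_bin bp width of the piecewise-constant depth bins.
#' @export
setClass("SequencingModel",
  representation(mean_depth = "numeric", depth_dispersion = "numeric",
                 error_rate = "numeric", missing_below = "numeric",
                 artifact_fraction = "numeric", depth_bin = "integer"))

setValidity("SequencingModel", function(object) {
  msg <- character()
  if (object@mean_depth <= 0) msg <- c(msg, "mean_depth must be > 0")
  if (object@error_rate < 0 || object@error_rate >= 0.5)
    msg <- c(msg, "error_rate must be in [0, 0.5)")
  if (object@depth_dispersion < 0)
    msg <- c(msg, "depth_dispersion must be >= 0")
  if (object@artifact_fraction < 0 || object@artifact_fraction >= 1)
    msg <- c(msg, "artifact_fraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SequencingModel
#'
#' Default mean depth follows the study design this simulator emulates
#' (19.2x short-read coverage); dispersion 0.2 gives realistic
#' coverage variance. `sequencingModel(error_rate = 0, depth_dispersion = 0,
#' missing_below = 0, artifact_fraction = 0)` is the noise-free limit.
#'
#' @param mean_depth,depth_dispersion,error_rate,missing_below see slots.
#' @param artifact_fraction,depth_bin see slots.
#' @return A [SequencingModel-class].
#' @export
sequencingModel <- function(mean_depth = 19.2, depth_dispersion = 0.2,
                            error_rate = 0.002, missing_below = 3,
                            artifact_fraction = 0.02, depth_bin = 100L) {
  new("SequencingModel", mean_depth = mean_depth,
      depth_dispersion = depth_dispersion, error_rate = error_rate,
      missing_below = as.numeric(missing_below),
      artifact_fraction = artifact_fraction, depth_bin = as.integer(depth_bin))
}

#' Ground truth of a simulated mutagenesis study
#'
#' @slot denovo DataFrame of de novo mutations: `lineage`, `chrom`, `pos`,
#'   `ref`, `alt`, `zygosity`, `generation`, `in_target`.
#' @slot standing DataFrame of standing variation: `stock` (stock id or
#'   `"__shared__"` for fixed differences from the reference common to all
#'   stocks), `chrom`, `pos`, `ref`, `alt`, `type` ("fixed"/"pocket"),
#'   `pocket` (pocket index or NA), `zygosity`.
#' @slot samples DataFrame of emitted samples: `sample_id`, `kind`
#'   ("background_individual", "mutagenized_individual",
#'   "isogenic_replicate"), `stock`, `lineage`, `line_id`, `generations`,
#'   `iso_chrom` (NA unless isogenic).
#' @slot iso_carriage DataFrame of variants carried (homozygous) on the
#'   isogenized chromosome per line: `line_id`, `chrom`, `pos`, `ref`, `alt`.
#' @slot pocket_carriage DataFrame recording which heterozygosity pockets
#'   were transmitted to each isogenic line: `line_id`, `stock`, `pocket`.
#' @export
setClass("SimTruth",
  representation(denovo = "DataFrame", standing = "DataFrame",
                 samples = "DataFrame", iso_carriage = "DataFrame",
                 pocket_carriage = "DataFrame"))

#' Per-sample run-length encoded depth tracks
#'
#' @slot tracks named list: sample id -> named list: chromosome ->
#'   [S4Vectors::Rle] of integer per-base depth.
#' @export
setClass("DepthTrackSet", representation(tracks = "list"))

setValidity("DepthTrackSet", function(object) {
  for (s in names(object@tracks))
    for (chrom in names(object@tracks[[s]]))
      if (!is(object@tracks[[s]][[chrom]], "Rle"))
        return(sprintf("tracks[[%s]][[%s]] is not an Rle", s, chrom))
  TRUE
})

#' Resampling enrichment result for one feature track
#'
#' @slot track track name.
#' @slot replicates DataFrame with one row per resampling replicate:
#'   `rep`, `focal_within`, `focal_beyond`, `bg_within`, `bg_beyond`,
#'   `odds_ratio`, `p_raw`, `p_adj`.
#' @slot params list of the enrichment parameters used (window, n_sample,
#'   n_reps, seed, with_replacement, degenerate flag).
#' @export
setClass("EnrichmentResult",
  representation(track = "character", replicates = "DataFrame",
                 params = "list"))
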