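#' @include AllClasses.R variant-io.R
NULL

BASES <- c("A", "C", "G", "T")

## sample n positions uniformly over the bases covered by a GRanges
.samplePosInRanges <- function(gr, n) {
  if (n == 0L) return(GRanges())
  w <- width(gr)
  cw <- cumsum(as.numeric(w))
  total <- cw[length(cw)]
  off <- pmax(1, ceiling(runif(n) * total))
  i <- findInterval(off - 1, cw) + 1L
  pos <- start(gr)[i] + (off - c(0, cw)[i]) - 1
  GRanges(seqnames(gr)[i], IRanges(as.integer(pos), width = 1L))
}

## reference bases at 1-based positions, batched per chromosome
.refBases <- function(sequences, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    out[k] <- as.character(Biostrings::extractAt(
      sequences[[ch]], IRanges(pos[k], width = 1L)))
  }
  out
}

#' PWM consensus sequence
#'
#' @param pwm a [PWMotif-class].
#' @return the consensus string (per-position most probable base).
#' @export
pwmConsensus <- function(pwm) {
  paste(BASES[apply(pwm@matrix, 2L, which.max)], collapse = "")
}

#' A small synthetic homeodomain-like PWM
#'
#' An 8-bp synthetic position weight matrix with a TAATCC core, used as the
#' default planted motif in simulations and examples. It is a synthetic
#' stand-in, not a database motif.
#'
#' @return A [PWMotif-class].
#' @export
examplePwm <- function() {
  consensus <- c("T", "A", "A", "T", "C", "C", "G", "C")
  m <- matrix(0.01, 4L, length(consensus), dimnames = list(BASES, NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 0.97
  PWMotif("synthetic_taatcc", m)
}

#' Build a simulated genome with planted motif sites and peaks
#'
#' Chromosome sequences are i.i.d. with the given GC content outside planted
#' sites. `n_motif_sites` non-overlapping motif matches (the PWM consensus,
#' on a random strand) are placed uniformly at random, allocated across
#' chromosomes proportionally to length; `n_peaks` regulatory intervals are
#' placed so that each contains at least one motif site.
#'
#' @param seed integer RNG seed; identical seeds give identical genomes.
#' @param chrom_lengths named integer vector of chromosome lengths (>= 10 kb
#'   recommended).
#' @param gc GC fraction of the background sequence.
#' @param pwm the [PWMotif-class] to plant.
#' @param n_motif_sites number of planted motif matches.
#' @param n_peaks number of peak intervals (each anchored on a motif site).
#' @param peak_width width of each peak interval in bp.
#' @return A [SimGenome-class].
#' @export
buildGenome <- function(seed, chrom_lengths, gc = 0.42, pwm = examplePwm(),
                        n_motif_sites = 60L, n_peaks = 20L,
                        peak_width = 500L) {
  stopifnot(length(chrom_lengths) >= 1L, !is.null(names(chrom_lengths)))
  set.seed(as.integer(seed))
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  w <- ncol(pwm@matrix)
  consensus <- strsplit(pwmConsensus(pwm), "")[[1L]]
  rc <- rev(chartr("ACGT", "TGCA", consensus))
  lens <- as.integer(chrom_lengths)
  names(lens) <- names(chrom_lengths)
  ## allocate sites proportionally to length, remainder to the longest
  alloc <- floor(n_motif_sites * lens / sum(lens))
  rem <- n_motif_sites - sum(alloc)
  if (rem > 0L) alloc[which.max(lens)] <- alloc[which.max(lens)] + rem
  seqs <- vector("list", length(lens))
  names(seqs) <- names(lens)
  site_list <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    base_v <- BASES[sample.int(4L, L, replace = TRUE, prob = probs)]
    n_sites <- alloc[[ch]]
    starts <- integer(0)
    if (n_sites > 0L) {
      if (n_sites * w * 2L > L)
        stop("capacity error: cannot place motif sites without overlap")
      tries <- 0L
      while (length(starts) < n_sites) {
        tries <- tries + 1L
        if (tries > 1000L)
          stop("capacity error: motif-site placement failed after bounded retries")
        cand <- sort(unique(c(starts,
                              sample.int(L - w + 1L, n_sites * 2L,
                                         replace = TRUE))))
        keep <- integer(0)
        last_end <- -1L
        for (s in cand) {
          if (s > last_end) { keep <- c(keep, s); last_end <- s + w - 1L }
          if (length(keep) == n_sites) break
        }
        starts <- keep
      }
      strands <- sample(c("+", "-"), n_sites, replace = TRUE)
      for (i in seq_len(n_sites)) {
        motif <- if (strands[i] == "+") consensus else rc
        base_v[starts[i]:(starts[i] + w - 1L)] <- motif
      }
      site_list[[ch]] <- GRanges(ch, IRanges(starts, width = w),
                                 strand = strands)
    }
    seqs[[ch]] <- paste(base_v, collapse = "")
  }
  sequences <- DNAStringSet(unlist(seqs))
  motif_sites <- if (length(site_list))
    sort(suppressWarnings(do.call(c, unname(site_list)))) else GRanges()
  n_found <- length(motif_sites)
  if (n_peaks > 0L) {
    if (n_peaks > n_found)
      stop("capacity error: n_peaks exceeds the number of motif sites")
    anchors <- motif_sites[sort(sample.int(n_found, n_peaks))]
    off <- floor(runif(n_peaks) * pmax(peak_width - width(anchors), 1L))
    pk_start <- pmax(1L, start(anchors) - as.integer(off))
    pk_end <- pmin(lens[as.character(seqnames(anchors))],
                   pk_start + peak_width - 1L)
    peaks <- sort(GRanges(seqnames(anchors), IRanges(pk_start, pk_end)))
  } else peaks <- GRanges()
  new("SimGenome", sequences = sequences, motif_sites = motif_sites,
      peak_sites = peaks, pwm = pwm)
}

.emptyVariantDF <- function(cols) {
  proto <- list(stock = character(0), lineage = character(0),
                chrom = character(0), pos = integer(0), ref = character(0),
                alt = character(0), type = character(0), pocket = integer(0),
                zygosity = character(0), generation = integer(0),
                in_target = logical(0), line_id = character(0))
  do.call(DataFrame, proto[cols])
}

.randomAlt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "",
         USE.NAMES = FALSE)
}

## non-deamination substitution: uniform over the alternatives that are NOT
## the deamination product, so that deamination_fraction is exactly the
## probability of a C>T / G>A change
.randomNonDeamAlt <- function(ref) {
  choices <- list(A = c("C", "G", "T"), T = c("A", "C", "G"),
                  C = c("A", "G"), G = c("C", "T"))
  vapply(ref, function(r) sample(choices[[r]], 1L), "", USE.NAMES = FALSE)
}

#' Simulate standing variation of laboratory stocks
#'
#' Each stock carries private fixed homozygous differences from the reference
#' (rate `fixed_diff_rate` per base) and `het_pocket_count` contiguous
#' pockets of residual heterozygosity of length `het_pocket_len`, shared by
#' every individual sampled from the stock. Fixed differences common to all
#' stocks (reference-vs-lab divergence) are generated at `shared_diff_rate`
#' under stock id `"__shared__"`.
#'
#' @param genome a [SimGenome-class].
#' @param n_stocks number of stocks (ids `stock1`, `stock2`, ...).
#' @param fixed_diff_rate per-base rate of stock-private fixed differences.
#' @param shared_diff_rate per-base rate of shared fixed differences.
#' @param het_pocket_count pockets of residual heterozygosity per stock.
#' @param het_pocket_len pocket length in bp.
#' @param pocket_het_rate per-base rate of heterozygous sites inside pockets.
#' @param seed integer RNG seed.
#' @return A [S4Vectors::DataFrame] of standing variants (the `standing`
#'   slot of [SimTruth-class]).
#' @export
simulateBackgroundStocks <- function(genome, n_stocks = 2L,
                                     fixed_diff_rate = 5e-4,
                                     shared_diff_rate = 2e-4,
                                     het_pocket_count = 2L,
                                     het_pocket_len = 1e4,
                                     pocket_het_rate = 2e-3, seed = 1L) {
  stopifnot(fixed_diff_rate >= 0, shared_diff_rate >= 0,
            pocket_het_rate >= 0, het_pocket_len >= 1)
  set.seed(as.integer(seed))
  lens <- Biostrings::width(genome@sequences)
  names(lens) <- names(genome@sequences)
  whole <- GRanges(names(lens), IRanges(1L, lens))
  total <- sum(as.numeric(lens))
  rows <- list()
  drawFixed <- function(stock, rate) {
    n <- rpois(1L, rate * total)
    if (n == 0L) return(NULL)
    gp <- .samplePosInRanges(whole, n)
    chrom <- as.character(seqnames(gp)); pos <- start(gp)
    dup <- duplicated(paste(chrom, pos))
    chrom <- chrom[!dup]; pos <- pos[!dup]
    ref <- .refBases(genome@sequences, chrom, pos)
    DataFrame(stock = stock, chrom = chrom, pos = as.integer(pos), ref = ref,
              alt = .randomAlt(ref), type = "fixed", pocket = NA_integer_,
              zygosity = "hom_alt")
  }
  rows$shared <- drawFixed("__shared__", shared_diff_rate)
  pocket_id <- 0L
  for (k in seq_len(n_stocks)) {
    stock <- paste0("stock", k)
    rows[[paste0(stock, "_fixed")]] <- drawFixed(stock, fixed_diff_rate)
    for (p in seq_len(het_pocket_count)) {
      pocket_id <- pocket_id + 1L
      anchor <- .samplePosInRanges(whole, 1L)
      ch <- as.character(seqnames(anchor))
      s <- min(start(anchor), lens[[ch]] - as.integer(het_pocket_len) + 1L)
      s <- max(1L, s)
      e <- min(lens[[ch]], s + as.integer(het_pocket_len) - 1L)
      n <- max(1L, rpois(1L, pocket_het_rate * (e - s + 1L)))
      pos <- sort(unique(s + floor(runif(n) * (e - s + 1L))))
      ref <- .refBases(genome@sequences, rep(ch, length(pos)), pos)
      rows[[paste0(stock, "_pocket", p)]] <-
        DataFrame(stock = stock, chrom = ch, pos = as.integer(pos),
                  ref = ref, alt = .randomAlt(ref), type = "pocket",
                  pocket = pocket_id, zygosity = "het")
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(.emptyVariantDF(c("stock", "chrom", "pos", "ref", "alt", "type",
                             "pocket", "zygosity")))
  out <- do.call(rbind, unname(rows))
  ## deduplicate within stock only; collisions between stocks stay
  out[!duplicated(paste(out$stock, out$chrom, out$pos)), ]
}

#' Elevated-rate target windows of a mutagenesis model
#'
#' Merged intervals formed by extending every planted motif site by
#' `target_window` bp on each side, clipped to the chromosomes.
#'
#' @param genome a [SimGenome-class].
#' @param model a [MutagenesisModel-class].
#' @return A GRanges of merged target windows.
#' @export
targetWindows <- function(genome, model) {
  lens <- Biostrings::width(genome@sequences)
  names(lens) <- names(genome@sequences)
  ms <- genome@motif_sites
  if (length(ms) == 0L) return(GRanges())
  ext <- GRanges(seqnames(ms),
                 IRanges(pmax(1L, start(ms) - as.integer(model@target_window)),
                         pmin(lens[as.character(seqnames(ms))],
                              end(ms) + as.integer(model@target_window))))
  reduce(sort(ext), ignore.strand = TRUE)
}

#' Expected observed per-base diploid mutation rate of a simulation
#'
#' The effective rate recovered by the downstream estimator on isogenized
#' chromosomes: the genome-averaged induced rate (base rate elevated
#' `target_rate_multiplier`-fold inside target windows), thinned by
#' isogenization (a heterozygous de novo mutation survives single-copy
#' sampling with probability 1/2; a homozygous one with probability 1).
#'
#' @param genome a [SimGenome-class].
#' @param model a [MutagenesisModel-class].
#' @param isogenized logical; apply the transmission thinning (default TRUE).
#' @return expected per-base per-generation diploid rate.
#' @export
expectedObservedRate <- function(genome, model, isogenized = TRUE) {
  L <- sum(as.numeric(Biostrings::width(genome@sequences)))
  W <- sum(as.numeric(width(targetWindows(genome, model))))
  genome_avg <- model@base_rate *
    ((L - W) + model@target_rate_multiplier * W) / L
  thin <- if (isogenized)
    model@het_fraction * 0.5 + (1 - model@het_fraction) else 1
  genome_avg * thin
}

#' Simulate germline mutagenesis along independent lineages
#'
#' Per lineage and generation, new mutation counts are Poisson with per-base
#' rate `base_rate` outside target windows and `base_rate *
#' target_rate_multiplier` inside. With probability `deamination_fraction`
#' an induced mutation is a deamination event at a C (yielding T) or a G
#' (yielding A); otherwise the substitution is uniform at a uniform position.
#' Each mutation is heterozygous with probability `het_fraction`, otherwise
#' homozygous. Lineages inherit all earlier mutations (accumulation across
#' generations is monotone).
#'
#' @param genome a [SimGenome-class].
#' @param model a [MutagenesisModel-class].
#' @param n_lineages number of independent lineages.
#' @param seed integer RNG seed.
#' @param lineage_ids optional character ids (default `L1`, `L2`, ...).
#' @return A [S4Vectors::DataFrame] of de novo mutations (the `denovo` slot
#'   of [SimTruth-class]).
#' @export
simulateMutagenesis <- function(genome, model, n_lineages, seed = 1L,
                                lineage_ids = paste0("L", seq_len(n_lineages))) {
  validObject(model)
  set.seed(as.integer(seed))
  lens <- Biostrings::width(genome@sequences)
  names(lens) <- names(genome@sequences)
  whole <- GRanges(names(lens), IRanges(1L, lens))
  win <- targetWindows(genome, model)
  outside <- GenomicRanges::setdiff(whole, win, ignore.strand = TRUE)
  W <- sum(as.numeric(width(win)))
  Lout <- sum(as.numeric(width(outside)))
  m <- model@target_rate_multiplier
  lambda_gen <- model@base_rate * (Lout + m * W)
  G <- model@generations
  counts <- rpois(n_lineages * G, lambda_gen)
  lineage <- rep(rep(lineage_ids, each = G), counts)
  generation <- rep(rep(seq_len(G), times = n_lineages), counts)
  M <- length(lineage)
  if (M == 0L)
    return(.emptyVariantDF(c("lineage", "chrom", "pos", "ref", "alt",
                             "zygosity", "generation", "in_target")))
  p_in <- if (W > 0) m * W / (m * W + Lout) else 0
  in_target <- runif(M) < p_in
  deam <- runif(M) < model@deamination_fraction
  chrom <- character(M); pos <- integer(M); ref <- character(M)
  drawRegion <- function(idx, region) {
    if (!length(idx)) return()
    gp <- .samplePosInRanges(region, length(idx))
    chrom[idx] <<- as.character(seqnames(gp))
    pos[idx] <<- start(gp)
    ref[idx] <<- .refBases(genome@sequences, chrom[idx], pos[idx])
  }
  drawRegion(which(in_target), win)
  drawRegion(which(!in_target), outside)
  ## deamination events must land on C or G: redraw within the same region
  for (iter in seq_len(1000L)) {
    bad <- which(deam & !(ref %in% c("C", "G")))
    if (!length(bad)) break
    drawRegion(bad[in_target[bad]], win)
    drawRegion(bad[!in_target[bad]], outside)
  }
  alt <- character(M)
  alt[deam] <- ifelse(ref[deam] == "C", "T", "A")
  if (any(!deam)) alt[!deam] <- .randomNonDeamAlt(ref[!deam])
  zyg <- ifelse(runif(M) < model@het_fraction, "het", "hom_alt")
  out <- DataFrame(lineage = lineage, chrom = chrom, pos = pos, ref = ref,
                   alt = alt, zygosity = zyg, generation = generation,
                   in_target = in_target)
  out[!duplicated(paste(out$lineage, out$chrom, out$pos)), ]
}

#' Assemble a SimTruth from simulator components
#'
#' @param denovo,standing,samples,iso_carriage,pocket_carriage see
#'   [SimTruth-class]; missing parts default to empty tables.
#' @return A [SimTruth-class].
#' @export
SimTruth <- function(denovo = NULL, standing = NULL, samples = NULL,
                     iso_carriage = NULL, pocket_carriage = NULL) {
  if (is.null(denovo))
    denovo <- .emptyVariantDF(c("lineage", "chrom", "pos", "ref", "alt",
                                "zygosity", "generation", "in_target"))
  if (is.null(standing))
    standing <- .emptyVariantDF(c("stock", "chrom", "pos", "ref", "alt",
                                  "type", "pocket", "zygosity"))
  if (is.null(samples))
    samples <- DataFrame(sample_id = character(0), kind = character(0),
                         stock = character(0), lineage = character(0),
                         line_id = character(0), generations = integer(0),
                         iso_chrom = character(0))
  if (is.null(iso_carriage))
    iso_carriage <- .emptyVariantDF(c("line_id", "chrom", "pos", "ref",
                                      "alt"))
  if (is.null(pocket_carriage))
    pocket_carriage <- DataFrame(line_id = character(0), stock = character(0),
                                 pocket = integer(0))
  new("SimTruth", denovo = denovo, standing = standing, samples = samples,
      iso_carriage = iso_carriage, pocket_carriage = pocket_carriage)
}

#' Derive an isogenic line from a lineage by single-copy sampling
#'
#' One chromosome copy of `iso_chrom` is sampled from the lineage:
#' a heterozygous de novo mutation is transmitted with probability 1/2 and a
#' homozygous one with probability 1; a residual-heterozygosity pocket of the
#' lineage's stock is transmitted (as a haplotype block, becoming homozygous)
#' with probability 1/2. `replicate_count` replicate samples share the
#' identical isogenized-chromosome variant set. On non-isogenized
#' chromosomes the replicates carry the stock's standing variation only
#' (the isogenizing crosses replace the lineage's other chromosomes).
#'
#' @param truth a [SimTruth-class] containing the lineage.
#' @param lineage lineage id present in `truth`.
#' @param replicate_count number of replicate samples (>= 1).
#' @param seed integer RNG seed.
#' @param iso_chrom the isogenized chromosome (default `"chr3"`).
#' @param line_id line label (default derived from the lineage).
#' @param stock the lineage's background stock (default: inferred from its
#'   sample rows, falling back to `"stock1"`).
#' @param generations the lineage's generation count G (default: inferred
#'   from its sample rows, falling back to the latest mutation generation).
#' @param include_parent also emit the lineage's parent individual as a
#'   member of the replicate group (the occasionally-sequenced male parent).
#' @return the updated [SimTruth-class].
#' @export
simulateIsogenization <- function(truth, lineage, replicate_count = 2L,
                                  seed = 1L, iso_chrom = "chr3",
                                  line_id = paste0("ISO_", lineage),
                                  stock = NULL, generations = NULL,
                                  include_parent = FALSE) {
  known <- unique(c(truth@samples$lineage, truth@denovo$lineage))
  if (!lineage %in% known)
    stop(sprintf("lookup error: unknown lineage '%s'", lineage))
  set.seed(as.integer(seed))
  samp <- truth@samples
  parent_row <- which(samp$lineage == lineage &
                      samp$kind == "mutagenized_individual")
  if (is.null(stock)) {
    stock <- if (length(parent_row)) samp$stock[parent_row[1L]] else
      unique(truth@samples$stock[truth@samples$lineage == lineage])[1L]
    if (is.na(stock) || !length(stock)) stock <- "stock1"
  }
  gen <- if (!is.null(generations)) generations
  else if (length(parent_row)) samp$generations[parent_row[1L]]
  else max(truth@denovo$generation[truth@denovo$lineage == lineage], 1L)
  dn <- truth@denovo[truth@denovo$lineage == lineage &
                     truth@denovo$chrom == iso_chrom, , drop = FALSE]
  keep <- dn$zygosity == "hom_alt" | runif(nrow(dn)) < 0.5
  carried <- dn[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  iso <- if (nrow(carried))
    cbind(DataFrame(line_id = rep(line_id, nrow(carried))), carried)
  else .emptyVariantDF(c("line_id", "chrom", "pos", "ref", "alt"))
  pockets <- unique(truth@standing$pocket[
    truth@standing$stock == stock & truth@standing$chrom == iso_chrom &
    truth@standing$type == "pocket"])
  pockets <- pockets[!is.na(pockets)]
  transmitted <- pockets[runif(length(pockets)) < 0.5]
  pc <- if (length(transmitted))
    DataFrame(line_id = line_id, stock = stock, pocket = transmitted)
  else DataFrame(line_id = character(0), stock = character(0),
                 pocket = integer(0))
  new_samples <- DataFrame(
    sample_id = paste0(line_id, "_rep", seq_len(replicate_count)),
    kind = "isogenic_replicate", stock = stock, lineage = lineage,
    line_id = line_id, generations = as.integer(gen), iso_chrom = iso_chrom)
  if (include_parent && length(parent_row))
    samp$line_id[parent_row[1L]] <- line_id
  new("SimTruth", denovo = truth@denovo, standing = truth@standing,
      samples = rbind(samp, new_samples),
      iso_carriage = rbind(truth@iso_carriage, iso),
      pocket_carriage = rbind(truth@pocket_carriage, pc))
}

## long carriage table: one row per (sample, variant) with allele dosage
.carriageTable <- function(truth) {
  dt_std <- data.table::as.data.table(as.data.frame(truth@standing))
  dt_dn <- data.table::as.data.table(as.data.frame(truth@denovo))
  dt_iso <- data.table::as.data.table(as.data.frame(truth@iso_carriage))
  dt_pc <- data.table::as.data.table(as.data.frame(truth@pocket_carriage))
  samp <- as.data.frame(truth@samples)
  out <- vector("list", nrow(samp))
  for (i in seq_len(nrow(samp))) {
    s <- samp[i, ]
    parts <- list()
    std <- dt_std[dt_std$stock %in% c("__shared__", s$stock), ]
    if (s$kind %in% c("background_individual", "mutagenized_individual")) {
      if (nrow(std))
        parts$std <- data.table::data.table(
          chrom = std$chrom, pos = std$pos, ref = std$ref, alt = std$alt,
          dosage = ifelse(std$zygosity == "het", 1L, 2L))
      dn <- dt_dn[dt_dn$lineage == s$lineage &
                  dt_dn$generation <= s$generations, ]
      if (nrow(dn))
        parts$dn <- data.table::data.table(
          chrom = dn$chrom, pos = dn$pos, ref = dn$ref, alt = dn$alt,
          dosage = ifelse(dn$zygosity == "het", 1L, 2L))
    } else if (s$kind == "isogenic_replicate") {
      iso_chrom <- s$iso_chrom
      other <- std[std$chrom != iso_chrom, ]
      if (nrow(other))
        parts$other <- data.table::data.table(
          chrom = other$chrom, pos = other$pos, ref = other$ref,
          alt = other$alt,
          dosage = ifelse(other$zygosity == "het", 1L, 2L))
      fixed_iso <- std[std$chrom == iso_chrom & std$type == "fixed", ]
      if (nrow(fixed_iso))
        parts$fixed <- data.table::data.table(
          chrom = fixed_iso$chrom, pos = fixed_iso$pos, ref = fixed_iso$ref,
          alt = fixed_iso$alt, dosage = 2L)
      tp <- dt_pc$pocket[dt_pc$line_id == s$line_id]
      pk <- std[std$chrom == iso_chrom & std$type == "pocket" &
                std$pocket %in% tp, ]
      if (nrow(pk))
        parts$pk <- data.table::data.table(
          chrom = pk$chrom, pos = pk$pos, ref = pk$ref, alt = pk$alt,
          dosage = 2L)
      iso <- dt_iso[dt_iso$line_id == s$line_id, ]
      if (nrow(iso))
        parts$iso <- data.table::data.table(
          chrom = iso$chrom, pos = iso$pos, ref = iso$ref, alt = iso$alt,
          dosage = 2L)
    }
    if (!length(parts)) next
    tab <- data.table::rbindlist(parts)
    tab$sample_id <- s$sample_id
    out[[i]] <- tab
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.table::data.table(sample_id = character(0),
                                  chrom = character(0), pos = integer(0),
                                  ref = character(0), alt = character(0),
                                  dosage = integer(0)))
  data.table::rbindlist(out)
}

## negative-binomial (or constant) depth per depth_bin-sized bin, as Rle
.simulateDepth <- function(samples, chrom_lengths, seq_model) {
  bin <- seq_model@depth_bin
  tracks <- lapply(samples, function(s) {
    per_chrom <- lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      nb <- ceiling(L / bin)
      vals <- if (seq_model@depth_dispersion == 0)
        rep(as.integer(round(seq_model@mean_depth)), nb)
      else as.integer(rnbinom(nb, mu = seq_model@mean_depth,
                              size = 1 / seq_model@depth_dispersion))
      lens <- rep(bin, nb)
      lens[nb] <- L - bin * (nb - 1L)
      Rle(vals, lens)
    })
    names(per_chrom) <- names(chrom_lengths)
    per_chrom
  })
  names(tracks) <- samples
  new("DepthTrackSet", tracks = tracks)
}

#' Emit a joint variant table, depth tracks and manifest from simulated truth
#'
#' Per-sample depth is drawn per bin from an overdispersed count
#' distribution around `mean_depth`; allele observations are binomial in the
#' true allele dosage with per-read error `error_rate`; genotypes are called
#' by allele-fraction thresholds (< 0.25 hom ref, > 0.75 hom alt, else het)
#' and emitted missing when DP < `missing_below`. True variant sites receive
#' a high QUAL; a configurable fraction of emitted records are injected
#' artifacts with QUAL < 10. The emitted manifest records per-sample
#' generation counts, mean depths, replicate groups and the per-chromosome
#' full/mutagenized/background sets (isogenic replicates belong to the
#' mutagenized set of their isogenized chromosome only).
#'
#' @param truth a [SimTruth-class].
#' @param genome the generating [SimGenome-class].
#' @param seq_model a [SequencingModel-class].
#' @param seed integer RNG seed.
#' @return list with `jvt` ([JointVariantTable-class]), `depth`
#'   ([DepthTrackSet-class]) and `manifest` ([SampleManifest-class]).
#' @export
emitJointTable <- function(truth, genome, seq_model, seed = 1L) {
  validObject(seq_model)
  set.seed(as.integer(seed))
  chrom_lengths <- Biostrings::width(genome@sequences)
  names(chrom_lengths) <- names(genome@sequences)
  samp <- as.data.frame(truth@samples)
  sample_ids <- samp$sample_id
  carriage <- .carriageTable(truth)
  sites <- unique(carriage[, c("chrom", "pos", "ref", "alt")])
  data.table::setorder(sites, chrom, pos, alt)
  n_true <- nrow(sites)
  ## injected artifact sites
  n_art <- if (seq_model@artifact_fraction > 0 && n_true > 0)
    rpois(1L, seq_model@artifact_fraction /
            (1 - seq_model@artifact_fraction) * n_true) else 0L
  if (n_art > 0L) {
    whole <- GRanges(names(chrom_lengths), IRanges(1L, chrom_lengths))
    gp <- .samplePosInRanges(whole, n_art)
    art_chrom <- as.character(seqnames(gp)); art_pos <- start(gp)
    keep <- !paste(art_chrom, art_pos) %in% paste(sites$chrom, sites$pos)
    art_chrom <- art_chrom[keep]; art_pos <- art_pos[keep]
    n_art <- length(art_chrom)
    art_ref <- .refBases(genome@sequences, art_chrom, art_pos)
    art <- data.table::data.table(chrom = art_chrom, pos = art_pos,
                                  ref = art_ref, alt = .randomAlt(art_ref))
  } else art <- NULL
  all_sites <- if (n_art > 0L) rbind(sites, art) else sites
  data.table::setorder(all_sites, chrom, pos, alt)
  ns <- nrow(all_sites)
  is_artifact <- if (n_art > 0L)
    paste(all_sites$chrom, all_sites$pos) %in% paste(art$chrom, art$pos)
  else rep(FALSE, ns)
  key <- paste(all_sites$chrom, all_sites$pos, all_sites$ref, all_sites$alt)
  ## dosage matrix
  D <- matrix(0L, ns, length(sample_ids),
              dimnames = list(NULL, sample_ids))
  if (nrow(carriage)) {
    ri <- match(paste(carriage$chrom, carriage$pos, carriage$ref,
                      carriage$alt), key)
    ci <- match(carriage$sample_id, sample_ids)
    D[cbind(ri, ci)] <- carriage$dosage
  }
  ## artifact carriers: one random sample each, low AO het-like signal
  art_cell <- if (any(is_artifact))
    cbind(which(is_artifact),
          sample.int(length(sample_ids), sum(is_artifact), replace = TRUE))
  else NULL
  depth <- .simulateDepth(sample_ids, chrom_lengths, seq_model)
  bin <- seq_model@depth_bin
  DP <- matrix(0L, ns, length(sample_ids))
  for (j in seq_along(sample_ids)) {
    tr <- depth@tracks[[sample_ids[j]]]
    for (ch in unique(all_sites$chrom)) {
      k <- which(all_sites$chrom == ch)
      binvals <- runValue(tr[[ch]])
      DP[k, j] <- binvals[pmin((all_sites$pos[k] - 1L) %/% bin + 1L,
                               length(binvals))]
    }
  }
  e <- seq_model@error_rate
  p_alt <- D / 2 * (1 - 2 * e) + e
  AO <- matrix(0L, ns, length(sample_ids))
  draw <- p_alt > 0
  AO[draw] <- rbinom(sum(draw), DP[draw], p_alt[draw])
  if (!is.null(art_cell)) {
    ## artifact signal: 1-2 alternative reads in the chosen sample
    AO[art_cell] <- pmin(DP[art_cell],
                         1L + rbinom(nrow(art_cell), 1L, 0.5))
  }
  RO <- DP - AO
  af <- ifelse(DP > 0, AO / DP, 0)
  GT <- matrix(GT_HOM_REF, ns, length(sample_ids))
  GT[af >= 0.25 & af <= 0.75 & (AO > 0)] <- GT_HET
  GT[af > 0.75] <- GT_HOM_ALT
  miss <- DP < seq_model@missing_below | DP == 0L
  GT[miss] <- NA_integer_
  DP[miss] <- NA_integer_; RO[miss] <- NA_integer_; AO[miss] <- NA_integer_
  qual <- round(runif(ns, 50, 2000), 1)
  qual[is_artifact] <- round(runif(sum(is_artifact), 0, 9.99), 2)
  colnames(GT) <- colnames(DP) <- colnames(RO) <- colnames(AO) <- sample_ids
  jvt <- JointVariantTable(chrom = all_sites$chrom, pos = all_sites$pos,
                           ref = all_sites$ref, alt = all_sites$alt,
                           qual = qual, GT = GT, DP = DP, RO = RO, AO = AO)
  ## manifest
  mean_depth <- vapply(sample_ids, function(s) {
    tr <- depth@tracks[[s]]
    tot <- sum(vapply(tr, function(r) sum(as.numeric(runValue(r)) *
                                            runLength(r)), 0))
    tot / sum(as.numeric(chrom_lengths))
  }, 0)
  sets <- lapply(names(chrom_lengths), function(ch) {
    iso_here <- samp$kind == "isogenic_replicate" &
      !is.na(samp$iso_chrom) & samp$iso_chrom == ch
    mut_ind <- samp$kind == "mutagenized_individual"
    bg <- samp$kind == "background_individual"
    mut <- mut_ind | iso_here
    list(full = samp$sample_id[mut | bg],
         mutagenized = samp$sample_id[mut],
         background = samp$sample_id[bg])
  })
  names(sets) <- names(chrom_lengths)
  manifest <- SampleManifest(
    sample_ids = sample_ids, line_id = samp$line_id,
    generations = samp$generations, mean_depth = mean_depth,
    role = ifelse(samp$kind == "isogenic_replicate",
                  paste0("isogenic_", samp$iso_chrom), samp$kind),
    sets = sets)
  list(jvt = jvt, depth = depth, manifest = manifest)
}

#' Simulate a complete mutagenesis study
#'
#' End-to-end orchestration of the forward simulator: genome construction,
#' standing variation of laboratory stocks, germline mutagenesis of
#' independent lineages under the elevated-rate model, natural mutation
#' accumulation in background individuals (the same generative process with
#' multiplier 1 and the background deamination fraction), isogenization of a
#' subset of lineages with replicate sequencing, and emission of the joint
#' variant table, depth tracks and manifest.
#'
#' All sub-steps derive their seeds from `seed`; identical seeds give
#' identical output.
#'
#' @param seed integer RNG seed.
#' @param chrom_lengths named chromosome lengths.
#' @param gc,pwm,n_motif_sites,n_peaks passed to [buildGenome()].
#' @param n_stocks,fixed_diff_rate,shared_diff_rate,het_pocket_count
#'   passed to [simulateBackgroundStocks()].
#' @param het_pocket_len,pocket_het_rate passed to
#'   [simulateBackgroundStocks()].
#' @param mut_model [MutagenesisModel-class] for mutagenized lineages.
#' @param bg_model [MutagenesisModel-class] for background individuals
#'   (natural mutation accumulation; multiplier 1).
#' @param n_mut_individuals mutagenized lineages sampled as diploid
#'   individuals.
#' @param n_iso_lines mutagenized lineages isogenized into replicate lines.
#' @param replicate_count replicates per isogenic line.
#' @param parent_fraction fraction of isogenic lines whose parent individual
#'   joins the replicate group.
#' @param n_background background individuals (spread across stocks).
#' @param seq_model a [SequencingModel-class].
#' @param iso_chrom chromosome that is isogenized.
#' @return list with `genome`, `truth`, `jvt`, `depth`, `manifest`.
#' @export
simulateStudy <- function(seed = 1L,
                          chrom_lengths = c(chr2 = 200000L, chr3 = 200000L),
                          gc = 0.42, pwm = examplePwm(),
                          n_motif_sites = 60L, n_peaks = 20L,
                          n_stocks = 2L, fixed_diff_rate = 5e-4,
                          shared_diff_rate = 2e-4, het_pocket_count = 2L,
                          het_pocket_len = 1e4, pocket_het_rate = 2e-3,
                          mut_model = mutagenesisModel(base_rate = 2e-6),
                          bg_model = mutagenesisModel(
                            base_rate = 2e-7, target_rate_multiplier = 1,
                            deamination_fraction = 0.45,
                            generations = mut_model@generations,
                            het_fraction = mut_model@het_fraction),
                          n_mut_individuals = 4L, n_iso_lines = 6L,
                          replicate_count = 2L, parent_fraction = 0.15,
                          n_background = 6L,
                          seq_model = sequencingModel(),
                          iso_chrom = "chr3") {
  seed <- as.integer(seed) %% 1000000000L
  genome <- buildGenome(seed + 1L, chrom_lengths, gc = gc, pwm = pwm,
                        n_motif_sites = n_motif_sites, n_peaks = n_peaks)
  standing <- simulateBackgroundStocks(
    genome, n_stocks = n_stocks, fixed_diff_rate = fixed_diff_rate,
    shared_diff_rate = shared_diff_rate,
    het_pocket_count = het_pocket_count, het_pocket_len = het_pocket_len,
    pocket_het_rate = pocket_het_rate, seed = seed + 2L)
  n_lineages <- n_mut_individuals + n_iso_lines
  denovo_mut <- simulateMutagenesis(genome, mut_model, n_lineages,
                                    seed = seed + 3L)
  bg_ids <- paste0("BG", seq_len(n_background))
  denovo_bg <- if (n_background > 0L)
    simulateMutagenesis(genome, bg_model, n_background, seed = seed + 4L,
                        lineage_ids = bg_ids)
  else NULL
  denovo <- if (!is.null(denovo_bg)) rbind(denovo_mut, denovo_bg)
  else denovo_mut
  stocks <- paste0("stock", seq_len(n_stocks))
  lineage_ids <- paste0("L", seq_len(n_lineages))
  ## mutagenized lineages derive from the same stocks that are sequenced as
  ## background, so stock-fixed differences are never private to either set
  lineage_stocks <- rep(stocks, length.out = n_lineages)
  names(lineage_stocks) <- lineage_ids
  samples <- DataFrame(
    sample_id = c(paste0("MUT_", lineage_ids)[seq_len(n_mut_individuals)],
                  bg_ids),
    kind = c(rep("mutagenized_individual", n_mut_individuals),
             rep("background_individual", n_background)),
    stock = c(unname(lineage_stocks[seq_len(n_mut_individuals)]),
              rep(stocks, length.out = n_background)),
    lineage = c(lineage_ids[seq_len(n_mut_individuals)], bg_ids),
    line_id = NA_character_,
    generations = c(rep(mut_model@generations, n_mut_individuals),
                    rep(bg_model@generations, n_background)),
    iso_chrom = NA_character_)
  truth <- SimTruth(denovo = denovo, standing = standing, samples = samples)
  set.seed(seed + 5L)
  with_parent <- runif(n_iso_lines) < parent_fraction
  iso_lineages <- lineage_ids[n_mut_individuals + seq_len(n_iso_lines)]
  for (i in seq_len(n_iso_lines)) {
    lg <- iso_lineages[i]
    line_id <- sprintf("ISO%02d", i)
    if (with_parent[i]) {
      parent <- DataFrame(sample_id = paste0(line_id, "_parent"),
                          kind = "mutagenized_individual",
                          stock = unname(lineage_stocks[lg]),
                          lineage = lg, line_id = line_id,
                          generations = mut_model@generations,
                          iso_chrom = NA_character_)
      truth@samples <- rbind(truth@samples, parent)
    }
    truth <- simulateIsogenization(truth, lg,
                                   replicate_count = replicate_count,
                                   seed = seed + 10L + i,
                                   iso_chrom = iso_chrom, line_id = line_id,
                                   stock = unname(lineage_stocks[lg]),
                                   generations = mut_model@generations)
  }
  emitted <- emitJointTable(truth, genome, seq_model, seed = seed + 9000L)
  c(list(genome = genome, truth = truth), emitted)
}
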