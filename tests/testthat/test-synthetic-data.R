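test_that("genome construction plants non-overlapping consensus sites", {
  g <- buildGenome(3, c(chrA = 100000L), n_motif_sites = 50L,
                   n_peaks = 15L)
  ms <- g@motif_sites
  expect_length(ms, 50L)
  expect_true(all(BiocGenerics::width(ms) == 8L))
  o <- order(BiocGenerics::start(ms))
  expect_true(all(diff(BiocGenerics::start(ms)[o]) >= 8L))
  cons <- pwmConsensus(g@pwm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  planted <- as.character(Biostrings::extractAt(
    g@sequences[["chrA"]],
    IRanges::IRanges(BiocGenerics::start(ms), BiocGenerics::end(ms))))
  expect_true(all(ifelse(as.character(BiocGenerics::strand(ms)) == "+",
                         planted == cons, planted == rc)))
  ## each peak contains at least one motif site
  ov <- GenomicRanges::countOverlaps(g@peak_sites, ms)
  expect_true(all(ov >= 1L))
})

test_that("gc = 0 yields A/T sequence outside planted sites", {
  g <- buildGenome(4, c(chrA = 20000L), gc = 0, n_motif_sites = 5L,
                   n_peaks = 2L)
  outside <- GenomicRanges::setdiff(
    GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 20000)),
    g@motif_sites, ignore.strand = TRUE)
  seqs <- as.character(Biostrings::extractAt(
    g@sequences[["chrA"]],
    IRanges::IRanges(BiocGenerics::start(outside),
                     BiocGenerics::end(outside))))
  expect_false(grepl("[CG]", paste(seqs, collapse = "")))
})

test_that("identical seeds give identical genomes and emitted tables", {
  a <- buildGenome(11, c(chrA = 30000L), n_motif_sites = 10L, n_peaks = 3L)
  b <- buildGenome(11, c(chrA = 30000L), n_motif_sites = 10L, n_peaks = 3L)
  expect_identical(as.character(a@sequences), as.character(b@sequences))
  expect_identical(BiocGenerics::start(a@motif_sites),
                   BiocGenerics::start(b@motif_sites))
  s1 <- simulateStudy(seed = 12, chrom_lengths = c(chr3 = 60000L),
                      n_motif_sites = 15L, n_peaks = 5L)
  s2 <- simulateStudy(seed = 12, chrom_lengths = c(chr3 = 60000L),
                      n_motif_sites = 15L, n_peaks = 5L)
  expect_identical(genotypes(s1$jvt), genotypes(s2$jvt))
  expect_identical(qualScore(s1$jvt), qualScore(s2$jvt))
})

test_that("stock simulation produces shared pockets and respects zero rates", {
  g <- buildGenome(5, c(chrA = 200000L), n_motif_sites = 10L, n_peaks = 3L)
  st <- simulateBackgroundStocks(g, n_stocks = 2L, fixed_diff_rate = 0,
                                 shared_diff_rate = 0,
                                 het_pocket_count = 2L,
                                 het_pocket_len = 5000, seed = 6)
  expect_true(all(st$type == "pocket"))
  for (stock in c("stock1", "stock2")) {
    sub <- st[st$stock == stock, ]
    expect_length(unique(sub$pocket), 2L)
    for (p in unique(sub$pocket)) {
      span <- range(sub$pos[sub$pocket == p])
      expect_lte(span[2] - span[1], 5000)
    }
    expect_true(all(sub$zygosity == "het"))
  }
  ## stock-private variant sets collide only at the Poisson expectation
  st2 <- simulateBackgroundStocks(g, n_stocks = 2L, fixed_diff_rate = 2e-3,
                                  shared_diff_rate = 0,
                                  het_pocket_count = 0L, seed = 7)
  k1 <- st2[st2$stock == "stock1", ]; k2 <- st2[st2$stock == "stock2", ]
  n_coll <- length(intersect(paste(k1$chrom, k1$pos),
                             paste(k2$chrom, k2$pos)))
  lambda <- nrow(k1) * nrow(k2) / 200000
  expect_lte(n_coll, qpois(0.9999, lambda))
})

test_that("mutagenesis places mutations uniformly when the multiplier is 1", {
  g <- buildGenome(8, c(chr3 = 200000L), n_motif_sites = 60L, n_peaks = 10L)
  m <- mutagenesisModel(base_rate = 3e-5, target_rate_multiplier = 1,
                        generations = 10L)
  dn <- simulateMutagenesis(g, m, n_lineages = 25L, seed = 9)
  expect_gte(nrow(dn), 1000L)
  w_frac <- sum(as.numeric(BiocGenerics::width(targetWindows(g, m)))) / 200000
  p_hat <- mean(dn$in_target)
  expect_lt(abs(p_hat - w_frac), 3 * sqrt(w_frac * (1 - w_frac) / nrow(dn)))
  ## in_target flags agree with the window intervals
  win <- targetWindows(g, m)
  inside <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(dn$chrom, IRanges::IRanges(dn$pos, dn$pos)),
    win) > 0
  expect_identical(unname(inside), unname(dn$in_target))
})

test_that("doubling generations roughly doubles mutation counts", {
  g <- buildGenome(8, c(chr3 = 200000L), n_motif_sites = 20L, n_peaks = 5L)
  n1 <- nrow(simulateMutagenesis(
    g, mutagenesisModel(base_rate = 1e-5, target_rate_multiplier = 1,
                        generations = 10L), 25L, seed = 21))
  n2 <- nrow(simulateMutagenesis(
    g, mutagenesisModel(base_rate = 1e-5, target_rate_multiplier = 1,
                        generations = 20L), 25L, seed = 22))
  ratio <- n2 / n1
  expect_lt(abs(ratio - 2), 0.35)
})

test_that("deamination_fraction controls the mutation spectrum exactly", {
  g <- buildGenome(8, c(chr3 = 150000L), n_motif_sites = 20L, n_peaks = 5L)
  dn <- simulateMutagenesis(
    g, mutagenesisModel(base_rate = 2e-5, deamination_fraction = 1,
                        generations = 10L), 5L, seed = 31)
  expect_true(all((dn$ref == "C" & dn$alt == "T") |
                  (dn$ref == "G" & dn$alt == "A")))
  dn5 <- simulateMutagenesis(
    g, mutagenesisModel(base_rate = 2e-5, deamination_fraction = 0.5,
                        generations = 10L), 10L, seed = 32)
  frac <- mean(classifyVariant(dn5$ref, dn5$alt) == "CtoT_GtoA")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(dn5)))
})

test_that("isogenization transmits heterozygous mutations at rate 1/2", {
  dn <- S4Vectors::DataFrame(
    lineage = "L1", chrom = "chr3", pos = seq_len(500L) * 10L,
    ref = "C", alt = "T", zygosity = "het", generation = 1L,
    in_target = FALSE)
  truth <- SimTruth(denovo = dn)
  t2 <- simulateIsogenization(truth, "L1", replicate_count = 2L, seed = 41)
  frac <- nrow(t2@iso_carriage) / 500
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 500))
  reps <- t2@samples[t2@samples$kind == "isogenic_replicate", ]
  expect_equal(nrow(reps), 2L)
  expect_length(unique(reps$line_id), 1L)
  ## homozygous mutations always transmit
  dn$zygosity <- "hom_alt"
  t3 <- simulateIsogenization(SimTruth(denovo = dn), "L1",
                              replicate_count = 1L, seed = 42)
  expect_equal(nrow(t3@iso_carriage), 500L)
  expect_equal(sum(t3@samples$kind == "isogenic_replicate"), 1L)
  expect_error(simulateIsogenization(truth, "nope", seed = 1),
               "lookup error")
})

test_that("noise-free deep-coverage emission reproduces truth genotypes", {
  sim <- simulateStudy(
    seed = 55, chrom_lengths = c(chr3 = 50000L), n_motif_sites = 10L,
    n_peaks = 3L, mut_model = mutagenesisModel(base_rate = 5e-6),
    seq_model = sequencingModel(mean_depth = 100, depth_dispersion = 0,
                                error_rate = 0, missing_below = 0,
                                artifact_fraction = 0),
    n_mut_individuals = 3L, n_iso_lines = 2L, n_background = 4L,
    parent_fraction = 0)
  gt <- genotypes(sim$jvt)
  expect_false(anyNA(gt))
  key <- paste(variantChrom(sim$jvt), variantPos(sim$jvt),
               altAllele(sim$jvt))
  ## one background individual: its calls must equal stock standing truth
  samp <- as.data.frame(sim$truth@samples)
  bg <- samp$sample_id[samp$kind == "background_individual"][1]
  st <- as.data.frame(sim$truth@standing)
  st <- st[st$stock %in% c("__shared__", samp$stock[samp$sample_id == bg]), ]
  dn_bg <- as.data.frame(sim$truth@denovo)
  dn_bg <- dn_bg[dn_bg$lineage == bg, ]
  want <- setNames(rep(0L, length(key)), key)
  if (nrow(st)) want[paste(st$chrom, st$pos, st$alt)] <-
    ifelse(st$zygosity == "het", 1L, 2L)
  if (nrow(dn_bg)) want[paste(dn_bg$chrom, dn_bg$pos, dn_bg$alt)] <-
    ifelse(dn_bg$zygosity == "het", 1L, 2L)
  expect_identical(unname(gt[, bg]), unname(want))
  ## one isogenic replicate: homozygous for the line's carried variants
  iso <- samp$sample_id[samp$kind == "isogenic_replicate"][1]
  line <- samp$line_id[samp$sample_id == iso]
  carried <- as.data.frame(sim$truth@iso_carriage)
  carried <- carried[carried$line_id == line, ]
  if (nrow(carried)) {
    idx <- match(paste(carried$chrom, carried$pos, carried$alt), key)
    expect_true(all(gt[idx, iso] == 2L))
  }
})

test_that("low depth with a missingness threshold blanks genotypes", {
  sim <- simulateStudy(
    seed = 56, chrom_lengths = c(chr3 = 40000L), n_motif_sites = 10L,
    n_peaks = 3L, mut_model = mutagenesisModel(base_rate = 2e-6),
    seq_model = sequencingModel(mean_depth = 5, depth_dispersion = 0,
                                missing_below = 10,
                                artifact_fraction = 0),
    n_iso_lines = 2L, n_background = 3L)
  expect_true(all(is.na(genotypes(sim$jvt))))
})

test_that("the injected artifact fraction shows up as low-QUAL records", {
  sim <- simulateStudy(
    seed = 57, chrom_lengths = c(chr2 = 150000L, chr3 = 150000L),
    n_motif_sites = 30L, n_peaks = 10L,
    mut_model = mutagenesisModel(base_rate = 2e-6),
    seq_model = sequencingModel(artifact_fraction = 0.1),
    n_iso_lines = 4L, n_background = 4L)
  frac <- mean(qualScore(sim$jvt) < 10)
  n <- nVariants(sim$jvt)
  expect_gt(n, 300L)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 0.01)
})

test_that("expectedObservedRate combines window elevation and transmission", {
  g <- buildGenome(61, c(chr3 = 100000L), n_motif_sites = 20L, n_peaks = 5L)
  m1 <- mutagenesisModel(base_rate = 1e-7, target_rate_multiplier = 1,
                         het_fraction = 0)
  expect_equal(expectedObservedRate(g, m1), 1e-7)
  m2 <- mutagenesisModel(base_rate = 1e-7, target_rate_multiplier = 1,
                         het_fraction = 1)
  expect_equal(expectedObservedRate(g, m2), 5e-8)
  expect_equal(expectedObservedRate(g, m2, isogenized = FALSE), 1e-7)
  m3 <- mutagenesisModel(base_rate = 1e-7, target_rate_multiplier = 50,
                         het_fraction = 0)
  W <- sum(as.numeric(BiocGenerics::width(targetWindows(g, m3))))
  expect_equal(expectedObservedRate(g, m3),
               1e-7 * ((1e5 - W) + 50 * W) / 1e5)
})
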