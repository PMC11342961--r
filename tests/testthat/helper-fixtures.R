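## Randomised fixtures shared across tests. Each generator takes a seed and
## is fully deterministic given it.

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

## small convenience constructor around JointVariantTable()
make_jvt <- function(chrom, pos, ref, alt, qual, gt, dp = NULL, ro = NULL,
                     ao = NULL) {
  code <- matrix(match(gt, GT_LEVELS) - 1L, nrow = length(pos),
                 dimnames = dimnames(gt))
  code[code == 3L] <- NA_integer_
  if (is.null(dp)) dp <- matrix(20L, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(ao)) ao <- matrix(10L, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(ro)) ro <- dp - ao
  dp[is.na(code)] <- NA_integer_
  ro[is.na(code)] <- NA_integer_
  ao[is.na(code)] <- NA_integer_
  JointVariantTable(chrom, pos, ref, alt, qual, code, dp, ro, ao)
}

## a random joint call plus the equivalent plain-list records and design for
## the brute-force oracle
random_instance <- function(seed, n_var = NULL, n_samples = NULL,
                            chrom = "chr3") {
  set.seed(seed)
  if (is.null(n_var)) n_var <- sample(50:500, 1)
  if (is.null(n_samples)) n_samples <- sample(8:20, 1)
  n_mut <- max(2L, floor(n_samples * 0.4))
  n_bg <- max(2L, floor(n_samples * 0.3))
  n_extra <- n_samples - n_mut - n_bg     # balancer-like, full set only
  samples <- sprintf("s%02d", seq_len(n_samples))
  mut <- samples[seq_len(n_mut)]
  bg <- samples[n_mut + seq_len(n_bg)]
  ## replicate groups of 2-3 among the mutagenized samples
  line_id <- setNames(rep(NA_character_, n_samples), samples)
  i <- 1L; l <- 0L
  while (i + 1L <= n_mut) {
    l <- l + 1L
    size <- min(sample(2:3, 1), n_mut - i + 1L)
    line_id[mut[i:(i + size - 1L)]] <- sprintf("line%02d", l)
    i <- i + size
  }
  mean_depth <- setNames(round(runif(n_samples, 3, 30), 1), samples)
  pos <- sort(sample.int(2000000L, n_var))
  ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), "", USE.NAMES = FALSE)
  qual <- round(runif(n_var, 0, 60), 1)
  gt <- matrix("hom_ref", n_var, n_samples,
               dimnames = list(NULL, samples))
  for (i in seq_len(n_var)) {
    n_carry <- sample(0:4, 1, prob = c(.25, .35, .2, .1, .1))
    if (n_carry > 0)
      gt[i, sample(samples, n_carry)] <-
        sample(c("het", "hom_alt"), n_carry, replace = TRUE,
               prob = c(.7, .3))
    n_miss <- rbinom(1, n_samples, 0.08)
    if (n_miss > 0) gt[i, sample(samples, n_miss)] <- "missing"
  }
  ## occasionally plant an introgression-like cluster in one mutagenized
  ## sample: many private variants within a short window
  if (runif(1) < 0.4 && n_var >= 60) {
    s <- sample(mut, 1)
    k <- sample(22:30, 1)
    rows <- sample.int(n_var, k)
    gt[rows, ] <- "hom_ref"
    gt[rows, s] <- "het"
    pos[rows] <- sort(sample(seq(100000L, 130000L), k))
    pos <- pmax(1L, pos)
  }
  dp <- matrix(sample(c(0:30, 150:210), n_var * n_samples, replace = TRUE),
               n_var, n_samples, dimnames = list(NULL, samples))
  ao <- matrix(0L, n_var, n_samples, dimnames = list(NULL, samples))
  ao[gt == "het"] <- sapply(dp[gt == "het"], function(d)
    sample.int(max(d, 1L), 1))
  ao[gt == "hom_alt"] <- dp[gt == "hom_alt"]
  ao <- pmin(ao, dp)
  ro <- dp - ao
  jvt <- make_jvt(rep(chrom, n_var), pos, ref, alt, qual, gt, dp, ro, ao)
  manifest <- SampleManifest(
    sample_ids = samples, line_id = line_id, generations = 10L,
    mean_depth = mean_depth,
    sets = setNames(list(list(full = samples, mutagenized = mut,
                              background = bg)), chrom))
  records <- lapply(seq_len(n_var), function(i) {
    g <- gt[i, ]
    list(chrom = chrom, pos = pos[i], ref = ref[i], alt = alt[i],
         qual = qual[i],
         gt = as.list(g),
         dp = as.list(ifelse(g == "missing", NA_integer_, dp[i, ])),
         ro = as.list(ifelse(g == "missing", NA_integer_, ro[i, ])),
         ao = as.list(ifelse(g == "missing", NA_integer_, ao[i, ])))
  })
  design <- list(full = samples, mut = mut, bg = bg, line_id = line_id,
                 mean_depth = mean_depth,
                 thresholds = list(chr2 = 9, chr3 = 5))
  list(jvt = jvt, manifest = manifest, records = records, design = design,
       chrom = chrom)
}

## random PWM with optional zero cells
random_pwm <- function(seed, width = NULL) {
  set.seed(seed)
  if (is.null(width)) width <- sample(4:10, 1)
  m <- matrix(runif(4 * width), 4, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  if (runif(1) < 0.3) m[sample.int(length(m), 3)] <- 0
  m <- sweep(m, 2, colSums(m), "/")
  PWMotif(sprintf("rand%d", seed), m)
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
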