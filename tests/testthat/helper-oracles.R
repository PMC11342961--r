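## Independent brute-force reference implementations, written as plain nested
## loops over samples and variants. They deliberately share no code with the
## package internals.

## ---- private-variant pipeline ----------------------------------------------
## records: list of list(chrom, pos, ref, alt, qual,
##                       gt/dp/ro/ao: named vectors over samples; gt in
##                       {"hom_ref","het","hom_alt","missing"})
## design: list(full, mut, bg, line_id (named), mean_depth (named),
##              thresholds = list(chr2 = 9, chr3 = 5))

bf_carries <- function(rec, s) rec$gt[[s]] %in% c("het", "hom_alt")

bf_private_records <- function(records, design, target, excluded) {
  tset <- setdiff(if (target == "mutagenized") design$mut else design$bg,
                  excluded)
  full <- setdiff(design$full, excluded)
  others <- setdiff(full, tset)
  out <- list()
  for (rec in records) {
    carriers <- character(0)
    for (s in tset) if (bf_carries(rec, s)) carriers <- c(carriers, s)
    outside <- FALSE
    for (s in others) if (bf_carries(rec, s)) outside <- TRUE
    if (length(carriers) > 0 && !outside) {
      rec$carriers <- carriers
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

bf_genotype_pass <- function(rec, s) {
  dp <- rec$dp[[s]]; ro <- rec$ro[[s]]; ao <- rec$ao[[s]]
  if (is.na(dp) || dp < 10 || dp > 200) return(FALSE)
  if (rec$gt[[s]] == "het") {
    if (is.na(ao) || is.na(ro)) return(FALSE)
    return(ao > 2 && ro > 2)
  }
  TRUE
}

bf_rescued <- function(rec, design) {
  lines <- character(0)
  for (s in rec$carriers) {
    l <- design$line_id[[s]]
    if (!is.na(l)) lines <- c(lines, l)
  }
  if (!length(lines)) return(FALSE)
  any(table(lines) >= 2)
}

bf_filter_stage <- function(privs, design) {
  out <- list()
  for (rec in privs) {
    any_pass <- FALSE
    for (s in rec$carriers) if (bf_genotype_pass(rec, s)) any_pass <- TRUE
    rec$rescued <- bf_rescued(rec, design)
    if (any_pass || rec$rescued) out[[length(out) + 1L]] <- rec
  }
  out
}

bf_cross_coverage <- function(privs, records, design, target, excluded,
                              min_samples = 2) {
  oset <- setdiff(if (target == "mutagenized") design$bg else design$mut,
                  excluded)
  keymap <- vapply(records, function(r)
    paste(r$chrom, r$pos, r$ref, r$alt), "")
  out <- list()
  for (rec in privs) {
    k <- paste(rec$chrom, rec$pos, rec$ref, rec$alt)
    full_rec <- records[[match(k, keymap)]]
    n_cov <- 0L
    for (s in oset) if (full_rec$gt[[s]] != "missing") n_cov <- n_cov + 1L
    if (n_cov >= min_samples) out[[length(out) + 1L]] <- rec
  }
  out
}

bf_introgression <- function(priv_sets, window_kb = 100, min_count = 20) {
  pos_by <- list()
  for (privs in priv_sets)
    for (rec in privs)
      for (s in rec$carriers) {
        k <- paste(s, rec$chrom)
        pos_by[[k]] <- c(pos_by[[k]], rec$pos)
      }
  flagged <- character(0)
  w <- window_kb * 1000
  for (k in names(pos_by)) {
    pos <- sort(pos_by[[k]])
    for (i in seq_along(pos)) {
      cnt <- 0L
      for (p in pos) if (p >= pos[i] && p < pos[i] + w) cnt <- cnt + 1L
      if (cnt >= min_count) {
        flagged <- c(flagged, strsplit(k, " ")[[1]][1])
        break
      }
    }
  }
  sort(unique(flagged))
}

bf_stages <- function(records, design, target, excluded) {
  privs <- bf_private_records(records, design, target, excluded)
  privs <- bf_filter_stage(privs, design)
  bf_cross_coverage(privs, records, design, target, excluded)
}

bf_pipeline <- function(records, design, chrom) {
  records <- Filter(function(r) r$chrom == chrom, records)
  records <- Filter(function(r) r$qual >= 10, records)
  pass1 <- lapply(c(mutagenized = "mutagenized", background = "background"),
                  function(tg) bf_stages(records, design, tg, character(0)))
  flagged <- bf_introgression(pass1)
  pass2 <- if (length(flagged))
    lapply(c(mutagenized = "mutagenized", background = "background"),
           function(tg) bf_stages(records, design, tg, flagged))
  else pass1
  thr <- design$thresholds[[chrom]]
  if (is.null(thr)) thr <- 5
  retained <- names(design$mean_depth)[design$mean_depth >= thr]
  finalize <- function(privs) {
    out <- list()
    for (rec in privs) {
      rec$carriers <- intersect(rec$carriers, retained)
      if (length(rec$carriers)) out[[length(out) + 1L]] <- rec
    }
    out
  }
  list(mutagenized = finalize(pass2$mutagenized),
       background = finalize(pass2$background), flagged = flagged)
}

## canonical string form of a brute-force private set for comparison
bf_canonical <- function(privs) {
  if (!length(privs)) return(character(0))
  sort(vapply(privs, function(rec) {
    carriers <- sort(rec$carriers)
    zyg <- vapply(carriers, function(s)
      if (rec$gt[[s]] == "hom_alt") "hom_alt" else "het", "")
    paste(rec$chrom, rec$pos, rec$ref, rec$alt, rec$rescued,
          paste(carriers, collapse = ","), paste(zyg, collapse = ","))
  }, ""))
}

pvs_canonical <- function(pvs) {
  df <- privateVariants(pvs)
  if (nrow(df) == 0L) return(character(0))
  sort(vapply(seq_len(nrow(df)), function(i) {
    carriers <- df$carriers[[i]]
    o <- order(carriers)
    paste(df$chrom[i], df$pos[i], df$ref[i], df$alt[i], df$rescued[i],
          paste(carriers[o], collapse = ","),
          paste(df$zygosity[[i]][o], collapse = ","))
  }, ""))
}

## ---- PWM scanning / clustering / distances ---------------------------------

bf_pwm_scan <- function(seq_chr, pwm, threshold) {
  m <- pwm@matrix
  if (any(m == 0)) m <- sweep(m + 0.01, 2, colSums(m + 0.01), "/")
  bg <- pwm@background
  bases <- strsplit(seq_chr, "")[[1]]
  w <- ncol(m)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (s in seq_len(length(bases) - w + 1L)) {
    win <- bases[s:(s + w - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    sc_p <- 0; sc_m <- 0
    for (j in seq_len(w)) {
      sc_p <- sc_p + log(m[win[j], j] / bg[[win[j]]])
      rcb <- comp[[win[w + 1L - j]]]
      sc_m <- sc_m + log(m[rcb, j] / bg[[rcb]])
    }
    if (sc_p >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, strand = "+",
                                              score = sc_p)
    if (sc_m >= threshold)
      rows[[length(rows) + 1L]] <- data.frame(start = s - 1L, strand = "-",
                                              score = sc_m)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), , drop = FALSE]
}

bf_cluster <- function(starts, ends, max_gap, min_hits) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  clusters <- list()
  cur <- NULL
  for (i in seq_along(starts)) {
    if (is.null(cur)) {
      cur <- list(start = starts[i], end = ends[i], n = 1L)
    } else if (starts[i] - cur$end <= max_gap) {
      cur$end <- max(cur$end, ends[i]); cur$n <- cur$n + 1L
    } else {
      clusters[[length(clusters) + 1L]] <- cur
      cur <- list(start = starts[i], end = ends[i], n = 1L)
    }
  }
  if (!is.null(cur)) clusters[[length(clusters) + 1L]] <- cur
  keep <- Filter(function(cl) cl$n >= min_hits, clusters)
  if (!length(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      n_hits = integer(0)))
  do.call(rbind, lapply(keep, function(cl)
    data.frame(start = cl$start, end = cl$end, n_hits = cl$n)))
}

## distance = bases strictly between a 1-based position and a 0-based
## half-open interval; 0 inside
bf_distance <- function(chrom, pos, track_bed) {
  vapply(seq_along(pos), function(i) {
    p0 <- pos[i] - 1L
    best <- Inf
    for (j in seq_len(nrow(track_bed))) {
      if (track_bed$chrom[j] != chrom[i]) next
      s <- track_bed$start[j]; e <- track_bed$end[j]
      d <- if (p0 >= s && p0 < e) 0
      else if (p0 < s) s - p0 - 1L
      else p0 - e
      best <- min(best, d)
    }
    best
  }, 0)
}

## ---- exact two-sided Fisher p by table enumeration -------------------------

bf_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; k <- a + c_; n <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, k - x) / choose(n, k)
  p_obs <- prob(a)
  xs <- max(0, k - r2):min(r1, k)
  sum(vapply(xs, function(x) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) px else 0
  }, 0))
}
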