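#' @include AllClasses.R
NULL

## ---- coordinate convention -------------------------------------------------
## VCF positions are 1-based; BED intervals are 0-based half-open. These two
## helpers are the only place in the package where +-1 coordinate arithmetic
## happens.

#' Convert between BED (0-based half-open) intervals and GRanges (1-based)
#'
#' The package holds all intervals internally as 1-based closed
#' [GenomicRanges::GRanges]; BED files are converted at the boundary. These
#' two helpers are the single location of the +-1 arithmetic.
#'
#' @param chrom,start,end BED fields (start 0-based inclusive, end exclusive).
#' @return `bedToGRanges`: a GRanges; `grangesToBed`: a data.frame with
#'   columns chrom, start, end in BED convention.
#' @export
bedToGRanges <- function(chrom, start, end) {
  GRanges(chrom, IRanges(as.integer(start) + 1L, as.integer(end)))
}

#' @rdname bedToGRanges
#' @param gr a GRanges.
#' @export
grangesToBed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

## ---- VCF -------------------------------------------------------------------

## Decompose one diploid GT string against n_alt alternative alleles: the
## per-alt dosage is the number of occurrences of that allele index in the
## genotype; other-alt copies count as reference for zygosity purposes.
.decomposeGt <- function(gt_strings, alt_index) {
  a1 <- sub("[/|].*$", "", gt_strings)
  a2 <- sub("^.*[/|]", "", gt_strings)
  dos <- (a1 == alt_index) + (a2 == alt_index)
  dos[a1 == "." | a2 == "." | is.na(gt_strings)] <- NA_integer_
  as.integer(dos)
}

.dosageToCode <- function(dos) {
  code <- dos
  code[!is.na(dos) & dos == 0L] <- GT_HOM_REF
  code[!is.na(dos) & dos == 1L] <- GT_HET
  code[!is.na(dos) & dos >= 2L] <- GT_HOM_ALT
  code
}

#' Read a joint multi-sample VCF into a JointVariantTable
#'
#' Reads a VCF v4.x text file whose FORMAT includes GT, DP, RO and AO
#' (freebayes-style allele observation counts). Multi-allelic records are
#' decomposed into one biallelic record per ALT allele: a diploid genotype
#' containing allele index k maps to het (one copy) or hom alt (two copies)
#' for that record, and copies of other alternative alleles count as
#' reference for zygosity purposes. AO is taken per allele; RO is the
#' record's reference observation count unchanged. Records with missing QUAL
#' get `qual = 0` (and so fail the QUAL >= 10 prefilter downstream).
#'
#' @param path path to a VCF text file.
#' @return A [JointVariantTable-class] with samples in file order.
#' @export
readJointVcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    stop(sprintf("malformed VCF header in '%s': no #CHROM line", path))
  header_fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(header_fields) < 10L || header_fields[9L] != "FORMAT")
    stop(sprintf("malformed VCF header at line %d: FORMAT column required",
                 hdr))
  samples <- header_fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    emptym <- function() matrix(integer(0), 0L, length(samples),
                                dimnames = list(NULL, samples))
    return(JointVariantTable(character(0), integer(0), character(0),
                             character(0), numeric(0), emptym(), emptym(),
                             emptym(), emptym()))
  }
  fmt <- vapply(strsplit(body, "\t", fixed = TRUE), `[`, "", 9L)
  bad <- which(!vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(f) "GT" %in% f, TRUE))
  if (length(bad))
    stop(sprintf("FORMAT lacking GT at line %d of '%s'", hdr + bad[1L], path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_str <- vcfR::extract.gt(v, "GT")
  dp_str <- vcfR::extract.gt(v, "DP")
  ro_str <- vcfR::extract.gt(v, "RO")
  ao_str <- vcfR::extract.gt(v, "AO")
  n <- nrow(fix)
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  row_idx <- rep.int(seq_len(n), n_alt)
  alt_k <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0
  asIntMat <- function(x) {
    m <- suppressWarnings(matrix(as.integer(x), nrow = nrow(x),
                                 dimnames = dimnames(x)))
    m
  }
  dp <- asIntMat(dp_str)
  ro <- asIntMat(ro_str)
  ao_split <- strsplit(ifelse(is.na(ao_str), "", ao_str), ",", fixed = TRUE)
  dim(ao_split) <- dim(ao_str)
  out_n <- length(row_idx)
  ns <- length(samples)
  GT <- DP <- RO <- AO <- matrix(NA_integer_, out_n, ns,
                                 dimnames = list(NULL, samples))
  for (j in seq_len(ns)) {
    dos <- .decomposeGt(gt_str[row_idx, j], as.character(alt_k))
    GT[, j] <- .dosageToCode(dos)
    DP[, j] <- dp[row_idx, j]
    RO[, j] <- ro[row_idx, j]
    ao_j <- ao_split[, j]
    AO[, j] <- vapply(seq_len(out_n), function(i) {
      parts <- ao_j[[row_idx[i]]]
      if (length(parts) < alt_k[i]) return(NA_integer_)
      suppressWarnings(as.integer(parts[alt_k[i]]))
    }, integer(1))
    miss <- is.na(GT[, j])
    DP[miss, j] <- NA_integer_
    RO[miss, j] <- NA_integer_
    AO[miss, j] <- NA_integer_
  }
  JointVariantTable(chrom = fix[row_idx, "CHROM"],
                    pos = as.integer(fix[row_idx, "POS"]),
                    ref = fix[row_idx, "REF"],
                    alt = unlist(alt_list, use.names = FALSE),
                    qual = qual[row_idx],
                    GT = GT, DP = DP, RO = RO, AO = AO)
}

#' Write a JointVariantTable as a VCF text file
#'
#' Emits a minimal VCF v4.2 with FORMAT `GT:DP:RO:AO`, one (biallelic) record
#' per variant, samples in column order. Missing genotypes are written as
#' `./.:.:.:.`. The output is plain text and byte-stable, and round-trips
#' through [readJointVcf()] field for field.
#'
#' @param jvt a [JointVariantTable-class].
#' @param path output path.
#' @param samples optional character vector giving the sample column order;
#'   must be exactly the samples of `jvt`.
#' @return `path`, invisibly.
#' @export
writeJointVcf <- function(jvt, path, samples = colnames(jvt)) {
  if (!setequal(samples, colnames(jvt)) ||
      length(samples) != ncol(jvt))
    stop("consistency error: 'samples' must be exactly the samples of the table")
  gt <- genotypes(jvt)[, samples, drop = FALSE]
  dp <- readDepth(jvt)[, samples, drop = FALSE]
  ro <- refObs(jvt)[, samples, drop = FALSE]
  ao <- altObs(jvt)[, samples, drop = FALSE]
  gts <- c("0/0", "0/1", "1/1")
  fmtNum <- function(x) ifelse(is.na(x), ".", as.character(x))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=highevoR",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="Reference allele observation count">',
    '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  n <- nVariants(jvt)
  if (n == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  cells <- matrix("./.:.:.:.", n, length(samples))
  filled <- !is.na(gt)
  cells[filled] <- paste(gts[gt[filled] + 1L], fmtNum(dp[filled]),
                         fmtNum(ro[filled]), fmtNum(ao[filled]), sep = ":")
  qual <- qualScore(jvt)
  qual_str <- ifelse(qual == floor(qual), sprintf("%d", as.integer(qual)),
                     sub("0+$", "", sprintf("%.6f", qual)))
  rows <- paste(variantChrom(jvt), variantPos(jvt), ".", refAllele(jvt),
                altAllele(jvt), qual_str, ".", ".", "GT:DP:RO:AO",
                sep = "\t")
  body <- paste(rows, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

## ---- BED -------------------------------------------------------------------

#' Read / write BED3 feature tracks
#'
#' `readBed` parses a tab-separated BED file (3 or more columns; extra
#' columns ignored) into a named, per-chromosome-sorted
#' [GenomicRanges::GRanges] (1-based internal convention). `writeBed` writes
#' the first three BED columns back (0-based half-open); the pair round-trips
#' exactly.
#'
#' @param path file path.
#' @param name track label, stored in `metadata(gr)$name`.
#' @return `readBed`: a GRanges; `writeBed`: `path` invisibly.
#' @export
readBed <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$name <- name
    return(gr)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop(sprintf("BED format error at line %d of '%s': fewer than 3 columns",
                 which(nf < 3L)[1L], path))
  chrom <- vapply(parts, `[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s < 0L | s >= e)
  if (length(bad))
    stop(sprintf("BED format error at line %d of '%s': need 0 <= start < end",
                 bad[1L], path))
  gr <- bedToGRanges(chrom, s, e)
  gr <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' @rdname readBed
#' @param gr a GRanges track.
#' @export
writeBed <- function(gr, path) {
  bed <- grangesToBed(gr)
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d", bed$chrom, bed$start, bed$end), path)
  invisible(path)
}

## ---- FASTA -----------------------------------------------------------------

#' Read / write FASTA sequence files
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] enforcing the package's contracts:
#' sequences are uppercased on read, duplicate sequence names are an error,
#' and writing wraps at 60 characters so the pair round-trips exactly.
#'
#' @param path file path.
#' @return `readFasta`: a [Biostrings::DNAStringSet]; `writeFasta`: `path`
#'   invisibly.
#' @export
readFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("consistency error: duplicate sequence names in '%s': %s",
                 path, names(seqs)[duplicated(names(seqs))][1L]))
  ## readDNAStringSet uppercases lowercase bases already (DNA alphabet)
  seqs
}

#' @rdname readFasta
#' @param seqs a named [Biostrings::DNAStringSet] (or named character vector).
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (anyDuplicated(names(seqs)))
    stop("consistency error: duplicate sequence names")
  writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

## ---- depth tables ----------------------------------------------------------

#' Read / write per-base depth tables
#'
#' The interchange format is the 3-column text table emitted by
#' `samtools depth`: chromosome, 1-based position, depth, tab-separated, one
#' file per sample. Internally depths are held run-length encoded
#' ([DepthTrackSet-class]). Positions absent from a file are depth 0; when
#' `chrom_lengths` is given each chromosome's track is padded to full length.
#'
#' @param paths named character vector of file paths; names are sample ids.
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return `readDepthTables`: a [DepthTrackSet-class]; `writeDepthTables`:
#'   the directory path invisibly.
#' @export
readDepthTables <- function(paths, chrom_lengths = NULL) {
  tracks <- lapply(paths, function(p) {
    dt <- data.table::fread(p, header = FALSE, sep = "\t",
                            col.names = c("chrom", "pos", "depth"))
    out <- list()
    for (chrom in unique(dt$chrom)) {
      sub <- dt[dt$chrom == chrom, ]
      len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths))
        chrom_lengths[[chrom]] else max(sub$pos)
      v <- integer(len)
      v[sub$pos] <- as.integer(sub$depth)
      out[[chrom]] <- Rle(v)
    }
    out
  })
  names(tracks) <- names(paths)
  new("DepthTrackSet", tracks = tracks)
}

#' @rdname readDepthTables
#' @param depth a [DepthTrackSet-class].
#' @param dir output directory; one `depth_<sample>.tsv` per sample.
#' @export
writeDepthTables <- function(depth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(depth@tracks)) {
    rows <- lapply(names(depth@tracks[[s]]), function(chrom) {
      r <- depth@tracks[[s]][[chrom]]
      data.table::data.table(chrom = chrom, pos = seq_len(length(r)),
                             depth = as.integer(r))
    })
    data.table::fwrite(data.table::rbindlist(rows),
                       file.path(dir, paste0("depth_", s, ".tsv")),
                       sep = "\t", col.names = FALSE)
  }
  invisible(dir)
}

## ---- manifest --------------------------------------------------------------

#' Read / write a sample manifest (YAML)
#'
#' The manifest format has a `samples` list (id, line, generations,
#' mean_depth, role) and a `sets` map: chromosome -> full / mutagenized /
#' background sample-id lists.
#'
#' @param path YAML file path.
#' @return `readSampleManifest`: a [SampleManifest-class];
#'   `writeSampleManifest`: `path` invisibly.
#' @export
readSampleManifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples) || is.null(y$sets))
    stop(sprintf("manifest '%s' must define 'samples' and 'sets'", path))
  ids <- vapply(y$samples, function(s) as.character(s$id), "")
  getf <- function(f, default, as) vapply(y$samples, function(s)
    if (is.null(s[[f]])) default else as(s[[f]]),
    default)
  SampleManifest(
    sample_ids = ids,
    line_id = getf("line", NA_character_, as.character),
    generations = getf("generations", NA_integer_, as.integer),
    mean_depth = getf("mean_depth", NA_real_, as.numeric),
    role = getf("role", NA_character_, as.character),
    sets = lapply(y$sets, function(s)
      list(full = as.character(unlist(s$full)),
           mutagenized = as.character(unlist(s$mutagenized)),
           background = as.character(unlist(s$background)))))
}

#' @rdname readSampleManifest
#' @param manifest a [SampleManifest-class].
#' @export
writeSampleManifest <- function(manifest, path) {
  df <- manifestSamples(manifest)
  samples <- lapply(rownames(df), function(id) {
    s <- list(id = id)
    if (!is.na(df[id, "line_id"])) s$line <- df[id, "line_id"]
    if (!is.na(df[id, "generations"])) s$generations <- df[id, "generations"]
    if (!is.na(df[id, "mean_depth"]))
      s$mean_depth <- round(df[id, "mean_depth"], 4)
    if (!is.na(df[id, "role"])) s$role <- df[id, "role"]
    s
  })
  yaml::write_yaml(list(samples = samples, sets = manifest@sets), path)
  invisible(path)
}
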