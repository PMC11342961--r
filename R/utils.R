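#' @include AllClasses.R
NULL

#' Round half-up
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' percentages in mutation-accumulation reports), unlike base R's
#' round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## stderr logging used by the run* pipeline commands
.log <- function(fmt, ..., verbose = TRUE) {
  if (verbose) message(sprintf(paste0("[highevoR] ", fmt), ...))
}

## md5 of a canonical YAML serialisation (config provenance in run manifests)
.configHash <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

## private-variant set as a plain exportable table
.pvsToTable <- function(pvs) {
  df <- pvs@variants
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), target = character(0),
                      carriers = character(0), zygosity = character(0),
                      carrier_pass = character(0), rescued = logical(0),
                      singleton = logical(0)))
  data.frame(
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    qual = df$qual, target = pvs@target,
    carriers = vapply(as.list(df$carriers), paste, "", collapse = ","),
    zygosity = vapply(as.list(df$zygosity), paste, "", collapse = ","),
    carrier_pass = vapply(as.list(df$carrier_pass),
                          function(p) paste(as.integer(p), collapse = ","),
                          ""),
    rescued = df$rescued,
    singleton = lengths(df$carriers) == 1L,
    stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
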