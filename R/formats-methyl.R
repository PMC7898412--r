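## Methylation-call TSV dialect: 11 tab-separated columns with a header.

.METHYL_COLS <- c("chromosome", "strand", "start", "end", "read_name",
                  "log_lik_ratio", "log_lik_methylated",
                  "log_lik_unmethylated", "num_calling_strands",
                  "num_motifs", "sequence")

#' Read a methylation call file
#'
#' Reads the tab-separated per-read CpG methylation call dialect produced by
#' HMM-based nanopore methylation callers: one row per grouped call, 11
#' columns (`chromosome`, `strand`, `start`, `end`, `read_name`,
#' `log_lik_ratio`, `log_lik_methylated`, `log_lik_unmethylated`,
#' `num_calling_strands`, `num_motifs`, `sequence`). Positions are 0-based;
#' `sequence` must contain exactly `num_motifs` occurrences of `CG`.
#' Malformed rows raise an error (with the offending line number) rather
#' than being skipped. Plain or gzip-compressed files are accepted.
#'
#' @param path path to the TSV (optionally `.gz`).
#' @return A [MethylCallSet].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(paste(c("chromosome","strand","start","end","read_name",
#'   "log_lik_ratio","log_lik_methylated","log_lik_unmethylated",
#'   "num_calling_strands","num_motifs","sequence"), collapse = "\t"),
#'   "chr1\t+\t100\t105\tr1\t4.1\t-10\t-14.1\t1\t2\tTTCGGATCGT"), f)
#' readMethylCalls(f)
#' @export
readMethylCalls <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              data.table = TRUE, showProgress = FALSE)
  miss <- setdiff(.METHYL_COLS, names(dt))
  if (length(miss))
    stop("methylation call file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  dt <- dt[, .METHYL_COLS, with = FALSE]
  setnames(dt, "chromosome", "chrom")
  if (!nrow(dt)) {
    df <- data.frame(chrom = character(), strand = character(),
                     start = integer(), end = integer(),
                     read_name = character(), log_lik_ratio = numeric(),
                     log_lik_methylated = numeric(),
                     log_lik_unmethylated = numeric(),
                     num_calling_strands = integer(), num_motifs = integer(),
                     sequence = character(), stringsAsFactors = FALSE)
    return(new("MethylCallSet", calls = df))
  }
  numc <- c("start", "end", "log_lik_ratio", "log_lik_methylated",
            "log_lik_unmethylated", "num_calling_strands", "num_motifs")
  for (cc in numc) {
    v <- suppressWarnings(as.numeric(dt[[cc]]))
    bad <- which(is.na(v) & !is.na(dt[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data line %d",
                   dt[[cc]][bad[1L]], cc, bad[1L]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at data line %d",
                   cc, which(is.na(v))[1L]), call. = FALSE)
    dt[[cc]] <- v
  }
  for (cc in c("start", "end", "num_calling_strands", "num_motifs"))
    dt[[cc]] <- as.integer(dt[[cc]])
  ncg <- .countSubstring(dt$sequence, "CG")
  bad <- which(ncg != dt$num_motifs)
  if (length(bad))
    stop(sprintf(paste0("sequence contains %d CG motif(s) but num_motifs ",
                        "is %d at data line %d"),
         ncg[bad[1L]], dt$num_motifs[bad[1L]], bad[1L]), call. = FALSE)
  new("MethylCallSet", calls = as.data.frame(dt))
}

#' Write a methylation call file
#'
#' Inverse of [readMethylCalls()]; writes the 11-column tab-separated
#' dialect with its header. Round-tripping is the identity.
#'
#' @param x a [MethylCallSet].
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
writeMethylCalls <- function(x, path) {
  df <- methCalls(x)
  out <- data.table(chromosome = df$chrom, strand = df$strand,
                    start = df$start, end = df$end,
                    read_name = df$read_name,
                    log_lik_ratio = df$log_lik_ratio,
                    log_lik_methylated = df$log_lik_methylated,
                    log_lik_unmethylated = df$log_lik_unmethylated,
                    num_calling_strands = df$num_calling_strands,
                    num_motifs = df$num_motifs, sequence = df$sequence)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a methylation frequency table
#'
#' Writes per-CpG methylation frequencies as a tab-separated table with
#' header `chromosome start end strand NumOfAllCalls NumOfModCalls
#' MethylFreq`. Frequencies are printed with six decimals. Records must be
#' sorted by (chrom, start); unsorted input is an error (sorting is the
#' caller's job).
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `n_all_calls`, `n_mod_calls`, `meth_freq` (as produced by
#'   [computeMethylationFrequency()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMethylFrequency <- function(records, path) {
  need <- c("chrom", "start", "end", "strand", "n_all_calls", "n_mod_calls",
            "meth_freq")
  miss <- setdiff(need, names(records))
  .assert(!length(miss), "missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records)) {
    o <- order(records$chrom, records$start)
    .assert(identical(o, seq_len(nrow(records))),
            "records must be sorted by (chrom, start)")
    .assert(all(records$n_mod_calls >= 0 &
                records$n_mod_calls <= records$n_all_calls),
            "n_mod_calls out of [0, n_all_calls]")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("chromosome", "start", "end", "strand", "NumOfAllCalls",
                     "NumOfModCalls", "MethylFreq"), collapse = "\t"), con)
  if (nrow(records)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%.6f",
                     records$chrom, as.integer(records$start),
                     as.integer(records$end), records$strand,
                     as.integer(records$n_all_calls),
                     as.integer(records$n_mod_calls), records$meth_freq)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a methylation frequency table
#'
#' @param path a file written by [writeMethylFrequency()].
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `n_all_calls`, `n_mod_calls`, `meth_freq`.
#' @export
readMethylFrequency <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  need <- c("chromosome", "start", "end", "strand", "NumOfAllCalls",
            "NumOfModCalls", "MethylFreq")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("frequency file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(chrom = as.character(dt$chromosome),
                   start = as.integer(dt$start), end = as.integer(dt$end),
                   strand = as.character(dt$strand),
                   n_all_calls = as.integer(dt$NumOfAllCalls),
                   n_mod_calls = as.integer(dt$NumOfModCalls),
                   meth_freq = as.numeric(dt$MethylFreq),
                   stringsAsFactors = FALSE)
  df
}
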