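## Expansion of grouped methylation call records into per-CpG calls with a
## methylation state. The upstream caller scores nearby CpGs (< 11 bp apart)
## as one group sharing a log-likelihood ratio; groups are expanded here,
## never re-scored or re-split.

#' Classify a log-likelihood ratio into a methylation state
#'
#' Positive ratios favour methylation. The boundary is inclusive:
#' `LLR >= threshold` is methylated, `LLR <= -threshold` unmethylated,
#' anything in between uncalled. (Whether a call exactly at the boundary
#' should count is a convention; this implementation includes it.)
#'
#' @param log_lik_ratio numeric vector of log-likelihood ratios
#'   (log P(methylated) - log P(unmethylated)).
#' @param threshold single positive number; default 2.0, the widely used
#'   cutoff for HMM-based nanopore methylation callers.
#' @return character vector of `"methylated"`, `"unmethylated"`,
#'   `"uncalled"`.
#' @examples
#' classifyCall(c(2.5, -3, 1, 2), threshold = 2)
#' @export
classifyCall <- function(log_lik_ratio, threshold = 2.0) {
  .assert(is.numeric(threshold) && length(threshold) == 1L && threshold > 0,
          "threshold must be a single positive number")
  if (any(!is.finite(log_lik_ratio)))
    stop("non-finite log-likelihood ratio", call. = FALSE)
  out <- rep("uncalled", length(log_lik_ratio))
  out[log_lik_ratio >= threshold] <- "methylated"
  out[log_lik_ratio <= -threshold] <- "unmethylated"
  out
}

#' Split grouped methylation records into per-CpG calls
#'
#' Each grouped record expands to exactly `num_motifs` per-CpG calls, one
#' per `CG` occurrence in its sequence context, every call carrying the
#' group's log-likelihood ratio. The i-th call position is
#' `start + (offset_i - offset_0)` where `offset_i` is the 0-based index of
#' the i-th `CG` in the context. Reverse-strand records are normalized to
#' the forward-strand C (position decremented by 1) so that both strands of
#' the palindromic CpG merge downstream.
#'
#' @param x a [MethylCallSet].
#' @param threshold LLR call cutoff passed to [classifyCall()].
#' @return A [CpGCallSet] with `sum(num_motifs)` calls.
#' @export
splitGroupedCalls <- function(x, threshold = 2.0) {
  df <- methCalls(x)
  if (!nrow(df)) {
    calls <- data.frame(chrom = character(), pos = integer(),
                        read_name = character(), log_lik_ratio = numeric(),
                        state = character(), stringsAsFactors = FALSE)
    return(new("CpGCallSet", calls = calls, threshold = threshold))
  }
  offs <- .substringOffsets0(df$sequence, "CG")
  nm <- lengths(offs)
  bad <- which(nm != df$num_motifs)
  if (length(bad))
    stop(sprintf("record %d: %d CG motif(s) in sequence but num_motifs %d",
                 bad[1L], nm[bad[1L]], df$num_motifs[bad[1L]]),
         call. = FALSE)
  rel <- unlist(lapply(offs, function(o) o - o[1L]), use.names = FALSE)
  idx <- rep.int(seq_len(nrow(df)), nm)
  pos <- df$start[idx] + rel
  pos <- pos - ifelse(df$strand[idx] == "-", 1L, 0L)
  calls <- data.frame(chrom = df$chrom[idx], pos = as.integer(pos),
                      read_name = df$read_name[idx],
                      log_lik_ratio = df$log_lik_ratio[idx],
                      state = classifyCall(df$log_lik_ratio[idx], threshold),
                      stringsAsFactors = FALSE)
  new("CpGCallSet", calls = calls, threshold = threshold)
}

#' Process a methylation call file into an indexed per-CpG call store
#'
#' Reads a methylation call file, expands every grouped record and returns
#' a [CpGCallSet] supporting lookup by read name ([callsByRead()]) and by
#' genomic interval ([callsInRegion()]). The total number of stored calls
#' equals the sum of `num_motifs` over the input rows.
#'
#' @param path methylation call TSV (see [readMethylCalls()]), or a
#'   [MethylCallSet].
#' @param threshold LLR call cutoff (see [classifyCall()]).
#' @return A [CpGCallSet].
#' @export
processMethylationFile <- function(path, threshold = 2.0) {
  x <- if (is(path, "MethylCallSet")) path else readMethylCalls(path)
  out <- splitGroupedCalls(x, threshold = threshold)
  stopifnot(nrow(cpgCalls(out)) == sum(methCalls(x)$num_motifs))
  out
}

#' Look up CpG calls by read name
#'
#' @param x a [CpGCallSet].
#' @param read_names character vector of read names; absent reads yield no
#'   rows (not an error).
#' @return data.frame of matching calls.
#' @export
callsByRead <- function(x, read_names) {
  df <- cpgCalls(x)
  df[df$read_name %in% read_names, , drop = FALSE]
}

#' Look up CpG calls overlapping a genomic interval
#'
#' @param x a [CpGCallSet].
#' @param chrom reference sequence name.
#' @param start,end 0-based half-open interval bounds.
#' @return data.frame of calls with `start <= pos < end`.
#' @export
callsInRegion <- function(x, chrom, start, end) {
  df <- cpgCalls(x)
  df[df$chrom == chrom & df$pos >= start & df$pos < end, , drop = FALSE]
}

#' Save / load a processed CpG call store
#'
#' The store round-trips through a plain tab-separated file whose first
#' line records the call threshold.
#'
#' @param x a [CpGCallSet].
#' @param path store path (conventionally `*.idx.tsv`).
#' @return `path` (save) or a [CpGCallSet] (load).
#' @export
saveCpGCalls <- function(x, path) {
  con <- file(path, "w")
  writeLines(sprintf("#call_threshold=%g", callThreshold(x)), con)
  close(con)
  fwrite(as.data.table(cpgCalls(x)), path, sep = "\t", append = TRUE,
         col.names = TRUE)
  invisible(path)
}

#' @rdname saveCpGCalls
#' @export
loadCpGCalls <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  first <- readLines(path, n = 1L)
  .assert(grepl("^#call_threshold=", first), "not a CpG call store: ", path)
  thr <- as.numeric(sub("^#call_threshold=", "", first))
  dt <- fread(path, sep = "\t", header = TRUE, skip = 1L,
              showProgress = FALSE)
  new("CpGCallSet", calls = as.data.frame(dt), threshold = thr)
}
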