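## Mock whole-genome-bisulfite conversion of phased reads: rewriting the
## CpG base of each per-read call so that a genome browser's bisulfite mode
## renders nanopore methylation directly. Bisulfite semantics: methylated
## cytosines survive conversion (base unchanged), unmethylated ones read as
## T on the forward strand (A at the G of reverse-strand reads), uncalled
## positions become N. Only bases participating in a CpG dinucleotide are
## ever rewritten, so conversion is idempotent.

#' Convert one read's CpG bases to mock-bisulfite form
#'
#' For each per-read CpG call, the read base aligned to the CpG cytosine
#' (forward-strand reads) or to the CpG guanine at `pos + 1` (reverse-
#' strand reads, i.e. the C of the opposite strand) is located through the
#' CIGAR and rewritten: unmethylated to `T` (forward) / `A` (reverse),
#' uncalled to `N`, methylated left unchanged. All other bases, the CIGAR
#' and coordinates are untouched. Calls whose target position is not
#' aligned in the read (deletion, outside span) are skipped and counted.
#'
#' @param read single-row data.frame (one row of [reads()]).
#' @param calls data.frame of this read's CpG calls (columns `pos`,
#'   `state`).
#' @return list with `seq` (converted sequence), `n_sub` (bases rewritten),
#'   `n_skipped` (calls with no aligned base).
#' @export
convertRead <- function(read, calls) {
  if (!nrow(calls))
    return(list(seq = read$seq, n_sub = 0L, n_skipped = 0L))
  is_rev <- .flagBit(read$flag, .FLAG_REVERSE)
  target <- calls$pos + if (is_rev) 1L else 0L
  qi <- .queryIndexAtRef(read$cigar, read$start, target)
  hit <- !is.na(qi$idx)
  sub <- ifelse(calls$state == "methylated", NA_character_,
                ifelse(calls$state == "unmethylated",
                       if (is_rev) "A" else "T", "N"))
  doSub <- hit & !is.na(sub)
  s <- strsplit(read$seq, "")[[1L]]
  changed <- doSub & s[ifelse(is.na(qi$idx), 1L, qi$idx)] != sub
  s[qi$idx[doSub]] <- sub[doSub]
  list(seq = paste(s, collapse = ""),
       n_sub = sum(changed, na.rm = TRUE),
       n_skipped = sum(!hit))
}

#' Convert a phased read set to mock-bisulfite form
#'
#' @param readset a [ReadSet] (typically one haplotype's reads).
#' @param cpg_store a [CpGCallSet] holding the reads' per-CpG calls.
#' @return list with `readset` (converted [ReadSet]), `n_sub` (total bases
#'   rewritten), `n_skipped` (calls without an aligned base).
#' @export
convertToMockBisulfite <- function(readset, cpg_store) {
  rd <- reads(readset)
  byRead <- split(cpgCalls(cpg_store), cpgCalls(cpg_store)$read_name)
  n_sub <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(rd))) {
    calls <- byRead[[rd$name[i]]]
    if (is.null(calls)) next
    res <- convertRead(rd[i, ], calls)
    rd$seq[i] <- res$seq
    n_sub <- n_sub + res$n_sub
    n_skipped <- n_skipped + res$n_skipped
  }
  list(readset = ReadSet(rd, seqLengths(readset)), n_sub = n_sub,
       n_skipped = n_skipped)
}

#' Write a haplotype pair of mock-bisulfite alignment files
#'
#' Converts each haplotype's reads and writes coordinate-sorted, indexed
#' BAMs (`<prefix>_HP1.bam`, `<prefix>_HP2.bam`) loadable in a browser's
#' bisulfite mode. An empty haplotype still yields a valid header-only
#' file.
#'
#' @param hp1_reads,hp2_reads [ReadSet]s of the two haplotypes.
#' @param cpg_store a [CpGCallSet] with the reads' calls.
#' @param path_prefix output prefix.
#' @return named character vector of the two BAM paths, invisibly.
#' @export
writeMockWgbsPair <- function(hp1_reads, hp2_reads, cpg_store, path_prefix) {
  out <- c(HP1 = paste0(path_prefix, "_HP1.bam"),
           HP2 = paste0(path_prefix, "_HP2.bam"))
  writeBam(convertToMockBisulfite(hp1_reads, cpg_store)$readset, out[["HP1"]])
  writeBam(convertToMockBisulfite(hp2_reads, cpg_store)$readset, out[["HP2"]])
  invisible(out)
}
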