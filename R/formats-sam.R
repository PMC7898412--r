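## Alignment I/O. Internally reads live in a flat ReadSet (0-based starts);
## SAM text is written directly and BAM conversion/sorting/indexing is
## delegated to Rsamtools (htslib).

#' Construct a ReadSet
#'
#' @param reads data.frame with columns `name`, `flag`, `chrom`, `start`
#'   (0-based leftmost mapped position), `mapq`, `cigar`, `seq`, `qual`;
#'   additional columns are kept as annotations.
#' @param seqlengths named integer vector of reference sequence lengths.
#' @return A [ReadSet].
#' @export
ReadSet <- function(reads, seqlengths) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  new("ReadSet", reads = reads,
      seqlengths = setNames(as.integer(seqlengths), names(seqlengths)))
}

#' Write a ReadSet as SAM text
#'
#' Writes a coordinate-sorted SAM file with `@HD`/`@SQ` header lines. The
#' optional `haplotype` annotation column is emitted as an `HP:i:` tag
#' (HP1 -> 1, HP2 -> 2), the convention genome browsers use to colour
#' haplotagged reads.
#'
#' @param x a [ReadSet].
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(x, path) {
  df <- reads(x)
  sl <- seqLengths(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)),
               sprintf("@PG\tID:haploMeth\tPN:haploMeth\tVN:%s",
                       as.character(packageVersion("haploMeth")))), con)
  if (nrow(df)) {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    tags <- rep("", nrow(df))
    if ("haplotype" %in% names(df)) {
      hp <- match(df$haplotype, c("HP1", "HP2"))
      tags <- ifelse(is.na(hp), "", sprintf("\tHP:i:%d", hp))
    }
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                       df$name, as.integer(df$flag), df$chrom,
                       as.integer(df$start) + 1L, as.integer(df$mapq),
                       df$cigar, df$seq, df$qual, tags), con)
  }
  invisible(path)
}

#' Write a ReadSet as a coordinate-sorted, indexed BAM
#'
#' @param x a [ReadSet].
#' @param path output path; `.bam` is appended if absent.
#' @return The BAM path, invisibly.
#' @export
writeBam <- function(x, path) {
  if (!grepl("\\.bam$", path)) path <- paste0(path, ".bam")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeSam(x, sam)
  dest <- sub("\\.bam$", "", path)
  asBam(sam, destination = dest, overwrite = TRUE, indexDestination = TRUE)
  invisible(path)
}

#' Read alignments into a ReadSet
#'
#' Reads a BAM (or plain SAM, converted internally) into the flat in-memory
#' representation used by the phasing and feature-extraction stages.
#' Unmapped records are kept (flagged) so that downstream read-partition
#' counters see every input read.
#'
#' @param path a `.bam` or `.sam` file.
#' @return A [ReadSet]; starts are 0-based.
#' @export
readAlignments <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- asBam(path, destination = dest, overwrite = TRUE,
                 indexDestination = FALSE)
    on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))))
    path <- bam
  }
  bf <- BamFile(path)
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]
  sl <- hdr$targets
  res <- scanBam(bf, param = ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual")))[[1L]]
  n <- length(res$qname)
  df <- data.frame(name = res$qname, flag = as.integer(res$flag),
                   chrom = as.character(res$rname),
                   start = ifelse(is.na(res$pos), NA_integer_,
                                  as.integer(res$pos) - 1L),
                   mapq = as.integer(res$mapq),
                   cigar = as.character(res$cigar),
                   seq = as.character(res$seq),
                   qual = as.character(res$qual), stringsAsFactors = FALSE)
  if (!n) df <- df[0L, , drop = FALSE]
  ReadSet(df, setNames(as.integer(sl), names(sl)))
}
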