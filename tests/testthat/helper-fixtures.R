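# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures on disk.

METHYL_HEADER <- paste(c("chromosome", "strand", "start", "end", "read_name",
                         "log_lik_ratio", "log_lik_methylated",
                         "log_lik_unmethylated", "num_calling_strands",
                         "num_motifs", "sequence"), collapse = "\t")

writeMethylFixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(METHYL_HEADER, rows), path)
  path
}

writeVcfFixture <- function(records, path = tempfile(fileext = ".vcf"),
                            sample = "S1") {
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000000>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t"),
               records), path)
  path
}

vcfRecord <- function(pos1, ref, alt, gt, qual = 100) {
  sprintf("chr1\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT\t%s", pos1, ref, alt,
          format(qual), gt)
}

# A hand-made ReadSet over an explicit reference string.
makeReadSet <- function(reads_df, ref_len = 1000L, chrom = "chr1") {
  ReadSet(reads_df, setNames(as.integer(ref_len), chrom))
}

simpleRead <- function(name, start, seq, cigar = NULL, qual_char = "I",
                       flag = 0L, mapq = 60L, chrom = "chr1") {
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  data.frame(name = name, flag = flag, chrom = chrom, start = start,
             mapq = mapq, cigar = cigar, seq = seq,
             qual = strrep(qual_char, nchar(seq)), stringsAsFactors = FALSE)
}

# Per-haplotype frequency table from raw counts (dma input shape).
freqFromCounts <- function(counts, hap = 1) {
  n <- counts[[paste0("n", hap)]]
  x <- counts[[paste0("x", hap)]]
  data.frame(chrom = counts$chrom, start = counts$pos,
             end = counts$pos + 1L, strand = "+", n_all_calls = n,
             n_mod_calls = x, meth_freq = x / n, stringsAsFactors = FALSE)
}

# Independent brute-force pileup: walks each CIGAR with a naive
# interpreter, one position at a time. Used as the oracle for pileupStats.
bruteForcePileup <- function(readset, reference) {
  rd <- reads(readset)
  L <- nchar(reference)
  cov <- integer(L); mmc <- integer(L); delc <- integer(L)
  insc <- integer(L); qsum <- numeric(L)
  refc <- strsplit(reference, "")[[1]]
  for (i in seq_len(nrow(rd))) {
    ops <- regmatches(rd$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]", rd$cigar[i]))[[1]]
    r <- rd$start[i]; q <- 0L
    sc <- strsplit(rd$seq[i], "")[[1]]
    qv <- utf8ToInt(rd$qual[i]) - 33L
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          cov[r + 1L] <- cov[r + 1L] + 1L
          qsum[r + 1L] <- qsum[r + 1L] + qv[q + 1L]
          if (sc[q + 1L] != refc[r + 1L]) mmc[r + 1L] <- mmc[r + 1L] + 1L
          r <- r + 1L; q <- q + 1L
        }
      } else if (type %in% c("D", "N")) {
        for (k in seq_len(n)) { delc[r + 1L] <- delc[r + 1L] + 1L; r <- r + 1L }
      } else if (type == "I") {
        insc[r] <- insc[r] + 1L  # follows ref position r-1 (0-based)
        q <- q + n
      } else if (type == "S") q <- q + n
    }
  }
  list(cov = cov, mm = mmc, del = delc, ins = insc, qsum = qsum)
}
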