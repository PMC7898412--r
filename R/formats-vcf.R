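## VCF input/output. Reading goes through vcfR; writing uses a minimal
## VCF 4.2 text writer (the workflow only ever emits simple biallelic SNV
## records with GT and a few INFO tags). POS is converted 1-based -> 0-based
## on read and back on write.

#' Read phased heterozygous SNVs from a VCF
#'
#' Emits only biallelic SNV records whose genotype (first sample) is a
#' phased heterozygote (`0|1` or `1|0`). The allele left of `|` becomes the
#' haplotype-1 allele. Homozygous, unphased (`0/1`), indel and multiallelic
#' records are skipped, with per-category counters reported on the returned
#' object ([skippedCounts()]). A missing GT FORMAT field is an error, as is
#' a malformed genotype string.
#'
#' @param path path to a VCF (plain or bgzip/gzip).
#' @return A [PhasedVariantSet]; positions are 0-based.
#' @export
readPhasedVcf <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  skipped <- c(hom = 0L, unphased = 0L, indel = 0L, multiallelic = 0L,
               missing = 0L)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      hp1_allele = character(), hp2_allele = character(),
                      qual = numeric(), phase_set = character(),
                      stringsAsFactors = FALSE)
  if (!n) return(new("PhasedVariantSet", variants = empty, skipped = skipped))
  if (!ncol(v@gt) || !any(grepl("GT", v@gt[, 1L], fixed = TRUE)))
    stop("VCF has no GT FORMAT field", call. = FALSE)
  gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1L])
  ps <- tryCatch(unname(suppressWarnings(
          vcfR::extract.gt(v, element = "PS"))[, 1L]),
        error = function(e) rep(NA_character_, n))
  chrom <- v@fix[, "CHROM"]
  pos1 <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))

  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  gt_missing <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  usable <- !multi & !indel & !gt_missing
  skipped["multiallelic"] <- sum(multi)
  skipped["indel"] <- sum(indel)
  skipped["missing"] <- sum(gt_missing & !multi & !indel)

  badfmt <- usable & !grepl("^[01]([/|])[01]", gt)
  if (any(badfmt))
    stop(sprintf("malformed genotype '%s' at %s:%d",
                 gt[badfmt][1L], chrom[badfmt][1L], pos1[badfmt][1L]),
         call. = FALSE)
  g <- substr(gt, 1L, 3L)
  a1 <- substr(g, 1L, 1L)
  sep <- substr(g, 2L, 2L)
  a2 <- substr(g, 3L, 3L)
  hom <- usable & a1 == a2
  unph <- usable & !hom & sep == "/"
  keep <- usable & !hom & sep == "|"
  skipped["hom"] <- sum(hom)
  skipped["unphased"] <- sum(unph)

  hp1 <- ifelse(a1 == "0", ref, alt)
  hp2 <- ifelse(a2 == "0", ref, alt)
  df <- data.frame(chrom = chrom[keep], pos = pos1[keep] - 1L,
                   ref_allele = ref[keep], alt_allele = alt[keep],
                   hp1_allele = hp1[keep], hp2_allele = hp2[keep],
                   qual = qual[keep], phase_set = ps[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new("PhasedVariantSet", variants = df, skipped = skipped)
}

#' Read simple biallelic genotypes from a VCF
#'
#' Lightweight genotype reader used for candidate SNVs and trio genotype
#' input: returns one row per biallelic SNV with the two genotype alleles
#' spelled out as bases (phased or unphased). Indels and multiallelic
#' records are dropped silently.
#'
#' @param path path to a VCF.
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `qual`, `allele1`, `allele2`, `phased` (logical).
#' @export
readGenotypeVcf <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(),
                      allele1 = character(), allele2 = character(),
                      phased = logical(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  .assert(ncol(v@gt) >= 2L, "VCF has no sample genotype column")
  gt <- unname(vcfR::extract.gt(v, element = "GT")[, 1L])
  chrom <- v@fix[, "CHROM"]
  pos1 <- as.integer(v@fix[, "POS"])
  ref <- v@fix[, "REF"]
  alt <- v@fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
  keep <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1L &
          nchar(alt) == 1L & !is.na(gt) & grepl("^[01]([/|])[01]", gt)
  g <- substr(gt, 1L, 3L)
  a1 <- ifelse(substr(g, 1L, 1L) == "0", ref, alt)
  a2 <- ifelse(substr(g, 3L, 3L) == "0", ref, alt)
  df <- data.frame(chrom = chrom[keep], pos = pos1[keep] - 1L,
                   ref = ref[keep], alt = alt[keep], qual = qual[keep],
                   allele1 = a1[keep], allele2 = a2[keep],
                   phased = substr(g[keep], 2L, 2L) == "|",
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos), , drop = FALSE]
}

## Minimal VCF 4.2 writer for the simple records this workflow emits.
## `df` needs chrom, pos (0-based), ref, alt, qual, gt; `info` is an optional
## character vector (one INFO string per row, "." for none).
#' @noRd
.writeSimpleVcf <- function(df, path, sample = "SAMPLE", info = NULL,
                            contigs = NULL, extra_header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=haploMeth-%s", as.character(packageVersion("haploMeth"))))
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, extra_header,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  writeLines(hdr, con)
  if (nrow(df)) {
    o <- order(df$chrom, df$pos)
    df <- df[o, , drop = FALSE]
    if (is.null(info)) info <- rep(".", nrow(df)) else info <- info[o]
    qual <- ifelse(is.na(df$qual), ".", formatC(df$qual, format = "fg",
                                                digits = 6))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s\tGT\t%s",
                       df$chrom, as.integer(df$pos) + 1L, df$ref, df$alt,
                       qual, info, df$gt), con)
  }
  invisible(path)
}

#' Write a phased VCF
#'
#' Writes a [PhasedVariantSet] (or the result of [trioMockPhase()]) as a
#' minimal VCF with phased `0|1`/`1|0` genotypes, suitable as input to the
#' read-phasing stage.
#'
#' @param x a [PhasedVariantSet].
#' @param path output path.
#' @param sample sample name for the genotype column.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(x, path, sample = "SAMPLE", contigs = NULL) {
  df <- variants(x)
  gt <- ifelse(df$hp1_allele == df$ref_allele, "0|1", "1|0")
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref_allele,
                    alt = df$alt_allele, qual = df$qual, gt = gt,
                    stringsAsFactors = FALSE)
  .writeSimpleVcf(out, path, sample = sample, contigs = contigs)
}
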