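## S4 containers for the workflow. Coordinates in all containers are 0-based
## half-open (the convention of the methylation-call dialect); conversion to
## 1-based GRanges/SAM happens at the boundary, never inside.

#' Grouped per-read methylation call records
#'
#' One row per methylation caller record: a group of one or more CpGs on one
#' read that were scored together and share a log-likelihood ratio. `start`
#' and `end` are the 0-based forward-strand positions of the first and last
#' CpG cytosine of the group; `sequence` is the sequence context and contains
#' exactly `num_motifs` occurrences of `"CG"`.
#'
#' @slot calls data.frame with columns `chrom`, `strand`, `start`, `end`,
#'   `read_name`, `log_lik_ratio`, `log_lik_methylated`,
#'   `log_lik_unmethylated`, `num_calling_strands`, `num_motifs`, `sequence`.
#' @seealso [readMethylCalls()], [splitGroupedCalls()]
#' @export
setClass("MethylCallSet", representation(calls = "data.frame"))

setValidity("MethylCallSet", function(object) {
  df <- object@calls
  need <- c("chrom", "strand", "start", "end", "read_name", "log_lik_ratio",
            "log_lik_methylated", "log_lik_unmethylated",
            "num_calling_strands", "num_motifs", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!nrow(df)) return(TRUE)
  if (any(df$end < df$start)) return("end < start in some records")
  if (any(df$num_motifs < 1L)) return("num_motifs must be >= 1")
  if (any(df$num_motifs == 1L & df$start != df$end))
    return("single-motif records must have start == end")
  ncg <- .countSubstring(df$sequence, "CG")
  if (any(ncg != df$num_motifs))
    return(sprintf("CG count in sequence disagrees with num_motifs at row %d",
                   which(ncg != df$num_motifs)[1L]))
  TRUE
})

#' Per-CpG, per-read methylation calls
#'
#' The expanded form of a [MethylCallSet]: one row per CpG per read, with a
#' methylation state derived from the group log-likelihood ratio. Positions
#' are 0-based forward-strand C positions.
#'
#' @slot calls data.frame with columns `chrom`, `pos`, `read_name`,
#'   `log_lik_ratio`, `state` (one of `"methylated"`, `"unmethylated"`,
#'   `"uncalled"`).
#' @slot threshold numeric, the absolute log-likelihood-ratio call cutoff.
#' @seealso [processMethylationFile()], [callsByRead()], [callsInRegion()]
#' @export
setClass("CpGCallSet",
         representation(calls = "data.frame", threshold = "numeric"))

setValidity("CpGCallSet", function(object) {
  df <- object@calls
  need <- c("chrom", "pos", "read_name", "log_lik_ratio", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(df) && any(df$pos < 0L)) return("negative CpG position")
  if (nrow(df) && !all(df$state %in% c("methylated", "unmethylated", "uncalled")))
    return("invalid state value")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  TRUE
})

#' Phased heterozygous SNVs
#'
#' Biallelic heterozygous SNVs with a known haplotype assignment of the two
#' alleles. `pos` is 0-based. `hp1_allele`/`hp2_allele` are the alleles on
#' haplotype 1 (left of `|` in the VCF genotype) and haplotype 2.
#'
#' @slot variants data.frame with columns `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `hp1_allele`, `hp2_allele`, `qual`, `phase_set`.
#' @slot skipped named integer vector of input records skipped by category
#'   (`hom`, `unphased`, `indel`, `multiallelic`, `missing`).
#' @seealso [readPhasedVcf()], [trioMockPhase()]
#' @export
setClass("PhasedVariantSet",
         representation(variants = "data.frame", skipped = "integer"))

setValidity("PhasedVariantSet", function(object) {
  df <- object@variants
  need <- c("chrom", "pos", "ref_allele", "alt_allele", "hp1_allele",
            "hp2_allele", "qual", "phase_set")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!nrow(df)) return(TRUE)
  if (any(df$hp1_allele == df$hp2_allele)) return("homozygous record present")
  ok <- (df$hp1_allele == df$ref_allele & df$hp2_allele == df$alt_allele) |
        (df$hp1_allele == df$alt_allele & df$hp2_allele == df$ref_allele)
  if (!all(ok)) return("haplotype alleles must be {ref, alt}")
  TRUE
})

#' A set of aligned long reads
#'
#' A flat in-memory alignment container mirroring the SAM fields the
#' workflow needs. `start` is the 0-based leftmost mapped position; `seq`
#' is stored in reference-forward orientation, `qual` is the Sanger-encoded
#' base-quality string.
#'
#' @slot reads data.frame with columns `name`, `flag`, `chrom`, `start`,
#'   `mapq`, `cigar`, `seq`, `qual`, plus optional annotation columns
#'   (e.g. `hp_truth` from the simulator, `haplotype` after phasing).
#' @slot seqlengths named integer vector of reference sequence lengths.
#' @seealso [readAlignments()], [writeSam()], [simulateReads()]
#' @export
setClass("ReadSet",
         representation(reads = "data.frame", seqlengths = "integer"))

setValidity("ReadSet", function(object) {
  df <- object@reads
  need <- c("name", "flag", "chrom", "start", "mapq", "cigar", "seq", "qual")
  miss <- setdiff(need, names(df))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!nrow(df)) return(TRUE)
  if (any(nchar(df$seq) != nchar(df$qual)))
    return("seq and qual lengths differ")
  if (is.null(names(object@seqlengths)) && length(object@seqlengths))
    return("seqlengths must be named")
  TRUE
})

#' Pileup-feature neural-network SNV classifier
#'
#' A fully connected network with four hidden ReLU layers and a sigmoid
#' output. The first hidden layer is six times the input width and each
#' subsequent layer halves (integer division): for the standard 20-feature
#' input the hidden widths are 120, 60, 30, 15.
#'
#' @slot spec list with `input_dim`, `hidden_dims`, `activation`, `seed`.
#' @slot weights list of weight matrices (input to output order).
#' @slot biases list of bias vectors.
#' @slot center,scale numeric feature standardization vectors (length
#'   `input_dim`); zero/one until the model is trained.
#' @slot trained logical.
#' @slot history data.frame of per-epoch training/validation loss (empty
#'   until trained).
#' @seealso [buildClassifier()], [trainClassifier()], [predictSnvWeight()]
#' @export
setClass("SnvClassifier",
         representation(spec = "list", weights = "list", biases = "list",
                        center = "numeric", scale = "numeric",
                        trained = "logical", history = "data.frame"))

setValidity("SnvClassifier", function(object) {
  sp <- object@spec
  if (is.null(sp$input_dim) || is.null(sp$hidden_dims))
    return("spec must contain input_dim and hidden_dims")
  hd <- sp$hidden_dims
  if (length(hd) != 4L) return("exactly four hidden layers required")
  if (hd[1L] != 6L * sp$input_dim)
    return("first hidden layer must be six times the input width")
  if (!all(hd[-1L] == hd[-4L] %/% 2L))
    return("hidden widths must halve (integer division)")
  if (length(object@weights) != 5L || length(object@biases) != 5L)
    return("five weight/bias sets expected (4 hidden + output)")
  TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "MethylCallSet", function(object) {
  df <- object@calls
  cat(sprintf("MethylCallSet: %d grouped records, %d CpG calls, %d reads\n",
              nrow(df), sum(df$num_motifs), length(unique(df$read_name))))
})

setMethod("show", "CpGCallSet", function(object) {
  df <- object@calls
  tab <- table(factor(df$state,
                      levels = c("methylated", "unmethylated", "uncalled")))
  cat(sprintf(paste0("CpGCallSet: %d calls on %d reads (|LLR| threshold %g)\n",
                     "  methylated %d, unmethylated %d, uncalled %d\n"),
              nrow(df), length(unique(df$read_name)), object@threshold,
              tab[["methylated"]], tab[["unmethylated"]], tab[["uncalled"]]))
})

setMethod("show", "PhasedVariantSet", function(object) {
  cat(sprintf("PhasedVariantSet: %d phased heterozygous SNVs\n",
              nrow(object@variants)))
  if (sum(object@skipped))
    cat("  skipped:", paste(sprintf("%s=%d", names(object@skipped),
                                    object@skipped), collapse = ", "), "\n")
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d reads on %d reference sequence(s)\n",
              nrow(object@reads), length(object@seqlengths)))
})

setMethod("show", "SnvClassifier", function(object) {
  cat(sprintf("SnvClassifier: %d -> %s -> 1 (%s)%s\n",
              object@spec$input_dim,
              paste(object@spec$hidden_dims, collapse = " -> "),
              object@spec$activation,
              if (object@trained) ", trained" else ", untrained"))
})

## ---- accessors ------------------------------------------------------------

#' Accessors for haploMeth containers
#'
#' `methCalls()`, `cpgCalls()`, `variants()`, `reads()` return the underlying
#' data.frame of the respective container; `skippedCounts()` returns the
#' reader's skip counters; `callThreshold()` the LLR cutoff of a
#' [CpGCallSet]; `seqLengths()` the reference lengths of a [ReadSet].
#'
#' @param x a haploMeth container object.
#' @return A data.frame (or named vector for the counter/length accessors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
methCalls <- function(x) {
  .assert(is(x, "MethylCallSet"), "not a MethylCallSet")
  x@calls
}

#' @rdname accessors
#' @export
cpgCalls <- function(x) {
  .assert(is(x, "CpGCallSet"), "not a CpGCallSet")
  x@calls
}

#' @rdname accessors
#' @export
variants <- function(x) {
  .assert(is(x, "PhasedVariantSet"), "not a PhasedVariantSet")
  x@variants
}

#' @rdname accessors
#' @export
reads <- function(x) {
  .assert(is(x, "ReadSet"), "not a ReadSet")
  x@reads
}

#' @rdname accessors
#' @export
skippedCounts <- function(x) {
  .assert(is(x, "PhasedVariantSet"), "not a PhasedVariantSet")
  x@skipped
}

#' @rdname accessors
#' @export
callThreshold <- function(x) {
  .assert(is(x, "CpGCallSet"), "not a CpGCallSet")
  x@threshold
}

#' @rdname accessors
#' @export
seqLengths <- function(x) {
  .assert(is(x, "ReadSet"), "not a ReadSet")
  x@seqlengths
}

#' @rdname accessors
#' @export
setMethod("length", "MethylCallSet", function(x) nrow(x@calls))

#' @rdname accessors
#' @export
setMethod("length", "CpGCallSet", function(x) nrow(x@calls))

#' @rdname accessors
#' @export
setMethod("length", "PhasedVariantSet", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("length", "ReadSet", function(x) nrow(x@reads))
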