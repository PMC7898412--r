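## Internal helpers shared across modules.

#' @noRd
.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

## Derive a reproducible child seed from a user seed and a stream label.
## Kept below 2^31 so it is always a valid R integer seed.
#' @noRd
.childSeed <- function(seed, stream) {
  .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
          "seed must be a single finite number")
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

## Count occurrences of a fixed substring (overlap-free, like gregexpr).
#' @noRd
.countSubstring <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)
  vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), integer(1L))
}

## 0-based offsets of a fixed substring within each string.
#' @noRd
.substringOffsets0 <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)
  lapply(hits, function(h) if (h[1L] == -1L) integer(0) else as.integer(h) - 1L)
}

## Phred string <-> integer vectors (Sanger +33 encoding).
#' @noRd
.phredToInt <- function(qual) utf8ToInt(qual) - 33L

#' @noRd
.intToPhred <- function(q) intToUtf8(pmax(0L, pmin(93L, as.integer(q))) + 33L)

## ---- CIGAR arithmetic -----------------------------------------------------
## All positions are 0-based reference coordinates; query offsets are 0-based
## indices into the stored read sequence (reference-forward orientation).

## Parse a CIGAR into an op table with 0-based ref/query start offsets
## relative to the alignment start.
#' @noRd
.cigarTable <- function(cigar) {
  ops <- explodeCigarOps(cigar)[[1L]]
  lens <- explodeCigarOpLengths(cigar)[[1L]]
  ref_adv <- ops %in% c("M", "=", "X", "D", "N")
  qry_adv <- ops %in% c("M", "=", "X", "I", "S")
  ref_off <- cumsum(c(0L, lens * ref_adv))[seq_along(ops)]
  qry_off <- cumsum(c(0L, lens * qry_adv))[seq_along(ops)]
  list(ops = ops, lens = lens, ref_off = ref_off, qry_off = qry_off,
       ref_span = sum(lens[ref_adv]))
}

## For a single read, map 0-based reference positions to 1-based indices into
## the stored sequence. Returns NA for positions under a deletion/skip or
## outside the aligned span. `deleted` marks positions inside the span that
## fall in a D/N op.
#' @noRd
.queryIndexAtRef <- function(cigar, read_start0, refpos0) {
  ct <- .cigarTable(cigar)
  keep <- ct$ops %in% c("M", "=", "X", "D", "N")
  ops <- ct$ops[keep]
  lens <- ct$lens[keep]
  rstart <- read_start0 + ct$ref_off[keep]
  qstart <- ct$qry_off[keep]
  idx <- rep(NA_integer_, length(refpos0))
  del <- rep(FALSE, length(refpos0))
  if (!length(ops)) return(list(idx = idx, deleted = del))
  i <- findInterval(refpos0, rstart)
  inside <- i >= 1L & refpos0 < (rstart[pmax(i, 1L)] + lens[pmax(i, 1L)])
  ok <- which(inside)
  if (length(ok)) {
    oo <- i[ok]
    aligned <- ops[oo] %in% c("M", "=", "X")
    idx[ok[aligned]] <- qstart[oo[aligned]] + (refpos0[ok[aligned]] - rstart[oo[aligned]]) + 1L
    del[ok[!aligned]] <- TRUE
  }
  list(idx = idx, deleted = del)
}

## Reference span consumed by a CIGAR.
#' @noRd
.refSpan <- function(cigar) {
  cigarWidthAlongReferenceSpace(cigar)
}

## SAM flag bit tests.
#' @noRd
.flagBit <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' @noRd
.FLAG_UNMAPPED <- 0x4L
#' @noRd
.FLAG_REVERSE <- 0x10L
#' @noRd
.FLAG_SECONDARY <- 0x100L
#' @noRd
.FLAG_QCFAIL <- 0x200L
#' @noRd
.FLAG_DUP <- 0x400L
#' @noRd
.FLAG_SUPPL <- 0x800L
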