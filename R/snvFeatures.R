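## Pileup feature extraction around candidate SNVs. A false SNV call from a
## nanopore base caller implies the surrounding 5-mers were mis-translated,
## so excess mismatches/indels and depressed base qualities in the adjacent
## windows separate false from true candidates.

#' Per-position pileup statistics
#'
#' Computes, for every reference position covered by at least one read:
#' the number of aligned bases (`cov`), spanning reads including deletions
#' (`span`), mismatches vs the reference (`n_mm`), deleted bases (`n_del`),
#' insertions immediately following the position (`n_ins`) and the sum of
#' aligned base qualities (`qual_sum`). Secondary/supplementary/unmapped
#' records are ignored.
#'
#' @param readset a [ReadSet].
#' @param reference reference sequence as a single character string (or a
#'   named character vector / `DNAStringSet` for multiple chromosomes).
#' @return data.table keyed by (`chrom`, `pos`) (0-based).
#' @export
pileupStats <- function(readset, reference) {
  if (is(reference, "DNAStringSet"))
    reference <- setNames(as.character(reference), names(reference))
  rd <- reads(readset)
  use <- !.flagBit(rd$flag, .FLAG_UNMAPPED) &
         !.flagBit(rd$flag, .FLAG_SECONDARY) &
         !.flagBit(rd$flag, .FLAG_SUPPL)
  rd <- rd[use, , drop = FALSE]
  if (length(reference) == 1L && is.null(names(reference)))
    names(reference) <- rd$chrom[1L]
  chunks <- vector("list", nrow(rd))
  dels <- vector("list", nrow(rd))
  inss <- vector("list", nrow(rd))
  for (i in seq_len(nrow(rd))) {
    ct <- .cigarTable(rd$cigar[i])
    st <- rd$start[i]
    refstr <- reference[[rd$chrom[i]]]
    qv <- .phredToInt(rd$qual[i])
    mIdx <- which(ct$ops %in% c("M", "=", "X"))
    if (length(mIdx)) {
      pos <- unlist(lapply(mIdx, function(k)
        (st + ct$ref_off[k]):(st + ct$ref_off[k] + ct$lens[k] - 1L)))
      qoff <- unlist(lapply(mIdx, function(k)
        (ct$qry_off[k] + 1L):(ct$qry_off[k] + ct$lens[k])))
      readb <- strsplit(rd$seq[i], "")[[1L]][qoff]
      refb <- strsplit(substring(refstr, min(pos) + 1L, max(pos) + 1L),
                       "")[[1L]][pos - min(pos) + 1L]
      chunks[[i]] <- data.table(chrom = rd$chrom[i], pos = pos,
                                q = qv[qoff], mm = readb != refb)
    }
    dIdx <- which(ct$ops %in% c("D", "N"))
    if (length(dIdx))
      dels[[i]] <- data.table(chrom = rd$chrom[i],
                              pos = unlist(lapply(dIdx, function(k)
        (st + ct$ref_off[k]):(st + ct$ref_off[k] + ct$lens[k] - 1L))))
    iIdx <- which(ct$ops == "I")
    if (length(iIdx))
      inss[[i]] <- data.table(chrom = rd$chrom[i],
                              pos = st + ct$ref_off[iIdx] - 1L)
  }
  al <- rbindlist(chunks)
  agg <- if (nrow(al)) al[, .(cov = .N, qual_sum = sum(q), n_mm = sum(mm)),
                          by = .(chrom, pos)]
         else data.table(chrom = character(), pos = integer(),
                         cov = integer(), qual_sum = numeric(),
                         n_mm = integer())
  dd <- rbindlist(dels)
  if (nrow(dd)) {
    dd <- dd[, .(n_del = .N), by = .(chrom, pos)]
    agg <- merge(agg, dd, by = c("chrom", "pos"), all = TRUE)
  } else data.table::set(agg, j = "n_del", value = 0L)
  ii <- rbindlist(inss)
  if (nrow(ii)) {
    ii <- ii[, .(n_ins = .N), by = .(chrom, pos)]
    agg <- merge(agg, ii, by = c("chrom", "pos"), all = TRUE)
  } else data.table::set(agg, j = "n_ins", value = 0L)
  for (cc in c("cov", "qual_sum", "n_mm", "n_del", "n_ins")) {
    v <- agg[[cc]]
    v[is.na(v)] <- 0L
    data.table::set(agg, j = cc, value = v)
  }
  data.table::set(agg, j = "span", value = agg$cov + agg$n_del)
  setkeyv(agg, c("chrom", "pos"))
  agg[]
}

## Feature order within a window: 5 positions x (mean base quality,
## mismatch freq, deletion freq, insertion freq), position-major.
#' @noRd
.FEATURES_PER_POS <- 4L

#' Extract 5-mer window features around candidate SNVs
#'
#' Every base is part of five 5-mers, so each candidate site yields (up to)
#' five windows `[site-4, site]` ... `[site, site+4]`; windows clipped by a
#' contig edge are dropped. Per window position the features are mean base
#' quality of aligned bases, and mismatch, deletion and insertion
#' frequencies (events over spanning coverage). Sites with zero aligned
#' coverage at the site itself are skipped with a warning.
#'
#' @param pileup result of [pileupStats()].
#' @param sites data.frame with `chrom` and `pos` (0-based) of candidates.
#' @param seqlengths named integer vector of contig lengths.
#' @return list with `features` (matrix, one row per window, 20 columns),
#'   `site_index` (row of `sites` each window belongs to), `window_start`
#'   (0-based), and `skipped` (indices of zero-coverage sites).
#' @export
extractWindowFeatures <- function(pileup, sites, seqlengths) {
  n <- nrow(sites)
  key <- paste(sites$chrom, sites$pos)
  pk <- paste(pileup$chrom, pileup$pos)
  covAt <- pileup$cov[match(key, pk)]
  skipped <- which(is.na(covAt) | covAt == 0L)
  if (length(skipped))
    warning(sprintf("%d candidate site(s) with zero aligned coverage skipped",
                    length(skipped)))
  keep <- setdiff(seq_len(n), skipped)

  ws <- unlist(lapply(sites$pos[keep], function(p) (p - 4L):p))
  site_index <- rep(keep, each = 5L)
  L <- seqlengths[sites$chrom[site_index]]
  ok <- ws >= 0L & (ws + 4L) < L
  ws <- ws[ok]; site_index <- site_index[ok]

  posmat <- outer(ws, 0L:4L, `+`)  # n_win x 5 reference positions
  chromv <- sites$chrom[site_index]
  idx <- match(paste(rep(chromv, 5L), as.vector(posmat)), pk)
  getv <- function(col, default = 0) {
    v <- pileup[[col]][idx]
    v[is.na(v)] <- default
    matrix(v, nrow = length(ws))
  }
  cov <- getv("cov"); span <- getv("span"); qs <- getv("qual_sum")
  mm <- getv("n_mm"); dl <- getv("n_del"); ins <- getv("n_ins")
  meanq <- ifelse(cov > 0, qs / cov, 0)
  f_mm <- ifelse(span > 0, mm / span, 0)
  f_dl <- ifelse(span > 0, dl / span, 0)
  f_in <- ifelse(span > 0, ins / span, 0)
  feat <- matrix(0, nrow = length(ws), ncol = 5L * .FEATURES_PER_POS)
  for (p in 1:5) {
    feat[, (p - 1L) * 4L + 1L] <- meanq[, p]
    feat[, (p - 1L) * 4L + 2L] <- f_mm[, p]
    feat[, (p - 1L) * 4L + 3L] <- f_dl[, p]
    feat[, (p - 1L) * 4L + 4L] <- f_in[, p]
  }
  colnames(feat) <- paste0(rep(paste0("p", 1:5), each = 4L), "_",
                           c("meanq", "mm", "del", "ins"))
  list(features = feat, site_index = site_index, window_start = ws,
       skipped = skipped)
}

#' Label candidate SNVs against a truth set
#'
#' A candidate is `true_snv` iff (chrom, pos, ref, alt) matches a truth
#' variant exactly — same position with a different alternative allele is
#' still a false call.
#'
#' @param candidates data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param truth data.frame with `chrom`, `pos`, `ref`/`ref_allele`,
#'   `alt`/`alt_allele` (a [PhasedVariantSet] is accepted).
#' @return `candidates` with a `label` column (`"true_snv"`/`"false_snv"`).
#' @export
labelTrainingSites <- function(candidates, truth) {
  if (is(truth, "PhasedVariantSet")) truth <- variants(truth)
  tref <- if ("ref_allele" %in% names(truth)) truth$ref_allele else truth$ref
  talt <- if ("alt_allele" %in% names(truth)) truth$alt_allele else truth$alt
  tkey <- paste(truth$chrom, truth$pos, tref, talt)
  ckey <- paste(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt)
  candidates$label <- ifelse(ckey %in% tkey, "true_snv", "false_snv")
  candidates
}
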