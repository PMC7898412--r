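## Differential methylation between haplotypes. The per-site test is a
## coverage-weighted two-proportion z (a fully specified substitute for
## shrinkage-based sequencing DMA tests); region calling follows the usual
## DMR grammar (significance runs with a merge distance, minimum length,
## minimum CpGs, percent-significant) plus an area-statistic confidence
## filter — the sum of per-CpG test statistics over the region.

#' Differential methylation configuration
#'
#' @param smoothing_span_bp window (bp) for optional coverage-weighted
#'   proportion smoothing; smoothing is applied only when the analysis
#'   requests it (the site-level test stays calibrated unsmoothed).
#' @param p_threshold per-site significance threshold for region
#'   candidates.
#' @param min_len_bp minimum region span.
#' @param min_cg minimum CpGs per region.
#' @param merge_dist_bp maximum gap between significant sites within a
#'   region, and merge distance between adjacent regions.
#' @param pct_sig minimum fraction of member sites significant.
#' @param area_stat_cutoff |area statistic| cutoff used by
#'   [filterDmrsByArea()].
#' @param boundary_delta_frac region edges are extended over adjacent
#'   sites whose raw methylation difference keeps the region's sign and
#'   at least this fraction of the region's mean difference; set to
#'   `NA` to disable edge refinement.
#' @return A validated list of class `haploMethDmaConfig`.
#' @export
dmaConfig <- function(smoothing_span_bp = 500L, p_threshold = 1e-3,
                      min_len_bp = 50L, min_cg = 3L, merge_dist_bp = 100L,
                      pct_sig = 0.5, area_stat_cutoff = 100,
                      boundary_delta_frac = 0.5) {
  .assert(all(c(smoothing_span_bp, p_threshold, min_len_bp, min_cg,
                merge_dist_bp, area_stat_cutoff) > 0),
          "all thresholds must be positive")
  .assert(pct_sig > 0 && pct_sig <= 1, "pct_sig must be in (0, 1]")
  structure(list(smoothing_span_bp = as.integer(smoothing_span_bp),
                 p_threshold = p_threshold,
                 min_len_bp = as.integer(min_len_bp),
                 min_cg = as.integer(min_cg),
                 merge_dist_bp = as.integer(merge_dist_bp),
                 pct_sig = pct_sig, area_stat_cutoff = area_stat_cutoff,
                 boundary_delta_frac = boundary_delta_frac),
            class = "haploMethDmaConfig")
}

#' Per-CpG two-proportion statistic
#'
#' Pooled two-proportion z test of the methylation proportions of the two
#' haplotypes at one site: with pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`, the statistic is
#' `(x1/n1 - x2/n2) / sqrt(p (1-p) (1/n1 + 1/n2))`, with a two-sided
#' normal p-value. Degenerate pools (`p` of 0 or 1) give statistic 0 and
#' p-value 1. Sites with zero coverage on either haplotype are the
#' caller's job to drop.
#'
#' @param n1,x1 haplotype-1 coverage and methylated count (vectorized).
#' @param n2,x2 haplotype-2 values.
#' @param smoothed_p1,smoothed_p2 optional smoothed proportions (see
#'   [smoothCounts()]) to use in the numerator instead of the raw ones.
#' @return data.frame with `diff`, `stat`, `p_value`.
#' @export
perCpgStatistic <- function(n1, x1, n2, x2, smoothed_p1 = NULL,
                            smoothed_p2 = NULL) {
  .assert(all(n1 > 0) && all(n2 > 0), "coverage must be positive")
  p1 <- if (is.null(smoothed_p1)) x1 / n1 else smoothed_p1
  p2 <- if (is.null(smoothed_p2)) x2 / n2 else smoothed_p2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  d <- p1 - p2
  stat <- ifelse(pool <= 0 | pool >= 1, 0, d / se)
  p <- ifelse(pool <= 0 | pool >= 1, 1, 2 * pnorm(-abs(stat)))
  data.frame(diff = d, stat = stat, p_value = pmin(p, 1))
}

#' Coverage-weighted smoothing of methylation proportions
#'
#' Moving average of `x/n` over `pos +/- span/2`, weighting each site by
#' its coverage. Raw counts are retained alongside; a constant-proportion
#' series and single sites are unchanged.
#'
#' @param pos sorted 0-based site positions (one chromosome).
#' @param n,x coverage and methylated counts.
#' @param span_bp window width in bp.
#' @return numeric vector of smoothed proportions.
#' @export
smoothCounts <- function(pos, n, x, span_bp = 500L) {
  .assert(!is.unsorted(pos), "positions must be sorted")
  half <- span_bp / 2
  lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + half, pos)
  cx <- c(0, cumsum(as.numeric(x))); cn <- c(0, cumsum(as.numeric(n)))
  sx <- cx[hi + 1L] - cx[lo]
  sn <- cn[hi + 1L] - cn[lo]
  sx / sn
}

#' Build the per-site statistics table for two haplotype frequency sets
#'
#' Joins the two per-haplotype frequency tables on CpG position (sites
#' covered on both haplotypes only) and computes the per-site statistic.
#'
#' @param freq_hp1,freq_hp2 data.frames from
#'   [computeMethylationFrequency()] (or [readMethylFrequency()]).
#' @param smooth apply [smoothCounts()] with the configured span before
#'   testing (off by default; the raw test is calibrated site-wise).
#' @param cfg a [dmaConfig()].
#' @return data.frame sorted by (chrom, pos) with counts, `diff`, `stat`,
#'   `p_value`.
#' @export
siteStatistics <- function(freq_hp1, freq_hp2, smooth = FALSE,
                           cfg = dmaConfig()) {
  a <- as.data.table(freq_hp1)[, .(chrom, pos = start, n1 = n_all_calls,
                                   x1 = n_mod_calls)]
  b <- as.data.table(freq_hp2)[, .(chrom, pos = start, n2 = n_all_calls,
                                   x2 = n_mod_calls)]
  m <- merge(a, b, by = c("chrom", "pos"))
  setorder(m, chrom, pos)
  if (!nrow(m))
    return(data.frame(chrom = character(), pos = integer(), n1 = integer(),
                      x1 = integer(), n2 = integer(), x2 = integer(),
                      diff = numeric(), stat = numeric(),
                      p_value = numeric()))
  if (smooth) {
    sp1 <- sp2 <- numeric(nrow(m))
    for (ch in unique(m$chrom)) {
      i <- which(m$chrom == ch)
      sp1[i] <- smoothCounts(m$pos[i], m$n1[i], m$x1[i],
                             cfg$smoothing_span_bp)
      sp2[i] <- smoothCounts(m$pos[i], m$n2[i], m$x2[i],
                             cfg$smoothing_span_bp)
    }
    st <- perCpgStatistic(m$n1, m$x1, m$n2, m$x2, sp1, sp2)
  } else {
    st <- perCpgStatistic(m$n1, m$x1, m$n2, m$x2)
  }
  cbind(as.data.frame(m), st)
}

## Region calling on one chromosome's sorted site table.
#' @noRd
.callDmrsChrom <- function(df, cfg) {
  sig <- df$p_value < cfg$p_threshold & df$stat != 0
  if (!any(sig)) return(NULL)
  sgn <- sign(df$stat)
  si <- which(sig)
  ## candidate = run of significant same-sign sites with gaps <= merge_dist
  brk <- c(TRUE, diff(df$pos[si]) > cfg$merge_dist_bp |
                 sgn[si][-1L] != sgn[si][-length(si)])
  grp <- cumsum(brk)
  cands <- lapply(split(si, grp), function(ii)
    c(first = ii[1L], last = ii[length(ii)], sign = sgn[ii[1L]]))

  ## edge refinement: absorb adjacent sites whose raw difference keeps the
  ## region's sign and magnitude (fraction of the region's mean |diff|)
  refine <- !is.na(cfg$boundary_delta_frac)
  regions <- lapply(cands, function(cc) {
    first <- cc[["first"]]; last <- cc[["last"]]; s <- cc[["sign"]]
    if (refine) {
      memb <- first:last
      delta <- cfg$boundary_delta_frac * mean(abs(df$diff[memb]))
      i <- first - 1L
      while (i >= 1L && sign(df$diff[i]) == s && abs(df$diff[i]) >= delta &&
             df$pos[i + 1L] - df$pos[i] <= cfg$merge_dist_bp) {
        first <- i; i <- i - 1L
      }
      i <- last + 1L
      while (i <= nrow(df) && sign(df$diff[i]) == s &&
             abs(df$diff[i]) >= delta &&
             df$pos[i] - df$pos[i - 1L] <= cfg$merge_dist_bp) {
        last <- i; i <- i + 1L
      }
    }
    c(first = first, last = last, sign = s)
  })

  ## merge adjacent same-sign regions closer than merge_dist (also repairs
  ## candidates split by a local run of non-significant sites)
  regions <- regions[order(vapply(regions, `[[`, 0, "first"))]
  merged <- list()
  for (r in regions) {
    if (length(merged)) {
      pr <- merged[[length(merged)]]
      gap <- df$pos[r[["first"]]] - df$pos[pr[["last"]]]
      if (r[["sign"]] == pr[["sign"]] &&
          (r[["first"]] <= pr[["last"]] + 1L || gap < cfg$merge_dist_bp)) {
        pr[["last"]] <- max(pr[["last"]], r[["last"]])
        merged[[length(merged)]] <- pr
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }

  rows <- lapply(merged, function(r) {
    memb <- r[["first"]]:r[["last"]]
    span <- df$pos[r[["last"]]] - df$pos[r[["first"]]] + 1L
    n_cpg <- length(memb)
    n_sig <- sum(sig[memb])
    if (span < cfg$min_len_bp || n_cpg < cfg$min_cg ||
        n_sig / n_cpg < cfg$pct_sig) return(NULL)
    area <- sum(df$stat[memb])
    data.frame(chrom = df$chrom[1L], start = df$pos[r[["first"]]],
               end = df$pos[r[["last"]]] + 1L, n_cpg = n_cpg,
               n_sig = n_sig, pct_sig = n_sig / n_cpg,
               mean_diff = mean(df$diff[memb]), area_stat = area,
               direction = if (r[["sign"]] > 0) "hyper-HP1" else "hyper-HP2",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
}

#' Call differentially methylated regions
#'
#' Candidate regions are maximal runs of consecutive significant (`p <
#' p_threshold`) same-sign sites whose neighbours lie within
#' `merge_dist_bp`; region edges are then extended over adjacent sites
#' whose raw difference keeps the sign and magnitude (see
#' [dmaConfig()]`$boundary_delta_frac`), same-sign regions closer than the
#' merge distance are merged, and regions failing the length / CpG-count /
#' percent-significant filters are dropped. The area statistic is the sum
#' of the per-CpG test statistics over the region's member sites.
#'
#' @param stats result of [siteStatistics()].
#' @param cfg a [dmaConfig()].
#' @return data.frame of DMRs, sorted and non-overlapping: `chrom`,
#'   `start`, `end` (0-based half-open), `n_cpg`, `n_sig`, `pct_sig`,
#'   `mean_diff`, `area_stat`, `direction`.
#' @export
callDmrs <- function(stats, cfg = dmaConfig()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(), n_sig = integer(),
                      pct_sig = numeric(), mean_diff = numeric(),
                      area_stat = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(stats)) return(empty)
  out <- lapply(split(stats, stats$chrom), .callDmrsChrom, cfg = cfg)
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter DMRs by area statistic
#'
#' Regions near known regulatory targets of allele-specific methylation
#' overwhelmingly carry `|area_stat| >= 100`, so the magnitude of the area
#' statistic is an effective confidence filter for the (numerous) called
#' regions.
#'
#' @param dmrs result of [callDmrs()].
#' @param cutoff keep regions with `|area_stat| >= cutoff`.
#' @return filtered data.frame.
#' @export
filterDmrsByArea <- function(dmrs, cutoff = 100) {
  dmrs[abs(dmrs$area_stat) >= cutoff, , drop = FALSE]
}

#' Full differential-methylation analysis between haplotypes
#'
#' @param freq_hp1,freq_hp2 per-haplotype frequency tables (data.frame or
#'   file path).
#' @param cfg a [dmaConfig()].
#' @param smooth smooth proportions before testing (see
#'   [siteStatistics()]).
#' @param area_filter apply [filterDmrsByArea()] at the configured cutoff.
#' @return list with `sites` (per-site statistics), `dmrs`.
#' @export
diffMethylation <- function(freq_hp1, freq_hp2, cfg = dmaConfig(),
                            smooth = FALSE, area_filter = FALSE) {
  if (is.character(freq_hp1)) freq_hp1 <- readMethylFrequency(freq_hp1)
  if (is.character(freq_hp2)) freq_hp2 <- readMethylFrequency(freq_hp2)
  sites <- siteStatistics(freq_hp1, freq_hp2, smooth = smooth, cfg = cfg)
  dmrs <- callDmrs(sites, cfg)
  if (area_filter) dmrs <- filterDmrsByArea(dmrs, cfg$area_stat_cutoff)
  list(sites = sites, dmrs = dmrs)
}

#' Convert a DMR table to GRanges
#'
#' @param dmrs result of [callDmrs()].
#' @return A `GRanges` (1-based) with the DMR columns as metadata.
#' @export
dmrsAsGRanges <- function(dmrs) {
  gr <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
  mcols(gr) <- DataFrame(dmrs[, setdiff(names(dmrs),
                                        c("chrom", "start", "end")),
                              drop = FALSE])
  gr
}

#' Map DMRs to annotation intervals
#'
#' Half-open interval intersection of DMRs against intervals expanded by a
#' strand-aware flank: `flank_up` extends upstream of the interval
#' (leftward for `+` strand, rightward for `-`), `flank_down` downstream.
#' With `tss_only = TRUE` the expansion is anchored at the transcription
#' start site instead of the whole interval — the promoter-window
#' convention (e.g. 1 kb up, 200 bp down of the TSS).
#'
#' @param dmrs DMR data.frame (0-based half-open `start`/`end`).
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), optional `strand` (default `+`) and `name`.
#' @param flank_up,flank_down flank sizes in bp.
#' @param tss_only anchor at the TSS rather than the interval body.
#' @return data.frame of (dmr_index, interval_index) overlap pairs with
#'   coordinates and names.
#' @export
mapDmrsToRegions <- function(dmrs, intervals, flank_up = 0L,
                             flank_down = 0L, tss_only = FALSE) {
  if (!nrow(dmrs) || !nrow(intervals))
    return(data.frame(dmr_index = integer(), interval_index = integer(),
                      chrom = character(), dmr_start = integer(),
                      dmr_end = integer(), interval_name = character(),
                      stringsAsFactors = FALSE))
  st <- if ("strand" %in% names(intervals)) intervals$strand else
          rep("+", nrow(intervals))
  plus <- st != "-"
  if (tss_only) {
    tss <- ifelse(plus, intervals$start, intervals$end - 1L)
    ws <- ifelse(plus, tss - flank_up, tss - flank_down + 1L)
    we <- ifelse(plus, tss + flank_down + 1L, tss + flank_up + 1L)
  } else {
    ws <- intervals$start - ifelse(plus, flank_up, flank_down)
    we <- intervals$end + ifelse(plus, flank_down, flank_up)
  }
  ws <- pmax(0L, as.integer(ws))
  gr_i <- GRanges(intervals$chrom, IRanges(ws + 1L, as.integer(we)))
  gr_d <- GRanges(dmrs$chrom, IRanges(dmrs$start + 1L, dmrs$end))
  ov <- findOverlaps(gr_d, gr_i)
  nm <- if ("name" %in% names(intervals)) intervals$name else
          as.character(seq_len(nrow(intervals)))
  data.frame(dmr_index = queryHits(ov), interval_index = subjectHits(ov),
             chrom = dmrs$chrom[queryHits(ov)],
             dmr_start = dmrs$start[queryHits(ov)],
             dmr_end = dmrs$end[queryHits(ov)],
             interval_name = nm[subjectHits(ov)],
             stringsAsFactors = FALSE)
}
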