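## Synthetic diploid generator. Reads are emitted pre-aligned with exact
## CIGARs built from the injected edits, so the truth (haplotype of origin,
## error positions, methylation states) is known exactly and no external
## aligner is involved.

#' Specification for a synthetic diploid dataset
#'
#' Defaults describe a single nanopore flow-cell-scale experiment on a 1-Mb
#' diploid genome: human-like GC content and heterozygosity (one het SNV
#' per kb), 20-fold coverage of 10-kb (log-normal) reads with ~10% base
#' error (6% mismatch, 2% insertion, 2% deletion), clustered-error hotspots
#' that spawn false SNV candidates, three 1-kb imprinted-like regions with
#' a 0.7 haplotype methylation difference over a 0.75 methylated
#' background, and a confident methylation caller (LLR scale 6, Gaussian
#' noise sd 2).
#'
#' @param genome_length genome size in bp.
#' @param gc_fraction GC content of the random reference.
#' @param het_snv_rate heterozygous SNV rate per bp.
#' @param read_coverage fold coverage.
#' @param read_length_mean,read_length_sd log-normal read length moments (bp).
#' @param mismatch_rate,ins_rate,del_rate per-base error rates.
#' @param hotspot_rate expected clustered-error hotspots per bp.
#' @param hotspot_error_multiplier factor applied to error rates inside a
#'   hotspot window.
#' @param hotspot_width_bp hotspot window width.
#' @param dmr_spec data.frame with columns `start`, `end` (0-based,
#'   half-open), `p_meth_hp1`, `p_meth_hp2`: regions of haplotype-specific
#'   methylation. `NULL` uses the default three regions; use a zero-row
#'   data.frame for none.
#' @param background_p_meth CpG methylation probability outside `dmr_spec`
#'   (both haplotypes).
#' @param llr_scale,llr_noise_sd emitted log-likelihood ratio is
#'   `llr_scale * (+/-1) + N(0, llr_noise_sd)`.
#' @param seed mandatory integer seed; every simulation operation derives
#'   its own stream from it and is fully deterministic.
#' @return A validated spec (list of class `haploMethSimSpec`).
#' @export
simulationSpec <- function(genome_length = 1e6L, gc_fraction = 0.42,
                           het_snv_rate = 1e-3, read_coverage = 20,
                           read_length_mean = 10000, read_length_sd = 5000,
                           mismatch_rate = 0.06, ins_rate = 0.02,
                           del_rate = 0.02, hotspot_rate = 2e-5,
                           hotspot_error_multiplier = 6,
                           hotspot_width_bp = 10L, dmr_spec = NULL,
                           background_p_meth = 0.75, llr_scale = 6,
                           llr_noise_sd = 2, seed) {
  .assert(!missing(seed), "seed is mandatory")
  if (is.null(dmr_spec)) {
    anchor <- round(genome_length * c(0.2, 0.5, 0.8))
    dmr_spec <- data.frame(start = anchor, end = anchor + 1000L,
                           p_meth_hp1 = c(0.85, 0.15, 0.85),
                           p_meth_hp2 = c(0.15, 0.85, 0.15))
  }
  spec <- list(genome_length = as.integer(genome_length),
               gc_fraction = gc_fraction, het_snv_rate = het_snv_rate,
               read_coverage = read_coverage,
               read_length_mean = read_length_mean,
               read_length_sd = read_length_sd,
               mismatch_rate = mismatch_rate, ins_rate = ins_rate,
               del_rate = del_rate, hotspot_rate = hotspot_rate,
               hotspot_error_multiplier = hotspot_error_multiplier,
               hotspot_width_bp = as.integer(hotspot_width_bp),
               dmr_spec = as.data.frame(dmr_spec),
               background_p_meth = background_p_meth,
               llr_scale = llr_scale, llr_noise_sd = llr_noise_sd,
               seed = as.integer(seed), chrom = "chr1")
  rates <- c(spec$gc_fraction, spec$het_snv_rate, spec$mismatch_rate,
             spec$ins_rate, spec$del_rate, spec$hotspot_rate,
             spec$background_p_meth)
  .assert(all(rates >= 0 & rates <= 1), "all rates must be in [0, 1]")
  .assert(spec$mismatch_rate + spec$ins_rate + spec$del_rate < 0.9,
          "combined error rate too high")
  if (nrow(spec$dmr_spec)) {
    .assert(all(spec$dmr_spec$start >= 0 &
                spec$dmr_spec$end <= spec$genome_length),
            "dmr intervals must lie within the genome")
    .assert(all(c(spec$dmr_spec$p_meth_hp1, spec$dmr_spec$p_meth_hp2) >= 0 &
                c(spec$dmr_spec$p_meth_hp1, spec$dmr_spec$p_meth_hp2) <= 1),
            "dmr methylation probabilities must be in [0, 1]")
  }
  class(spec) <- "haploMethSimSpec"
  spec
}

#' @export
print.haploMethSimSpec <- function(x, ...) {
  cat(sprintf(paste0("haploMeth simulation spec: %s bp genome, %gx coverage,",
                     " het rate %g, error %g/%g/%g (mm/ins/del), %d ASM",
                     " region(s), seed %d\n"),
              format(x$genome_length, big.mark = ","), x$read_coverage,
              x$het_snv_rate, x$mismatch_rate, x$ins_rate, x$del_rate,
              nrow(x$dmr_spec), x$seed))
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

## Hotspot windows are drawn from their own seed stream so that reads and
## candidate VCF simulation agree on them.
#' @noRd
.simHotspots <- function(spec) {
  set.seed(.childSeed(spec$seed, "hotspots"))
  n <- rpois(1L, spec$hotspot_rate * spec$genome_length)
  if (!n) return(data.frame(start = integer(), end = integer()))
  start <- sort(sample.int(spec$genome_length - spec$hotspot_width_bp, n))
  data.frame(start = start, end = start + spec$hotspot_width_bp)
}

#' Simulate a diploid genome with phased heterozygous SNVs
#'
#' Generates a random reference, places heterozygous SNVs by a per-base
#' Bernoulli process at `het_snv_rate` (Poisson in expectation), assigns
#' each alternative allele to haplotype 1 or 2 at random, and builds the
#' two haplotype sequences. Deterministic under the spec seed.
#'
#' @param spec a [simulationSpec()].
#' @return list with `reference`, `hap1`, `hap2` (character strings),
#'   `variants` (a [PhasedVariantSet], 0-based positions), `chrom`,
#'   `hotspots` (data.frame of clustered-error windows).
#' @export
simulateDiploid <- function(spec) {
  set.seed(.childSeed(spec$seed, "diploid"))
  L <- spec$genome_length
  p <- c((1 - spec$gc_fraction) / 2, spec$gc_fraction / 2,
         spec$gc_fraction / 2, (1 - spec$gc_fraction) / 2)
  ref <- sample(.BASES, L, replace = TRUE, prob = p)
  pos <- which(runif(L) < spec$het_snv_rate) - 1L  # 0-based
  refb <- ref[pos + 1L]
  altb <- .BASES[(match(refb, .BASES) + sample.int(3L, length(pos),
                                                   replace = TRUE) - 1L) %% 4L + 1L]
  alt_on_hp1 <- runif(length(pos)) < 0.5
  hap1 <- ref; hap2 <- ref
  hap1[pos + 1L] <- ifelse(alt_on_hp1, altb, refb)
  hap2[pos + 1L] <- ifelse(alt_on_hp1, refb, altb)
  df <- data.frame(chrom = rep(spec$chrom, length(pos)), pos = pos,
                   ref_allele = refb, alt_allele = altb,
                   hp1_allele = ifelse(alt_on_hp1, altb, refb),
                   hp2_allele = ifelse(alt_on_hp1, refb, altb),
                   qual = rep(NA_real_, length(pos)),
                   phase_set = rep("1", length(pos)),
                   stringsAsFactors = FALSE)
  list(reference = paste(ref, collapse = ""),
       hap1 = paste(hap1, collapse = ""),
       hap2 = paste(hap2, collapse = ""),
       variants = new("PhasedVariantSet", variants = df,
                      skipped = c(hom = 0L, unphased = 0L, indel = 0L,
                                  multiallelic = 0L, missing = 0L)),
       chrom = spec$chrom, hotspots = .simHotspots(spec))
}

## Per-genome-position error-rate multiplier from the hotspot windows.
#' @noRd
.hotspotMultiplier <- function(spec, hotspots) {
  mult <- rep(1, spec$genome_length)
  if (nrow(hotspots))
    for (i in seq_len(nrow(hotspots)))
      mult[(hotspots$start[i] + 1L):hotspots$end[i]] <-
        spec$hotspot_error_multiplier
  mult
}

#' Simulate pre-aligned reads from the two haplotypes
#'
#' Reads alternate between the haplotypes, start uniformly, have log-normal
#' lengths and carry mismatch/insertion/deletion errors at the spec rates
#' (multiplied inside hotspot windows). Base qualities are drawn high at
#' correct bases and low at error bases. Each read is emitted pre-aligned
#' at its true position with the CIGAR implied by the injected edits.
#'
#' @param spec a [simulationSpec()].
#' @param diploid result of [simulateDiploid()].
#' @return A [ReadSet] with truth annotation columns `hp_truth`
#'   (`"HP1"`/`"HP2"`) and `ref_span`.
#' @export
simulateReads <- function(spec, diploid) {
  set.seed(.childSeed(spec$seed, "reads"))
  L <- spec$genome_length
  n <- max(1L, round(spec$read_coverage * L / spec$read_length_mean))
  m <- spec$read_length_mean; s <- spec$read_length_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  lens <- pmin(L, pmax(200L, round(rlnorm(n, meanlog, sdlog))))
  starts <- floor(runif(n, 0, L - lens + 1))  # 0-based
  hap <- rep_len(c(1L, 2L), n)
  rev_strand <- runif(n) < 0.5
  mult <- .hotspotMultiplier(spec, diploid$hotspots)
  hapchars <- list(strsplit(diploid$hap1, "")[[1L]],
                   strsplit(diploid$hap2, "")[[1L]])
  baseidx <- c(A = 1L, C = 2L, G = 3L, T = 4L)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- lens[i]; st <- starts[i]
    src <- hapchars[[hap[i]]][(st + 1L):(st + len)]
    mloc <- mult[(st + 1L):(st + len)]
    pm <- pmin(0.45, spec$mismatch_rate * mloc)
    pd <- pmin(0.25, spec$del_rate * mloc)
    pi_ <- pmin(0.25, spec$ins_rate * mloc)
    r <- runif(len)
    mm <- r < pm
    del <- !mm & r < pm + pd
    ins <- !mm & !del & r < pm + pd + pi_
    nb <- src
    if (any(mm))
      nb[mm] <- .BASES[(baseidx[src[mm]] + sample.int(3L, sum(mm),
                        replace = TRUE) - 1L) %% 4L + 1L]
    q <- pmax(15L, pmin(45L, round(rnorm(len, 30, 4))))
    q[mm] <- pmax(3L, pmin(15L, round(rnorm(sum(mm), 10, 3))))
    n_ins <- sum(ins)
    ins_b <- if (n_ins) sample(.BASES, n_ins, replace = TRUE) else character()
    ins_q <- if (n_ins) pmax(3L, pmin(15L, round(rnorm(n_ins, 10, 3)))) else integer()

    keep <- !del
    key_primary <- 2L * seq_len(len)
    bases <- c(nb[keep], ins_b)
    quals <- c(q[keep], ins_q)
    keys <- c(key_primary[keep], key_primary[ins] + 1L)
    o <- order(keys)
    seqc <- paste(bases[o], collapse = "")
    qualc <- .intToPhred(quals[o])

    ops <- c(ifelse(del, "D", "M"), rep("I", n_ins))
    okeys <- c(key_primary, key_primary[ins] + 1L)
    oo <- order(okeys)
    rl <- rle(ops[oo])
    # SAM alignments cannot begin or end with a deletion
    st0 <- st
    while (length(rl$values) && rl$values[1L] == "D") {
      st0 <- st0 + rl$lengths[1L]
      rl$values <- rl$values[-1L]; rl$lengths <- rl$lengths[-1L]
    }
    while (length(rl$values) && rl$values[length(rl$values)] == "D") {
      rl$values <- rl$values[-length(rl$values)]
      rl$lengths <- rl$lengths[-length(rl$lengths)]
    }
    cigar <- paste0(rl$lengths, rl$values, collapse = "")
    ref_span <- sum(rl$lengths[rl$values %in% c("M", "D")])
    out[[i]] <- list(name = sprintf("read_%05d", i),
                     flag = if (rev_strand[i]) .FLAG_REVERSE else 0L,
                     chrom = spec$chrom, start = st0, mapq = 60L,
                     cigar = cigar, seq = seqc, qual = qualc,
                     hp_truth = paste0("HP", hap[i]), ref_span = ref_span)
  }
  df <- rbindlist(out)
  ReadSet(as.data.frame(df), setNames(L, spec$chrom))
}

#' Simulate per-read methylation call records
#'
#' For every CpG of the reference covered by a read, the true methylation
#' state is Bernoulli with the probability of the read's haplotype at that
#' position (`dmr_spec` regions differ between haplotypes; elsewhere
#' `background_p_meth` applies to both). The emitted log-likelihood ratio
#' is `llr_scale * (+1/-1) + N(0, llr_noise_sd)`. CpGs on the same read
#' closer than 11 bp are emitted as one grouped record sharing the group's
#' mean LLR, mimicking the grouped scoring of HMM-based callers.
#'
#' @param spec a [simulationSpec()].
#' @param diploid result of [simulateDiploid()].
#' @param readset result of [simulateReads()].
#' @return list with `calls` (a [MethylCallSet]), `truth` (data.frame of
#'   per-read per-CpG true states) and `cpg_pos` (0-based reference CpG
#'   positions).
#' @export
simulateMethylationCalls <- function(spec, diploid, readset) {
  set.seed(.childSeed(spec$seed, "meth"))
  cpg <- .substringOffsets0(diploid$reference, "CG")[[1L]]
  p1 <- rep(spec$background_p_meth, length(cpg))
  p2 <- p1
  if (nrow(spec$dmr_spec)) {
    for (i in seq_len(nrow(spec$dmr_spec))) {
      inr <- cpg >= spec$dmr_spec$start[i] & cpg < spec$dmr_spec$end[i]
      p1[inr] <- spec$dmr_spec$p_meth_hp1[i]
      p2[inr] <- spec$dmr_spec$p_meth_hp2[i]
    }
  }
  rd <- reads(readset)
  if (!"ref_span" %in% names(rd))
    rd$ref_span <- .refSpan(rd$cigar)
  hapnum <- if ("hp_truth" %in% names(rd)) match(rd$hp_truth, c("HP1", "HP2"))
            else rep_len(c(1L, 2L), nrow(rd))

  per_read <- vector("list", nrow(rd))
  for (i in seq_len(nrow(rd))) {
    lo <- rd$start[i]; hi <- rd$start[i] + rd$ref_span[i] - 2L
    j <- which(cpg >= lo & cpg <= hi)
    if (!length(j)) next
    p <- if (hapnum[i] == 1L) p1[j] else p2[j]
    st <- rbinom(length(j), 1L, p)
    llr <- spec$llr_scale * (2 * st - 1) + rnorm(length(j), 0, spec$llr_noise_sd)
    per_read[[i]] <- data.table(read = i, pos = cpg[j], state = st,
                                llr = llr)
  }
  big <- rbindlist(per_read)
  .assert(nrow(big) > 0, "no CpGs covered by any read")
  newgrp <- c(TRUE, diff(big$read) != 0L | diff(big$pos) >= 11L)
  big[, grp := cumsum(newgrp)]
  grp <- big[, .(read = read[1L], start = pos[1L], end = pos[.N],
                 num_motifs = .N, llr = mean(llr)), by = grp]
  L <- spec$genome_length
  ctx_start <- pmax(0L, grp$start - 5L)
  ctx_end <- pmin(L, grp$end + 7L)  # 0-based half-open
  ctx <- substring(diploid$reference, ctx_start + 1L, ctx_end)
  bad <- which(.countSubstring(ctx, "CG") != grp$num_motifs)
  if (length(bad))  # fall back to the minimal exact context
    ctx[bad] <- substring(diploid$reference, grp$start[bad] + 1L,
                          grp$end[bad] + 2L)
  calls <- data.frame(chrom = spec$chrom, strand = "+",
                      start = grp$start, end = grp$end,
                      read_name = rd$name[grp$read],
                      log_lik_ratio = grp$llr,
                      log_lik_methylated = grp$llr / 2,
                      log_lik_unmethylated = -grp$llr / 2,
                      num_calling_strands = 1L,
                      num_motifs = grp$num_motifs, sequence = ctx,
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_name = rd$name[big$read], pos = big$pos,
                      state = big$state, stringsAsFactors = FALSE)
  list(calls = new("MethylCallSet", calls = calls), truth = truth,
       cpg_pos = cpg)
}

#' Simulate a candidate SNV call set with hotspot-driven false positives
#'
#' All truth SNVs appear as candidates with call qualities from a high
#' distribution; additional false candidates are planted inside the
#' clustered-error hotspot windows with qualities from a lower but
#' overlapping distribution, so that raw quality alone is an imperfect
#' discriminator the refinement stage can improve on.
#'
#' @param spec a [simulationSpec()].
#' @param diploid result of [simulateDiploid()].
#' @param fp_per_hotspot false candidates planted per hotspot window.
#' @param qual_true,qual_false `c(mean, sd)` of the (clipped to `[1, 999]`)
#'   quality distributions.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, `qual`,
#'   `is_true`.
#' @export
simulateCandidateVcf <- function(spec, diploid, fp_per_hotspot = 4L,
                                 qual_true = c(650, 120),
                                 qual_false = c(480, 120)) {
  set.seed(.childSeed(spec$seed, "candidates"))
  tv <- variants(diploid$variants)
  refchars <- strsplit(diploid$reference, "")[[1L]]
  baseidx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  hs <- diploid$hotspots
  fp_pos <- integer()
  if (nrow(hs) && fp_per_hotspot > 0L) {
    fp_pos <- unlist(lapply(seq_len(nrow(hs)), function(i) {
      w <- hs$start[i]:(hs$end[i] - 1L)
      sample(w, min(fp_per_hotspot, length(w)))
    }))
    fp_pos <- setdiff(unique(fp_pos), tv$pos)
  }
  fp_ref <- refchars[fp_pos + 1L]
  fp_alt <- .BASES[(baseidx[fp_ref] + sample.int(3L, length(fp_pos),
                    replace = TRUE) - 1L) %% 4L + 1L]
  qt <- pmax(1, pmin(999, rnorm(nrow(tv), qual_true[1L], qual_true[2L])))
  qf <- pmax(1, pmin(999, rnorm(length(fp_pos), qual_false[1L],
                                qual_false[2L])))
  df <- rbind(
    data.frame(chrom = rep(spec$chrom, nrow(tv)), pos = tv$pos,
               ref = tv$ref_allele, alt = tv$alt_allele, qual = qt,
               is_true = rep(TRUE, nrow(tv)), stringsAsFactors = FALSE),
    data.frame(chrom = rep(spec$chrom, length(fp_pos)), pos = fp_pos,
               ref = fp_ref, alt = fp_alt, qual = qf,
               is_true = rep(FALSE, length(fp_pos)),
               stringsAsFactors = FALSE))
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate per-CpG haplotype count tables
#'
#' Site-level generator for the differential-methylation stage: per-CpG
#' coverage and methylated counts for the two haplotypes, with optional
#' planted DMRs. Outside DMRs both haplotypes share a per-site methylation
#' proportion drawn uniformly from `[0.25, 0.75]`; coverage is Poisson with
#' a floor of 5 calls per haplotype (sites below that would be discarded by
#' a coverage filter in practice).
#'
#' @param n_sites number of CpG sites.
#' @param mean_spacing_bp mean CpG spacing (geometric) outside planted
#'   DMRs.
#' @param dmr_spacing_bp mean CpG spacing inside planted DMRs (default 12:
#'   imprinting control regions are CpG islands, markedly denser than the
#'   genomic background).
#' @param coverage mean per-haplotype call coverage.
#' @param dmrs data.frame with columns `first_site`, `last_site` (1-based
#'   site indices, inclusive), `p1`, `p2`; `NULL` for a fully null genome.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list with `counts` (data.frame `chrom`, `pos`, `n1`, `x1`, `n2`,
#'   `x2`) and `truth` (data.frame of planted DMR site/bp bounds).
#' @export
simulateHaplotypeCounts <- function(n_sites, mean_spacing_bp = 25,
                                    dmr_spacing_bp = 12, coverage = 15,
                                    dmrs = NULL, seed, chrom = "chr1") {
  set.seed(.childSeed(seed, "sitecounts"))
  spacing_mean <- rep(mean_spacing_bp, n_sites)
  if (!is.null(dmrs) && nrow(dmrs))
    for (i in seq_len(nrow(dmrs)))
      spacing_mean[dmrs$first_site[i]:dmrs$last_site[i]] <- dmr_spacing_bp
  pos <- cumsum(2L + stats::rgeom(n_sites, 1 / (spacing_mean - 1)))
  p1 <- p2 <- runif(n_sites, 0.25, 0.75)
  truth <- data.frame(first_site = integer(), last_site = integer(),
                      start = integer(), end = integer(), p1 = numeric(),
                      p2 = numeric())
  if (!is.null(dmrs) && nrow(dmrs)) {
    for (i in seq_len(nrow(dmrs))) {
      j <- dmrs$first_site[i]:dmrs$last_site[i]
      p1[j] <- dmrs$p1[i]
      p2[j] <- dmrs$p2[i]
    }
    truth <- data.frame(first_site = dmrs$first_site,
                        last_site = dmrs$last_site,
                        start = pos[dmrs$first_site],
                        end = pos[dmrs$last_site] + 1L,
                        p1 = dmrs$p1, p2 = dmrs$p2)
  }
  n1 <- pmax(5L, rpois(n_sites, coverage))
  n2 <- pmax(5L, rpois(n_sites, coverage))
  counts <- data.frame(chrom = chrom, pos = pos,
                       n1 = n1, x1 = rbinom(n_sites, n1, p1),
                       n2 = n2, x2 = rbinom(n_sites, n2, p2),
                       stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Convenience wrapper running [simulateDiploid()], [simulateReads()],
#' [simulateMethylationCalls()] and [simulateCandidateVcf()] under one
#' spec. With `outdir` set, writes `reference.fa`, `truth.vcf` (phased),
#' `candidates.vcf`, `reads.bam` (sorted + indexed), `methcalls.tsv` and
#' `truth_labels.tsv`.
#'
#' @param spec a [simulationSpec()].
#' @param outdir optional output directory.
#' @param components character subset of
#'   `c("reads", "methylation", "candidates")` to generate beyond the
#'   diploid genome.
#' @return list with `diploid`, `reads`, `methylation`, `candidates` (those
#'   requested), and `paths` when `outdir` is given.
#' @export
simulateDataset <- function(spec, outdir = NULL,
                            components = c("reads", "methylation",
                                           "candidates")) {
  dip <- simulateDiploid(spec)
  out <- list(diploid = dip)
  if ("reads" %in% components)
    out$reads <- simulateReads(spec, dip)
  if ("methylation" %in% components) {
    .assert(!is.null(out$reads), "methylation requires reads")
    out$methylation <- simulateMethylationCalls(spec, dip, out$reads)
  }
  if ("candidates" %in% components)
    out$candidates <- simulateCandidateVcf(spec, dip)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    fa <- DNAStringSet(setNames(dip$reference, spec$chrom))
    paths$reference <- file.path(outdir, "reference.fa")
    writeXStringSet(fa, paths$reference)
    paths$truth_vcf <- file.path(outdir, "truth.vcf")
    writePhasedVcf(dip$variants, paths$truth_vcf, sample = "SIM",
                   contigs = setNames(spec$genome_length, spec$chrom))
    if (!is.null(out$reads)) {
      paths$bam <- file.path(outdir, "reads.bam")
      writeBam(out$reads, paths$bam)
    }
    if (!is.null(out$methylation)) {
      paths$methcalls <- file.path(outdir, "methcalls.tsv")
      writeMethylCalls(out$methylation$calls, paths$methcalls)
    }
    if (!is.null(out$candidates)) {
      cd <- out$candidates
      paths$candidates <- file.path(outdir, "candidates.vcf")
      .writeSimpleVcf(data.frame(chrom = cd$chrom, pos = cd$pos,
                                 ref = cd$ref, alt = cd$alt, qual = cd$qual,
                                 gt = "0/1"),
                      paths$candidates, sample = "SIM",
                      contigs = setNames(spec$genome_length, spec$chrom))
      paths$truth_labels <- file.path(outdir, "truth_labels.tsv")
      fwrite(as.data.table(cd), paths$truth_labels, sep = "\t")
    }
    out$paths <- paths
  }
  out
}
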