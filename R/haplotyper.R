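## Read haplotagging from phased heterozygous SNVs, and everything that
## follows a haplotype decision: per-haplotype methylation call splitting,
## per-CpG frequency tables, trio mock phasing, regional concordance.

#' Phasing configuration
#'
#' Filters a read must pass to be assigned to a haplotype. A base at a
#' phased SNV counts only if its quality is at least `min_base_quality`
#' (default 7; below that, residual false-positive SNVs and sequencing
#' errors dominate). The winning haplotype must hold at least
#' `haplotype_ratio` (default 0.75, inclusive) of the counted observations,
#' and both the winner count and the total must reach `min_snvs`
#' (default 2; both interpretations of the minimum are enforced, which is
#' the stricter reading). Duplicated, QC-failed, unmapped and secondary
#' reads are always ignored; supplementary alignments are ignored unless
#' `include_supplementary`; `min_mapq` (default 20) guards against
#' ambiguous mappings.
#'
#' @param min_base_quality minimum Phred base quality at a phased SNV.
#' @param haplotype_ratio minimum winner fraction, in (0.5, 1].
#' @param min_snvs minimum number of counted phased SNVs.
#' @param min_mapq minimum mapping quality.
#' @param include_supplementary include supplementary alignments.
#' @return A validated list of class `haploMethPhaseConfig`.
#' @export
phaseConfig <- function(min_base_quality = 7L, haplotype_ratio = 0.75,
                        min_snvs = 2L, min_mapq = 20L,
                        include_supplementary = FALSE) {
  .assert(haplotype_ratio > 0.5 && haplotype_ratio <= 1,
          "haplotype_ratio must be in (0.5, 1]")
  .assert(min_snvs >= 1L, "min_snvs must be >= 1")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 haplotype_ratio = haplotype_ratio,
                 min_snvs = as.integer(min_snvs),
                 min_mapq = as.integer(min_mapq),
                 include_supplementary = isTRUE(include_supplementary)),
            class = "haploMethPhaseConfig")
}

## Does this read pass the flag/mapq filters?
#' @noRd
.readPassesFilters <- function(flag, mapq, cfg) {
  !.flagBit(flag, .FLAG_UNMAPPED) & !.flagBit(flag, .FLAG_SECONDARY) &
    !.flagBit(flag, .FLAG_DUP) & !.flagBit(flag, .FLAG_QCFAIL) &
    (cfg$include_supplementary | !.flagBit(flag, .FLAG_SUPPL)) &
    !is.na(mapq) & mapq >= cfg$min_mapq
}

#' Collect a read's observations at phased SNVs
#'
#' Walks the read's CIGAR to find the base (and its quality) aligned to
#' each phased SNV position the read spans. Positions under a deletion
#' yield `supports = "neither"`; bases matching neither haplotype allele
#' also count as `"neither"`. Observations below the base-quality cutoff
#' are kept but marked `filtered` and excluded from haplotype counting.
#'
#' @param read single-row data.frame (one row of [reads()]).
#' @param variants data.frame of phased variants on the read's chromosome
#'   (see [variants()]), sorted by `pos`.
#' @param cfg a [phaseConfig()].
#' @return data.frame with columns `pos`, `read_base`, `base_quality`,
#'   `supports` (`"HP1"`, `"HP2"`, `"neither"`), `filtered`.
#' @export
collectReadSnvObservations <- function(read, variants, cfg = phaseConfig()) {
  span <- .refSpan(read$cigar)
  v <- variants[variants$pos >= read$start &
                variants$pos < read$start + span, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(pos = integer(), read_base = character(),
                      base_quality = integer(), supports = character(),
                      filtered = logical(), stringsAsFactors = FALSE))
  qi <- .queryIndexAtRef(read$cigar, read$start, v$pos)
  base <- rep("-", nrow(v))
  bq <- rep(NA_integer_, nrow(v))
  hit <- !is.na(qi$idx)
  if (any(hit)) {
    base[hit] <- substring(read$seq, qi$idx[hit], qi$idx[hit])
    bq[hit] <- .phredToInt(read$qual)[qi$idx[hit]]
  }
  supports <- ifelse(base == v$hp1_allele, "HP1",
                     ifelse(base == v$hp2_allele, "HP2", "neither"))
  data.frame(pos = v$pos, read_base = base, base_quality = bq,
             supports = supports,
             filtered = is.na(bq) | bq < cfg$min_base_quality,
             stringsAsFactors = FALSE)
}

#' Assign a read to a haplotype from its SNV observations
#'
#' Counts quality-passing HP1/HP2 supports (`c1`, `c2`); the winner `W` is
#' assigned iff `c1 + c2 >= min_snvs`, `c_W >= min_snvs` and
#' `c_W / (c1 + c2) >= haplotype_ratio` (inclusive). Ties are unassigned.
#'
#' @param observations result of [collectReadSnvObservations()].
#' @param cfg a [phaseConfig()].
#' @return list with `haplotype` (`"HP1"`, `"HP2"`, `"unassigned"`),
#'   `c_hp1`, `c_hp2`, `ratio`.
#' @export
assignHaplotype <- function(observations, cfg = phaseConfig()) {
  keep <- !observations$filtered
  c1 <- sum(observations$supports[keep] == "HP1")
  c2 <- sum(observations$supports[keep] == "HP2")
  tot <- c1 + c2
  ratio <- if (tot > 0L) max(c1, c2) / tot else NA_real_
  hap <- "unassigned"
  if (tot >= cfg$min_snvs && c1 != c2) {
    w <- if (c1 > c2) c1 else c2
    if (w >= cfg$min_snvs && w / tot >= cfg$haplotype_ratio)
      hap <- if (c1 > c2) "HP1" else "HP2"
  }
  list(haplotype = hap, c_hp1 = c1, c_hp2 = c2, ratio = ratio)
}

#' Phase reads and their CpG methylation calls
#'
#' The central step of the workflow: every read lands in exactly one of
#' five bins — `flag_filtered` (unmapped/secondary/duplicate/QC-fail/
#' supplementary/low MAPQ), `no_snv` (no phased SNV observed), `unassigned`
#' (observed SNVs but failed the [phaseConfig()] criteria), `HP1` or `HP2`.
#' Each phased read's CpG calls are copied to its haplotype's call set.
#'
#' @param readset a [ReadSet] (or path to a BAM/SAM).
#' @param phased a [PhasedVariantSet] (or path to a phased VCF).
#' @param cpg_store optional [CpGCallSet] whose calls follow the reads.
#' @param cfg a [phaseConfig()].
#' @return list with `assignments` (per-read data.frame: `name`, `bin`,
#'   `c_hp1`, `c_hp2`, `ratio`), `counts` (named integer, the five bins),
#'   `reads_hp1`/`reads_hp2` ([ReadSet]s with a `haplotype` column), and —
#'   when `cpg_store` is given — `calls_hp1`/`calls_hp2` ([CpGCallSet]s).
#' @export
phaseReadsAndMethylation <- function(readset, phased, cpg_store = NULL,
                                     cfg = phaseConfig()) {
  if (is.character(readset)) readset <- readAlignments(readset)
  if (is.character(phased)) phased <- readPhasedVcf(phased)
  rd <- reads(readset)
  pv <- variants(phased)
  pv <- pv[order(pv$chrom, pv$pos), , drop = FALSE]

  n <- nrow(rd)
  bin <- character(n)
  c1v <- integer(n); c2v <- integer(n); ratio <- rep(NA_real_, n)
  pass <- .readPassesFilters(rd$flag, rd$mapq, cfg)
  bin[!pass] <- "flag_filtered"
  byChrom <- split(seq_len(nrow(pv)), pv$chrom)
  for (i in which(pass)) {
    vi <- byChrom[[rd$chrom[i]]]
    if (is.null(vi)) { bin[i] <- "no_snv"; next }
    obs <- collectReadSnvObservations(rd[i, ], pv[vi, ], cfg)
    if (!nrow(obs)) { bin[i] <- "no_snv"; next }
    a <- assignHaplotype(obs, cfg)
    c1v[i] <- a$c_hp1; c2v[i] <- a$c_hp2; ratio[i] <- a$ratio
    bin[i] <- if (a$haplotype == "unassigned") "unassigned" else a$haplotype
  }
  counts <- c(HP1 = sum(bin == "HP1"), HP2 = sum(bin == "HP2"),
              unassigned = sum(bin == "unassigned"),
              no_snv = sum(bin == "no_snv"),
              flag_filtered = sum(bin == "flag_filtered"))
  stopifnot(sum(counts) == n)  # partition invariant

  asg <- data.frame(name = rd$name, bin = bin, c_hp1 = c1v, c_hp2 = c2v,
                    ratio = ratio, stringsAsFactors = FALSE)
  mkSubset <- function(hp) {
    sub <- rd[bin == hp, , drop = FALSE]
    sub$haplotype <- rep(hp, nrow(sub))
    ReadSet(sub, seqLengths(readset))
  }
  out <- list(assignments = asg, counts = counts,
              reads_hp1 = mkSubset("HP1"), reads_hp2 = mkSubset("HP2"))
  if (!is.null(cpg_store)) {
    thr <- callThreshold(cpg_store)
    out$calls_hp1 <- new("CpGCallSet",
                         calls = callsByRead(cpg_store,
                                             asg$name[bin == "HP1"]),
                         threshold = thr)
    out$calls_hp2 <- new("CpGCallSet",
                         calls = callsByRead(cpg_store,
                                             asg$name[bin == "HP2"]),
                         threshold = thr)
  }
  out
}

#' Per-CpG methylation frequency
#'
#' Aggregates per-read CpG calls to one record per forward-strand CpG
#' position: `n_all_calls` counts methylated plus unmethylated calls
#' (uncalled are excluded), `n_mod_calls` the methylated ones, and
#' `meth_freq` their ratio. Sites with only uncalled evidence emit no
#' record.
#'
#' @param x a [CpGCallSet] (typically one haplotype's calls).
#' @return data.frame sorted by (chrom, start) with columns `chrom`,
#'   `start`, `end`, `strand`, `n_all_calls`, `n_mod_calls`, `meth_freq`,
#'   ready for [writeMethylFrequency()].
#' @export
computeMethylationFrequency <- function(x) {
  df <- as.data.table(cpgCalls(x))
  df <- df[state != "uncalled"]
  if (!nrow(df))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_all_calls = integer(), n_mod_calls = integer(),
                      meth_freq = numeric(), stringsAsFactors = FALSE))
  agg <- df[, .(n_all_calls = .N,
                n_mod_calls = sum(state == "methylated")),
            by = .(chrom, pos)]
  setorder(agg, chrom, pos)
  data.frame(chrom = agg$chrom, start = agg$pos, end = agg$pos + 1L,
             strand = "+", n_all_calls = agg$n_all_calls,
             n_mod_calls = agg$n_mod_calls,
             meth_freq = agg$n_mod_calls / agg$n_all_calls,
             stringsAsFactors = FALSE)
}

#' Mock-phase a child's heterozygous SNVs from parental genotypes
#'
#' For each child heterozygous site, an allele is called paternal iff the
#' father carries it and the mother does not (and symmetrically maternal);
#' when both alleles are informative the two decisions must agree. Sites
#' where parents are uninformative (e.g. all three genotypes identical)
#' stay unphased, and sites where a child allele is absent from both
#' parents are counted as Mendelian violations and stay unphased.
#' Haplotype 1 of the output is paternal, haplotype 2 maternal.
#'
#' @param child,father,mother data.frames as returned by
#'   [readGenotypeVcf()] (columns `chrom`, `pos`, `ref`, `alt`, `allele1`,
#'   `allele2`), or paths to VCFs.
#' @return list with `phased` (a [PhasedVariantSet], HP1 = paternal) and
#'   `counts` (named integer: `phased`, `uninformative`,
#'   `mendelian_violation`, `child_hom`).
#' @export
trioMockPhase <- function(child, father, mother) {
  if (is.character(child)) child <- readGenotypeVcf(child)
  if (is.character(father)) father <- readGenotypeVcf(father)
  if (is.character(mother)) mother <- readGenotypeVcf(mother)
  key <- function(d) paste(d$chrom, d$pos)
  fa <- father[match(key(child), key(father)), , drop = FALSE]
  mo <- mother[match(key(child), key(mother)), , drop = FALSE]

  het <- child$allele1 != child$allele2
  counts <- c(phased = 0L, uninformative = 0L, mendelian_violation = 0L,
              child_hom = sum(!het))
  res <- vector("list", nrow(child))
  for (i in which(het)) {
    a <- child$allele1[i]; b <- child$allele2[i]
    fset <- c(fa$allele1[i], fa$allele2[i])
    mset <- c(mo$allele1[i], mo$allele2[i])
    if (anyNA(fset) || anyNA(mset)) { counts["uninformative"] <- counts["uninformative"] + 1L; next }
    if (!(a %in% fset || a %in% mset) || !(b %in% fset || b %in% mset)) {
      counts["mendelian_violation"] <- counts["mendelian_violation"] + 1L
      next
    }
    pat_a <- a %in% fset && !(a %in% mset)
    pat_b <- b %in% fset && !(b %in% mset)
    mat_a <- a %in% mset && !(a %in% fset)
    mat_b <- b %in% mset && !(b %in% fset)
    paternal <- NA_character_
    if ((pat_a && mat_b) || (pat_a && !pat_b && !mat_a)) paternal <- a
    else if ((pat_b && mat_a) || (pat_b && !pat_a && !mat_b)) paternal <- b
    else if (mat_a && !mat_b && !pat_a) paternal <- b
    else if (mat_b && !mat_a && !pat_b) paternal <- a
    if (is.na(paternal)) { counts["uninformative"] <- counts["uninformative"] + 1L; next }
    maternal <- if (paternal == a) b else a
    counts["phased"] <- counts["phased"] + 1L
    res[[i]] <- data.frame(chrom = child$chrom[i], pos = child$pos[i],
                           ref_allele = child$ref[i],
                           alt_allele = child$alt[i],
                           hp1_allele = paternal, hp2_allele = maternal,
                           qual = child$qual[i], phase_set = "trio",
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(df))
    df <- data.frame(chrom = character(), pos = integer(),
                     ref_allele = character(), alt_allele = character(),
                     hp1_allele = character(), hp2_allele = character(),
                     qual = numeric(), phase_set = character(),
                     stringsAsFactors = FALSE)
  list(phased = new("PhasedVariantSet", variants = df,
                    skipped = c(hom = counts[["child_hom"]], unphased = 0L,
                                indel = 0L, multiallelic = 0L,
                                missing = 0L)),
       counts = counts)
}

#' Regional concordance between two read phasings
#'
#' Bins reads by start position; within each bin with at least `min_reads`
#' reads assigned in both phasings, determines the majority mapping of
#' A-haplotype labels onto B-haplotype labels; reads contradicting that
#' mapping are discordant. A global (or per-region) label swap between the
#' phasings is therefore absorbed.
#'
#' @param phasing_a,phasing_b data.frames with columns `name`, `chrom`,
#'   `start`, `haplotype` (`"HP1"`/`"HP2"`; other values ignored).
#' @param bin_size bin width in bp (default 10 kb).
#' @param min_reads minimum common phased reads per bin (default 3, i.e.
#'   regions with more than two phased reads are kept).
#' @return list with `examined`, `discordant`, `fraction`, `n_bins`.
#' @export
evaluateRegionalConcordance <- function(phasing_a, phasing_b,
                                        bin_size = 10000L, min_reads = 3L) {
  a <- phasing_a[phasing_a$haplotype %in% c("HP1", "HP2"), ]
  b <- phasing_b[phasing_b$haplotype %in% c("HP1", "HP2"), ]
  m <- match(a$name, b$name)
  keep <- !is.na(m)
  dt <- data.table(chrom = a$chrom[keep],
                   bin = a$start[keep] %/% bin_size,
                   ha = a$haplotype[keep], hb = b$haplotype[m[keep]])
  if (!nrow(dt))
    return(list(examined = 0L, discordant = 0L, fraction = NA_real_,
                n_bins = 0L))
  per <- dt[, {
    same <- sum(ha == hb); cross <- .N - same
    .(n = .N, disc = min(same, cross))
  }, by = .(chrom, bin)]
  per <- per[per$n >= min_reads]
  examined <- sum(per$n)
  discordant <- sum(per$disc)
  list(examined = examined, discordant = discordant,
       fraction = if (examined) discordant / examined else NA_real_,
       n_bins = nrow(per))
}
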