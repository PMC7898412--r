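mkVariants <- function(pos, hp1, hp2, ref = hp1, alt = hp2) {
  data.frame(chrom = "chr1", pos = pos, ref_allele = ref, alt_allele = alt,
             hp1_allele = hp1, hp2_allele = hp2, qual = 100,
             phase_set = "1", stringsAsFactors = FALSE)
}

test_that("SNV observations follow a manual CIGAR walk", {
  # read spans ref [10, 22) with a deletion at [15, 17): CIGAR 5M2D5M
  ref_seq <- "AAAAACCTTTTT"  # what the read sees: AAAAA (del CC) TTTTT
  rd <- simpleRead("r1", 10, "AAAAATTTTT", cigar = "5M2D5M")
  v <- mkVariants(c(12L, 15L, 18L), hp1 = c("A", "C", "T"),
                  hp2 = c("G", "G", "G"))
  obs <- collectReadSnvObservations(rd, v)
  expect_equal(nrow(obs), 3L)
  # pos 12 aligned to read index 3 -> base A -> HP1
  expect_equal(obs$read_base[1], "A")
  expect_equal(obs$supports[1], "HP1")
  # pos 15 inside the deletion -> gap, supports neither
  expect_equal(obs$read_base[2], "-")
  expect_equal(obs$supports[2], "neither")
  # pos 18 aligned past the deletion: read index 5 + (18-17) + 1 = 7 -> T
  expect_equal(obs$read_base[3], "T")
  expect_equal(obs$supports[3], "HP1")
  # base quality threshold marks, not drops
  rd_lowq <- rd; rd_lowq$qual <- strrep(rawToChar(as.raw(33 + 5)), 10)
  obs2 <- collectReadSnvObservations(rd_lowq, v)
  expect_true(all(obs2$filtered[c(1, 3)]))
})

test_that("haplotype assignment enforces ratio, min-SNV and tie rules", {
  mkObs <- function(supports, bq = 30) {
    data.frame(pos = seq_along(supports), read_base = "A",
               base_quality = bq, supports = supports,
               filtered = bq < 7, stringsAsFactors = FALSE)
  }
  # 2:1 -> ratio 0.667 < 0.75 -> unassigned
  expect_equal(assignHaplotype(mkObs(c("HP1", "HP1", "HP2")))$haplotype,
               "unassigned")
  # 3:1 -> ratio exactly 0.75 -> assigned (boundary inclusive)
  a <- assignHaplotype(mkObs(c("HP1", "HP1", "HP1", "HP2")))
  expect_equal(a$haplotype, "HP1")
  expect_equal(a$ratio, 0.75)
  # a single observation never assigns (min_snvs = 2)
  expect_equal(assignHaplotype(mkObs("HP1"))$haplotype, "unassigned")
  # ties are unassigned
  expect_equal(assignHaplotype(mkObs(c("HP1", "HP2")))$haplotype,
               "unassigned")
  # low-quality observations are not counted
  expect_equal(assignHaplotype(mkObs(rep("HP1", 5), bq = 3))$haplotype,
               "unassigned")
})

test_that("read bins partition the input and flag filters are honoured", {
  spec <- simulationSpec(genome_length = 50000L, read_coverage = 5,
                         seed = 330)
  sim <- simulateDataset(spec, components = "reads")
  rd <- reads(sim$reads)
  # plant pathological records: secondary, duplicate, unmapped, low MAPQ
  rd$flag[1] <- bitwOr(rd$flag[1], 0x100L)
  rd$flag[2] <- bitwOr(rd$flag[2], 0x400L)
  rd$flag[3] <- bitwOr(rd$flag[3], 0x4L)
  rd$mapq[4] <- 5L
  rs <- ReadSet(rd, seqLengths(sim$reads))
  res <- phaseReadsAndMethylation(rs, sim$diploid$variants)
  expect_equal(sum(res$counts), nrow(rd))
  expect_gte(res$counts[["flag_filtered"]], 4L)
  expect_equal(res$assignments$bin[1:4],
               rep("flag_filtered", 4))
  # HP1 and HP2 sets are disjoint
  expect_length(intersect(reads(res$reads_hp1)$name,
                          reads(res$reads_hp2)$name), 0L)
})

test_that("a dataset with zero phased variants puts every read in no-SNV", {
  spec <- simulationSpec(genome_length = 30000L, read_coverage = 4,
                         het_snv_rate = 0, seed = 331)
  sim <- simulateDataset(spec, components = "reads")
  res <- phaseReadsAndMethylation(sim$reads, sim$diploid$variants)
  expect_equal(res$counts[["no_snv"]], length(sim$reads))
})

test_that("noise-free phasing recovers every eligible read for any seed", {
  for (s in c(332, 333, 334)) {
    spec <- simulationSpec(genome_length = 100000L, read_coverage = 6,
                           mismatch_rate = 0, ins_rate = 0, del_rate = 0,
                           seed = s)
    sim <- simulateDataset(spec, components = "reads")
    res <- phaseReadsAndMethylation(sim$reads, sim$diploid$variants)
    asg <- res$assignments
    truth <- reads(sim$reads)$hp_truth
    assigned <- asg$bin %in% c("HP1", "HP2")
    expect_true(all(asg$bin[assigned] == truth[assigned]))
    # every read observing >= 2 SNVs is assigned
    expect_true(all(asg$bin[asg$c_hp1 + asg$c_hp2 >= 2] %in%
                    c("HP1", "HP2")))
  }
})

test_that("label swap symmetry holds exactly", {
  spec <- simulationSpec(genome_length = 50000L, read_coverage = 6,
                         seed = 335)
  sim <- simulateDataset(spec, components = c("reads", "methylation"))
  store <- processMethylationFile(sim$methylation$calls)
  v <- variants(sim$diploid$variants)
  vswap <- v
  vswap$hp1_allele <- v$hp2_allele
  vswap$hp2_allele <- v$hp1_allele
  pvswap <- new("PhasedVariantSet", variants = vswap,
                skipped = skippedCounts(sim$diploid$variants))
  r1 <- phaseReadsAndMethylation(sim$reads, sim$diploid$variants, store)
  r2 <- phaseReadsAndMethylation(sim$reads, pvswap, store)
  swap <- c(HP1 = "HP2", HP2 = "HP1", unassigned = "unassigned",
            no_snv = "no_snv", flag_filtered = "flag_filtered")
  expect_equal(unname(swap[r1$assignments$bin]), r2$assignments$bin)
  expect_equal(r1$counts[["HP1"]], r2$counts[["HP2"]])

  # |freq_HP1 - freq_HP2| per site is unchanged under the swap
  f <- function(res) {
    a <- computeMethylationFrequency(res$calls_hp1)
    b <- computeMethylationFrequency(res$calls_hp2)
    m <- merge(a[, c("start", "meth_freq")], b[, c("start", "meth_freq")],
               by = "start")
    m[order(m$start), ]
  }
  m1 <- f(r1); m2 <- f(r2)
  expect_equal(m1$start, m2$start)
  expect_equal(abs(m1$meth_freq.x - m1$meth_freq.y),
               abs(m2$meth_freq.x - m2$meth_freq.y))
})

test_that("methylation frequency counts calls and excludes uncalled", {
  calls <- data.frame(
    chrom = "chr1", pos = 100L,
    read_name = paste0("r", 1:8),
    log_lik_ratio = c(5, 5, 5, 5, 5, -5, -5, 0.5),
    state = c(rep("methylated", 5), rep("unmethylated", 2), "uncalled"),
    stringsAsFactors = FALSE)
  cs <- new("CpGCallSet", calls = calls, threshold = 2)
  fr <- computeMethylationFrequency(cs)
  expect_equal(fr$n_all_calls, 7L)
  expect_equal(fr$n_mod_calls, 5L)
  expect_equal(fr$meth_freq, 5 / 7)
  # a site with only uncalled evidence emits nothing
  cs2 <- new("CpGCallSet", calls = transform(calls, state = "uncalled"),
             threshold = 2)
  expect_equal(nrow(computeMethylationFrequency(cs2)), 0L)
})

test_that("a planted imprinted region shows the planted frequency difference", {
  dmr <- data.frame(start = 5000L, end = 15000L, p_meth_hp1 = 0.9,
                    p_meth_hp2 = 0.1)
  spec <- simulationSpec(genome_length = 30000L, read_coverage = 20,
                         dmr_spec = dmr, seed = 336)
  sim <- simulateDataset(spec, components = c("reads", "methylation"))
  # permissive call threshold: grouped records averaged over mixed states
  # would otherwise be dropped as uncalled, biasing frequencies outward
  store <- processMethylationFile(sim$methylation$calls, threshold = 0.5)
  res <- phaseReadsAndMethylation(sim$reads, sim$diploid$variants, store)
  a <- computeMethylationFrequency(res$calls_hp1)
  b <- computeMethylationFrequency(res$calls_hp2)
  m <- merge(a, b, by = "start")
  m <- m[m$start >= 5000 & m$start < 15000, ]
  expect_gt(nrow(m), 50)
  expect_lt(abs(mean(m$meth_freq.x - m$meth_freq.y) - 0.8), 0.1)
  # per-haplotype calls at a site never exceed the unphased total
  tot <- table(cpgCalls(store)$pos)
  ca <- table(cpgCalls(res$calls_hp1)$pos)
  expect_true(all(ca <= tot[names(ca)]))
})

test_that("trio mock phasing applies Mendelian logic and counts violations", {
  gdf <- function(a1, a2) data.frame(
    chrom = "chr1", pos = 10L, ref = "A", alt = "G", qual = 50,
    allele1 = a1, allele2 = a2, phased = FALSE, stringsAsFactors = FALSE)
  # father A/A, mother G/G -> paternal A, maternal G
  r <- trioMockPhase(gdf("A", "G"), gdf("A", "A"), gdf("G", "G"))
  expect_equal(variants(r$phased)$hp1_allele, "A")
  expect_equal(variants(r$phased)$hp2_allele, "G")
  # all three heterozygous -> uninformative
  r2 <- trioMockPhase(gdf("A", "G"), gdf("A", "G"), gdf("A", "G"))
  expect_equal(length(r2$phased), 0L)
  expect_equal(r2$counts[["uninformative"]], 1L)
  # child allele absent from both parents -> violation counter
  r3 <- trioMockPhase(gdf("A", "G"), gdf("G", "G"), gdf("G", "G"))
  expect_equal(length(r3$phased), 0L)
  expect_equal(r3$counts[["mendelian_violation"]], 1L)
  # child homozygous sites are not phased
  r4 <- trioMockPhase(gdf("A", "A"), gdf("A", "A"), gdf("A", "G"))
  expect_equal(r4$counts[["child_hom"]], 1L)
})

test_that("regional concordance absorbs label swaps and measures flips", {
  set.seed(42)
  n <- 6000
  pa <- data.frame(name = sprintf("r%d", 1:n), chrom = "chr1",
                   start = sort(sample(0:1499999, n)),
                   haplotype = sample(c("HP1", "HP2"), n, TRUE),
                   stringsAsFactors = FALSE)
  expect_equal(evaluateRegionalConcordance(pa, pa)$fraction, 0)
  pb <- pa
  pb$haplotype <- ifelse(pa$haplotype == "HP1", "HP2", "HP1")
  expect_equal(evaluateRegionalConcordance(pa, pb)$fraction, 0)
  flip <- runif(n) < 0.05
  pc <- pa
  pc$haplotype[flip] <- ifelse(pa$haplotype[flip] == "HP1", "HP2", "HP1")
  cc <- evaluateRegionalConcordance(pa, pc)
  # every flipped read (and only those) is detected as discordant ...
  expect_equal(cc$discordant, sum(flip))
  # ... and the measured fraction sits within a point of the planted rate
  expect_lt(abs(cc$fraction - 0.05), 0.01)
})
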