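test_that("every simulation stage is deterministic under its seed", {
  spec <- simulationSpec(genome_length = 20000L, read_coverage = 4,
                         seed = 350)
  a <- simulateDataset(spec)
  b <- simulateDataset(spec)
  expect_identical(a$diploid$reference, b$diploid$reference)
  expect_identical(variants(a$diploid$variants), variants(b$diploid$variants))
  expect_identical(reads(a$reads), reads(b$reads))
  expect_identical(methCalls(a$methylation$calls),
                   methCalls(b$methylation$calls))
  expect_identical(a$candidates, b$candidates)
})

test_that("heterozygous SNV placement follows the requested rate", {
  # rate 0 -> no variants
  s0 <- simulationSpec(genome_length = 20000L, het_snv_rate = 0, seed = 351)
  expect_equal(length(simulateDiploid(s0)$variants), 0L)
  # rate 1e-3 over 300 kb -> count within 3 sigma of 300
  s1 <- simulationSpec(genome_length = 300000L, het_snv_rate = 1e-3,
                       seed = 352)
  n <- length(simulateDiploid(s1)$variants)
  expect_lt(abs(n - 300), 3 * sqrt(300))
  # haplotype sequences differ from the reference exactly at the variants
  dip <- simulateDiploid(simulationSpec(genome_length = 5000L, seed = 353))
  v <- variants(dip$variants)
  rc <- strsplit(dip$reference, "")[[1]]
  h1 <- strsplit(dip$hap1, "")[[1]]
  h2 <- strsplit(dip$hap2, "")[[1]]
  expect_equal(which(h1 != rc | h2 != rc) - 1L, v$pos)
  expect_equal(h1[v$pos + 1L], v$hp1_allele)
  expect_equal(h2[v$pos + 1L], v$hp2_allele)
})

test_that("error-free reads are exact haplotype substrings at their position", {
  spec <- simulationSpec(genome_length = 30000L, read_coverage = 4,
                         mismatch_rate = 0, ins_rate = 0, del_rate = 0,
                         seed = 354)
  sim <- simulateDataset(spec, components = "reads")
  rd <- reads(sim$reads)
  hap <- list(HP1 = sim$diploid$hap1, HP2 = sim$diploid$hap2)
  for (i in seq_len(nrow(rd))) {
    src <- substring(hap[[rd$hp_truth[i]]], rd$start[i] + 1L,
                     rd$start[i] + nchar(rd$seq[i]))
    expect_identical(rd$seq[i], src)
    expect_equal(rd$cigar[i], paste0(nchar(rd$seq[i]), "M"))
  }
})

test_that("coverage lands near the requested depth", {
  spec <- simulationSpec(genome_length = 200000L, read_coverage = 10,
                         seed = 355)
  sim <- simulateDataset(spec, components = "reads")
  rd <- reads(sim$reads)
  depth <- sum(as.numeric(rd$ref_span)) / spec$genome_length
  expect_lt(abs(depth - 10) / 10, 0.1)
})

test_that("hotspots concentrate mismatches as configured", {
  spec <- simulationSpec(genome_length = 200000L, read_coverage = 15,
                         hotspot_rate = 1e-4, hotspot_error_multiplier = 6,
                         seed = 356)
  sim <- simulateDataset(spec, components = "reads")
  hs <- sim$diploid$hotspots
  expect_gt(nrow(hs), 5L)
  pu <- pileupStats(sim$reads, sim$diploid$reference)
  inh <- rep(FALSE, spec$genome_length)
  for (i in seq_len(nrow(hs))) inh[(hs$start[i] + 1L):hs$end[i]] <- TRUE
  # exclude het SNV positions (those mismatch by construction)
  snv <- variants(sim$diploid$variants)$pos
  use <- !(pu$pos %in% snv)
  mm_in <- sum(pu$n_mm[use & inh[pu$pos + 1L]]) /
           sum(pu$span[use & inh[pu$pos + 1L]])
  mm_out <- sum(pu$n_mm[use & !inh[pu$pos + 1L]]) /
            sum(pu$span[use & !inh[pu$pos + 1L]])
  expect_gt(mm_in, (spec$hotspot_error_multiplier / 2) * mm_out)
})

test_that("methylation records group CpGs closer than 11 bp", {
  spec <- simulationSpec(genome_length = 20000L, read_coverage = 3,
                         seed = 357)
  sim <- simulateDataset(spec, components = c("reads", "methylation"))
  mc <- methCalls(sim$methylation$calls)
  # scan oracle: recompute expected group count per read from CpG runs
  cpg <- sim$methylation$cpg_pos
  rd <- reads(sim$reads)
  expected <- 0L
  for (i in seq_len(nrow(rd))) {
    j <- cpg[cpg >= rd$start[i] & cpg <= rd$start[i] + rd$ref_span[i] - 2L]
    if (!length(j)) next
    expected <- expected + 1L + sum(diff(j) >= 11L)
  }
  expect_equal(nrow(mc), expected)
  # grouped records satisfy the format invariants (validity runs on new())
  expect_s4_class(sim$methylation$calls, "MethylCallSet")
})

test_that("a confident caller lets downstream classification recover states", {
  # uniform methylation (no mixed groups) and a large LLR scale
  spec <- simulationSpec(genome_length = 20000L, read_coverage = 4,
                         background_p_meth = 1, dmr_spec = data.frame(
                           start = integer(), end = integer(),
                           p_meth_hp1 = numeric(), p_meth_hp2 = numeric()),
                         llr_scale = 12, llr_noise_sd = 1, seed = 358)
  sim <- simulateDataset(spec, components = c("reads", "methylation"))
  cs <- processMethylationFile(sim$methylation$calls)
  expect_gt(mean(cpgCalls(cs)$state == "methylated"), 0.99)

  # fully imprinted region: frequencies 1 and 0 in the noise-free limit
  dmr <- data.frame(start = 0L, end = 20000L, p_meth_hp1 = 1,
                    p_meth_hp2 = 0)
  spec2 <- simulationSpec(genome_length = 20000L, read_coverage = 6,
                          mismatch_rate = 0, ins_rate = 0, del_rate = 0,
                          dmr_spec = dmr, llr_scale = 12, llr_noise_sd = 0.5,
                          seed = 359)
  sim2 <- simulateDataset(spec2, components = c("reads", "methylation"))
  store <- processMethylationFile(sim2$methylation$calls)
  res <- phaseReadsAndMethylation(sim2$reads, sim2$diploid$variants, store)
  f1 <- computeMethylationFrequency(res$calls_hp1)
  f2 <- computeMethylationFrequency(res$calls_hp2)
  expect_equal(mean(f1$meth_freq), 1)
  expect_equal(mean(f2$meth_freq), 0)
})

test_that("candidate simulation plants recoverable false positives", {
  # no hotspots -> candidates equal the truth set
  s0 <- simulationSpec(genome_length = 50000L, hotspot_rate = 0, seed = 360)
  d0 <- simulateDiploid(s0)
  c0 <- simulateCandidateVcf(s0, d0)
  expect_equal(c0$pos, variants(d0$variants)$pos)
  expect_true(all(c0$is_true))

  # planted false positives are exactly the non-truth labels
  s1 <- simulationSpec(genome_length = 200000L, hotspot_rate = 2e-4,
                       seed = 361)
  d1 <- simulateDiploid(s1)
  c1 <- simulateCandidateVcf(s1, d1, fp_per_hotspot = 3L)
  lab <- labelTrainingSites(data.frame(chrom = c1$chrom, pos = c1$pos,
                                       ref = c1$ref, alt = c1$alt),
                            d1$variants)
  expect_equal(sum(lab$label == "false_snv"), sum(!c1$is_true))
  expect_gt(sum(!c1$is_true), 30L)

  # raw quality separates the classes at roughly the designed AUC
  auc <- rocAuc(c1$is_true, c1$qual)
  designed <- pnorm((650 - 480) / sqrt(2 * 120^2))
  expect_lt(abs(auc - designed), 0.05)
})
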