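test_that("classifier architecture follows the six-times-then-halve rule", {
  m <- buildClassifier(20)
  expect_equal(m@spec$hidden_dims, c(120L, 60L, 30L, 15L))
  expect_equal(vapply(m@weights, nrow, 0L), c(20L, 120L, 60L, 30L, 15L))
  expect_equal(vapply(m@weights, ncol, 0L), c(120L, 60L, 30L, 15L, 1L))
  # non-conforming widths rejected
  expect_error(buildClassifier(20, hidden_dims = c(100, 50, 25, 12)),
               "six-times")
  # fixed seed -> identical weights across two builds
  expect_identical(buildClassifier(20, seed = 7)@weights,
                   buildClassifier(20, seed = 7)@weights)
  # output is a probability
  p <- predictWindowProb(buildClassifier(20), matrix(rnorm(40), 2))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("confusion metrics reproduce the benchmark arithmetic", {
  m <- confusionMetrics(tp = 2768084, fp = 943304, fn = 223581,
                        tn = 2777463)
  expect_equal(round(m$accuracy, 3), 0.826)
  expect_equal(round(m$precision, 3), 0.746)
  expect_equal(round(m$recall, 3), 0.925)
  expect_equal(round(m$f1, 3), 0.826)

  perfect <- confusionMetrics(10, 0, 0, 10)
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  f1 = 1))
  # degenerate: zero denominators stay undefined, not 0
  degen <- confusionMetrics(0, 5, 5, 0)
  expect_equal(degen$precision, 0)
  expect_equal(degen$recall, 0)
  expect_true(is.na(degen$f1))
})

test_that("quality normalization is a bounded product", {
  expect_equal(normalizeQuality(730, 0.5), 365)
  expect_equal(normalizeQuality(412, 1), 412)
  expect_equal(normalizeQuality(412, 0), 0)
  q <- runif(50, 0, 999); w <- runif(50)
  expect_true(all(normalizeQuality(q, w) <= q))
  # ordering by weight is invariant to the quality attached
  o1 <- order(w)
  expect_equal(order(normalizeQuality(rep(100, 50), w)), o1)
})

test_that("pileup features match hand-walked and brute-force oracles", {
  ref <- strrep("ACGTT", 20)  # 100 bp
  # 3 reads over [10, 30); read c carries a 2-bp deletion at positions 15-16
  rdf <- rbind(simpleRead("a", 10, substr(ref, 11, 30)),
               simpleRead("b", 10, substr(ref, 11, 30)),
               simpleRead("c", 10, paste0(substr(ref, 11, 15),
                                          substr(ref, 18, 30)),
                          cigar = "5M2D13M"))
  rs <- makeReadSet(rdf, ref_len = 100L)
  pu <- pileupStats(rs, ref)
  at <- function(p) pu[pu$pos == p]
  # deletion spanning 2 positions -> deletion frequency 1/3 at both
  expect_equal(at(15)$n_del / at(15)$span, 1 / 3)
  expect_equal(at(16)$n_del / at(16)$span, 1 / 3)
  # error-free pileup: no mismatches/insertions, mean quality = constant
  expect_equal(sum(pu$n_mm), 0L)
  expect_equal(sum(pu$n_ins), 0L)
  expect_equal(unique(pu$qual_sum / pu$cov), utf8ToInt("I") - 33)

  # 2 of 10 reads mismatching at one site -> mismatch frequency 0.2
  rdf2 <- do.call(rbind, lapply(1:10, function(i)
    simpleRead(paste0("m", i), 40,
               if (i <= 2) sub("^A", "T", substr(ref, 41, 60))
               else substr(ref, 41, 60))))
  pu2 <- pileupStats(makeReadSet(rdf2, 100L), ref)
  s40 <- pu2[pu2$pos == 40]
  expect_equal(s40$n_mm / s40$span, 0.2)

  # full brute-force recount on a <= 50-read noisy fixture
  spec <- simulationSpec(genome_length = 5000L, read_coverage = 8,
                         read_length_mean = 1000, read_length_sd = 300,
                         seed = 320)
  sim <- simulateDataset(spec, components = "reads")
  expect_lte(length(sim$reads), 50L)
  pu3 <- pileupStats(sim$reads, sim$diploid$hap1)  # hap1 as arbitrary ref
  bf <- bruteForcePileup(sim$reads, sim$diploid$hap1)
  covered <- which(bf$cov + bf$del > 0) - 1L
  expect_equal(pu3$pos, covered)
  expect_equal(pu3$cov, bf$cov[covered + 1L])
  expect_equal(pu3$n_mm, bf$mm[covered + 1L])
  expect_equal(pu3$n_del, bf$del[covered + 1L])
  expect_equal(pu3$n_ins, bf$ins[covered + 1L])
  expect_equal(pu3$qual_sum, bf$qsum[covered + 1L])
})

test_that("window extraction yields five windows per interior site and clips edges", {
  ref <- strrep("ACGTT", 40)
  rdf <- do.call(rbind, lapply(1:5, function(i)
    simpleRead(paste0("r", i), 0, ref)))
  rs <- makeReadSet(rdf, nchar(ref))
  pu <- pileupStats(rs, ref)
  sl <- c(chr1 = nchar(ref))
  fw <- extractWindowFeatures(pu, data.frame(chrom = "chr1", pos = 50L), sl)
  expect_equal(nrow(fw$features), 5L)
  expect_equal(fw$window_start, 46:50)
  # a site 2 bp from the contig edge keeps only the realizable windows
  fw2 <- extractWindowFeatures(pu, data.frame(chrom = "chr1", pos = 2L), sl)
  expect_equal(nrow(fw2$features), 3L)
  # zero-coverage site skipped with a warning
  expect_warning(
    fw3 <- extractWindowFeatures(pu, data.frame(chrom = "chr1",
                                                pos = c(50L, 5000L)), sl),
    "zero aligned coverage")
  expect_equal(fw3$skipped, 2L)
})

test_that("training-site labelling is allele-aware", {
  truth <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = c("A", "C"),
                      alt = c("G", "T"))
  cand <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     ref = c("A", "C", "G"), alt = c("G", "A", "T"))
  lab <- labelTrainingSites(cand, truth)
  expect_equal(lab$label, c("true_snv", "false_snv", "false_snv"))

  spec <- simulationSpec(genome_length = 100000L, het_snv_rate = 2e-3,
                         hotspot_rate = 2e-4, seed = 321)
  dip <- simulateDiploid(spec)
  cand2 <- simulateCandidateVcf(spec, dip)
  lab2 <- labelTrainingSites(
    data.frame(chrom = cand2$chrom, pos = cand2$pos, ref = cand2$ref,
               alt = cand2$alt), dip$variants)
  expect_equal(lab2$label == "true_snv", cand2$is_true)
})

test_that("the classifier learns separable features and is seed-deterministic", {
  # synthetic windows: false sites carry elevated neighbourhood mismatch
  # and depressed quality
  set.seed(99)
  n <- 1500
  mkX <- function(n, mm_mu, q_mu) {
    X <- matrix(0, n, 20)
    for (p in 1:5) {
      X[, (p - 1) * 4 + 1] <- rnorm(n, q_mu, 3)
      X[, (p - 1) * 4 + 2] <- pmax(0, rnorm(n, mm_mu, 0.05))
      X[, (p - 1) * 4 + 3] <- pmax(0, rnorm(n, 0.02, 0.02))
      X[, (p - 1) * 4 + 4] <- pmax(0, rnorm(n, 0.02, 0.02))
    }
    X
  }
  X <- rbind(mkX(n, 0.05, 30), mkX(n, 0.30, 15))
  y <- rep(c(TRUE, FALSE), each = n)
  fit <- trainClassifier(buildClassifier(20, seed = 5), X, y, epochs = 15)
  expect_gt(fit$report$val_auc, 0.9)

  # label permutation destroys the signal
  yperm <- sample(y)
  fit0 <- trainClassifier(buildClassifier(20, seed = 5), X, yperm,
                          epochs = 15)
  expect_lt(abs(fit0$report$val_auc - 0.5), 0.05)

  # identical rerun -> identical validation loss
  fit2 <- trainClassifier(buildClassifier(20, seed = 5), X, y, epochs = 15)
  expect_identical(fit$report$val_loss, fit2$report$val_loss)

  # single-class input is an error
  expect_error(trainClassifier(buildClassifier(20), X, rep(TRUE, nrow(X))),
               "both classes")

  # model round-trips through its portable file
  f <- tempfile(fileext = ".json")
  saveClassifier(fit$model, f)
  back <- loadClassifier(f)
  expect_equal(predictWindowProb(back, X[1:20, ]),
               predictWindowProb(fit$model, X[1:20, ]), tolerance = 1e-12)
})

test_that("site weight is the mean of its window probabilities", {
  m <- buildClassifier(20, seed = 3)
  X <- matrix(rnorm(100), 5, 20)
  expect_equal(predictSnvWeight(m, X), mean(predictWindowProb(m, X)))
  expect_equal(predictSnvWeight(m, X[3, , drop = FALSE]),
               predictWindowProb(m, X[3, , drop = FALSE]))
  expect_error(predictSnvWeight(m, X[0, , drop = FALSE]), "at least one")
  # constant input -> constant weight
  Z <- matrix(0, 5, 20)
  expect_equal(predictSnvWeight(m, Z), predictWindowProb(m, Z)[1])
})

test_that("threshold suggestion finds the inter-mode valley and is deterministic", {
  set.seed(11)
  x <- c(rnorm(3000, 50, 15), rnorm(3000, 600, 80))
  thr <- suggestThreshold(x)
  expect_equal(thr$method, "valley")
  expect_gt(thr$threshold, 100)
  expect_lt(thr$threshold, 520)
  thr2 <- suggestThreshold(x)
  expect_identical(thr$threshold, thr2$threshold)

  # unimodal distribution takes the fallback with a warning
  set.seed(12)
  u <- rnorm(5000, 300, 40)
  expect_warning(thrU <- suggestThreshold(u), "fallback")
  expect_equal(thrU$method, "fallback")

  expect_error(suggestThreshold(rnorm(100)), "1000")
})
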