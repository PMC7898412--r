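## The SNV refinement classifier: a small fully connected network written
## directly on matrix operations. Four hidden ReLU layers; the first is six
## times the input width and each subsequent layer halves (integer
## division), so the standard 20-feature input gives 120-60-30-15; a
## sigmoid output yields the per-window probability of a true SNV.

#' Build an untrained SNV classifier
#'
#' @param input_dim number of input features (20: 5 window positions times
#'   4 pileup statistics).
#' @param seed integer seed for the weight initialization (He-scaled
#'   normal); the same seed and data reproduce the model exactly.
#' @param hidden_dims optional explicit hidden widths; must equal the
#'   six-times-then-halve rule or construction fails.
#' @return An untrained [SnvClassifier].
#' @examples
#' buildClassifier(20)@spec$hidden_dims  # 120 60 30 15
#' @export
buildClassifier <- function(input_dim = 20L, seed = 1L,
                            hidden_dims = NULL) {
  input_dim <- as.integer(input_dim)
  rule <- integer(4L)
  rule[1L] <- 6L * input_dim
  for (k in 2:4) rule[k] <- rule[k - 1L] %/% 2L
  if (is.null(hidden_dims)) hidden_dims <- rule
  .assert(identical(as.integer(hidden_dims), rule),
          "hidden_dims must follow the six-times-then-halve rule: ",
          paste(rule, collapse = ", "))
  dims <- c(input_dim, rule, 1L)
  set.seed(.childSeed(seed, "init"))
  W <- vector("list", 5L); b <- vector("list", 5L)
  for (k in 1:5) {
    W[[k]] <- matrix(rnorm(dims[k] * dims[k + 1L], 0,
                           sqrt(2 / dims[k])), dims[k], dims[k + 1L])
    b[[k]] <- numeric(dims[k + 1L])
  }
  new("SnvClassifier",
      spec = list(input_dim = input_dim, hidden_dims = rule,
                  activation = "relu", seed = as.integer(seed)),
      weights = W, biases = b, center = numeric(input_dim),
      scale = rep(1, input_dim), trained = FALSE,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()))
}

#' @noRd
.sigmoid <- function(z) 1 / (1 + exp(-z))

## Forward pass on standardized features; returns activations when
## `keep = TRUE` (for backprop).
#' @noRd
.forward <- function(model, X, keep = FALSE) {
  A <- list(X)
  for (k in 1:4) {
    Z <- sweep(A[[k]] %*% model@weights[[k]], 2L, model@biases[[k]], `+`)
    A[[k + 1L]] <- pmax(Z, 0)
  }
  Z5 <- sweep(A[[5L]] %*% model@weights[[5L]], 2L, model@biases[[5L]], `+`)
  p <- .sigmoid(as.vector(Z5))
  if (keep) list(p = p, A = A) else p
}

#' Per-window probabilities from the classifier
#'
#' @param model a trained [SnvClassifier].
#' @param features numeric matrix with `input_dim` columns (one row per
#'   window), on the raw feature scale.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predictWindowProb <- function(model, features) {
  features <- matrix(features, ncol = model@spec$input_dim)
  X <- sweep(sweep(features, 2L, model@center, `-`), 2L, model@scale, `/`)
  .forward(model, X)
}

#' Train the SNV classifier
#'
#' Mini-batch Adam on binary cross-entropy. Classes are balanced by
#' down-sampling the majority class; a held-out fraction provides the
#' validation loss and AUC. Fully deterministic for a fixed model seed and
#' input.
#'
#' @param model an [SnvClassifier] from [buildClassifier()].
#' @param features numeric matrix (windows x features, raw scale).
#' @param labels logical/0-1 vector, `TRUE` for windows of true SNVs.
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param val_fraction held-out fraction for validation.
#' @param balance down-sample the majority class first.
#' @return list with `model` (trained), `report` (list: `val_auc`,
#'   `val_loss`, `n_train`, `n_val`) — the loss curve is in
#'   `model@history`.
#' @export
trainClassifier <- function(model, features, labels, epochs = 30L,
                            batch_size = 128L, learning_rate = 1e-3,
                            val_fraction = 0.2, balance = TRUE) {
  y <- as.integer(as.logical(labels))
  .assert(length(unique(y)) == 2L,
          "training data must contain both classes")
  .assert(nrow(features) == length(y), "features/labels length mismatch")
  set.seed(.childSeed(model@spec$seed, "train"))
  if (balance) {
    i1 <- which(y == 1L); i0 <- which(y == 0L)
    m <- min(length(i1), length(i0))
    keep <- c(sample(i1, m), sample(i0, m))
    features <- features[keep, , drop = FALSE]
    y <- y[keep]
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2L, sd)
  scl[scl < 1e-8] <- 1
  model@center <- ctr; model@scale <- scl
  X <- sweep(sweep(features, 2L, ctr, `-`), 2L, scl, `/`)

  n <- nrow(X)
  perm <- sample.int(n)
  n_val <- max(1L, round(val_fraction * n))
  vi <- perm[seq_len(n_val)]
  ti <- perm[-seq_len(n_val)]
  Xt <- X[ti, , drop = FALSE]; yt <- y[ti]
  Xv <- X[vi, , drop = FALSE]; yv <- y[vi]

  W <- model@weights; b <- model@biases
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
  bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12)))
  hist_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(yt))
    for (s in seq(1L, length(ord), by = batch_size)) {
      ii <- ord[s:min(s + batch_size - 1L, length(ord))]
      Xb <- Xt[ii, , drop = FALSE]; yb <- yt[ii]
      model@weights <- W; model@biases <- b
      fw <- .forward(model, Xb, keep = TRUE)
      nb <- length(yb)
      delta <- matrix((fw$p - yb) / nb, ncol = 1L)  # dL/dZ5
      gW <- vector("list", 5L); gb <- vector("list", 5L)
      for (k in 5:1) {
        gW[[k]] <- t(fw$A[[k]]) %*% delta
        gb[[k]] <- colSums(delta)
        if (k > 1L) {
          delta <- (delta %*% t(W[[k]])) * (fw$A[[k]] > 0)
        }
      }
      t <- t + 1L
      for (k in 1:5) {
        mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gW[[k]]
        vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gW[[k]]^2
        mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gb[[k]]
        vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gb[[k]]^2
        mhW <- mW[[k]] / (1 - beta1^t); vhW <- vW[[k]] / (1 - beta2^t)
        mhb <- mb[[k]] / (1 - beta1^t); vhb <- vb[[k]] / (1 - beta2^t)
        W[[k]] <- W[[k]] - learning_rate * mhW / (sqrt(vhW) + eps)
        b[[k]] <- b[[k]] - learning_rate * mhb / (sqrt(vhb) + eps)
      }
    }
    model@weights <- W; model@biases <- b
    hist_rows[[ep]] <- data.frame(epoch = ep,
                                  train_loss = bce(.forward(model, Xt), yt),
                                  val_loss = bce(.forward(model, Xv), yv))
  }
  model@weights <- W; model@biases <- b
  model@trained <- TRUE
  model@history <- do.call(rbind, hist_rows)
  pv <- .forward(model, Xv)
  val_auc <- rocAuc(yv == 1L, pv)
  list(model = model,
       report = list(val_auc = val_auc,
                     val_loss = model@history$val_loss[epochs],
                     n_train = length(yt), n_val = length(yv)))
}

#' Area under the ROC curve
#'
#' Thin wrapper around `pROC` with fixed direction (higher score = positive
#' class).
#'
#' @param labels logical vector (TRUE = positive).
#' @param scores numeric scores.
#' @return AUC as a plain number.
#' @export
rocAuc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = as.integer(labels),
                                 predictor = as.numeric(scores),
                                 levels = c(0L, 1L), direction = "<",
                                 quiet = TRUE)))
}

#' SNV weight: mean probability over a site's windows
#'
#' Each candidate site is scored in up to five 5-mer windows; the site
#' weight is the arithmetic mean of the per-window probabilities (sites
#' near a contig edge average over the realizable windows only).
#'
#' @param model a trained [SnvClassifier].
#' @param windows numeric matrix of 1-5 window feature rows for one site.
#' @return weight in `[0, 1]`.
#' @export
predictSnvWeight <- function(model, windows) {
  windows <- matrix(windows, ncol = model@spec$input_dim)
  .assert(nrow(windows) >= 1L, "at least one window required")
  .assert(nrow(windows) <= 5L, "at most five windows per site")
  mean(predictWindowProb(model, windows))
}

#' Normalize a variant call quality by a classifier weight
#'
#' @param qual non-negative caller quality (vectorized).
#' @param weight classifier weight in `[0, 1]` (vectorized).
#' @return `qual * weight`; never exceeds `qual`.
#' @export
normalizeQuality <- function(qual, weight) {
  .assert(all(qual >= 0), "qual must be non-negative")
  .assert(all(weight >= 0 & weight <= 1), "weight must be in [0, 1]")
  qual * weight
}

#' Suggest a filtering threshold from a normalized-quality distribution
#'
#' After re-weighting, false calls pile up near zero and true calls keep
#' high quality, so the distribution is bimodal; the suggested cutoff is
#' the first local minimum (valley) after the first local maximum (peak)
#' of a kernel density estimate (normal reference bandwidth). If the
#' density has no such valley, a fallback at 17% of the observed quality
#' range above the minimum is returned with a warning — the regime in
#' which re-weighted nanopore call-quality thresholds typically land.
#'
#' @param normalized_quals at least 1000 values.
#' @return list with `threshold`, `method` (`"valley"`/`"fallback"`),
#'   `density` (the fitted density object).
#' @export
suggestThreshold <- function(normalized_quals) {
  x <- normalized_quals[is.finite(normalized_quals)]
  if (length(x) < 1000L)
    stop("need at least 1000 values to locate the valley reliably; ",
         "set a threshold manually", call. = FALSE)
  d <- density(x, bw = "nrd")
  y <- d$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                     y[2:(n - 1L)] >= y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1L)] < y[1:(n - 2L)] &
                     y[2:(n - 1L)] <= y[3:n], FALSE)
  pk <- which(is_max)
  if (length(pk)) {
    vl <- which(is_min & seq_len(n) > pk[1L])
    if (length(vl))
      return(list(threshold = d$x[vl[1L]], method = "valley", density = d))
  }
  warning("no valley after the first peak; using fallback threshold")
  list(threshold = min(x) + 0.17 * (max(x) - min(x)), method = "fallback",
       density = d)
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn non-negative counts; the total must be positive.
#' @return list with `accuracy`, `precision`, `recall`, `f1`. A metric
#'   with a zero denominator is `NA` (undefined), never 0. `f1` is the
#'   harmonic mean of the unrounded precision and recall.
#' @examples
#' confusionMetrics(tp = 2768084, fp = 943304, fn = 223581, tn = 2777463)
#' @export
confusionMetrics <- function(tp, fp, fn, tn) {
  .assert(all(c(tp, fp, fn, tn) >= 0), "counts must be non-negative")
  total <- tp + fp + fn + tn
  .assert(total > 0, "at least one count must be positive")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
          2 * precision * recall / (precision + recall) else NA_real_
  list(accuracy = (tp + tn) / total, precision = precision,
       recall = recall, f1 = f1)
}

#' Save / load a classifier
#'
#' The model round-trips through a single portable JSON file recording the
#' architecture spec, seed, standardization and weights.
#'
#' @param model an [SnvClassifier].
#' @param path output path.
#' @return `path` (save) or an [SnvClassifier] (load).
#' @export
saveClassifier <- function(model, path) {
  obj <- list(spec = model@spec,
              center = model@center, scale = model@scale,
              trained = model@trained,
              weights = lapply(model@weights, function(w)
                list(dim = dim(w), data = as.vector(w))),
              biases = model@biases,
              history = model@history)
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  W <- lapply(obj$weights, function(w)
    matrix(as.numeric(unlist(w$data)), unlist(w$dim)[1L], unlist(w$dim)[2L]))
  hist <- if (length(obj$history))
    do.call(rbind, lapply(obj$history, as.data.frame))
  else data.frame(epoch = integer(), train_loss = numeric(),
                  val_loss = numeric())
  new("SnvClassifier",
      spec = list(input_dim = as.integer(obj$spec$input_dim),
                  hidden_dims = as.integer(unlist(obj$spec$hidden_dims)),
                  activation = obj$spec$activation,
                  seed = as.integer(obj$spec$seed)),
      weights = W, biases = lapply(obj$biases, as.numeric),
      center = as.numeric(obj$center), scale = as.numeric(obj$scale),
      trained = isTRUE(obj$trained), history = hist)
}

#' Refine a candidate SNV set
#'
#' End-to-end refinement: extracts window features for every candidate,
#' scores them with the classifier, and multiplies each candidate's caller
#' quality by its weight to give the normalized quality.
#'
#' @param candidates data.frame with `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `qual`.
#' @param model a trained [SnvClassifier].
#' @param pileup result of [pileupStats()] over the same alignments.
#' @param seqlengths named integer contig lengths.
#' @return `candidates` with added `weight` and `normalized_qual` columns;
#'   zero-coverage sites get `NA` weight and are left unrefined.
#' @export
refineCandidates <- function(candidates, model, pileup, seqlengths) {
  fw <- extractWindowFeatures(pileup, candidates, seqlengths)
  probs <- predictWindowProb(model, fw$features)
  w <- rep(NA_real_, nrow(candidates))
  agg <- tapply(probs, fw$site_index, mean)
  w[as.integer(names(agg))] <- as.numeric(agg)
  candidates$weight <- w
  candidates$normalized_qual <- ifelse(is.na(w), candidates$qual,
                                       normalizeQuality(candidates$qual,
                                                        ifelse(is.na(w), 0, w)))
  candidates
}

#' Write refined candidates as a VCF
#'
#' QUAL holds the normalized quality; the original quality and the
#' classifier weight are preserved in `INFO/RAWQ` and `INFO/W`.
#'
#' @param candidates result of [refineCandidates()].
#' @param path output path.
#' @param contigs optional named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
writeRefinedVcf <- function(candidates, path, contigs = NULL) {
  info <- sprintf("RAWQ=%.6g;W=%.6g", candidates$qual,
                  ifelse(is.na(candidates$weight), 1, candidates$weight))
  df <- data.frame(chrom = candidates$chrom, pos = candidates$pos,
                   ref = candidates$ref, alt = candidates$alt,
                   qual = candidates$normalized_qual, gt = "0/1",
                   stringsAsFactors = FALSE)
  .writeSimpleVcf(df, path, sample = "SAMPLE", info = info,
                  contigs = contigs, extra_header = c(
    "##INFO=<ID=RAWQ,Number=1,Type=Float,Description=\"Original caller quality\">",
    "##INFO=<ID=W,Number=1,Type=Float,Description=\"Classifier weight\">"))
}
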