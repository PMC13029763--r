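# Shared fixtures, built in code. Heavy artifacts are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

tiny_spec <- function(...) {
  synthetic_spec(n_compounds = 120L, n_scaffold_families = 12L, seed = 11L,
                 ...)
}

# small labeled fingerprint dataset with one planted informative bit pattern
toy_fp_data <- function(n = 200L, p = 64L, seed = 9L, noise = 0.1) {
  set.seed(seed)
  x <- matrix(rbinom(n * p, 1L, 0.2), n)
  colnames(x) <- sprintf("F%d", seq_len(p) - 1L)
  y <- as.integer(x[, 3] == 1L)
  flip <- sample(n, round(noise * n))
  y[flip] <- 1L - y[flip]
  list(x = x, y = y)
}

# brute-force metric oracles, independent of the package implementations
oracle_auc <- function(prob, label) {
  pos <- which(label == 1L); neg <- which(label == 0L)
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (prob[i] > prob[j]) + 0.5 * (prob[i] == prob[j])
  }
  tot / (length(pos) * length(neg))
}

oracle_ap <- function(prob, label) {
  npos <- sum(label == 1L)
  if (npos == 0L || npos == length(label)) return(NA_real_)
  th <- sort(unique(prob), decreasing = TRUE)
  prev_rec <- 0; total <- 0
  for (t in th) {
    sel <- prob >= t
    prec <- sum(label[sel]) / sum(sel)
    rec <- sum(label[sel]) / npos
    total <- total + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  total
}

oracle_mcc <- function(prob, label, threshold = 0.5) {
  p <- as.integer(prob >= threshold)
  tp <- sum(p & label); fp <- sum(p & !label)
  fn <- sum(!p & label); tn <- sum(!p & !label)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

oracle_ba <- function(prob, label, threshold = 0.5) {
  p <- as.integer(prob >= threshold)
  sens <- sum(p & label) / sum(label)
  spec <- sum(!p & !label) / sum(!label)
  mean(c(sens, spec))
}

# exhaustive sphere-exclusion reference (direct transcription of the
# published algorithm, no shared code with the package implementation)
oracle_butina <- function(D, score, ids, cutoff) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= cutoff))
  taken <- rep(FALSE, n)
  out <- list()
  while (any(!taken)) {
    free <- which(!taken)
    cnt <- sapply(free, function(i) length(intersect(nbrs[[i]], free)))
    cand <- free[order(-cnt, -score[free], ids[free])]
    c0 <- cand[1]
    mem <- intersect(nbrs[[c0]], free)
    taken[mem] <- TRUE
    out[[length(out) + 1L]] <- list(centroid = ids[c0], members = sort(ids[mem]))
  }
  out
}
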