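# Applicability-domain analysis by Tanimoto similarity plus stratified error
# analysis over similarity, physicochemical, prediction-confidence and
# scaffold-frequency slices.

#' Similarity of query compounds to a reference set
#'
#' Exact (non-approximate) maximum Tanimoto similarity of each query
#' fingerprint to the reference fingerprints, plus the mean over the top five
#' most similar references (over all references when fewer than five).
#'
#' @param query_fp,reference_fp 0/1 fingerprint matrices, equal column count.
#' @return data.frame with `max_sim` and `top5_mean` per query row.
#' @export
similarity_to_reference <- function(query_fp, reference_fp) {
  if (is.null(dim(reference_fp)) || nrow(reference_fp) == 0L) {
    stop("empty reference set")
  }
  S <- tanimoto_matrix(query_fp, reference_fp)
  k <- min(5L, ncol(S))
  t5 <- apply(S, 1, function(r) mean(sort(r, decreasing = TRUE)[seq_len(k)]))
  data.frame(max_sim = apply(S, 1, max), top5_mean = t5)
}

#' Applicability-domain membership
#'
#' In-domain iff the maximum Tanimoto similarity to the reference set is
#' `>= threshold` (inclusive; default 0.35).
#'
#' @param max_sim numeric in \[0,1\].
#' @param threshold similarity cutoff.
#' @return logical vector.
#' @export
classify_domain <- function(max_sim, threshold = 0.35) {
  stopifnot(all(max_sim >= 0 & max_sim <= 1))
  max_sim >= threshold
}

#' Scaffold frequency of test compounds in the train+val reference
#'
#' Each test compound is annotated with the occurrence count of its scaffold
#' in the combined training and validation subset, binned as 0 (unseen
#' scaffold), 1, 2-5, 6-20, >=21. The empty scaffold is one shared group.
#'
#' @param test_scaffolds,ref_scaffolds character vectors of scaffold SMILES.
#' @return data.frame with `count` and `bin` (factor with the five levels).
#' @export
scaffold_frequency <- function(test_scaffolds, ref_scaffolds) {
  tab <- table(ref_scaffolds)
  cnt <- as.integer(tab[match(test_scaffolds, names(tab))])
  cnt[is.na(cnt)] <- 0L
  lv <- c("0 (unseen scaffold)", "1", "2-5", "6-20", ">=21")
  bin <- cut(cnt, breaks = c(-0.5, 0.5, 1.5, 5.5, 20.5, Inf), labels = lv)
  data.frame(count = cnt, bin = bin)
}

.similarity_bins <- function(x) {
  # half-open [lo, hi), last bin closed at 1.0
  lv <- c("0.00-0.20", "0.20-0.35", "0.35-0.50", "0.50-0.70", "0.70-1.00")
  edges <- c(0, 0.2, 0.35, 0.5, 0.7, 1.0)
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  factor(lv[pmin(i, 5L)], levels = lv)
}

# quartile bins on the observed distribution; duplicate edges merged
.quartile_bins <- function(x) {
  qs <- unique(stats::quantile(x, probs = 0:4 / 4, na.rm = TRUE, type = 7))
  if (length(qs) < 2L) return(factor(rep(sprintf("[%g]", qs[1]), length(x))))
  cut(x, breaks = qs, include.lowest = TRUE, dig.lab = 4)
}

.stratum_eval <- function(prob, label, idx, threshold = 0.5) {
  if (length(idx) == 0L) {
    return(data.frame(n = 0L, auc = NA_real_, ap = NA_real_, mcc = NA_real_,
                      balanced_accuracy = NA_real_))
  }
  e <- evaluate_predictions(prob[idx], label[idx], threshold)
  data.frame(n = length(idx), auc = e$auc, ap = e$ap, mcc = e$mcc,
             balanced_accuracy = e$balanced_accuracy)
}

#' Stratified test-set performance
#'
#' Slices held-out predictions along: fixed similarity bins (0.00-0.20,
#' 0.20-0.35, 0.35-0.50, 0.50-0.70, 0.70-1.00), the binary applicability
#' domain, per-descriptor quartiles, predicted-probability quartiles and
#' scaffold-frequency bins. AUC/AP are reported only when both classes are
#' present in a stratum (NA marker otherwise); MCC and balanced accuracy use
#' a fixed threshold of 0.5.
#'
#' @param pred data.frame with columns `prob`, `label` (0/1), `max_sim`, and
#'   optionally descriptor columns plus `scaffold_count`.
#' @param descriptors character vector of descriptor column names to slice
#'   by quartiles.
#' @param seed seed identifier carried into the output rows.
#' @param ad_threshold applicability-domain cutoff.
#' @return data.frame of per-stratum metrics: `dimension`, `stratum`, `n`,
#'   `auc`, `ap`, `mcc`, `balanced_accuracy`, `seed`. Within each dimension
#'   the stratum sizes sum to `nrow(pred)`.
#' @export
stratify_performance <- function(pred, descriptors = character(0), seed = NA,
                                 ad_threshold = 0.35) {
  stopifnot(all(c("prob", "label", "max_sim") %in% names(pred)))
  dims <- list(similarity = .similarity_bins(pred$max_sim),
               domain = factor(ifelse(classify_domain(pred$max_sim,
                                                      ad_threshold),
                                      "in-domain", "out-of-domain"),
                               levels = c("in-domain", "out-of-domain")),
               probability = .quartile_bins(pred$prob))
  for (d in descriptors) {
    if (d %in% names(pred)) dims[[d]] <- .quartile_bins(pred[[d]])
  }
  if ("scaffold_count" %in% names(pred)) {
    lv <- c("0 (unseen scaffold)", "1", "2-5", "6-20", ">=21")
    dims$scaffold_frequency <- cut(pred$scaffold_count,
                                   breaks = c(-0.5, 0.5, 1.5, 5.5, 20.5, Inf),
                                   labels = lv)
  }
  rows <- list()
  for (dn in names(dims)) {
    f <- dims[[dn]]
    for (lev in levels(f)) {
      r <- .stratum_eval(pred$prob, pred$label, which(f == lev))
      r <- cbind(data.frame(dimension = dn, stratum = lev), r,
                 data.frame(seed = seed))
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
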