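# Ensemble library screening: per-seed probability averaging, ranking,
# applicability-domain annotation, chemical-space embedding and Butina
# diversity selection.

#' Ensemble-score a screening library
#'
#' Each seed model predicts a probability per library compound; the mean and
#' inter-seed sample SD are retained. Ranking is by descending mean with a
#' deterministic tie-break on `public_id`.
#'
#' @param models list of `ns_model` objects (one per seed).
#' @param library_fp fingerprint matrix of the prepared library; its
#'   `fp_hash` attribute must match `expected_fp_hash` when supplied.
#' @param public_ids identifiers aligned with the fingerprint rows.
#' @param expected_fp_hash training fingerprint parameter hash to assert the
#'   training/screening featurization echo.
#' @return data.frame `public_id`, `mean_prob`, `sd_prob`, `rank`, ordered
#'   by rank.
#' @export
ensemble_score <- function(models, library_fp, public_ids,
                           expected_fp_hash = NULL) {
  stopifnot(length(models) >= 1L, nrow(library_fp) == length(public_ids))
  if (!is.null(expected_fp_hash) &&
      !identical(attr(library_fp, "fp_hash"), expected_fp_hash)) {
    stop("screening fingerprints were not built with the training parameters")
  }
  P <- vapply(models, function(m) predict_prob(m, library_fp),
              numeric(nrow(library_fp)))
  P <- matrix(P, nrow = nrow(library_fp))
  mean_prob <- rowMeans(P)
  sd_prob <- if (ncol(P) > 1L) apply(P, 1, stats::sd) else rep(0, nrow(P))
  ord <- order(-mean_prob, public_ids)
  out <- data.frame(public_id = public_ids[ord], mean_prob = mean_prob[ord],
                    sd_prob = sd_prob[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-n ranked subset
#' @param scores output of [ensemble_score()].
#' @param n subset size; when larger than the library all rows are returned
#'   with a warning.
#' @return the first `n` rows by rank.
#' @export
select_top <- function(scores, n = 200L) {
  if (n > nrow(scores)) {
    warning("n exceeds library size; returning all rows")
    n <- nrow(scores)
  }
  scores[seq_len(n), , drop = FALSE]
}

#' Annotate screening scores with applicability-domain membership
#'
#' Maximum Tanimoto similarity of each library compound to the reference
#' (training + validation of the designated seed) with the inclusive 0.35
#' threshold of [classify_domain()].
#'
#' @param scores output of [ensemble_score()] (any row order).
#' @param library_fp fingerprints aligned with `public_ids`.
#' @param public_ids identifiers aligned with `library_fp` rows.
#' @param reference_fp fingerprints of the reference compounds.
#' @param threshold similarity cutoff.
#' @return `scores` with `max_sim` and `in_domain` columns appended.
#' @export
ad_annotate <- function(scores, library_fp, public_ids, reference_fp,
                        threshold = 0.35) {
  sim <- similarity_to_reference(library_fp, reference_fp)
  idx <- match(scores$public_id, public_ids)
  scores$max_sim <- sim$max_sim[idx]
  scores$in_domain <- classify_domain(scores$max_sim, threshold)
  scores
}

#' 2-D chemical-space embedding
#'
#' PCA to at most 50 components (limited by sample size) followed by a
#' nonlinear 2-D reduction (Kruskal non-metric MDS on the component
#' distances). For large libraries a seeded random subsample is embedded
#' while all `top_ids` are force-included.
#'
#' @param library_fp fingerprint matrix.
#' @param public_ids identifiers aligned with rows.
#' @param top_ids identifiers that must be embedded.
#' @param subsample_size maximum number of embedded compounds.
#' @param seed integer seed for the subsample.
#' @return data.frame `public_id`, `x`, `y`, `in_subsample`.
#' @export
embed_chemspace <- function(library_fp, public_ids, top_ids = character(0),
                            subsample_size = 2000L, seed = 1L) {
  n <- nrow(library_fp)
  if (n < 3L) stop("at least 3 compounds required")
  forced <- which(public_ids %in% top_ids)
  pick <- if (n > subsample_size) {
    extra <- with_seed(seed, sample(setdiff(seq_len(n), forced),
                                    max(0L, subsample_size - length(forced))))
    sort(unique(c(forced, extra)))
  } else seq_len(n)
  X <- matrix(as.numeric(library_fp[pick, , drop = FALSE]), length(pick))
  k <- min(50L, length(pick) - 1L, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  Z <- pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
  d <- stats::dist(Z)
  d[d == 0] <- 1e-8
  coords <- tryCatch(
    MASS::isoMDS(d, y = stats::cmdscale(d, 2), k = 2, trace = FALSE)$points,
    error = function(e) stats::cmdscale(d, 2)
  )
  data.frame(public_id = public_ids[pick], x = coords[, 1], y = coords[, 2],
             in_subsample = TRUE, stringsAsFactors = FALSE)
}

#' Butina sphere-exclusion clustering with representative selection
#'
#' Neighbour lists are built at Tanimoto distance `<= cutoff`
#' (distance = 1 - similarity). Iteratively, the unassigned compound with
#' the most unassigned neighbours becomes a centroid (ties: higher score,
#' then id) and claims its unassigned neighbours; every member lies within
#' the cutoff of its centroid. Each cluster's representative is its
#' highest-scoring member; the shortlist is the top `shortlist_n`
#' representatives by score.
#'
#' @param candidate_fp fingerprints of the candidate set.
#' @param scores data.frame with `public_id` and `mean_prob` aligned by id.
#' @param public_ids identifiers aligned with `candidate_fp` rows.
#' @param cutoff Tanimoto distance cutoff.
#' @param shortlist_n shortlist size.
#' @return list: `clusters` (list of `cluster_id`, `centroid`, `members`,
#'   `representative`), `shortlist` (data.frame of representatives, ordered
#'   by descending score).
#' @export
butina_select <- function(candidate_fp, scores, public_ids, cutoff = 0.35,
                          shortlist_n = 20L) {
  n <- nrow(candidate_fp)
  if (n == 0L) stop("empty candidate set")
  sc <- scores$mean_prob[match(public_ids, scores$public_id)]
  S <- tanimoto_matrix(candidate_fp, candidate_fp)
  D <- 1 - S
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= cutoff)) # incl. self
  assigned <- rep(FALSE, n)
  clusters <- list()
  repeat {
    un <- which(!assigned)
    if (length(un) == 0L) break
    counts <- vapply(un, function(i) sum(!assigned[nbr[[i]]]), integer(1))
    ord <- order(-counts, -sc[un], public_ids[un])
    centroid <- un[ord[1]]
    members <- nbr[[centroid]][!assigned[nbr[[centroid]]]]
    assigned[members] <- TRUE
    rep_i <- members[order(-sc[members], public_ids[members])][1]
    clusters[[length(clusters) + 1L]] <- list(
      cluster_id = length(clusters) + 1L,
      centroid = public_ids[centroid],
      members = public_ids[members],
      representative = public_ids[rep_i],
      representative_score = sc[rep_i])
  }
  reps <- data.frame(
    public_id = vapply(clusters, `[[`, character(1), "representative"),
    mean_prob = vapply(clusters, `[[`, numeric(1), "representative_score"),
    cluster_id = vapply(clusters, `[[`, integer(1), "cluster_id"),
    stringsAsFactors = FALSE)
  reps <- reps[order(-reps$mean_prob, reps$public_id), , drop = FALSE]
  shortlist <- utils::head(reps, shortlist_n)
  rownames(shortlist) <- NULL
  list(clusters = clusters, shortlist = shortlist)
}
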