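# Feature attribution, fingerprint-bit environment reconstruction and
# R-group series analysis.

#' Sample explanation and background sets
#'
#' Without-replacement row samples under the split seed: up to `n_explain`
#' rows to explain and up to `n_background` rows as the reference
#' distribution.
#'
#' @param x feature matrix (train+val rows).
#' @param seed integer seed.
#' @param n_explain,n_background maximum sample sizes.
#' @return list with integer row indices `explain` and `background`.
#' @export
sample_explain_sets <- function(x, seed, n_explain = 2000L,
                                n_background = 200L) {
  n <- nrow(x)
  with_seed(seed, {
    explain <- sort(sample.int(n, min(n, n_explain)))
    background <- sort(sample.int(n, min(n, n_background)))
    list(explain = explain, background = background)
  })
}

# flatten a ranger probability forest into the C++ tree layout
.ranger_trees <- function(fit) {
  lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    predcols <- grep("^pred", names(ti), value = TRUE)
    pc <- predcols[length(predcols)] # positive class = last factor level "1"
    leaf <- is.na(ti$leftChild)
    list(left = ifelse(leaf, -1L, ti$leftChild),
         right = ifelse(leaf, -1L, ti$rightChild),
         feature = ifelse(leaf, -1L, ti$splitvarID),
         threshold = ifelse(leaf, 0, ti$splitval),
         value = ifelse(leaf, ti[[pc]], 0))
  })
}

# Monte-Carlo permutation Shapley estimate for arbitrary probability models
.sampling_shap <- function(predfun, x_explain, x_background, n_samples,
                           seed) {
  p <- ncol(x_explain)
  phi <- matrix(0, nrow(x_explain), p)
  base <- mean(predfun(x_background))
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      perm <- sample.int(p)
      b <- x_background[sample.int(nrow(x_background), nrow(x_explain),
                                   replace = TRUE), , drop = FALSE]
      cur <- b
      prev <- predfun(cur)
      for (j in perm) {
        cur[, j] <- x_explain[, j]
        nxt <- predfun(cur)
        phi[, j] <- phi[, j] + (nxt - prev)
        prev <- nxt
      }
    }
  })
  list(phi = phi / n_samples, base = base)
}

#' Feature attribution for the positive class
#'
#' Explainer matched to the model family: exact path-dependent TreeSHAP
#' (compiled) for random forests, the library TreeSHAP (`predcontrib`) for
#' gradient boosting (log-odds scale), exact linear attributions for
#' penalized logistic regression (link scale), and a seeded sampling
#' estimator for anything else. Tree and linear attributions satisfy local
#' accuracy: `base + rowSums(phi)` equals the model output.
#'
#' @param model an `ns_model`.
#' @param x_explain rows to explain (max 2000).
#' @param x_background reference rows (max 200; must be non-empty).
#' @param seed integer seed (sampling fallback only).
#' @param n_samples permutation draws for the sampling fallback.
#' @return list of class `ns_attribution`: `phi` (samples x features),
#'   `base_value`, `scale` ("probability", "log-odds" or "link"), `family`,
#'   `seed`.
#' @export
attribute <- function(model, x_explain, x_background, seed = model$seed,
                      n_samples = 64L) {
  stopifnot(inherits(model, "ns_model"))
  if (is.null(dim(x_background)) || nrow(x_background) == 0L) {
    stop("empty background set")
  }
  if (nrow(x_explain) > 2000L) stop("explain set capped at 2000 rows")
  if (nrow(x_background) > 200L) stop("background set capped at 200 rows")
  out <- switch(
    model$family,
    random_forest = {
      r <- .treeshap_cpp(.ranger_trees(model$fit), x_explain, x_background)
      list(phi = r$phi, base_value = r$base, scale = "probability")
    },
    gradient_boosting = {
      pc <- stats::predict(model$fit,
                           xgboost::xgb.DMatrix(x_explain, nthread = 1L),
                           predcontrib = TRUE)
      list(phi = pc[, -ncol(pc), drop = FALSE],
           base_value = unname(pc[1, ncol(pc)]), scale = "log-odds")
    },
    logistic_regression = {
      beta <- as.numeric(stats::coef(model$fit))[-1]
      b0 <- as.numeric(stats::coef(model$fit))[1]
      mu <- colMeans(x_background)
      phi <- sweep(x_explain, 2, mu) * rep(beta, each = nrow(x_explain))
      list(phi = phi, base_value = b0 + sum(beta * mu), scale = "link")
    },
    {
      fam <- model_families()[[model$family]]
      r <- .sampling_shap(function(m) fam$predict(model$fit, m),
                          x_explain, x_background, n_samples, seed)
      list(phi = r$phi, base_value = r$base, scale = "probability")
    }
  )
  colnames(out$phi) <- colnames(x_explain)
  out$family <- model$family
  out$seed <- seed
  class(out) <- "ns_attribution"
  out
}

#' Cross-seed global feature importance
#'
#' Within each seed, importance is the mean absolute attribution per feature
#' across explained samples; across seeds the mean and sample SD are
#' reported, ranked descending by cross-seed mean.
#'
#' @param attributions list of `ns_attribution` objects (one per seed).
#' @return data.frame: `feature` (column name), `feature_index` (0-based),
#'   `mean_abs`, `sd_abs`, `rank`.
#' @export
global_importance <- function(attributions) {
  stopifnot(length(attributions) >= 1L)
  per_seed <- vapply(attributions, function(a) colMeans(abs(a$phi)),
                     numeric(ncol(attributions[[1]]$phi)))
  per_seed <- matrix(per_seed, ncol = length(attributions))
  m <- rowMeans(per_seed)
  s <- if (ncol(per_seed) > 1L) apply(per_seed, 1, stats::sd) else
    rep(0, nrow(per_seed))
  nm <- colnames(attributions[[1]]$phi)
  out <- data.frame(feature = nm, feature_index = seq_along(m) - 1L,
                    mean_abs = m, sd_abs = s)
  out <- out[order(-out$mean_abs, out$feature_index), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Reconstruct the atom-centred environments behind a fingerprint bit
#'
#' For every compound activating the bit, emits each (center atom, radius)
#' pair that hashes to it together with the induced substructure as SMILES.
#' A bit may encode several distinct environments (hash collisions); all are
#' reported.
#'
#' @param bit 0-based bit index (< `n_bits`).
#' @param smiles character vector of compound SMILES.
#' @param params [fp_params()] used for training.
#' @param ids optional compound identifiers (defaults to row numbers).
#' @return data.frame: `compound_id`, `center_atom`, `radius`,
#'   `environment_smiles`; zero rows when nothing activates the bit.
#' @export
map_bit_environments <- function(bit, smiles, params = fp_params(),
                                 ids = NULL) {
  if (bit < 0L || bit >= params$n_bits) stop("bit index out of range")
  ids <- ids %||% as.character(seq_along(smiles))
  rows <- list()
  for (i in seq_along(smiles)) {
    fo <- fingerprint_one(smiles[i], params)
    hit <- fo$info[fo$info$bit == bit, , drop = FALSE]
    if (nrow(hit) == 0L) next
    for (r in seq_len(nrow(hit))) {
      env_atoms <- .atoms_within(fo$graph, hit$atom[r], hit$radius[r])
      env_smi <- molblock_to_smiles(subgraph_molblock(fo$graph, env_atoms))
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = ids[i], center_atom = hit$atom[r],
        radius = hit$radius[r], environment_smiles = env_smi,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(compound_id = character(0), center_atom = integer(0),
                      radius = integer(0), environment_smiles = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# heavy atoms within graph distance `radius` of `center`
.atoms_within <- function(g, center, radius) {
  cur <- center
  seen <- center
  if (radius > 0L) {
    adj <- .adj_list(g$n_atoms, g$bonds)
    for (r in seq_len(radius)) {
      nxt <- setdiff(unique(unlist(adj[cur])), seen)
      seen <- c(seen, nxt)
      cur <- nxt
      if (length(cur) == 0L) break
    }
  }
  sort(seen[g$elem[seen] != "H"])
}

# --- R-group decomposition -------------------------------------------------

.mol_igraph <- function(g) {
  zn <- .atomic_number[g$elem]
  zn[is.na(zn)] <- 0
  ig <- igraph::make_empty_graph(n = g$n_atoms, directed = FALSE)
  if (nrow(g$bonds) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$a1, g$bonds$a2))
  }
  igraph::V(ig)$color <- as.integer(zn)
  ig
}

# Decompose one member against a core scaffold. Returns data.frame
# (core_atom, substituent_smiles) or NULL when no clean decomposition exists.
.decompose_member <- function(member_graph, core_graph) {
  gm <- .mol_igraph(member_graph)
  gc <- .mol_igraph(core_graph)
  isos <- igraph::subgraph_isomorphisms(pattern = gc, target = gm,
                                        method = "vf2")
  if (length(isos) == 0L) return(NULL)
  best <- NULL
  best_key <- NULL
  for (iso in isos) {
    map <- as.integer(iso) # core vertex i -> member vertex map[i]
    outside <- setdiff(seq_len(member_graph$n_atoms), map)
    if (length(outside) == 0L) {
      cand <- data.frame(core_atom = integer(0),
                         substituent_smiles = character(0))
      key <- ""
    } else {
      sub_bonds <- member_graph$bonds[
        member_graph$bonds$a1 %in% outside &
          member_graph$bonds$a2 %in% outside, , drop = FALSE]
      comp <- .components(member_graph$n_atoms, sub_bonds)
      ok <- TRUE
      recs <- list()
      for (cid in unique(comp[outside])) {
        atoms <- intersect(which(comp == cid), outside)
        att <- member_graph$bonds[
          xor(member_graph$bonds$a1 %in% atoms,
              member_graph$bonds$a2 %in% atoms), , drop = FALSE]
        core_att <- unique(ifelse(att$a1 %in% atoms, att$a2, att$a1))
        core_att <- intersect(core_att, map)
        if (length(core_att) != 1L) { ok <- FALSE; break }
        frag_att <- intersect(unique(c(att$a1, att$a2)), atoms)
        smi <- molblock_to_smiles(
          subgraph_molblock(member_graph, atoms,
                            extra_dummy_bond_to = frag_att[1]))
        if (is.na(smi)) { ok <- FALSE; break }
        recs[[length(recs) + 1L]] <- data.frame(
          core_atom = match(core_att, map), substituent_smiles = smi,
          stringsAsFactors = FALSE)
      }
      if (!ok) next
      cand <- do.call(rbind, recs)
      cand <- cand[order(cand$core_atom, cand$substituent_smiles), ,
                   drop = FALSE]
      key <- paste(cand$core_atom, cand$substituent_smiles,
                   collapse = "|", sep = ":")
    }
    if (is.null(best_key) || key < best_key) {
      best <- cand
      best_key <- key
    }
  }
  best
}

#' R-group series analysis of scored compounds
#'
#' Selects the modal Murcko scaffold among the scored set as the series core
#' (ties broken by higher mean score then lexicographic SMILES), decomposes
#' every member into position-wise substituents against that core, and
#' summarizes substituent counts and mean scores per position. Pairwise
#' R1 x R2 mean-score cells are reported only when observed in at least
#' `pair_support` compounds.
#'
#' @param scored data.frame with `smiles` and `score` columns (`scaffold`
#'   optional; computed when absent).
#' @param min_series_size minimum members sharing the core scaffold.
#' @param min_substituent_count substituents below this count are flagged
#'   out of comparisons (but still listed).
#' @param pair_support minimum support for an R1 x R2 grid cell.
#' @return list of class `ns_rgroup`: `core_scaffold`, `series` (member
#'   table with position columns), `positions` (per-position substituent
#'   summaries), `grid` (R1 x R2 data.frame), `series_mean`; or a list with
#'   `no_series = TRUE` when no scaffold reaches `min_series_size`.
#' @export
rgroup_series <- function(scored, min_series_size = 10L,
                          min_substituent_count = 2L, pair_support = 3L) {
  stopifnot(all(c("smiles", "score") %in% names(scored)))
  scaff <- scored$scaffold %||% murcko_scaffold(scored$smiles)
  tab <- table(scaff[nzchar(scaff)])
  if (length(tab) == 0L) return(list(no_series = TRUE, reason = "no ring scaffolds"))
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L) {
    ms <- vapply(cand, function(s) mean(scored$score[scaff == s]), numeric(1))
    cand <- cand[order(-ms, cand)]
  }
  core <- cand[1]
  if (tab[[core]] < min_series_size) {
    return(list(no_series = TRUE, reason = "largest series below minimum size",
                core_scaffold = core, size = as.integer(tab[[core]])))
  }
  members <- which(scaff == core)
  core_graph <- parse_molblock(smiles_to_molblock(core))
  mb <- smiles_to_molblock(canonical_smiles(scored$smiles[members]))
  decomp <- lapply(seq_along(members), function(k) {
    .decompose_member(parse_molblock(mb[k]), core_graph)
  })
  keep <- !vapply(decomp, is.null, logical(1))
  members <- members[keep]
  decomp <- decomp[keep]
  pos_atoms <- sort(unique(unlist(lapply(decomp, function(d) d$core_atom))))
  pos_label <- stats::setNames(sprintf("R%d", seq_along(pos_atoms)),
                               pos_atoms)
  series <- data.frame(smiles = scored$smiles[members],
                       score = scored$score[members],
                       stringsAsFactors = FALSE)
  for (pl in pos_label) series[[pl]] <- "[H]"
  for (k in seq_along(decomp)) {
    d <- decomp[[k]]
    for (r in seq_len(nrow(d))) {
      series[k, pos_label[as.character(d$core_atom[r])]] <-
        d$substituent_smiles[r]
    }
  }
  positions <- lapply(pos_label, function(pl) {
    ag <- stats::aggregate(series$score, by = list(substituent = series[[pl]]),
                           FUN = function(v) c(n = length(v), mean = mean(v)))
    out <- data.frame(substituent = ag$substituent,
                      n = as.integer(ag$x[, "n"]),
                      mean_score = ag$x[, "mean"])
    out$included_in_comparison <- out$n >= min_substituent_count
    out[order(-out$mean_score), ]
  })
  names(positions) <- pos_label
  grid <- NULL
  if (length(pos_label) >= 2L) {
    key <- paste(series$R1, series$R2, sep = "\r")
    ag <- stats::aggregate(series$score, by = list(key = key),
                           FUN = function(v) c(n = length(v), mean = mean(v)))
    parts <- strsplit(ag$key, "\r", fixed = TRUE)
    grid <- data.frame(R1 = vapply(parts, `[`, character(1), 1),
                       R2 = vapply(parts, `[`, character(1), 2),
                       n = as.integer(ag$x[, "n"]),
                       mean_score = ag$x[, "mean"],
                       stringsAsFactors = FALSE)
    grid <- grid[grid$n >= pair_support, , drop = FALSE]
    grid <- grid[order(-grid$mean_score), , drop = FALSE]
    rownames(grid) <- NULL
  }
  out <- list(no_series = FALSE, core_scaffold = core, series = series,
              positions = positions, grid = grid,
              series_mean = mean(series$score),
              n_members = nrow(series))
  class(out) <- "ns_rgroup"
  out
}
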