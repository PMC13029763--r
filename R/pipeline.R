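# End-to-end pipeline: synthesize -> curate -> canonicalize/dedup -> scaffold
# split (seeds) -> fit/evaluate -> calibrate/threshold -> screen -> Butina
# shortlist, with deterministic CSV exports.

.write_csv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full screening pipeline on a synthetic study
#'
#' Executes every stage of the analysis on data drawn from `spec`, returning
#' all intermediate artifacts and (optionally) writing deterministic CSVs.
#' Identical inputs produce byte-identical outputs.
#'
#' @param spec a [synthetic_spec()].
#' @param seeds scaffold-split seeds (default 1:3).
#' @param family model family evaluated per seed.
#' @param tune `TRUE` runs the 25-configuration randomized search per seed;
#'   `FALSE` fits the family defaults (faster fixed-budget run).
#' @param n_library screening-library size before defect injection.
#' @param top_n size of the top-ranked screening subset.
#' @param shortlist_n Butina shortlist size.
#' @param out_dir optional output directory for CSV exports.
#' @return list with `compounds`, `splits`, `split_summaries`, `models`,
#'   `evaluations`, `aggregate`, `thresholds`, `calibrations`, `library`,
#'   `scores`, `top`, `selection`, `fp_params`, `manifest`.
#' @export
run_pipeline <- function(spec, seeds = 1:3, family = "random_forest",
                         tune = FALSE, n_library = 600L, top_n = 100L,
                         shortlist_n = 20L, out_dir = NULL) {
  stopifnot(inherits(spec, "ns_synth_spec"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  params <- fp_params()

  # --- curation ------------------------------------------------------------
  gen <- generate_activity_table(spec)
  cur <- curate_records(gen$records, curation_config())
  .write_csv(gen$records, out_dir, "activity_records.csv")
  .write_csv(cur$compounds, out_dir, "compounds_labeled.csv")
  .write_csv(cur$rejected, out_dir, "curation_rejections.csv")

  # --- structures ----------------------------------------------------------
  ca <- canonicalize_audit(cur$compounds$smiles)
  valid <- !is.na(ca$canonical)
  tab <- data.frame(canonical_smiles = ca$canonical[valid],
                    pic50 = cur$compounds$pactivity[valid],
                    label = cur$compounds$label[valid],
                    compound_id = cur$compounds$compound_id[valid],
                    n_records = cur$compounds$n_records[valid],
                    stringsAsFactors = FALSE)
  dd <- deduplicate_structures(tab, aux_numeric = "n_records")
  compounds <- dd$compounds
  compounds$scaffold <- murcko_scaffold(compounds$canonical_smiles)
  desc <- compute_descriptors(compounds$canonical_smiles)
  compounds <- cbind(compounds, desc)
  .write_csv(ca$audit, out_dir, "structure_audit.csv")
  .write_csv(compounds, out_dir, "compounds_dedup.csv")

  X <- fingerprint_matrix(compounds$canonical_smiles, params)
  y <- as.integer(compounds$label == "positive")

  # --- splits, models, evaluation -----------------------------------------
  groups <- group_by_scaffold(data.frame(compound_id = compounds$compound_id,
                                         scaffold = compounds$scaffold))
  splits <- list(); models <- list(); evals <- list()
  thresholds <- list(); calibrations <- list()
  for (sd in seeds) {
    sp <- assign_split(groups, seed = sd)
    splits[[as.character(sd)]] <- sp
    sub <- sp$assignments$subset[match(compounds$compound_id,
                                       sp$assignments$compound_id)]
    tv <- sub %in% c("train", "val")
    te <- sub == "test"
    model <- if (tune) {
      tune_and_fit(X[tv, , drop = FALSE], y[tv],
                   model_config(family, seed = sd))
    } else {
      fit_model(X[tv, , drop = FALSE], y[tv], family, seed = sd)
    }
    models[[as.character(sd)]] <- model
    oof <- oof_predict(X[tv, , drop = FALSE], y[tv], family,
                       params = model$params, seed = sd)
    test_prob <- if (any(te)) predict_prob(model, X[te, , drop = FALSE])
                 else numeric(0)
    ev_oof <- evaluate_predictions(oof, y[tv])
    ev_te <- if (any(te)) evaluate_predictions(test_prob, y[te]) else NULL
    evals[[as.character(sd)]] <- data.frame(
      model = family, seed = sd,
      oof_auc = ev_oof$auc, oof_ap = ev_oof$ap,
      test_auc = ev_te$auc %||% NA_real_, test_ap = ev_te$ap %||% NA_real_,
      mcc = ev_te$mcc %||% NA_real_,
      balanced_accuracy = ev_te$balanced_accuracy %||% NA_real_)
    calibrations[[as.character(sd)]] <- list(
      oof = calibrate(oof, y[tv]),
      test = if (any(te)) calibrate(test_prob, y[te]) else NULL)
    thresholds[[as.character(sd)]] <- select_threshold(
      oof, y[tv], "mcc", test_prob, if (any(te)) y[te] else NULL)
    exp_tab <- data.frame(compound_id = compounds$compound_id,
                          canonical_smiles = compounds$canonical_smiles,
                          label = compounds$label,
                          scaffold = compounds$scaffold,
                          subset = sub, seed = sd)
    .write_csv(exp_tab, out_dir, sprintf("split_seed%d.csv", sd))
  }
  eval_tab <- do.call(rbind, evals)
  rownames(eval_tab) <- NULL
  agg <- aggregate_seeds(eval_tab)
  .write_csv(eval_tab, out_dir, "evaluations.csv")
  .write_csv(agg, out_dir, "aggregate_metrics.csv")

  # --- screening -----------------------------------------------------------
  raw_lib <- generate_screening_library(spec, n_library = n_library)
  prep <- prepare_screening_library(raw_lib, keep_largest = TRUE)
  lib_fp <- fingerprint_matrix(prep$library$canonical_smiles, params)
  scores <- ensemble_score(models, lib_fp, prep$library$public_id,
                           expected_fp_hash = params$hash)
  sp1 <- splits[[as.character(seeds[1])]]
  sub1 <- sp1$assignments$subset[match(compounds$compound_id,
                                       sp1$assignments$compound_id)]
  ref_fp <- X[sub1 %in% c("train", "val"), , drop = FALSE]
  scores <- ad_annotate(scores, lib_fp, prep$library$public_id, ref_fp)
  scores$name <- prep$library$name[match(scores$public_id,
                                         prep$library$public_id)]
  scores$canonical_smiles <- prep$library$canonical_smiles[
    match(scores$public_id, prep$library$public_id)]
  top <- select_top(scores, min(top_n, nrow(scores)))
  cand <- top[top$in_domain, , drop = FALSE]
  selection <- if (nrow(cand) > 0L) {
    cf <- lib_fp[match(cand$public_id, prep$library$public_id), ,
                 drop = FALSE]
    butina_select(cf, cand, cand$public_id, cutoff = 0.35,
                  shortlist_n = shortlist_n)
  } else NULL
  .write_csv(prep$library, out_dir, "screening_library.csv")
  .write_csv(scores, out_dir, "screening_scores.csv")
  .write_csv(top, out_dir, "screening_top.csv")
  if (!is.null(selection)) {
    .write_csv(selection$shortlist, out_dir, "shortlist.csv")
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    files <- sort(list.files(out_dir, pattern = "\\.csv$"))
    manifest <- data.frame(
      file = files,
      sha256 = vapply(file.path(out_dir, files), file_checksum, character(1)),
      stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", pretty = TRUE)
  }

  list(compounds = compounds, splits = splits,
       split_summaries = lapply(splits, summarize_split,
                                labels = compounds[, c("compound_id", "label")]),
       models = models, evaluations = eval_tab, aggregate = agg,
       thresholds = thresholds, calibrations = calibrations,
       library = prep$library, scores = scores, top = top,
       selection = selection, fp_params = params, fingerprints = X,
       labels = y, manifest = manifest)
}
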