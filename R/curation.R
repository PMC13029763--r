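#' Curation configuration
#'
#' Filtering and labeling settings for raw activity records. Defaults follow
#' common public-database curation practice: concentration assay types, nM/uM
#' units, assay confidence >= 7, exact relations only, and an inclusive
#' pActivity >= 6.0 labeling threshold (1 uM). Labeling uses IC50-derived
#' records only; other assay types survive filtering but are excluded from
#' label aggregation via `label_stage_type`.
#'
#' @param allowed_types assay types retained by the record filter.
#' @param allowed_units concentration units retained.
#' @param min_confidence minimum assay confidence score.
#' @param aggregation per-compound aggregation: "max" (default), "mean" or
#'   "median".
#' @param pactivity_threshold label threshold in log10 units (inclusive).
#' @param label_stage_type assay type whose records feed labeling.
#' @return list of class `ns_curation_config`.
#' @export
curation_config <- function(allowed_types = c("IC50", "Ki", "Kd", "EC50"),
                            allowed_units = c("nM", "uM"),
                            min_confidence = 7L,
                            aggregation = c("max", "mean", "median"),
                            pactivity_threshold = 6.0,
                            label_stage_type = "IC50") {
  aggregation <- match.arg(aggregation)
  stopifnot(is.finite(pactivity_threshold))
  cfg <- list(allowed_types = allowed_types, allowed_units = allowed_units,
              min_confidence = as.integer(min_confidence),
              aggregation = aggregation,
              pactivity_threshold = pactivity_threshold,
              label_stage_type = label_stage_type)
  class(cfg) <- "ns_curation_config"
  cfg
}

.record_cols <- c("compound_id", "smiles", "assay_type", "relation", "value",
                  "unit", "confidence", "standardization_flag")

#' Filter raw activity records
#'
#' Applies the full predicate set and logs one rejection reason per dropped
#' row, using first-failing-predicate order: type, unit, confidence, value,
#' relation, smiles, flag.
#'
#' @param records data.frame with the activity-record columns (`compound_id`,
#'   `smiles`, `assay_type`, `relation`, `value`, `unit`, `confidence`,
#'   `standardization_flag`).
#' @param config a [curation_config()].
#' @return list with `retained` (subset of `records`) and `rejected`
#'   (`records` rows plus a `reason` column). Retained and rejected rows are
#'   disjoint and jointly exhaust the input.
#' @export
filter_records <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "ns_curation_config"))
  miss <- setdiff(.record_cols, names(records))
  if (length(miss) > 0L) {
    stop("missing required columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  fail <- function(cond, why) {
    hit <- is.na(reason) & cond
    reason[hit] <<- why
  }
  fail(!(records$assay_type %in% config$allowed_types), "type")
  fail(!(records$unit %in% config$allowed_units), "unit")
  fail(is.na(records$confidence) |
         records$confidence < config$min_confidence, "confidence")
  fail(is.na(suppressWarnings(as.numeric(records$value))) |
         suppressWarnings(as.numeric(records$value)) <= 0, "value")
  fail(records$relation != "=", "relation")
  fail(is.na(records$smiles) | !nzchar(records$smiles), "smiles")
  fail(!(records$standardization_flag %in% c("validated", "unassigned")),
       "flag")
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Standardize a concentration to nanomolar
#'
#' @param value positive concentration value(s).
#' @param unit "nM" or "uM" (recycled against `value`).
#' @return value in nM; uM inputs are multiplied by exactly 1000.
#' @export
standardize_to_nM <- function(value, unit) {
  if (any(!unit %in% c("nM", "uM"))) {
    stop("unknown unit: ", paste(unique(setdiff(unit, c("nM", "uM"))), collapse = ", "))
  }
  if (any(value <= 0)) stop("non-positive concentration")
  ifelse(unit == "uM", value * 1000, value)
}

#' pActivity transform
#'
#' Negative base-10 logarithm of the molar concentration:
#' `9 - log10(value_nM)`. 1000 nM maps exactly to 6.0.
#'
#' @param value_nM positive finite concentration(s) in nM.
#' @return pActivity in log10 units.
#' @export
to_pactivity <- function(value_nM) {
  if (any(!is.finite(value_nM)) || any(value_nM <= 0)) {
    stop("value_nM must be positive and finite")
  }
  9 - log10(value_nM)
}

#' Aggregate per-compound pActivity and assign labels
#'
#' One row per compound: aggregated pActivity (max by default, the most
#' favourable reported interaction), binary label (positive iff aggregate >=
#' threshold, inclusive), and the contributing record count.
#'
#' @param records data.frame with `compound_id`, `pactivity` and (optionally)
#'   `smiles` columns; all pactivity values must be finite.
#' @param config a [curation_config()].
#' @return data.frame with `compound_id`, `smiles` (if supplied), `pactivity`,
#'   `label` ("positive"/"negative") and `n_records`.
#' @export
aggregate_and_label <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "ns_curation_config"))
  if (!all(c("compound_id", "pactivity") %in% names(records))) {
    stop("records must carry compound_id and pactivity")
  }
  if (any(!is.finite(records$pactivity))) stop("non-finite pactivity")
  f <- switch(config$aggregation, max = max, mean = mean, median = stats::median)
  ids <- unique(records$compound_id)
  agg <- vapply(ids, function(id) {
    f(records$pactivity[records$compound_id == id])
  }, numeric(1))
  nrec <- vapply(ids, function(id) sum(records$compound_id == id), integer(1))
  out <- data.frame(compound_id = ids, pactivity = unname(agg),
                    label = ifelse(agg >= config$pactivity_threshold,
                                   "positive", "negative"),
                    n_records = unname(nrec), stringsAsFactors = FALSE)
  if ("smiles" %in% names(records)) {
    out$smiles <- records$smiles[match(ids, records$compound_id)]
    out <- out[, c("compound_id", "smiles", "pactivity", "label", "n_records")]
  }
  rownames(out) <- NULL
  out
}

#' Run the full record-level curation stage
#'
#' Filters records, restricts to the labeling assay type, converts to nM,
#' transforms to pActivity, aggregates per compound and assigns labels.
#'
#' @param records raw activity-record table.
#' @param config a [curation_config()].
#' @return list with `compounds` (labeled per-compound table), `retained`,
#'   `rejected` (the filter log) and `label_records` (the per-record
#'   IC50-stage table with pactivity).
#' @export
curate_records <- function(records, config = curation_config()) {
  flt <- filter_records(records, config)
  lab <- flt$retained[flt$retained$assay_type == config$label_stage_type, ,
                      drop = FALSE]
  if (nrow(lab) > 0L) {
    lab$value_nM <- standardize_to_nM(as.numeric(lab$value), lab$unit)
    lab$pactivity <- to_pactivity(lab$value_nM)
  } else {
    lab$value_nM <- numeric(0)
    lab$pactivity <- numeric(0)
  }
  compounds <- aggregate_and_label(lab, config)
  list(compounds = compounds, retained = flt$retained,
       rejected = flt$rejected, label_records = lab)
}
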