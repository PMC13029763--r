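#' Canonicalize SMILES with failure auditing
#'
#' Wraps [canonical_smiles()] and returns, alongside the canonical strings, a
#' structure audit with one row per failed input (`row_index`, `input_smiles`,
#' `failure_category`). Failures are values, not exceptions, so whole-table
#' audits can continue.
#'
#' @param smiles character vector.
#' @return list with `canonical` (character, `NA` on failure) and `audit`
#'   data.frame. Categories: `parse_error` (unparsable or blank input),
#'   `empty_after_fragment_keep` (canonicalization returned no structure).
#' @export
canonicalize_audit <- function(smiles) {
  can <- canonical_smiles(smiles)
  bad <- which(is.na(can))
  cat_for <- function(i) {
    if (is.na(smiles[i]) || !nzchar(trimws(smiles[i]))) "parse_error"
    else if (is.na(can[i])) "parse_error" else "empty_after_fragment_keep"
  }
  audit <- data.frame(row_index = bad,
                      input_smiles = smiles[bad],
                      failure_category = vapply(bad, cat_for, character(1)),
                      stringsAsFactors = FALSE)
  list(canonical = can, audit = audit)
}

#' Keep the largest fragment of a multi-fragment SMILES
#'
#' Retains the fragment with the most heavy atoms; ties are broken by taking
#' the fragment whose canonical SMILES sorts first lexicographically, making
#' the result independent of fragment order.
#'
#' @param smiles character vector (multi- or single-fragment).
#' @return canonical SMILES of the kept fragment, `NA` where input fails.
#' @export
keep_largest_fragment <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0L) return(NA_character_)
    can <- canonical_smiles(frags)
    if (anyNA(can)) return(NA_character_)
    mbs <- smiles_to_molblock(can)
    if (anyNA(mbs)) return(NA_character_)
    hv <- vapply(mbs, function(mb) heavy_atom_count(parse_molblock(mb)),
                 numeric(1))
    ord <- order(-hv, can)
    can[ord[1]]
  }, character(1), USE.NAMES = FALSE)
}

#' Deduplicate compounds at the canonical-structure level
#'
#' Merges rows sharing a canonical SMILES under fixed rules: pIC50 = maximum
#' over sources, label = positive if any source is positive, auxiliary
#' numeric columns = median, non-numeric columns inherited from the first
#' source row in input order; `n_source_records` counts contributors.
#'
#' @param tab data.frame with `canonical_smiles`, `pic50`, `label` plus any
#'   auxiliary columns.
#' @param aux_numeric names of numeric columns to median-aggregate.
#' @return list with `compounds` (one row per canonical structure, input
#'   first-occurrence order) and `audit` (machine-readable settings echo and
#'   input/output counts).
#' @export
deduplicate_structures <- function(tab, aux_numeric = NULL) {
  need <- c("canonical_smiles", "pic50", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("missing columns: ", paste(miss, collapse = ", "))
  aux_numeric <- intersect(aux_numeric %||% character(0), names(tab))
  keys <- unique(tab$canonical_smiles)
  rows <- lapply(keys, function(k) {
    src <- tab[tab$canonical_smiles == k, , drop = FALSE]
    rep_row <- src[1, , drop = FALSE]
    rep_row$pic50 <- max(src$pic50)
    rep_row$label <- if (any(src$label == "positive")) "positive" else "negative"
    for (a in aux_numeric) rep_row[[a]] <- stats::median(src[[a]])
    rep_row$n_source_records <- nrow(src)
    rep_row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  audit <- list(
    n_input = nrow(tab), n_output = nrow(out),
    n_duplicate_rows = nrow(tab) - nrow(out),
    n_positive_in = sum(tab$label == "positive"),
    n_positive_out = sum(out$label == "positive"),
    settings = list(pic50 = "max", label = "any-positive",
                    aux_numeric = "median", representative = "first-in-order",
                    aux_columns = aux_numeric)
  )
  list(compounds = out, audit = audit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepare a screening library
#'
#' Canonicalizes structures (optionally keeping only the largest fragment
#' first), drops and logs invalid rows, assigns stable public identifiers
#' ("FDB"-style, zero-padded to 6 digits, when no id column is supplied) and
#' keeps the first occurrence of each canonical SMILES. Re-running on its own
#' output is the identity.
#'
#' @param raw data.frame with a `smiles` column; `id` and `name` optional.
#' @param keep_largest drop counterions/mixture partners by heavy-atom count.
#' @return list with `library` (data.frame `public_id`, `name`,
#'   `canonical_smiles`), `dropped` (audit log of removed rows with reasons)
#'   and `audit` (counts + settings echo).
#' @export
prepare_screening_library <- function(raw, keep_largest = TRUE) {
  if (!"smiles" %in% names(raw)) stop("raw table must have a smiles column")
  n <- nrow(raw)
  ids <- if ("id" %in% names(raw)) as.character(raw$id)
         else sprintf("FDB%06d", seq_len(n))
  nm <- if ("name" %in% names(raw)) as.character(raw$name) else ids
  smi <- as.character(raw$smiles)
  can <- if (keep_largest) keep_largest_fragment(smi) else canonical_smiles(smi)
  bad <- is.na(can)
  dup <- !bad & duplicated(can)
  keep <- !bad & !dup
  dropped <- data.frame(
    row_index = which(!keep), public_id = ids[!keep],
    input_smiles = smi[!keep],
    reason = ifelse(bad[!keep], "invalid_structure", "duplicate_structure"),
    stringsAsFactors = FALSE
  )
  lib <- data.frame(public_id = ids[keep], name = nm[keep],
                    canonical_smiles = can[keep], stringsAsFactors = FALSE)
  rownames(lib) <- NULL
  audit <- list(n_input = n, n_output = nrow(lib),
                n_invalid = sum(bad), n_duplicate = sum(dup),
                settings = list(keep_largest = keep_largest,
                                dedup = "first-occurrence",
                                id_style = "FDB-6-digit-when-missing"))
  list(library = lib, dropped = dropped, audit = audit)
}

#' SHA-256 checksum of a file
#' @param path file path.
#' @return lowercase hex digest string.
#' @export
file_checksum <- function(path) {
  digest::digest(file = path, algo = "sha256")
}
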