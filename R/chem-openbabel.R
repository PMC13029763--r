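#' @useDynLib nutrascreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# OpenBabel conversion stops emitting output at the first unparsable record.
# All batch helpers below therefore tag every input with a synthetic title,
# align the echoed titles against the inputs, mark the first unmatched row as
# failed and resume conversion after it.

.ob_tag <- function(n) sprintf("nsx%07d", seq_len(n))

# Rows containing whitespace or empty strings never reach OpenBabel: the
# SMI reader would mis-split them.
.ob_prescreen <- function(smiles) {
  !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
}

.ob_batch <- function(smiles, to) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  ok <- .ob_prescreen(smiles)
  idx <- which(ok)
  tags <- .ob_tag(n)
  sep <- if (to == "SDF") "\\${4}\n?" else "\n"
  while (length(idx) > 0L) {
    inp <- paste0(smiles[idx], "\t", tags[idx], "\n", collapse = "")
    res <- suppressWarnings(ChemmineOB::convertFormat("SMI", to, inp))
    pieces <- if (nzchar(res)) strsplit(res, sep)[[1]] else character(0)
    pieces <- pieces[nzchar(trimws(pieces))]
    k <- 0L
    for (p in pieces) {
      title <- if (to == "SDF") {
        trimws(strsplit(p, "\n", fixed = TRUE)[[1]][1])
      } else {
        f <- strsplit(trimws(p), "\t", fixed = TRUE)[[1]]
        if (length(f) >= 2L) f[2] else ""
      }
      if (k + 1L <= length(idx) && identical(title, tags[idx[k + 1L]])) {
        k <- k + 1L
        out[idx[k]] <- p
      } else {
        break # misalignment: stop trusting this batch, re-run the tail
      }
    }
    if (k == length(idx)) break
    # row k+1 failed to convert; skip it and resume
    idx <- idx[-seq_len(k + 1L)]
  }
  out
}

#' Canonical isomeric SMILES
#'
#' Converts SMILES strings to OpenBabel canonical isomeric SMILES. The result
#' is a fixed point: canonicalizing a canonical string returns it unchanged.
#' Unparsable inputs yield `NA` rather than an error so that structure audits
#' can continue over a whole table.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' \dontrun{
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1")) # identical output
#' }
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  raw <- .ob_batch(smiles, "CAN")
  out <- rep(NA_character_, length(smiles))
  got <- !is.na(raw)
  out[got] <- vapply(raw[got], function(p) {
    strsplit(trimws(p), "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

# SMILES -> V2000 molblock text (one per input, NA on failure).
smiles_to_molblock <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  .ob_batch(smiles, "SDF")
}

# molblock text -> canonical SMILES (single structure; NA on failure).
molblock_to_smiles <- function(molblock) {
  res <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("MOL", "CAN", molblock)),
    error = function(e) ""
  )
  if (!nzchar(res)) return(NA_character_)
  s <- strsplit(trimws(res), "[\t\n]")[[1]][1]
  if (!nzchar(s)) NA_character_ else s
}

# Bulk physicochemical properties from OpenBabel (MW, logP, HBD, HBA, TPSA).
# Returns a data.frame aligned with `smiles`; NA rows where parsing failed.
ob_properties <- function(smiles) {
  n <- length(smiles)
  cols <- c("MW", "logP", "HBD", "HBA2", "TPSA")
  out <- as.data.frame(matrix(NA_real_, n, length(cols)))
  names(out) <- cols
  ok <- which(.ob_prescreen(smiles))
  if (length(ok) == 0L) return(out)
  for (i in ok) {
    p <- tryCatch(
      ChemmineOB::forEachMol("SMILES", paste0(smiles[i], "\tm\n"),
                             function(m) ChemmineOB::prop_OB(m)),
      error = function(e) NULL
    )
    if (is.list(p) && length(p) >= 1L && is.data.frame(p[[1]])) {
      d <- p[[1]]
      for (cl in cols) if (cl %in% names(d)) out[i, cl] <- as.numeric(d[1, cl])
    }
  }
  out
}
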