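# Synthetic activity-record and screening-library generator. Emulates the
# regime of a public bioactivity extract (mixed nM/uM units, inexact
# relations, replicates, salts, unparsable rows) and a food-compound library
# (decoy chemotypes, duplicates), with known ground truth: every compound is
# a ring-system core from a fixed catalogue plus two pool substituents whose
# planted effects shift a latent pActivity.

.ns_cache <- new.env(parent = emptyenv())

#' Run code under a private, restored RNG state
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`; the caller's RNG state is left untouched.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.paren <- function(x) ifelse(nzchar(x), paste0("(", x, ")"), "")

# one-slot chain units: sprintf(fmt, ring_digit, branch_slot)
.chain_units <- c(
  benzene    = "c%1$dccc%2$scc%1$d",
  pyridine_a = "c%1$dccc%2$scn%1$d",
  pyridine_b = "c%1$dccc%2$snc%1$d",
  pyrimidine = "c%1$dncc%2$scn%1$d",
  thiophene  = "c%1$dcc%2$scs%1$d",
  furan      = "c%1$dcc%2$sco%1$d",
  nmepyrrole = "c%1$dcc%2$scn%1$dC",
  thiazole   = "c%1$dncc%2$ss%1$d"
)

# two-slot head units: sprintf(fmt, ring_digit, R1_slot, suffix)
.head_units <- c(
  benzene    = "c%1$dcc%2$sccc%1$d%3$s",
  pyridine   = "c%1$dcc%2$scnc%1$d%3$s",
  pyrimidine = "c%1$dnc%2$sncc%1$d%3$s",
  thiophene  = "c%1$dsc%2$scc%1$d%3$s",
  furan      = "c%1$doc%2$scc%1$d%3$s"
)

# assemble a core SMILES from a head unit plus 0..3 chained units, with R1 on
# the head ring and R2 on the terminal ring
.core_smiles <- function(head, chain, r1, r2) {
  if (length(chain) == 0L) {
    return(sprintf(.head_units[head], 1L, .paren(r1), r2))
  }
  d <- length(chain) + 1L
  inner <- sprintf(.chain_units[chain[length(chain)]], d, .paren(r2))
  if (length(chain) > 1L) {
    for (k in rev(seq_len(length(chain) - 1L))) {
      inner <- sprintf(.chain_units[chain[k]], k + 1L, .paren(paste0("-", inner)))
    }
  }
  sprintf(.head_units[head], 1L, .paren(r1), paste0("-", inner))
}

#' Catalogue of distinct scaffold-family cores
#'
#' Deterministically enumerates ring-system cores (a head ring optionally
#' chained to further rings), canonicalizes the bare cores and keeps the first
#' `n` with pairwise-distinct canonical scaffolds. Each core exposes two
#' substitution positions (R1 on the head ring, R2 on the terminal ring).
#'
#' @param n number of distinct families required.
#' @return data.frame with `head`, `chain` (list column), `scaffold_smiles`.
#' @export
core_catalog <- function(n) {
  stopifnot(n >= 1L)
  key <- paste0("cores", n)
  if (!is.null(.ns_cache[[key]])) return(.ns_cache[[key]])
  heads <- names(.head_units)
  units <- names(.chain_units)
  combos <- list()
  for (len in 0:3) {
    tails <- if (len == 0L) list(character(0)) else {
      grid <- do.call(expand.grid,
                      c(rep(list(units), len), stringsAsFactors = FALSE))
      grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
      lapply(seq_len(nrow(grid)), function(i) as.character(grid[i, ]))
    }
    for (h in heads) for (tl in tails) combos[[length(combos) + 1L]] <- list(h, tl)
    if (length(combos) >= 4L * n + 20L) break
  }
  bare <- vapply(combos, function(x) .core_smiles(x[[1]], x[[2]], "", ""),
                 character(1))
  # the family key is the Murcko scaffold of the bare core (ring-appended
  # methyls such as an N-methyl are themselves side chains)
  can <- rep(NA_character_, length(bare))
  ok <- !is.na(canonical_smiles(bare))
  can[ok] <- murcko_scaffold(bare[ok])
  keep <- !is.na(can) & nzchar(can) & !duplicated(can)
  combos <- combos[keep]
  can <- can[keep]
  if (length(combos) < n) stop("core catalogue cannot supply ", n, " families")
  out <- data.frame(scaffold_smiles = can[seq_len(n)], stringsAsFactors = FALSE)
  out$head <- vapply(combos[seq_len(n)], `[[`, character(1), 1L)
  out$chain <- lapply(combos[seq_len(n)], `[[`, 2L)
  .ns_cache[[key]] <- out
  out
}

#' Default substituent pool
#'
#' Acyclic branch fragments (SMILES written in branch form) attachable at the
#' R1/R2 positions; `""` denotes hydrogen. Acyclic fragments leave the
#' Bemis-Murcko scaffold of each family unchanged.
#' @return named character vector of fragments.
#' @export
default_substituents <- function() {
  c(H = "", methyl = "C", hydroxy = "O", methoxy = "OC", fluoro = "F",
    chloro = "Cl", amino = "N", dimethylamino = "N(C)C",
    trifluoromethyl = "C(F)(F)F", carboxyl = "C(=O)O",
    carboxamide = "C(=O)N", sulfonamide = "S(=O)(=O)N")
}

#' Default planted substituent effects (log10 units on latent pActivity)
#' @return named numeric vector keyed by substituent fragment SMILES.
#' @export
default_motif_effects <- function() {
  c("S(=O)(=O)N" = 1.5, "C(=O)N" = 0.8, "C(=O)O" = -0.7)
}

.invalid_smiles_pool <- c("notasmiles", "C1CC", "xx##yy", "C1CC1C1", "c1ccc1q", "[Qq]")

#' Specification of a synthetic study
#'
#' Fixes every stochastic element of the generated bioactivity table and
#' screening library. An identical spec (including `seed`) yields
#' byte-identical output tables.
#'
#' @param n_compounds number of parent compounds.
#' @param n_scaffold_families number of distinct Murcko scaffold families.
#' @param substituent_pool named character vector of branch fragments.
#' @param motif_effects named numeric, fragment -> latent pActivity shift.
#' @param base_pactivity baseline latent pActivity (log10 units).
#' @param noise_sd Gaussian assay noise SD (log10 units), applied once to the
#'   compound latent value and once per record.
#' @param micromolar_fraction proportion of records reported in uM.
#' @param replicate_rate Poisson mean of extra records per compound.
#' @param inexact_relation_rate proportion of records with relation ">".
#' @param invalid_smiles_rate proportion of records with unparsable SMILES.
#' @param salt_rate proportion of records emitted as hydrochloride salts.
#' @param seed integer RNG seed.
#' @return validated list of class `ns_synth_spec`.
#' @export
synthetic_spec <- function(n_compounds = 2000L, n_scaffold_families = 60L,
                           substituent_pool = default_substituents(),
                           motif_effects = default_motif_effects(),
                           base_pactivity = 5.2, noise_sd = 0.3,
                           micromolar_fraction = 0.3, replicate_rate = 0.4,
                           inexact_relation_rate = 0.05,
                           invalid_smiles_rate = 0.02, salt_rate = 0.05,
                           seed = 1L) {
  spec <- list(n_compounds = as.integer(n_compounds),
               n_scaffold_families = as.integer(n_scaffold_families),
               substituent_pool = substituent_pool,
               motif_effects = motif_effects,
               base_pactivity = base_pactivity, noise_sd = noise_sd,
               micromolar_fraction = micromolar_fraction,
               replicate_rate = replicate_rate,
               inexact_relation_rate = inexact_relation_rate,
               invalid_smiles_rate = invalid_smiles_rate,
               salt_rate = salt_rate, seed = as.integer(seed))
  props <- c("micromolar_fraction", "inexact_relation_rate",
             "invalid_smiles_rate", "salt_rate")
  for (p in props) {
    v <- spec[[p]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(p, " must be in [0,1]")
  }
  if (spec$n_compounds < 1L) stop("n_compounds must be positive")
  if (spec$n_scaffold_families < 1L) stop("n_scaffold_families must be positive")
  if (length(spec$substituent_pool) == 0L) stop("empty substituent pool")
  if (spec$noise_sd < 0 || spec$replicate_rate < 0) stop("negative rate")
  class(spec) <- "ns_synth_spec"
  spec
}

.gen_compounds <- function(spec) {
  cores <- core_catalog(spec$n_scaffold_families)
  n <- spec$n_compounds
  fam <- rep_len(seq_len(spec$n_scaffold_families), n)
  pool <- spec$substituent_pool
  i1 <- sample.int(length(pool), n, replace = TRUE)
  i2 <- sample.int(length(pool), n, replace = TRUE)
  r1 <- unname(pool[i1]); r2 <- unname(pool[i2])
  smi <- vapply(seq_len(n), function(i) {
    .core_smiles(cores$head[fam[i]], cores$chain[[fam[i]]], r1[i], r2[i])
  }, character(1))
  eff <- function(fr) {
    v <- spec$motif_effects[fr]
    ifelse(is.na(v), 0, v)
  }
  latent <- spec$base_pactivity + eff(r1) + eff(r2) +
    stats::rnorm(n, 0, spec$noise_sd)
  motifs <- vapply(seq_len(n), function(i) {
    m <- intersect(unique(c(r1[i], r2[i])), names(spec$motif_effects))
    paste(sort(m), collapse = ";")
  }, character(1))
  data.frame(compound_id = sprintf("SYN%05d", seq_len(n)), smiles = smi,
             family = fam, scaffold_smiles = cores$scaffold_smiles[fam],
             r1 = r1, r2 = r2, latent_pactivity = latent,
             planted_motifs = motifs, stringsAsFactors = FALSE)
}

#' Generate a synthetic activity-record table with ground truth
#'
#' Compounds are cores plus substituents; each record reports
#' `IC50 = 10^(9 - (latent +/- record noise))` in nM, with a fraction
#' converted to uM. Replicates, inexact relations, invalid SMILES and salt
#' forms are injected at the spec rates and flagged in the output
#' (`inj_invalid`, `inj_salt`). Draw order under the single seed stream:
#' substituents, latent noise, replicate counts, then per-record noise, unit,
#' relation, assay type, confidence, flag, year, salt, invalid.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (activity table) and `truth` (one row per
#'   generated compound: id, smiles, family, scaffold, latent pActivity,
#'   planted motifs).
#' @export
generate_activity_table <- function(spec) {
  stopifnot(inherits(spec, "ns_synth_spec"))
  with_seed(spec$seed, {
    cmp <- .gen_compounds(spec)
    n_rec <- 1L + stats::rpois(nrow(cmp), spec$replicate_rate)
    idx <- rep(seq_len(nrow(cmp)), n_rec)
    m <- length(idx)
    p_obs <- cmp$latent_pactivity[idx] + stats::rnorm(m, 0, spec$noise_sd)
    value_nm <- 10^(9 - p_obs)
    uM <- stats::runif(m) < spec$micromolar_fraction
    value <- ifelse(uM, value_nm / 1000, value_nm)
    unit <- ifelse(uM, "uM", "nM")
    relation <- ifelse(stats::runif(m) < spec$inexact_relation_rate, ">", "=")
    assay_type <- sample(c("IC50", "Ki", "Kd", "EC50"), m, replace = TRUE,
                         prob = c(0.8, 0.1, 0.05, 0.05))
    confidence <- sample(c(5L, 6L, 7L, 8L, 9L), m, replace = TRUE,
                         prob = c(0.05, 0.05, 0.1, 0.3, 0.5))
    flag <- sample(c("validated", "unassigned", "other"), m, replace = TRUE,
                   prob = c(0.7, 0.25, 0.05))
    year <- sample(2000:2023, m, replace = TRUE)
    salt <- stats::runif(m) < spec$salt_rate
    invalid <- stats::runif(m) < spec$invalid_smiles_rate
    smiles <- cmp$smiles[idx]
    smiles[salt] <- paste0(smiles[salt], ".Cl")
    if (any(invalid)) {
      smiles[invalid] <- rep_len(.invalid_smiles_pool, sum(invalid))
    }
    records <- data.frame(
      compound_id = cmp$compound_id[idx], smiles = smiles,
      assay_type = assay_type, relation = relation, value = value,
      unit = unit, confidence = confidence, standardization_flag = flag,
      year = year, inj_invalid = invalid, inj_salt = salt & !invalid,
      stringsAsFactors = FALSE
    )
    list(records = records, truth = cmp)
  })
}

# deterministic aliphatic decoy chemotypes (far from the aromatic cores)
.decoy_smiles <- function(n) {
  caps <- c("O", "N", "C(=O)O", "C(=O)OC", "OC(=O)C", "C(=O)N", "CO")
  len <- 5L + (seq_len(n) %% 8L)
  cap <- caps[1L + (seq_len(n) %% length(caps))]
  branch <- ifelse(seq_len(n) %% 3L == 0L, "C(C)", "C")
  vapply(seq_len(n), function(i) {
    paste0(paste(rep(branch[i], len[i]), collapse = ""), cap[i])
  }, character(1))
}

#' Generate a synthetic screening library
#'
#' Mixes in-family compounds (same scaffold cores and substituent pool as the
#' activity table, fresh combinations) with out-of-family aliphatic decoy
#' chemotypes, plus duplicates, salts and invalid rows at the stated rates.
#' Seeded from `spec$seed` offset by a fixed constant so library and training
#' draws do not overlap.
#'
#' @param spec a [synthetic_spec()].
#' @param n_library number of library rows before defect injection.
#' @param decoy_fraction proportion of out-of-family decoys.
#' @param duplicate_rate proportion of rows duplicated verbatim (at least one
#'   duplicate whenever the rate is positive and the library has >= 2 rows).
#' @return data.frame with `id` ("FDB"-prefixed, zero-padded), `name`,
#'   `smiles`, plus a logical `is_decoy` ground-truth column.
#' @export
generate_screening_library <- function(spec, n_library = 1500L,
                                       decoy_fraction = 0.4,
                                       duplicate_rate = 0.02) {
  stopifnot(inherits(spec, "ns_synth_spec"))
  if (decoy_fraction < 0 || decoy_fraction > 1) stop("decoy_fraction in [0,1]")
  if (duplicate_rate < 0 || duplicate_rate > 1) stop("duplicate_rate in [0,1]")
  with_seed(spec$seed + 104729L, {
    n <- as.integer(n_library)
    n_dec <- round(n * decoy_fraction)
    n_fam <- n - n_dec
    cores <- core_catalog(spec$n_scaffold_families)
    pool <- spec$substituent_pool
    fam <- sample.int(spec$n_scaffold_families, n_fam, replace = TRUE)
    r1 <- unname(pool[sample.int(length(pool), n_fam, replace = TRUE)])
    r2 <- unname(pool[sample.int(length(pool), n_fam, replace = TRUE)])
    fam_smi <- vapply(seq_len(n_fam), function(i) {
      .core_smiles(cores$head[fam[i]], cores$chain[[fam[i]]], r1[i], r2[i])
    }, character(1))
    smi <- c(fam_smi, .decoy_smiles(n_dec))
    is_decoy <- c(rep(FALSE, n_fam), rep(TRUE, n_dec))
    ord <- sample.int(n)
    smi <- smi[ord]; is_decoy <- is_decoy[ord]
    dup <- stats::runif(n) < duplicate_rate
    dup[1] <- FALSE
    if (duplicate_rate > 0 && n >= 2L && !any(dup)) dup[2] <- TRUE
    for (i in which(dup)) {
      j <- sample.int(i - 1L, 1L)
      smi[i] <- smi[j]; is_decoy[i] <- is_decoy[j]
    }
    salt <- stats::runif(n) < spec$salt_rate & !dup
    smi[salt] <- paste0(smi[salt], ".Cl")
    invalid <- stats::runif(n) < spec$invalid_smiles_rate & !dup & !salt
    if (any(invalid)) smi[invalid] <- rep_len(.invalid_smiles_pool, sum(invalid))
    data.frame(id = sprintf("FDB%06d", seq_len(n)),
               name = sprintf("synthetic food compound %d", seq_len(n)),
               smiles = smi, is_decoy = is_decoy, stringsAsFactors = FALSE)
  })
}
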