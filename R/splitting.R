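#' Group compounds by Bemis-Murcko scaffold
#'
#' @param compounds data.frame with `compound_id` and `scaffold` columns
#'   (compute scaffolds with [murcko_scaffold()]); the empty scaffold `""`
#'   forms one shared group.
#' @return named list scaffold -> character vector of member compound ids.
#' @export
group_by_scaffold <- function(compounds) {
  stopifnot(all(c("compound_id", "scaffold") %in% names(compounds)))
  split(compounds$compound_id, compounds$scaffold)
}

#' Scaffold-grouped train/validation/test assignment
#'
#' Groups are ranked by size (descending, ties by scaffold string), randomly
#' permuted under the seed, then assigned sequentially: each group goes to
#' the subset whose compound count is currently furthest below its target
#' (ties resolved train > val > test). No group is ever split across subsets.
#'
#' @param groups named list scaffold -> member ids (from
#'   [group_by_scaffold()]).
#' @param fractions target compound fractions for (train, val, test).
#' @param seed integer seed; the permutation is the only stochastic step.
#' @return list of class `ns_split`: `assignments` (data.frame
#'   `compound_id`, `scaffold`, `subset`), `seed`, `fractions`.
#' @export
assign_split <- function(groups, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(groups) == 0L) stop("empty dataset")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))
  groups <- groups[ord]
  perm <- with_seed(seed, sample.int(length(groups)))
  groups <- groups[perm]
  n_total <- sum(lengths(groups))
  targets <- fractions * n_total
  counts <- c(train = 0, val = 0, test = 0)
  subset_of <- character(length(groups))
  for (i in seq_along(groups)) {
    deficit <- targets - counts
    subset_of[i] <- c("train", "val", "test")[which.max(deficit)]
    counts[subset_of[i]] <- counts[subset_of[i]] + length(groups[[i]])
  }
  assignments <- data.frame(
    compound_id = unlist(groups, use.names = FALSE),
    scaffold = rep(names(groups), lengths(groups)),
    subset = rep(subset_of, lengths(groups)),
    stringsAsFactors = FALSE
  )
  rownames(assignments) <- NULL
  out <- list(assignments = assignments, seed = as.integer(seed),
              fractions = fractions)
  class(out) <- "ns_split"
  out
}

#' Summarize a scaffold split
#'
#' @param split an `ns_split` from [assign_split()].
#' @param labels optional data.frame `compound_id`, `label` to count
#'   positives per subset.
#' @return data.frame, one row per subset: `subset`, `n_compounds`,
#'   `n_scaffolds`, `n_positive` (NA when labels absent), `seed`.
#' @export
summarize_split <- function(split, labels = NULL) {
  stopifnot(inherits(split, "ns_split"))
  a <- split$assignments
  subs <- c("train", "val", "test")
  out <- do.call(rbind, lapply(subs, function(s) {
    rows <- a[a$subset == s, , drop = FALSE]
    npos <- NA_integer_
    if (!is.null(labels)) {
      lab <- labels$label[match(rows$compound_id, labels$compound_id)]
      npos <- sum(lab == "positive", na.rm = TRUE)
    }
    data.frame(subset = s, n_compounds = nrow(rows),
               n_scaffolds = length(unique(rows$scaffold)),
               n_positive = npos, seed = split$seed,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
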