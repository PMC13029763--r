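test_that("canonicalization unifies dialects, is idempotent, fails as a value", {
  can <- canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
  expect_identical(can[1], can[2])
  expect_identical(canonical_smiles(can[1]), can[1])
  aud <- canonicalize_audit(c("CCO", "notasmiles", "c1ccccc1"))
  expect_equal(aud$audit$row_index, 2L)
  expect_equal(aud$audit$failure_category, "parse_error")
  expect_false(anyNA(aud$canonical[c(1, 3)]))
})

test_that("largest-fragment keep counts heavy atoms and breaks ties deterministically", {
  expect_identical(keep_largest_fragment("CC(=O)[O-].[Na+]"),
                   canonical_smiles("CC(=O)[O-]"))
  expect_identical(keep_largest_fragment("CCO"), canonical_smiles("CCO"))
  # equal fragments: canonical-sort-first rule, independent of order
  a <- keep_largest_fragment("CCO.OCC")
  b <- keep_largest_fragment("OCC.CCO")
  expect_identical(a, b)
  expect_identical(a, canonical_smiles("CCO"))
  expect_true(is.na(keep_largest_fragment("notasmiles")))
})

test_that("structure dedup applies max-pIC50, OR-label and median-aux rules", {
  tab <- data.frame(
    canonical_smiles = c("A", "A", "A", "B"),
    pic50 = c(5.0, 6.2, 5.5, 4.0),
    label = c("negative", "positive", "negative", "negative"),
    aux = c(1, 2, 100, 7),
    meta = c("first", "second", "third", "only"),
    stringsAsFactors = FALSE)
  dd <- deduplicate_structures(tab, aux_numeric = "aux")
  a <- dd$compounds[dd$compounds$canonical_smiles == "A", ]
  expect_equal(a$pic50, 6.2)
  expect_equal(a$label, "positive")
  expect_equal(a$aux, 2)
  expect_equal(a$meta, "first")     # representative = first source row
  expect_equal(a$n_source_records, 3L)
  expect_equal(dd$compounds$n_source_records[2], 1L)
  expect_equal(dd$audit$n_input, 4L)
  expect_equal(dd$audit$n_output, 2L)
})

test_that("dedup rules hold exhaustively on enumerated two-row tables", {
  vals <- c(4.5, 6.5)
  labs <- c("negative", "positive")
  for (p1 in vals) for (p2 in vals) for (l1 in labs) for (l2 in labs) {
    tab <- data.frame(canonical_smiles = "S", pic50 = c(p1, p2),
                      label = c(l1, l2), stringsAsFactors = FALSE)
    out <- deduplicate_structures(tab)$compounds
    expect_equal(out$pic50, max(p1, p2))
    expect_equal(out$label,
                 if (l1 == "positive" || l2 == "positive") "positive"
                 else "negative")
  }
})

test_that("dedup conserves label mass", {
  gen <- generate_activity_table(tiny_spec())
  cur <- curate_records(gen$records)
  ca <- canonicalize_audit(cur$compounds$smiles)
  ok <- !is.na(ca$canonical)
  tab <- data.frame(canonical_smiles = ca$canonical[ok],
                    pic50 = cur$compounds$pactivity[ok],
                    label = cur$compounds$label[ok])
  dd <- deduplicate_structures(tab)
  expect_lte(sum(dd$compounds$label == "positive"),
             sum(tab$label == "positive"))
  for (k in dd$compounds$canonical_smiles) {
    src_pos <- any(tab$label[tab$canonical_smiles == k] == "positive")
    expect_equal(dd$compounds$label[dd$compounds$canonical_smiles == k] ==
                   "positive", src_pos)
  }
})

test_that("screening-library prep dedups on first occurrence and logs drops", {
  raw <- data.frame(smiles = c("OCC", "CCO", "notasmiles", "CC(=O)O.[Na+]",
                               "CCC"),
                    stringsAsFactors = FALSE)
  prep <- prepare_screening_library(raw)
  expect_equal(nrow(prep$library), 3L) # OCC==CCO dedup, invalid dropped
  expect_equal(prep$library$public_id[1], "FDB000001")
  expect_setequal(prep$dropped$reason,
                  c("invalid_structure", "duplicate_structure"))
  # salt simplified to parent acid
  expect_identical(prep$library$canonical_smiles[2],
                   keep_largest_fragment("CC(=O)O.[Na+]"))
  # conservation: n valid unique structures in -> n entries out
  raw2 <- data.frame(smiles = c("CCO", "CCC", "CCN"))
  expect_equal(nrow(prepare_screening_library(raw2)$library), 3L)
})

test_that("library prep is idempotent on its own output", {
  lib <- generate_screening_library(tiny_spec(), n_library = 80L)
  p1 <- prepare_screening_library(lib)
  again <- data.frame(id = p1$library$public_id, name = p1$library$name,
                      smiles = p1$library$canonical_smiles)
  p2 <- prepare_screening_library(again)
  expect_equal(p2$library$canonical_smiles, p1$library$canonical_smiles)
  expect_equal(p2$library$public_id, p1$library$public_id)
  expect_equal(nrow(p2$dropped), 0L)
})
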