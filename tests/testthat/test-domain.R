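test_that("similarity summaries match an exhaustive double-loop oracle", {
  set.seed(17)
  Q <- matrix(rbinom(20 * 64, 1, 0.25), 20)
  R <- matrix(rbinom(20 * 64, 1, 0.25), 20)
  sim <- similarity_to_reference(Q, R)
  for (i in 1:20) {
    s <- sapply(seq_len(nrow(R)), function(j) {
      inter <- sum(Q[i, ] & R[j, ]); un <- sum(Q[i, ] | R[j, ])
      if (un == 0) 0 else inter / un
    })
    expect_equal(sim$max_sim[i], max(s), tolerance = 1e-12)
    expect_equal(sim$top5_mean[i], mean(sort(s, decreasing = TRUE)[1:5]),
                 tolerance = 1e-12)
    expect_lte(sim$top5_mean[i], sim$max_sim[i])
  }
})

test_that("top-5 mean uses all references when fewer than five exist", {
  Q <- matrix(rbinom(4 * 32, 1, 0.3), 4)
  R <- matrix(rbinom(3 * 32, 1, 0.3), 3)
  sim <- similarity_to_reference(Q, R)
  S <- tanimoto_matrix(Q, R)
  expect_equal(sim$top5_mean, rowMeans(S), tolerance = 1e-12)
  expect_error(similarity_to_reference(Q, R[0, , drop = FALSE]), "empty")
  # identical query/reference compound
  sim2 <- similarity_to_reference(R[1, , drop = FALSE], R)
  expect_equal(sim2$max_sim, 1)
})

test_that("domain boundary is inclusive at 0.35", {
  expect_true(classify_domain(0.35))
  expect_false(classify_domain(0.3499))
  expect_true(classify_domain(1.0))
  expect_false(classify_domain(0))
  x <- runif(500)
  d <- classify_domain(x)
  expect_equal(sum(d) + sum(!d), 500L)   # partition
})

test_that("scaffold frequency bins follow the published edges", {
  ref <- c(rep("A", 6), rep("B", 2), "C", rep("D", 21))
  out <- scaffold_frequency(c("A", "B", "C", "D", "Z"), ref)
  expect_equal(out$count, c(6L, 2L, 1L, 21L, 0L))
  expect_equal(as.character(out$bin),
               c("6-20", "2-5", "1", ">=21", "0 (unseen scaffold)"))
  # empty-scaffold compounds counted like any group
  out2 <- scaffold_frequency(c("", ""), c("", "", ""))
  expect_equal(out2$count, c(3L, 3L))
})

test_that("under scaffold splitting every non-empty test scaffold is unseen", {
  gen <- generate_activity_table(tiny_spec())
  cur <- curate_records(gen$records)
  ca <- canonicalize_audit(cur$compounds$smiles)
  ok <- !is.na(ca$canonical)
  sc <- murcko_scaffold(ca$canonical[ok])
  cmp <- data.frame(compound_id = cur$compounds$compound_id[ok],
                    scaffold = sc, stringsAsFactors = FALSE)
  sp <- assign_split(group_by_scaffold(cmp), seed = 2)
  sub <- sp$assignments$subset[match(cmp$compound_id,
                                     sp$assignments$compound_id)]
  te <- sub == "test" & nzchar(cmp$scaffold)
  if (any(te)) {
    sf <- scaffold_frequency(cmp$scaffold[te],
                             cmp$scaffold[sub %in% c("train", "val")])
    expect_true(all(sf$count == 0L))
  }
})

test_that("similarity bins partition [0,1] with half-open edges", {
  x <- c(0, 0.1999, 0.2, 0.34999, 0.35, 0.4999, 0.5, 0.6999, 0.7, 1)
  b <- nutrascreen:::.similarity_bins(x)
  expect_equal(as.character(b),
               c("0.00-0.20", "0.00-0.20", "0.20-0.35", "0.20-0.35",
                 "0.35-0.50", "0.35-0.50", "0.50-0.70", "0.50-0.70",
                 "0.70-1.00", "0.70-1.00"))
  expect_false(anyNA(b))
})

test_that("stratified metrics degenerate to global metrics in one stratum", {
  set.seed(23)
  n <- 120
  pred <- data.frame(prob = runif(n), label = rbinom(n, 1, 0.5),
                     max_sim = runif(n, 0.71, 0.99))  # all in last bin
  st <- stratify_performance(pred, seed = 1)
  simrows <- st[st$dimension == "similarity", ]
  expect_equal(sum(simrows$n), n)
  glob <- evaluate_predictions(pred$prob, pred$label)
  hit <- simrows[simrows$stratum == "0.70-1.00", ]
  expect_equal(hit$auc, glob$auc)
  expect_equal(hit$mcc, glob$mcc)
})

test_that("one-class strata report NA discrimination but keep MCC/BA", {
  pred <- data.frame(prob = c(0.9, 0.8, 0.2, 0.1),
                     label = c(1, 1, 0, 0),
                     max_sim = c(0.9, 0.9, 0.1, 0.1)) # bins split by class
  st <- stratify_performance(pred, seed = 1)
  hi <- st[st$dimension == "similarity" & st$stratum == "0.70-1.00", ]
  expect_true(is.na(hi$auc))
  expect_false(is.na(hi$mcc))
  expect_false(is.na(hi$balanced_accuracy))
})

test_that("quartile strata hold about a quarter of compounds each", {
  set.seed(31)
  n <- 400
  pred <- data.frame(prob = runif(n), label = rbinom(n, 1, 0.5),
                     max_sim = runif(n), mw = rnorm(n, 350, 80))
  st <- stratify_performance(pred, descriptors = "mw", seed = 1)
  mw <- st[st$dimension == "mw", ]
  expect_equal(sum(mw$n), n)
  expect_true(all(abs(mw$n - n / 4) <= n * 0.05))
  # against direct quantile computation on the same vector
  qs <- unique(quantile(pred$mw, 0:4 / 4))
  direct <- table(cut(pred$mw, qs, include.lowest = TRUE, dig.lab = 4))
  expect_equal(unname(mw$n), unname(as.integer(direct)))
})
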