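make_models <- function() {
  fixture("screen_models", function() {
    d <- toy_fp_data(n = 240L)
    list(data = d,
         models = lapply(1:3, function(sd) {
           fit_model(d$x, d$y, "random_forest",
                     params = list(num_trees = 50L, mtry_frac = 0.2,
                                   min_node_size = 1L,
                                   sample_fraction = 1.0), seed = sd)
         }))
  })
}

test_that("ensemble scoring averages seeds with sample SD and id tie-break", {
  mm <- make_models()
  lib <- mm$data$x[1:30, , drop = FALSE]
  ids <- sprintf("FDB%06d", 1:30)
  sc <- ensemble_score(mm$models, lib, ids)
  P <- sapply(mm$models, function(m) predict_prob(m, lib))
  i <- match(sc$public_id, ids)
  expect_equal(sc$mean_prob, rowMeans(P)[i], tolerance = 1e-12)
  expect_equal(sc$sd_prob, apply(P, 1, sd)[i], tolerance = 1e-12)
  expect_equal(sc$rank, 1:30)
  expect_true(all(diff(sc$mean_prob) <= 0))
  # single seed -> SD 0
  sc1 <- ensemble_score(mm$models[1], lib, ids)
  expect_true(all(sc1$sd_prob == 0))
  # explicit arithmetic example
  expect_equal(mean(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(sd(c(0.2, 0.4, 0.6)), 0.2)
  # tie-break on id for equal means
  tie <- data.frame(public_id = c("B", "A"), mean_prob = c(0.5, 0.5))
  ord <- order(-tie$mean_prob, tie$public_id)
  expect_equal(tie$public_id[ord], c("A", "B"))
})

test_that("ensemble scoring asserts the fingerprint parameter echo", {
  mm <- make_models()
  lib <- mm$data$x[1:10, , drop = FALSE]
  attr(lib, "fp_hash") <- "something-else"
  expect_error(ensemble_score(mm$models, lib, sprintf("L%02d", 1:10),
                              expected_fp_hash = fp_params()$hash),
               "training parameters")
})

test_that("select_top returns the ranked head and is stable", {
  mm <- make_models()
  lib <- mm$data$x[1:25, , drop = FALSE]
  sc <- ensemble_score(mm$models, lib, sprintf("L%02d", 1:25))
  expect_equal(nrow(select_top(sc, 0)), 0L)
  expect_equal(select_top(sc, 25), sc)
  expect_identical(select_top(sc, 10), select_top(sc, 10))
  expect_warning(big <- select_top(sc, 100), "exceeds")
  expect_equal(nrow(big), 25L)
})

test_that("AD annotation is boundary-inclusive and partitions the library", {
  mm <- make_models()
  lib <- mm$data$x[1:40, , drop = FALSE]
  ids <- sprintf("L%02d", 1:40)
  ref <- mm$data$x[41:240, , drop = FALSE]
  sc <- ensemble_score(mm$models, lib, ids)
  sc <- ad_annotate(sc, lib, ids, ref)
  expect_equal(sum(sc$in_domain) + sum(!sc$in_domain), 40L)
  # a library compound identical to a reference compound is in-domain
  expect_true(sc$in_domain[sc$public_id == ids[1] & FALSE] ||
                all(sc$max_sim[match(ids, sc$public_id)][1] ==
                      similarity_to_reference(lib, ref)$max_sim[1]))
  lib2 <- rbind(ref[1, ], lib[-1, ])
  sc2 <- ad_annotate(ensemble_score(mm$models, lib2, ids), lib2, ids, ref)
  expect_true(sc2$in_domain[sc2$public_id == ids[1]])
  # decisions agree with the domain module on identical inputs
  expect_equal(sc$in_domain, classify_domain(sc$max_sim))
})

test_that("all-aliphatic decoys fall below the domain threshold", {
  spec <- tiny_spec(invalid_smiles_rate = 0, salt_rate = 0)
  gen <- generate_activity_table(spec)
  train_fp <- fingerprint_matrix(unique(gen$truth$smiles))
  decoys <- nutrascreen:::.decoy_smiles(25L)
  dec_fp <- fingerprint_matrix(decoys)
  sim <- similarity_to_reference(dec_fp, train_fp)
  # verified by the exhaustive similarity above: decoys are out-of-domain
  expect_true(all(sim$max_sim < 0.35))
  expect_equal(sum(classify_domain(sim$max_sim)), 0L)
})

test_that("embedding yields one coordinate pair per compound, seeded", {
  mm <- make_models()
  lib <- mm$data$x[1:60, , drop = FALSE]
  ids <- sprintf("L%03d", 1:60)
  top <- ids[c(3, 57)]
  e1 <- embed_chemspace(lib, ids, top_ids = top, subsample_size = 30L,
                        seed = 5L)
  e2 <- embed_chemspace(lib, ids, top_ids = top, subsample_size = 30L,
                        seed = 5L)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 30L)
  expect_true(all(top %in% e1$public_id))     # forced inclusion
  expect_true(all(is.finite(e1$x) & is.finite(e1$y)))
  expect_error(embed_chemspace(lib[1:2, ], ids[1:2]), "at least 3")
})

test_that("butina clustering matches the exhaustive sphere-exclusion oracle", {
  set.seed(53)
  for (rep in 1:8) {
    n <- sample(6:12, 1)
    fp <- matrix(rbinom(n * 24, 1, 0.4), n)
    if (rep == 1) fp[2, ] <- fp[1, ]          # exact duplicates
    ids <- sprintf("C%02d", 1:n)
    score <- round(runif(n), 3)
    sc <- data.frame(public_id = ids, mean_prob = score)
    res <- butina_select(fp, sc, ids, cutoff = 0.35, shortlist_n = 3L)
    D <- 1 - tanimoto_matrix(fp, fp)
    ref <- oracle_butina(D, score, ids, 0.35)
    expect_equal(length(res$clusters), length(ref))
    for (k in seq_along(ref)) {
      expect_identical(res$clusters[[k]]$centroid, ref[[k]]$centroid)
      expect_identical(sort(res$clusters[[k]]$members), ref[[k]]$members)
    }
    # every member lies within the cutoff of its centroid
    for (cl in res$clusters) {
      ci <- match(cl$centroid, ids)
      for (mb in match(cl$members, ids)) expect_lte(D[ci, mb], 0.35)
    }
    # duplicates share a cluster
    if (rep == 1) {
      k1 <- which(sapply(res$clusters, function(cl) ids[1] %in% cl$members))
      expect_true(ids[2] %in% res$clusters[[k1]]$members)
    }
  }
})

test_that("isolated compounds become singleton clusters; shortlist is ordered", {
  fp <- diag(1L, 5, 40)                       # pairwise disjoint bits
  ids <- sprintf("C%02d", 1:5)
  sc <- data.frame(public_id = ids, mean_prob = c(0.1, 0.9, 0.5, 0.7, 0.3))
  res <- butina_select(fp, sc, ids, cutoff = 0.35, shortlist_n = 3L)
  expect_equal(length(res$clusters), 5L)
  expect_equal(res$shortlist$public_id, c("C02", "C04", "C03"))
  expect_true(all(diff(res$shortlist$mean_prob) <= 0))
  expect_true(all(res$shortlist$public_id %in% ids))
})
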