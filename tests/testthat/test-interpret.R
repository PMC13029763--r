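test_that("tree attribution satisfies local accuracy to 1e-6", {
  d <- toy_fp_data(n = 250L)
  m <- fit_model(d$x, d$y, "random_forest",
                 params = list(num_trees = 60L, mtry_frac = 0.2,
                               min_node_size = 1L, sample_fraction = 1.0),
                 seed = 5L)
  xe <- d$x[1:80, , drop = FALSE]
  xb <- d$x[81:250, , drop = FALSE]
  a <- attribute(m, xe, xb)
  expect_equal(a$base_value + rowSums(a$phi), predict_prob(m, xe),
               tolerance = 1e-6)
  expect_equal(a$base_value, mean(predict_prob(m, xb)), tolerance = 1e-6)
})

test_that("gradient-boosting and linear attributions are additive on their scales", {
  d <- toy_fp_data(n = 220L)
  xe <- d$x[1:60, , drop = FALSE]; xb <- d$x[61:220, , drop = FALSE]
  mg <- fit_model(d$x, d$y, "gradient_boosting", seed = 2L)
  ag <- attribute(mg, xe, xb)
  expect_equal(ag$base_value + rowSums(ag$phi),
               qlogis(predict_prob(mg, xe)), tolerance = 1e-4)
  ml <- fit_model(d$x, d$y, "logistic_regression", seed = 2L)
  al <- attribute(ml, xe, xb)
  expect_equal(plogis(al$base_value + rowSums(al$phi)),
               predict_prob(ml, xe), tolerance = 1e-9)
})

test_that("a constant model attributes approximately nothing", {
  n <- 120L
  x <- matrix(rbinom(n * 16, 1, 0.3), n)
  colnames(x) <- sprintf("F%d", 0:15)
  y <- rep(c(0L, 1L), n / 2)           # label independent of features
  x[, ] <- 0L; x[, 1] <- rep(c(0L, 1L), each = n / 2)
  m <- fit_model(x, y, "random_forest",
                 params = list(num_trees = 20L, mtry_frac = 1.0,
                               min_node_size = 60L, sample_fraction = 1.0),
                 seed = 1L)
  a <- attribute(m, x[1:20, ], x[21:120, ])
  expect_lt(max(abs(a$phi)), 0.06)
})

test_that("a stump on one informative bit attributes with the right sign", {
  set.seed(41)
  n <- 200L
  x <- matrix(rbinom(n * 8, 1, 0.5), n)
  colnames(x) <- sprintf("F%d", 0:7)
  y <- x[, 4]                          # feature F3 drives the label
  m <- fit_model(x, y, "random_forest",
                 params = list(num_trees = 30L, mtry_frac = 1.0,
                               min_node_size = 1L, sample_fraction = 1.0),
                 seed = 3L)
  a <- attribute(m, x[1:50, ], x[51:200, ])
  on <- x[1:50, 4] == 1L
  expect_true(all(a$phi[on, 4] > 0))
  expect_true(all(a$phi[!on, 4] < 0))
})

test_that("global importance aggregates seeds and ranks null features last", {
  d <- toy_fp_data(n = 150L)
  m <- fit_model(d$x, d$y, "random_forest", seed = 1L)
  a1 <- attribute(m, d$x[1:40, ], d$x[41:150, ])
  imp_same <- global_importance(list(a1, a1))
  expect_true(all(imp_same$sd_abs == 0))          # identical matrices
  # the planted informative bit (F2) ranks first
  expect_equal(imp_same$feature[1], "F2")
  # a feature never non-zero has importance 0 and ranks last
  x2 <- d$x; x2[, 10] <- 0L
  m2 <- fit_model(x2, d$y, "random_forest", seed = 1L)
  a2 <- attribute(m2, x2[1:40, ], x2[41:150, ])
  imp2 <- global_importance(list(a2))
  expect_equal(imp2$mean_abs[imp2$feature == "F9"], 0)
})

test_that("bit environments cover benzene's six equivalent carbons", {
  fo <- fingerprint_one("c1ccccc1")
  bit0 <- fo$info$bit[fo$info$radius == 0][1]
  env <- map_bit_environments(bit0, "c1ccccc1")
  expect_equal(sort(unique(env$center_atom)), 1:6)
  expect_error(map_bit_environments(2048, "c1ccccc1"), "out of range")
  # a bit activated by no compound returns an empty frame, not an error
  dead <- setdiff(0:2047, fo$info$bit)[1]
  expect_equal(nrow(map_bit_environments(dead, "c1ccccc1")), 0L)
})

test_that("reported environments regenerate their bit and embed in the source", {
  smi <- "CC(=O)Nc1ccccc1O"
  fo <- fingerprint_one(smi)
  some_bits <- unique(fo$info$bit[fo$info$radius == 2])[1:3]
  for (b in some_bits) {
    env <- map_bit_environments(b, smi)
    expect_gt(nrow(env), 0L)
    for (r in seq_len(nrow(env))) {
      rec <- fo$info[fo$info$atom == env$center_atom[r] &
                       fo$info$radius == env$radius[r], ]
      expect_true(b %in% rec$bit)      # round trip under same parameters
      # substructure embeds in the parent molecule
      eg <- nutrascreen:::parse_molblock(
        nutrascreen:::smiles_to_molblock(env$environment_smiles[r]))
      pg <- fo$graph
      iso <- igraph::subgraph_isomorphisms(
        pattern = nutrascreen:::.mol_igraph(eg),
        target = nutrascreen:::.mol_igraph(pg), method = "vf2")
      expect_gt(length(iso), 0L)
    }
  }
})

test_that("r-group series analysis decomposes a substituted benzene series", {
  smi <- c("c1cc(OC)ccc1S(=O)(=O)N", "c1cc(OC)ccc1C(=O)O", "c1cc(F)ccc1C(=O)O",
           "c1cc(OC)ccc1S(=O)(=O)N", "c1cc(F)ccc1S(=O)(=O)N",
           "c1cc(OC)ccc1S(=O)(=O)N", "c1cc(F)ccc1C(=O)O", "c1cc(F)ccc1C(=O)O")
  score <- c(0.9, 0.4, 0.35, 0.88, 0.86, 0.92, 0.3, 0.33)
  rg <- rgroup_series(data.frame(smiles = smi, score = score),
                      min_series_size = 5L, min_substituent_count = 2L,
                      pair_support = 3L)
  expect_false(rg$no_series)
  expect_identical(rg$core_scaffold, canonical_smiles("c1ccccc1"))
  expect_equal(rg$n_members, 8L)
  # per-position counts sum to series size
  for (p in rg$positions) expect_equal(sum(p$n), 8L)
  # combination seen >= 3 times appears; pairs seen twice do not
  expect_true(all(rg$grid$n >= 3L))
  expect_gt(nrow(rg$grid), 0L)
  # sulfonamide-bearing members out-score the series mean (direction check)
  pos_sulf <- grepl("S\\(", smi)
  expect_gt(mean(score[pos_sulf]), rg$series_mean)
})

test_that("degenerate and empty series cases are explicit", {
  smi3 <- rep("c1cc(OC)ccc1F", 3)
  rg <- rgroup_series(data.frame(smiles = smi3, score = c(0.5, 0.6, 0.7)),
                      min_series_size = 3L)
  expect_false(rg$no_series)
  for (p in rg$positions) {
    expect_equal(nrow(p), 1L)          # single substituent per position
    expect_equal(p$n, 3L)
  }
  rg0 <- rgroup_series(data.frame(smiles = smi3, score = c(0.5, 0.6, 0.7)),
                       min_series_size = 10L)
  expect_true(rg0$no_series)
})
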