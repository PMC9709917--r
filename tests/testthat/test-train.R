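test_that("ROC AUC equals the exhaustive pair-counting oracle", {
  # hand-listed scores with ties
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  r <- evaluate_roc(scores, labels)
  expect_equal(r$auc, auc_pair_count(scores, labels))
  # random cases, exact equality including ties
  set.seed(14)
  for (i in 1:5) {
    s <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    l <- rbinom(40, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_identical(evaluate_roc(s, l)$auc, auc_pair_count(s, l))
  }
  expect_equal(evaluate_roc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_roc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(evaluate_roc(1:4, rep(1, 4)), "both classes")
  # curve starts at (0,0) and ends at (1,1)
  cv <- r$curve
  expect_equal(unlist(cv[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), ]), c(fpr = 1, tpr = 1))
})

test_that("agreement with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- rnorm(60)
  l <- rbinom(60, 1, 0.5)
  expect_equal(evaluate_roc(s, l)$auc,
    as.numeric(suppressMessages(pROC::auc(l, s, direction = "<",
      levels = c(0, 1)))))
})

test_that("pairwise distances are metric and match the closed form", {
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  set.seed(4)
  X <- matrix(rnorm(50), 10, 5)
  D <- pairwise_distances(X)
  # brute-force loop oracle
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D[i, j], sqrt(sum((X[i, ] - X[j, ])^2)), tolerance = 1e-9)
  }
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # triangle inequality
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
  expect_error(pairwise_distances(list(1:3, 1:4)), "length mismatch")
})

test_that("hierarchical clustering separates constructed blobs", {
  set.seed(8)
  blob1 <- matrix(rnorm(40, mean = 0, sd = 0.1), 20, 2)
  blob2 <- matrix(rnorm(40, mean = 5, sd = 0.1), 20, 2)
  D <- pairwise_distances(rbind(blob1, blob2))
  hc <- hierarchical_cluster(D)
  top2 <- cutree(hc, 2)
  expect_equal(length(unique(top2[1:20])), 1)
  expect_equal(length(unique(top2[21:40])), 1)
  expect_false(top2[1] == top2[21])
  # merge heights non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))
  # identical points merge at height 0
  D0 <- pairwise_distances(rbind(c(1, 1), c(1, 1), c(9, 9)))
  expect_equal(min(hierarchical_cluster(D0)$height), 0)
})

test_that("cluster splitting is single-linkage and leakage-free", {
  idm <- diag(1, 4)
  idm[1, 2] <- idm[2, 1] <- 0.5
  idm[2, 3] <- idm[3, 2] <- 0.4
  idm[1, 3] <- idm[3, 1] <- 0.1
  split <- sequence_cluster_split(idm, test_fraction = 0.5, seed = 1)
  # A, B, C chain into one cluster; D alone
  expect_equal(length(unique(split[1:3])), 1)
  # no pair above threshold straddles the split (brute force)
  for (i in 1:4) for (j in 1:4) {
    if (i != j && idm[i, j] > 0.3) expect_equal(split[i], split[j])
  }
  # all-zero identities: every structure its own cluster
  split0 <- sequence_cluster_split(diag(1, 10), test_fraction = 0.3,
    seed = 2)
  expect_true(sum(!split0) >= 3)
  bad <- idm; bad[1, 2] <- 0.9
  expect_error(sequence_cluster_split(bad), "symmetric")
  # randomized check on a larger matrix
  set.seed(9)
  m <- matrix(runif(400, 0, 0.6), 20, 20)
  m <- (m + t(m)) / 2; diag(m) <- 1
  sp <- sequence_cluster_split(m, seed = 3)
  for (i in 1:20) for (j in 1:20) {
    if (i != j && m[i, j] > 0.3) expect_equal(sp[i], sp[j])
  }
})

test_that("k-mer identity is 1 on self and 0 for disjoint sequences", {
  m <- kmer_identity(c("ACDEFGH", "ACDEFGH", "WWWWWWW"))
  expect_equal(diag(m), rep(1, 3))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], 0)
  expect_true(isSymmetric(m))
})

test_that("metric training rejects malformed pair lists", {
  ds <- make_map_dataset(n_classes = 2, n_per_class = 2, n_side = 2,
    seed = 1)
  bad <- data.frame(id_a = 1, id_b = 99, label = 1)
  cfg <- train_config("metric", epochs = 1, batch_size = 2,
    pairs_per_epoch = 2)
  expect_error(train_metric(ds$maps, bad, cfg, split = rep(TRUE, 4)),
    "missing pocket id")
  self <- data.frame(id_a = 1, id_b = 1, label = 1)
  expect_error(train_metric(ds$maps, self, cfg, split = rep(TRUE, 4)),
    "self-pairs")
})

test_that("learning-rate schedule decays by 0.1 every 25 epochs", {
  cfg <- train_config("classify")
  expect_equal(pocketsphere:::lr_at_epoch(cfg, 1), 0.05)
  expect_equal(pocketsphere:::lr_at_epoch(cfg, 25), 0.05)
  expect_equal(pocketsphere:::lr_at_epoch(cfg, 26), 0.005)
  expect_equal(pocketsphere:::lr_at_epoch(cfg, 51), 0.0005)
  expect_error(train_config("classify", nonsense = 1), "unknown")
})

test_that("classifier training is deterministic and separates easy classes", {
  # tiny deep-separable dataset at low resolution for speed
  ds <- make_map_dataset(n_classes = 2, n_per_class = 6, n_side = 4,
    seed = 5)
  cfg <- train_config("classify", epochs = 12, batch_size = 4, folds = 2,
    seed = 7, lr = 0.01)
  net_cfg <- network_config("classifier", n_classes = 2,
    channels = c(8, 16), embedding = 16, n_side = 4, k = 8)
  r1 <- train_classifier(ds$maps, ds$labels, cfg, net_cfg)
  r2 <- train_classifier(ds$maps, ds$labels, cfg, net_cfg)
  expect_identical(r1$history, r2$history)       # same seed, same curves
  expect_gte(r1$mean_train_accuracy, 0.9)
  expect_error(train_classifier(ds$maps, ds$labels,
    train_config("classify", epochs = 1, folds = 12), net_cfg),
    "fold")
})
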