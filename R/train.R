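# Training loops for the two objectives, leakage-safe data splitting, and
# similarity/classification evaluation.

#' Training configuration
#'
#' Defaults follow the two published recipes: classification uses Adam at
#' lr 0.05 (decayed by 0.1 every 25 epochs), batch 32, 60 epochs; metric
#' learning uses lr 0.0005, margin 1.0, 25,000 pairs per epoch in batches
#' of 128, 50 epochs. Weight decay 0 and betas (0.9, 0.999) for both.
#'
#' @param objective `"classify"` or `"metric"`.
#' @param ... Overrides of the defaults (e.g. `epochs`, `batch_size`).
#' @return A `train_config` list.
#' @export
train_config <- function(objective = c("classify", "metric"), ...) {
  objective <- match.arg(objective)
  cfg <- if (objective == "classify") {
    list(objective = "classify", lr = 0.05, weight_decay = 0,
         betas = c(0.9, 0.999), batch_size = 32L, epochs = 60L,
         lr_step = 25L, lr_factor = 0.1, augment = TRUE, folds = 5L,
         seed = 1L)
  } else {
    list(objective = "metric", lr = 0.0005, weight_decay = 0,
         betas = c(0.9, 0.999), batch_size = 128L, epochs = 50L,
         margin = 1.0, pairs_per_epoch = 25000L, augment = TRUE,
         seed = 1L)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), c(names(cfg), "lr_step", "lr_factor",
    "margin", "pairs_per_epoch", "folds"))
  if (length(bad)) stop("unknown training options: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "train_config"
  cfg
}

lr_at_epoch <- function(cfg, epoch) {
  if (is.null(cfg$lr_step)) return(cfg$lr)
  cfg$lr * cfg$lr_factor^((epoch - 1) %/% cfg$lr_step)
}

maps_to_array <- function(maps_list) {
  n_pix <- ncol(maps_list[[1]]$channels)
  arr <- array(0, c(n_pix, length(maps_list), nrow(maps_list[[1]]$channels)))
  for (b in seq_along(maps_list)) arr[, b, ] <- t(maps_list[[b]]$channels)
  arr
}

augment_batch <- function(arr, grid) {
  for (b in seq_len(dim(arr)[2])) {
    src <- healpix_lookup(grid, grid$vec %*% random_rotation_matrix())
    arr[, b, ] <- arr[src, b, ]
  }
  arr
}

#' Train the pocket classifier
#'
#' Stratified k-fold cross validation of the softmax head: per fold, Adam
#' optimization of the cross-entropy with stepped learning-rate decay and
#' per-sample random rotation augmentation; per-class one-vs-rest AUC and
#' combined accuracy are averaged over folds. Fully reproducible for a
#' given seed.
#'
#' @param maps_list List of `spherical_maps`.
#' @param labels Integer class labels (1..n_classes).
#' @param cfg A [train_config()] with objective `"classify"`.
#' @param net_cfg Optional [network_config()] override.
#' @param verbose Print per-epoch losses.
#' @param folds_to_run Optionally train only the first n folds (the split
#'   is still a full k-fold partition); useful for quick sanity runs.
#' @return List with `folds` (per-fold nets and metrics), `mean_auc`
#'   (per class), `mean_accuracy`, `history`.
#' @export
train_classifier <- function(maps_list, labels, cfg = train_config("classify"),
                             net_cfg = NULL, verbose = FALSE,
                             folds_to_run = NULL) {
  stopifnot(cfg$objective == "classify")
  labels <- as.integer(labels)
  n_classes <- max(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (is.null(net_cfg)) {
    net_cfg <- network_config("classifier", n_classes = n_classes,
      n_side = maps_list[[1]]$n_side)
  }
  set.seed(cfg$seed)
  folds <- make_stratified_folds(labels, cfg$folds)
  grid <- healpix_grid(net_cfg$n_side)
  graphs <- sphere_graph_hierarchy(net_cfg$n_side, length(net_cfg$channels),
    net_cfg$k)
  arr_all <- maps_to_array(maps_list)

  n_run <- if (is.null(folds_to_run)) length(folds) else
    min(folds_to_run, length(folds))
  fold_out <- vector("list", n_run)
  for (fi in seq_len(n_run)) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_along(labels), test_idx)
    if (length(unique(labels[test_idx])) < n_classes ||
        length(unique(labels[train_idx])) < n_classes) {
      stop("a class is absent from fold ", fi, "; use fewer folds")
    }
    net <- network_init(net_cfg, seed = cfg$seed + fi, graphs = graphs)
    state <- adam_state(net)
    hist <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, ep)
      ord <- sample(train_idx)
      ep_loss <- 0; nb <- 0
      for (s in seq(1, length(ord), by = cfg$batch_size)) {
        bidx <- ord[s:min(s + cfg$batch_size - 1, length(ord))]
        xb <- arr_all[, bidx, , drop = FALSE]
        if (cfg$augment) xb <- augment_batch(xb, grid)
        Y <- matrix(0, length(bidx), n_classes)
        Y[cbind(seq_along(bidx), labels[bidx])] <- 1
        fw <- network_forward(net, xb, training = TRUE)
        loss <- cross_entropy(fw$out, Y)
        dz <- (fw$out - Y) / length(bidx)
        gr <- network_backward(net, fw, dz)
        net <- bn_update_running(net, fw)
        up <- adam_step(net, state, gr, lr, cfg$betas, cfg$weight_decay)
        net <- up$net; state <- up$state
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      hist[ep] <- ep_loss / nb
      if (verbose) message(sprintf("fold %d epoch %d loss %.4f", fi, ep, hist[ep]))
    }
    # evaluate
    pr_tr <- network_forward(net, arr_all[, train_idx, , drop = FALSE])$out
    pr_te <- network_forward(net, arr_all[, test_idx, , drop = FALSE])$out
    acc_tr <- mean(max.col(pr_tr) == labels[train_idx])
    acc_te <- mean(max.col(pr_te) == labels[test_idx])
    aucs <- vapply(seq_len(n_classes), function(cl) {
      lab <- as.integer(labels[test_idx] == cl)
      if (length(unique(lab)) < 2) return(NA_real_)
      evaluate_roc(pr_te[, cl], lab)$auc
    }, numeric(1))
    fold_out[[fi]] <- list(net = net, history = hist,
      train_accuracy = acc_tr, test_accuracy = acc_te, auc = aucs,
      test_idx = test_idx)
  }
  aucm <- do.call(rbind, lapply(fold_out, `[[`, "auc"))
  list(folds = fold_out,
       mean_auc = colMeans(aucm, na.rm = TRUE),
       mean_accuracy = mean(vapply(fold_out, `[[`, numeric(1),
         "test_accuracy")),
       mean_train_accuracy = mean(vapply(fold_out, `[[`, numeric(1),
         "train_accuracy")),
       history = lapply(fold_out, `[[`, "history"))
}

make_stratified_folds <- function(labels, k) {
  folds <- vector("list", k)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    asg <- rep(seq_len(k), length.out = length(idx))
    for (fi in seq_len(k)) {
      folds[[fi]] <- c(folds[[fi]], idx[asg == fi])
    }
  }
  lapply(folds, sort)
}

#' Train the metric-learning embedder
#'
#' Minimizes the contrastive margin loss over labeled pocket pairs. Per
#' epoch at most `pairs_per_epoch` training pairs are subsampled without
#' replacement (reseeded per epoch from the master seed); random rotations
#' are applied to both members of every pair. Pairs crossing the
#' train/test split are excluded (counted); evaluation scores test pairs
#' by negative descriptor distance and reports ROC/AUC.
#'
#' @param maps_list List of `spherical_maps`, indexed by pocket id.
#' @param pairs Data frame with columns `id_a`, `id_b` (indices into
#'   `maps_list`) and `label` (1 similar / 0 dissimilar).
#' @param cfg A [train_config()] with objective `"metric"`.
#' @param split Logical vector (`TRUE` = train) per pocket, e.g. from
#'   [sequence_cluster_split()].
#' @param net_cfg Optional [network_config()] override.
#' @param verbose Print per-epoch losses.
#' @return List with `net`, `auc` (test ROC/AUC), `history`,
#'   `n_excluded_pairs`, `test_scores`.
#' @export
train_metric <- function(maps_list, pairs, cfg = train_config("metric"),
                         split, net_cfg = NULL, verbose = FALSE) {
  stopifnot(cfg$objective == "metric")
  if (any(pairs$id_a > length(maps_list) | pairs$id_b > length(maps_list) |
          pairs$id_a < 1 | pairs$id_b < 1)) {
    stop("pair list references a missing pocket id")
  }
  if (any(pairs$id_a == pairs$id_b)) stop("self-pairs are not allowed")
  if (!all(pairs$label %in% c(0, 1))) stop("pair labels must be 0/1")
  stopifnot(length(split) == length(maps_list))
  if (is.null(net_cfg)) {
    net_cfg <- network_config("embedder", n_side = maps_list[[1]]$n_side)
  }
  in_train <- split[pairs$id_a] & split[pairs$id_b]
  in_test <- !split[pairs$id_a] & !split[pairs$id_b]
  n_excluded <- sum(!in_train & !in_test)
  train_pairs <- pairs[in_train, , drop = FALSE]
  test_pairs <- pairs[in_test, , drop = FALSE]
  if (!nrow(train_pairs)) stop("no training pairs inside the split")

  grid <- healpix_grid(net_cfg$n_side)
  graphs <- sphere_graph_hierarchy(net_cfg$n_side, length(net_cfg$channels),
    net_cfg$k)
  arr_all <- maps_to_array(maps_list)
  set.seed(cfg$seed)
  net <- network_init(net_cfg, seed = cfg$seed, graphs = graphs)
  state <- adam_state(net)
  hist <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    set.seed(cfg$seed * 1000L + ep)
    take <- sample(nrow(train_pairs),
      min(cfg$pairs_per_epoch, nrow(train_pairs)))
    ep_loss <- 0; nb <- 0
    for (s in seq(1, length(take), by = cfg$batch_size)) {
      bp <- train_pairs[take[s:min(s + cfg$batch_size - 1, length(take))], ]
      B <- nrow(bp)
      xa <- arr_all[, bp$id_a, , drop = FALSE]
      xb <- arr_all[, bp$id_b, , drop = FALSE]
      if (cfg$augment) {
        xa <- augment_batch(xa, grid)
        xb <- augment_batch(xb, grid)
      }
      x <- array(0, c(dim(xa)[1], 2 * B, dim(xa)[3]))
      x[, seq_len(B), ] <- xa
      x[, B + seq_len(B), ] <- xb
      fw <- network_forward(net, x, training = TRUE)
      f1 <- fw$out[seq_len(B), , drop = FALSE]
      f2 <- fw$out[B + seq_len(B), , drop = FALSE]
      y <- bp$label
      dvec <- f1 - f2
      d <- sqrt(rowSums(dvec^2))
      loss <- contrastive_loss(f1, f2, y, cfg$margin)
      # gradients wrt f1/f2
      hinge <- pmax(0, cfg$margin - d)
      safe_d <- pmax(d, 1e-12)
      coef <- (2 * y - 2 * (1 - y) * hinge / safe_d) / B
      df1 <- dvec * coef
      dz <- rbind(df1, -df1)
      gr <- network_backward(net, fw, dz)
      net <- bn_update_running(net, fw)
      up <- adam_step(net, state, gr, cfg$lr, cfg$betas, cfg$weight_decay)
      net <- up$net; state <- up$state
      ep_loss <- ep_loss + loss; nb <- nb + 1
    }
    hist[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, hist[ep]))
  }
  out <- list(net = net, history = hist, n_excluded_pairs = n_excluded)
  if (nrow(test_pairs) && length(unique(test_pairs$label)) == 2) {
    ids <- sort(unique(c(test_pairs$id_a, test_pairs$id_b)))
    emb <- network_forward(net, arr_all[, ids, , drop = FALSE])$out
    rownames(emb) <- as.character(ids)
    d <- sqrt(rowSums((emb[as.character(test_pairs$id_a), , drop = FALSE] -
      emb[as.character(test_pairs$id_b), , drop = FALSE])^2))
    roc <- evaluate_roc(-d, test_pairs$label)
    out$auc <- roc$auc
    out$test_scores <- data.frame(test_pairs, distance = d)
  }
  out
}

#' Sequence-identity cluster split
#'
#' Structures sharing identity above the threshold are linked into
#' single-linkage clusters (connected components of the thresholded
#' identity graph); whole clusters are then assigned at random to the
#' train or test side, targeting the requested test fraction, so no pair
#' above the threshold straddles the split.
#'
#' @param identity Symmetric matrix of fractional sequence identities in
#'   `[0, 1]`.
#' @param threshold Linkage threshold (default 0.30).
#' @param test_fraction Target fraction of structures on the test side.
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = train.
#' @export
sequence_cluster_split <- function(identity, threshold = 0.30,
                                   test_fraction = 0.3, seed = 1L) {
  identity <- as.matrix(identity)
  if (!isSymmetric(unname(identity), tol = 1e-9)) {
    stop("identity matrix must be symmetric")
  }
  n <- nrow(identity)
  adj <- identity > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  set.seed(seed)
  cl_ids <- sample(unique(comp))
  train <- rep(TRUE, n)
  n_test <- 0
  target <- test_fraction * n
  for (cl in cl_ids) {
    if (n_test >= target) break
    members <- which(comp == cl)
    train[members] <- FALSE
    n_test <- n_test + length(members)
  }
  train
}

#' Fractional k-mer sequence identity
#'
#' Alignment-free fallback when no identity matrix is supplied: the
#' fraction of shared k-mers (multiset intersection over the shorter
#' sequence's k-mer count).
#'
#' @param seqs Character vector of sequences.
#' @param k k-mer length (default 3).
#' @return Symmetric identity matrix in `[0, 1]`.
#' @export
kmer_identity <- function(seqs, k = 3L) {
  kmers <- lapply(seqs, function(s) {
    s <- toupper(s)
    if (nchar(s) < k) return(character(0))
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  })
  n <- length(seqs)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    ti <- table(kmers[[i]])
    for (j in (i + 1):n) {
      tj <- table(kmers[[j]])
      shared <- sum(pmin(ti[names(tj)], tj), na.rm = TRUE)
      denom <- min(length(kmers[[i]]), length(kmers[[j]]))
      m[i, j] <- m[j, i] <- if (denom > 0) shared / denom else 0
    }
  }
  m
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive outranks
#' a random negative, with ties counted half (computed from rank sums, so
#' it agrees exactly with exhaustive pair counting); the curve sweeps all
#' score thresholds.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @return List with `auc`, and `curve` (data frame of FPR/TPR).
#' @export
evaluate_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  keep <- c(diff(scores[ord]) != 0, TRUE)
  curve <- data.frame(fpr = c(0, fp[keep] / n_neg),
                      tpr = c(0, tp[keep] / n_pos))
  list(auc = auc, curve = curve)
}

#' Pairwise Euclidean distances between descriptors
#'
#' @param descriptors n x d matrix (rows are pockets) or list of
#'   equal-length vectors.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(descriptors) {
  if (is.list(descriptors) && !is.matrix(descriptors)) {
    len <- vapply(descriptors, length, integer(1))
    if (length(unique(len)) != 1) stop("descriptor length mismatch")
    descriptors <- do.call(rbind, descriptors)
  }
  as.matrix(stats::dist(descriptors))
}

#' Hierarchical clustering of pocket descriptors
#'
#' Average-linkage agglomerative clustering of a descriptor distance
#' matrix (deterministic leaf order with index tie-breaks, as implemented
#' by `hclust`).
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param linkage Linkage method (default `"average"`).
#' @return An `hclust` tree.
#' @export
hierarchical_cluster <- function(D, linkage = "average") {
  stats::hclust(stats::as.dist(D), method = linkage)
}
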