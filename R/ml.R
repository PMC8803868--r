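# Supervised analyses on graph feature vectors: 2D embedding for
# visualisation, random-forest classification of locomotor conditions
# against shuffled-label chance, and GLM prediction of behavioural
# features with cross-validation and permutation baselines.

# training-split standardisation with median imputation; returns the
# transform so the test split is mapped identically
.fit_preprocess <- function(Xtr) {
  med <- apply(Xtr, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  any_na <- colSums(!is.finite(Xtr)) > 0
  imp <- function(X) {
    for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]
    X
  }
  Xtr <- imp(Xtr)
  mu <- colMeans(Xtr); sg <- apply(Xtr, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(
    apply = function(X) {
      miss <- !is.finite(X)
      X <- sweep(sweep(imp(X), 2, mu), 2, sg, "/")
      if (any(any_na)) {
        X <- cbind(X, (miss[, any_na, drop = FALSE]) * 1)
      }
      colnames(X) <- paste0("f", seq_len(ncol(X)))
      X
    }
  )
}

#' Embed feature vectors in two dimensions with t-SNE
#'
#' Exact t-SNE of a feature table, deterministic given `seed`, with
#' per-group centroids (coordinate-wise medians) and interquartile
#' dispersion when group labels are supplied. The embedding is an
#' exploratory visualisation; distances in it carry no tested meaning.
#'
#' @param features numeric matrix or data.frame (maps x features).
#' @param groups optional factor of group labels.
#' @param perplexity t-SNE perplexity (default 10, suited to cohorts of
#'   about a hundred maps).
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations.
#' @return list with `coords` (n x 2), and when `groups` is given
#'   `centroids` (per-group medians) and `dispersion` (IQRs).
#' @export
tsne_embed <- function(features, groups = NULL, perplexity = 10, seed = 1,
                       n_iter = 500) {
  X <- as.matrix(features)
  if (nrow(X) < 3 * perplexity) {
    stop("need at least 3 x perplexity samples (", 3 * perplexity, ")")
  }
  X[!is.finite(X)] <- 0
  Y <- .tsne(X, dims = 2, perplexity = perplexity, n_iter = n_iter,
             seed = seed)
  colnames(Y) <- c("tsne1", "tsne2")
  out <- list(coords = Y)
  if (!is.null(groups)) {
    groups <- factor(groups)
    out$centroids <- t(vapply(levels(groups), function(g) {
      apply(Y[groups == g, , drop = FALSE], 2, stats::median)
    }, numeric(2)))
    out$dispersion <- t(vapply(levels(groups), function(g) {
      apply(Y[groups == g, , drop = FALSE], 2, stats::IQR)
    }, numeric(2)))
  }
  out
}

.stratified_split <- function(labels, train_frac) {
  unlist(lapply(split(seq_along(labels), labels), function(ix) {
    n_tr <- round(train_frac * length(ix))
    n_tr <- min(max(n_tr, 1L), length(ix) - 1L)
    sample(ix, n_tr)
  }), use.names = FALSE)
}

#' Classify locomotor conditions with a random forest
#'
#' The published protocol: over `n_trials` stratified train/test splits
#' (80:20 by default), fit a random forest of `n_trees` trees with
#' maximum depth `max_depth` on the training split (features standardised
#' on that split, missing entries imputed by training medians with
#' missingness indicators) and measure accuracy on the held-out split.
#' The identical protocol is rerun with class labels shuffled within the
#' training split (or globally, see `shuffle`) to estimate chance.
#'
#' @param features numeric matrix or data.frame (maps x features).
#' @param labels condition labels (factor or character), >= 2 classes
#'   with >= 2 members each.
#' @param n_trees trees per forest (default 150).
#' @param max_depth maximum tree depth (default 30).
#' @param n_trials number of stratified trials (default 100).
#' @param train_frac training fraction (default 0.8).
#' @param seed integer seed.
#' @param shuffle chance-baseline protocol: `"within_train"` permutes
#'   training labels anew each trial, `"global"` applies one fixed global
#'   permutation before the trials.
#' @return object of class `eval_result`: list with per-trial `accuracy`
#'   and `accuracy_shuffled`, `confusion` (row-normalised probabilities,
#'   actual arm), `summary` (means and SDs).
#' @export
classify_conditions <- function(features, labels, n_trees = 150,
                                max_depth = 30, n_trials = 100,
                                train_frac = 0.8, seed = 1,
                                shuffle = c("within_train", "global")) {
  shuffle <- match.arg(shuffle)
  X <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 classes")
  if (any(table(labels) < 2L)) {
    stop("every class needs >= 2 members for stratification")
  }
  set.seed(seed)
  if (shuffle == "global") labels_shuf_global <- sample(labels)
  K <- nlevels(labels)
  conf <- matrix(0, K, K, dimnames = list(levels(labels), levels(labels)))
  acc <- acc_sh <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    tr <- .stratified_split(labels, train_frac)
    te <- setdiff(seq_len(nrow(X)), tr)
    pp <- .fit_preprocess(X[tr, , drop = FALSE])
    Xtr <- pp$apply(X[tr, , drop = FALSE])
    Xte <- pp$apply(X[te, , drop = FALSE])
    dtr <- data.frame(.y = labels[tr], Xtr)
    fit <- ranger::ranger(.y ~ ., data = dtr, num.trees = n_trees,
                          max.depth = max_depth, num.threads = 1,
                          seed = seed + t)
    pred <- predict(fit, data.frame(Xte), num.threads = 1)$predictions
    acc[t] <- mean(pred == labels[te])
    tab <- table(factor(labels[te], levels(labels)),
                 factor(pred, levels(labels)))
    conf <- conf + tab
    # chance arm: same split, labels carry no information
    ytr_sh <- if (shuffle == "within_train") sample(labels[tr])
              else labels_shuf_global[tr]
    dtr$.y <- ytr_sh
    fit_sh <- ranger::ranger(.y ~ ., data = dtr, num.trees = n_trees,
                             max.depth = max_depth, num.threads = 1,
                             seed = seed + n_trials + t)
    pred_sh <- predict(fit_sh, data.frame(Xte), num.threads = 1)$predictions
    acc_sh[t] <- mean(pred_sh == labels[te])
  }
  conf <- conf / pmax(rowSums(conf), 1)
  structure(
    list(accuracy = acc, accuracy_shuffled = acc_sh, confusion = conf,
         summary = c(mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
                     mean_shuffled = mean(acc_sh),
                     sd_shuffled = stats::sd(acc_sh))),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  s <- x$summary
  cat("Evaluation over", length(x[[1]]), "trials\n")
  print(round(s, 4))
  invisible(x)
}

#' Predict behavioural features from graph features with a GLM
#'
#' Fits the interaction model
#' Y = beta0 + sum_j beta_j G_j + sum_j gamma_j T G_j + eps
#' (Gaussian family, identity link) under repeated random train/test
#' splits (75:25 by default), reporting the Pearson correlation between
#' held-out predictions and observations and the mean squared error per
#' trial. A paired chance baseline refits on targets shuffled within the
#' training split of the same trial.
#'
#' @param features numeric matrix (maps x features).
#' @param targets behavioural feature, one value per map.
#' @param group_codes +/-1 group code per map (0 turns the interaction
#'   off for that map).
#' @param n_trials number of random splits (default 100).
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed.
#' @param standardize standardise features on the training split.
#' @return object of class `eval_result`: list with per-trial `r`,
#'   `mse`, `r_shuffled`, `mse_shuffled`, full-data `coefficients`
#'   (named: intercept, beta_j, gamma_j), `rank_deficient` flag,
#'   `summary`.
#' @export
glm_predict <- function(features, targets, group_codes = NULL,
                        n_trials = 100, train_frac = 0.75, seed = 1,
                        standardize = TRUE) {
  G <- as.matrix(features)
  n <- nrow(G); p <- ncol(G)
  if (length(targets) != n) stop("one target value per map is required")
  if (is.null(group_codes)) group_codes <- rep(0, n)
  if (length(group_codes) != n) stop("one group code per map is required")
  has_groups <- any(group_codes != 0)
  design <- function(G) {
    D <- if (has_groups) cbind(G, group_codes_cur * G) else G
    colnames(D) <- c(paste0("beta_", seq_len(p)),
                     if (has_groups) paste0("gamma_", seq_len(p)))
    D
  }
  # scale-only standardisation: centering the features would induce a
  # group main-effect term that the interaction model has no column for
  scale_fit <- function(Gtr) {
    med <- apply(Gtr, 2, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    imp <- function(X) {
      for (j in seq_len(ncol(X))) X[!is.finite(X[, j]), j] <- med[j]
      X
    }
    sg <- apply(imp(Gtr), 2, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    function(X) sweep(imp(X), 2, sg, "/")
  }
  set.seed(seed)
  r <- mse <- r_sh <- mse_sh <- numeric(n_trials)
  n_tr <- round(train_frac * n)
  for (t in seq_len(n_trials)) {
    tr <- sample.int(n, n_tr)
    te <- setdiff(seq_len(n), tr)
    Gtr <- G[tr, , drop = FALSE]; Gte <- G[te, , drop = FALSE]
    if (standardize) {
      sc <- scale_fit(Gtr)
      Gtr <- sc(Gtr); Gte <- sc(Gte)
    }
    group_codes_cur <- group_codes[tr]
    Dtr <- design(Gtr)
    group_codes_cur <- group_codes[te]
    Dte <- design(Gte)
    fit <- stats::lm.fit(cbind(1, Dtr), targets[tr])
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    pred <- as.numeric(cbind(1, Dte) %*% cf)
    r[t] <- suppressWarnings(stats::cor(targets[te], pred))
    mse[t] <- mean((targets[te] - pred)^2)
    y_sh <- sample(targets[tr])
    fit_sh <- stats::lm.fit(cbind(1, Dtr), y_sh)
    cf_sh <- fit_sh$coefficients; cf_sh[is.na(cf_sh)] <- 0
    pred_sh <- as.numeric(cbind(1, Dte) %*% cf_sh)
    r_sh[t] <- suppressWarnings(stats::cor(targets[te], pred_sh))
    mse_sh[t] <- mean((targets[te] - pred_sh)^2)
  }
  # full-data coefficients on the raw feature scale
  group_codes_cur <- group_codes
  Dfull <- design(G)
  full <- stats::lm(targets ~ Dfull)
  rank_deficient <- any(is.na(stats::coef(full)))
  if (rank_deficient) {
    warning("rank-deficient design: some coefficients are aliased")
  }
  coefs <- stats::coef(full)
  names(coefs) <- c("intercept", colnames(Dfull))
  structure(
    list(r = r, mse = mse, r_shuffled = r_sh, mse_shuffled = mse_sh,
         coefficients = coefs, rank_deficient = rank_deficient,
         summary = c(mean_r = mean(r, na.rm = TRUE),
                     sd_r = stats::sd(r, na.rm = TRUE),
                     mean_mse = mean(mse),
                     mean_r_shuffled = mean(r_sh, na.rm = TRUE),
                     mean_mse_shuffled = mean(mse_sh))),
    class = "eval_result"
  )
}
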