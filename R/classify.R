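# Classifier benchmark: six algorithms on reconfiguration features with
# repeated matched subsampling (one-vs-rest per target group).
#
# The R stack here ships no SVM/forest/boosting/MLP packages, so compact
# implementations are built in: an RBF-kernel SVM in its least-squares
# formulation (ridge in the kernel feature space), a random forest and a
# logistic gradient boosting machine on a shared compiled CART learner,
# a single-hidden-layer perceptron trained by Adam, Gaussian naive Bayes,
# and k-nearest neighbours via FNN.

# ---- individual classifiers: fit(x, y01) -> model; predict -> p(class 1)

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(x, sc)
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_svm <- function(x, y, seed, C = 1) {
  gamma <- 1 / (ncol(x) * max(mean(apply(x, 2, var)), 1e-12))
  K <- rbf_kernel(x, x, gamma)
  yy <- ifelse(y > 0, 1, -1)
  alpha <- solve(K + diag(1 / C, nrow(K)), yy)
  list(kind = "svm", x = x, alpha = alpha, gamma = gamma)
}
predict_svm <- function(m, x) {
  f <- as.vector(rbf_kernel(x, m$x, m$gamma) %*% m$alpha)
  1 / (1 + exp(-3 * f)) # monotone squashing; decision threshold at f = 0
}

fit_rf <- function(x, y, seed, ntree = 200) {
  mtry <- max(1L, as.integer(floor(sqrt(ncol(x)))))
  list(kind = "rf",
       trees = rf_fit_cpp(x, as.numeric(y), as.integer(ntree), mtry, 12L,
                          1L, seed))
}
predict_rf <- function(m, x) as.vector(forest_predict_cpp(m$trees, x))

fit_gb <- function(x, y, seed, ntree = 100) {
  list(kind = "gb",
       model = gb_fit_cpp(x, as.numeric(y), as.integer(ntree), 3L, 1L,
                          0.1, seed))
}
predict_gb <- function(m, x) as.vector(gb_predict_cpp(m$model, x))

fit_mlp <- function(x, y, seed, hidden = 32L, epochs = 300L, lr = 0.01) {
  rs <- get_rng(seed)
  p <- ncol(x); n <- nrow(x)
  W1 <- matrix(rs$norm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rs$norm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
  b2 <- 0
  mW1 <- vW1 <- matrix(0, p, hidden); mb1 <- vb1 <- numeric(hidden)
  mW2 <- vW2 <- matrix(0, hidden, 1); mb2 <- vb2 <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    H <- tanh(sweep(x %*% W1, 2, b1, "+"))
    z <- as.vector(H %*% W2) + b2
    pr <- 1 / (1 + exp(-z))
    dz <- (pr - y) / n
    gW2 <- crossprod(H, dz); gb2 <- sum(dz)
    dH <- (dz %*% t(W2)) * (1 - H^2)
    gW1 <- crossprod(x, dH); gb1 <- colSums(dH)
    upd <- function(m, v, g) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t); vh <- v / (1 - beta2^t)
      list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
    }
    u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$step
    u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$step
    u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$step
    u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$step
  }
  list(kind = "mlp", W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}
predict_mlp <- function(m, x) {
  H <- tanh(sweep(x %*% m$W1, 2, m$b1, "+"))
  1 / (1 + exp(-(as.vector(H %*% m$W2) + m$b2)))
}

fit_knn <- function(x, y, seed, k = 5L) {
  list(kind = "knn", x = x, y = y, k = min(k, nrow(x)))
}
predict_knn <- function(m, x) {
  idx <- FNN::knnx.index(m$x, x, k = m$k)
  rowMeans(matrix(m$y[idx], nrow(idx), ncol(idx)))
}

fit_nb <- function(x, y, seed) {
  stats_for <- function(rows) {
    mu <- colMeans(x[rows, , drop = FALSE])
    s2 <- apply(x[rows, , drop = FALSE], 2, var)
    s2[!is.finite(s2) | s2 < 1e-9] <- 1e-9
    list(mu = mu, s2 = s2)
  }
  list(kind = "nb", c0 = stats_for(y == 0), c1 = stats_for(y == 1),
       prior1 = mean(y))
}
predict_nb <- function(m, x) {
  ll <- function(s) rowSums(-0.5 * log(2 * pi * matrix(s$s2, nrow(x),
                                                       ncol(x), TRUE)) -
                              sweep(x, 2, s$mu, "-")^2 /
                              (2 * matrix(s$s2, nrow(x), ncol(x), TRUE)))
  d <- ll(m$c1) + log(max(m$prior1, 1e-12)) -
    ll(m$c0) - log(max(1 - m$prior1, 1e-12))
  1 / (1 + exp(-pmax(pmin(d, 50), -50)))
}

classifier_registry <- function() {
  list(svm = list(fit = fit_svm, predict = predict_svm),
       rf = list(fit = fit_rf, predict = predict_rf),
       gb = list(fit = fit_gb, predict = predict_gb),
       mlp = list(fit = fit_mlp, predict = predict_mlp),
       knn = list(fit = fit_knn, predict = predict_knn),
       nb = list(fit = fit_nb, predict = predict_nb))
}

score_binary <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1)
}

#' Benchmark six classifiers with repeated matched subsampling
#'
#' Binary task `target_group` vs rest. Per repetition, 20% of the target
#' subjects form the positive test set together with an equal-sized random
#' sample of non-target subjects; training uses all remaining target
#' subjects plus an equal-sized non-target sample disjoint from the test
#' set (size-matched, so chance level is 0.5). Features are standardized
#' with training-set statistics only.
#'
#' @param features numeric subject x feature matrix.
#' @param labels group label per subject (rows of `features`).
#' @param target_group the positive class.
#' @param n_repetitions random subsampling repetitions (1000 by default;
#'   reduce for quick runs).
#' @param test_fraction fraction of target subjects held out (0.2).
#' @param classifiers subset of `c("svm","rf","gb","mlp","knn","nb")`.
#' @param seed integer seed.
#' @return Object of class `classification_report`: list with `scores`
#'   (classifier x statistic mean and sd data frame), `n_repetitions`,
#'   `target_group`, `feature_description`, `seed`.
#' @export
benchmark_classifiers <- function(features, labels, target_group,
                                  n_repetitions = 1000, test_fraction = 0.2,
                                  classifiers = c("svm", "rf", "gb", "mlp",
                                                  "knn", "nb"),
                                  seed = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  reg <- classifier_registry()[classifiers]
  pos <- which(labels == target_group)
  neg <- which(labels != target_group)
  n_test_pos <- max(1L, round(length(pos) * test_fraction))
  if (length(pos) < 5L) stop("target group too small (< 5)", call. = FALSE)
  if (length(neg) < 2L * n_test_pos)
    stop("non-target pool too small for matched sampling", call. = FALSE)
  rs <- get_rng(seed)
  acc <- array(NA_real_, c(n_repetitions, length(reg), 4),
               dimnames = list(NULL, names(reg),
                               c("accuracy", "precision", "recall", "f1")))
  for (r in seq_len(n_repetitions)) {
    test_pos <- pos[rs$perm(length(pos))][seq_len(n_test_pos)]
    test_neg <- neg[rs$perm(length(neg))][seq_len(n_test_pos)]
    train_pos <- setdiff(pos, test_pos)
    neg_rest <- setdiff(neg, test_neg)
    n_train_neg <- min(length(train_pos), length(neg_rest))
    train_neg <- neg_rest[rs$perm(length(neg_rest))][seq_len(n_train_neg)]
    tr <- c(train_pos, train_neg)
    te <- c(test_pos, test_neg)
    ytr <- as.numeric(tr %in% pos)
    yte <- as.numeric(te %in% pos)
    sc <- standardize_fit(features[tr, , drop = FALSE])
    xtr <- standardize_apply(features[tr, , drop = FALSE], sc)
    xte <- standardize_apply(features[te, , drop = FALSE], sc)
    for (ci in seq_along(reg)) {
      m <- reg[[ci]]$fit(xtr, ytr, seed = seed * 131L + r)
      pr <- as.numeric(reg[[ci]]$predict(m, xte) > 0.5)
      acc[r, ci, ] <- score_binary(yte, pr)
    }
  }
  scores <- do.call(rbind, lapply(seq_along(reg), function(ci) {
    data.frame(classifier = names(reg)[ci],
               statistic = dimnames(acc)[[3]],
               mean = apply(acc[, ci, , drop = FALSE], 3, mean),
               sd = apply(acc[, ci, , drop = FALSE], 3, sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(scores = scores, n_repetitions = n_repetitions,
                 target_group = target_group,
                 feature_description = sprintf("%d features x %d subjects",
                                               ncol(features),
                                               nrow(features)),
                 seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> target=%s, %d repetitions\n",
              x$target_group, x$n_repetitions))
  acc <- x$scores[x$scores$statistic == "accuracy", ]
  for (i in seq_len(nrow(acc)))
    cat(sprintf("  %-4s accuracy %.3f +/- %.3f\n", acc$classifier[i],
                acc$mean[i], acc$sd[i]))
  invisible(x)
}
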