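#' Classifier specification
#'
#' One cell of the classifier grid: a family plus its family-specific
#' kernel/metric/architecture. Families and options:
#' * `svm` — kernel `linear`, `quadratic`, `cubic` or `gaussian` (e1071).
#' * `knn` — metric `euclidean`, `cosine` or `minkowski` (order 3), with
#'   `k` neighbours (default 5).
#' * `decision_tree` — CART (rpart).
#' * `linear_discriminant`, `quadratic_discriminant` — MASS lda/qda.
#' * `logistic_regression` — binomial GLM.
#' * `feedforward_nn` — two-hidden-layer perceptron; `hidden` gives the
#'   layer sizes, e.g. `c(10, 8)`.
#' * `ensemble` — `adaboost` (discrete AdaBoost over stumps),
#'   `bagged_trees` (bootstrap-aggregated trees) or `rusboost` (AdaBoost
#'   with per-round random undersampling of the majority class).
#'
#' @param family classifier family (see above).
#' @param kernel kernel / metric / ensemble type where applicable.
#' @param k neighbours for `knn`.
#' @param hidden hidden layer sizes for `feedforward_nn`.
#' @param seed RNG seed for stochastic fits.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "knn", "decision_tree",
                                       "linear_discriminant",
                                       "quadratic_discriminant",
                                       "logistic_regression",
                                       "feedforward_nn", "ensemble"),
                            kernel = NULL, k = 5L, hidden = c(10L, 8L),
                            seed = 1L) {
  family <- match.arg(family)
  legal <- list(svm = c("linear", "quadratic", "cubic", "gaussian"),
                knn = c("euclidean", "cosine", "minkowski"),
                ensemble = c("adaboost", "bagged_trees", "rusboost"))
  if (family %in% names(legal)) {
    if (is.null(kernel)) kernel <- legal[[family]][1]
    if (!kernel %in% legal[[family]])
      stop("'", kernel, "' is not a legal kernel/metric for family '",
           family, "'", call. = FALSE)
  } else if (family == "feedforward_nn") {
    if (length(hidden) != 2L || any(hidden < 1L))
      stop("feedforward_nn needs two positive hidden layer sizes", call. = FALSE)
    kernel <- paste0("hidden=(", paste(hidden, collapse = ","), ")")
  } else {
    kernel <- family
  }
  structure(list(family = family, kernel = kernel, k = as.integer(k),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- two-hidden-layer MLP -------------------------------------------------

mlp_pack <- function(p, h1, h2) {
  sizes <- c(W1 = p * h1, b1 = h1, W2 = h1 * h2, b2 = h2, W3 = h2, b3 = 1)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes))
}

mlp_unpack <- function(theta, p, h1, h2, lay) {
  g <- function(i) theta[lay$starts[i]:lay$ends[i]]
  list(W1 = matrix(g(1), p, h1), b1 = g(2),
       W2 = matrix(g(3), h1, h2), b2 = g(4),
       W3 = matrix(g(5), h2, 1), b3 = g(6))
}

mlp_forward <- function(X, w) {
  Z1 <- sweep(X %*% w$W1, 2, w$b1, `+`); A1 <- tanh(Z1)
  Z2 <- sweep(A1 %*% w$W2, 2, w$b2, `+`); A2 <- tanh(Z2)
  z3 <- as.vector(A2 %*% w$W3) + w$b3
  p <- 1 / (1 + exp(-z3))
  list(A1 = A1, A2 = A2, p = p)
}

mlp_fit <- function(X, y01, hidden, decay = 1e-2, maxit = 150L, seed = 1L) {
  p <- ncol(X); h1 <- hidden[1]; h2 <- hidden[2]
  lay <- mlp_pack(p, h1, h2)
  n <- nrow(X)
  obj <- function(theta) {
    w <- mlp_unpack(theta, p, h1, h2, lay)
    fw <- mlp_forward(X, w)
    pr <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    -mean(y01 * log(pr) + (1 - y01) * log(1 - pr)) + decay * sum(theta^2)
  }
  grad <- function(theta) {
    w <- mlp_unpack(theta, p, h1, h2, lay)
    fw <- mlp_forward(X, w)
    d3 <- (fw$p - y01) / n                         # n vector
    gW3 <- t(fw$A2) %*% d3
    gb3 <- sum(d3)
    d2 <- (d3 %*% t(w$W3)) * (1 - fw$A2^2)         # n x h2
    gW2 <- t(fw$A1) %*% d2
    gb2 <- colSums(d2)
    d1 <- (d2 %*% t(w$W2)) * (1 - fw$A1^2)
    gW1 <- t(X) %*% d1
    gb1 <- colSums(d1)
    c(as.vector(gW1), gb1, as.vector(gW2), gb2, as.vector(gW3), gb3) +
      2 * decay * theta
  }
  local_seed(seed, {
    theta0 <- runif(lay$total, -0.5, 0.5) / sqrt(p)
    fit <- optim(theta0, obj, grad, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-8))
    mlp_unpack(fit$par, p, h1, h2, lay)
  })
}

# ---- knn with pluggable metric -------------------------------------------

knn_distances <- function(train, test, metric) {
  if (metric == "euclidean") {
    cross <- test %*% t(train)
    d2 <- outer(rowSums(test^2), rowSums(train^2), `+`) - 2 * cross
    sqrt(pmax(d2, 0))
  } else if (metric == "cosine") {
    nt <- sqrt(rowSums(test^2)); nr <- sqrt(rowSums(train^2))
    nt[nt == 0] <- 1e-12; nr[nr == 0] <- 1e-12
    1 - (test %*% t(train)) / outer(nt, nr)
  } else {  # minkowski, order 3
    out <- matrix(NA_real_, nrow(test), nrow(train))
    for (i in seq_len(nrow(test)))
      out[i, ] <- (colSums(abs(t(train) - test[i, ])^3))^(1 / 3)
    out
  }
}

knn_predict <- function(train, y, test, k, metric) {
  dm <- knn_distances(train, test, metric)
  lev <- levels(y)
  apply_row <- function(i) {
    ord <- order(dm[i, ])[seq_len(min(k, ncol(dm)))]
    votes <- table(y[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) top else as.character(y[ord[1]])  # tie: nearest
  }
  factor(vapply(seq_len(nrow(test)), apply_row, character(1)), levels = lev)
}

# ---- boosting ------------------------------------------------------------

fit_stump <- function(df, w) {
  rpart::rpart(label ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                              minsplit = 2, xval = 0))
}

adaboost_fit <- function(X, y, rounds = 40L, rus = FALSE, seed = 1L) {
  df <- as.data.frame(X)
  df$label <- y
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  lev <- levels(y)
  local_seed(seed, {
    for (t in seq_len(rounds)) {
      if (rus) {
        # balance classes by weighted sampling before fitting the stump
        n_min <- min(table(y))
        idx <- unlist(lapply(lev, function(l) {
          pool <- which(y == l)
          pool[sample.int(length(pool), n_min, replace = TRUE,
                          prob = w[pool] / sum(w[pool]))]
        }))
        stump <- fit_stump(df[idx, , drop = FALSE], rep(1, length(idx)))
      } else {
        stump <- fit_stump(df, w * n)
      }
      pred <- predict(stump, df, type = "class")
      miss <- pred != y
      err <- sum(w * miss)
      if (err <= 1e-12) {
        stumps[[t]] <- stump; alphas[t] <- 10; break
      }
      if (err >= 0.5) break
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[t]] <- stump; alphas[t] <- alpha
      w <- w * exp(alpha * (2 * miss - 1))
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0L) {
    # no useful stump: fall back to the single best-effort stump
    stumps <- list(fit_stump(df, w * n)); alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = lev)
}

adaboost_predict <- function(model, X) {
  df <- as.data.frame(X)
  score <- rep(0, nrow(df))
  for (t in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[t]], df, type = "class")
    score <- score + model$alphas[t] * ifelse(pred == model$levels[2], 1, -1)
  }
  factor(ifelse(score > 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

# ---- registry ------------------------------------------------------------

svm_kernel_args <- function(kernel) {
  switch(kernel,
         linear = list(kernel = "linear"),
         quadratic = list(kernel = "polynomial", degree = 2, coef0 = 1),
         cubic = list(kernel = "polynomial", degree = 3, coef0 = 1),
         gaussian = list(kernel = "radial"))
}

#' Fit a classifier from a spec
#'
#' Dispatches to the implementation behind a [classifier_spec()] and returns
#' a fitted model that [predict_classifier()] can apply to new feature rows.
#'
#' @param spec a [classifier_spec()].
#' @param X numeric feature matrix (rows = samples).
#' @param y factor of two class labels.
#' @param seed RNG seed overriding the spec's (used per fold).
#' @return List of class `vascmap_model`.
#' @export
fit_classifier <- function(spec, X, y, seed = spec$seed) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2L) stop("need exactly 2 classes in training data", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  fit <- switch(
    spec$family,
    svm = local_seed(seed, do.call(e1071::svm, c(list(x = Xs, y = y, scale = FALSE),
                                                 svm_kernel_args(spec$kernel)))),
    knn = list(train = Xs, y = y, k = spec$k, metric = spec$kernel),
    decision_tree = {
      df <- as.data.frame(Xs); df$label <- y
      rpart::rpart(label ~ ., data = df, method = "class",
                   control = rpart::rpart.control(xval = 0))
    },
    linear_discriminant = MASS::lda(Xs, y),
    quadratic_discriminant = MASS::qda(Xs, y),
    logistic_regression = {
      df <- as.data.frame(Xs); df$label <- y
      suppressWarnings(glm(label ~ ., data = df, family = binomial()))
    },
    feedforward_nn = mlp_fit(Xs, as.numeric(y) - 1, spec$hidden, seed = seed),
    ensemble = switch(spec$kernel,
      bagged_trees = local_seed(seed,
        randomForest::randomForest(x = Xs, y = y, ntree = 100L,
                                   mtry = ncol(Xs))),
      adaboost = adaboost_fit(Xs, y, rounds = 40L, rus = FALSE, seed = seed),
      rusboost = adaboost_fit(Xs, y, rounds = 40L, rus = TRUE, seed = seed)))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 center = ctr, scale = scl),
            class = "vascmap_model")
}

#' Predict classes for new samples
#'
#' @param model a [fit_classifier()] result.
#' @param X numeric feature matrix with the training columns.
#' @return Factor of predicted labels.
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  Xs <- scale(X, model$center, model$scale)
  spec <- model$spec
  lev <- model$levels
  out <- switch(
    spec$family,
    svm = predict(model$fit, Xs),
    knn = knn_predict(model$fit$train, model$fit$y, Xs, model$fit$k,
                      model$fit$metric),
    decision_tree = predict(model$fit, as.data.frame(Xs), type = "class"),
    linear_discriminant = predict(model$fit, Xs)$class,
    quadratic_discriminant = predict(model$fit, Xs)$class,
    logistic_regression = {
      p <- predict(model$fit, as.data.frame(Xs), type = "response")
      factor(ifelse(p > 0.5, lev[2], lev[1]), levels = lev)
    },
    feedforward_nn = {
      p <- mlp_forward(Xs, model$fit)$p
      factor(ifelse(p > 0.5, lev[2], lev[1]), levels = lev)
    },
    ensemble = if (spec$kernel == "bagged_trees") predict(model$fit, Xs)
               else adaboost_predict(model$fit, Xs))
  factor(as.character(out), levels = lev)
}

#' Default classifier grid
#'
#' The classifier families and kernels exercised by the benchmark
#' experiments. `compact = TRUE` returns a 4-spec subset for quick runs.
#'
#' @param compact return the reduced grid.
#' @return List of [classifier_spec()] objects.
#' @export
default_classifier_grid <- function(compact = FALSE) {
  if (compact)
    return(list(classifier_spec("svm", "gaussian"),
                classifier_spec("knn", "euclidean"),
                classifier_spec("logistic_regression"),
                classifier_spec("decision_tree")))
  c(lapply(c("linear", "quadratic", "cubic", "gaussian"),
           function(k) classifier_spec("svm", k)),
    lapply(c("euclidean", "cosine", "minkowski"),
           function(k) classifier_spec("knn", k)),
    list(classifier_spec("decision_tree"),
         classifier_spec("linear_discriminant"),
         classifier_spec("quadratic_discriminant"),
         classifier_spec("logistic_regression"),
         classifier_spec("feedforward_nn", hidden = c(10L, 8L))),
    lapply(c("adaboost", "bagged_trees", "rusboost"),
           function(k) classifier_spec("ensemble", k)))
}
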