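# Model zoo: each model exposes class-probability prediction so that hard
# predictions (argmax, ties to class 0) and soft voting share one code path.
# All fits are wrapped in with_seed(random_state) for bit-reproducibility.

MODEL_NAMES <- c("SVM", "LR", "KNN", "RF", "AdaBoost", "Voting")
VOTING_MEMBERS <- c("SVM", "KNN", "LR", "RF", "AdaBoost")
# models that expect z-scored inputs on continuous data
SCALE_SENSITIVE <- c("SVM", "KNN", "LR")

#' Model specification
#'
#' @param name One of SVM, KNN, LR, RF, AdaBoost, Voting. Voting is the
#'   soft-voting ensemble of the other five.
#' @param random_state Seed fixed for every fit (default 0).
#' @param hyperparameters Named list of overrides; unset parameters use the
#'   package defaults (RBF-kernel SVM with cost 1, KNN with 5 neighbors,
#'   ridge-penalized logistic regression with lambda = 1/n, random forest
#'   with 100 trees, AdaBoost with 50 depth-1 stumps).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, random_state = 0L, hyperparameters = list()) {
  name <- match.arg(name, MODEL_NAMES)
  structure(list(name = name, random_state = as.integer(random_state),
                 hyperparameters = hyperparameters),
            class = "model_spec")
}

model_hyper <- function(hyper, key, default) {
  if (!is.null(hyper[[key]])) hyper[[key]] else default
}

# Returns an n x 2 matrix of class probabilities, columns c("0","1").
# `std` is a standardize_fit() result or NULL; scale-sensitive models apply
# it, tree ensembles ignore it.
predict_proba_model <- function(name, Xtr, ytr, Xte, std = NULL,
                                random_state = 0L, hyper = list()) {
  if (name == "Voting") {
    ps <- lapply(VOTING_MEMBERS, predict_proba_model, Xtr = Xtr, ytr = ytr,
                 Xte = Xte, std = std, random_state = random_state,
                 hyper = hyper)
    s <- Reduce(`+`, ps)
    return(s / rowSums(s))
  }
  if (name %in% SCALE_SENSITIVE && !is.null(std)) {
    Xtr <- standardize_apply(Xtr, std)
    Xte <- standardize_apply(Xte, std)
  }
  p1 <- switch(
    name,
    SVM = proba_svm(Xtr, ytr, Xte, random_state, hyper),
    KNN = proba_knn(Xtr, ytr, Xte, random_state, hyper),
    LR = proba_lr(Xtr, ytr, Xte, random_state, hyper),
    RF = proba_rf(Xtr, ytr, Xte, random_state, hyper),
    AdaBoost = proba_adaboost(Xtr, ytr, Xte, random_state, hyper),
    stop("unknown model: ", name)
  )
  cbind("0" = 1 - p1, "1" = p1)
}

# Hard prediction: argmax of the probability pair, exact tie -> class 0.
fit_predict_model <- function(name, Xtr, ytr, Xte, std = NULL,
                              random_state = 0L, hyper = list()) {
  p <- predict_proba_model(name, Xtr, ytr, Xte, std, random_state, hyper)
  as.integer(p[, "1"] > p[, "0"])
}

proba_svm <- function(Xtr, ytr, Xte, seed, hyper) {
  yf <- factor(ytr, levels = c(0, 1))
  fit <- with_seed(seed, e1071::svm(
    x = Xtr, y = yf, kernel = "radial",
    cost = model_hyper(hyper, "cost", 1),
    probability = TRUE, scale = FALSE))
  pr <- attr(stats::predict(fit, Xte, probability = TRUE), "probabilities")
  unname(pr[, "1"])
}

proba_knn <- function(Xtr, ytr, Xte, seed, hyper) {
  k <- model_hyper(hyper, "k", 5L)
  yf <- factor(ytr, levels = c(0, 1))
  pred <- with_seed(seed, class::knn(Xtr, Xte, yf, k = k, prob = TRUE))
  pwin <- attr(pred, "prob")
  ifelse(pred == "1", pwin, 1 - pwin)
}

proba_lr <- function(Xtr, ytr, Xte, seed, hyper) {
  # ridge-penalized logistic regression, lambda = 1/n
  lam <- model_hyper(hyper, "lambda", 1 / nrow(Xtr))
  pad <- ncol(Xtr) == 1L
  if (pad) { Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0) }
  fit <- with_seed(seed, glmnet::glmnet(
    Xtr, factor(ytr, levels = c(0, 1)), family = "binomial", alpha = 0,
    lambda = lam, standardize = FALSE))
  as.numeric(stats::predict(fit, Xte, type = "response"))
}

proba_rf <- function(Xtr, ytr, Xte, seed, hyper) {
  fit <- with_seed(seed, randomForest::randomForest(
    x = Xtr, y = factor(ytr, levels = c(0, 1)),
    ntree = model_hyper(hyper, "ntree", 100L)))
  pr <- stats::predict(fit, Xte, type = "prob")
  unname(pr[, "1"])
}

# Discrete AdaBoost (SAMME) over depth-1 decision stumps. The stump search
# is vectorized over all features and thresholds: per round, weighted class
# cumsums along each feature's sort order give every split's error at once.
proba_adaboost <- function(Xtr, ytr, Xte, seed, hyper) {
  n_rounds <- model_hyper(hyper, "n_rounds", 50L)
  n <- nrow(Xtr)
  p <- ncol(Xtr)
  y1 <- as.numeric(ytr == 1)
  ord <- apply(Xtr, 2L, order)              # n x p sort orders, fixed
  flat <- cbind(as.vector(ord), rep(seq_len(p), each = n))
  Xsort <- matrix(Xtr[flat], n, p)
  # split after sorted position i is valid when the next value differs;
  # position n (everything left) encodes the constant stump
  valid <- rbind(Xsort[-1L, , drop = FALSE] >
                   Xsort[-n, , drop = FALSE], TRUE)
  y1s <- matrix(y1[ord], n, p)
  w <- rep(1 / n, n)
  votes1 <- rep(0, nrow(Xte))               # alpha-weighted votes for class 1
  total <- 0
  for (m in seq_len(n_rounds)) {
    ws <- matrix(w[ord], n, p)
    cum1 <- apply(ws * y1s, 2L, cumsum)     # class-1 weight left of split
    cum0 <- apply(ws * (1 - y1s), 2L, cumsum)
    T1 <- sum(w * y1)
    # rule A: predict 1 left / 0 right; rule B is its complement
    errA <- cum0 + (T1 - cum1)
    errA[!valid] <- Inf
    errB <- 1 - errA
    errB[!valid] <- Inf
    err <- min(errA, errB)
    if (err >= 0.5 - 1e-12) break           # no stump beats chance
    # deterministic argmin: rule A first, then feature index, then position
    ruleA <- TRUE
    hit <- which(errA <= err + 1e-15)
    if (length(hit) == 0L) {
      ruleA <- FALSE
      hit <- which(errB <= err + 1e-15)
    }
    hit <- hit[1L]
    i <- (hit - 1L) %% n + 1L
    j <- (hit - 1L) %/% n + 1L
    thr <- if (i == n) Inf else (Xsort[i, j] + Xsort[i + 1L, j]) / 2
    pred1_tr <- if (ruleA) Xtr[, j] <= thr else Xtr[, j] > thr
    pred1_te <- if (ruleA) Xte[, j] <= thr else Xte[, j] > thr
    if (err <= 1e-12) {                     # perfect stump decides alone
      big <- log((1 - 1e-10) / 1e-10)
      votes1 <- votes1 + big * pred1_te
      total <- total + big
      break
    }
    alpha <- log((1 - err) / err)
    votes1 <- votes1 + alpha * pred1_te
    total <- total + alpha
    mis <- pred1_tr != (ytr == 1)
    w <- w * exp(alpha * mis)
    w <- w / sum(w)
  }
  if (total == 0) {                         # no usable stump: majority class
    return(rep(mean(ytr == 1), nrow(Xte)))
  }
  votes1 / total
}
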