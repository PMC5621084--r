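#' @include AllClasses.R features-direct.R
NULL

.with_seed <- function(seed, expr) {
  # run expr under a private RNG stream, restoring the caller's state
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean cross-entropy of predicted class probabilities
#'
#' \eqn{E = -\frac{1}{l}\sum_j \sum_i T_{ij} \ln S_{ij}} over \eqn{l} samples,
#' with one-hot targets: perfect one-hot predictions score 0 and uniform
#' predictions over k classes score \eqn{\ln k}.
#'
#' @param probs numeric samples x classes matrix of probabilities.
#' @param classIndex integer vector, the target class column per sample.
#' @return numeric scalar.
#' @export
crossEntropy <- function(probs, classIndex) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), classIndex)], 1e-300)))
}

.mlp_sizes <- function(d, h, k)
  list(W1 = d * h, b1 = h, W2 = h * k, b2 = k)

.mlp_unpack <- function(par, d, h, k) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- par[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlp_obj <- function(par, X, Yk, d, h, k, decay) {
  w <- .mlp_unpack(par, d, h, k)
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
  P <- .softmax(sweep(H %*% w$W2, 2, w$b2, `+`))
  -mean(log(pmax(P[cbind(seq_len(nrow(X)), Yk)], 1e-300))) +
    decay * (sum(w$W1^2) + sum(w$W2^2))
}

.mlp_grad <- function(par, X, Yk, d, h, k, decay) {
  w <- .mlp_unpack(par, d, h, k)
  n <- nrow(X)
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, `+`))
  P <- .softmax(sweep(H %*% w$W2, 2, w$b2, `+`))
  dZ <- P
  dZ[cbind(seq_len(n), Yk)] <- dZ[cbind(seq_len(n), Yk)] - 1
  dZ <- dZ / n
  dW2 <- crossprod(H, dZ) + 2 * decay * w$W2
  db2 <- colSums(dZ)
  dH <- tcrossprod(dZ, w$W2) * (1 - H^2)
  dW1 <- crossprod(X, dH) + 2 * decay * w$W1
  db1 <- colSums(dH)
  c(as.numeric(dW1), db1, as.numeric(dW2), db2)
}

#' Train the i-12-k tanh/softmax multilayer perceptron
#'
#' Single hidden layer of \code{hidden} (default 12) hyperbolic-tangent
#' units, softmax output over the classes present, mean cross-entropy loss
#' (plus a small L2 weight penalty for numerical conditioning), minimized
#' with Polak-Ribiere conjugate gradients (\code{optim(method = "CG",
#' type = 2)}). Inputs are z-score standardized with parameters fitted here
#' and stored in the model, so prediction applies the same transform.
#' Training is deterministic given \code{seed} (weight initialization is
#' small uniform noise drawn from a private RNG stream).
#'
#' @param x numeric samples x features matrix.
#' @param labels integer class labels, at least two distinct values.
#' @param seed integer seed for weight initialization.
#' @param hidden hidden-layer width (default 12).
#' @param decay L2 weight penalty (default 1e-4).
#' @param maxit maximum conjugate-gradient iterations (default 300).
#' @return an \linkS4class{MlpModel}.
#' @export
mlpTrain <- function(x, labels, seed = 1, hidden = 12, decay = 1e-4,
                     maxit = 300) {
  x <- as.matrix(x)
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2L) stop("at least two classes are required", call. = FALSE)
  Yk <- match(as.integer(labels), classes)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  X <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  d <- ncol(X); h <- as.integer(hidden); k <- length(classes)
  npar <- d * h + h + h * k + k
  par0 <- .with_seed(seed, runif(npar, -0.5, 0.5))
  fit <- optim(par0, fn = .mlp_obj, gr = .mlp_grad,
               X = X, Yk = Yk, d = d, h = h, k = k, decay = decay,
               method = "CG",
               control = list(maxit = maxit, type = 2, reltol = 1e-10))
  if (!is.finite(fit$value))
    stop("training diverged: non-finite loss", call. = FALSE)
  w <- .mlp_unpack(fit$par, d, h, k)
  fn <- colnames(x)
  if (is.null(fn)) fn <- paste0("f", seq_len(d))
  new("MlpModel", W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
      center = as.numeric(ctr), scale = as.numeric(scl),
      classes = classes, featureNames = fn)
}

#' Predict class probabilities and labels
#'
#' Applies the stored standardization, the tanh hidden layer and the softmax
#' output. Probability rows sum to 1; the label is the argmax class, ties
#' resolved toward the lowest class index.
#'
#' @param model an \linkS4class{MlpModel}.
#' @param x numeric samples x features matrix with the model's input width.
#' @return list with \code{prob} (samples x classes matrix, columns named by
#'   class) and \code{labels} (integer vector).
#' @export
mlpPredict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model@W1))
    stop(sprintf("model expects %d features, got %d", nrow(model@W1), ncol(x)),
         call. = FALSE)
  X <- sweep(sweep(x, 2, model@center), 2, model@scale, `/`)
  H <- tanh(sweep(X %*% model@W1, 2, model@b1, `+`))
  P <- .softmax(sweep(H %*% model@W2, 2, model@b2, `+`))
  colnames(P) <- model@classes
  list(prob = P, labels = model@classes[max.col(P, ties.method = "first")])
}

.stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' Repeated stratified k-fold cross-validation of the MLP
#'
#' For every repetition, trials are partitioned into stratified folds (each
#' class spread evenly across folds); for every fold, the network is trained
#' on the remaining trials and the recognition rate (fraction of correctly
#' classified held-out trials) recorded. The overall performance measure is
#' the mean rate over all repetitions x folds. Fully reproducible from
#' \code{seed}.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param featureSubset character vector of feature names to use.
#' @param repetitions number of CV repetitions (default 10).
#' @param folds number of folds (default 10); every class needs at least
#'   \code{folds} trials.
#' @param seed integer master seed.
#' @param ... passed to [mlpTrain()] (e.g. \code{maxit}, \code{hidden}).
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateCv <- function(features, featureSubset = NULL, repetitions = 10,
                       folds = 10, seed = 1, ...) {
  x <- featureValues(features)
  if (!is.null(featureSubset)) {
    missing <- setdiff(featureSubset, colnames(x))
    if (length(missing))
      stop("unknown features: ", paste(missing, collapse = ", "), call. = FALSE)
    x <- x[, featureSubset, drop = FALSE]
  }
  y <- situations(features)
  counts <- table(y)
  if (min(counts) < folds)
    stop(sprintf("smallest class has %d trials; use at most %d folds",
                 min(counts), min(counts)), call. = FALSE)
  classes <- sort(unique(y))
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(classes, classes))
  rates <- matrix(NA_real_, repetitions, folds)
  for (r in seq_len(repetitions)) {
    fold <- .stratified_folds(y, folds, seed = seed + r * 131)
    for (f in seq_len(folds)) {
      test <- fold == f
      model <- mlpTrain(x[!test, , drop = FALSE], y[!test],
                        seed = seed + r * 947 + f * 61, ...)
      pred <- mlpPredict(model, x[test, , drop = FALSE])$labels
      rates[r, f] <- mean(pred == y[test])
      for (i in seq_along(pred))
        conf[as.character(y[test][i]), as.character(pred[i])] <-
          conf[as.character(y[test][i]), as.character(pred[i])] + 1L
    }
  }
  new("EvalReport", foldRates = rates, repetitionMeans = rowMeans(rates),
      meanRate = mean(rates), confusion = conf, seed = as.integer(seed))
}

#' Save or load an MLP model as a portable JSON weight file
#'
#' @param model an \linkS4class{MlpModel}.
#' @param path JSON file path.
#' @return \code{writeMlpModel}: invisibly \code{path};
#'   \code{readMlpModel}: an \linkS4class{MlpModel}.
#' @export
writeMlpModel <- function(model, path) {
  jsonlite::write_json(
    list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
         center = model@center, scale = model@scale,
         classes = model@classes, featureNames = model@featureNames),
    path, digits = NA)
  invisible(path)
}

#' @rdname writeMlpModel
#' @export
readMlpModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("MlpModel", W1 = as.matrix(o$W1), b1 = as.numeric(o$b1),
      W2 = as.matrix(o$W2), b2 = as.numeric(o$b2),
      center = as.numeric(o$center), scale = as.numeric(o$scale),
      classes = as.integer(o$classes), featureNames = as.character(o$featureNames))
}

#' Export an evaluation report as JSON
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path JSON file path.
#' @return invisibly, \code{path}.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(
    list(mean_rate = report@meanRate,
         repetition_means = report@repetitionMeans,
         fold_rates = report@foldRates,
         confusion = report@confusion,
         seed = report@seed),
    path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(path)
}
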