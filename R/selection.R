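#' @include AllClasses.R features-direct.R classifier.R
NULL

.feature_vec <- function(features, feature) {
  x <- featureValues(features)
  if (!feature %in% colnames(x))
    stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  x[, feature]
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

.fisher_raw <- function(x1, x2) {
  denom <- var(x1) + var(x2)
  num <- (mean(x2) - mean(x1))^2
  if (denom == 0) return(if (num == 0) 0 else Inf)
  num / denom
}

.ttest2_raw <- function(x1, x2) {
  # Welch two-sample t statistic, absolute value
  se2 <- var(x1) / length(x1) + var(x2) / length(x2)
  num <- mean(x2) - mean(x1)
  if (se2 == 0) return(if (num == 0) 0 else Inf)
  abs(num) / sqrt(se2)
}

.pearson_raw <- function(x1, x2) {
  if (length(x1) != length(x2))
    stop("Pearson class-similarity score needs equal class sizes", call. = FALSE)
  s1 <- .pop_sd(x1); s2 <- .pop_sd(x2)
  if (s1 == 0 || s2 == 0) {
    warning("zero-dispersion class: Pearson score set to 0", call. = FALSE)
    return(0)
  }
  abs(mean((x1 - mean(x1)) * (x2 - mean(x2))) / (s1 * s2))
}

#' Two-class filter scores for a single feature
#'
#' Classifier-independent relevance scores of one feature for separating two
#' situations:
#' \describe{
#'   \item{fisherScore}{\eqn{F = (\mu_2-\mu_1)^2 / (\sigma_1^2+\sigma_2^2)},
#'     the squared mean separation over the summed dispersions.}
#'   \item{ttest2Score}{the absolute Welch two-sample t statistic
#'     \eqn{|t| = |\mu_2-\mu_1| / \sqrt{\sigma_1^2/n + \sigma_2^2/m}}.}
#'   \item{pearsonScore}{the absolute between-class correlation
#'     \eqn{|R| = |\frac{1}{n}\sum_j (x_{1j}-\mu_1)(x_{2j}-\mu_2)| /
#'     (\sigma_1\sigma_2)}, pairing trials by index within each class
#'     (requires equal class sizes).}
#' }
#' All three are invariant to affine rescaling of the feature. A vanishing
#' denominator with equal means scores 0; with unequal means, Fisher and t
#' return \code{Inf} (capped to a large finite value inside
#' [aggregateFilter()] before normalization).
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param feature a feature name.
#' @param classA,classB two situation labels.
#' @return numeric scalar score.
#' @export
fisherScore <- function(features, feature, classA, classB) {
  x <- .feature_vec(features, feature); y <- situations(features)
  .fisher_raw(x[y == classA], x[y == classB])
}

#' @rdname fisherScore
#' @export
ttest2Score <- function(features, feature, classA, classB) {
  x <- .feature_vec(features, feature); y <- situations(features)
  .ttest2_raw(x[y == classA], x[y == classB])
}

#' @rdname fisherScore
#' @export
pearsonScore <- function(features, feature, classA, classB) {
  x <- .feature_vec(features, feature); y <- situations(features)
  .pearson_raw(x[y == classA], x[y == classB])
}

#' One-way ANOVA filter score for a single feature
#'
#' The classical one-way ANOVA F statistic of the feature across all classes
#' (the multi-class extension of the two-sample t test). Zero within-class
#' variance everywhere with distinct means yields \code{Inf} (capped inside
#' [aggregateFilter()]).
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param feature a feature name.
#' @return numeric scalar F statistic.
#' @export
anovaScore <- function(features, feature) {
  x <- .feature_vec(features, feature)
  g <- factor(situations(features))
  within <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (within == 0) {
    means <- tapply(x, g, mean)
    return(if (max(means) == min(means)) 0 else Inf)
  }
  stats::anova(stats::lm(x ~ g))[["F value"]][1]
}

#' ReliefF multi-class feature weights
#'
#' Neighbor-based relevance: for every anchor trial, the per-feature
#' differences to its k nearest same-class neighbors (hits) are subtracted
#' and the differences to the k nearest neighbors of every other class
#' (misses, weighted by the prior of that class renormalized over the
#' non-anchor classes) are added; weights are averaged over anchors and
#' neighbors. Features are range-normalized to [0, 1] before distance
#' (Manhattan) and difference computation, the canonical ReliefF setting.
#' Every trial serves as an anchor.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param featureSet character vector of feature names (default: all).
#' @param k neighbors per class (default 10); reduced with a warning when a
#'   class is smaller than k + 1.
#' @return named numeric vector of ReliefF weights.
#' @export
relieffScore <- function(features, featureSet = NULL, k = 10) {
  x <- featureValues(features)
  if (!is.null(featureSet)) x <- x[, featureSet, drop = FALSE]
  y <- situations(features)
  n <- nrow(x)
  counts <- table(y)
  kmax <- min(counts) - 1L
  if (k > kmax) {
    warning(sprintf("smallest class supports only %d neighbors; reducing k from %d",
                    kmax, k), call. = FALSE)
    k <- kmax
  }
  if (k < 1L) stop("every class needs at least 2 trials", call. = FALSE)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1                 # constant features contribute no diffs
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, `/`)
  D <- as.matrix(dist(xn, method = "manhattan"))
  prior <- as.numeric(counts) / n
  names(prior) <- names(counts)
  W <- numeric(ncol(xn))
  for (i in seq_len(n)) {
    d <- D[i, ]; d[i] <- Inf
    same <- which(y == y[i])
    hits <- same[order(d[same])[seq_len(k)]]
    hit_term <- colSums(abs(xn[hits, , drop = FALSE] -
                            matrix(xn[i, ], k, ncol(xn), byrow = TRUE))) / k
    miss_term <- numeric(ncol(xn))
    panchor <- prior[as.character(y[i])]
    for (cl in setdiff(unique(y), y[i])) {
      other <- which(y == cl)
      miss <- other[order(d[other])[seq_len(k)]]
      pc <- prior[as.character(cl)] / (1 - panchor)
      miss_term <- miss_term + pc *
        colSums(abs(xn[miss, , drop = FALSE] -
                    matrix(xn[i, ], k, ncol(xn), byrow = TRUE))) / k
    }
    W <- W + (miss_term - hit_term) / n
  }
  names(W) <- colnames(xn)
  W
}

.minmax <- function(s) {
  fin <- is.finite(s)
  if (any(!fin)) s[!fin] <- max(s[fin], 0) + 1   # cap Inf above the finite max
  rng <- max(s) - min(s)
  if (rng == 0) return(rep(0, length(s)))
  (s - min(s)) / rng
}

.pairwise_mean <- function(x, y, fun) {
  classes <- sort(unique(y))
  pairs <- utils::combn(classes, 2)
  mean(apply(pairs, 2, function(p) fun(x[y == p[1]], x[y == p[2]])))
}

#' Filter-model scoring, normalization and ranking
#'
#' Scores every feature with the five filter tests -- Fisher, two-sample t
#' and Pearson averaged over all unordered class pairs, ANOVA and ReliefF
#' natively multi-class -- min-max normalizes each test's score vector to
#' [0, 1] (infinite scores are first capped one unit above the finite
#' maximum; a constant score vector normalizes to all-0), and aggregates by
#' the per-feature mean of the five normalized scores. Rankings (descending,
#' ties broken by table order) are exposed per individual test and for the
#' aggregate, so both a single-test filter (e.g. the two-sample t variant)
#' and the combined-score variant are available downstream.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param relieffK ReliefF neighbor count (default 10).
#' @return a \linkS4class{FilterScores}.
#' @export
aggregateFilter <- function(features, relieffK = 10) {
  x <- featureValues(features)
  y <- situations(features)
  p <- ncol(x)
  raw <- matrix(NA_real_, p, 5,
                dimnames = list(colnames(x),
                                c("fisher", "ttest2", "pearson", "anova", "relieff")))
  for (j in seq_len(p)) {
    raw[j, "fisher"] <- .pairwise_mean(x[, j], y, .fisher_raw)
    raw[j, "ttest2"] <- .pairwise_mean(x[, j], y, .ttest2_raw)
    raw[j, "pearson"] <- suppressWarnings(.pairwise_mean(x[, j], y, .pearson_raw))
    g <- factor(y)
    within <- sum(tapply(x[, j], g, function(v) sum((v - mean(v))^2)))
    raw[j, "anova"] <- if (within == 0) {
      means <- tapply(x[, j], g, mean)
      if (max(means) == min(means)) 0 else Inf
    } else stats::anova(stats::lm(x[, j] ~ g))[["F value"]][1]
  }
  raw[, "relieff"] <- suppressWarnings(relieffScore(features, k = relieffK))
  normalized <- apply(raw, 2, .minmax)
  dimnames(normalized) <- dimnames(raw)
  aggregate <- rowMeans(normalized)
  rank_of <- function(s) colnames(x)[order(-s, seq_along(s))]
  ranking <- c(lapply(seq_len(5), function(t) rank_of(normalized[, t])),
               list(rank_of(aggregate)))
  names(ranking) <- c(colnames(raw), "aggregate")
  new("FilterScores", raw = raw, normalized = normalized,
      aggregate = aggregate, ranking = ranking)
}

#' Top-ranked features of a filter variant
#'
#' @param scores a \linkS4class{FilterScores}.
#' @param variant one of "fisher", "ttest2", "pearson", "anova", "relieff",
#'   "aggregate".
#' @param n how many features to keep (default 20).
#' @return character vector of the n highest-ranked feature names.
#' @export
topFeatures <- function(scores, variant = c("ttest2", "aggregate", "fisher",
                                            "pearson", "anova", "relieff"),
                        n = 20) {
  variant <- match.arg(variant)
  head(scores@ranking[[variant]], n)
}

#' Sequential forward selection wrapped around the classifier
#'
#' Greedy wrapper selection: starting from an empty final set, each step adds
#' the candidate feature whose addition gives the highest mean
#' cross-validated recognition rate of the network, until every candidate has
#' been added; the recorded accuracy after each addition is the trace. The
#' retained subset is the shortest prefix of the greedy ordering whose
#' accuracy is within \code{tol} of the trace maximum. The default evaluator
#' is one repetition of stratified \code{folds}-fold CV with a fold
#' assignment fixed by \code{seed}, so the whole search is deterministic;
#' ties at a step go to the earlier candidate in the supplied order.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param initialFeatures character, the candidate set (e.g. a filter top-20).
#' @param evaluator optional function(featureNames) -> mean accuracy; when
#'   omitted the internal CV harness is used.
#' @param folds CV folds of the default evaluator (default 10).
#' @param seed integer seed for the default evaluator.
#' @param tol prefix-retention tolerance on accuracy (default 0.001).
#' @param ... passed to [mlpTrain()] by the default evaluator.
#' @return a \linkS4class{SelectionResult}.
#' @export
sfsWrapper <- function(features, initialFeatures, evaluator = NULL,
                       folds = 10, seed = 1, tol = 0.001, ...) {
  if (length(initialFeatures) == 0L)
    stop("initialFeatures must be non-empty", call. = FALSE)
  if (is.null(evaluator)) {
    evaluator <- function(fset)
      meanRate(evaluateCv(features, fset, repetitions = 1, folds = folds,
                          seed = seed, ...))
  }
  remaining <- initialFeatures
  chosen <- character()
  trace <- numeric()
  while (length(remaining)) {
    accs <- vapply(remaining, function(f) {
      tryCatch(evaluator(c(chosen, f)), error = function(e)
        stop(sprintf("evaluator failed on {%s}: %s",
                     paste(c(chosen, f), collapse = ", "),
                     conditionMessage(e)), call. = FALSE))
    }, numeric(1))
    best <- which.max(accs)           # ties -> earliest candidate
    chosen <- c(chosen, remaining[best])
    trace <- c(trace, accs[best])
    remaining <- remaining[-best]
  }
  keep <- which(trace >= max(trace) - tol)[1]
  new("SelectionResult", rankedFeatures = chosen, accuracyTrace = unname(trace),
      selected = chosen[seq_len(keep)])
}

#' Hybrid filter + wrapper feature selection
#'
#' The two-stage reduction: the filter model preselects the \code{nKeep}
#' highest-ranked features (fast, classifier-independent), then the SFS
#' wrapper orders that candidate set by cross-validated network accuracy and
#' retains the shortest near-optimal prefix. Applicable unchanged to the
#' 60-feature direct bank, a graphic occupancy bank, or their combination.
#'
#' @param features a \linkS4class{PostureFeatures}.
#' @param variant filter variant: "ttest2" (single-test) or "aggregate"
#'   (mean of the five normalized scores), or any single test name.
#' @param nKeep filter preselection size (default 20).
#' @param folds,seed,tol,... passed to [sfsWrapper()].
#' @param relieffK ReliefF neighbor count for the filter stage.
#' @return a \linkS4class{SelectionResult}.
#' @examples
#' \donttest{
#' corpus <- generateCorpus(nPerSituation = 12, seed = 1)
#' ft <- extractDirect(corpus, defaultLayout())
#' sel <- hybridSelect(ft, variant = "ttest2", folds = 4, maxit = 80)
#' selectedFeatures(sel)
#' }
#' @export
hybridSelect <- function(features, variant = c("ttest2", "aggregate", "fisher",
                                               "pearson", "anova", "relieff"),
                         nKeep = 20, folds = 10, seed = 1, tol = 0.001,
                         relieffK = 10, ...) {
  variant <- match.arg(variant)
  scores <- aggregateFilter(features, relieffK = relieffK)
  candidates <- topFeatures(scores, variant, nKeep)
  sfsWrapper(features, candidates, folds = folds, seed = seed, tol = tol, ...)
}

#' Export a selection result as CSV
#'
#' Rows of (rank, feature, cv_accuracy_after_adding, selected).
#'
#' @param result a \linkS4class{SelectionResult}.
#' @param path output CSV file.
#' @return invisibly, \code{path}.
#' @export
writeSelection <- function(result, path) {
  write.csv(data.frame(rank = seq_along(result@rankedFeatures),
                       feature = result@rankedFeatures,
                       cv_accuracy_after_adding = result@accuracyTrace,
                       selected = result@rankedFeatures %in% result@selected),
            path, row.names = FALSE)
  invisible(path)
}
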