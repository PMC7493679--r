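#' Static (non-biomimetic) model specification
#'
#' Hyper-parameters for the margin- and entropy-based static classifiers:
#' support vector machines with linear, radial-basis (gamma 0.99) or
#' sigmoid kernels, and a random decision forest of 10 trees with a minimum
#' of two samples to split a node and at most three features considered per
#' split.
#'
#' @param family One of `"svm_linear"`, `"svm_rbf"`, `"svm_sigmoid"`,
#'   `"rdf"`.
#' @param gamma Kernel coefficient for the RBF and sigmoid kernels.
#' @param cost SVM regularization constant C.
#' @param n_trees,mtry,min_split Forest size, features per split, and
#'   minimum samples required to split.
#' @param seed Integer seed (forest bootstrap / any internal randomness).
#' @return List of class `static_model_spec`.
#' @export
static_model_spec <- function(family = c("svm_linear", "svm_rbf", "svm_sigmoid", "rdf"),
                              gamma = 0.99, cost = 1, n_trees = 10, mtry = 3,
                              min_split = 2, seed = 1) {
  family <- match.arg(family)
  structure(
    list(
      family = family, gamma = gamma, cost = cost, n_trees = as.integer(n_trees),
      mtry = as.integer(mtry), min_split = as.integer(min_split),
      seed = as.integer(seed)
    ),
    class = "static_model_spec"
  )
}

#' Train a static classifier on a feature table
#'
#' Fits one of the non-biomimetic model families to fixed-length feature
#' vectors: a (kernelized) maximum-margin hyperplane via libsvm, or a
#' random decision forest with majority vote over its trees. Feature
#' scaling is expected to be done beforehand with a train-frozen
#' [fit_scaler()]; libsvm's internal rescaling is disabled.
#'
#' @param features Numeric `N x F` matrix of feature vectors.
#' @param labels Binary class labels, one per row.
#' @param spec A [static_model_spec()].
#' @param scaler Optional frozen `scaler_stats` to store with the model.
#' @return A `gait_static` model (also class `trained_model`).
#' @export
train_static <- function(features, labels, spec = static_model_spec(), scaler = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    stop("training labels must contain exactly two classes", call. = FALSE)
  }
  y <- factor(labels, levels = lev)
  fit <- with_seed(spec$seed, {
    if (spec$family == "rdf") {
      randomForest::randomForest(
        x = features, y = y,
        ntree = spec$n_trees,
        mtry = min(spec$mtry, ncol(features)),
        nodesize = max(1L, spec$min_split - 1L)
      )
    } else {
      kernel <- switch(spec$family,
        svm_linear = "linear", svm_rbf = "radial", svm_sigmoid = "sigmoid"
      )
      e1071::svm(
        x = features, y = y, kernel = kernel,
        gamma = spec$gamma, cost = spec$cost, scale = FALSE
      )
    }
  })
  structure(
    list(
      family = spec$family, fit = fit, levels = lev, spec = spec,
      scaler = scaler, manifest = list(n_features = ncol(features), n_train = nrow(features))
    ),
    class = c("gait_static", "trained_model")
  )
}

#' Predict with a static classifier
#'
#' @param object A `gait_static` model.
#' @param features Numeric `N x F` matrix with the training feature layout.
#' @param ... Unused.
#' @return Tibble with one row per sample: `label` plus the two class
#'   probability columns. For the forest these are tree vote fractions
#'   (majority vote decides the label); for SVMs a logistic transform of
#'   the signed decision value, a monotone surrogate so the most probable
#'   class equals the margin-side class.
#' @export
predict.gait_static <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$manifest$n_features) {
    stop(sprintf(
      "feature count mismatch: model expects %d features, got %d",
      object$manifest$n_features, ncol(features)
    ), call. = FALSE)
  }
  lev <- object$levels
  if (object$family == "rdf") {
    votes <- predict(object$fit, features, type = "prob")
    probs <- votes[, lev, drop = FALSE]
    label <- lev[max.col(probs, ties.method = "first")]
  } else {
    pred <- predict(object$fit, features, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # decision value is signed toward the first level named in the colname
    pos <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    p_pos <- sigmoid(as.numeric(dv))
    probs <- cbind(p_pos, 1 - p_pos)
    colnames(probs) <- c(pos, setdiff(lev, pos))
    probs <- probs[, lev, drop = FALSE]
    label <- as.character(pred)
  }
  out <- tibble::as_tibble(as.data.frame(probs))
  colnames(out) <- lev
  out$label <- label
  out[, c("label", lev)]
}
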