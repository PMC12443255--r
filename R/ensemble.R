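#' @name ensemble_model
#' @title Soft-voting tree ensemble
#' @description
#' The final classifier: a soft-voting ensemble whose default members
#' are a random forest, an exact-split gradient-boosted tree model and
#' a histogram-based gradient-boosted tree model. Members predict
#' positive-class probabilities which are combined by a normalized
#' weighted arithmetic mean. Members are pluggable by name so
#' single-model comparisons reuse the same machinery.
NULL

# member registry: each entry has fit(X, y01, seed, params) and
# prob(fit, X) returning positive-class probabilities
member_registry <- function() {
  xgb_fit <- function(tree_method) function(X, y01, seed, params) {
    p <- utils::modifyList(list(
      objective = "binary:logistic", eta = 0.1, max_depth = 3L,
      tree_method = tree_method, nthread = 1L, seed = seed), params)
    nrounds <- p$nrounds %||% 150L
    p$nrounds <- NULL
    dtrain <- xgboost::xgb.DMatrix(X, label = y01)
    xgboost::xgb.train(params = p, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  }
  xgb_prob <- function(fit, X) {
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(X)))
  }
  list(
    random_forest = list(
      fit = function(X, y01, seed, params) {
        ntree <- params$ntree %||% 300L
        with_seed(seed, randomForest::randomForest(
          x = X, y = factor(y01, levels = c(0L, 1L)), ntree = ntree))
      },
      prob = function(fit, X) {
        unname(stats::predict(fit, X, type = "prob")[, "1"])
      }),
    gradient_boosting = list(
      fit = xgb_fit("exact"), prob = xgb_prob),
    hist_gradient_boosting = list(
      fit = xgb_fit("hist"), prob = xgb_prob)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble configuration
#'
#' @param members ordered character vector of base-learner names;
#'   available: `"random_forest"`, `"gradient_boosting"`,
#'   `"hist_gradient_boosting"`.
#' @param weights per-member non-negative voting weights (default
#'   equal); normalized to sum 1 at voting time.
#' @param seed shared integer seed pinned into every member fit.
#' @param params optional named list (per member name) of hyperparameter
#'   overrides; members otherwise use library defaults.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(members = c("random_forest",
                                        "gradient_boosting",
                                        "hist_gradient_boosting"),
                            weights = NULL, seed = 1L, params = list()) {
  stopifnot(length(members) >= 1L,
            all(members %in% names(member_registry())))
  if (is.null(weights)) weights <- rep(1, length(members))
  stopifnot(length(weights) == length(members), all(weights >= 0),
            sum(weights) > 0)
  structure(list(members = members, weights = weights,
                 seed = as.integer(seed), params = params),
            class = "ensemble_config")
}

#' Train the soft-voting ensemble
#'
#' @param data a [labeled_matrix] containing both classes.
#' @param config an [ensemble_config()].
#' @return A `trained_ensemble`: fitted members, config echo, feature
#'   dimensionality `d` and class order `c(0, 1)`.
#' @export
train_ensemble <- function(data, config = ensemble_config()) {
  stopifnot(inherits(data, "labeled_matrix"))
  if (length(unique(data$y)) < 2L) stop("training data has a single class")
  reg <- member_registry()
  X <- data$X
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  fits <- lapply(config$members, function(m) {
    reg[[m]]$fit(X, data$y, config$seed, config$params[[m]] %||% list())
  })
  names(fits) <- make.unique(config$members)
  structure(list(fits = fits, members = config$members,
                 config = config, d = ncol(X),
                 feature_names = colnames(X), classes = c(0L, 1L)),
            class = "trained_ensemble")
}

#' Soft-voting probability combination
#'
#' Weighted arithmetic mean of per-member positive-class probability
#' vectors, with weights normalized to sum 1.
#'
#' @param prob_rows a members x n matrix (or list of equal-length
#'   vectors) of probabilities in `[0, 1]`.
#' @param weights per-member non-negative weights.
#' @return Combined probability vector of length n.
#' @export
soft_vote <- function(prob_rows, weights = NULL) {
  if (is.list(prob_rows)) {
    len <- vapply(prob_rows, length, integer(1))
    if (length(unique(len)) != 1L) stop("probability vectors differ in length")
    prob_rows <- do.call(rbind, prob_rows)
  }
  if (is.null(weights)) weights <- rep(1, nrow(prob_rows))
  stopifnot(length(weights) == nrow(prob_rows), all(weights >= 0),
            sum(weights) > 0, all(prob_rows >= 0 & prob_rows <= 1))
  as.numeric(crossprod(prob_rows, weights / sum(weights)))
}

#' Predict with a trained ensemble
#'
#' Combined probability at or above `threshold` yields the positive
#' label (a probability exactly at the threshold is positive).
#'
#' @param object a `trained_ensemble`.
#' @param X feature matrix with the training dimensionality.
#' @param threshold decision threshold on the combined positive-class
#'   probability (default 0.5).
#' @param ... unused.
#' @return List with `labels` (0/1), `prob` (combined positive-class
#'   probabilities) and `member_probs` (members x n matrix).
#' @export
predict.trained_ensemble <- function(object, X, threshold = 0.5, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$d) stop("feature dimensionality mismatch: model has ",
                                object$d, ", input has ", ncol(X))
  colnames(X) <- object$feature_names
  reg <- member_registry()
  member_probs <- do.call(rbind, lapply(seq_along(object$fits), function(i) {
    reg[[object$members[i]]]$prob(object$fits[[i]], X)
  }))
  rownames(member_probs) <- names(object$fits)
  prob <- soft_vote(member_probs, object$config$weights)
  list(labels = as.integer(prob >= threshold), prob = prob,
       member_probs = member_probs)
}

#' Save / load a trained ensemble
#'
#' Single-archive persistence with a format-version stamp and the
#' configuration echoed alongside the fitted members.
#'
#' @param model a `trained_ensemble`.
#' @param path archive path.
#' @return `path` invisibly; `load_ensemble` returns the model.
#' @export
save_ensemble <- function(model, path) {
  stopifnot(inherits(model, "trained_ensemble"))
  saveRDS(list(format = "acpkit-ensemble-1", model = model), path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "acpkit-ensemble-1")) {
    stop("not an acpkit ensemble archive: ", path)
  }
  obj$model
}
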