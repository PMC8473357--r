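#' Classifier specification
#'
#' Settings for the four classification methods: C-SVM with an RBF
#' kernel (one-vs-one multiclass), k-nearest neighbours, linear
#' discriminant analysis, and a feed-forward neural network with one
#' hidden layer of 30 nodes.  SVM cost/width and the KNN k are selected
#' by five-fold cross-validation over `grid`; passing a single-row grid
#' fixes the hyperparameters and skips the search.
#'
#' @param method one of `"SVM"`, `"KNN"`, `"LDA"`, `"ANN"`.
#' @param grid data frame of candidate hyperparameters; defaults to the
#'   conventional log-spaced grids (SVM: cost 2^-5..2^15, gamma
#'   2^-15..2^3 in log2 steps of 2; KNN: odd k in 1..25; LDA and ANN have
#'   no searched parameters).
#' @param cv_folds number of cross-validation folds (>= 2).
#' @param seed RNG seed for fold assignment and ANN initialisation.
#' @param ann_maxit,ann_decay ANN training budget and weight decay.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(method = c("SVM", "KNN", "LDA", "ANN"),
                            grid = NULL, cv_folds = 5L, seed = 1L,
                            ann_maxit = 500L, ann_decay = 0) {
  method <- match.arg(method)
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (is.null(grid)) {
    grid <- switch(method,
      SVM = expand.grid(cost = 2^seq(-5, 15, by = 2),
                        gamma = 2^seq(-15, 3, by = 2)),
      KNN = data.frame(k = seq(1L, 25L, by = 2L)),
      LDA = data.frame(row.names = 1),
      ANN = data.frame(size = 30L)
    )
  }
  structure(list(method = method, grid = grid, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), ann_maxit = as.integer(ann_maxit),
                 ann_decay = ann_decay),
            class = "classifier_spec")
}

fit_backend <- function(method, X, y, params, spec) {
  switch(method,
    SVM = e1071::svm(x = X, y = y, type = "C-classification",
                     kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(X)),
                     scale = FALSE),
    KNN = list(train = X, cl = y, k = as.integer(params$k %||% 5L)),
    LDA = MASS::lda(x = X, grouping = y),
    ANN = with_seed(spec$seed, {
      nnet::nnet(x = X, y = nnet::class.ind(y),
                 size = as.integer(params$size %||% 30L), softmax = TRUE,
                 decay = spec$ann_decay, maxit = spec$ann_maxit,
                 MaxNWts = 100000L, trace = FALSE)
    })
  )
}

predict_backend <- function(method, fit, X, levels) {
  pred <- switch(method,
    SVM = as.character(stats::predict(fit, X)),
    KNN = as.character(class::knn(fit$train, X, fit$cl, k = fit$k,
                                  use.all = TRUE)),
    LDA = as.character(stats::predict(fit, X)$class),
    ANN = {
      p <- stats::predict(fit, X, type = "raw")
      colnames(p)[max.col(p, ties.method = "first")]
    }
  )
  factor(pred, levels = levels)
}

#' Split trials into training and test sets
#'
#' Reproducibly partitions a trial list into `n_sets` near-equal random
#' sets; all but one set train the model (and the normalization bounds),
#' the held-out set is never seen before testing.
#'
#' @param trials list of trials.
#' @param n_sets number of sets; default 6 (5 train : 1 test).
#' @param seed RNG seed.
#' @return List with `train`, `test` (trial lists) and `assignment`
#'   (set id per trial).
#' @export
split_trials <- function(trials, n_sets = 6L, seed = 1L) {
  n <- length(trials)
  n_sets <- as.integer(n_sets)
  if (n < n_sets) {
    stop("need at least ", n_sets, " trials to form ", n_sets, " sets, got ", n)
  }
  assignment <- with_seed(seed, {
    sets <- rep(seq_len(n_sets), length.out = n)
    sets[sample.int(n)]
  })
  list(train = trials[assignment != n_sets],
       test = trials[assignment == n_sets],
       assignment = assignment)
}

#' Tune and train a classifier
#'
#' Grid-searches the spec's hyperparameter grid by stratified k-fold
#' cross-validation on the training rows (steady-state data only, by the
#' caller's mask), refits the best setting on all rows, and returns the
#' fitted model.  Deterministic under the spec's seed.
#'
#' @param X numeric feature matrix (normalized training rows).
#' @param y labels (factor or coercible); every class must be present.
#' @param spec a [classifier_spec()].
#' @return A `gait_model` with the fitted backend, class list, tuned
#'   values and the cross-validation table.
#' @export
tune_and_train <- function(X, y, spec) {
  if (!inherits(spec, "classifier_spec")) stop("spec must be a classifier_spec")
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  counts <- table(y)
  if (any(counts == 0L)) {
    stop("class(es) absent from training data: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  grid <- spec$grid
  cv <- NULL
  best <- if (nrow(grid) > 0L) as.list(grid[1L, , drop = FALSE]) else list()
  if (nrow(grid) > 1L) {
    folds <- with_seed(spec$seed, {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep(seq_len(spec$cv_folds), length.out = length(idx)))
      }
      f
    })
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      hits <- 0L
      for (k in seq_len(spec$cv_folds)) {
        tr <- folds != k
        if (length(unique(y[tr])) < length(levels(y))) next
        fit <- fit_backend(spec$method, X[tr, , drop = FALSE], y[tr], params, spec)
        pred <- predict_backend(spec$method, fit, X[!tr, , drop = FALSE], levels(y))
        hits <- hits + sum(pred == y[!tr])
      }
      acc[g] <- hits / length(y)
    }
    cv <- cbind(grid, cv_accuracy = acc)
    best <- as.list(grid[which.max(acc), , drop = FALSE])
  }
  fit <- fit_backend(spec$method, X, y, best, spec)
  structure(list(method = spec$method, fit = fit, levels = levels(y),
                 tuned = best, cv = cv, spec = spec,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "gait_model")
}

#' Per-sample streaming prediction
#'
#' Applies a trained model to every feature row, yielding the raw
#' (pre-vote) label stream; a pure function of the model and each row.
#'
#' @param model a [tune_and_train()] result.
#' @param X normalized feature matrix with the model's columns.
#' @return Factor of predicted labels, one per row.
#' @export
predict_stream <- function(model, X) {
  if (!inherits(model, "gait_model")) stop("model must be a gait_model")
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop("feature count mismatch: model expects ", model$n_features,
         " columns, got ", ncol(X))
  }
  predict_backend(model$method, model$fit, X, model$levels)
}

#' @export
print.gait_model <- function(x, ...) {
  tuned <- if (length(x$tuned)) {
    paste(names(x$tuned), unlist(x$tuned), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<gait_model> %s on %d features, classes: %s\n  tuned: %s\n",
              x$method, x$n_features, paste(x$levels, collapse = ", "), tuned))
  invisible(x)
}
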