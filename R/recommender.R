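#' Base learners for the recommender
#'
#' A base learner is a pair of closures `fit(X, y, seed)` / `predict(model,
#' X)` over a binary or multi-class factor response.  Bundled learners:
#' `"rf"`, a random forest (default `ntree = 10` trees, mirroring the
#' ensemble size the recommender was tuned with), and `"linear"`, a
#' linear-margin support-vector classifier (default `cost = 1`).  A response
#' with a single observed class yields a constant learner rather than an
#' error, so labels without positive examples degrade to constant-negative
#' stubs.
#'
#' @param spec `"rf"` or `"linear"`
#' @param ntree number of trees (`rf`)
#' @param cost margin cost (`linear`)
#' @return a list with `fit`, `predict`, `spec`
#' @export
base_learner <- function(spec = c("rf", "linear"), ntree = 10, cost = 1) {
  spec <- match.arg(spec)
  fit_fun <- if (spec == "rf") {
    function(X, y, seed) {
      yf <- droplevels(factor(y))
      if (nlevels(yf) < 2L)
        return(structure(list(constant = levels(yf)[1] %||% "0"),
                         class = "rxv_const_learner"))
      with_seed(seed, randomForest::randomForest(x = X, y = yf, ntree = ntree))
    }
  } else {
    function(X, y, seed) {
      yf <- droplevels(factor(y))
      if (nlevels(yf) < 2L)
        return(structure(list(constant = levels(yf)[1] %||% "0"),
                         class = "rxv_const_learner"))
      with_seed(seed, e1071::svm(x = X, y = yf, kernel = "linear",
                                 cost = cost, scale = FALSE))
    }
  }
  pred_fun <- function(model, X) {
    if (inherits(model, "rxv_const_learner"))
      return(rep(model$constant, nrow(X)))
    # make sure the learner's S3 predict method is registered even when the
    # model was deserialized into a fresh session
    requireNamespace(if (inherits(model, "svm")) "e1071" else "randomForest",
                     quietly = TRUE)
    # prediction is RNG-pinned: random forests break exact vote ties with
    # the RNG, and predictions must be pure functions of (model, X)
    with_seed(0, as.character(stats::predict(model, X)))
  }
  list(spec = spec, fit = fit_fun, predict = pred_fun)
}

#' Fit a reaction class recommender
#'
#' Trains a multi-label classifier on a pivoted starting-material dataset
#' using one of four problem-transformation strategies:
#'
#' * `"br"` (binary relevance): one independent binary learner per class.
#' * `"cc"` (classifier chain): like BR, but each learner in the chain also
#'   receives the predictions for the earlier labels as extra feature
#'   columns (at prediction time the chain feeds forward its own
#'   predictions).
#' * `"rakeld"` (disjoint random k-labelsets): the vocabulary is randomly
#'   partitioned into subsets of size `labelset_size`; one label-powerset
#'   multi-class learner is trained per subset.
#' * `"rakelo"` (overlapping random k-labelsets): `model_count` random
#'   subsets of size `labelset_size` (default twice the number of labels,
#'   the standard ensemble sizing); a label is predicted positive when a
#'   strict majority of the subsets covering it votes positive.
#'
#' An empty prediction set is legitimate output ("no recommendation"): every
#' binary decision can be negative.
#'
#' @param x a training `rxv_mlds` (see [pivot_merge()], [stratified_split()])
#' @param strategy one of `"br"`, `"cc"`, `"rakeld"`, `"rakelo"`
#' @param base a base learner spec (string passed to [base_learner()], or a
#'   list as returned by it)
#' @param labelset_size RAkEL labelset size k (default 3)
#' @param model_count RAkELo ensemble size (default `2 * n_labels`)
#' @param chain_order CC chain order (default vocabulary order)
#' @param seed RNG seed controlling subset draws and base-learner randomness
#' @param ... passed to [base_learner()] when `base` is a string
#' @return an object of class `reaction_recommender`
#' @examples
#' \dontrun{
#' rxns <- generate_classified_reactions(fixture_spec(n_reactions = 500))
#' ds <- pivot_merge(build_labeled_entries(rxns, level = 3), "keys166")
#' sp <- stratified_split(ds, 0.8, seed = 7)
#' rec <- reaction_recommender(sp$train, strategy = "cc")
#' predict(rec, sp$test)[1:3]
#' }
#' @export
reaction_recommender <- function(x, strategy = c("cc", "br", "rakeld", "rakelo"),
                                 base = "rf", labelset_size = 3,
                                 model_count = NULL, chain_order = NULL,
                                 seed = 11, ...) {
  stopifnot(inherits(x, "rxv_mlds"), nrow(x$X) > 0L)
  strategy <- match.arg(strategy)
  if (is.character(base)) base <- base_learner(base, ...)
  V <- ncol(x$Y)
  stopifnot(labelset_size >= 1)
  learners <- list()
  labelsets <- NULL
  if (strategy %in% c("br", "cc")) {
    chain <- if (strategy == "cc") (chain_order %||% seq_len(V)) else seq_len(V)
    stopifnot(length(chain) == V, setequal(chain, seq_len(V)))
    Xa <- x$X
    preds <- NULL
    for (pos in seq_along(chain)) {
      j <- chain[pos]
      m <- base$fit(Xa, x$Y[, j], seed + pos)
      learners[[pos]] <- m
      if (strategy == "cc") {
        p <- as.integer(base$predict(m, Xa) == "1")
        newcol <- matrix(p, ncol = 1,
                         dimnames = list(NULL, paste0("chain", pos)))
        Xa <- cbind(Xa, newcol)
      }
    }
    labelsets <- as.list(chain)
  } else {
    if (strategy == "rakeld") {
      perm <- with_seed(seed, sample(V))
      k <- min(labelset_size, V)
      labelsets <- split(perm, ceiling(seq_along(perm) / k))
      labelsets <- unname(labelsets)
    } else {
      mc <- as.integer(model_count %||% (2L * V))
      stopifnot(mc >= 1)
      k <- min(labelset_size, V)
      labelsets <- with_seed(seed, lapply(seq_len(mc), function(i) sample(V, k)))
    }
    for (s in seq_along(labelsets)) {
      cols <- labelsets[[s]]
      combo <- apply(x$Y[, cols, drop = FALSE], 1, paste, collapse = "")
      learners[[s]] <- base$fit(x$X, combo, seed + s)
    }
  }
  structure(list(strategy = strategy, base = base, labelsets = labelsets,
                 chain_order = if (strategy == "cc") unlist(labelsets) else NULL,
                 learners = learners, vocabulary = x$vocabulary,
                 scheme = x$scheme, level = x$level, seed = seed,
                 n_train = nrow(x$X),
                 version = pkg_version()),
            class = "reaction_recommender")
}

#' @export
print.reaction_recommender <- function(x, ...) {
  cat("Reaction class recommender\n")
  cat("  strategy:   ", toupper(x$strategy), " (base: ", x$base$spec, ")\n", sep = "")
  cat("  descriptor: ", x$scheme, "\n", sep = "")
  cat("  classes:    ", length(x$vocabulary$labels), " at level ",
      x$level, "\n", sep = "")
  cat("  trained on: ", x$n_train, " entries\n", sep = "")
  invisible(x)
}

#' @export
summary.reaction_recommender <- function(object, ...) {
  print(object)
  if (object$strategy %in% c("rakeld", "rakelo")) {
    sizes <- lengths(object$labelsets)
    cat("  labelsets:  ", length(sizes), " (sizes ",
        paste(sort(unique(sizes)), collapse = "/"), ")\n", sep = "")
  }
  invisible(object)
}

# Coerce prediction input to a feature matrix under the model's scheme.
as_feature_matrix <- function(object, newdata) {
  if (inherits(newdata, "rxv_mlds")) {
    if (!identical(newdata$scheme, object$scheme))
      stop("dataset scheme ", newdata$scheme, " does not match model scheme ",
           object$scheme)
    return(newdata$X)
  }
  if (inherits(newdata, "rxv_bfp")) newdata <- list(newdata)
  if (inherits(newdata, "rxv_mol")) newdata <- list(newdata)
  if (is.character(newdata)) newdata <- lapply(newdata, mol_from_smiles)
  if (is.list(newdata)) {
    n_bits <- get_scheme(object$scheme, "binary")$n_bits
    X <- matrix(0L, length(newdata), n_bits,
                dimnames = list(NULL, paste0("b", seq_len(n_bits))))
    for (i in seq_along(newdata)) {
      e <- newdata[[i]]
      fp <- if (inherits(e, "rxv_bfp")) e else binary_fingerprint(e, object$scheme)
      if (!identical(fp$scheme, object$scheme))
        stop("fingerprint scheme ", fp$scheme, " does not match model scheme ",
             object$scheme)
      X[i, fp$bits] <- 1L
    }
    return(X)
  }
  if (is.matrix(newdata)) return(newdata)
  stop("cannot interpret newdata for prediction")
}

#' Predict recommended reaction classes
#'
#' @param object a `reaction_recommender`
#' @param newdata an `rxv_mlds`, a feature matrix, molecules / SMILES, or
#'   fingerprints (must match the model's scheme)
#' @param type `"labels"` for a list of recommended label sets (possibly
#'   empty: no recommendation), `"matrix"` for the binary prediction matrix
#' @param ... unused
#' @return per `type`; label sets are lists of `rxv_label`
#' @export
predict.reaction_recommender <- function(object, newdata,
                                         type = c("labels", "matrix"), ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(object, newdata)
  V <- length(object$vocabulary$labels)
  n <- nrow(X)
  Yp <- matrix(0L, n, V, dimnames = list(NULL, object$vocabulary$text))
  if (object$strategy == "br") {
    for (pos in seq_len(V)) {
      j <- object$labelsets[[pos]]
      Yp[, j] <- as.integer(object$base$predict(object$learners[[pos]], X) == "1")
    }
  } else if (object$strategy == "cc") {
    Xa <- X
    for (pos in seq_len(V)) {
      j <- object$labelsets[[pos]]
      p <- as.integer(object$base$predict(object$learners[[pos]], Xa) == "1")
      Yp[, j] <- p
      newcol <- matrix(p, ncol = 1, dimnames = list(NULL, paste0("chain", pos)))
      Xa <- cbind(Xa, newcol)
    }
  } else {
    votes <- matrix(0L, n, V)
    cover <- integer(V)
    for (s in seq_along(object$labelsets)) {
      cols <- object$labelsets[[s]]
      cover[cols] <- cover[cols] + 1L
      combo <- object$base$predict(object$learners[[s]], X)
      bits <- do.call(rbind, strsplit(combo, ""))
      votes[, cols] <- votes[, cols] + matrix(as.integer(bits), n)
    }
    if (object$strategy == "rakeld") {
      Yp[] <- as.integer(votes > 0L)
    } else {
      # strict majority of covering subsets; uncovered labels stay negative
      for (j in seq_len(V))
        if (cover[j] > 0L) Yp[, j] <- as.integer(2L * votes[, j] > cover[j])
    }
  }
  if (type == "matrix") return(Yp)
  lapply(seq_len(n), function(i) object$vocabulary$labels[Yp[i, ] == 1L])
}

#' Micro-averaged multi-label metrics
#'
#' Metrics from globally pooled confusion counts across all entries and
#' labels: recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and their harmonic
#' mean F1.  A zero denominator gives metric 0, keeping the aggregation
#' total on degenerate predictions.
#'
#' @param Y_true,Y_pred binary matrices of identical shape
#' @return list with `tp`, `fp`, `fn`, `tn`, `recall`, `precision`, `f1`
#' @export
micro_metrics <- function(Y_true, Y_pred) {
  if (!all(dim(Y_true) == dim(Y_pred)))
    stop("Y_true and Y_pred must have the same shape")
  tp <- sum(Y_true == 1 & Y_pred == 1)
  fp <- sum(Y_true == 0 & Y_pred == 1)
  fn <- sum(Y_true == 1 & Y_pred == 0)
  tn <- sum(Y_true == 0 & Y_pred == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (recall + precision > 0) 2 * recall * precision / (recall + precision) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = recall, precision = precision, f1 = f1)
}

#' Three-outcome evaluation against annotated classes
#'
#' Every annotated starting material receives one of three outcomes: correct
#' when the recommended classes contain the annotated class,
#' no-recommendation when the recommendation set is empty, wrong otherwise.
#' Evaluation may be run at a more generic hierarchy level than the model's:
#' both the recommendation and the annotation are truncated first, which can
#' only convert wrong outcomes into correct ones.
#'
#' @param model a `reaction_recommender`
#' @param newdata prediction input (see [predict.reaction_recommender()])
#' @param true_labels list of annotated `rxv_label`, one per entry
#' @param level evaluation level (default: the model's level)
#' @return list with `correct_pct`, `wrong_pct`, `norec_pct` (summing to
#'   100), `mean_recs_all`, `mean_recs_nonempty`, `n`
#' @export
evaluate_three_outcome <- function(model, newdata, true_labels, level = NULL) {
  level <- level %||% model$level
  recs <- predict(model, newdata, type = "labels")
  stopifnot(length(recs) == length(true_labels))
  outcome <- character(length(recs))
  nrec <- lengths(recs)
  for (i in seq_along(recs)) {
    if (nrec[i] == 0L) { outcome[i] <- "norec"; next }
    truth <- true_labels[[i]]
    hit <- any(vapply(recs[[i]], matches_at_level, logical(1),
                      b = truth, level = level))
    outcome[i] <- if (hit) "correct" else "wrong"
  }
  n <- length(recs)
  list(correct_pct = 100 * sum(outcome == "correct") / n,
       wrong_pct = 100 * sum(outcome == "wrong") / n,
       norec_pct = 100 * sum(outcome == "norec") / n,
       mean_recs_all = mean(nrec),
       mean_recs_nonempty = if (any(nrec > 0)) mean(nrec[nrec > 0]) else 0,
       n = n)
}

#' Save / load a fitted recommender
#'
#' The model directory holds a JSON manifest (strategy, scheme, vocabulary,
#' level, version) plus the fitted learners as an opaque blob.  Loading
#' refuses a manifest written by a different package version.
#'
#' @param model a `reaction_recommender`
#' @param dir directory to create/use
#' @export
save_recommender <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(strategy = model$strategy, scheme = model$scheme,
                   level = model$level, seed = model$seed,
                   vocabulary = model$vocabulary$text,
                   version = model$version)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_recommender
#' @export
load_recommender <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  now <- pkg_version()
  if (!identical(manifest$version, now))
    stop("model was saved by package version ", manifest$version,
         ", refusing to load into ", now)
  readRDS(file.path(dir, "model.rds"))
}
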