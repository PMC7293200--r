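# Small synthetic dataset where bit j decides label j perfectly.
bitwise_ds <- function(n = 120, V = 6, seed = 2) {
  set.seed(seed)
  X <- matrix(rbinom(n * 10, 1, 0.4), n, 10,
              dimnames = list(NULL, paste0("b", 1:10)))
  X[rowSums(X[, 1:V]) == 0, 1] <- 1L       # keep every row labelled
  Y <- X[, 1:V]
  colnames(Y) <- paste0("Class", 1:V)
  vocab <- label_vocabulary(lapply(colnames(Y), parse_label), 1)
  structure(list(X = X, Y = Y, vocabulary = vocab, scheme = "keys166",
                 level = 1, member_count = rep(1L, n),
                 entry_ids = as.list(seq_len(n))), class = "rxv_mlds")
}

test_that("labelset construction follows the strategy definitions", {
  ds <- bitwise_ds(n = 80, V = 10)
  md <- reaction_recommender(ds, strategy = "rakeld", labelset_size = 3, seed = 1)
  sizes <- lengths(md$labelsets)
  expect_equal(sort(sizes, decreasing = TRUE), c(3, 3, 3, 1))
  expect_setequal(unlist(md$labelsets), 1:10)      # a partition of V
  expect_false(any(duplicated(unlist(md$labelsets))))
  mo <- reaction_recommender(ds, strategy = "rakelo", labelset_size = 3, seed = 1)
  expect_length(mo$labelsets, 20)                   # 2 x |V| models
  expect_true(all(lengths(mo$labelsets) == 3))
  for (s in mo$labelsets) expect_false(any(duplicated(s)))
  mo5 <- reaction_recommender(ds, strategy = "rakelo", labelset_size = 3,
                              model_count = 5, seed = 1)
  expect_length(mo5$labelsets, 5)
})

test_that("all strategies recover a perfectly separable bit-label mapping", {
  ds <- bitwise_ds()
  # binary learners see the deciding bit directly: exact recovery
  for (strat in c("br", "cc")) {
    m <- reaction_recommender(ds, strategy = strat, base = "rf", seed = 11)
    expect_equal(mean(predict(m, ds, type = "matrix") == ds$Y), 1)
  }
  # label-powerset ensembles recombine subset combos; rare combos may cost
  # isolated cells but recovery stays essentially exact
  for (strat in c("rakeld", "rakelo")) {
    m <- reaction_recommender(ds, strategy = strat, base = "rf", seed = 11)
    expect_gte(mean(predict(m, ds, type = "matrix") == ds$Y), 0.99)
  }
  # a test entry with bits {3, 5} set yields exactly labels 3 and 5
  m <- reaction_recommender(ds, strategy = "br", base = "rf", seed = 11)
  x <- matrix(0L, 1, 10, dimnames = list(NULL, paste0("b", 1:10)))
  x[, c(3, 5)] <- 1L
  labs <- predict(m, x)[[1]]
  expect_setequal(vapply(labs, label_text, ""), c("Class3", "Class5"))
})

test_that("a chain-blinded classifier chain degenerates to binary relevance", {
  ds <- fx_split()$train
  p <- ncol(ds$X)
  rf <- base_learner("rf")
  blinded <- list(spec = "blinded-rf",
                  fit = function(X, y, seed) rf$fit(X[, 1:p, drop = FALSE], y, seed),
                  predict = function(m, X) rf$predict(m, X[, 1:p, drop = FALSE]))
  mcc <- reaction_recommender(ds, strategy = "cc", base = blinded, seed = 11)
  mbr <- reaction_recommender(ds, strategy = "br", base = blinded, seed = 11)
  Xt <- fx_split()$test
  expect_identical(predict(mcc, Xt, type = "matrix"),
                   predict(mbr, Xt, type = "matrix"))
})

test_that("micro metrics implement the pooled-count formulas", {
  Yt <- matrix(c(1, 1, 1, 0, 0, 1), 2, 3)
  Yp <- matrix(c(1, 1, 0, 1, 0, 1), 2, 3)
  m <- micro_metrics(Yt, Yp)
  expect_equal(m$tp, 3)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  # spelled-out example: TP=3, FP=1, FN=2
  Yt2 <- matrix(c(rep(1, 5), 0), 1)
  Yp2 <- matrix(c(1, 1, 1, 0, 0, 1), 1)
  m2 <- micro_metrics(Yt2, Yp2)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$f1, 2 / 3)
  # degenerate conventions
  expect_equal(micro_metrics(Yt, Yt)$f1, 1)
  none <- micro_metrics(Yt, matrix(0, 2, 3))
  expect_equal(c(none$recall, none$precision, none$f1), c(0, 0, 0))
  expect_error(micro_metrics(Yt, matrix(0, 3, 2)), "same shape")
})

test_that("micro metrics equal brute-force counting on random matrices", {
  set.seed(9)
  for (i in 1:40) {
    Yt <- matrix(rbinom(50, 1, 0.3), 10, 5)
    Yp <- matrix(rbinom(50, 1, 0.4), 10, 5)
    got <- micro_metrics(Yt, Yp)
    want <- oracle_micro(Yt, Yp)
    expect_equal(got$recall, want$recall)
    expect_equal(got$precision, want$precision)
    expect_equal(got$f1, want$f1)
    if (got$recall + got$precision > 0)
      expect_equal(got$f1, 2 * got$recall * got$precision /
                            (got$recall + got$precision))
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- fx_split()$train
  for (strat in c("br", "rakelo")) {
    m1 <- reaction_recommender(ds, strategy = strat, base = "rf", seed = 5)
    m2 <- reaction_recommender(ds, strategy = strat, base = "rf", seed = 5)
    expect_identical(predict(m1, fx_split()$test, type = "matrix"),
                     predict(m2, fx_split()$test, type = "matrix"))
    expect_identical(m1$labelsets, m2$labelsets)
  }
})

test_that("empty recommendations and scheme mismatches are handled", {
  # when every binary decision is negative the recommendation set is empty
  ds <- bitwise_ds(n = 40, V = 3)
  allneg <- list(spec = "neg",
                 fit = function(X, y, seed) structure(list(), class = "neg"),
                 predict = function(m, X) rep("0", nrow(X)))
  m0 <- reaction_recommender(ds, strategy = "br", base = allneg, seed = 1)
  recs <- predict(m0, ds)
  expect_true(all(lengths(recs) == 0))
  ev <- evaluate_three_outcome(m0, ds, lapply(seq_len(nrow(ds$Y)), function(i)
    parse_label("Class1")))
  expect_equal(ev$norec_pct, 100)
  expect_equal(ev$mean_recs_all, 0)
  wrong <- binary_fingerprint("CCO", "fg")
  expect_error(predict(fx_model(), wrong), "scheme")
})

test_that("models survive a save/load cycle and refuse version skew", {
  m <- fx_model()
  d <- tempfile()
  save_recommender(m, d)
  back <- load_recommender(d)
  expect_identical(predict(back, fx_split()$test, type = "matrix"),
                   predict(m, fx_split()$test, type = "matrix"))
  mani <- jsonlite::read_json(file.path(d, "manifest.json"), simplifyVector = TRUE)
  mani$version <- "99.0.0"
  jsonlite::write_json(mani, file.path(d, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_recommender(d), "version")
})

test_that("three-outcome evaluation books every entry exactly once", {
  m <- fx_model()
  sp <- fx_split()
  truths <- lapply(seq_len(nrow(sp$test$Y)), function(i)
    parse_label(colnames(sp$test$Y)[which(sp$test$Y[i, ] == 1)[1]]))
  ev <- evaluate_three_outcome(m, sp$test, truths)
  expect_equal(ev$correct_pct + ev$wrong_pct + ev$norec_pct, 100)
  expect_gte(ev$mean_recs_nonempty, ev$mean_recs_all)
  # moving the evaluation level from 3 to 1 never loses correct outcomes
  ev1 <- evaluate_three_outcome(m, sp$test, truths, level = 1)
  expect_gte(ev1$correct_pct, ev$correct_pct)
  expect_equal(ev1$norec_pct, ev$norec_pct)
})
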