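sep_1d <- function(n_each = 100) {
  tibble::tibble(f1 = c(rep(0, n_each), rep(10, n_each)),
                 label = c(rep(0L, n_each), rep(1L, n_each)))
}

blob_2d <- function(n = 200, shift = 3, seed = 77) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    tibble::tibble(f1 = stats::rnorm(n) + shift * y,
                   f2 = stats::rnorm(n) - shift * y,
                   label = as.integer(y))
  })
}

test_that("zero iterations give the prior log-odds constant classifier", {
  d <- tibble::tibble(f1 = stats::runif(30), label = rep(c(1L, 1L, 0L), 10))
  m <- adtree(d, iterations = 0)
  expect_equal(nrow(m$rules), 0L)
  expect_equal(m$root_value, 0.5 * log(20 / 10))
  expect_true(all(predict(m, d, type = "class") == 1L))
  expect_error(adtree(tibble::tibble(f1 = 1:5, label = rep(1L, 5))),
               "both classes")
})

test_that("1-D separable data is solved in one iteration with an interior threshold", {
  d <- sep_1d()
  m <- adtree(d, iterations = 1)
  expect_equal(nrow(m$rules), 1L)
  expect_gt(m$rules$threshold, 0)
  expect_lt(m$rules$threshold, 10)
  expect_equal(predict(m, d, type = "class"), d$label)
  # exhaustive check: the chosen split minimises Z over the finite threshold set
  w <- rep(1, nrow(d)) # root value is 0 for balanced classes, weights unchanged
  y <- ifelse(d$label == 1, 1, -1)
  zs <- vapply(c(5), function(t) {
    s <- d$f1 <= t
    2 * (sqrt(sum(w[s & y > 0]) * sum(w[s & y < 0])) +
           sqrt(sum(w[!s & y > 0]) * sum(w[!s & y < 0])))
  }, numeric(1))
  expect_equal(m$rules$threshold, 5)   # only midpoint between the 2 values
  expect_equal(zs, 0)
})

test_that("training-set exponential loss is non-increasing over boosting iterations", {
  d <- blob_2d()
  y <- ifelse(d$label == 1, 1, -1)
  losses <- vapply(0:20, function(it) {
    m <- adtree(d, iterations = it)
    sum(exp(-y * predict_margin(m, d)))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-9))
  expect_lt(losses[21], losses[1])
})

test_that("margins equal the recursive path-enumeration oracle on random trees", {
  withr::with_seed(606, {
    for (rep in 1:20) {
      model <- random_adtree_model(n_rules = sample(1:8, 1), n_features = 4,
                                   seed = sample.int(1e6, 1))
      x <- tibble::as_tibble(matrix(stats::runif(5 * 4, -3, 3), 5, 4,
                                    dimnames = list(NULL, model$feature_names)))
      got <- predict_margin(model, x)
      want <- vapply(seq_len(5), function(i) oracle_margin(model, x[i, ]),
                     numeric(1))
      expect_equal(got, want)
    }
  })
})

test_that("rules nested under one branch never fire for instances taking the other", {
  model <- structure(list(
    root_value = 0.5,
    rules = tibble::tibble(
      id = 1:2,
      precondition_node = c(0L, 1L),   # rule 2 hangs under rule 1's left node
      feature = c("f1", "f2"),
      threshold = c(2, 0),
      left_value = c(0.3, 5),
      right_value = c(-0.4, -5)),
    feature_names = c("f1", "f2"),
    meta = list()), class = "adtree")
  # f1 = 1 goes left at rule 1: margin includes rule 2
  expect_equal(predict_margin(model, tibble::tibble(f1 = 1, f2 = -1)),
               0.5 + 0.3 + 5)
  # f1 = 3 goes right at rule 1: rule 2 is unreachable whatever f2 is
  expect_equal(predict_margin(model, tibble::tibble(f1 = 3, f2 = -1)),
               0.5 - 0.4)
  expect_equal(predict_margin(model, tibble::tibble(f1 = 3, f2 = 1)),
               0.5 - 0.4)
})

test_that("the two-term worked margins and the strict zero rule hold", {
  model <- structure(list(
    root_value = 0.5,
    rules = tibble::tibble(id = 1L, precondition_node = 0L, feature = "f0",
                           threshold = 2, left_value = 0.3, right_value = -0.4),
    feature_names = "f0", meta = list()), class = "adtree")
  expect_equal(predict_margin(model, tibble::tibble(f0 = 1)), 0.8)
  expect_equal(predict_margin(model, tibble::tibble(f0 = 3)), 0.1)
  # classification is margin > 0, strictly: a zero margin is negative
  zero <- structure(list(root_value = 0, rules = model$rules[0, ],
                         feature_names = "f0", meta = list()),
                    class = "adtree")
  expect_equal(adtree_classify(zero, tibble::tibble(f0 = 1)), 0L)
  expect_equal(adtree_classify(model, tibble::tibble(f0 = 1)), 1L)
  expect_equal(adtree_classify(model, tibble::tibble(f0 = 30)), 1L)
  neg <- model; neg$root_value <- -0.5
  expect_equal(adtree_classify(neg, tibble::tibble(f0 = 3)), 0L)
  expect_error(predict_margin(model, tibble::tibble(w = 1)), "lacks feature")
})

test_that("nine iterations yield at most 19 prediction nodes", {
  d <- blob_2d(n = 300)
  m <- adtree(d, iterations = 9)
  expect_lte(2L * nrow(m$rules) + 1L, 19L)
  expect_equal(glance(m)$n_prediction_nodes, 2L * nrow(m$rules) + 1L)
})

test_that("training is deterministic for identical inputs", {
  d <- blob_2d(n = 100, seed = 13)
  m1 <- adtree(d, iterations = 6)
  m2 <- adtree(d, iterations = 6)
  expect_identical(m1$rules, m2$rules)
  expect_identical(predict_margin(m1, d), predict_margin(m2, d))
})

test_that("JSON serialisation round-trips margins bit-exactly", {
  d <- blob_2d(n = 150, seed = 14)
  m <- adtree(d, iterations = 5)
  m$calibration <- fit_calibration(predict_margin(m, d), d$label)
  path <- withr::local_tempfile(fileext = ".json")
  write_adtree(m, path)
  back <- read_adtree(path)
  x <- blob_2d(n = 100, seed = 15)
  expect_identical(predict_margin(back, x), predict_margin(m, x))
  expect_equal(back$calibration$slope, m$calibration$slope)
  # a root-only model survives the round trip too
  m0 <- adtree(d, iterations = 0)
  write_adtree(m0, path)
  expect_equal(read_adtree(path)$root_value, m0$root_value)
})

test_that("tree renderings follow the drawing conventions", {
  d <- sep_1d(20)
  m1 <- adtree(d, iterations = 1)
  dot <- export_tree(m1, "dot")
  expect_equal(stringr::str_count(dot, "shape=ellipse"), 3L)
  expect_equal(stringr::str_count(dot, "shape=box"), 1L)

  d3 <- blob_2d(n = 200, seed = 16)
  m3 <- adtree(d3, iterations = 3)
  txt <- export_tree(m3, "text")
  # discovery order rendered in parentheses after the feature name
  expect_true(grepl(paste0(m3$rules$feature[3], " \\(3\\)"), txt))
  expect_error(export_tree(m1, "png"), "arg")
})

test_that("class-weighted initialisation balances the root prior", {
  withr::with_seed(17, {
    d <- tibble::tibble(f1 = stats::rnorm(200),
                        label = rep(c(0L, 0L, 0L, 1L), 50))
  })
  m <- adtree(d, iterations = 0, class_weighted = TRUE)
  expect_equal(m$root_value, 0)
  m2 <- adtree(d, iterations = 0)
  expect_lt(m2$root_value, 0)
})
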