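# Multi-label evaluation metrics against hand computations and a naive
# reference implementation.

test_that("confusion counts are exact 2x2 tallies per class", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                TRUE, FALSE, TRUE, FALSE), ncol = 2)
  pred <- labels_df_from_matrix(m)
  expect_equal(confusion(pred, pred)$FP, c(0, 0))
  expect_equal(confusion(pred, pred)$FN, c(0, 0))

  # hand-enumerated 8-report fixture
  p <- matrix(c(1,1,1,0,0,0,1,0,  1,0,1,0,1,0,0,1), ncol = 2) == 1
  r <- matrix(c(1,0,1,0,0,1,1,0,  0,0,1,1,1,0,0,0), ncol = 2) == 1
  cc <- confusion(labels_df_from_matrix(p), labels_df_from_matrix(r))
  expect_equal(cc$TP, c(3, 2))
  expect_equal(cc$FP, c(1, 2))
  expect_equal(cc$FN, c(1, 1))
  expect_equal(cc$TN, c(3, 3))
  expect_true(all(cc$TP + cc$FP + cc$FN + cc$TN == 8))

  # single report, single class, predicted true / reference false
  cc2 <- confusion(labels_df_from_matrix(matrix(TRUE)),
                   labels_df_from_matrix(matrix(FALSE)))
  expect_equal(unlist(cc2[c("TP", "FP", "FN", "TN")]),
               c(TP = 0, FP = 1, FN = 0, TN = 0))

  expect_error(confusion(labels_df_from_matrix(matrix(TRUE)),
                         data.frame(id = "zzz", C1 = TRUE)),
               "ids do not match")
})

test_that("label metrics follow their defining ratios", {
  lm <- label_metrics(data.frame(TP = 3, FP = 1, FN = 1, TN = 5))
  expect_equal(lm$precision, 0.75)
  expect_equal(lm$sensitivity, 0.75)
  expect_equal(lm$specificity, 5 / 6)
  expect_equal(lm$f1, 0.75)
  expect_equal(lm$accuracy, 0.8)

  perfect <- label_metrics(data.frame(TP = 4, FP = 0, FN = 0, TN = 6))
  expect_equal(unlist(perfect[c("precision", "sensitivity",
                                "specificity", "f1")]),
               c(precision = 1, sensitivity = 1, specificity = 1, f1 = 1))

  # degenerate denominators surface as NA with a warning, never silent 0
  w <- capture_warnings(
    und <- label_metrics(data.frame(TP = 0, FP = 0, FN = 2, TN = 5)))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(und$precision))
  expect_equal(und$sensitivity, 0)
})

test_that("example-based metrics match direct counting", {
  a <- labels_df_from_matrix(matrix(c(TRUE, TRUE, TRUE, FALSE), ncol = 2))
  b <- labels_df_from_matrix(matrix(c(TRUE, TRUE, FALSE, FALSE), ncol = 2))
  m <- suppressWarnings(multilabel_metrics(a, b))
  expect_equal(m$hamming_loss, 0.25)
  expect_equal(m$exact_match_ratio, 0.5)

  ident <- suppressWarnings(multilabel_metrics(a, a))
  expect_equal(ident$hamming_loss, 0)
  expect_equal(ident$exact_match_ratio, 1)

  ref <- labels_df_from_matrix(matrix(c(1,1, 1,0, 0,0) == 1, nrow = 2))
  m2 <- suppressWarnings(multilabel_metrics(ref, ref))
  expect_equal(m2$cardinality, 1.5)
  expect_equal(m2$label_density, 0.5)

  expect_error(multilabel_metrics(a[0, ], b[0, ]), "empty")
})

test_that("micro averages equal label metrics of the pooled counts", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    k <- sample(2:6, 1)
    p <- matrix(stats::runif(n * k) < 0.5, n, k)
    r <- matrix(stats::runif(n * k) < 0.4, n, k)
    m <- suppressWarnings(multilabel_metrics(labels_df_from_matrix(p),
                                             labels_df_from_matrix(r)))
    pooled <- suppressWarnings(label_metrics(data.frame(
      TP = sum(m$counts$TP), FP = sum(m$counts$FP),
      FN = sum(m$counts$FN), TN = sum(m$counts$TN))))
    expect_identical(m$micro$precision, pooled$precision)
    expect_identical(m$micro$sensitivity, pooled$sensitivity)
    expect_identical(m$micro$f1, pooled$f1)
  }
})

test_that("all metrics agree with a naive reference implementation", {
  set.seed(92)
  for (i in 1:100) {
    n <- sample(2:15, 1)
    k <- sample(1:5, 1)
    p <- matrix(stats::runif(n * k) < 0.5, n, k)
    r <- matrix(stats::runif(n * k) < 0.5, n, k)
    m <- suppressWarnings(multilabel_metrics(labels_df_from_matrix(p),
                                             labels_df_from_matrix(r)))
    o <- oracle_multilabel(p, r)
    expect_equal(m$hamming_loss, o$hamming, tolerance = 1e-12)
    expect_equal(m$exact_match_ratio, o$emr, tolerance = 1e-12)
    expect_equal(m$cardinality, o$cardinality, tolerance = 1e-12)
    expect_equal(m$label_density, o$density, tolerance = 1e-12)
    for (nm in c("precision", "sensitivity", "specificity", "f1")) {
      expect_equal(m$micro[[nm]], unname(o$micro[nm]), tolerance = 1e-12)
    }
    for (j in seq_len(k)) {
      for (nm in c("precision", "sensitivity", "specificity", "f1")) {
        expect_equal(m$per_class[[nm]][j], unname(o$per_class[[j]][nm]),
                     tolerance = 1e-12)
      }
    }
    # hamming loss vanishes exactly when every report is an exact match
    expect_equal(m$hamming_loss == 0, m$exact_match_ratio == 1)
  }
})

test_that("Cohen's kappa matches its closed form and degenerates to NA", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_warning(k <- cohens_kappa(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_true(is.na(k))
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "length")

  set.seed(93)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    a <- stats::runif(n) < 0.5
    b <- stats::runif(n) < 0.5
    expect_equal(suppressWarnings(cohens_kappa(a, b)), oracle_kappa(a, b),
                 tolerance = 1e-12)
  }

  # data.frame interface: per class and pooled over all labels
  p <- labels_df_from_matrix(matrix(c(TRUE, FALSE, TRUE, TRUE), ncol = 2))
  r <- labels_df_from_matrix(matrix(c(TRUE, TRUE, TRUE, FALSE), ncol = 2))
  kk <- suppressWarnings(cohens_kappa(p, r))
  expect_named(kk, c("per_class", "pooled"))
  expect_length(kk$per_class, 2)
})
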