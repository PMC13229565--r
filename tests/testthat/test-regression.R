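# Design matrices, ridge/logistic fits, permutation nulls, selection.

fake_network <- function(id, genes) {
  structure(
    list(
      drug_id = id, targets = genes[1], genes = sort(genes),
      scores = NULL, threshold = 1, edges = NULL
    ),
    class = "drug_network"
  )
}

test_that("design matrix encodes membership over the sorted gene union", {
  nets <- list(
    D1 = fake_network("D1", c("A", "B")),
    D2 = fake_network("D2", c("B", "C"))
  )
  x <- build_design_matrix(nets)
  expect_equal(colnames(x), c("A", "B", "C"))
  expect_equal(unname(x["D1", ]), c(1L, 1L, 0L))
  expect_equal(unname(x["D2", ]), c(0L, 1L, 1L))
  expect_true(all(colSums(x) >= 1))

  nets$D3 <- fake_network("D3", c("B", "C"))
  x3 <- build_design_matrix(nets)
  expect_equal(unname(x3["D2", ]), unname(x3["D3", ]))

  expect_error(build_design_matrix(nets["D1"]), "at least 2")
  expect_error(
    build_design_matrix(stats::setNames(nets[c(1, 1)], c("D1", "D1"))),
    "duplicate drug id"
  )
})

test_that("ridge fit matches the closed form and shrinkage limits", {
  # X = [[1], [0]], y = (1, 0), alpha = 1, no intercept -> beta = 0.5
  x <- matrix(c(1, 0), 2, 1, dimnames = list(c("D1", "D2"), "G1"))
  f <- fit_l2(x, c(D1 = 1, D2 = 0),
    model_spec(alpha = 1, intercept = FALSE, split = 1)
  )
  expect_equal(f$coefficient, 0.5)

  # constant outcome with intercept: all coefficients zero
  withr::local_seed(2)
  xb <- matrix(rbinom(40, 1, 0.5), 8, 5,
    dimnames = list(paste0("D", 1:8), paste0("G", 1:5))
  )
  fc <- fit_l2(xb, stats::setNames(rep(2, 8), rownames(xb)),
    model_spec(split = 1)
  )
  expect_equal(fc$coefficient, rep(0, 5), tolerance = 1e-10)
  expect_equal(attr(fc, "intercept"), 2, tolerance = 1e-10)

  # enormous penalty drives all coefficients to zero
  y <- stats::setNames(rnorm(8), rownames(xb))
  fbig <- fit_l2(xb, y, model_spec(alpha = 1e9, split = 1))
  expect_lt(max(abs(fbig$coefficient)), 1e-6)

  expect_error(model_spec(alpha = 0), "alpha")
  expect_error(
    fit_l2(xb, c(ZZZ = 1), model_spec()),
    "no drug ids shared"
  )
})

test_that("ridge SVD route equals the closed-form oracle on random data", {
  withr::local_seed(13)
  for (rep in 1:10) {
    x <- matrix(rnorm(200), 20, 10,
      dimnames = list(paste0("D", 1:20), paste0("G", 1:10))
    )
    y <- stats::setNames(rnorm(20), rownames(x))
    alpha <- stats::runif(1, 0.1, 5)
    f <- fit_l2(x, y, model_spec(alpha = alpha, intercept = FALSE, split = 1))
    expect_equal(f$coefficient, oracle_ridge(x, y, alpha),
      tolerance = 1e-8
    )
  }
})

test_that("coefficients map to genes independently of column order", {
  withr::local_seed(4)
  x <- matrix(rbinom(60, 1, 0.5), 12, 5,
    dimnames = list(paste0("D", 1:12), c("B", "E", "A", "D", "C"))
  )
  y <- stats::setNames(rnorm(12), rownames(x))
  f1 <- fit_l2(x, y, model_spec(split = 1))
  f2 <- fit_l2(x[, order(colnames(x))], y, model_spec(split = 1))
  m1 <- stats::setNames(f1$coefficient, f1$gene)
  m2 <- stats::setNames(f2$coefficient, f2$gene)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))], tolerance = 1e-10)
})

test_that("holdout metrics appear only with a split and are seeded", {
  withr::local_seed(9)
  x <- matrix(rbinom(300, 1, 0.4), 30, 10,
    dimnames = list(paste0("D", 1:30), paste0("G", 1:10))
  )
  y <- stats::setNames(rnorm(30), rownames(x))
  f_full <- fit_l2(x, y, model_spec(split = 1))
  expect_null(attr(f_full, "metrics"))
  f_split <- fit_l2(x, y, model_spec(split = 0.7, seed = 5))
  m <- attr(f_split, "metrics")
  expect_named(m, c("mse", "r_squared"))
  expect_gte(m[["mse"]], 0)
  # coefficients for downstream stages come from the full fit
  expect_equal(f_split$coefficient, f_full$coefficient, tolerance = 1e-10)
  f_split2 <- fit_l2(x, y, model_spec(split = 0.7, seed = 5))
  expect_equal(attr(f_split2, "metrics"), m)
})

test_that("logistic fit recovers separating structure with sane signs", {
  withr::local_seed(21)
  x <- matrix(rbinom(200, 1, 0.5), 40, 5,
    dimnames = list(paste0("D", 1:40), paste0("G", 1:5))
  )
  eta <- 2 * x[, 1] - 2 * x[, 2]
  y <- stats::setNames(rbinom(40, 1, stats::plogis(eta)), rownames(x))
  f <- fit_l2(x, y, model_spec(kind = "logistic_l2", split = 1))
  expect_gt(f$coefficient[f$gene == "G1"], 0)
  expect_lt(f$coefficient[f$gene == "G2"], 0)
  expect_error(
    fit_l2(x, stats::setNames(rnorm(40), rownames(x)),
      model_spec(kind = "logistic_l2", split = 1)
    ),
    "0/1"
  )
})

test_that("permutation null summarizes shuffled refits reproducibly", {
  withr::local_seed(6)
  x <- matrix(rbinom(150, 1, 0.5), 15, 10,
    dimnames = list(paste0("D", 1:15), paste0("G", 1:10))
  )
  y <- stats::setNames(rnorm(15), rownames(x))
  n1 <- permutation_null(x, y, model_spec(), n_shuffles = 12, seed = 8)
  n2 <- permutation_null(x, y, model_spec(), n_shuffles = 12, seed = 8)
  expect_identical(n1, n2)
  expect_true(all(n1$null_min <= n1$null_median))
  expect_true(all(n1$null_median <= n1$null_max))
  expect_true(all(n1$null_mean >= n1$null_min & n1$null_mean <= n1$null_max))

  # constant outcome: every shuffle identical, coefficients all zero
  nc <- permutation_null(x, stats::setNames(rep(1, 15), rownames(x)),
    model_spec(),
    n_shuffles = 5, seed = 1
  )
  expect_equal(nc$null_min, rep(0, 10), tolerance = 1e-10)
  expect_equal(nc$null_max, rep(0, 10), tolerance = 1e-10)

  expect_error(permutation_null(x, y, model_spec(), n_shuffles = 1), ">= 2")
})

test_that("permutation-null means shrink toward zero as shuffles grow", {
  withr::local_seed(14)
  x <- matrix(rbinom(400, 1, 0.5), 40, 10,
    dimnames = list(paste0("D", 1:40), paste0("G", 1:10))
  )
  y <- stats::setNames(x[, 1] + rnorm(40, 0, 0.3), rownames(x))
  m_small <- mean(abs(
    permutation_null(x, y, model_spec(), 10, seed = 2)$null_mean
  ))
  m_big <- mean(abs(
    permutation_null(x, y, model_spec(), 160, seed = 2)$null_mean
  ))
  expect_lt(m_big, m_small)
})

test_that("gene selection applies threshold, top-k and quantile rules", {
  coeffs <- structure(
    data.frame(
      gene = sprintf("g%02d", 1:12),
      coefficient = c(
        0.45, 0.31, 0.25, 0.21, 0.1, 0.02,
        -0.02, -0.05, -0.12, -0.18, -0.22, -0.40
      )
    ),
    class = c("coefficient_table", "data.frame")
  )
  # screen-style rule: positive > 0.20 / negative < -0.17, positive favorable
  sel <- select_genes(coeffs, selection_rule("threshold",
    upper = 0.20, lower = -0.17, favorable_sign = 1
  ))
  expect_equal(sel$favorable, sprintf("g%02d", 1:4)) # 4 genes > 0.20
  expect_equal(sel$unfavorable, sprintf("g%02d", 10:12)) # 3 genes < -0.17

  # flipped convention: negative coefficients are the favorable list
  self <- select_genes(coeffs, selection_rule("threshold",
    upper = 0.20, lower = -0.17, favorable_sign = -1
  ))
  expect_equal(self$favorable, sprintf("g%02d", 10:12))

  # top-k with lexicographic tie-break
  tied <- structure(
    data.frame(gene = c("g1", "g2", "g3"), coefficient = c(0.5, 0.5, 0.1)),
    class = c("coefficient_table", "data.frame")
  )
  sk <- select_genes(tied, selection_rule("top_k", k = 2))
  expect_equal(sk$favorable, c("g1", "g2"))
  expect_warning(
    select_genes(tied, selection_rule("top_k", k = 5)),
    "exceeds"
  )

  # all-zero coefficients select nothing in threshold mode
  zero <- structure(
    data.frame(gene = c("a", "b"), coefficient = c(0, 0)),
    class = c("coefficient_table", "data.frame")
  )
  sz <- select_genes(zero, selection_rule("threshold",
    upper = 0.1, lower = -0.1
  ))
  expect_length(sz$favorable, 0)
  expect_length(sz$unfavorable, 0)

  sq <- select_genes(coeffs, selection_rule("quantile", fraction = 0.25))
  expect_true(all(sq$favorable %in% sprintf("g%02d", 1:3)))
})
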