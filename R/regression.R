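# Drug x gene design matrices and L2-regularized regression of screen
# outcomes on network-protein membership, with permutation nulls and the
# coefficient-based gene selection rules used ahead of enrichment.

#' Build a binary drug x gene design matrix from drug networks
#'
#' Cell (d, g) is 1 exactly when gene g (target or downstream) is in drug
#' d's network.  Columns are the lexicographically sorted union of all
#' network genes, so every column has at least one nonzero cell by
#' construction.
#'
#' @param networks List of `drug_network` objects (at least two, each
#'   nonempty); names default to their `drug_id`s.
#' @return Integer matrix with drug ids as row names and genes as column
#'   names.
#' @export
build_design_matrix <- function(networks) {
  if (length(networks) < 2L) {
    stop_ps("need at least 2 drug networks to build a design matrix")
  }
  ids <- names(networks) %||%
    vapply(networks, function(n) n$drug_id, "")
  if (anyDuplicated(ids)) {
    stop_ps("duplicate drug id: ", ids[duplicated(ids)][1])
  }
  gene_lists <- lapply(networks, `[[`, "genes")
  if (any(lengths(gene_lists) == 0L)) stop_ps("empty drug network")
  genes <- sort(unique(unlist(gene_lists, use.names = FALSE)))
  x <- matrix(0L, length(ids), length(genes),
    dimnames = list(ids, genes)
  )
  col_idx <- lapply(gene_lists, match, genes)
  for (i in seq_along(ids)) x[i, col_idx[[i]]] <- 1L
  x
}

#' Specify an L2-regularized regression model
#'
#' @param kind `"linear_ridge"` (default; used even for 0/1 outcomes, so
#'   that mean-squared error and R-squared holdout metrics are defined) or
#'   `"logistic_l2"`.
#' @param alpha Penalty strength on the squared coefficient norm
#'   (default 1); the intercept is never penalized.
#' @param intercept Fit an intercept (default TRUE).
#' @param split Fraction of drug rows used for training when computing
#'   holdout metrics; 1 means fit on all rows with no metrics
#'   (default 0.7).
#' @param seed Seed for the train/test row shuffle.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("linear_ridge", "logistic_l2"),
                       alpha = 1.0, intercept = TRUE, split = 0.7,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || alpha <= 0) stop_ps("alpha must be > 0")
  if (split <= 0 || split > 1) stop_ps("split must be in (0, 1]")
  structure(
    list(
      kind = kind, alpha = alpha, intercept = isTRUE(intercept),
      split = split, seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

# Ridge solve via SVD of the (optionally centered) design; the closed
# form (X'X + aI)^-1 X'y is the independent oracle in the tests.
ridge_svd <- function(x, alpha, intercept) {
  if (intercept) {
    xm <- colMeans(x)
    xc <- sweep(x, 2, xm)
  } else {
    xm <- NULL
    xc <- x
  }
  sv <- svd(xc)
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  list(
    u = sv$u[, keep, drop = FALSE], d = sv$d[keep],
    v = sv$v[, keep, drop = FALSE], xm = xm, alpha = alpha
  )
}

ridge_coef_from_svd <- function(fac, y, intercept) {
  ym <- if (intercept) mean(y) else 0
  uty <- crossprod(fac$u, y - ym)
  beta <- fac$v %*% (uty * fac$d / (fac$d^2 + fac$alpha))
  b0 <- if (intercept) ym - sum(fac$xm * beta) else 0
  list(beta = as.numeric(beta), intercept = b0)
}

logistic_l2_fit <- function(x, y, alpha, intercept, max_iter = 100L,
                            tol = 1e-10) {
  # penalized IRLS; the intercept column is unpenalized
  xx <- if (intercept) cbind(`(Intercept)` = 1, x) else x
  p <- ncol(xx)
  pen <- rep(alpha, p)
  if (intercept) pen[1] <- 0
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xx %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(xx, y - mu)) - pen * beta
    hess <- crossprod(xx * w, xx)
    diag(hess) <- diag(hess) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (intercept) {
    list(beta = beta[-1], intercept = beta[1])
  } else {
    list(beta = beta, intercept = 0)
  }
}

#' Fit an L2-regularized regression of screen outcomes on the design
#'
#' Rows of the design matrix and the screen table are inner-joined on
#' drug id (keeping the design matrix row order).  Coefficients reported
#' for downstream stages always come from the full-matrix fit; when
#' `split < 1` the rows are additionally partitioned by a seeded shuffle
#' into train/test and holdout mean-squared error and R-squared from the
#' train-only fit are attached.
#'
#' @param x Design matrix from [build_design_matrix()].
#' @param y A `screen_table` (or named numeric vector of outcomes keyed by
#'   drug id).
#' @param spec A [model_spec()].
#' @return A `coefficient_table`: data frame gene/coefficient plus
#'   attributes `intercept`, `metrics` (named numeric with `mse` and
#'   `r_squared`, present iff a holdout was used), `kind`, `n_drugs`.
#' @export
fit_l2 <- function(x, y, spec = model_spec()) {
  stopifnot(is.matrix(x))
  yv <- if (inherits(y, "screen_table")) {
    stats::setNames(y$outcome, y$drug_id)
  } else {
    y
  }
  common <- intersect(rownames(x), names(yv))
  if (!length(common)) {
    stop_ps("no drug ids shared between design matrix and screen table")
  }
  xs <- x[common, , drop = FALSE]
  ys <- unname(yv[common])
  if (spec$kind == "linear_ridge" && !all(is.finite(ys))) {
    stop_ps("non-finite outcomes")
  }
  fit_full <- if (spec$kind == "linear_ridge") {
    fac <- ridge_svd(xs, spec$alpha, spec$intercept)
    ridge_coef_from_svd(fac, ys, spec$intercept)
  } else {
    if (!all(ys %in% c(0, 1))) {
      stop_ps("logistic_l2 requires a 0/1 outcome")
    }
    logistic_l2_fit(xs, ys, spec$alpha, spec$intercept)
  }
  metrics <- NULL
  if (spec$split < 1 && length(ys) >= 4L) {
    set.seed(spec$seed)
    perm <- sample(length(ys))
    n_train <- max(2L, floor(spec$split * length(ys)))
    tr <- perm[seq_len(n_train)]
    te <- perm[-seq_len(n_train)]
    fit_tr <- if (spec$kind == "linear_ridge") {
      ridge_coef_from_svd(
        ridge_svd(xs[tr, , drop = FALSE], spec$alpha, spec$intercept),
        ys[tr], spec$intercept
      )
    } else {
      logistic_l2_fit(
        xs[tr, , drop = FALSE], ys[tr], spec$alpha, spec$intercept
      )
    }
    pred <- drop(xs[te, , drop = FALSE] %*% fit_tr$beta) + fit_tr$intercept
    if (spec$kind == "logistic_l2") pred <- stats::plogis(pred)
    resid <- ys[te] - pred
    ss_tot <- sum((ys[te] - mean(ys[te]))^2)
    metrics <- c(
      mse = mean(resid^2),
      r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
    )
  }
  structure(
    data.frame(
      gene = colnames(xs), coefficient = fit_full$beta,
      stringsAsFactors = FALSE
    ),
    intercept = fit_full$intercept, metrics = metrics,
    kind = spec$kind, n_drugs = length(ys),
    class = c("coefficient_table", "data.frame")
  )
}

#' Permutation null for regression coefficients
#'
#' Refits the model `n_shuffles` times with the outcome column randomly
#' permuted (rows of the design untouched; full-matrix fits, no holdout)
#' and reports per-gene min, max, mean and median coefficients over the
#' shuffles.  Iteration i uses seed `seed + i`, so summaries are
#' reproducible.
#'
#' @inheritParams fit_l2
#' @param n_shuffles Number of shuffles (default 100, minimum 2).
#' @param seed Base seed.
#' @return A `null_coefficient_summary` data frame with columns `gene`,
#'   `null_min`, `null_max`, `null_mean`, `null_median`; attributes
#'   `n_shuffles`, `seed`.
#' @export
permutation_null <- function(x, y, spec = model_spec(), n_shuffles = 100L,
                             seed = 1L) {
  if (n_shuffles < 2L) stop_ps("n_shuffles must be >= 2")
  yv <- if (inherits(y, "screen_table")) {
    stats::setNames(y$outcome, y$drug_id)
  } else {
    y
  }
  common <- intersect(rownames(x), names(yv))
  if (!length(common)) {
    stop_ps("no drug ids shared between design matrix and screen table")
  }
  xs <- x[common, , drop = FALSE]
  ys <- unname(yv[common])
  fac <- if (spec$kind == "linear_ridge") {
    ridge_svd(xs, spec$alpha, spec$intercept)
  } else {
    NULL
  }
  coefs <- matrix(0, ncol(xs), n_shuffles,
    dimnames = list(colnames(xs), NULL)
  )
  for (i in seq_len(n_shuffles)) {
    set.seed(seed + i)
    yp <- ys[sample(length(ys))]
    coefs[, i] <- if (spec$kind == "linear_ridge") {
      ridge_coef_from_svd(fac, yp, spec$intercept)$beta
    } else {
      logistic_l2_fit(xs, yp, spec$alpha, spec$intercept)$beta
    }
  }
  structure(
    data.frame(
      gene = colnames(xs),
      null_min = apply(coefs, 1, min),
      null_max = apply(coefs, 1, max),
      null_mean = rowMeans(coefs),
      null_median = apply(coefs, 1, stats::median),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
    class = c("null_coefficient_summary", "data.frame")
  )
}

#' Define a coefficient-based gene selection rule
#'
#' @param mode `"threshold"` (strictly beyond signed bounds), `"top_k"`
#'   (k largest / k smallest, lexicographic tie-break), or `"quantile"`
#'   (top/bottom fraction by coefficient quantile, strict).
#' @param upper,lower Signed bounds for threshold mode (positive genes
#'   with coefficient > `upper`; negative genes with coefficient <
#'   `lower`).
#' @param k Count for top_k mode.
#' @param fraction Fraction for quantile mode.
#' @param favorable_sign +1 if positive-coefficient genes are the
#'   favorable list for this screen, -1 if negative-coefficient genes are.
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(mode = c("threshold", "top_k", "quantile"),
                           upper = NULL, lower = NULL, k = NULL,
                           fraction = NULL, favorable_sign = 1L) {
  mode <- match.arg(mode)
  if (!favorable_sign %in% c(-1L, 1L)) {
    stop_ps("favorable_sign must be +1 or -1")
  }
  if (mode == "threshold" && (is.null(upper) || is.null(lower))) {
    stop_ps("threshold mode needs both `upper` and `lower` bounds")
  }
  if (mode == "threshold" && (upper < lower)) {
    stop_ps("threshold bounds must satisfy lower <= upper")
  }
  if (mode == "top_k" && (is.null(k) || k < 1)) {
    stop_ps("top_k mode needs k >= 1")
  }
  if (mode == "quantile" &&
    (is.null(fraction) || fraction <= 0 || fraction >= 1)) {
    stop_ps("quantile mode needs fraction in (0, 1)")
  }
  structure(
    list(
      mode = mode, upper = upper, lower = lower, k = k,
      fraction = fraction, favorable_sign = as.integer(favorable_sign)
    ),
    class = "selection_rule"
  )
}

#' Select favorable/unfavorable gene lists from a coefficient table
#'
#' @param coeffs A [fit_l2()] coefficient table.
#' @param rule A [selection_rule()].
#' @return A `gene_selection`: list with sorted `favorable` and
#'   `unfavorable` gene vectors (disjoint by construction) and the `rule`.
#' @export
select_genes <- function(coeffs, rule) {
  stopifnot(inherits(coeffs, "coefficient_table"),
    inherits(rule, "selection_rule"))
  gene <- coeffs$gene
  b <- coeffs$coefficient
  if (rule$mode == "threshold") {
    pos <- gene[b > rule$upper]
    neg <- gene[b < rule$lower]
  } else if (rule$mode == "top_k") {
    k <- rule$k
    if (k > length(gene)) {
      warn_ps("k exceeds the number of genes; returning all genes")
      k <- length(gene)
    }
    pos <- gene[order(-b, gene)][seq_len(k)]
    neg <- gene[order(b, gene)][seq_len(k)]
    neg <- setdiff(neg, pos)
  } else {
    qs <- stats::quantile(b, c(rule$fraction, 1 - rule$fraction),
      names = FALSE
    )
    pos <- gene[b > qs[2]]
    neg <- gene[b < qs[1]]
  }
  if (rule$favorable_sign == 1L) {
    favorable <- pos
    unfavorable <- neg
  } else {
    favorable <- neg
    unfavorable <- pos
  }
  structure(
    list(
      favorable = sort(favorable), unfavorable = sort(unfavorable),
      rule = rule
    ),
    class = "gene_selection"
  )
}

#' Write a coefficient table (with optional null summary) to TSV
#'
#' Columns: gene, coefficient, and when a null summary is supplied,
#' null_min, null_max, null_mean, null_median.
#'
#' @param coeffs A `coefficient_table`.
#' @param path Output path.
#' @param null_summary Optional matching [permutation_null()] result.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(coeffs, path, null_summary = NULL) {
  out <- as.data.frame(coeffs)[, c("gene", "coefficient")]
  if (!is.null(null_summary)) {
    out <- merge(out, as.data.frame(null_summary), by = "gene", sort = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
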