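# Shared in-code fixtures: tiny graphs and tables built fresh per test.

toy_interactome <- function() {
  # T - A (0.9), A - C (0.8), T - B (0.4): the worked threshold example
  as_interactome(data.frame(
    gene_a = c("T", "A", "T"),
    gene_b = c("A", "C", "B"),
    evidence_score = c(0.9, 0.8, 0.4)
  ))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_interactome <- function(n_nodes, p_edge = 0.25) {
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[1] <- TRUE
  as_interactome(data.frame(
    gene_a = sprintf("N%02d", pairs[keep, 1]),
    gene_b = sprintf("N%02d", pairs[keep, 2]),
    evidence_score = stats::runif(sum(keep), 0.05, 1)
  ))
}

# Independent oracle: per-node max path-product by exhaustive simple-path
# enumeration over an igraph view of the interactome.
oracle_node_scores <- function(interactome, targets, max_depth) {
  g <- igraph::graph_from_data_frame(
    interactome$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = interactome$genes
  )
  w <- interactome$edges$evidence_score
  score <- stats::setNames(numeric(length(interactome$genes)),
    interactome$genes)
  score[targets] <- 1
  for (tg in targets) {
    for (v in setdiff(interactome$genes, tg)) {
      paths <- igraph::all_simple_paths(g, from = tg, to = v,
        cutoff = max_depth)
      for (p in paths) {
        nodes <- names(p)
        prod_w <- 1
        for (i in seq_len(length(nodes) - 1)) {
          a <- nodes[i]; b <- nodes[i + 1]
          hit <- (interactome$edges$gene_a == a &
            interactome$edges$gene_b == b) |
            (interactome$edges$gene_a == b & interactome$edges$gene_b == a)
          prod_w <- prod_w * max(w[hit])
        }
        score[v] <- max(score[v], prod_w)
      }
    }
  }
  score[score > 0]
}

# Independent oracle: brute-force threshold sweep straight from the
# objective's definition.
oracle_select_threshold <- function(down_scores) {
  cand <- sort(unique(down_scores))
  best_j <- -1
  best_theta <- NA_real_
  for (theta in cand) {
    members <- down_scores[down_scores >= theta]
    mu <- mean(members)
    j <- sum(members > mu)
    if (j >= best_j) { # later thetas win ties (cand ascending)
      best_j <- j
      best_theta <- theta
    }
  }
  best_theta
}

# Independent oracle: hypergeometric tail by explicit enumeration.
oracle_fisher_p <- function(overlap, n_set, n_draw, n_universe) {
  ks <- overlap:min(n_set, n_draw)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_draw - ks)) /
    choose(n_universe, n_draw)
}

# Independent oracle: BH step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Independent oracle: ridge closed form (X'X + aI)^-1 X'y, no intercept.
oracle_ridge <- function(x, y, alpha) {
  unname(drop(solve(crossprod(x) + alpha * diag(ncol(x)), crossprod(x, y))))
}

small_study <- function(seed = 42, ...) {
  simulate_screen_study(synthetic_scenario(
    seed = seed, n_genes = 60, n_drugs = 25, n_phenotypes = 8,
    genes_per_phenotype = 10, n_terms = 8, genes_per_term = 8,
    n_planted_favorable = 3, n_planted_unfavorable = 3, ...
  ))
}
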