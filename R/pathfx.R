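# Per-drug pathway network prediction and phenotype association.
#
# The network step propagates evidence scores outward from drug targets:
# a downstream protein's score is the best path-product of edge evidence
# over paths of at most `max_depth` edges from any target (targets are
# pinned at 1.0).  An empirical threshold search then keeps the score
# cutoff that maximizes the number of downstream proteins scoring above
# the mean score of the candidate neighborhood, so that the retained
# network is the most differentiated from its local score background.
# Phenotype association is a one-sided Fisher exact test of the overlap
# between network genes and phenotype-annotated genes within the
# interactome universe, filtered against a random-target-network null and
# Benjamini-Hochberg correction.

#' Propagate evidence scores from drug targets through the interactome
#'
#' Computes, for every protein reachable within `max_depth` edges of a
#' target, the maximum over connecting paths of the product of edge
#' evidence scores along the path.  Because evidence scores lie in
#' (0, 1], walks that revisit nodes can never beat the simple path they
#' contain, so a bounded best-score relaxation computes the simple-path
#' optimum exactly.  Targets are fixed at score 1.
#'
#' @param interactome An [as_interactome()] object.
#' @param targets Character vector of target gene symbols.  Targets absent
#'   from the interactome are dropped with a warning; if none remain the
#'   drug cannot be modeled and an error is thrown.
#' @param max_depth Maximum number of edges from a target (default 2).
#' @return A `node_score_map`: list with `score` (named numeric, targets
#'   first), `provenance` (named character: "target"/"downstream"),
#'   `targets`, `max_depth`.
#' @export
compute_node_scores <- function(interactome, targets, max_depth = 2L) {
  stopifnot(inherits(interactome, "interactome"))
  if (max_depth < 1L) stop_ps("max_depth must be >= 1")
  targets <- unique(toupper_trim(targets))
  idx <- match(targets, interactome$genes)
  if (anyNA(idx)) {
    missing <- targets[is.na(idx)]
    if (all(is.na(idx))) {
      stop_ps(
        "drug not connected: no target found in the interactome (",
        paste(missing, collapse = ", "), ")"
      )
    }
    warn_ps(
      "dropping target(s) absent from the interactome: ",
      paste(missing, collapse = ", ")
    )
    targets <- targets[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  n <- length(interactome$genes)
  score <- numeric(n)
  score[idx] <- 1
  frontier <- idx
  adj_idx <- interactome$adj_idx
  adj_score <- interactome$adj_score
  for (depth in seq_len(max_depth)) {
    if (!length(frontier)) break
    nb_list <- adj_idx[frontier]
    deg <- lengths(nb_list)
    if (!sum(deg)) break
    nb <- unlist(nb_list, use.names = FALSE)
    w <- unlist(adj_score[frontier], use.names = FALSE)
    cand <- rep.int(score[frontier], deg) * w
    # best candidate per neighbor from the previous round's snapshot
    o <- order(nb, -cand)
    nb <- nb[o]; cand <- cand[o]
    first <- !duplicated(nb)
    nb <- nb[first]; cand <- cand[first]
    improved <- cand > score[nb]
    frontier <- nb[improved]
    score[frontier] <- cand[improved]
  }
  scored <- which(score > 0)
  ord <- c(idx, setdiff(scored, idx))
  structure(
    list(
      score = stats::setNames(score[ord], interactome$genes[ord]),
      provenance = stats::setNames(
        ifelse(ord %in% idx, "target", "downstream"),
        interactome$genes[ord]
      ),
      targets = interactome$genes[idx],
      max_depth = as.integer(max_depth)
    ),
    class = "node_score_map"
  )
}

#' Select the evidence-score threshold for a drug network
#'
#' Sweeps every distinct downstream score as a candidate threshold
#' \eqn{\theta}.  For each candidate the network is the targets plus all
#' downstream proteins scoring at least \eqn{\theta}; the objective is the
#' number of downstream members scoring strictly above the mean downstream
#' score of that network.  The candidate maximizing the objective wins;
#' ties break toward the largest threshold (the sparsest network, the
#' conservative choice against over-prediction).
#'
#' @param node_scores A [compute_node_scores()] result.
#' @param interactome The interactome the scores came from (used to induce
#'   the retained edge set); optional, edges are omitted when `NULL`.
#' @param drug_id Optional drug identifier carried on the result.
#' @return A `drug_network`: list with `drug_id`, `targets`, `genes`
#'   (targets + retained downstream, sorted), `scores` (named, retained
#'   genes), `threshold`, `edges` (induced edge data frame or NULL).
#' @export
select_threshold <- function(node_scores, interactome = NULL,
                             drug_id = NA_character_) {
  stopifnot(inherits(node_scores, "node_score_map"))
  down <- node_scores$score[node_scores$provenance == "downstream"]
  targets <- node_scores$targets
  if (!length(down)) {
    return(new_drug_network(
      drug_id, targets, targets,
      node_scores$score[targets], 1.0, interactome
    ))
  }
  s_desc <- sort(unname(down), decreasing = TRUE)
  cand <- unique(s_desc) # descending candidate thresholds
  m_at <- findInterval(-cand, -s_desc) # members with score >= candidate
  mu <- cumsum(s_desc)[m_at] / m_at
  s_asc <- rev(s_desc)
  # objective: downstream members scoring strictly above the network mean.
  # Every score > mu is >= the candidate (mu >= candidate by construction),
  # so the count above mu over all downstream scores equals the count over
  # the retained members.
  j <- length(s_asc) - findInterval(mu, s_asc)
  best <- which.max(j) # candidates descend, so first max = largest theta
  theta <- cand[best]
  keep <- names(down)[down >= theta]
  genes <- sort(c(targets, keep))
  new_drug_network(
    drug_id, targets, genes, node_scores$score[genes], theta, interactome
  )
}

new_drug_network <- function(drug_id, targets, genes, scores, threshold,
                             interactome = NULL) {
  edges <- NULL
  if (!is.null(interactome)) {
    e <- interactome$edges
    inside <- e$gene_a %in% genes & e$gene_b %in% genes
    edges <- e[inside, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(
    list(
      drug_id = drug_id, targets = sort(targets), genes = genes,
      scores = scores, threshold = threshold, edges = edges
    ),
    class = "drug_network"
  )
}

#' @export
print.drug_network <- function(x, ...) {
  cat(
    "<drug_network> ", x$drug_id, ": ", length(x$targets), " target(s), ",
    length(x$genes) - length(x$targets),
    " downstream gene(s), threshold = ", signif(x$threshold, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Build the pathway network for one drug
#'
#' Composition of [compute_node_scores()] and [select_threshold()];
#' deterministic given its inputs.
#'
#' @inheritParams compute_node_scores
#' @param drug_id Drug identifier carried on the result.
#' @param with_edges Induce the retained edge set (slower; needed only for
#'   network file export).
#' @return A `drug_network`.
#' @export
build_drug_network <- function(interactome, targets, drug_id = NA_character_,
                               max_depth = 2L, with_edges = FALSE) {
  ns <- compute_node_scores(interactome, targets, max_depth)
  select_threshold(ns,
    interactome = if (with_edges) interactome else NULL,
    drug_id = drug_id
  )
}

#' Associate a drug network with phenotype gene sets
#'
#' One row per phenotype: the 2x2 overlap table of network membership
#' against phenotype annotation within the interactome universe, and the
#' one-sided (enrichment) Fisher exact p-value of the overlap.
#' Phenotypes with no annotated gene in the universe are skipped with a
#' warning.
#'
#' @param network A `drug_network`.
#' @param catalog A `phenotype_catalog`.
#' @param universe Character vector of universe genes (all interactome
#'   genes).
#' @param warn_empty Warn about phenotypes disjoint from the universe.
#' @return An `association_table` data frame with columns `drug_id`,
#'   `phenotype`, `a`, `b`, `c`, `d` (contingency counts), `p_value`, and
#'   a list-column `overlap_genes`.
#' @export
associate_phenotypes <- function(network, catalog, universe,
                                 warn_empty = TRUE) {
  stopifnot(inherits(network, "drug_network"))
  universe <- unique(universe)
  net <- intersect(network$genes, universe)
  n_net <- length(net)
  n_u <- length(universe)
  labels <- names(catalog$sets)
  rows <- lapply(labels, function(ph) {
    ann <- intersect(catalog$sets[[ph]], universe)
    if (!length(ann)) {
      return(NULL)
    }
    ov <- intersect(net, ann)
    a <- length(ov)
    data.frame(
      drug_id = network$drug_id, phenotype = ph,
      a = a, b = n_net - a, c = length(ann) - a,
      d = n_u - n_net - length(ann) + a,
      p_value = hypergeom_tail_p(a, length(ann), n_net, n_u),
      overlap_genes = I(list(ov)),
      stringsAsFactors = FALSE
    )
  })
  skipped <- labels[vapply(rows, is.null, TRUE)]
  if (length(skipped) && warn_empty) {
    warn_ps(
      "skipping phenotype(s) with no gene in the universe: ",
      paste(skipped, collapse = ", ")
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(
      drug_id = character(), phenotype = character(),
      a = integer(), b = integer(), c = integer(), d = integer(),
      p_value = numeric(), overlap_genes = I(list())
    )
  }
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' Filter associations against a random drug-network null
#'
#' Draws `n_iter` random target sets of the same size as the drug's, runs
#' each through network construction and phenotype association, and keeps
#' an observed association only when its p-value is more significant than
#' (strictly below) the median p-value of that phenotype across the random
#' networks.  Phenotype rows missing from a null iteration count as p = 1
#' (absence of enrichment).
#'
#' @param association_table The observed [associate_phenotypes()] result.
#' @param interactome The interactome.
#' @param catalog The phenotype catalog.
#' @param n_targets Number of targets of the observed drug.
#' @param n_iter Number of random networks (default 100).
#' @param seed Integer seed; the null is reproducible given (seed,
#'   n_targets).
#' @param target_pool Gene pool the random target sets are drawn from;
#'   defaults to all interactome genes, but should be the set of genes
#'   targeted by at least one drug when a drug-target map is available.
#' @param max_depth Passed to network construction (threshold selection is
#'   re-run per random target set).
#' @return The association table with added columns `null_median_p` and
#'   `retained`.
#' @export
null_filter <- function(association_table, interactome, catalog,
                        n_targets, n_iter = 100L, seed = 1L,
                        target_pool = NULL, max_depth = 2L) {
  stopifnot(inherits(association_table, "association_table"))
  if (n_targets < 1L) stop_ps("n_targets must be >= 1")
  pool <- target_pool %||% interactome$genes
  pool <- intersect(pool, interactome$genes)
  if (n_targets > length(pool)) {
    stop_ps(
      "n_targets (", n_targets, ") exceeds the eligible gene pool (",
      length(pool), ")"
    )
  }
  med <- null_median_pvalues(
    interactome, catalog, n_targets, n_iter, seed, pool, max_depth,
    phenotypes = association_table$phenotype
  )
  association_table$null_median_p <-
    unname(med[association_table$phenotype])
  association_table$retained <-
    association_table$p_value < association_table$null_median_p
  association_table
}

# Median null p per phenotype; shared by null_filter and the pipeline
# cache (drugs with the same target count share one null distribution).
null_median_pvalues <- function(interactome, catalog, n_targets, n_iter,
                                seed, pool, max_depth, phenotypes = NULL) {
  phenotypes <- phenotypes %||% names(catalog$sets)
  set.seed(seed)
  pmat <- matrix(1, nrow = length(phenotypes), ncol = n_iter,
    dimnames = list(phenotypes, NULL)
  )
  for (i in seq_len(n_iter)) {
    rnd_targets <- sample(pool, n_targets)
    net <- build_drug_network(interactome, rnd_targets,
      drug_id = "null", max_depth = max_depth
    )
    assoc <- associate_phenotypes(net, catalog, interactome$genes,
      warn_empty = FALSE
    )
    hit <- assoc$phenotype %in% phenotypes
    pmat[assoc$phenotype[hit], i] <- assoc$p_value[hit]
  }
  apply(pmat, 1, stats::median)
}

#' Apply BH correction and the significance filter to an association table
#'
#' @param association_table A null-filtered association table.
#' @param alpha Adjusted-p cutoff for retention (default 0.05).
#' @return The table with `adjusted_p` added and `retained` updated to
#'   require both the null filter and `adjusted_p <= alpha`.
#' @export
adjust_associations <- function(association_table, alpha = 0.05) {
  stopifnot(inherits(association_table, "association_table"))
  association_table$adjusted_p <- bh_adjust(association_table$p_value)
  if (!is.null(association_table$retained)) {
    association_table$retained <- association_table$retained &
      association_table$adjusted_p <= alpha
  } else {
    association_table$retained <- association_table$adjusted_p <= alpha
  }
  association_table
}

#' Summarize retained psychiatric predictions across drugs
#'
#' Counts, over retained association rows whose phenotype is one of the
#' tracked labels: drugs per phenotype, total drug-phenotype pairs, and a
#' ranking of network genes by the number of (drug, phenotype) overlap
#' relationships they support.
#'
#' @param tables List of per-drug association tables (null-filtered and
#'   BH-adjusted, i.e. carrying a `retained` flag).
#' @param labels Phenotype labels to track (default: the five psychiatric
#'   conditions).
#' @return List with `drugs_per_phenotype` (named integer),
#'   `n_pairs` (total retained drug-phenotype pairs), `n_drugs` (distinct
#'   drugs with at least one retained pair), and `gene_ranking` (data
#'   frame gene/n_relationships, decreasing).
#' @export
summarize_predictions <- function(tables,
                                  labels = default_psychiatric_labels()) {
  rows <- do.call(rbind, lapply(tables, function(tb) {
    if (is.null(tb) || !nrow(tb)) {
      return(NULL)
    }
    keep <- (tb$retained %||% rep(TRUE, nrow(tb))) & tb$phenotype %in% labels
    tb[keep, , drop = FALSE]
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(list(
      drugs_per_phenotype = stats::setNames(integer(length(labels)), labels),
      n_pairs = 0L, n_drugs = 0L,
      gene_ranking = data.frame(
        gene = character(),
        n_relationships = integer()
      )
    ))
  }
  per_ph <- tapply(rows$drug_id, rows$phenotype, function(d) {
    length(unique(d))
  })
  drugs_per_phenotype <- stats::setNames(integer(length(labels)), labels)
  drugs_per_phenotype[names(per_ph)] <- as.integer(per_ph)
  genes <- unlist(rows$overlap_genes, use.names = FALSE)
  ranking <- if (length(genes)) {
    counts <- sort(table(genes), decreasing = TRUE)
    data.frame(
      gene = names(counts), n_relationships = as.integer(counts),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(gene = character(), n_relationships = integer())
  }
  list(
    drugs_per_phenotype = drugs_per_phenotype,
    n_pairs = nrow(rows),
    n_drugs = length(unique(rows$drug_id)),
    gene_ranking = ranking
  )
}

#' Write the two graph-viewer import files for a drug network
#'
#' Mirrors the pathway tool's default export: a tab-delimited neighborhood
#' file of retained protein-protein edges plus gene-phenotype rows for
#' retained associations, and a node-type file labelling each node as
#' drug, target, downstream, or phenotype.
#'
#' @param network A `drug_network` built with `with_edges = TRUE`.
#' @param associations Optional association table; retained rows become
#'   phenotype nodes/edges.
#' @param dir Output directory.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_network_files <- function(network, associations = NULL, dir = ".") {
  stopifnot(inherits(network, "drug_network"))
  if (is.null(network$edges)) {
    stop_ps("network was built without edges; use with_edges = TRUE")
  }
  id <- network$drug_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb_path <- file.path(
    dir, paste0(id, "_merged_neighborhood__withDrugTargsAndPhens.txt")
  )
  type_path <- file.path(dir, paste0(id, "_network_nodeType.txt"))
  rows <- rbind(
    data.frame(
      node1 = id, node2 = network$targets,
      score = 1, edge_type = "drug-target", stringsAsFactors = FALSE
    ),
    data.frame(
      node1 = network$edges$gene_a, node2 = network$edges$gene_b,
      score = network$edges$evidence_score, edge_type = "ppi",
      stringsAsFactors = FALSE
    )
  )
  if (!is.null(associations) && nrow(associations)) {
    keep <- associations$retained %||% rep(TRUE, nrow(associations))
    ph <- associations[keep, , drop = FALSE]
    if (nrow(ph)) {
      gene <- unlist(ph$overlap_genes, use.names = FALSE)
      phen <- rep.int(ph$phenotype, lengths(ph$overlap_genes))
      if (length(gene)) {
        rows <- rbind(rows, data.frame(
          node1 = gene, node2 = phen, score = NA_real_,
          edge_type = "gene-phenotype", stringsAsFactors = FALSE
        ))
      }
    }
  }
  utils::write.table(rows, nb_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  node_type <- rbind(
    data.frame(node = id, type = "drug", stringsAsFactors = FALSE),
    data.frame(node = network$targets, type = "target"),
    data.frame(
      node = setdiff(network$genes, network$targets),
      type = "downstream"
    )
  )
  if (!is.null(associations) && nrow(associations)) {
    keep <- associations$retained %||% rep(TRUE, nrow(associations))
    if (any(keep)) {
      node_type <- rbind(node_type, data.frame(
        node = unique(associations$phenotype[keep]), type = "phenotype"
      ))
    }
  }
  utils::write.table(node_type, type_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(c(nb_path, type_path))
}
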