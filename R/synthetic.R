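# Synthetic study generator.  Emulates the statistical structure the
# cross-screen analysis assumes — an evidence-scored heavy-tailed
# interactome, a drug library with degree-biased targets, phenotype and
# gene-set annotations, and screen outcomes driven by planted gene-level
# effects — so that every pipeline stage is testable without the
# restricted source datasets (drug-target vocabularies, raw screen
# files).  All generators are seeded and reproducible; stage s of a
# scenario with seed s0 uses seed s0 + a fixed offset, so regenerating
# any one artifact never perturbs the others.

SEED_OFFSETS <- c(
  interactome = 101L, planted = 102L, drugs = 103L, annotations = 104L,
  screen_binary = 105L, screen_phenoscore = 106L, screen_odds_ratio = 107L,
  coefficient_screens = 108L
)

#' Define a synthetic study scenario
#'
#' The defaults are the study conditions used throughout the package's
#' property checks: a 500-gene preferential-attachment interactome with
#' Beta(2, 2) edge evidence rescaled into (0.05, 1], a 200-drug library
#' with max(1, Poisson(1.5)) degree-biased targets per drug, six planted
#' favorable and six planted unfavorable genes with effect size 0.5, and
#' outcome noise sd 0.05.
#'
#' @param seed Base seed for all generators.
#' @param n_genes Number of interactome genes (>= 10).
#' @param pa_power Preferential-attachment exponent (1 = linear, the
#'   classic heavy-tailed regime).
#' @param edges_per_node Edges added per new node in the attachment
#'   process (2 keeps the graph connected and non-tree-like).
#' @param score_shape1,score_shape2 Beta parameters of the edge evidence
#'   distribution.
#' @param score_min Lower end of the rescaled evidence support.
#' @param n_drugs Number of drugs in the library.
#' @param targets_lambda Poisson mean of targets per drug (minimum 1
#'   target is always drawn).
#' @param n_phenotypes,genes_per_phenotype Annotation catalog size.
#' @param phenotype_enrichment Sampling-weight multiplier concentrating
#'   phenotype annotations on planted genes.
#' @param n_terms,genes_per_term Gene-set library size.
#' @param planted_term_purity Minimum fraction of the planted terms'
#'   genes that are planted genes.
#' @param n_planted_favorable,n_planted_unfavorable Planted gene counts.
#' @param effect_size Per-gene outcome effect magnitude \eqn{\beta}.
#' @param noise_sd Outcome noise: sd of additive Gaussian noise for
#'   continuous screens, logistic temperature for binary screens, and the
#'   background-coefficient scale for coefficient-level screens (0 makes
#'   all of them deterministic).
#' @param or_log_scale Log-scale shrinkage applied to the linear
#'   predictor of odds-ratio-like screens before exponentiation; clinical
#'   odds ratios carry modest log-effects, and the shrinkage keeps the
#'   exponential map near-linear so regression semantics are preserved.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_genes = 500L,
                               pa_power = 1,
                               edges_per_node = 2L,
                               score_shape1 = 2, score_shape2 = 2,
                               score_min = 0.05,
                               n_drugs = 200L,
                               targets_lambda = 1.5,
                               n_phenotypes = 20L,
                               genes_per_phenotype = 30L,
                               phenotype_enrichment = 3,
                               n_terms = 30L,
                               genes_per_term = 15L,
                               planted_term_purity = 0.6,
                               n_planted_favorable = 6L,
                               n_planted_unfavorable = 6L,
                               effect_size = 0.5,
                               noise_sd = 0.05,
                               or_log_scale = 0.3) {
  if (n_genes < 10L) stop_ps("n_genes must be >= 10")
  stopifnot(
    n_drugs > 0, targets_lambda > 0, n_phenotypes > 0,
    genes_per_phenotype > 0, n_terms > 0, genes_per_term > 0,
    effect_size > 0, noise_sd >= 0, or_log_scale > 0,
    n_planted_favorable > 0, n_planted_unfavorable > 0
  )
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      pa_power = pa_power, edges_per_node = as.integer(edges_per_node),
      score_shape1 = score_shape1, score_shape2 = score_shape2,
      score_min = score_min,
      n_drugs = as.integer(n_drugs), targets_lambda = targets_lambda,
      n_phenotypes = as.integer(n_phenotypes),
      genes_per_phenotype = as.integer(genes_per_phenotype),
      phenotype_enrichment = phenotype_enrichment,
      n_terms = as.integer(n_terms),
      genes_per_term = as.integer(genes_per_term),
      planted_term_purity = planted_term_purity,
      n_planted_favorable = as.integer(n_planted_favorable),
      n_planted_unfavorable = as.integer(n_planted_unfavorable),
      effect_size = effect_size, noise_sd = noise_sd,
      or_log_scale = or_log_scale,
      planted_favorable = NULL, planted_unfavorable = NULL
    ),
    class = "synthetic_scenario"
  )
}

#' Generate a synthetic evidence-scored interactome
#'
#' A connected preferential-attachment (heavy-tailed degree) graph on
#' `n_genes` genes named G0001..; edge evidence scores are i.i.d.
#' Beta(shape1, shape2) rescaled into (`score_min`, 1].
#'
#' @param scenario A [synthetic_scenario()].
#' @return An `interactome`.
#' @export
generate_interactome <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(scenario$seed + SEED_OFFSETS[["interactome"]])
  g <- igraph::sample_pa(
    scenario$n_genes,
    power = scenario$pa_power,
    m = scenario$edges_per_node, directed = FALSE
  )
  if (!igraph::is_connected(g)) {
    stop_ps("attachment parameters produced a disconnected graph")
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  genes <- sprintf("G%04d", seq_len(scenario$n_genes))
  score <- scenario$score_min +
    (1 - scenario$score_min) *
      stats::rbeta(nrow(el), scenario$score_shape1, scenario$score_shape2)
  as_interactome(data.frame(
    gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
    evidence_score = score, stringsAsFactors = FALSE
  ))
}

node_degrees <- function(interactome) {
  tabulate(
    match(
      c(interactome$edges$gene_a, interactome$edges$gene_b),
      interactome$genes
    ),
    nbins = length(interactome$genes)
  )
}

#' Choose the planted effect genes for a scenario
#'
#' A planted effect is only recoverable when the planted gene's network
#' membership pattern is identifiable: hubs sit in nearly every drug
#' network (no contrast), peripheral genes in almost none, and a gene
#' whose membership is duplicated by another protein splits its
#' regression credit in principle.  When per-drug `networks` are
#' supplied, planted genes are therefore sampled from columns of the
#' membership matrix with moderate prevalence and bounded pairwise /
#' duplicate correlation (the correlation cap is relaxed stepwise if the
#' candidate pool runs dry).  Without networks, a mid-degree band is
#' used as a proxy.
#'
#' @param scenario A [synthetic_scenario()].
#' @param interactome The matching [generate_interactome()] output.
#' @param networks Optional named list of `drug_network`s for the
#'   scenario's drug library.
#' @param prevalence Membership-prevalence band for eligible genes.
#' @param max_pair_cor Maximum membership correlation between two
#'   planted genes.
#' @param max_dup_cor Maximum membership correlation between a planted
#'   gene and any other gene.
#' @param rank_band Degree ranks eligible for the degree-band fallback.
#' @return The scenario with `planted_favorable` and
#'   `planted_unfavorable` filled in.
#' @export
plant_effect_genes <- function(scenario, interactome, networks = NULL,
                               prevalence = c(0.08, 0.40),
                               max_pair_cor = 0.35, max_dup_cor = 0.5,
                               rank_band = 21:120) {
  stopifnot(inherits(interactome, "interactome"))
  set.seed(scenario$seed + SEED_OFFSETS[["planted"]])
  n_need <- scenario$n_planted_favorable + scenario$n_planted_unfavorable
  picked <- character(0)
  if (!is.null(networks)) {
    x <- build_design_matrix(networks)
    prev <- colMeans(x)
    in_band <- prev >= prevalence[1] & prev <= prevalence[2]
    for (dup_cap in unique(pmin(1, max_dup_cor + c(0, 0.1, 0.2, 0.3)))) {
      cand <- colnames(x)[in_band]
      if (length(cand) < n_need) break
      cor_all <- suppressWarnings(stats::cor(x[, cand, drop = FALSE], x))
      cor_all[cbind(seq_along(cand), match(cand, colnames(x)))] <- 0
      cand <- cand[apply(abs(cor_all), 1, max) <= dup_cap]
      if (length(cand) < n_need) next
      cor_cand <- suppressWarnings(stats::cor(x[, cand, drop = FALSE]))
      picked <- character(0)
      for (g in sample(cand)) {
        if (length(picked) &&
          any(abs(cor_cand[g, picked]) > max_pair_cor)) {
          next
        }
        picked <- c(picked, g)
        if (length(picked) == n_need) break
      }
      if (length(picked) == n_need) break
    }
  }
  if (length(picked) < n_need) {
    # degree-band fallback (also the rescue when membership filtering
    # cannot find enough identifiable genes)
    deg <- node_degrees(interactome)
    ord <- order(-deg, interactome$genes)
    band <- interactome$genes[ord[rank_band[rank_band <= length(ord)]]]
    band <- setdiff(band, picked)
    if (length(band) + length(picked) < n_need) {
      stop_ps("planting band smaller than the requested planted sets")
    }
    picked <- c(picked, sample(band, n_need - length(picked)))
  }
  scenario$planted_favorable <-
    sort(picked[seq_len(scenario$n_planted_favorable)])
  scenario$planted_unfavorable <-
    sort(picked[-seq_len(scenario$n_planted_favorable)])
  scenario
}

#' Generate a synthetic drug library
#'
#' `n_drugs` drugs with ids DB90001.. and max(1, Poisson(lambda)) targets
#' each, sampled without replacement with probability proportional to
#' interactome degree (real drug targets are biased toward
#' well-connected proteins, which stresses the hub handling of the
#' network stage).
#'
#' @param scenario A [synthetic_scenario()].
#' @param interactome The matching interactome.
#' @return A `drug_target_map`.
#' @export
generate_drug_library <- function(scenario, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  set.seed(scenario$seed + SEED_OFFSETS[["drugs"]])
  genes <- interactome$genes
  deg <- node_degrees(interactome)
  ids <- sprintf("DB9%04d", seq_len(scenario$n_drugs))
  names <- sprintf("SYNDRUG-%04d", seq_len(scenario$n_drugs))
  rows <- lapply(seq_len(scenario$n_drugs), function(i) {
    k <- max(1L, stats::rpois(1, scenario$targets_lambda))
    k <- min(k, length(genes))
    data.frame(
      drug_id = ids[i], drug_name = names[i],
      gene = sample(genes, k, prob = deg), stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  drug_target_map(tab$drug_id, tab$drug_name, tab$gene)
}

#' Generate synthetic phenotype and gene-set annotations
#'
#' Phenotype gene sets are sampled with weight `phenotype_enrichment` on
#' planted genes; the first five labels are the tracked psychiatric
#' conditions so the prediction-summary path is exercised.  The gene-set
#' library holds `n_terms` random terms plus one planted term per
#' direction ("SYN:FAV", "SYN:UNF") whose genes are at least
#' `planted_term_purity` planted — the recovery target for the
#' enrichment stage.
#'
#' @param scenario A scenario with planted genes filled in
#'   ([plant_effect_genes()]).
#' @param interactome The matching interactome.
#' @return List with `catalog` (a `phenotype_catalog`) and `sets`
#'   (a `gene_set_collection`).
#' @export
generate_annotations <- function(scenario, interactome) {
  if (is.null(scenario$planted_favorable)) {
    stop_ps("scenario has no planted genes; call plant_effect_genes() first")
  }
  set.seed(scenario$seed + SEED_OFFSETS[["annotations"]])
  genes <- interactome$genes
  if (scenario$genes_per_phenotype > length(genes) ||
    scenario$genes_per_term > length(genes)) {
    stop_ps("requested set sizes exceed the gene pool")
  }
  planted <- c(scenario$planted_favorable, scenario$planted_unfavorable)
  w <- ifelse(genes %in% planted, scenario$phenotype_enrichment, 1)
  labels <- c(
    default_psychiatric_labels(),
    sprintf("synthetic phenotype %02d", seq_len(
      max(0L, scenario$n_phenotypes - 5L)
    ))
  )[seq_len(scenario$n_phenotypes)]
  ph_rows <- do.call(rbind, lapply(labels, function(lb) {
    data.frame(
      label = lb,
      gene = sample(genes, scenario$genes_per_phenotype, prob = w),
      stringsAsFactors = FALSE
    )
  }))
  catalog <- phenotype_catalog(ph_rows$label, ph_rows$gene)

  term_sets <- lapply(seq_len(scenario$n_terms), function(i) {
    sample(genes, scenario$genes_per_term)
  })
  names(term_sets) <- sprintf("SYN:%04d", seq_len(scenario$n_terms))
  planted_term <- function(core) {
    size <- max(
      length(core),
      min(scenario$genes_per_term, ceiling(length(core) /
        scenario$planted_term_purity))
    )
    filler <- sample(setdiff(genes, planted), size - length(core))
    sort(c(core, filler))
  }
  term_sets[["SYN:FAV"]] <- planted_term(scenario$planted_favorable)
  term_sets[["SYN:UNF"]] <- planted_term(scenario$planted_unfavorable)
  term_names <- stats::setNames(
    c(
      sprintf("synthetic term %04d", seq_len(scenario$n_terms)),
      "planted favorable module", "planted unfavorable module"
    ),
    names(term_sets)
  )
  sets <- new_gene_sets(
    lapply(term_sets, function(g) sort(unique(g))),
    term_names,
    class = "gene_set_collection"
  )
  list(catalog = catalog, sets = sets)
}

planted_beta <- function(scenario, favorable_sign) {
  beta_fav <- favorable_sign * scenario$effect_size
  data.frame(
    gene = c(scenario$planted_favorable, scenario$planted_unfavorable),
    direction = rep(
      c("favorable", "unfavorable"),
      c(
        length(scenario$planted_favorable),
        length(scenario$planted_unfavorable)
      )
    ),
    beta = c(
      rep(beta_fav, length(scenario$planted_favorable)),
      rep(-beta_fav, length(scenario$planted_unfavorable))
    ),
    stringsAsFactors = FALSE
  )
}

#' Generate screen outcomes from drug networks and planted effects
#'
#' The linear predictor of drug d is
#' \eqn{\eta(d) = \sum_g \beta_g 1[g \in network(d)]} with
#' \eqn{\beta_g = s \beta} for planted favorable genes and
#' \eqn{-s \beta} for planted unfavorable genes, where s is the screen's
#' favorable coefficient sign.  `phenoscore` screens return
#' \eqn{\eta + N(0, \sigma)}; `odds_ratio` screens return
#' \eqn{\exp(c (\eta + N(0, \sigma)))} with c = `or_log_scale` (modest,
#' near-linear log-effects on a positive scale); `binary` screens draw
#' Bernoulli(logistic(\eqn{\eta/\sigma})), degenerating to the
#' deterministic step \eqn{1[\eta > 0]} at \eqn{\sigma = 0}.
#'
#' @param scenario A scenario with planted genes filled in.
#' @param networks Named list of `drug_network`s for the synthetic
#'   library.
#' @param kind `"binary"`, `"phenoscore"`, or `"odds_ratio"`.
#' @param favorable_sign Coefficient sign deemed favorable for this
#'   screen; defaults to -1 for binary (phagocytosis-style: outcome 1 is
#'   the unfavorable increase) and +1 otherwise.
#' @param seed Seed for the outcome noise; defaults to the scenario seed
#'   plus a per-kind offset.
#' @param screen_name Name carried on the screen table (default: kind).
#' @return List with `screen` (a `screen_table`) and `truth` (a
#'   `ground_truth`: planted gene/direction/beta table, the screen's
#'   favorable sign, and the expected shared favorable/unfavorable
#'   sets).
#' @export
generate_screen_outcomes <- function(scenario, networks,
                                     kind = c(
                                       "binary", "phenoscore",
                                       "odds_ratio"
                                     ),
                                     favorable_sign = NULL, seed = NULL,
                                     screen_name = NULL) {
  kind <- match.arg(kind)
  if (is.null(scenario$planted_favorable)) {
    stop_ps("scenario has no planted genes; call plant_effect_genes() first")
  }
  favorable_sign <- as.integer(
    favorable_sign %||% if (kind == "binary") -1L else 1L
  )
  planted <- planted_beta(scenario, favorable_sign)
  hits <- vapply(networks, function(nw) {
    sum(planted$gene %in% nw$genes)
  }, numeric(1))
  if (!any(hits > 0)) {
    stop_ps("no planted gene appears in any network; scenario unidentifiable")
  }
  eta <- vapply(networks, function(nw) {
    sum(planted$beta[planted$gene %in% nw$genes])
  }, numeric(1))
  ids <- names(networks) %||% vapply(networks, `[[`, "", "drug_id")
  set.seed(seed %||% (scenario$seed + SEED_OFFSETS[[paste0("screen_", kind)]]))
  outcome <- switch(kind,
    binary = {
      if (scenario$noise_sd == 0) {
        as.numeric(eta > 0)
      } else {
        stats::rbinom(
          length(eta), 1,
          stats::plogis(eta / scenario$noise_sd)
        )
      }
    },
    phenoscore = eta + stats::rnorm(length(eta), 0, scenario$noise_sd),
    odds_ratio = exp(scenario$or_log_scale *
      (eta + stats::rnorm(length(eta), 0, scenario$noise_sd)))
  )
  screen <- screen_table(
    drug_id = ids, outcome = outcome,
    outcome_type = if (kind == "binary") "binary" else "continuous",
    favorable_sign = favorable_sign,
    screen_name = screen_name %||% kind
  )
  truth <- structure(
    list(
      planted = planted, favorable_sign = favorable_sign,
      expected_shared_favorable = scenario$planted_favorable,
      expected_shared_unfavorable = scenario$planted_unfavorable
    ),
    class = "ground_truth"
  )
  list(screen = screen, truth = truth)
}

#' Generate a synthetic coefficient-screen triple
#'
#' Emulates the consensus stage's unit of account directly: per-screen
#' coefficient tables over a gene universe, where planted favorable
#' genes carry coefficient \eqn{s (\beta + N(0, \sigma))}, planted
#' unfavorable genes \eqn{-s (\beta + N(0, \sigma))}, and background
#' genes \eqn{N(0, \sigma)} — so at \eqn{\sigma = 0} a threshold at half
#' the effect size exactly brackets the planted effects in every screen.
#' The default triple mirrors the cross-platform study: an in-silico-like
#' screen with favorable sign -1 and two screens with favorable sign +1.
#'
#' @param scenario A scenario with planted genes filled in.
#' @param genes Gene universe for the tables (planted genes must be
#'   included).
#' @param conventions Named vector of per-screen favorable signs.
#' @param seed Base seed (one increment per screen).
#' @return List with `coefficients` (named list of `coefficient_table`s),
#'   `conventions`, `rules` (per-screen threshold [selection_rule()]s at
#'   half the effect size), and `truth`.
#' @export
generate_coefficient_screens <- function(scenario, genes,
                                         conventions = c(
                                           insilico = -1L,
                                           zebrafish = 1L,
                                           clinical = 1L
                                         ),
                                         seed = NULL) {
  if (is.null(scenario$planted_favorable)) {
    stop_ps("scenario has no planted genes; call plant_effect_genes() first")
  }
  genes <- sort(unique(genes))
  if (!all(c(scenario$planted_favorable, scenario$planted_unfavorable)
  %in% genes)) {
    stop_ps("gene universe must contain the planted genes")
  }
  base_seed <- seed %||%
    (scenario$seed + SEED_OFFSETS[["coefficient_screens"]])
  eff <- scenario$effect_size
  sd_ <- scenario$noise_sd
  coeffs <- list()
  rules <- list()
  for (i in seq_along(conventions)) {
    s <- names(conventions)[i]
    fs <- as.integer(conventions[[i]])
    set.seed(base_seed + i)
    b <- stats::rnorm(length(genes), 0, sd_)
    fav <- genes %in% scenario$planted_favorable
    unf <- genes %in% scenario$planted_unfavorable
    b[fav] <- fs * (eff + stats::rnorm(sum(fav), 0, sd_))
    b[unf] <- -fs * (eff + stats::rnorm(sum(unf), 0, sd_))
    coeffs[[s]] <- structure(
      data.frame(gene = genes, coefficient = b, stringsAsFactors = FALSE),
      intercept = 0, metrics = NULL, kind = "linear_ridge",
      n_drugs = NA_integer_,
      class = c("coefficient_table", "data.frame")
    )
    rules[[s]] <- selection_rule("threshold",
      upper = eff / 2, lower = -eff / 2, favorable_sign = fs
    )
  }
  truth <- structure(
    list(
      planted = planted_beta(scenario, 1L), favorable_sign = conventions,
      expected_shared_favorable = scenario$planted_favorable,
      expected_shared_unfavorable = scenario$planted_unfavorable
    ),
    class = "ground_truth"
  )
  list(
    coefficients = coeffs, conventions = conventions, rules = rules,
    truth = truth
  )
}

#' Generate a full synthetic three-screen study
#'
#' Convenience orchestrator: interactome, drug library, per-drug
#' networks, identifiable planted genes, annotations, and the three
#' screens of the cross-platform design — an in-silico-like screen with
#' favorable sign -1, a phenoscore-like screen, and an odds-ratio-like
#' screen — sharing one planted favorable set.  By default the
#' in-silico-like screen uses the continuous link with the sign flipped;
#' set `binary_insilico = TRUE` for the Bernoulli/step link (sign-level
#' information only).
#'
#' @param scenario A [synthetic_scenario()].
#' @param binary_insilico Use the binary link for the in-silico-like
#'   screen.
#' @param max_depth Network propagation depth.
#' @return List with `scenario` (planted genes filled), `interactome`,
#'   `drugs`, `networks`, `catalog`, `sets`, `screens` (named list of
#'   `screen_table`s), `truths` (named list of ground truths).
#' @export
simulate_screen_study <- function(scenario, binary_insilico = FALSE,
                                  max_depth = 2L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  interactome <- generate_interactome(scenario)
  drugs <- generate_drug_library(scenario, interactome)
  networks <- lapply(names(drugs$targets), function(id) {
    build_drug_network(interactome, drugs$targets[[id]],
      drug_id = id, max_depth = max_depth
    )
  })
  names(networks) <- names(drugs$targets)
  scenario <- plant_effect_genes(scenario, interactome, networks)
  ann <- generate_annotations(scenario, interactome)
  screen_plan <- list(
    insilico = list(
      kind = if (binary_insilico) "binary" else "phenoscore",
      favorable_sign = -1L
    ),
    zebrafish = list(kind = "phenoscore", favorable_sign = 1L),
    clinical = list(kind = "odds_ratio", favorable_sign = 1L)
  )
  screens <- list()
  truths <- list()
  for (i in seq_along(screen_plan)) {
    s <- names(screen_plan)[i]
    out <- generate_screen_outcomes(
      scenario, networks,
      kind = screen_plan[[s]]$kind,
      favorable_sign = screen_plan[[s]]$favorable_sign,
      seed = scenario$seed + 110L + 10L * i,
      screen_name = s
    )
    screens[[s]] <- out$screen
    truths[[s]] <- out$truth
  }
  list(
    scenario = scenario, interactome = interactome, drugs = drugs,
    networks = networks, catalog = ann$catalog, sets = ann$sets,
    screens = screens, truths = truths
  )
}
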