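# End-to-end orchestration: pathway networks -> phenotype associations ->
# design matrices -> regression + permutation null -> gene selection ->
# enrichment -> cross-screen consensus, with a deterministic manifest.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (read with the io readers) or the
#' corresponding in-memory objects.  Each screen entry carries its
#' outcome table plus the screen-specific modeling choices.
#'
#' @param interactome Path to an interactome TSV or an `interactome`.
#' @param drug_targets Path to a drug-target TSV or a `drug_target_map`.
#' @param phenotypes Path to a phenotype TSV or a `phenotype_catalog`.
#' @param gene_sets Path to a GMT file or a `gene_set_collection`.
#' @param screens Named list; each element is a list with `table` (path
#'   to a screen CSV or a `screen_table`), `outcome_type`,
#'   `favorable_sign`, optional `model` ([model_spec()]) and `selection`
#'   ([selection_rule()]).
#' @param out_dir Output directory for stage files.
#' @param max_depth Network propagation depth (default 2).
#' @param null_iters Random networks per target-count for the association
#'   null filter (default 100).
#' @param alpha Adjusted-p retention cutoff (default 0.05).
#' @param top_k Enrichment terms kept per list (default 10).
#' @param seed Global seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(interactome, drug_targets, phenotypes,
                            gene_sets, screens, out_dir,
                            max_depth = 2L, null_iters = 100L,
                            alpha = 0.05, top_k = 10L, seed = 1L) {
  structure(
    list(
      interactome = interactome, drug_targets = drug_targets,
      phenotypes = phenotypes, gene_sets = gene_sets, screens = screens,
      out_dir = out_dir, max_depth = as.integer(max_depth),
      null_iters = as.integer(null_iters), alpha = alpha,
      top_k = as.integer(top_k), seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a declarative YAML file
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `interactome`,
#' `drug_targets`, `phenotypes`, `gene_sets` (paths), `out_dir`, scalar
#' parameters, and a `screens` map whose entries have `path`,
#' `outcome_type`, `favorable_sign`, and optional `model` /
#' `selection` parameter maps.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  screens <- lapply(cfg$screens, function(s) {
    sc <- list(
      table = s$path,
      outcome_type = s$outcome_type %||% "continuous",
      favorable_sign = as.integer(s$favorable_sign %||% 1L)
    )
    if (!is.null(s$model)) sc$model <- do.call(model_spec, s$model)
    if (!is.null(s$selection)) {
      sc$selection <- do.call(selection_rule, s$selection)
    }
    sc
  })
  pipeline_config(
    interactome = cfg$interactome, drug_targets = cfg$drug_targets,
    phenotypes = cfg$phenotypes, gene_sets = cfg$gene_sets,
    screens = screens, out_dir = cfg$out_dir,
    max_depth = cfg$max_depth %||% 2L,
    null_iters = cfg$null_iters %||% 100L,
    alpha = cfg$alpha %||% 0.05, top_k = cfg$top_k %||% 10L,
    seed = cfg$seed %||% 1L
  )
}

load_input <- function(x, reader, class) {
  if (inherits(x, class)) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(reader(x))
  }
  stop_ps("cannot interpret input as path or ", class)
}

log_line <- function(log, stage, ...) {
  entry <- paste0("stage=", stage, " ", paste0(..., collapse = " "))
  message(format(Sys.time(), "%H:%M:%S "), entry)
  c(log, entry)
}

#' Run the full cross-screen pathway analysis pipeline
#'
#' Executes, in order: pathway network construction for every drug with
#' targets, phenotype association with null filtering and BH correction,
#' per-screen design matrices, L2 regression with permutation nulls,
#' coefficient-based gene selection, Fisher gene-set enrichment of both
#' selections, and (given at least two screens) the cross-screen
#' consensus.  Every stochastic step is seeded from the config seed, and
#' a rerun with the same config reproduces the output files bit for bit;
#' the manifest records seeds, input hashes and stage counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage objects plus `out_dir` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()

  interactome <- load_input(config$interactome, read_interactome,
    "interactome")
  drugs <- load_input(config$drug_targets, read_drug_targets,
    "drug_target_map")
  catalog <- load_input(
    config$phenotypes,
    function(p) read_gene_sets(p, "tsv"), "phenotype_catalog"
  )
  sets <- load_input(
    config$gene_sets,
    function(p) read_gene_sets(p, "gmt"), "gene_set_collection"
  )
  screens <- lapply(names(config$screens), function(s) {
    sc <- config$screens[[s]]
    tb <- if (inherits(sc$table, "screen_table")) {
      sc$table
    } else {
      read_screen_table(sc$table,
        outcome_type = sc$outcome_type %||% "continuous",
        favorable_sign = sc$favorable_sign %||% 1L, screen_name = s
      )
    }
    tb
  })
  names(screens) <- names(config$screens)
  log <- log_line(
    log, "load", "genes=", length(interactome$genes),
    " drugs=", length(drugs$targets), " screens=", length(screens)
  )

  # --- pathway networks for every drug with targets in the interactome
  modelable <- names(drugs$targets)[vapply(drugs$targets, function(tg) {
    any(tg %in% interactome$genes)
  }, TRUE)]
  networks <- lapply(modelable, function(id) {
    build_drug_network(interactome, drugs$targets[[id]],
      drug_id = id, max_depth = config$max_depth
    )
  })
  names(networks) <- modelable
  if (!length(networks)) stop_ps("stage networks: no modelable drug")
  log <- log_line(
    log, "networks", "n=", length(networks),
    " seed=", config$seed
  )

  # --- phenotype associations with a target-count-cached null filter
  target_pool <- sort(unique(unlist(drugs$targets)))
  target_pool <- intersect(target_pool, interactome$genes)
  null_cache <- new.env(parent = emptyenv())
  associations <- lapply(networks, function(nw) {
    assoc <- associate_phenotypes(nw, catalog, interactome$genes,
      warn_empty = FALSE
    )
    n_t <- length(nw$targets)
    key <- as.character(n_t)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- null_median_pvalues(
        interactome, catalog, n_t, config$null_iters,
        seed = config$seed + n_t, pool = target_pool,
        max_depth = config$max_depth
      )
    }
    med <- null_cache[[key]]
    assoc$null_median_p <- unname(med[assoc$phenotype])
    assoc$retained <- assoc$p_value < assoc$null_median_p
    adjust_associations(assoc, alpha = config$alpha)
  })
  summary_psy <- summarize_predictions(associations,
    labels = catalog$psychiatric_labels
  )
  reference_genes <- summary_psy$gene_ranking$gene
  log <- log_line(
    log, "associations",
    "pairs=", summary_psy$n_pairs, " drugs=", summary_psy$n_drugs
  )

  # --- per-screen regression, selection, enrichment
  coeff_tables <- list()
  null_summaries <- list()
  selections <- list()
  enrich_fav <- list()
  enrich_unf <- list()
  conventions <- integer()
  for (s in names(screens)) {
    sc <- config$screens[[s]]
    tb <- screens[[s]]
    fs <- attr(tb, "favorable_sign")
    present <- intersect(tb$drug_id, names(networks))
    if (length(present) < 2L) {
      warn_ps("screen ", s, " has <2 modelable drugs; skipped")
      log <- log_line(log, "regression", "screen=", s, " skipped")
      next
    }
    x <- build_design_matrix(networks[present])
    spec <- sc$model %||% model_spec(seed = config$seed)
    coeffs <- fit_l2(x, tb, spec)
    nul <- permutation_null(x, tb, spec,
      n_shuffles = max(2L, config$null_iters), seed = config$seed
    )
    rule <- sc$selection %||% selection_rule("quantile",
      fraction = 0.05, favorable_sign = fs
    )
    sel <- select_genes(coeffs, rule)
    coeff_tables[[s]] <- coeffs
    null_summaries[[s]] <- nul
    selections[[s]] <- sel
    conventions[[s]] <- fs
    background <- interactome$genes
    if (length(sel$favorable)) {
      enrich_fav[[s]] <- fisher_enrichment(sel$favorable, background, sets)
    }
    if (length(sel$unfavorable)) {
      enrich_unf[[s]] <- fisher_enrichment(sel$unfavorable, background, sets)
    }
    write_coefficient_table(
      coeffs, file.path(config$out_dir, paste0("coeffs_", s, ".tsv")), nul
    )
    if (!is.null(enrich_fav[[s]])) {
      write_enrichment_table(
        top_terms(enrich_fav[[s]], config$top_k),
        file.path(config$out_dir, paste0("enrichment_", s, "_favorable.tsv"))
      )
    }
    if (!is.null(enrich_unf[[s]])) {
      write_enrichment_table(
        top_terms(enrich_unf[[s]], config$top_k),
        file.path(
          config$out_dir, paste0("enrichment_", s, "_unfavorable.tsv")
        )
      )
    }
    log <- log_line(
      log, "regression", "screen=", s, " drugs=", length(present),
      " genes=", ncol(x), " favorable=", length(sel$favorable),
      " unfavorable=", length(sel$unfavorable)
    )
  }

  # --- consensus (needs >= 2 screens)
  consensus <- NULL
  shared <- NULL
  shared_term_reports <- list()
  if (length(coeff_tables) >= 2L) {
    if (length(coeff_tables) < length(screens)) {
      warn_ps("consensus computed on ", length(coeff_tables),
        " of ", length(screens), " screens")
    }
    consensus <- consensus_table(coeff_tables, conventions)
    shared <- shared_genes(selections, reference = reference_genes)
    if (length(enrich_fav) >= 2L) {
      shared_term_reports$favorable <- shared_terms(enrich_fav,
        alpha = config$alpha
      )
    }
    if (length(enrich_unf) >= 2L) {
      shared_term_reports$unfavorable <- shared_terms(enrich_unf,
        alpha = config$alpha
      )
    }
    utils::write.table(
      as.data.frame(consensus),
      file.path(config$out_dir, "consensus.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    shared_df <- data.frame(
      gene = c(shared$favorable_shared, shared$unfavorable_shared),
      direction = rep(
        c("favorable", "unfavorable"),
        c(length(shared$favorable_shared), length(shared$unfavorable_shared))
      )
    )
    utils::write.table(shared_df,
      file.path(config$out_dir, "shared_genes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    for (dir_ in names(shared_term_reports)) {
      utils::write.table(
        as.data.frame(shared_term_reports[[dir_]]),
        file.path(config$out_dir, paste0("shared_terms_", dir_, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
    }
    jsonlite::write_json(
      shared$venn,
      file.path(config$out_dir, "venn_counts.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    log <- log_line(
      log, "consensus",
      "shared_favorable=", length(shared$favorable_shared),
      " shared_unfavorable=", length(shared$unfavorable_shared)
    )
  } else {
    warn_ps("fewer than 2 screens with fits; consensus skipped")
    log <- log_line(log, "consensus", "error=fewer-than-2-screens skipped")
  }

  # --- manifest + log
  input_hash <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      NA_character_
    }
  }
  manifest <- list(
    package = "pathscreen",
    version = as.character(utils::packageVersion("pathscreen")),
    seed = config$seed,
    parameters = list(
      max_depth = config$max_depth, null_iters = config$null_iters,
      alpha = config$alpha, top_k = config$top_k
    ),
    inputs = list(
      interactome = input_hash(config$interactome),
      drug_targets = input_hash(config$drug_targets),
      phenotypes = input_hash(config$phenotypes),
      gene_sets = input_hash(config$gene_sets)
    ),
    counts = list(
      genes = length(interactome$genes),
      drugs = length(drugs$targets),
      networks = length(networks),
      screens_fit = length(coeff_tables),
      psychiatric_pairs = summary_psy$n_pairs,
      shared_favorable = if (!is.null(shared)) {
        length(shared$favorable_shared)
      } else {
        NA_integer_
      },
      shared_unfavorable = if (!is.null(shared)) {
        length(shared$unfavorable_shared)
      } else {
        NA_integer_
      }
    )
  )
  jsonlite::write_json(manifest,
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  jsonlite::write_json(summary_psy["drugs_per_phenotype"],
    file.path(config$out_dir, "psychiatric_summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(log, file.path(config$out_dir, "run.log"))

  invisible(list(
    interactome = interactome, drugs = drugs, catalog = catalog,
    sets = sets, screens = screens, networks = networks,
    associations = associations, psychiatric_summary = summary_psy,
    coefficients = coeff_tables, null_summaries = null_summaries,
    selections = selections, enrichment_favorable = enrich_fav,
    enrichment_unfavorable = enrich_unf, consensus = consensus,
    shared_genes = shared, shared_terms = shared_term_reports,
    manifest = manifest, out_dir = config$out_dir
  ))
}
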