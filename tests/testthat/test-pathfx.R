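# Network construction, threshold search, phenotype association.

test_that("node scores equal the max path-product within depth", {
  ia <- toy_interactome()
  ns <- compute_node_scores(ia, "T", max_depth = 2)
  expect_equal(ns$score[["T"]], 1.0)
  expect_equal(ns$score[["A"]], 0.9)
  expect_equal(ns$score[["B"]], 0.4)
  expect_equal(ns$score[["C"]], 0.72) # 0.9 * 0.8 two-edge path

  # two targets sharing a neighbor: the stronger edge wins
  ia2 <- as_interactome(data.frame(
    gene_a = c("T1", "T2"), gene_b = c("A", "A"),
    evidence_score = c(0.5, 0.7)
  ))
  ns2 <- compute_node_scores(ia2, c("T1", "T2"), 2)
  expect_equal(ns2$score[["A"]], 0.7)

  # isolated target: only the target itself, score 1
  ia3 <- as_interactome(data.frame(
    gene_a = c("X", "T"), gene_b = c("Y", "X"), evidence_score = c(0.5, 0.3)
  ))
  ns3 <- compute_node_scores(ia3, "Y", 1)
  expect_equal(ns3$score[["Y"]], 1.0)
  expect_equal(ns3$score[["X"]], 0.5)
  expect_false("T" %in% names(ns3$score))

  expect_error(
    compute_node_scores(ia, "ZZZ"),
    "drug not connected"
  )
  expect_warning(
    compute_node_scores(ia, c("T", "ZZZ")),
    "dropping target"
  )
})

test_that("node scores match exhaustive simple-path enumeration", {
  withr::local_seed(11)
  for (rep in 1:8) {
    ia <- random_interactome(8, p_edge = 0.35)
    targets <- sample(ia$genes, 2)
    for (depth in 1:3) {
      got <- compute_node_scores(ia, targets, depth)$score
      want <- oracle_node_scores(ia, targets, depth)
      expect_equal(
        got[order(names(got))], want[order(names(want))],
        tolerance = 1e-12
      )
    }
  }
})

test_that("threshold selection maximizes above-mean membership", {
  ia <- toy_interactome()
  nw <- build_drug_network(ia, "T", drug_id = "D1")
  # J(0.4) = 2, J(0.72) = 1, J(0.9) = 0 -> theta* = 0.4, all nodes kept
  expect_equal(nw$threshold, 0.4)
  expect_setequal(nw$genes, c("T", "A", "B", "C"))

  # single downstream node: J = 0 at its own score, kept at theta = score
  ia1 <- as_interactome(data.frame(
    gene_a = "T", gene_b = "A", evidence_score = 0.6
  ))
  nw1 <- build_drug_network(ia1, "T")
  expect_equal(nw1$threshold, 0.6)
  expect_setequal(nw1$genes, c("T", "A"))

  # all downstream scores equal: every J = 0, theta* = that score
  iaq <- as_interactome(data.frame(
    gene_a = c("T", "T", "T"), gene_b = c("A", "B", "C"),
    evidence_score = c(0.5, 0.5, 0.5)
  ))
  nwq <- build_drug_network(iaq, "T")
  expect_equal(nwq$threshold, 0.5)
  expect_setequal(nwq$genes, c("T", "A", "B", "C"))

  # no downstream at all: targets-only network, threshold 1
  ia0 <- as_interactome(data.frame(
    gene_a = c("X", "T"), gene_b = c("Y", "X"), evidence_score = c(0.5, 0.3)
  ))
  nw0 <- select_threshold(compute_node_scores(ia0, "Y", 1))
  expect_equal(setdiff(nw0$genes, "Y"), "X")
})

test_that("threshold selection equals the brute-force sweep", {
  withr::local_seed(23)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    ia <- random_interactome(n, p_edge = 0.2)
    targets <- sample(ia$genes, min(length(ia$genes), sample(1:2, 1)))
    ns <- compute_node_scores(ia, targets, 2)
    nw <- select_threshold(ns)
    down <- ns$score[ns$provenance == "downstream"]
    if (!length(down)) {
      expect_equal(nw$threshold, 1.0)
      next
    }
    expect_equal(nw$threshold, oracle_select_threshold(unname(down)))
    # monotonicity: raising the threshold never adds a gene
    cand <- sort(unique(unname(down)))
    sizes <- vapply(cand, function(th) sum(down >= th), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("phenotype association computes the one-sided Fisher tail", {
  # universe 20, network 5, phenotype 4, overlap 3 -> p ~ 0.0320
  universe <- sprintf("U%02d", 1:20)
  nw <- structure(
    list(
      drug_id = "D", targets = "U01", genes = universe[1:5],
      scores = NULL, threshold = 1, edges = NULL
    ),
    class = "drug_network"
  )
  cat <- phenotype_catalog(
    label = rep(c("hit", "none", "sat"), c(4, 2, 20)),
    gene = c(universe[3:6], universe[10:11], universe)
  )
  at <- associate_phenotypes(nw, cat, universe)
  expect_equal(
    at$p_value[at$phenotype == "hit"],
    oracle_fisher_p(3, 4, 5, 20),
    tolerance = 1e-12
  )
  expect_equal(round(at$p_value[at$phenotype == "hit"], 4), 0.032)
  expect_equal(at$p_value[at$phenotype == "none"], 1) # zero overlap
  # phenotype = whole universe: overlap is forced, p = 1
  expect_equal(at$p_value[at$phenotype == "sat"], 1)
  expect_equal(at$a + at$b, rep(5L, 3))
  expect_equal(at$a + at$c, c(4L, 2L, 20L)[match(at$phenotype, c("hit", "none", "sat"))])
})

test_that("Fisher p equals tail enumeration on all small 2x2 tables", {
  for (n_u in c(10, 25, 50)) {
    for (n_set in c(1, 3, n_u %/% 2)) {
      for (n_draw in c(1, 4, n_u %/% 3)) {
        for (ov in 0:min(n_set, n_draw)) {
          expect_equal(
            hypergeom_tail_p(ov, n_set, n_draw, n_u),
            oracle_fisher_p(ov, n_set, n_draw, n_u),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("BH adjustment matches the hand step-up and its contracts", {
  expect_equal(
    bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
    c(0.04, 0.04, 0.05, 0.05)
  )
  expect_equal(bh_adjust(0.37), 0.37) # m = 1 identity
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(5)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # permutation invariance up to re-indexing
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
    # monotone in ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("null filter keeps only sub-median associations, reproducibly", {
  withr::local_seed(31)
  ia <- random_interactome(15, p_edge = 0.3)
  cat <- phenotype_catalog(
    label = rep(c("ph1", "ph2"), each = 5),
    gene = sample(ia$genes, 10, replace = TRUE)
  )
  nw <- build_drug_network(ia, ia$genes[1], drug_id = "D1")
  at <- associate_phenotypes(nw, cat, ia$genes, warn_empty = FALSE)
  f1 <- null_filter(at, ia, cat, n_targets = 1, n_iter = 9, seed = 99)
  f2 <- null_filter(at, ia, cat, n_targets = 1, n_iter = 9, seed = 99)
  expect_equal(f1$null_median_p, f2$null_median_p) # same seed, same null
  expect_equal(f1$retained, f1$p_value < f1$null_median_p)
  # a p-value of 1 can never beat a median that is at most 1
  expect_false(any(f1$retained[f1$p_value == 1]))
  expect_error(
    null_filter(at, ia, cat, n_targets = 100, n_iter = 4),
    "exceeds"
  )
})

test_that("prediction summaries count retained psychiatric pairs", {
  mk <- function(drug, phen, retained, genes) {
    structure(
      data.frame(
        drug_id = drug, phenotype = phen, a = 1L, b = 1L, c = 1L, d = 1L,
        p_value = 0.01, retained = retained,
        overlap_genes = I(genes), stringsAsFactors = FALSE
      ),
      class = c("association_table", "data.frame")
    )
  }
  tabs <- list(
    mk("D1", c("schizophrenia", "bipolar disorder"), c(TRUE, TRUE),
      list(c("GNB1", "POMC"), "GNB1")),
    mk("D2", c("schizophrenia", "unipolar depression"), c(TRUE, TRUE),
      list("GNB1", "OXT"))
  )
  s <- summarize_predictions(tabs)
  expect_equal(s$n_pairs, 4L) # 2 drugs x 2 retained phenotypes
  expect_equal(s$n_drugs, 2L)
  expect_equal(unname(s$drugs_per_phenotype["schizophrenia"]), 2L)
  expect_equal(
    s$gene_ranking$n_relationships[s$gene_ranking$gene == "GNB1"], 3L
  )
  # retained flags gate everything
  tabs[[1]]$retained <- FALSE
  s2 <- summarize_predictions(tabs)
  expect_equal(s2$n_pairs, 2L)
  expect_equal(summarize_predictions(list())$n_pairs, 0L)
})

test_that("network export writes neighborhood and node-type files", {
  ia <- toy_interactome()
  nw <- build_drug_network(ia, "T", drug_id = "DB00001", with_edges = TRUE)
  cat <- phenotype_catalog("schizophrenia", "A")
  at <- associate_phenotypes(nw, cat, ia$genes)
  at$retained <- TRUE
  dir <- withr::local_tempdir()
  paths <- write_network_files(nw, at, dir)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[1]), "^DB00001_merged_neighborhood")
  types <- utils::read.table(paths[2], sep = "\t", header = TRUE)
  expect_setequal(
    types$type, c("drug", "target", "downstream", "phenotype")
  )
})

test_that("the drug to association-table path is seed-reproducible", {
  run <- function() {
    withr::with_seed(77, {
      ia <- random_interactome(20, 0.25)
      cat <- phenotype_catalog(
        rep(c("p1", "p2", "p3"), each = 4),
        sample(ia$genes, 12, replace = TRUE)
      )
      nw <- build_drug_network(ia, ia$genes[1:2], drug_id = "D")
      at <- associate_phenotypes(nw, cat, ia$genes, warn_empty = FALSE)
      adjust_associations(
        null_filter(at, ia, cat, 2, n_iter = 6, seed = 3)
      )
    })
  }
  expect_identical(run(), run())
})
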