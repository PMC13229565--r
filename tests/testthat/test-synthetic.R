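# Generator contracts: determinism, ranges, planted structure.

test_that("interactome generation is seeded, connected, range-safe", {
  sc <- synthetic_scenario(seed = 3, n_genes = 40)
  ia1 <- generate_interactome(sc)
  ia2 <- generate_interactome(sc)
  expect_identical(ia1$edges, ia2$edges)
  expect_gte(nrow(ia1$edges), 39) # connected needs >= n - 1 edges
  expect_true(all(
    ia1$edges$evidence_score > 0.05 & ia1$edges$evidence_score <= 1
  ))
  g <- igraph::graph_from_data_frame(ia1$edges[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))

  # tree-like attachment at the minimum size still connects
  sc10 <- synthetic_scenario(seed = 4, n_genes = 10, edges_per_node = 1)
  ia10 <- generate_interactome(sc10)
  expect_gte(nrow(ia10$edges), 9)
  expect_error(synthetic_scenario(n_genes = 5), "n_genes")
})

test_that("drug library has seeded degree-biased targets in range", {
  sc <- synthetic_scenario(seed = 5, n_genes = 60, n_drugs = 50,
    targets_lambda = 2)
  ia <- generate_interactome(sc)
  d1 <- generate_drug_library(sc, ia)
  d2 <- generate_drug_library(sc, ia)
  expect_identical(d1$targets, d2$targets)
  expect_length(d1$targets, 50)
  expect_true(all(grepl("^DB9[0-9]{4}$", names(d1$targets))))
  expect_true(all(unlist(d1$targets) %in% ia$genes))
  expect_true(all(lengths(d1$targets) >= 1))
  # Poisson(2) with a floor of 1: mean within sampling error of ~2.2
  expect_gt(mean(lengths(d1$targets)), 1.3)
  expect_lt(mean(lengths(d1$targets)), 3.2)
})

test_that("annotations concentrate planted terms and reproduce", {
  sc <- synthetic_scenario(seed = 6, n_genes = 80)
  ia <- generate_interactome(sc)
  expect_error(generate_annotations(sc, ia), "no planted genes")
  sc <- plant_effect_genes(sc, ia)
  a1 <- generate_annotations(sc, ia)
  a2 <- generate_annotations(sc, ia)
  expect_identical(a1$sets$sets, a2$sets$sets)
  fav_term <- a1$sets$sets[["SYN:FAV"]]
  expect_true(all(sc$planted_favorable %in% fav_term))
  expect_gte(
    mean(fav_term %in% sc$planted_favorable),
    sc$planted_term_purity - 1e-9
  )
  expect_length(intersect(
    a1$sets$sets[["SYN:FAV"]], a1$sets$sets[["SYN:UNF"]]
  ), 0)
  expect_equal(
    names(a1$catalog$sets)[names(a1$catalog$sets) %in%
      a1$catalog$psychiatric_labels] |> length(),
    5L
  )
  expect_false(is.null(sc$planted_favorable))
  expect_length(
    intersect(sc$planted_favorable, sc$planted_unfavorable), 0
  )
})

test_that("zero-noise outcomes are exact functions of membership", {
  sc <- synthetic_scenario(
    seed = 8, n_genes = 60, n_drugs = 20, noise_sd = 0,
    n_planted_favorable = 1, n_planted_unfavorable = 1,
    effect_size = 0.3
  )
  ia <- generate_interactome(sc)
  drugs <- generate_drug_library(sc, ia)
  nets <- lapply(names(drugs$targets), function(id) {
    build_drug_network(ia, drugs$targets[[id]], drug_id = id)
  })
  names(nets) <- names(drugs$targets)
  sc <- plant_effect_genes(sc, ia, nets)
  # single planted favorable gene, beta = 0.3, sigma = 0: outcomes of
  # drugs whose networks contain it differ from the rest by exactly the
  # planted contrast
  fav <- sc$planted_favorable
  unf <- sc$planted_unfavorable
  out <- generate_screen_outcomes(sc, nets, kind = "phenoscore")
  y <- stats::setNames(out$screen$outcome, out$screen$drug_id)
  memb_f <- vapply(nets, function(nw) fav %in% nw$genes, TRUE)
  memb_u <- vapply(nets, function(nw) unf %in% nw$genes, TRUE)
  expect_equal(
    unname(y[names(nets)]),
    0.3 * as.numeric(memb_f) - 0.3 * as.numeric(memb_u),
    tolerance = 1e-12
  )

  # no planted gene in any network is unidentifiable
  sc_bad <- sc
  sc_bad$planted_favorable <- "ZZZ1"
  sc_bad$planted_unfavorable <- "ZZZ2"
  expect_error(
    generate_screen_outcomes(sc_bad, nets, "phenoscore"),
    "unidentifiable"
  )

  # binary link at zero noise is the deterministic step
  scb <- sc
  outb <- generate_screen_outcomes(scb, nets, kind = "binary")
  eta_fav <- 0.3 * as.numeric(memb_f) - 0.3 * as.numeric(memb_u)
  expect_equal(
    unname(outb$screen$outcome[match(names(nets), outb$screen$drug_id)]),
    as.numeric(-eta_fav > 0) # favorable sign -1 flips the predictor
  )

  # odds-ratio outcomes are positive and log-linear in the predictor
  outo <- generate_screen_outcomes(sc, nets, kind = "odds_ratio")
  expect_true(all(outo$screen$outcome > 0))
  expect_equal(
    log(unname(outo$screen$outcome[match(names(nets), outo$screen$drug_id)])),
    sc$or_log_scale * eta_fav,
    tolerance = 1e-12
  )
})

test_that("constant outcomes arise when nothing is planted to differ", {
  sc <- synthetic_scenario(
    seed = 7, n_genes = 60, n_drugs = 15, noise_sd = 0, effect_size = 0.4
  )
  ia <- generate_interactome(sc)
  drugs <- generate_drug_library(sc, ia)
  nets <- lapply(names(drugs$targets), function(id) {
    build_drug_network(ia, drugs$targets[[id]], drug_id = id)
  })
  names(nets) <- names(drugs$targets)
  # plant genes sitting in every network (this draw has three):
  # memberships identical, so all outcomes coincide at zero noise
  in_all <- Reduce(intersect, lapply(nets, `[[`, "genes"))
  expect_gte(length(in_all), 2)
  sc$planted_favorable <- in_all[1]
  sc$planted_unfavorable <- in_all[2]
  out <- generate_screen_outcomes(sc, nets, "phenoscore")
  expect_equal(stats::sd(out$screen$outcome), 0, tolerance = 1e-12)
})

test_that("full study simulation is reproducible end to end", {
  s1 <- small_study(seed = 11)
  s2 <- small_study(seed = 11)
  expect_identical(s1$scenario$planted_favorable,
    s2$scenario$planted_favorable)
  expect_identical(s1$screens$zebrafish$outcome,
    s2$screens$zebrafish$outcome)
  expect_identical(names(s1$screens), c("insilico", "zebrafish", "clinical"))
  expect_equal(attr(s1$screens$insilico, "favorable_sign"), -1L)
  expect_equal(attr(s1$screens$clinical, "favorable_sign"), 1L)
})

test_that("regression route keeps most planted favorable genes shared", {
  # full-pipeline recovery at moderate noise: the consensus favorable
  # set from an inclusive per-screen selection retains >= 80% of the
  # planted favorable genes on average
  recalls <- vapply(1:5, function(r) {
    st <- simulate_screen_study(
      synthetic_scenario(seed = 7000 + r, noise_sd = 0.1)
    )
    x <- build_design_matrix(st$networks)
    sels <- lapply(names(st$screens), function(s) {
      f <- fit_l2(x, st$screens[[s]], model_spec(seed = r))
      select_genes(f, selection_rule("top_k",
        k = 12,
        favorable_sign = attr(st$screens[[s]], "favorable_sign")
      ))
    })
    names(sels) <- names(st$screens)
    sh <- shared_genes(sels)
    length(intersect(sh$favorable_shared, st$scenario$planted_favorable)) /
      length(st$scenario$planted_favorable)
  }, numeric(1))
  expect_gte(mean(recalls), 0.8)
})
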