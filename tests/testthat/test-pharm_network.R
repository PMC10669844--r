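cascade_fixture <- function(n = 40, seed = 3) {
  tab <- compound_fixture(n, seed = seed)
  withr::with_seed(seed + 1, {
    tab$qed <- runif(n)
    tab$reference_similar <- runif(n) < 0.5
    tab$targets <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) character(0) else sample(sprintf("G%02d", 1:20), 2)
    })
    tab$known_activities <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.3) "AOX" else character(0)
    })
  })
  tab
}

test_that("the cascade applies the four criteria in order and conserves counts", {
  tab <- cascade_fixture()
  res <- candidate_cascade(tab)
  expect_equal(res$stages$n_in[1], nrow(tab))
  expect_true(all(diff(res$stages$n_out) <= 0))
  expect_equal(res$stages$n_out[-4], res$stages$n_in[-1])
  expect_equal(res$stages$n_excluded + res$stages$n_out, res$stages$n_in)
  expect_equal(nrow(res$survivors), res$stages$n_out[4])

  # brute-force membership: intersection of the four pure filters
  brute <- tab$qed > 0.5 & tab$reference_similar &
    lengths(tab$targets) > 0 & lengths(tab$known_activities) == 0
  expect_setequal(res$survivors$compound_id, tab$compound_id[brute])

  # a compound with known activity never survives
  expect_false(any(lengths(res$survivors$known_activities) > 0))

  empty <- candidate_cascade(tab[0, ])
  expect_equal(nrow(empty$survivors), 0)
  expect_true(all(empty$stages$n_in == 0))

  expect_error(candidate_cascade(tab[, setdiff(names(tab), "qed")]), "qed")
})

structural_fixture <- function() {
  plants <- tibble::tibble(
    plant_id = "P1", family = "F", genus = "G", species = "s",
    activities = list(character(0)), has_evidence = FALSE,
    compound_ids = list("C1"),
    other_annotations = list(character(0))
  )
  compounds <- compound_fixture(1)
  compounds$targets <- list("T1")
  pathways <- structure(list(PW1 = c("T1", "G2", "G3")),
                        pathway_names = c(PW1 = "toy"),
                        class = "pathway_db")
  list(plants = plants, compounds = compounds, pathways = pathways)
}

test_that("structural network matches hand enumeration", {
  fx <- structural_fixture()
  g <- build_structural_network(fx$plants, fx$compounds, fx$pathways)
  # nodes: species, C1, T1, G2, G3; edges: P-C, C-T, T-G2, T-G3
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  types <- table(igraph::V(g)$node_type)
  expect_equal(as.integer(types[c("species", "compound", "target", "gene")]),
               c(1L, 1L, 1L, 2L))

  # compound without targets stays isolated from the gene layer
  fx$compounds$targets <- list(character(0))
  g2 <- build_structural_network(fx$plants, fx$compounds, fx$pathways)
  expect_equal(igraph::degree(g2)[["C1"]], 1)  # containment edge only
  expect_false("target" %in% igraph::V(g2)$node_type)
})

test_that("network node and edge counts survive a brute-force recount", {
  d <- generate_dataset(synth_config(seed = 19))
  scored <- score_qed(d$compounds[!d$compounds$is_reference, ])
  scored$reference_similar <- d$truth$prototype[scored$compound_id] == 1
  surv <- candidate_cascade(scored)$survivors
  g <- build_structural_network(d$plants, surv, d$pathways)

  targets <- unique(unlist(surv$targets))
  tg_pairs <- unique(do.call(rbind, lapply(d$pathways, function(set) {
    t_in <- intersect(targets, set)
    if (length(t_in) == 0) return(NULL)
    do.call(rbind, lapply(t_in, function(t) {
      partners <- setdiff(set, t)
      cbind(pmin(t, partners), pmax(t, partners))
    }))
  })))
  n_ct <- sum(lengths(surv$targets))
  pc <- unlist(lapply(d$plants$compound_ids, intersect, surv$compound_id))
  genes <- setdiff(unique(c(tg_pairs)), targets)
  n_species <- sum(vapply(d$plants$compound_ids, function(ids) {
    length(intersect(ids, surv$compound_id)) > 0
  }, logical(1)))
  expect_equal(igraph::vcount(g),
               n_species + nrow(surv) + length(targets) + length(genes))
  expect_equal(igraph::ecount(g),
               length(pc) + n_ct + nrow(tg_pairs))
})

test_that("candidate plants are evidence-free and the planted plant wins", {
  res <- run_pipeline(config = synth_config(seed = 23))
  cand <- res$candidates$plants
  expect_true(all(!cand$has_evidence))
  expect_equal(cand$plant_id[1], res$data$truth$planted_plant)
  expect_lte(igraph::vcount(res$candidates$subnetwork), 10)

  # a plant whose compounds' targets miss every pathway gene is excluded
  fx <- structural_fixture()
  fx$compounds$targets <- list("ZZ9")  # not in any pathway
  g <- build_structural_network(fx$plants, fx$compounds, fx$pathways)
  out <- candidate_plants(g, fx$plants, fx$compounds, fx$pathways)
  expect_equal(nrow(out$plants), 0)
})

test_that("the candidate report counts match brute-force set intersections", {
  res <- run_pipeline(config = synth_config(seed = 29))
  surv <- res$cascade$survivors
  rep_tab <- res$report
  expect_gt(nrow(rep_tab), 0)
  path_genes <- unique(unlist(res$data$pathways))
  for (i in seq_len(nrow(rep_tab))) {
    plant <- res$data$plants[res$data$plants$species == rep_tab$species[i] &
                               res$data$plants$genus == rep_tab$genus[i], ]
    ids <- intersect(plant$compound_ids[[1]], surv$compound_id)
    sub <- surv[surv$compound_id %in% ids, ]
    expect_equal(rep_tab$n_compounds_with_targets[i],
                 sum(lengths(sub$targets) > 0))
    expect_equal(rep_tab$n_interacting_targets[i],
                 length(intersect(unique(unlist(sub$targets)), path_genes)))
  }

  # plants without surviving compounds never appear
  fx <- structural_fixture()
  fx$plants$compound_ids <- list(character(0))
  expect_equal(nrow(candidate_report(fx$plants, fx$compounds, fx$pathways)),
               0)
})
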