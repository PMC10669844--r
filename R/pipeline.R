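# End-to-end orchestration: ingest/simulate -> activity networks -> QED ->
# toxicity/target gates -> fingerprint clustering against the reference
# panel -> candidate cascade -> structural network -> enrichment (-> edema
# statistics).  Every stage is a pure function of the data and the seed;
# the run directory holds stage outputs, the funnel table and a JSON-lines
# provenance log.

#' Run the full screening pipeline
#'
#' @param data Either a dataset list as returned by [generate_dataset()]
#'   (elements `plants`, `compounds`, `pathways`) or `NULL` to simulate one
#'   from `config`.
#' @param config `synth_config` used when `data` is `NULL` and for the
#'   clustering/enrichment seeds.
#' @param out_dir Output directory (created); `NULL` skips file output.
#' @param qed_threshold Drug-likeness gate threshold.
#' @param flags_considered Toxicity flags applied.
#' @param K_max Largest cluster count scanned by the elbow rule.
#' @param K Cluster count; `"auto"` (default) selects by the elbow rule.
#' @param hub_metric `"degree"` or `"mcc"`.
#' @param restart RWR restart probability for the XD-score.
#' @param alpha Raw-p significance gate for enrichment.
#' @param run_invivo Also simulate and analyse the paw-edema experiment.
#' @return List with all stage outputs, including `funnel` (tibble of
#'   per-stage counts) and `log` (list of stage records).
#' @export
run_pipeline <- function(data = NULL, config = synth_config(),
                         out_dir = NULL, qed_threshold = 0.5,
                         flags_considered = TOX_FLAGS, K_max = 10,
                         K = "auto", hub_metric = "degree", restart = 0.7,
                         alpha = 0.05, run_invivo = FALSE) {
  log <- list()
  current_stage <- "ingest"
  note <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    log[[length(log) + 1]] <<- rec
    rec
  }
  # any stage failure aborts with the stage name; outputs written so far
  # (the stage log) are persisted when a run directory was requested
  on_stage_error <- function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      lines <- vapply(log, function(rec) {
        jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
      }, character(1))
      writeLines(lines, file.path(out_dir, "log.jsonl"))
    }
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  result <- withCallingHandlers(
    error = function(e) on_stage_error(e),
    {
  if (is.null(data)) data <- generate_dataset(config)
  plants <- data$plants
  compounds <- data$compounds
  pathways <- data$pathways
  note("ingest", n_plants = nrow(plants), n_compounds = nrow(compounds),
       n_pathways = length(pathways))

  # phases 1-2: activity networks and hub queries
  current_stage <- "activity_network"
  tax_net <- build_taxonomy_activity_network(plants,
                                             include_compounds = TRUE)
  hubs <- rank_hubs(tax_net, hub_metric, top_k = 20)
  multi <- multi_effect_plants(plants, min_classes = 1)
  gaps <- evidence_gap_ranking(plants, compounds, metric = hub_metric)
  note("activity_network", nodes = igraph::vcount(tax_net),
       edges = igraph::ecount(tax_net))

  # phase 3: drug-likeness
  current_stage <- "qed_gate"
  phyto <- compounds[!compounds$is_reference, ]
  refs <- compounds[compounds$is_reference, ]
  scored <- score_qed(phyto)
  gate1 <- qed_gate(scored, qed_threshold)
  note("qed_gate", n_in = nrow(scored), n_pass = nrow(gate1$passed),
       threshold = qed_threshold)

  # phase 4: toxicity and target availability
  current_stage <- "toxicity_gate"
  gate2 <- toxicity_gate(gate1$passed, flags_considered)
  note("toxicity_gate", n_in = nrow(gate1$passed),
       n_pass = nrow(gate2$clean),
       flags = paste(flags_considered, collapse = ","))
  gate3 <- target_gate(gate2$clean)
  note("target_gate", n_in = nrow(gate2$clean),
       n_pass = nrow(gate3$with_targets))

  # phase 5: fingerprint clustering against the reference panel
  current_stage <- "clustering"
  pool <- dplyr::bind_rows(gate3$with_targets, score_qed(refs))
  fps <- stats::setNames(pool$fingerprint, pool$compound_id)
  sim <- similarity_matrix(fps)
  dist <- tanimoto_distance(sim)
  K_max_eff <- min(K_max, nrow(pool) - 1)
  ward <- ward_cluster(dist, K_max_eff)
  K_sel <- if (identical(K, "auto")) elbow_select(ward$wss_profile)
           else as.integer(K)
  labels <- ward_cut(ward, max(K_sel, 2))
  km <- kmeans_binary(fps, max(K_sel, 2), seed = config$seed)
  validity <- list(
    silhouette = silhouette_index(dist, labels),
    dunn = dunn_index(dist, labels)
  )
  members <- reference_cluster_members(labels, pool)
  note("clustering", K = K_sel, n_clustered = nrow(pool),
       n_reference_similar = nrow(members$selected),
       mean_silhouette = validity$silhouette$mean_silhouette,
       dunn = validity$dunn)

  # phase 6: cascade and structural network
  current_stage <- "cascade"
  scored$reference_similar <- scored$compound_id %in%
    members$selected$compound_id
  cascade <- candidate_cascade(scored, qed_threshold)
  note("cascade", n_in = nrow(scored), n_survivors = nrow(cascade$survivors))
  net <- build_structural_network(plants, cascade$survivors, pathways)
  cand <- candidate_plants(net, plants, cascade$survivors, pathways,
                           top_k = 10, metric = hub_metric)
  report <- candidate_report(cand$plants, cascade$survivors, pathways)
  note("structural_network", nodes = igraph::vcount(net),
       edges = igraph::ecount(net), n_candidate_plants = nrow(cand$plants))

  # phase 6b: enrichment of the survivors' targets
  current_stage <- "enrichment"
  enrichment <- NULL
  query <- unique(unlist(cascade$survivors$targets))
  gene_sub <- igraph::induced_subgraph(
    net, igraph::V(net)$node_type %in% c("target", "gene"))
  background <- igraph::V(gene_sub)$name
  query <- intersect(query, background)
  if (length(query) > 0) {
    enrichment <- enrich_with_xd(query, pathways, background, gene_sub,
                                 r = restart, alpha = alpha)
    note("enrichment", n_query = length(query),
         n_significant = sum(enrichment$significant))
  } else {
    note("enrichment", n_query = 0, n_significant = 0)
  }

  # funnel of per-stage compound counts
  funnel <- tibble::tibble(
    stage = c("total", "qed_pass", "non_toxic", "with_targets",
              "reference_similar", "cascade_survivors"),
    n = c(nrow(scored), nrow(gate1$passed), nrow(gate2$clean),
          nrow(gate3$with_targets),
          sum(scored$reference_similar &
                scored$compound_id %in% gate3$with_targets$compound_id),
          nrow(cascade$survivors))
  )

  current_stage <- "invivo"
  invivo <- NULL
  if (run_invivo) {
    edema <- generate_edema(config)
    peak <- config$edema$times[which.max(
      config$edema$trajectories["carrageenan", ])]
    summ <- group_summary(edema, peak)
    test <- anova_dunnett(edema[edema$time == peak, ],
                          control = "carrageenan", alpha = alpha,
                          seed = config$seed)
    invivo <- list(records = edema, peak_time = peak, summary = summ,
                   test = test)
    note("invivo", peak_time = peak, F = test$F,
         n_significant = sum(test$contrasts$significant))
  }

  list(
    data = data, taxonomy_network = tax_net, hubs = hubs,
    multi_effect = multi, evidence_gaps = gaps, qed = gate1,
    toxicity = gate2, targets = gate3, ward = ward, K = K_sel,
    labels = labels, kmeans = km, validity = validity,
    reference_members = members, cascade = cascade,
    structural_network = net, candidates = cand, report = report,
    enrichment = enrichment, funnel = funnel, invivo = invivo, log = log
  )
    })
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_table(result$funnel, p("funnel.tsv"))
  write_table(result$multi_effect, p("multi_effect_plants.tsv"))
  write_table(result$evidence_gaps, p("evidence_gap_ranking.tsv"))
  write_table(result$hubs, p("taxonomy_hubs.tsv"))
  write_table(result$cascade$stages, p("cascade_stages.tsv"))
  write_table(result$candidates$plants, p("candidate_plants.tsv"))
  if (!is.null(result$report) && nrow(result$report) > 0) {
    write_table(result$report, p("candidate_report.tsv"))
  }
  if (!is.null(result$enrichment)) {
    write_table(result$enrichment, p("enrichment.tsv"))
  }
  write_network(result$taxonomy_network, p("taxonomy_network.sif"), "sif")
  write_network(result$structural_network, p("structural_network.sif"),
                "sif")
  labels_tab <- tibble::tibble(compound_id = names(result$labels),
                               cluster = as.integer(result$labels))
  write_table(labels_tab, p("cluster_labels.tsv"))
  if (!is.null(result$invivo)) {
    write_table(result$invivo$summary, p("edema_summary.tsv"))
    write_table(result$invivo$test$contrasts, p("edema_dunnett.tsv"))
  }
  lines <- vapply(result$log, function(rec) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, p("log.jsonl"))
  invisible(out_dir)
}
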