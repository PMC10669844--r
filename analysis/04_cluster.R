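#!/usr/bin/env Rscript
# Phase 5: Tanimoto fingerprint clustering of the screened phytochemicals
# together with the reference-drug panel: Ward tree, elbow-selected K,
# k-means corroboration, silhouette/Dunn validation, and the set of
# phytochemicals co-clustered with at least one reference drug.

suppressMessages(library(phytoscreen))

cfg <- synth_config(seed = 1L)
d <- generate_dataset(cfg)
out <- "results"
dir.create(out, showWarnings = FALSE)

phyto <- score_qed(d$compounds[!d$compounds$is_reference, ])
pool <- dplyr::bind_rows(
  target_gate(toxicity_gate(qed_gate(phyto)$passed)$clean)$with_targets,
  score_qed(d$compounds[d$compounds$is_reference, ])
)
fps <- stats::setNames(pool$fingerprint, pool$compound_id)
dist <- tanimoto_distance(fps)

ward <- ward_cluster(dist, K_max = 8)
K <- elbow_select(ward$wss_profile)
cat(sprintf("clustered %d compounds; elbow selects K = %d\n",
            nrow(pool), K))
labels <- ward_cut(ward, K)

km <- kmeans_binary(fps, K, seed = cfg$seed)
cat(sprintf("k-means corroboration: ARI vs Ward = %.3f\n",
            mclust::adjustedRandIndex(km$labels, labels)))

sil <- silhouette_index(dist, labels)
cat(sprintf("validity: mean silhouette %.3f, Dunn %.3f\n",
            sil$mean_silhouette, dunn_index(dist, labels)))

members <- reference_cluster_members(labels, pool)
cat(sprintf("%d phytochemicals co-cluster with the reference panel\n",
            nrow(members$selected)))

write_table(tibble::tibble(compound_id = names(labels),
                           ward_cluster = as.integer(labels),
                           kmeans_cluster = as.integer(km$labels)),
            file.path(out, "cluster_labels.tsv"))
write_table(members$selected, file.path(out, "reference_similar.tsv"))
write_table(tibble::tibble(K = seq_along(ward$wss_profile),
                           wss = unname(ward$wss_profile)),
            file.path(out, "wss_profile.tsv"))
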