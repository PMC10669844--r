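#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a taxonomy forest of 180 plant
# species with sparse activity evidence, 150 phytochemicals + an 18-drug
# reference panel drawn from 3 fingerprint prototypes, toxicity flags,
# compound-target maps, and 15 pathway gene sets with one planted enriched
# set.  Writes the tables consumed by the downstream steps.

suppressMessages(library(phytoscreen))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

d <- generate_dataset(synth_config(seed = seed))

write_table(d$plants, file.path(out, "plants.tsv"))
write_table(d$compounds, file.path(out, "compounds.tsv"))
write_gmt(d$pathways, file.path(out, "pathways.gmt"))
write_table(
  tibble::tibble(compound_id = names(d$truth$prototype),
                 prototype = as.integer(d$truth$prototype)),
  file.path(out, "truth_prototypes.tsv"))

cat(sprintf("plants: %d (%d with activity evidence)\n",
            nrow(d$plants), sum(d$plants$has_evidence)))
cat(sprintf("compounds: %d phytochemicals + %d references\n",
            sum(!d$compounds$is_reference), sum(d$compounds$is_reference)))
cat(sprintf("pathways: %d; planted enriched set: %s\n",
            length(d$pathways), d$truth$planted_pathway))
cat(sprintf("planted candidate plant: %s\n", d$truth$planted_plant))
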