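#!/usr/bin/env Rscript
# Phases 3-4: QED drug-likeness scoring with the strict > 0.5 gate, then the
# toxicity-alert and target-availability filters.

suppressMessages(library(phytoscreen))

d <- generate_dataset(synth_config(seed = 1L))
out <- "results"
dir.create(out, showWarnings = FALSE)

phyto <- d$compounds[!d$compounds$is_reference, ]
scored <- score_qed(phyto)
write_table(scored[, c("compound_id", "name", QED_DESCRIPTORS, "qed")],
            file.path(out, "qed_report.tsv"))

g1 <- qed_gate(scored, 0.5)
cat(sprintf("QED > 0.5: %d of %d pass (median QED %.3f)\n",
            nrow(g1$passed), nrow(scored), stats::median(scored$qed)))

g2 <- toxicity_gate(g1$passed)
cat(sprintf("alert-free: %d of %d (flags: %s)\n",
            nrow(g2$clean), nrow(g1$passed),
            paste(TOX_FLAGS, collapse = ", ")))

g3 <- target_gate(g2$clean)
cat(sprintf("with reported targets: %d of %d\n",
            nrow(g3$with_targets), nrow(g2$clean)))

write_table(g3$with_targets, file.path(out, "screened_compounds.tsv"))
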