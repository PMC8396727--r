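#!/usr/bin/env Rscript
# Simulate a panel of synthetic transporter families covering the four
# fold-type archetypes (broken vs reentrant core, both orientations), with
# known true topologies, trees and noisy predicted topologies. Downstream
# scripts consume these files. Everything is seeded and regenerable.

suppressPackageStartupMessages(library(cpatopo))

out_dir <- "results/families"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed0 <- 20260901

panel <- list(
  bart_like      = list(label = "8H-2BH-Nin",  p_miss = 0.2),
  cpa_broken     = list(label = "12H-2BH-Nin", p_miss = 0.2),
  cpa_reentrant  = list(label = "10H-2RH-Nout", p_miss = 1.0),
  rhr_like       = list(label = "9H-2RH-Nin",  p_miss = 1.0))

summary_rows <- list()
for (nm in names(panel)) {
  p <- panel[[nm]]
  spec <- family_spec(p$label, n_sequences = 20,
                      p_miss_noncanonical = p$p_miss,
                      seed = seed0 + match(nm, names(panel)))
  fam <- generate_family(spec)
  write_topology_fasta(
    fam$msa,
    vapply(names(fam$msa), function(id)
      project_topology(fam$msa[[id]], fam$predicted[[id]]), character(1)),
    file.path(out_dir, paste0(nm, "_predicted.fa")))
  write_topology_fasta(
    fam$msa,
    vapply(names(fam$msa), function(id)
      project_topology(fam$msa[[id]], fam$truth[[id]]), character(1)),
    file.path(out_dir, paste0(nm, "_truth.fa")))
  ape::write.tree(fam$tree, file.path(out_dir, paste0(nm, ".nwk")))
  meff <- compute_meff(fam$msa)
  pred_labels <- vapply(fam$predicted, function(s)
    tryCatch(format(topology_label(parse_topology_string(s))),
             error = function(e) NA_character_), character(1))
  summary_rows[[nm]] <- data.frame(
    family = nm, true_label = p$label, n = length(fam$msa),
    meff = meff,
    columns = nchar(fam$msa[[1]]),
    predictions_matching_truth = sum(pred_labels == p$label, na.rm = TRUE))
  message(sprintf("%-14s %-12s n=%d Meff=%d, %d/%d predictions see truth",
                  nm, p$label, length(fam$msa), meff,
                  sum(pred_labels == p$label, na.rm = TRUE),
                  length(fam$msa)))
}
summary <- do.call(rbind, summary_rows)
write.table(summary, file.path("results", "family_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("The reentrant-core families are prediction-blind (no row shows a ",
        "reentrant helix); their recovery is the job of script 03.")
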