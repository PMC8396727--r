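#!/usr/bin/env Rscript
# Core-helix sequence features: extract the non-canonical (broken or
# reentrant) helix of each repeat from broken- and reentrant-core families,
# build position frequency / information-content motifs, and compare
# insertion free energy and Gly/Pro content between the two core types —
# the compositional signature separating the fold-types.

suppressPackageStartupMessages(library(cpatopo))
dir.create("results", showWarnings = FALSE)

core_submsa <- function(label, seed) {
  spec <- family_spec(label, n_sequences = 18,
                      core_gly_pro_enrichment = 0.35, seed = seed)
  fam <- generate_family(spec)
  rep_id <- names(fam$msa)[1]
  t <- parse_topology_string(fam$truth[[rep_id]])
  lapply(c(N = "N", C = "C"), function(ru)
    extract_core_helix_submsa(fam$msa, t, fam$annotation, ru,
                              representative = rep_id))
}

reentrant <- core_submsa("10H-2RH-Nout", 20260941)
broken <- core_submsa("12H-2BH-Nin", 20260942)

write_motif <- function(sub, path) {
  m <- motif(sub$msa)
  tab <- data.frame(position = seq_along(m$ic), round(m$freq, 4),
                    ic_bits = round(m$ic, 4))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m
}
m_rn <- write_motif(reentrant$N, "results/motif_reentrant_Ncore.tsv")
m_bn <- write_motif(broken$N, "results/motif_broken_Ncore.tsv")
message(sprintf("mean IC (bits): reentrant N-core %.2f, broken N-core %.2f",
                mean(m_rn$ic), mean(m_bn$ic)))

summ <- fold_type_feature_summary(list(
  reentrant_core = unname(degap(c(reentrant$N$msa, reentrant$C$msa))),
  broken_core = unname(degap(c(broken$N$msa, broken$C$msa)))))
write.table(summ, "results/core_feature_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (r in seq_len(nrow(summ)))
  message(sprintf(
    "%-15s n=%3d  dG mean %+6.2f [%+.2f, %+.2f]  G/P freq %.3f",
    summ$group[r], summ$n[r], summ$dg_mean[r], summ$dg_q25[r],
    summ$dg_q75[r], summ$gly_pro_freq[r]))
message("reentrant cores score less hydrophobic (higher dG) and more ",
        "G/P-rich than broken cores: ",
        summ$dg_mean[summ$group == "reentrant_core"] >
          summ$dg_mean[summ$group == "broken_core"] &&
          summ$gly_pro_freq[summ$group == "reentrant_core"] >
          summ$gly_pro_freq[summ$group == "broken_core"])
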