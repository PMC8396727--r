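#!/usr/bin/env Rscript
# Family/repeat homology network and the figure-grade data products: a
# designed cluster/satellite/outlier hit table is deduplicated and built
# into the log10(E)-weighted network; an internal-repeat self-alignment
# becomes an E-value-coloured dotplot; toy helical-bundle coordinates give
# a CA distance map.

suppressPackageStartupMessages(library(cpatopo))
dir.create("results", showWarnings = FALSE)

## network: one dense cluster, thin satellites, disconnected outliers ------
cluster <- c("cpa_broken_1", "cpa_broken_2", "cpa_reentrant_1",
             "cpa_reentrant_2", "cpa_reentrant_3", "pse_1")
satellites <- c("bart_1", "bart_2")
outliers <- c("lrga", "lysa")
hits <- generate_hit_table(clusters = list(cluster),
                           satellites = satellites, outliers = outliers,
                           seed = 20260951)
hits <- dedupe_bidirectional(hits)
nodes <- data.frame(
  id = c(cluster, satellites, outliers),
  fold_type = c(rep("CPA", 6), rep("BART", 2), rep("RHR", 2)))
g <- build_network(hits, nodes)
write_network(g, "results/family_network.graphml",
              "results/family_network_edges.tsv")
comp <- igraph::components(g)
message(sprintf("network: %d nodes, %d edges (%d thick), largest component %d",
                igraph::vcount(g), igraph::ecount(g),
                sum(igraph::E(g)$class == "thick"), max(comp$csize)))
in_main <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
message("cluster families all in the main component: ",
        all(cluster %in% in_main),
        "; outliers excluded: ", !any(outliers %in% in_main))

## dotplot: internal inverted-repeat self-alignment ------------------------
set.seed(20260952)
spec <- family_spec("10H-2RH-Nout", n_sequences = 3, seed = 20260953)
fam <- generate_family(spec)
rep_seq <- degap(fam$msa[[1]])
t <- parse_topology_string(fam$truth[[1]])
ann <- fam$annotation
# self-alignment shifted by the repeat period: N-repeat residues pair with
# their C-repeat counterparts, an off-diagonal band in the dotplot
offset <- ann$c_repeat[1] - ann$n_repeat[1]
aln <- pairwise_alignment(
  "rep", "rep",
  q_aln = paste0(strrep("-", offset), rep_seq),
  t_aln = paste0(rep_seq, strrep("-", offset)),
  e_value = 1e-6)
dp <- alignment_dotplot(aln, q_topology = t, t_topology = t)
write.table(dp$points, "results/repeat_dotplot_points.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
offsets <- unique(dp$points$t_pos - dp$points$q_pos)
message(sprintf(
  "repeat self-alignment dotplot: %d points on the %+d-offset band",
  nrow(dp$points), offsets))

## distance map: toy helical bundle ----------------------------------------
helix_coords <- function(n, phase = 0, cx = 0, cy = 0) {
  i <- seq_len(n)
  cbind(x = cx + 2.3 * cos(100 * pi / 180 * i + phase),
        y = cy + 2.3 * sin(100 * pi / 180 * i + phase),
        z = 1.5 * i)
}
bundle <- rbind(helix_coords(30), helix_coords(30, pi, 9, 0)[30:1, ])
dm <- distance_map(bundle)
write.table(round(dm$distances, 3), "results/bundle_distance_map.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
clipped <- clip_distances(dm)
message(sprintf(
  "distance map: %dx%d, raw range %.1f..%.1f A, rendered %.1f..%.1f A",
  nrow(dm$distances), ncol(dm$distances), min(dm$distances),
  max(dm$distances), min(clipped), max(clipped)))
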