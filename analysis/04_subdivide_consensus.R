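#!/usr/bin/env Rscript
# Partition the PC1/PC2 plane into an equal-sized rectangular grid, label
# each occupied region by its phylum/class composition (IA / IB / II /
# mixed / sparse), and write one consensus sequence per non-sparse region.
# With the three simulated classes a 2x2 grid isolates each class in its
# own cell and the cell consensus reproduces the class template.

suppressPackageStartupMessages(library(hydrin))
coords <- read_tsv("results/pca/coordinates.tsv")
msa <- read_fasta_msa("results/pca/alignment.fasta")
ann <- read_tsv("results/sequences/annotations.tsv")
truth <- read_tsv("results/sequences/truth.tsv")

proj <- structure(list(
  eigenvalues = read_tsv("results/pca/eigenvalues.tsv")$eigenvalue,
  coordinates = as.matrix(`rownames<-`(coords[, c("PC1", "PC2")], coords$id)),
  component_count = 2L), class = "projection")

dir.create("results/regions", showWarnings = FALSE, recursive = TRUE)
grid <- partition(proj, nx = 2, ny = 2)
occupied <- sort(unique(grid$membership))
rows <- list(); cons <- character(0)
for (cell in occupied) {
  s <- summarize_region(grid, cell, ann)
  ids <- names(grid$membership)[grid$membership == cell]
  it_mean <- if (length(ids) >= 2) identity_table(msa, ids)$mean else NA
  rows[[length(rows) + 1L]] <- data.frame(
    cell = cell, n = s$n_sequences, label = s$label,
    mean_pairwise_identity = round(it_mean, 1),
    frac_ascomycota = s$phylum_fractions[["Ascomycota"]],
    frac_basidiomycota = s$phylum_fractions[["Basidiomycota"]],
    frac_class_II = s$class_fractions[["II"]])
  if (s$label != "sparse")
    cons[paste0("cell", cell, "_", s$label)] <-
      region_consensus(msa, ids)$letters
}
summ <- do.call(rbind, rows)
write_tsv(summ, "results/regions/regions.tsv")
write_fasta(cons, "results/regions/consensus.fasta")
print(summ)

# consensus fidelity against the generating templates
cl <- truth$class_label[match(names(grid$membership), truth$id)]
for (k in c("IA", "IB", "II")) {
  main <- as.integer(names(which.max(table(grid$membership[cl == k]))))
  ids <- names(grid$membership)[grid$membership == main & cl == k]
  c_seq <- gsub("[-x]", "", region_consensus(msa, ids)$letters)
  tmpl <- truth$template[match(ids[1], truth$id)]
  cat(sprintf("  %-3s consensus vs template identity: %.1f%%\n", k,
              percent_identity(global_align(c_seq, tmpl), "all")))
}
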