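#!/usr/bin/env Rscript
# Simulate the sequence inputs for the pipeline: three class-structured
# hydrophobin-like sets (Class IA, IB, II; 100 sequences each) carrying the
# canonical eight-cysteine arrangement, plus 20 negative controls that break
# it. Writes FASTA, a ground-truth table and a phylum/class annotation
# sidecar under results/sequences/.

suppressPackageStartupMessages(library(hydrin))
out <- "results/sequences"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

specs <- list(class_spec("IA"), class_spec("IB"), class_spec("II"))
gen <- gen_sequences(specs, n = 100, seed = seed)
neg <- gen_negatives(20, seed = seed + 1L)

write_fasta(c(gen$sequences, neg$sequences), file.path(out, "sequences.fasta"))
write_tsv(gen$truth, file.path(out, "truth.tsv"))
write_tsv(neg$truth, file.path(out, "negatives_truth.tsv"))

ann <- data.frame(
  id = c(gen$truth$id, neg$truth$id),
  phylum = c(gen$truth$phylum, rep("unknown", nrow(neg$truth))),
  class_annotation = c(ifelse(gen$truth$class_label == "II", "II", "I"),
                       rep("none", nrow(neg$truth))))
write_tsv(ann, file.path(out, "annotations.tsv"))

cat(sprintf("Wrote %d positive sequences (3 classes) and %d negatives to %s\n",
            length(gen$sequences), length(neg$sequences), out))
cat("Class templates (inter-cysteine segment lengths):\n")
for (sp in specs)
  cat(sprintf("  %-3s L1..L7 = %s\n", sp$class_label,
              paste(sp$seg_mean, collapse = ", ")))
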