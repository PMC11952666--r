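#!/usr/bin/env Rscript
# Simulate the synthetic two-group proteome/phosphoproteome study that the
# downstream analyses consume: 4 control vs 4 mutant replicates, 2000
# proteins (10% truly differential at |log2FC| = 2), 1000 phosphosites
# tracking their parent proteins, and five kinases of which K1 is shifted
# down and K2 up by one noise-SD on their 30 substrates each.

library(phosflow)

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
study <- simulate_study(cfg)

write_intensity_tsv(study$proteome$matrix, file.path(out, "proteome.tsv"))
write_intensity_tsv(study$phospho$matrix, file.path(out, "phospho.tsv"))
write_tsv(study$proteome$metadata, file.path(out, "metadata.tsv"))
write_tsv(study$phospho$site_table, file.path(out, "sites.tsv"))
write_tsv(study$phospho$annotation, file.path(out, "annotation.tsv"))
write_pssm_tsv(study$kinase_models, file.path(out, "pssm.tsv"))
jsonlite::write_json(
  list(de_labels = as.list(study$proteome$truth$de_labels),
       module_labels = as.list(study$proteome$truth$module_labels),
       kinase_shifts = as.list(study$phospho$truth$kinase_shifts),
       substrate_map = study$phospho$truth$substrate_map),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE)
for (f in list.files(out, pattern = "\\.tsv$")) {
  write_provenance(file.path(out, f), "simdata", unclass(cfg))
}

truth <- study$proteome$truth
cat(sprintf("simulated %d proteins x %d samples (%d truly differential)\n",
            nrow(study$proteome$matrix), ncol(study$proteome$matrix),
            sum(truth$de_labels != "null")))
cat(sprintf("simulated %d phosphosites; kinase shifts: %s\n",
            nrow(study$phospho$matrix),
            paste(names(study$phospho$truth$kinase_shifts),
                  study$phospho$truth$kinase_shifts,
                  sep = "=", collapse = ", ")))
cat("outputs in", out, "\n")
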