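#!/usr/bin/env Rscript
# Step 1: generate the synthetic study system — a titin-like multi-isoform
# gene model and three population call sets (a superset cohort plus two
# partially overlapping subset cohorts with planted subset-unique false
# positives), with exact truth labels for every planted variant.
#
# Outputs: results/sim_bundle/ (model.json, locus.fa, cohort_*.vcf,
# coverage.tsv, truth.tsv, simconfig.yaml) and a run manifest.

suppressMessages(library(ttnsift))

seed <- 1L
cfg <- sim_config(seed = seed)
sim <- simulate_cohort(cfg)
out <- file.path("results", "sim_bundle")
write_sim_bundle(sim, out)
write_manifest(file.path("results", "simulate_manifest.json"),
               config = list(seed = seed, n_exons = cfg$n_exons,
                             class_counts = as.list(cfg$class_counts)),
               inputs = file.path(out, "model.json"), seed = seed)

cat(sprintf("gene model: %d exons (+1 novex-like), %d transcripts, CDS %d bp\n",
            cfg$n_exons, length(sim$model$transcripts),
            nchar(cds_sequence(sim$model, reference_transcript(sim$model)))))
cat(sprintf("planted %d variants across %d datasets:\n", nrow(sim$truth),
            length(sim$records_by_dataset)))
print(table(sim$truth$class))
cat(sprintf("singleton fraction %.2f; PASS fraction %.2f\n",
            mean(sim$truth$AC == 1), mean(sim$truth$pass)))
cat(sprintf("bundle written to %s\n", out))
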