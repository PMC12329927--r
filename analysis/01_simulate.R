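#!/usr/bin/env Rscript
# Stage 1 — generate the study inputs: the 51-species / 35-genus taxonomy
# with ITS1/ITS2 marker sequences, the two reference databases (one
# complete and fully annotated, one 90%-complete with 10% of entries
# unannotated at species level), the 37 five-species mock communities, and
# error-free paired reads for every community and marker. Writes FASTQ,
# reference FASTA + taxonomy, the community registry and the read truth
# tables under results/inputs/.

suppressPackageStartupMessages(library(dmcbench))

seed <- 1
outdir <- "results/inputs"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- benchmark_config(seed = seed)
inputs <- generate_inputs(cfg)

cat(sprintf("species pool: %d species in %d genera\n",
            nrow(inputs$taxa), length(unique(inputs$taxa$genus))))
cat(sprintf("communities: %d (replicate pair: %s == %s)\n",
            nrow(inputs$communities),
            inputs$communities$dmc_id[37], inputs$communities$replicate_of[37]))

for (nm in names(inputs$dbs)) {
  write_reference_db(inputs$dbs[[nm]], file.path(outdir, "db"))
}

registry <- data.frame(
  dmc_id = inputs$communities$dmc_id,
  replicate_of = inputs$communities$replicate_of,
  members = vapply(inputs$communities$members, paste, "", collapse = ";"))
write_tsv(registry, file.path(outdir, "communities.tsv"))

params <- read_sim_params(reads_per_community = cfg$reads_per_community,
                          seed = seed)
truth_all <- list()
for (i in seq_len(nrow(inputs$communities))) {
  community <- inputs$communities[i, , drop = FALSE]
  for (marker in cfg$markers) {
    sim <- simulate_reads(community, inputs$taxa, marker, params)
    base <- file.path(outdir, sprintf("%s_%s", community$dmc_id, marker))
    write_fastq(sim$fwd, paste0(base, "_R1.fastq"))
    write_fastq(sim$rev, paste0(base, "_R2.fastq"))
    truth_all[[paste(community$dmc_id, marker)]] <- sim$truth
  }
}
write_tsv(do.call(rbind, truth_all), file.path(outdir, "read_truth.tsv"))
cat("wrote reads + truth for", nrow(inputs$communities), "communities x",
    length(cfg$markers), "markers to", outdir, "\n")
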