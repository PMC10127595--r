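#!/usr/bin/env Rscript
# Build the synthetic lysogen used by the downstream steps: a 40-kb circular
# replicon with one 8-kb active prophage (1,000-fold enriched over
# background in the phage fraction, with a right-hand over-packaged flank),
# one IS family with a copy inside the prophage and six chromosomal copies,
# induced-phage and host-control read sets, and duplicate culture counts.

suppressMessages(library(lysoscan))
dir.create("results", showWarnings = FALSE)
seed <- 1

genome <- simulate_genome(
  40000, gc = 0.635,
  prophage_specs = list(prophage_spec(
    15000, 23000, core_rate = 4000, flank_side = "right",
    flank_rate = 120, flank_extent = 3000)),
  is_specs = list(is_spec("IS66", 1000,
                          starts = c(18000, 1000, 4500, 8000, 11500,
                                     29000, 33500))),
  seed = seed)
print(genome)

write_genome_fasta(genome, "results/lysogen.fasta")
write_truth(genome, bed_path = "results/truth.bed",
            json_path = "results/truth.json")

phage_params <- read_sim_params(
  read_length = 100, error_rate = 0.002, background_rate = 4,
  contaminant_fraction = 0.08, seed = seed, max_reads = 5e5)
phage_reads <- simulate_phage_reads(genome, phage_params)
write_reads_fastq(phage_reads, "results/phage_fraction.fastq")
cat(sprintf("phage fraction: %d reads (%.1f%% contaminant by truth)\n",
            nrow(phage_reads), 100 * mean(phage_reads$label == "contaminant")))

host_reads <- simulate_host_reads(genome, depth = 200, read_length = 100,
                                  error_rate = 0.002, seed = seed + 1,
                                  max_reads = 5e5)
write_reads_fastq(host_reads, "results/host_control.fastq")
cat(sprintf("host control: %d reads at 200x target depth\n", nrow(host_reads)))

counts <- simulate_growth_counts(growth_params(seed = seed))
write.table(counts, "results/growth_counts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote results/: lysogen.fasta, truth.bed/json, *.fastq, growth_counts.tsv\n")
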