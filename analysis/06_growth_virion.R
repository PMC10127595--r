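#!/usr/bin/env Rscript
# Culture kinetics and virion morphometrics: doubling time from the
# simulated counts, the PLP-to-bacterium ratio series, and capsid-based
# genome-size estimates.

suppressMessages(library(lysoscan))

counts <- read_count_series("results/growth_counts.tsv")

# doubling time over the exponential stretch, per replicate
for (r in unique(counts$replicate)) {
  s <- counts[counts$replicate == r, ]
  g <- doubling_time(s$cells_per_ml[1], s$cells_per_ml[nrow(s)],
                     s$time_h[nrow(s)] - s$time_h[1])
  cat(sprintf("replicate %d: doubling time %.1f h over %g h\n",
              r, g, s$time_h[nrow(s)]))
}

ratios <- plp_ratio_series(counts)
print(ratios$ratios)
cat(sprintf("PLP:bacterium maximum %.2f at %g h\n",
            ratios$max_ratio, ratios$t_max))
write.table(ratios$ratios, "results/plp_ratios.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# virion morphometrics for the observed capsid diameters
virions <- tibble::tibble(
  capsid_nm = c(70, 65, 63, 57),
  volume_nm3 = capsid_volume(c(70, 65, 63, 57)))
virions$volume_2sf <- format_sig2(virions$volume_nm3)
virions$genome_kb_lower <- vapply(virions$capsid_nm,
                                  function(d) genome_size_from_capsid(d)[["lower"]],
                                  numeric(1))
virions$genome_kb_upper <- vapply(virions$capsid_nm,
                                  function(d) genome_size_from_capsid(d)[["upper"]],
                                  numeric(1))
print(virions)
write.table(virions, "results/virion_morphometrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("a ~60-nm capsid implies %.0f-%.0f kb of packaged dsDNA\n",
            genome_size_from_capsid(60)[["lower"]],
            genome_size_from_capsid(60)[["upper"]]))
cat("wrote results/: plp_ratios.tsv, virion_morphometrics.tsv\n")
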