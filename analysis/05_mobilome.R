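#!/usr/bin/env Rscript
# Mobilome profiling on a synthetic IS annotation set shaped like an
# HRS-leaning bradyrhizobial chromosome: several DDE families plus IS110
# (DEDD), IS91 (HUH) and ISCNY (unclassified), with tandem runs of IS21 and
# IS66. Also reproduces the printed worked example: 151 IS on a
# 9,863,878-bp chromosome is 15 per Mb.

suppressMessages(library(lysoscan))
set.seed(5)

chrom_len <- 2e6
fams <- c(IS21 = 40, IS66 = 25, IS630 = 15, IS5 = 12, IS110 = 18,
          IS91 = 4, ISCNY = 3)
rows <- list()
pos <- 0
for (f in names(fams)) {
  starts <- sort(sample(0:(chrom_len - 1500), fams[[f]]))
  rows[[f]] <- tibble::tibble(replicon_id = "chrom", start = starts,
                              end = starts + 1200, family = f)
}
ann <- do.call(rbind, rows)
# plant tandem duplicate runs (gap 100 bp) of IS21 and IS66
tandem <- tibble::tibble(
  replicon_id = "chrom",
  start = c(500000, 501300, 502600, 800000, 801300),
  end = c(501200, 502500, 503800, 801200, 802500),
  family = c("IS21", "IS21", "IS21", "IS66", "IS66"))
ann <- rbind(ann, tandem)

totals <- is_totals_and_density(ann, c(chrom = chrom_len), rounding = "nearest")
print(totals)

dens <- windowed_density(ann, chrom_len, window = 10000, normalize = TRUE)
writeLines(sprintf("chrom\t%d\t%d\t%d", dens$window_start, dens$window_end,
                   dens$count),
           "results/is_density_10kb.bedGraph")
cat(sprintf("windowed density: %d windows, max %d IS per 10 kb\n",
            nrow(dens), max(dens$count)))

fa <- family_abundance(ann, chrom_len)
print(fa[order(-fa$log_abundance), ])
write.table(fa, "results/is_family_abundance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cd <- consecutive_duplicates(ann, max_gap = 500)
cat("consecutive duplicates (max_gap 500):\n")
print(cd)
write.table(cd, "results/is_consecutive_duplicates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# worked example on printed numbers
ex_starts <- seq(0, by = 65000, length.out = 151)
ex <- is_totals_and_density(
  tibble::tibble(replicon_id = "S10J_chrom", start = ex_starts,
                 end = ex_starts + 1000, family = "IS21"),
  c(S10J_chrom = 9863878), rounding = "nearest")
cat(sprintf("worked example: 151 IS / 9,863,878 bp -> %d per Mb\n",
            ex$per_replicon$density_per_mb))

# plasmid backbone screen on a mock annotation table
genes <- tibble::tibble(
  id = c("repA", "repB", "repC", "traG", "parA", "parB", "g7"),
  product = c("replication initiator", "replication protein B",
              "replication protein C", "conjugal transfer protein",
              "partition ATPase", "partition protein",
              "transposase, partial"))
scr <- plasmid_feature_screen(genes)
cat(sprintf("plasmid screen: repABC=%s tra=%s par=%s\n",
            scr$repABC_present, scr$tra_present, scr$par_present))
cat("wrote results/: is_*.tsv, is_density_10kb.bedGraph\n")
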