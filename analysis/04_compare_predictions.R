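#!/usr/bin/env Rscript
# Compare the mapped prophage call against synthetic stand-ins for external
# prophage predictions. Real predictor output is not reproducible here
# without running those tools, so three mock prediction sets are generated
# with the failure modes such tools show in practice: truncated calls,
# fragmented calls, and boundary offsets.

suppressMessages(library(lysoscan))

report <- jsonlite::read_json("results/delineation_report.json",
                              simplifyVector = TRUE)
core <- report$regions[report$regions$klass == "core", ]
s0 <- core$start - 1  # back to 0-based
e0 <- core$end

# synthetic predictions relative to the called core
bedA <- "results/predictions_synthetic_toolA.bed"
writeLines(sprintf("chr\t%d\t%d\tintact", s0 + 2000, e0 - 3000), bedA)
bedB <- "results/predictions_synthetic_toolB.bed"
writeLines(c(sprintf("chr\t%d\t%d\tincomplete", s0 - 500, s0 + 2500),
             sprintf("chr\t%d\t%d\tquestionable", e0 - 2000, e0 + 1000),
             "chr\t33000\t36000\tincomplete"), bedB)
gffC <- "results/predictions_synthetic_toolC.gff3"
writeLines(c("##gff-version 3",
             sprintf("chr\ttoolC\tprophage\t%d\t%d\t.\t+\t.\tID=pp1",
                     s0 + 1001, e0 + 1500)), gffC)

preds <- rbind(load_intervals(bedA, tool = "toolA"),
               load_intervals(bedB, tool = "toolB"),
               load_intervals(gffC))
cmp <- compare_intervals(core, preds)
print(cmp)

write.table(cmp$matches, "results/prediction_overlap.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(cmp$unmatched_per_tool, "results/prediction_unmatched.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("no prediction matches the mapped core exactly: max jaccard %.2f\n",
            max(cmp$matches$jaccard)))
cat("wrote results/: prediction_overlap.tsv, prediction_unmatched.tsv\n")
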