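#!/usr/bin/env Rscript
# Turns the raw probing signals from 01 into normalized, classified profiles:
# replicate averaging, box-plot normalization, three-class SHAPE
# classification, and recovery of the planted profile from
# mutational-profiling counts.

library(lncstruct)

reps <- lapply(sprintf("results/reactivity_rep%d.tsv", 1:3),
               read_reactivity_table)
avg <- combine_replicates(reps)
norm <- normalize_boxplot(avg)
write_reactivity_table(norm$profile, "results/reactivity_normalized.tsv")

classes <- classify(norm$profile)
write.table(data.frame(position = seq_along(classes), class = classes),
            "results/reactivity_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
occ <- table(classes)
message(sprintf("classification occupancy: %s",
                paste(names(occ), occ, sep = "=", collapse = ", ")))

truth <- parse_dotbracket(readLines("results/core_structure.db"))
paired <- truth$pt != 0
v <- as.numeric(norm$profile)
message(sprintf("paired positions below 0.40: %.1f%% (unpaired: %.1f%%)",
                100 * mean(v[paired] < 0.40, na.rm = TRUE),
                100 * mean(v[!paired] < 0.40, na.rm = TRUE)))

# mutational profiling: counts -> background-corrected rates -> normalized
counts <- read_map_counts("results/map_counts.tsv")
rec <- normalize_boxplot(map_reactivity(counts))$profile
write_reactivity_table(rec, "results/map_recovered.tsv")
planted <- read_reactivity_table("results/map_truth.tsv")
r <- cor(as.numeric(rec), as.numeric(planted), use = "complete.obs")
message(sprintf("MaP recovery: Pearson r = %.4f vs the planted profile", r))
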