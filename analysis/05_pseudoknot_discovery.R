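#!/usr/bin/env Rscript
# The core inference: scan the folded transcript for kissing-loop registers
# between the hairpin-loop motif and distal single-stranded tandem repeats,
# design the compensatory rescue panel for a loop point mutation, and score
# conservation/covariation across the 41-species alignment. Also
# demonstrates the splice-variant coordinate arithmetic on the MEG3 v1
# reference model.

library(lncstruct)

seq <- read_fasta("results/core.fa")[[1]]
truth <- parse_dotbracket(readLines("results/core_structure.db"))

registers <- scan_kissing(seq, truth, scan_params())
write.table(registers, "results/kissing_registers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("scanner: %d mutually exclusive registers (%s)",
                nrow(registers), paste(registers$label, collapse = ", ")))
writeLines(write_dotbracket(annotate_pseudoknot(truth, registers, 3)),
           "results/core_with_pseudoknot.db")

# compensatory panel: mutate the central motif G (wobble-paired to U in
# every register) to C; each register is rescued by its own U -> G
motif_mid <- 80L
panel <- design_rescue_panel(registers, position = motif_mid,
                             from = "G", to = "C", sequence = seq)
write.table(panel, "results/rescue_panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("rescue panel: %d double mutants (%s)",
                nrow(panel), paste(panel$construct, collapse = ", ")))

aln <- read_stockholm("results/core_alignment.sto")
cons <- repeat_conservation(aln, min_count = 3)
write.table(cons, "results/repeat_conservation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("repeat conservation: %d/%d species carry >= 3 repeats",
                sum(cons$pass), nrow(cons)))

cv <- covariation(aln, n_perm = 200, seed = 99)
write.table(cv, "results/covariation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("covariation: %d/%d structure pairs with E <= 0.05 (median score %.2f)",
                sum(cv$evalue <= 0.05), nrow(cv), median(cv$score)))

# reference-coordinate demo: E5 deletion turns the 1,595-nt v1 into a
# 1,481-nt variant, and positions downstream shift by the exon length
m <- meg3_v1_model()
v1_seq <- paste(sample(c("A", "C", "G", "U"), 1595, replace = TRUE),
                collapse = "")
v9 <- build_variant(m, variant_spec(
  deletions = data.frame(start = 936, end = 1049)), v1_seq, name = "v9")
message(sprintf("variant arithmetic: v1 %d nt -> v9 %d nt; v9 position 936 maps to v1 %d",
                m$length, v9$variant$length, map_position(v9$variant, 936L)))
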