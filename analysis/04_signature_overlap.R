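#!/usr/bin/env Rscript
# Fold-change signatures and overlap statistics on a synthetic expression
# matrix: two conditions with 200 planted (>= 2-fold) upregulated probes each
# sharing half their members in a 20,000-probe universe, plus an independent
# (null) condition. Signatures are thresholded at two-fold against the
# reference and compared by the two-sided Fisher exact test on the 2x2
# overlap confusion matrix.

library(cscplasticity)

dir.create("results", showWarnings = FALSE)

universe <- 20000L
sets <- plant_overlapping_sets(universe, 200, 0.5, seed = 41)
set.seed(42)
null_up <- sort(sample.int(universe, 200))
spec <- synthetic_expression_spec(
  universe,
  conditions = list(condA = list(up = sets$A, fold = 4),
                    condB = list(up = sets$B, fold = 4),
                    condNull = list(up = null_up, fold = 4)),
  noise_sdlog = 0.1, seed = 43)
tab <- generate_expression(spec)
write_expression_table(tab, "results/expression.csv")

sigs <- lapply(c("condA", "condB", "condNull"), function(cond) {
  s <- derive_signature(tab, cond, "up")
  write_signature(s, sprintf("results/signature_up_%s.txt", cond))
  s
})
names(sigs) <- c("condA", "condB", "condNull")

rep <- overlap_report(
  list(A_vs_B = list(A = sigs$condA, B = sigs$condB),
       A_vs_null = list(A = sigs$condA, B = sigs$condNull)),
  universe_size = universe)
write.csv(rep, "results/overlap_report.csv", row.names = FALSE)
print(rep)
stopifnot(rep$significant[rep$pair == "A_vs_B"])
cat("finding: the planted 50% signature overlap is far beyond chance;\n")
cat("the independent pair shows no significant overlap.\n")
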