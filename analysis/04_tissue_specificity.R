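#!/usr/bin/env Rscript
# Stage 4: fractional tissue specificity.
#
# Ts_i = x_i / sum(x) per gene; maxTs summarises specificity (1 = all
# expression in one tissue, 1/n = uniform). Labels use maxTs >= 0.8 for
# tissue-specific and <= 2/n for constitutive.

suppressPackageStartupMessages(library(spliceatlas))

expr <- read_expression("results/data/expression.tsv")
tsp <- ts_profile(expr)
spliceatlas:::write_tsv_with_header(tsp, "results/ts_profiles.tsv")

lab <- table(tsp$label)
cat(sprintf("%d genes over %d tissues; maxTs range [%.4f, %.4f]\n",
            nrow(tsp), ncol(expr), min(tsp$maxTs, na.rm = TRUE),
            max(tsp$maxTs, na.rm = TRUE)))
print(lab)
cat(sprintf("uniform-expression floor 1/n = %.4f\n", 1 / ncol(expr)))
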