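#!/usr/bin/env Rscript
# Stage 6: gene-family filtering and Ks dating.
#
# Demonstrates the homology filter (E < 1e-10, identity > 40, coverage > 95,
# then a required-domain check) on a small constructed hit table, and
# estimates synonymous divergence for the simulated codon pairs with the
# NG86 counting method, dating them via T = Ks / (2 x 6.5e-9).

suppressPackageStartupMessages(library(spliceatlas))

# toy homology screen: 8 candidate subjects, 5 of which survive all filters
hits <- data.frame(
  query = "PAL_query",
  subject = paste0("cand", 1:8),
  evalue = c(1e-30, 1e-12, 1e-8, 1e-50, 1e-11, 1e-20, 1e-15, 1e-40),
  identity = c(75, 41, 80, 39, 55, 62, 48, 90),
  coverage = c(99, 96, 98, 97, 94, 97, 96, 99))
surv <- filter_hits(hits)
domains <- data.frame(
  candidate = c("cand1", "cand1", "cand2", "cand6", "cand7", "cand8"),
  domain = c("PF00221", "PF00222", "PF00221", "PF00221", "PF00221",
             "PF00221"))
confirmed <- domain_filter(surv$subjects, "PF00221", domains)
cat(sprintf("homology filter: %d/%d hits survive; domain check: %d confirmed\n",
            length(surv$subjects), nrow(hits), length(confirmed)))

members <- data.frame(
  family = rep(c("PAL", "CAD", "POD"), times = c(4, 6, 9)),
  species = "Phyllostachys_edulis",
  gene_id = sprintf("fam%02d", 1:19))
fams <- family_copy_summary(members)
cat(sprintf("family copies: mean %.1f, largest %s, smallest %s\n",
            fams$mean_copies, fams$largest, fams$smallest))

pairs <- spliceatlas:::read_tsv_with_header("results/data/codon_pairs.tsv")
est <- t(vapply(seq_len(nrow(pairs)), function(i) {
  r <- ng86_ks(pairs$seq_a[i], pairs$seq_b[i])
  c(ks = r$Ks, ka = r$Ka)
}, numeric(2)))
ks_df <- data.frame(pair_id = pairs$pair_id, target_ks = pairs$target_ks,
                    ks = est[, "ks"], ka = est[, "ka"],
                    t_mya = ks_to_time(pmax(est[, "ks"], 0)))
spliceatlas:::write_tsv_with_header(ks_df, "results/ks_estimates.tsv")

by_target <- aggregate(cbind(ks, t_mya) ~ target_ks, ks_df, mean)
jsonlite::write_json(
  list(confirmed_candidates = confirmed,
       family_mean_copies = fams$mean_copies,
       ks_recovery = by_target),
  "results/family_ks_summary.json", auto_unbox = TRUE, pretty = TRUE,
  dataframe = "rows", digits = 6)

cat("Ks recovery by target (mean estimate and dated Mya):\n")
print(by_target)
cat(sprintf("mean Ka across all pairs: %.2e (synonymous-only simulation)\n",
            mean(ks_df$ka)))
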