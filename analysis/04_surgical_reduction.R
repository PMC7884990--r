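#!/usr/bin/env Rscript
# Stage 4: where does surgery reduce abnormality?
#
# Relabels hemispheres ipsi/contralateral to each patient's surgery, groups
# nodes into six areas per side, and compares the proportion of abnormal
# nodes between presurgery and spared networks within each outcome group
# (paired t across patients per area, BH-corrected). Also compares the
# absolute and proportional whole-network load reduction between groups.

suppressMessages(library(sparenet))

coh <- read_cohort("results/cohort")
ref <- build_reference(coh$controls)

sets <- lapply(coh$patients, function(p) {
  zn <- z_score_network(p$connectome, ref)
  sp <- apply_resection(zn, p$resection)
  list(pre = abnormality_load(node_abnormality_profile(zn, 2.8), 10)$nodes,
       spared = abnormality_load(node_abnormality_profile(sp, 2.8), 10)$nodes,
       side = p$resection$side,
       pre_load = abnormality_load(node_abnormality_profile(zn, 2.8), 10)$load,
       spared_load = abnormality_load(node_abnormality_profile(sp, 2.8), 10)$load)
})

for (g in c("seizure_free", "not_seizure_free")) {
  idx <- which(coh$outcomes$label == g)
  res <- area_proportion_change(lapply(sets[idx], `[[`, "pre"),
                                lapply(sets[idx], `[[`, "spared"),
                                coh$nodes,
                                vapply(sets[idx], `[[`, "", "side"))
  testable <- !is.na(res$p)
  res$p_bh <- NA_real_
  res$p_bh[testable] <- bh_fdr(res$p[testable], q = 0.05)$adjusted
  out <- sprintf("results/regional_change_%s.tsv", g)
  write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("\n==", g, sprintf("(n = %d) ==\n", length(idx)))
  sig <- res[!is.na(res$p_bh) & res$p_bh < 0.05, ]
  if (nrow(sig) == 0) {
    cat("no area shows a significant drop after BH correction\n")
  } else {
    cat("significant drops (BH-corrected p < 0.05):\n")
    print(sig[, c("side", "area", "pre", "spared", "drop", "t", "p_bh")],
          row.names = FALSE)
  }
  cat("table written to", out, "\n")
}

lab <- coh$outcomes$label
keep <- lab != "ilae2"
rc <- reduction_comparison(vapply(sets[keep], `[[`, 0, "pre_load"),
                           vapply(sets[keep], `[[`, 0, "spared_load"),
                           lab[keep] == "seizure_free")
cat("\nload reduction, seizure-free vs not seizure-free:\n")
print(rc$tests, row.names = FALSE)
write.table(rc$tests, "results/load_reduction_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
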