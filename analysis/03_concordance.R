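#!/usr/bin/env Rscript

# Compare the inferred phenotypes against serology: per-antigen and
# per-system accuracies, their unweighted average, and the enumerated
# discordances (one row per donor-subsystem, with direction).
#
# Writes results/concordance_antigens.tsv, results/concordance_systems.tsv
# and results/discordances.tsv.

library(bloodgroupr)

res <- run_pipeline("results/fixture/cohort.vcf",
                    "results/fixture/depth.tsv",
                    "results/fixture/serology.tsv")
rep <- res$concordance

write.table(data.frame(antigen = names(rep$antigen_accuracy),
                       accuracy = rep$antigen_accuracy),
            "results/concordance_antigens.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(system = names(rep$system_accuracy),
                       accuracy = rep$system_accuracy),
            "results/concordance_systems.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rep$discordances, "results/discordances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(rep)
cat("\nPer-antigen accuracy (%):\n")
print(rep$antigen_accuracy)
cat("\nDiscordances:\n")
print(rep$discordances)
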