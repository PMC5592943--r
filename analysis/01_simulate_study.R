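#!/usr/bin/env Rscript
# Stage 1: simulate the miRIL study that all later stages analyse.
#
# 33 recombinant inbred lines segregating N2 (P1) and CB4856 (P2) alleles
# over six chromosomes, kept homozygous P1 at the selected locus IV:11.7 Mb,
# with 5000 expression features carrying planted cis effects (N2-biased),
# isolated trans effects and three clustered trans-bands in unit noise.

library(mirilqtl)

seed <- 1
out <- "results/01_simulate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_miril_study(seed = seed)

write_genotypes(study$geno, file.path(out, "genotypes_truth.tsv"))
write_genotypes(study$geno_informative,
                file.path(out, "genotypes_informative.tsv"))
write_expression(study$expr, file.path(out, "expression.tsv"))
mirilqtl:::write_tsv(study$arch$effects, file.path(out, "architecture_truth.tsv"))
mirilqtl:::write_tsv(study$arch$bands, file.path(out, "planted_bands.tsv"))
mirilqtl:::write_tsv(study$panel, file.path(out, "reference_cis_panel.tsv"))
mirilqtl:::write_tsv(study$annotation, file.path(out, "annotation.tsv"))
for (i in seq_along(study$ref_eqtl)) {
  mirilqtl:::write_tsv(study$ref_eqtl[[i]],
                       file.path(out, sprintf("reference_eqtl_set%d.tsv", i)))
}

freq <- colMeans(study$geno$calls)
cat(sprintf("Simulated %d lines x %d raw markers (%d informative after pruning).\n",
            nrow(study$geno$calls), ncol(study$geno$calls),
            ncol(study$geno_informative$calls)))
cat(sprintf("P1 frequency: %.2f at the selected locus, %.2f genome-wide.\n",
            freq[study$geno$selected_locus$marker], mean(freq)))
cat(sprintf("Planted effects: %d cis, %d trans, %d in %d trans-bands.\n",
            sum(study$arch$effects$class == "cis"),
            sum(study$arch$effects$class == "trans"),
            sum(study$arch$effects$class == "transband"),
            nrow(study$arch$bands)))
cat(sprintf("Outputs in %s/.\n", out))
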