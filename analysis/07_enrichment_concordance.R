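#!/usr/bin/env Rscript
# Stage 7: enrichment of trans-eQTL genes and modifier-allele concordance.
#
# Hypergeometric enrichment of the trans-eQTL gene set against the
# annotation catalogue (Bonferroni < 0.05, category size > 3, overlap > 2),
# then a concordance analysis at the largest planted trans-band: eQTL
# allelic effects vs simulated transgenic allelic differences in which 80%
# of genes respond to the shared regulator.

library(mirilqtl)

seed <- 1
out <- "results/07_downstream"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_miril_study(seed = seed)
rec_file <- "results/04_eqtl/eqtl_records.tsv"
records <- if (file.exists(rec_file)) {
  utils::read.table(rec_file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
} else {
  scanm <- eqtl_scan(study$expr, study$geno_informative)
  thr <- permutation_threshold(study$expr, study$geno_informative, q = 0.1,
                               n_perm = 10, seed = seed + 101,
                               scan_obs = scanm)
  classify_cis_trans(call_peaks(scanm, thr$threshold))
}

universe <- unique(study$arch$features$gene_id)
query <- intersect(unique(records$gene_id[records$class == "trans"]), universe)
enr <- enrich(query, study$annotation, universe, alpha = 0.05)
mirilqtl:::write_tsv(enr, file.path(out, "enrichment_trans.tsv"))
cat(sprintf("Enrichment: %d of %d categories pass all filters.\n",
            sum(enr$pass), nrow(enr)))
print(utils::head(enr[enr$pass, ], 5))

# concordance at the largest planted band: emulate transgenic measurements
band <- study$arch$bands[which.max(study$arch$bands$n_spots), ]
at_locus <- records[records$class == "trans" &
                      records$peak_chrom == band$chrom &
                      records$peak_pos >= band$bin_start - 1e6 &
                      records$peak_pos <= band$bin_end + 1e6, ]
ef <- study$arch$effects
truth <- ef[!is.na(ef$band_id) & ef$band_id == band$band_id, ]
fi <- match(truth$spot_id, study$arch$features$spot_id)
set.seed(seed + 3)
flip <- sample(c(1, -1), nrow(truth), replace = TRUE, prob = c(0.8, 0.2))
transgenic <- data.frame(gene_id = study$arch$features$gene_id[fi],
                         diff = truth$effect * flip +
                           stats::rnorm(nrow(truth), 0, 0.3),
                         stringsAsFactors = FALSE)
transgenic <- transgenic[!duplicated(transgenic$gene_id), ]
cc <- allelic_concordance(at_locus, transgenic)
mirilqtl:::write_tsv(cc$pairs, file.path(out, "concordance_pairs.tsv"))
cat(sprintf("Concordance at %s:%d-%d Mb: %d/%d genes share the allelic direction (R2 = %.2f).\n",
            band$chrom, band$bin_start %/% 1e6, band$bin_end %/% 1e6,
            cc$n_concordant, cc$n_total, cc$r2))
cat(sprintf("Outputs in %s/.\n", out))
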