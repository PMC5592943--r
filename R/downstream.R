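#' Hypergeometric gene-set enrichment with category and overlap filters
#'
#' Tests each annotation category for over-representation among the (unique)
#' query genes with an upper-tail hypergeometric test, Bonferroni-corrects
#' over the categories actually tested (those with more than 3 genes), and
#' flags categories passing all of: corrected p < `alpha`, category size > 3,
#' overlap > 2.
#'
#' @param query_genes Character vector of genes of interest (deduplicated
#'   internally); must be a subset of `universe`.
#' @param categories Data frame with columns `category_id`, `gene_id`;
#'   entries outside the universe are dropped.
#' @param universe Character vector: all genes on the platform.
#' @param alpha Significance level on the Bonferroni-corrected p.
#' @return Data frame per category: `category_id`, `category_size`,
#'   `query_size`, `overlap`, `p_raw`, `p_bonferroni`, `pass`.
#' @export
enrich <- function(query_genes, categories, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_("empty universe")
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    stop_("%d query genes are not in the universe (e.g. %s)",
          length(outside), outside[1])
  }
  cats <- unique(categories[categories$gene_id %in% universe,
                            c("category_id", "gene_id")])
  sizes <- table(cats$category_id)
  n_tested <- sum(sizes > 3)

  N <- length(universe)
  n_q <- length(query_genes)
  out <- do.call(rbind, lapply(names(sizes), function(cid) {
    members <- cats$gene_id[cats$category_id == cid]
    K <- length(members)
    k <- sum(query_genes %in% members)
    p <- stats::phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(category_id = cid, category_size = K, query_size = n_q,
               overlap = k, p_raw = p,
               p_bonferroni = min(1, p * max(n_tested, 1)),
               stringsAsFactors = FALSE)
  }))
  out$pass <- out$p_bonferroni < alpha & out$category_size > 3 & out$overlap > 2
  out <- out[order(out$p_raw), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Concordance between trans-eQTL effects and transgenic allelic differences
#'
#' For the genes whose eQTL map to a modifier locus, compares the signed
#' eQTL allelic effect (positive = higher on the P1/N2 allele) with the
#' expression difference measured between transgenic lines carrying the two
#' alleles of the candidate modifier: Pearson correlation, R-squared, and the
#' count of genes whose signs agree. A zero transgenic difference is counted
#' as discordant.
#'
#' @param records_at_locus eQTL records (with `gene_id` and `effect`) whose
#'   peaks colocalize with the locus; one effect per gene (the strongest spot
#'   is used when a gene has several).
#' @param transgenic_diff Data frame `gene_id`, `diff` (allelic expression
#'   difference, same sign convention).
#' @return An object of class `miril_concordance`: list with `pairs`
#'   (gene_id, eqtl_effect, transgenic_diff, concordant), `r`, `r2`,
#'   `n_concordant`, `n_total`, `concordance`.
#' @export
allelic_concordance <- function(records_at_locus, transgenic_diff) {
  r <- records_at_locus[order(-abs(records_at_locus$effect)), , drop = FALSE]
  r <- r[!duplicated(r$gene_id), , drop = FALSE]
  shared <- intersect(r$gene_id, transgenic_diff$gene_id)
  if (length(shared) < 3) {
    stop_("only %d genes shared between locus records and transgenic table; need >= 3",
          length(shared))
  }
  e <- r$effect[match(shared, r$gene_id)]
  d <- transgenic_diff$diff[match(shared, transgenic_diff$gene_id)]
  conc <- sign(e) == sign(d) & d != 0
  pr <- stats::cor(e, d)
  structure(list(
    pairs = data.frame(gene_id = shared, eqtl_effect = e,
                       transgenic_diff = d, concordant = conc,
                       stringsAsFactors = FALSE),
    r = pr, r2 = pr^2,
    n_concordant = sum(conc), n_total = length(shared),
    concordance = mean(conc)),
    class = "miril_concordance")
}

#' @export
print.miril_concordance <- function(x, ...) {
  cat(sprintf("miril_concordance: %d/%d genes concordant (%.0f%%), R2 = %.2f\n",
              x$n_concordant, x$n_total, 100 * x$concordance, x$r2))
  invisible(x)
}
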