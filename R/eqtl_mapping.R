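#' Single-marker eQTL genome scan
#'
#' Fits, for every feature x marker pair, the linear model
#' `expression ~ genotype` by ordinary least squares on the binary genotype
#' (P1 = 1, P2 = 0) and reports -log10 of the two-sided p-value of the
#' genotype coefficient together with the signed allelic effect
#' (mean in the P1 group minus mean in the P2 group, log2 units). With a
#' binary predictor this is exactly the equal-variance two-sample t-test.
#' Strains with a missing genotype at a marker are excluded for that marker;
#' markers left with fewer than two strains in either genotype class are
#' skipped (-log10(p) = 0, flagged).
#'
#' @param expression A `miril_expr` (any matrix-bearing object with `values`
#'   features x strains and a `features` table).
#' @param genotypes A `miril_geno` (strains x markers).
#' @param min_shared_strains Required size of the strain intersection.
#' @return An object of class `miril_scan`: list with `neglogp` and `effect`
#'   (features x markers), `tstat`, `df`, `map`, `features`, and `skipped`
#'   (logical per marker: monomorphic or underpowered class sizes).
#' @export
eqtl_scan <- function(expression, genotypes, min_shared_strains = 8) {
  strains <- intersect(colnames(expression$values), rownames(genotypes$calls))
  if (length(strains) == 0) stop_("expression and genotype strain sets do not overlap")
  if (length(strains) < min_shared_strains) {
    stop_("only %d shared strains; need >= %d", length(strains),
          min_shared_strains)
  }
  E <- expression$values[, strains, drop = FALSE]
  G <- genotypes$calls[strains, , drop = FALSE]

  G1 <- (G == 1L) & !is.na(G)
  G0 <- (G == 0L) & !is.na(G)
  storage.mode(G1) <- storage.mode(G0) <- "double"
  n1 <- colSums(G1)
  n0 <- colSums(G0)
  ok <- n1 >= 2 & n0 >= 2
  if (!any(ok)) stop_("every marker has fewer than 2 strains per genotype class")

  S1 <- E %*% G1
  S0 <- E %*% G0
  E2 <- E^2
  Q1 <- E2 %*% G1
  Q0 <- E2 %*% G0
  m1 <- sweep(S1, 2, pmax(n1, 1), "/")
  m0 <- sweep(S0, 2, pmax(n0, 1), "/")
  ssw <- (Q1 - sweep(m1^2, 2, n1, "*")) + (Q0 - sweep(m0^2, 2, n0, "*"))
  ssw[ssw < 0] <- 0  # numerical guard
  df <- n1 + n0 - 2
  s2 <- sweep(ssw, 2, pmax(df, 1), "/")
  se <- sqrt(sweep(s2, 2, 1 / n1 + 1 / n0, "*"))
  tstat <- (m1 - m0) / se
  tstat[!is.finite(tstat) & (m1 - m0) == 0] <- 0

  neglogp <- matrix(0, nrow(E), ncol(G), dimnames = dimnames(tstat))
  for (dfv in unique(df[ok])) {
    cols <- which(ok & df == dfv)
    lp <- stats::pt(abs(tstat[, cols, drop = FALSE]), df = dfv,
                    lower.tail = FALSE, log.p = TRUE) + log(2)
    neglogp[, cols] <- -lp / log(10)
  }
  # perfect separation (zero residual variance) gives t = Inf; cap at the
  # smallest representable two-sided p
  neglogp[!is.finite(neglogp)] <- 320
  neglogp[, !ok] <- 0
  effect <- m1 - m0
  effect[, !ok] <- 0
  tstat[, !ok] <- 0

  structure(list(neglogp = neglogp, effect = effect, tstat = tstat, df = df,
                 map = genotypes$map, features = expression$features,
                 skipped = !ok),
            class = "miril_scan")
}

#' @export
print.miril_scan <- function(x, ...) {
  cat(sprintf("miril_scan: %d features x %d markers (max -log10(p) = %.2f)\n",
              nrow(x$neglogp), ncol(x$neglogp), max(x$neglogp)))
  invisible(x)
}

#' Call eQTL peaks with drop-based confidence intervals
#'
#' For each feature and each chromosome carrying at least one marker at or
#' above `threshold`, reports the chromosome's maximal marker (leftmost on
#' ties) as the peak, with a confidence interval equal to the maximal
#' contiguous run of markers around the peak whose -log10(p) stays strictly
#' above `peak - ci_drop`.
#'
#' @param scanm A `miril_scan`.
#' @param threshold Genome-wide -log10(p) significance threshold (> 0).
#' @param ci_drop Drop in -log10(p) defining the confidence interval.
#' @return Data frame of eQTL records: `spot_id`, `gene_id`, `gene_chrom`,
#'   `gene_pos`, `peak_marker`, `peak_chrom`, `peak_pos`, `neglogp`, `effect`,
#'   `ci_start`, `ci_end` (bp of first and last CI marker). One row per
#'   feature per qualifying chromosome.
#' @export
call_peaks <- function(scanm, threshold, ci_drop = 1.5) {
  if (threshold <= 0) stop_("threshold must be > 0")
  map <- scanm$map
  feats <- scanm$features
  recs <- list()
  for (cn in unique(map$chrom)) {
    idx <- which(map$chrom == cn)
    M <- scanm$neglogp[, idx, drop = FALSE]
    rmax <- do.call(pmax, as.data.frame(M))
    hits <- which(rmax >= threshold)
    for (f in hits) {
      v <- M[f, ]
      p <- which.max(v)  # leftmost maximum
      lo <- p
      while (lo > 1L && v[lo - 1L] > v[p] - ci_drop) lo <- lo - 1L
      hi <- p
      while (hi < length(v) && v[hi + 1L] > v[p] - ci_drop) hi <- hi + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        spot_id = feats$spot_id[f], gene_id = feats$gene_id[f],
        gene_chrom = feats$chrom[f], gene_pos = feats$pos[f],
        peak_marker = map$marker[idx[p]], peak_chrom = cn,
        peak_pos = map$pos[idx[p]], neglogp = v[p],
        effect = scanm$effect[f, idx[p]],
        ci_start = map$pos[idx[lo]], ci_end = map$pos[idx[hi]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) {
    return(data.frame(spot_id = character(), gene_id = character(),
                      gene_chrom = character(), gene_pos = integer(),
                      peak_marker = character(), peak_chrom = character(),
                      peak_pos = integer(), neglogp = numeric(),
                      effect = numeric(), ci_start = integer(),
                      ci_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  row.names(out) <- NULL
  out
}

#' Classify eQTL records as cis or trans
#'
#' An eQTL is cis when its gene lies on the peak chromosome and either within
#' `cis_window` of the peak position or inside the peak's confidence interval;
#' otherwise it is trans. Records whose gene has no position are dropped with
#' a warning.
#'
#' @param records Output of [call_peaks()].
#' @param cis_window Cis distance in bp (default 2 Mb).
#' @return The records with a `class` column added.
#' @export
classify_cis_trans <- function(records, cis_window = 2e6) {
  unplaced <- is.na(records$gene_pos) | is.na(records$gene_chrom)
  if (any(unplaced)) {
    warning(sprintf("%d records with unplaced genes excluded", sum(unplaced)))
    records <- records[!unplaced, , drop = FALSE]
  }
  same <- records$gene_chrom == records$peak_chrom
  near <- abs(records$gene_pos - records$peak_pos) <= cis_window
  in_ci <- records$gene_pos >= records$ci_start &
    records$gene_pos <= records$ci_end
  records$class <- ifelse(same & (near | in_ci), "cis", "trans")
  records
}

#' Cross-tabulate eQTL counts by class and allelic-effect sign
#'
#' Counts genes and spots per class (cis/trans) and effect direction
#' (positive = higher on the P1/N2 allele). Genes represented by multiple
#' spots are deduplicated per class (and per sign within class), so a gene
#' can contribute to both the cis and trans rows, and the per-class total can
#' be below the sum of the sign rows.
#'
#' @param records Classified eQTL records.
#' @return Data frame with columns `class`, `direction`, `genes`, `spots`.
#' @export
summarize_counts <- function(records) {
  classes <- c("cis", "trans")
  out <- do.call(rbind, lapply(classes, function(cl) {
    r <- records[records$class == cl, , drop = FALSE]
    pos <- r$effect > 0
    data.frame(
      class = cl,
      direction = c("P1_higher", "P2_higher", "total"),
      genes = c(length(unique(r$gene_id[pos])),
                length(unique(r$gene_id[!pos])),
                length(unique(r$gene_id))),
      spots = c(length(unique(r$spot_id[pos])),
                length(unique(r$spot_id[!pos])),
                length(unique(r$spot_id))),
      stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
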