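#' Exact Poisson tail probability
#'
#' Upper tail returns `P(X >= k)`, lower tail `P(X <= k)`, for X ~
#' Poisson(`lam`). Computed through the regularized incomplete gamma routine
#' underlying [stats::ppois()], which is stable in log space for small tails.
#'
#' @param k Non-negative integer count (vectorized).
#' @param lam Poisson expectation (> 0).
#' @param side "upper" or "lower".
#' @return Probability in [0, 1].
#' @export
poisson_tail <- function(k, lam, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (any(lam <= 0)) stop_("lam must be > 0")
  if (any(k < 0) || any(k != floor(k))) stop_("k must be a non-negative integer")
  if (side == "upper") {
    stats::ppois(k - 1, lam, lower.tail = FALSE)
  } else {
    stats::ppois(k, lam)
  }
}

#' Detect trans-bands (eQTL hotspots) by Poisson bin counts
#'
#' Bins trans-eQTL spot peaks into consecutive `bin_size` windows per
#' chromosome (half-open: position p falls in bin `floor((p-1)/bin_size)`),
#' estimates the expected count per occupied bin as
#' `lambda = total spots / occupied bins`, flags bins whose upper-tail
#' Poisson probability `P(X >= count)` is below `sig_level`, and merges
#' adjacent significant bins into bands.
#'
#' @param trans_records Classified eQTL records with `class == "trans"` (rows
#'   of other classes are ignored); must carry `peak_chrom`, `peak_pos`,
#'   `spot_id`, `gene_id`.
#' @param bin_size Bin width in bp.
#' @param sig_level Per-bin significance level.
#' @param merge Merge adjacent significant bins into bands.
#' @return Data frame of bands: `chrom`, `start_mb`, `end_mb`, `n_bins`,
#'   `n_spots`, `n_genes`, `p_value` (minimum member-bin p), with attributes
#'   `lambda`, `n_occupied_bins`, `n_trans_spots`, and `bins` (the full
#'   per-bin table).
#' @export
detect_trans_bands <- function(trans_records, bin_size = 1e6,
                               sig_level = 0.001, merge = TRUE) {
  tr <- trans_records[is.null(trans_records$class) |
                        trans_records$class == "trans", , drop = FALSE]
  empty <- data.frame(chrom = character(), start_mb = numeric(),
                      end_mb = numeric(), n_bins = integer(),
                      n_spots = integer(), n_genes = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(tr) == 0) {
    attr(empty, "lambda") <- NA_real_
    return(empty)
  }
  bin <- floor((tr$peak_pos - 1) / bin_size)
  key <- paste(tr$peak_chrom, bin, sep = ":")
  counts <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(counts) <- c("key", "n_spots")
  parts <- strsplit(counts$key, ":", fixed = TRUE)
  counts$chrom <- vapply(parts, `[`, "", 1L)
  counts$bin <- as.integer(vapply(parts, `[`, "", 2L))
  counts <- counts[order(counts$chrom, counts$bin), , drop = FALSE]

  lambda <- nrow(tr) / nrow(counts)
  counts$p_value <- poisson_tail(counts$n_spots, lambda, "upper")
  counts$significant <- counts$p_value < sig_level

  sig <- counts[counts$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    attr(empty, "lambda") <- lambda
    attr(empty, "n_occupied_bins") <- nrow(counts)
    attr(empty, "n_trans_spots") <- nrow(tr)
    attr(empty, "bins") <- counts
    return(empty)
  }
  if (merge && nrow(sig) > 1) {
    new_band <- c(TRUE, !(sig$chrom[-1] == sig$chrom[-nrow(sig)] &
                            sig$bin[-1] == sig$bin[-nrow(sig)] + 1L))
    band_id <- cumsum(new_band)
  } else {
    band_id <- seq_len(nrow(sig))
  }
  bands <- do.call(rbind, lapply(split(seq_len(nrow(sig)), band_id), function(i) {
    member_keys <- sig$key[i]
    in_band <- key %in% member_keys
    data.frame(chrom = sig$chrom[i[1]],
               start_mb = sig$bin[i[1]] * bin_size / 1e6,
               end_mb = (sig$bin[i[length(i)]] + 1L) * bin_size / 1e6,
               n_bins = length(i),
               n_spots = sum(sig$n_spots[i]),
               n_genes = length(unique(tr$gene_id[in_band])),
               p_value = min(sig$p_value[i]),
               stringsAsFactors = FALSE)
  }))
  row.names(bands) <- NULL
  attr(bands, "lambda") <- lambda
  attr(bands, "n_occupied_bins") <- nrow(counts)
  attr(bands, "n_trans_spots") <- nrow(tr)
  attr(bands, "bins") <- counts
  bands
}

#' Smallest bin count declared significant at a given level
#'
#' Returns the smallest integer c such that a bin with MORE than c spots is
#' significant, i.e. `P(X >= c + 1) < sig_level` under Poisson(`lam`) — the
#' "more than c spots" phrasing used for hotspot admission.
#'
#' @param lam Poisson expectation per occupied bin.
#' @param sig_level Significance level.
#' @return Integer cutoff c ("> c spots" is significant).
#' @export
hotspot_count_cutoff <- function(lam, sig_level) {
  k <- 0L
  while (poisson_tail(k + 1L, lam, "upper") >= sig_level) k <- k + 1L
  k
}

#' Replication of eQTL against reference studies
#'
#' A gene with a cis-eQTL replicates when any reference set reports a
#' cis-eQTL for the same gene; a gene with a trans-eQTL replicates when any
#' reference set reports a trans-eQTL for the same gene on the same
#' chromosome.
#'
#' @param records Classified eQTL records of this study.
#' @param reference_sets List of data frames with columns `gene_id`, `class`,
#'   `chrom` (the eQTL chromosome).
#' @return An object of class `miril_replication`: list with `genes` (per
#'   gene/class: replicated flag), `cis_rate`, `trans_rate`.
#' @export
replication_overlap <- function(records, reference_sets) {
  if (!is.list(reference_sets) || is.data.frame(reference_sets)) {
    reference_sets <- list(reference_sets)
  }
  need <- c("gene_id", "class", "chrom")
  for (i in seq_along(reference_sets)) {
    missing_cols <- setdiff(need, names(reference_sets[[i]]))
    if (length(missing_cols) > 0) {
      stop_("reference set %d lacks column(s): %s", i,
            paste(missing_cols, collapse = ", "))
    }
  }
  ref <- do.call(rbind, lapply(reference_sets,
                               function(r) r[need]))

  cis_q <- unique(records$gene_id[records$class == "cis"])
  cis_ref <- unique(ref$gene_id[ref$class == "cis"])
  cis_rep <- cis_q %in% cis_ref

  tr <- records[records$class == "trans", , drop = FALSE]
  tr_key_q <- unique(paste(tr$gene_id, tr$peak_chrom, sep = "|"))
  tr_ref_key <- unique(paste(ref$gene_id[ref$class == "trans"],
                             ref$chrom[ref$class == "trans"], sep = "|"))
  tr_genes <- unique(tr$gene_id)
  tr_rep <- vapply(tr_genes, function(g) {
    any(tr_key_q[startsWith(tr_key_q, paste0(g, "|"))] %in% tr_ref_key)
  }, TRUE)

  genes <- rbind(
    data.frame(gene_id = cis_q, class = "cis", replicated = cis_rep,
               stringsAsFactors = FALSE),
    data.frame(gene_id = tr_genes, class = "trans", replicated = tr_rep,
               stringsAsFactors = FALSE))
  row.names(genes) <- NULL
  structure(list(genes = genes,
                 cis_rate = if (length(cis_q)) mean(cis_rep) else NA_real_,
                 trans_rate = if (length(tr_genes)) mean(tr_rep) else NA_real_),
            class = "miril_replication")
}

#' @export
print.miril_replication <- function(x, ...) {
  cat(sprintf("miril_replication: cis %.1f%%, trans %.1f%% of genes replicated\n",
              100 * x$cis_rate, 100 * x$trans_rate))
  invisible(x)
}

#' Trans-band uniqueness (replication-depletion) test
#'
#' Tests whether a trans-band's genes replicate in previous studies less
#' often than expected: the lower-tail Poisson probability
#' `P(X <= n_replicated)` with `lambda = expected_rate * n_genes`. A small p
#' indicates the band is specific to this population.
#'
#' @param n_genes Genes with a trans-eQTL in the band.
#' @param n_replicated How many of them replicate in reference studies.
#' @param expected_rate Genome-wide expected replication fraction.
#' @return Lower-tail probability.
#' @export
transband_uniqueness_test <- function(n_genes, n_replicated, expected_rate) {
  if (n_replicated < 0 || n_replicated > n_genes) {
    stop_("n_replicated must be in [0, n_genes]")
  }
  if (expected_rate <= 0 || expected_rate >= 1) {
    stop_("expected_rate must be in (0, 1)")
  }
  poisson_tail(n_replicated, expected_rate * n_genes, "lower")
}

#' Per-band replication and uniqueness summary
#'
#' Combines detected trans-bands, trans-eQTL records and a replication report
#' into a band-level table: genes (spots), replicated fraction, and the
#' uniqueness p-value.
#'
#' @param bands Output of [detect_trans_bands()].
#' @param trans_records Trans eQTL records used for band detection.
#' @param replication A `miril_replication` over the same records.
#' @param expected_rate Expected replication fraction; defaults to the
#'   genome-wide trans replication rate in `replication`.
#' @return Data frame: band interval, `n_genes`, `n_spots`, `n_replicated`,
#'   `replicated_fraction`, `uniqueness_p`.
#' @export
transband_replication <- function(bands, trans_records, replication,
                                  expected_rate = replication$trans_rate) {
  tr <- trans_records[trans_records$class == "trans", , drop = FALSE]
  rep_genes <- replication$genes
  rep_trans <- rep_genes$gene_id[rep_genes$class == "trans" &
                                   rep_genes$replicated]
  out <- bands
  out$n_replicated <- NA_integer_
  out$replicated_fraction <- NA_real_
  out$uniqueness_p <- NA_real_
  for (b in seq_len(nrow(bands))) {
    in_band <- tr$peak_chrom == bands$chrom[b] &
      tr$peak_pos > bands$start_mb[b] * 1e6 &
      tr$peak_pos <= bands$end_mb[b] * 1e6
    genes <- unique(tr$gene_id[in_band])
    n_rep <- sum(genes %in% rep_trans)
    out$n_replicated[b] <- n_rep
    out$replicated_fraction[b] <- if (length(genes)) n_rep / length(genes) else NA
    out$uniqueness_p[b] <- if (length(genes)) {
      transband_uniqueness_test(length(genes), n_rep, expected_rate)
    } else NA_real_
  }
  out
}
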