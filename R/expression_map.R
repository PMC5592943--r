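#' Center expression on the parental mean
#'
#' Transforms each strain's log2 intensity to the deviation from the mean of
#' the two parental lines: `R = Y - 0.5 * (Y_P1 + Y_P2)`, where the parental
#' values are averaged over their replicate arrays. A strain equal to one of
#' the parents at a feature gets R of +/- half the parental difference, with
#' sign indicating which parent it resembles; this is what makes windowed
#' correlation against reference cis-eQTL effects a genotype call.
#'
#' @param expression A `miril_expr` with parental replicate profiles.
#' @return A `miril_expr` whose `values` and `parents` are centered; flagged
#'   with `attr(, "centered") = TRUE`.
#' @export
center_on_parents <- function(expression) {
  if (is.null(expression$parents)) {
    stop_("parental profile columns are required for centering")
  }
  pm <- 0.5 * (rowMeans(expression$parents$P1) + rowMeans(expression$parents$P2))
  out <- expression
  out$values <- expression$values - pm
  out$parents$P1 <- expression$parents$P1 - pm
  out$parents$P2 <- expression$parents$P2 - pm
  attr(out, "centered") <- TRUE
  out
}

# Correlate one window's reference effects against a value matrix
# (window-features x columns); returns per-column r, NA where undefined.
window_cor <- function(ref_effects, vals) {
  if (stats::sd(ref_effects) == 0) return(rep(NA_real_, ncol(vals)))
  r <- suppressWarnings(stats::cor(ref_effects, vals))
  as.numeric(r)
}

#' Call expression markers by windowed correlation with a cis-eQTL panel
#'
#' Matches panel genes to expression features by gene id, partitions them into
#' consecutive position-ordered blocks of `window` genes per chromosome, and
#' correlates each strain's parental-centered intensities in a block with the
#' block's reference N2 cis-eQTL effects. A positive correlation means the
#' strain's expression follows the N2 (P1) allelic pattern; negative means
#' CB4856 (P2). Calls with |r| <= `call_threshold` are left missing. Parental
#' replicate profiles are called the same way for downstream QC.
#'
#' @param centered A centered `miril_expr` (see [center_on_parents()]).
#' @param panel Reference cis-eQTL panel: data frame `gene_id`, `chrom`,
#'   `pos`, `effect` (positive = higher in P1/N2).
#' @param window Genes per marker window (>= 2). Markers per chromosome =
#'   floor(matched genes on that chromosome / window).
#' @param call_threshold Absolute correlation above which a call is made.
#' @return An object of class `miril_calls`: list with `calls` and `r`
#'   (strains x windows), `windows` (window_id, chrom, pos = median bp of the
#'   window's genes), `parent_calls` and `parent_r` (parental replicates x
#'   windows), and the thresholds used.
#' @export
call_expression_markers <- function(centered, panel, window = 20,
                                    call_threshold = 0.6) {
  if (window < 2) stop_("window must be >= 2, got %d", window)
  if (is.null(attr(centered, "centered"))) {
    warning("expression does not look parental-centered; calling anyway")
  }
  feats <- centered$features
  hit <- match(panel$gene_id, feats$gene_id)   # first spot per gene
  matched <- which(!is.na(hit))
  if (length(matched) < window) {
    stop_("only %d panel genes matched to expression features; need >= %d",
          length(matched), window)
  }
  pan <- panel[matched, , drop = FALSE]
  pan$feature_row <- hit[matched]
  pan <- pan[order(chrom_factor(pan$chrom, data.frame(chrom = unique(pan$chrom))),
                   pan$pos), , drop = FALSE]

  blocks <- list()
  for (cn in unique(pan$chrom)) {
    rows <- which(pan$chrom == cn)
    n_b <- floor(length(rows) / window)
    for (b in seq_len(n_b)) {
      blocks[[length(blocks) + 1L]] <- rows[((b - 1L) * window + 1L):(b * window)]
    }
  }
  if (length(blocks) == 0) stop_("no complete window on any chromosome")

  n_w <- length(blocks)
  strains <- colnames(centered$values)
  par_mat <- cbind(centered$parents$P1, centered$parents$P2)
  r_mat <- matrix(NA_real_, length(strains), n_w,
                  dimnames = list(strains, NULL))
  pr_mat <- matrix(NA_real_, ncol(par_mat), n_w,
                   dimnames = list(colnames(par_mat), NULL))
  windows <- data.frame(window_id = sprintf("win_%03d", seq_len(n_w)),
                        chrom = NA_character_, pos = NA_integer_,
                        stringsAsFactors = FALSE)
  zero_var <- FALSE
  for (w in seq_len(n_w)) {
    rows <- blocks[[w]]
    e <- pan$effect[rows]
    v <- centered$values[pan$feature_row[rows], , drop = FALSE]
    r <- window_cor(e, v)
    if (all(is.na(r))) zero_var <- TRUE
    r_mat[, w] <- r
    pr_mat[, w] <- window_cor(e, par_mat[pan$feature_row[rows], , drop = FALSE])
    windows$chrom[w] <- pan$chrom[rows[1]]
    windows$pos[w] <- as.integer(stats::median(pan$pos[rows]))
  }
  if (zero_var) warning("zero-variance window produced missing calls")

  to_call <- function(r) {
    out <- matrix(NA_integer_, nrow(r), ncol(r), dimnames = dimnames(r))
    out[!is.na(r) & r > call_threshold] <- 1L
    out[!is.na(r) & r < -call_threshold] <- 0L
    out
  }
  structure(list(calls = to_call(r_mat), r = r_mat, windows = windows,
                 parent_calls = to_call(pr_mat), parent_r = pr_mat,
                 window = window, call_threshold = call_threshold),
            class = "miril_calls")
}

#' Quality-filter expression-marker windows
#'
#' Keeps only windows where (a) every parental replicate is called as its own
#' genotype (all P1 replicates called P1, all P2 replicates called P2) and
#' (b) more than `min_fraction_called` of the strains show an absolute
#' correlation above `qc_threshold`.
#'
#' @param calls A `miril_calls`.
#' @param parental_calls Parental replicate call matrix; defaults to the one
#'   embedded in `calls`. Row names must start with `P1`/`P2`.
#' @param min_fraction_called Required fraction of strains with |r| >
#'   `qc_threshold` (strictly greater than this fraction).
#' @param qc_threshold Absolute correlation used in (b).
#' @return A `miril_calls` restricted to passing windows.
#' @export
qc_filter_markers <- function(calls, parental_calls = calls$parent_calls,
                              min_fraction_called = 0.5, qc_threshold = 0.5) {
  expected <- ifelse(startsWith(rownames(parental_calls), "P1"), 1L, 0L)
  parent_ok <- vapply(seq_len(ncol(parental_calls)), function(w) {
    cw <- parental_calls[, w]
    !anyNA(cw) && all(cw == expected)
  }, TRUE)
  frac <- colMeans(abs(calls$r) > qc_threshold, na.rm = TRUE)
  frac[is.nan(frac)] <- 0
  keep <- which(parent_ok & frac > min_fraction_called)
  if (length(keep) == 0) {
    message("qc_filter_markers: no window passed QC")
  }
  out <- calls
  out$calls <- calls$calls[, keep, drop = FALSE]
  out$r <- calls$r[, keep, drop = FALSE]
  out$parent_calls <- calls$parent_calls[, keep, drop = FALSE]
  out$parent_r <- calls$parent_r[, keep, drop = FALSE]
  out$windows <- calls$windows[keep, , drop = FALSE]
  row.names(out$windows) <- NULL
  out
}

#' Impute interior missing calls and extend chromosome ends
#'
#' Converts quality-filtered window calls into a genotype matrix. A missing
#' call flanked by two identical calls takes that call (provenance "imputed");
#' a missing call between discordant calls stays missing and is flagged as a
#' crossover interval; missing calls distal to the outermost assigned marker
#' copy the distal-most assigned call (provenance "end-extended").
#'
#' @param calls A `miril_calls`, typically after [qc_filter_markers()].
#' @return A `miril_geno` on the window map, with a `provenance` attribute
#'   (strains x windows character matrix: "correlated", "imputed",
#'   "end-extended", or "crossover" for still-missing positions).
#' @export
impute_and_extend <- function(calls) {
  g <- calls$calls
  prov <- matrix(ifelse(is.na(g), NA_character_, "correlated"),
                 nrow(g), ncol(g), dimnames = dimnames(g))
  win <- calls$windows
  ord <- order(chrom_factor(win$chrom, data.frame(chrom = unique(win$chrom))),
               win$pos)
  g <- g[, ord, drop = FALSE]
  prov <- prov[, ord, drop = FALSE]
  win <- win[ord, , drop = FALSE]

  for (s in seq_len(nrow(g))) {
    for (cn in unique(win$chrom)) {
      idx <- which(win$chrom == cn)
      v <- g[s, idx]
      if (all(is.na(v))) {
        stop_("strain %s has no called marker on chromosome %s",
              rownames(g)[s], cn)
      }
      known <- which(!is.na(v))
      # interior gaps
      if (length(known) >= 2) {
        for (k in seq_len(length(known) - 1L)) {
          a <- known[k]; b <- known[k + 1L]
          if (b > a + 1L) {
            gap <- (a + 1L):(b - 1L)
            if (v[a] == v[b]) {
              v[gap] <- v[a]
              prov[s, idx[gap]] <- "imputed"
            } else {
              prov[s, idx[gap]] <- "crossover"
            }
          }
        }
      }
      # chromosome ends
      first <- known[1]; last <- known[length(known)]
      if (first > 1L) {
        v[1:(first - 1L)] <- v[first]
        prov[s, idx[1:(first - 1L)]] <- "end-extended"
      }
      if (last < length(v)) {
        v[(last + 1L):length(v)] <- v[last]
        prov[s, idx[(last + 1L):length(v)]] <- "end-extended"
      }
      g[s, idx] <- v
    }
  }
  map <- data.frame(marker = win$window_id, chrom = win$chrom, pos = win$pos,
                    stringsAsFactors = FALSE)
  colnames(g) <- colnames(prov) <- map$marker
  structure(list(calls = g, map = map, selected_locus = NULL),
            class = "miril_geno", provenance = prov)
}

#' Prune a genotype map to informative markers
#'
#' Drops markers whose minor-genotype frequency (among called strains) is at
#' or below `min_minor_freq` — this removes regions fixed by selection, such
#' as the surroundings of an introgressed locus — then collapses runs of
#' adjacent markers with identical genotype columns to their first member, so
#' each retained marker indicates the border of a crossover event. A
#' marker-by-marker correlation matrix over the retained markers is attached
#' for map QC.
#'
#' @param genotypes A `miril_geno`.
#' @param min_minor_freq Markers with minor-genotype frequency <= this are
#'   dropped (i.e. only markers strictly above it are kept).
#' @return A pruned `miril_geno` with attribute `cor_matrix`.
#' @export
prune_informative_markers <- function(genotypes, min_minor_freq = 0.15) {
  g <- genotypes$calls
  if (nrow(g) < 2) stop_("need >= 2 strains")
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  called <- n1 + n0
  minor <- pmin(n1, n0) / pmax(called, 1L)
  keep <- which(called > 0 & minor > min_minor_freq)
  if (length(keep) == 0) stop_("all markers pruned: no informative marker left")

  map <- genotypes$map[keep, , drop = FALSE]
  g <- g[, keep, drop = FALSE]
  # collapse adjacent identical genotype columns (within chromosome)
  col_key <- apply(g, 2, function(x) paste(ifelse(is.na(x), "M", x), collapse = ""))
  keep2 <- rep(TRUE, ncol(g))
  for (j in seq_len(ncol(g))[-1]) {
    if (map$chrom[j] == map$chrom[j - 1L] && col_key[j] == col_key[j - 1L]) {
      keep2[j] <- FALSE
    }
  }
  # representative = first of each run; runs of identical columns may be
  # interrupted, so only strictly adjacent duplicates collapse
  g <- g[, keep2, drop = FALSE]
  map <- map[keep2, , drop = FALSE]
  row.names(map) <- NULL
  cm <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  structure(list(calls = g, map = map,
                 selected_locus = genotypes$selected_locus),
            class = "miril_geno", cor_matrix = cm)
}
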