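#' Permutation-based genome-wide eQTL significance threshold
#'
#' Estimates a genome-wide -log10(p) cutoff controlling the FDR by permuting
#' each feature's strain labels independently, rescanning, and comparing real
#' discoveries (RDS: features whose genome-wide maximum reaches a candidate
#' cutoff) with the mean number of permutation discoveries (FDS). The
#' selected threshold is the smallest candidate t with
#' `m0_ratio * FDS(t) / RDS(t) <= q_eff`, where `q_eff` is `q` optionally
#' corrected by `log(m)` (m = number of features tested). The default is the
#' plain permutation-FDR estimator (`m0_ratio = 1`, no log correction).
#'
#' @param expression A `miril_expr`.
#' @param genotypes A `miril_geno`.
#' @param q Target FDR level (0 < q < 1).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @param m0_ratio Assumed fraction of true null features, m0/m.
#' @param log_m_correction One of "none", "multiply", "divide": whether and
#'   how to scale q by log(m).
#' @param scan_obs Optional precomputed `eqtl_scan(expression, genotypes)`.
#' @return An object of class `miril_threshold`: list with `grid`, `RDS`,
#'   `FDS`, `m`, `q`, `q_eff`, `m0_ratio`, `n_perm`, `threshold`.
#' @export
permutation_threshold <- function(expression, genotypes, q = 0.1, n_perm = 10,
                                  seed = 1, m0_ratio = 1,
                                  log_m_correction = c("none", "multiply",
                                                       "divide"),
                                  scan_obs = NULL) {
  if (q <= 0 || q >= 1) stop_("q must be in (0,1), got %g", q)
  if (n_perm < 1) stop_("n_perm must be >= 1")
  log_m_correction <- match.arg(log_m_correction)

  if (is.null(scan_obs)) scan_obs <- eqtl_scan(expression, genotypes)
  obs_max <- row_max(scan_obs$neglogp)
  m <- length(obs_max)
  q_eff <- q * switch(log_m_correction, none = 1, multiply = log(m),
                      divide = 1 / log(m))

  strains <- intersect(colnames(expression$values), rownames(genotypes$calls))
  E <- expression$values[, strains, drop = FALSE]
  perm_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      Ep <- E
      for (f in seq_len(nrow(E))) Ep[f, ] <- E[f, sample.int(ncol(E))]
      expr_p <- expression
      expr_p$values <- Ep
      row_max(eqtl_scan(expr_p, genotypes)$neglogp)
    }, numeric(m))
  })

  grid <- sort(unique(obs_max[obs_max > 0]))
  # count_ge(v, t) = #\{v >= t\} = n - #\{v < t\}, vectorized over the grid
  count_ge <- function(sorted_vals, ts) {
    length(sorted_vals) - findInterval(ts, sorted_vals, left.open = TRUE)
  }
  RDS <- count_ge(sort(obs_max), grid)
  FDS <- rowMeans(vapply(seq_len(n_perm),
                         function(p) count_ge(sort(perm_max[, p]), grid),
                         numeric(length(grid))))

  ratio <- m0_ratio * FDS / RDS
  sel <- which(RDS > 0 & ratio <= q_eff)
  if (length(sel) == 0) {
    stop_("no candidate threshold satisfies the FDR criterion (q_eff = %g)",
          q_eff)
  }
  structure(list(grid = grid, RDS = RDS, FDS = FDS, m = m, q = q,
                 q_eff = q_eff, m0_ratio = m0_ratio, n_perm = n_perm,
                 log_m_correction = log_m_correction,
                 threshold = grid[min(sel)]),
            class = "miril_threshold")
}

#' @export
print.miril_threshold <- function(x, ...) {
  i <- match(x$threshold, x$grid)
  cat(sprintf(paste0("miril_threshold: -log10(p) > %.3f at q = %g ",
                     "(RDS = %d, FDS = %.1f, %d permutations)\n"),
              x$threshold, x$q, x$RDS[i], x$FDS[i], x$n_perm))
  invisible(x)
}

#' Effect size (in noise-SD units) for a target explained variance
#'
#' Inverts `R2 = 0.25 a^2 / (0.25 a^2 + 1)`, the explained variance of an
#' allelic effect `a` at a balanced biallelic marker under 0/1 genotype coding
#' with unit residual noise: `a = 2 sqrt(r2 / (1 - r2))`. On this scale a
#' peak size of 1 explains 20% of the variance.
#'
#' @param r2 Target explained variance, in [0, 1).
#' @return Effect size in units of the residual SD.
#' @export
effect_size_for_r2 <- function(r2) {
  if (any(r2 < 0) || any(r2 >= 1)) stop_("r2 must be in [0, 1)")
  2 * sqrt(r2 / (1 - r2))
}

#' Map-aware QTL detection power simulation
#'
#' For every marker of the supplied map and every explained-variance level,
#' simulates phenotypes as `effect_size_for_r2(r2) * genotype + N(0,1)`,
#' scans each phenotype genome-wide, and scores a simulated QTL as detected
#' when the genome-wide peak reaches `threshold`, lies on the simulated
#' marker's chromosome, and its drop-based confidence interval covers the
#' simulated marker. Pure-noise phenotypes estimate the per-scan family-wise
#' false-positive rate.
#'
#' @param genotypes A `miril_geno`, normally pruned to informative markers.
#' @param threshold Genome-wide -log10(p) threshold.
#' @param r2_grid Explained-variance levels to simulate.
#' @param reps_per_marker Simulated QTL per marker and level.
#' @param ci_drop Drop defining the peak confidence interval used by the
#'   location criterion.
#' @param n_null Number of no-QTL phenotypes for the false-positive rate.
#' @param seed Integer seed.
#' @return An object of class `miril_power`: list with `table` (per r2 level:
#'   detection rate, mean absolute error of estimated explained variance,
#'   mean |location error| in markers and bp), `fp_rate`, and the settings.
#' @export
simulate_power <- function(genotypes, threshold = 3.2,
                           r2_grid = seq(0.2, 0.8, by = 0.05),
                           reps_per_marker = 10, ci_drop = 1.5,
                           n_null = 1000, seed = 1) {
  G <- genotypes$calls
  if (is.null(G) || ncol(G) == 0) stop_("empty genotype matrix")
  map <- genotypes$map
  n <- nrow(G)
  m <- ncol(G)
  Gnum <- G
  Gnum[is.na(Gnum)] <- 0L  # uncalled strains contribute noise only

  scan_phenos <- function(P) {
    # P: phenotypes x strains; reuse the scan core via a minimal expression
    expr <- structure(list(
      values = P,
      features = data.frame(spot_id = rownames(P), gene_id = rownames(P),
                            chrom = NA_character_, pos = NA_integer_,
                            stringsAsFactors = FALSE)), class = "miril_expr")
    eqtl_scan(expr, genotypes)
  }

  with_seed(seed, {
    rows <- lapply(seq_along(r2_grid), function(gi) {
      r2 <- r2_grid[gi]
      a <- effect_size_for_r2(r2)
      sim_marker <- rep(seq_len(m), each = reps_per_marker)
      P <- a * t(Gnum[, sim_marker, drop = FALSE]) +
        matrix(stats::rnorm(length(sim_marker) * n), length(sim_marker), n)
      rownames(P) <- sprintf("sim_%d_%d", gi, seq_len(nrow(P)))
      colnames(P) <- rownames(G)
      sc <- scan_phenos(P)

      det <- logical(nrow(P))
      r2_err <- loc_mark <- loc_bp <- rep(NA_real_, nrow(P))
      peak_all <- max.col(sc$neglogp, ties.method = "first")
      peak_val <- sc$neglogp[cbind(seq_len(nrow(P)), peak_all)]
      for (i in which(peak_val >= threshold)) {
        p <- peak_all[i]
        tm <- sim_marker[i]
        if (map$chrom[p] != map$chrom[tm]) next
        # CI on the peak chromosome
        idx <- which(map$chrom == map$chrom[p])
        v <- sc$neglogp[i, idx]
        pp <- match(p, idx)
        lo <- pp
        while (lo > 1L && v[lo - 1L] > v[pp] - ci_drop) lo <- lo - 1L
        hi <- pp
        while (hi < length(v) && v[hi + 1L] > v[pp] - ci_drop) hi <- hi + 1L
        tmp <- match(tm, idx)
        if (tmp >= lo && tmp <= hi) {
          det[i] <- TRUE
          tt <- sc$tstat[i, p]
          r2_err[i] <- abs(tt^2 / (tt^2 + sc$df[p]) - r2)
          loc_mark[i] <- abs(p - tm)
          loc_bp[i] <- abs(map$pos[p] - map$pos[tm])
        }
      }
      data.frame(r2 = r2,
                 detection_rate = mean(det),
                 mean_abs_r2_error = mean(r2_err[det]),
                 mean_marker_error = mean(loc_mark[det]),
                 mean_bp_error = mean(loc_bp[det]),
                 n_sim = nrow(P), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)

    fp <- NA_real_
    if (n_null > 0) {
      P0 <- matrix(stats::rnorm(n_null * n), n_null, n,
                   dimnames = list(sprintf("null_%d", seq_len(n_null)),
                                   rownames(G)))
      sc0 <- scan_phenos(P0)
      fp <- mean(apply(sc0$neglogp, 1, max) >= threshold)
    }
    structure(list(table = tab, fp_rate = fp, threshold = threshold,
                   reps_per_marker = reps_per_marker, ci_drop = ci_drop,
                   seed = seed),
              class = "miril_power")
  })
}

#' @export
print.miril_power <- function(x, ...) {
  cat(sprintf("miril_power: threshold %.2f, %d reps/marker, FP rate %.3f\n",
              x$threshold, x$reps_per_marker, x$fp_rate))
  print(x$table, digits = 3)
  invisible(x)
}

#' Analytic detection power at a single balanced marker
#'
#' Closed-form cross-check for [simulate_power()]: the power of the
#' single-marker F(1, n-2) test at significance `10^-threshold` for a QTL
#' explaining `r2` of the variance in a balanced population of `n` lines,
#' from the noncentral F distribution with ncp = n * r2 / (1 - r2).
#'
#' @param n Number of lines.
#' @param r2 Explained variance.
#' @param threshold -log10(p) significance threshold.
#' @return Detection probability.
#' @export
analytic_power_balanced <- function(n, r2, threshold = 3.2) {
  ncp <- n * r2 / (1 - r2)
  fc <- stats::qf(10^(-threshold), 1, n - 2, lower.tail = FALSE)
  stats::pf(fc, 1, n - 2, ncp = ncp, lower.tail = FALSE)
}
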