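# Independent reference for peak/CI calling: direct scalar implementation of
# the rules (chromosome maximum, leftmost tie, contiguous run above
# peak - drop), used to check the packaged version on toy profiles.
ref_peaks_one_chrom <- function(v, threshold, ci_drop) {
  if (max(v) < threshold) return(NULL)
  peak <- which(v == max(v))[1]
  in_ci <- v > max(v) - ci_drop
  lo <- peak
  while (lo > 1 && in_ci[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(v) && in_ci[hi + 1]) hi <- hi + 1
  c(peak = peak, lo = lo, hi = hi)
}

scan_from_profile <- function(profiles, chrom, pos) {
  # wrap hand-made -log10(p) profiles as a miril_scan
  structure(list(
    neglogp = profiles, effect = profiles * 0 + 1,
    tstat = profiles, df = rep(31, ncol(profiles)),
    map = data.frame(marker = marker_ids_for(chrom, pos), chrom = chrom,
                     pos = as.integer(pos), stringsAsFactors = FALSE),
    features = data.frame(spot_id = rownames(profiles),
                          gene_id = rownames(profiles),
                          chrom = "I", pos = 1L, stringsAsFactors = FALSE),
    skipped = rep(FALSE, ncol(profiles))), class = "miril_scan")
}

test_that("scan -log10(p) equals the equal-variance two-sample t-test", {
  set.seed(101)
  n <- 24
  g <- toy_geno(matrix(rbinom(n * 5, 1, 0.5), n, 5), chrom = rep("I", 5),
                pos = (1:5) * 1e6)
  e <- toy_expr(matrix(rnorm(40 * n), 40, n,
                       dimnames = list(NULL, rownames(g$calls))))
  sc <- eqtl_scan(e, g)
  draws <- cbind(sample(40, 200, replace = TRUE),
                 sample(5, 200, replace = TRUE))
  for (k in seq_len(nrow(draws))) {
    f <- draws[k, 1]; m <- draws[k, 2]
    y <- e$values[f, ]; x <- g$calls[, m]
    tt <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
    expect_equal(sc$neglogp[f, m], -log10(tt$p.value), tolerance = 1e-10)
    ols <- summary(lm(y ~ x))$coefficients[2, 4]
    expect_equal(sc$neglogp[f, m], -log10(ols), tolerance = 1e-10)
  }
})

test_that("scan handles degenerate inputs per contract", {
  n <- 12
  g <- toy_geno(cbind(rep(c(0L, 1L), each = 6), rep(1L, n), c(0L, rep(1L, n - 1))),
                chrom = rep("I", 3), pos = c(1e6, 2e6, 3e6))
  # constant expression -> p = 1 everywhere
  e <- toy_expr(matrix(5, 2, n, dimnames = list(NULL, rownames(g$calls))))
  sc <- eqtl_scan(e, g)
  expect_equal(unname(sc$neglogp[1, ]), c(0, 0, 0))
  # monomorphic marker (col 2) and 1-vs-rest marker (col 3) are skipped
  expect_identical(unname(sc$skipped), c(FALSE, TRUE, TRUE))
  # perfect separation: finite capped neglogp, sign preserved
  e2 <- toy_expr(matrix(as.numeric(g$calls[, 1]), 1, n,
                        dimnames = list(NULL, rownames(g$calls))))
  sc2 <- eqtl_scan(e2, g)
  expect_true(is.finite(sc2$neglogp[1, 1]) && sc2$neglogp[1, 1] > 100)
  expect_gt(sc2$effect[1, 1], 0)
  # disjoint strains -> error
  e3 <- toy_expr(matrix(0, 1, 3, dimnames = list(NULL, c("x", "y", "z"))))
  expect_error(eqtl_scan(e3, g), "overlap")
})

test_that("scan is invariant to strain order and signs follow group means", {
  st <- default_study()
  sc <- default_scan()
  perm <- sample(ncol(st$expr$values))
  e2 <- st$expr
  e2$values <- e2$values[, perm]
  g2 <- st$geno_informative
  sc2 <- eqtl_scan(e2, g2)
  expect_equal(sc2$neglogp, sc$neglogp, tolerance = 1e-12)
  # effect-sign contract on a sample of cells
  set.seed(7)
  idx <- cbind(sample(nrow(sc$effect), 50), sample(ncol(sc$effect), 50))
  for (k in 1:50) {
    f <- idx[k, 1]; m <- idx[k, 2]
    x <- st$geno_informative$calls[, m]
    d <- mean(st$expr$values[f, x == 1]) - mean(st$expr$values[f, x == 0])
    expect_equal(sign(sc$effect[f, m]), sign(d))
  }
})

test_that("peak calling matches a brute-force reference on toy profiles", {
  # [1, 4, 1]: CI collapses to the peak marker
  p1 <- matrix(c(1, 4, 1), 1, 3, dimnames = list("f1", NULL))
  sc <- scan_from_profile(p1, rep("I", 3), c(1e6, 2e6, 3e6))
  rec <- call_peaks(sc, threshold = 3.2, ci_drop = 1.5)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$peak_pos, 2e6)
  expect_equal(c(rec$ci_start, rec$ci_end), c(2e6, 2e6))
  # flat profile at threshold: CI spans the chromosome
  p2 <- matrix(3.2, 1, 4, dimnames = list("f1", NULL))
  rec2 <- call_peaks(scan_from_profile(p2, rep("I", 4), (1:4) * 1e6), 3.2)
  expect_equal(c(rec2$ci_start, rec2$ci_end), c(1e6, 4e6))
  expect_equal(rec2$peak_pos, 1e6)  # leftmost tie
  # two chromosomes above threshold -> two records
  p3 <- matrix(c(4, 1, 1, 5), 1, 4, dimnames = list("f1", NULL))
  rec3 <- call_peaks(scan_from_profile(p3, c("I", "I", "II", "II"),
                                       c(1e6, 2e6, 1e6, 2e6)), 3.2)
  expect_equal(nrow(rec3), 2)
  expect_equal(rec3$peak_chrom, c("I", "II"))
  # randomized profiles against the reference implementation
  set.seed(33)
  for (k in 1:50) {
    v <- round(runif(8, 0, 6), 2)
    pos <- (1:8) * 1e6
    rec <- call_peaks(scan_from_profile(matrix(v, 1, 8,
                                               dimnames = list("f", NULL)),
                                        rep("I", 8), pos),
                      threshold = 3, ci_drop = 1.5)
    ref <- ref_peaks_one_chrom(v, 3, 1.5)
    if (is.null(ref)) {
      expect_equal(nrow(rec), 0)
    } else {
      expect_equal(rec$peak_pos, pos[ref["peak"]])
      expect_equal(rec$ci_start, pos[ref["lo"]])
      expect_equal(rec$ci_end, pos[ref["hi"]])
    }
  }
  expect_error(call_peaks(sc, threshold = 0), "threshold")
})

test_that("widening the CI drop never shrinks an interval", {
  sc <- default_scan()
  r1 <- call_peaks(sc, threshold = 3.2, ci_drop = 1.0)
  r2 <- call_peaks(sc, threshold = 3.2, ci_drop = 2.0)
  key <- paste(r1$spot_id, r1$peak_chrom)
  m <- match(key, paste(r2$spot_id, r2$peak_chrom))
  expect_false(anyNA(m))
  expect_true(all(r2$ci_start[m] <= r1$ci_start))
  expect_true(all(r2$ci_end[m] >= r1$ci_end))
})

test_that("cis/trans classification applies the 2-Mb window and the CI rule", {
  rec <- data.frame(
    spot_id = c("a", "b", "c"), gene_id = c("a", "b", "c"),
    gene_chrom = c("I", "II", "I"), gene_pos = c(3.9e6, 1e6, 8e6),
    peak_marker = "I_002000000", peak_chrom = "I", peak_pos = 2e6,
    neglogp = 5, effect = 1,
    ci_start = c(1e6, 1e6, 1e6), ci_end = c(2e6, 2e6, 9e6),
    stringsAsFactors = FALSE)
  out <- classify_cis_trans(rec, cis_window = 2e6)
  # a: 1.9 Mb from peak -> cis; b: other chromosome -> trans;
  # c: 6 Mb away but inside the wide CI -> cis
  expect_equal(out$class, c("cis", "trans", "cis"))
  # unplaced genes are dropped with a warning
  rec$gene_pos[2] <- NA
  expect_warning(out2 <- classify_cis_trans(rec), "unplaced")
  expect_equal(nrow(out2), 2)
})

test_that("count summaries deduplicate spots to genes", {
  rec <- data.frame(
    spot_id = c("s1", "s2", "s3"), gene_id = c("g1", "g1", "g2"),
    gene_chrom = "I", gene_pos = 1e6, peak_marker = "m", peak_chrom = "I",
    peak_pos = 1e6, neglogp = 5, effect = c(2, 2, -1),
    ci_start = 1e6, ci_end = 1e6,
    class = c("cis", "cis", "trans"), stringsAsFactors = FALSE)
  tab <- summarize_counts(rec)
  expect_equal(tab$genes[tab$class == "cis" & tab$direction == "P1_higher"], 1)
  expect_equal(tab$spots[tab$class == "cis" & tab$direction == "P1_higher"], 2)
  expect_equal(tab$genes[tab$class == "trans" & tab$direction == "P2_higher"], 1)
  # empty records give an all-zero table
  tab0 <- summarize_counts(rec[0, ])
  expect_true(all(tab0$genes == 0) && all(tab0$spots == 0))
})

test_that("planted signs are recovered at the planted markers", {
  # large-population recovery: strong effects map with the right sign
  g <- cached("geno_recovery", simulate_miril_genotypes(200, seed = 61))
  arch <- simulate_architecture(g, n_features = 400, n_panel_cis = 60,
                                n_cis_extra = 20, n_trans = 40,
                                band_spots = 40, seed = 62)
  e <- simulate_expression(g, arch, seed = 63)
  gi <- prune_informative_markers(g)
  sc <- eqtl_scan(e, gi)
  rec <- classify_cis_trans(call_peaks(sc, threshold = 3.2))
  ef <- arch$effects
  v <- vapply(ef$marker, function(m) {
    x <- g$calls[, m]
    mean(x) * (1 - mean(x))
  }, 0)
  r2 <- v * ef$effect^2 / (v * ef$effect^2 + 1)
  strong <- which(r2 >= 0.4)
  ok <- vapply(strong, function(k) {
    r <- rec[rec$spot_id == ef$spot_id[k], , drop = FALSE]
    tm_chrom <- g$map$chrom[g$map$marker == ef$marker[k]]
    r <- r[r$peak_chrom == tm_chrom, , drop = FALSE]
    nrow(r) > 0 && sign(r$effect[1]) == sign(ef$effect[k])
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})
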