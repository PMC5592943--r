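make_centered <- function(values, parents_p1, parents_p2, chrom = NULL,
                          pos = NULL, gene_id = NULL) {
  e <- toy_expr(values, chrom = chrom, pos = pos, gene_id = gene_id)
  e$parents <- list(P1 = parents_p1, P2 = parents_p2)
  center_on_parents(e)
}

test_that("parental centering subtracts the parental mean and is symmetric", {
  v <- matrix(c(5, 4, 6), 1, 3,
              dimnames = list("s001", c("a", "b", "c")))
  p1 <- matrix(4, 1, 1, dimnames = list("s001", "P1_rep1"))
  p2 <- matrix(6, 1, 1, dimnames = list("s001", "P2_rep1"))
  cen <- make_centered(v, p1, p2)
  expect_equal(unname(cen$values[1, ]), c(0, -1, 1))
  # swapping the parents leaves R unchanged
  cen_swap <- make_centered(v, p2, p1)
  expect_equal(cen$values, cen_swap$values)
  # parental columns retained and centered too
  expect_equal(unname(cen$parents$P1[1, 1]), -1)
  # missing parents rejected
  expect_error(center_on_parents(toy_expr(v)), "parental")
})

test_that("windowed calling yields floor(n/window) markers and perfect calls on exact profiles", {
  # 100 single-chromosome panel genes; strain profiles built from the
  # reference effects themselves
  n_genes <- 100
  eff <- stats::rnorm(n_genes, 0, 1.5)
  panel <- data.frame(gene_id = sprintf("g%03d", 1:n_genes), chrom = "I",
                      pos = seq(1e5, by = 1e5, length.out = n_genes),
                      effect = eff, stringsAsFactors = FALSE)
  vals <- cbind(p1_like = eff, p2_like = -eff, scaled = 2 * eff)
  rownames(vals) <- panel$gene_id
  cen <- make_centered(vals, matrix(eff, ncol = 1), matrix(-eff, ncol = 1),
                       chrom = panel$chrom, pos = panel$pos,
                       gene_id = panel$gene_id)
  calls <- call_expression_markers(cen, panel, window = 20)
  expect_equal(nrow(calls$windows), 5)   # floor(100/20)
  expect_true(all(calls$calls["p1_like", ] == 1L))
  expect_true(all(calls$calls["p2_like", ] == 0L))
  expect_true(all(calls$calls["scaled", ] == 1L))
  expect_equal(unname(calls$r["p1_like", ]), rep(1, 5), tolerance = 1e-12)
  # representative position is the median of the window genes
  expect_equal(calls$windows$pos[1], as.integer(stats::median(panel$pos[1:20])))
  # too few matched genes rejected
  expect_error(call_expression_markers(cen, panel[1:10, ], window = 20),
               "matched")
})

test_that("calling is antisymmetric under negation of the reference effects", {
  st <- default_study()
  cen <- center_on_parents(st$expr)
  calls <- call_expression_markers(cen, st$panel)
  neg_panel <- st$panel
  neg_panel$effect <- -neg_panel$effect
  flipped <- call_expression_markers(cen, neg_panel)
  expect_identical(flipped$calls, 1L - calls$calls)
  expect_equal(flipped$r, -calls$r, tolerance = 1e-12)
})

test_that("QC drops windows with misassigned parents or weak correlations", {
  calls <- structure(list(
    calls = matrix(c(1L, 0L, 1L, 0L), 2, 2,
                   dimnames = list(c("sA", "sB"), NULL)),
    r = matrix(c(0.9, -0.8, 0.9, -0.45), 2, 2,
               dimnames = list(c("sA", "sB"), NULL)),
    windows = data.frame(window_id = c("win_001", "win_002"),
                         chrom = "I", pos = c(1e6L, 2e6L),
                         stringsAsFactors = FALSE),
    parent_calls = matrix(c(1L, 0L, 0L, 0L), 2, 2,
                          dimnames = list(c("P1_rep1", "P2_rep1"), NULL)),
    parent_r = matrix(c(0.9, -0.9, -0.9, -0.9), 2, 2),
    window = 20, call_threshold = 0.6), class = "miril_calls")
  # window 2 misassigns the P1 replicate (called P2): dropped even though
  # strain correlations are fine for window 1 criteria
  kept <- qc_filter_markers(calls, qc_threshold = 0.5,
                            min_fraction_called = 0.5)
  expect_equal(kept$windows$window_id, "win_001")
  # a window with only 40% of strains above |r| > 0.5 is dropped
  calls2 <- calls
  calls2$parent_calls <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                                dimnames = list(c("P1_rep1", "P2_rep1"), NULL))
  calls2$r <- matrix(c(0.9, 0.8, 0.45, 0.45), 2, 2,
                     dimnames = list(c("sA", "sB"), NULL))
  kept2 <- qc_filter_markers(calls2, qc_threshold = 0.5,
                             min_fraction_called = 0.6)
  expect_equal(kept2$windows$window_id, "win_001")
})

test_that("imputation follows the flank decision rules exhaustively", {
  # enumerate all 3-marker single-strain patterns over {P1, P2, MISSING}
  # with at least one call; expected output derived by the stated rules:
  # interior MISSING takes equal flanks, stays missing between discordant
  # flanks, chromosome ends copy the distal-most call
  codes <- c(1L, 0L, NA_integer_)
  expected_fill <- function(v) {
    out <- v
    known <- which(!is.na(v))
    if (length(known) == 0) return(NULL)
    for (g in which(is.na(v))) {
      left <- known[known < g]
      right <- known[known > g]
      if (length(left) == 0) {
        out[g] <- v[min(right)]
      } else if (length(right) == 0) {
        out[g] <- v[max(left)]
      } else if (v[max(left)] == v[min(right)]) {
        out[g] <- v[max(left)]
      }  # discordant flanks: stays NA
    }
    out
  }
  for (a in codes) for (b in codes) for (c in codes) {
    v <- c(a, b, c)
    if (all(is.na(v))) next
    calls <- structure(list(
      calls = matrix(v, 1, 3, dimnames = list("s", NULL)),
      r = matrix(0.9, 1, 3), windows = data.frame(
        window_id = c("w1", "w2", "w3"), chrom = "I",
        pos = c(1e6L, 2e6L, 3e6L), stringsAsFactors = FALSE),
      parent_calls = NULL, parent_r = NULL), class = "miril_calls")
    out <- impute_and_extend(calls)
    expect_equal(unname(out$calls[1, ]), expected_fill(v),
                 info = paste(v, collapse = ","))
  }
  # crossover gap is flagged
  calls <- structure(list(
    calls = matrix(c(1L, NA, 0L), 1, 3, dimnames = list("s", NULL)),
    r = matrix(0.9, 1, 3), windows = data.frame(
      window_id = c("w1", "w2", "w3"), chrom = "I",
      pos = c(1e6L, 2e6L, 3e6L), stringsAsFactors = FALSE),
    parent_calls = NULL, parent_r = NULL), class = "miril_calls")
  out <- impute_and_extend(calls)
  expect_equal(attr(out, "provenance")[1, 2], "crossover")
  # a strain with an uncalled chromosome errors with strain and chromosome
  calls$calls[1, ] <- NA_integer_
  expect_error(impute_and_extend(calls), "s .*chromosome I|chromosome I")
})

test_that("imputation leaves fully-called strains untouched", {
  st <- default_study()
  cen <- center_on_parents(st$expr)
  q <- qc_filter_markers(call_expression_markers(cen, st$panel))
  full <- !apply(q$calls, 1, anyNA)
  out <- impute_and_extend(q)
  ord <- match(colnames(out$calls), q$windows$window_id)
  expect_equal(unname(out$calls[full, , drop = FALSE]),
               unname(q$calls[full, ord, drop = FALSE]))
})

test_that("pruning drops rare-genotype and duplicate-adjacent markers, and is idempotent", {
  # 33 strains: marker B has minor genotype 4/33 (dropped), markers C and D
  # identical (D dropped), E distinct
  set.seed(42)
  a <- rep(c(0L, 1L), length.out = 33)
  b <- c(rep(1L, 29), rep(0L, 4))
  cc <- sample(c(0L, 1L), 33, replace = TRUE)
  e <- sample(c(0L, 1L), 33, replace = TRUE)
  g <- toy_geno(cbind(a, b, cc, cc, e), chrom = rep("I", 5),
                pos = c(1e6, 2e6, 3e6, 4e6, 5e6))
  pruned <- prune_informative_markers(g, min_minor_freq = 0.15)
  expect_equal(pruned$map$pos, as.integer(c(1e6, 3e6, 5e6)))
  expect_true(!is.null(attr(pruned, "cor_matrix")))
  # idempotent
  again <- prune_informative_markers(pruned, min_minor_freq = 0.15)
  expect_identical(again$calls, pruned$calls)
  expect_identical(again$map, pruned$map)
  # all-pruned errors
  fixed <- toy_geno(matrix(1L, 33, 2), chrom = c("I", "I"), pos = c(1e6, 2e6))
  expect_error(prune_informative_markers(fixed), "pruned")
})

test_that("selection strips the selected chromosome from the informative map", {
  st <- default_study()
  raw_iv <- sum(st$geno$map$chrom == "IV")
  kept_iv <- sum(st$geno_informative$map$chrom == "IV")
  expect_lt(kept_iv / raw_iv, 0.5)
})

test_that("expression-marker calls match the simulation truth", {
  st <- default_study()
  cen <- center_on_parents(st$expr)
  q <- qc_filter_markers(call_expression_markers(cen, st$panel))
  em <- impute_and_extend(q)
  truth <- truth_at_windows(em, st$geno)
  # error rate of made (correlated) calls mirrors the sub-1% per-strain claim
  ord <- match(colnames(em$calls), q$windows$window_id)
  raw_err <- mean(q$calls[, ord] != truth, na.rm = TRUE)
  expect_lt(raw_err, 0.01)
})

test_that("genotype recovery exceeds 99% at full window density", {
  # complete-design window density (hundreds of windows); at the reduced
  # 5000-feature test scale imputation/extension spans more bp per window
  # and point accuracy is lower (documented in the vignette)
  st <- cached("study_dense",
               simulate_miril_study(seed = 4, n_features = 45220,
                                    n_panel_cis = 8480, n_cis_extra = 500,
                                    n_trans = 600))
  cen <- center_on_parents(st$expr)
  q <- qc_filter_markers(call_expression_markers(cen, st$panel))
  em <- impute_and_extend(q)
  truth <- truth_at_windows(em, st$geno)
  acc <- mean(em$calls == truth, na.rm = TRUE)
  expect_gte(acc, 0.99)
})
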