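# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_study <- function(seed = 1) {
  cached(paste0("study_", seed), simulate_miril_study(seed = seed))
}

default_scan <- function(seed = 1) {
  st <- default_study(seed)
  cached(paste0("scan_", seed), eqtl_scan(st$expr, st$geno_informative))
}

default_threshold <- function(seed = 1) {
  st <- default_study(seed)
  cached(paste0("thr_", seed),
         permutation_threshold(st$expr, st$geno_informative, q = 0.1,
                               n_perm = 10, seed = seed + 500,
                               scan_obs = default_scan(seed)))
}

default_records <- function(seed = 1) {
  cached(paste0("rec_", seed), {
    classify_cis_trans(call_peaks(default_scan(seed),
                                  threshold = default_threshold(seed)$threshold))
  })
}

# Small two-chromosome genotype fixture with hand-set calls.
toy_geno <- function(calls, chrom, pos) {
  map <- data.frame(marker = marker_ids_for(chrom, pos), chrom = chrom,
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  colnames(calls) <- map$marker
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  }
  structure(list(calls = calls, map = map, selected_locus = NULL),
            class = "miril_geno")
}

marker_ids_for <- function(chrom, pos) sprintf("%s_%09d", chrom, as.integer(pos))

# Wrap a plain matrix as an expression object.
toy_expr <- function(values, chrom = NULL, pos = NULL, gene_id = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%03d", seq_len(n))
  structure(list(
    values = values,
    features = data.frame(
      spot_id = rownames(values),
      gene_id = if (is.null(gene_id)) rownames(values) else gene_id,
      chrom = if (is.null(chrom)) rep("I", n) else chrom,
      pos = if (is.null(pos)) rep(1L, n) else as.integer(pos),
      stringsAsFactors = FALSE),
    parents = NULL), class = "miril_expr")
}

# True genotype at each expression-marker window position, for accuracy checks.
truth_at_windows <- function(emap, geno) {
  idx <- vapply(seq_len(nrow(emap$map)), function(w) {
    on_chr <- which(geno$map$chrom == emap$map$chrom[w])
    on_chr[which.min(abs(geno$map$pos[on_chr] - emap$map$pos[w]))]
  }, 0L)
  geno$calls[, idx, drop = FALSE]
}
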