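# Tab-delimited, UTF-8, '#'-commented files; 1-based inclusive coordinates.
# Numeric columns are written with 6 significant digits so reruns diff clean.

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(signif(x, digits), format = "g",
                                 digits = digits))
}

write_tsv <- function(df, path, num_digits = 6) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]], num_digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      stop_("%s lacks required column(s): %s", path,
            paste(missing_cols, collapse = ", "))
    }
  }
  df
}

geno_map_path <- function(path) sub("(\\.[^.]+)?$", "_map.tsv",
                                    sub("\\.tsv$", "", path))

#' Write / read a genotype matrix as TSV
#'
#' Calls are written as `P1` / `P2` / `MISSING` with strains in rows and
#' marker ids in columns; the marker map (marker, chrom, pos, 1-based bp) goes
#' to a sidecar file `<path minus .tsv>_map.tsv`.
#'
#' @param genotypes A `miril_geno`.
#' @param path Output TSV path for the calls.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  code <- matrix("MISSING", nrow(genotypes$calls), ncol(genotypes$calls))
  code[genotypes$calls == 1L] <- "P1"
  code[genotypes$calls == 0L] <- "P2"
  df <- data.frame(strain = rownames(genotypes$calls), code,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("strain", colnames(genotypes$calls))
  write_tsv(df, path)
  write_tsv(genotypes$map, geno_map_path(path))
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path, required = "strain")
  if (anyDuplicated(df$strain)) {
    stop_("duplicate strain id in %s: %s", path,
          df$strain[duplicated(df$strain)][1])
  }
  map <- read_tsv(geno_map_path(path), required = c("marker", "chrom", "pos"))
  if (anyDuplicated(map$marker)) stop_("duplicate marker id in map")
  for (cn in unique(map$chrom)) {
    p <- map$pos[map$chrom == cn]
    if (any(diff(p) <= 0)) {
      stop_("marker positions not strictly increasing on chromosome %s", cn)
    }
  }
  code <- as.matrix(df[, -1, drop = FALSE])
  bad <- setdiff(unique(as.vector(code)), c("P1", "P2", "MISSING", NA))
  if (length(bad) > 0) {
    stop_("invalid genotype code(s) in %s: %s (only homozygous P1/P2/MISSING allowed)",
          path, paste(bad, collapse = ", "))
  }
  if (!identical(colnames(code), map$marker)) {
    stop_("marker columns of %s do not match the sidecar map", path)
  }
  calls <- matrix(NA_integer_, nrow(code), ncol(code),
                  dimnames = list(df$strain, colnames(code)))
  calls[code == "P1"] <- 1L
  calls[code == "P2"] <- 0L
  structure(list(calls = calls, map = map, selected_locus = NULL),
            class = "miril_geno")
}

#' Write / read an expression matrix as TSV
#'
#' Rows are features with `spot_id`, `gene_id`, `chrom`, `pos` columns
#' followed by one numeric column per strain; parental replicate columns are
#' written with their `P1_rep*` / `P2_rep*` names.
#'
#' @param expression A `miril_expr`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expression, path) {
  df <- cbind(expression$features,
              as.data.frame(expression$values, check.names = FALSE))
  if (!is.null(expression$parents)) {
    df <- cbind(df, as.data.frame(expression$parents$P1, check.names = FALSE),
                as.data.frame(expression$parents$P2, check.names = FALSE))
  }
  write_tsv(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, required = c("spot_id", "gene_id", "chrom", "pos"))
  if (anyDuplicated(df$spot_id)) {
    stop_("duplicated spot id in %s: %s", path,
          df$spot_id[duplicated(df$spot_id)][1])
  }
  meta <- c("spot_id", "gene_id", "chrom", "pos")
  val_cols <- setdiff(names(df), meta)
  for (cn in val_cols) {
    if (!is.numeric(df[[cn]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop_("non-numeric value in %s, column %s, row %d", path, cn, bad_row)
    }
  }
  vals <- as.matrix(df[val_cols])
  rownames(vals) <- df$spot_id
  is_p1 <- grepl("^P1_rep", val_cols)
  is_p2 <- grepl("^P2_rep", val_cols)
  parents <- NULL
  if (any(is_p1) && any(is_p2)) {
    parents <- list(P1 = vals[, is_p1, drop = FALSE],
                    P2 = vals[, is_p2, drop = FALSE])
  }
  structure(list(values = vals[, !is_p1 & !is_p2, drop = FALSE],
                 features = df[meta], parents = parents),
            class = "miril_expr")
}

#' Load a typed input table
#'
#' Dispatcher over the pipeline's file formats with validation: `genotype`
#' (calls + sidecar map), `expression`, `panel` (reference cis-eQTL effects),
#' `eqtl` (result records), `annotation` (category_id, gene_id).
#'
#' @param path File path.
#' @param kind One of "genotype", "expression", "panel", "eqtl", "annotation".
#' @return The typed object (see the individual readers).
#' @export
load_matrix <- function(path, kind = c("genotype", "expression", "panel",
                                       "eqtl", "annotation")) {
  kind <- match.arg(kind)
  switch(kind,
         genotype = read_genotypes(path),
         expression = read_expression(path),
         panel = {
           p <- read_tsv(path, required = c("gene_id", "chrom", "pos",
                                            "effect"))
           if (any(!is.finite(p$effect)) || any(p$effect == 0)) {
             stop_("panel %s contains zero or non-finite effects", path)
           }
           p[order(p$chrom, p$pos), , drop = FALSE]
         },
         eqtl = read_tsv(path, required = c("gene_id", "class")),
         annotation = read_tsv(path, required = c("category_id", "gene_id")))
}

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the reference
#' analysis: 20-gene windows called at |r| > 0.6 and QC'd at |r| > 0.5 in
#' more than half the strains, informative markers above 15% minor-genotype
#' frequency, permutation FDR at q = 0.1 with 10 permutations, 2-Mb cis
#' window, 1.5-drop confidence intervals, 1-Mb hotspot bins at a per-bin
#' significance of 0.001.
#'
#' @param out_dir Output directory for stage TSVs and the run report.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides for any default listed above (see the returned list).
#' @return A validated config list of class `miril_config`.
#' @export
miril_config <- function(out_dir = tempfile("miril_run_"), seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    n_lines = 33, n_features = 5000,
    map_source = "truth",          # "truth" or "expression"
    window = 20, call_threshold = 0.6, qc_threshold = 0.5,
    min_fraction = 0.5, min_minor_freq = 0.15,
    cis_window = 2e6, ci_drop = 1.5,
    q = 0.1, n_perm = 10, threshold = NULL,
    bin_size = 1e6, sig_level = 0.001,
    alpha = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop_("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (cfg$q <= 0 || cfg$q >= 1) stop_("config: q must be in (0,1)")
  if (!cfg$map_source %in% c("truth", "expression")) {
    stop_("config: map_source must be 'truth' or 'expression'")
  }
  if (cfg$cis_window <= 0 || cfg$bin_size <= 0 || cfg$ci_drop < 0) {
    stop_("config: cis_window/bin_size/ci_drop out of range")
  }
  class(cfg) <- "miril_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [miril_config()] fields.
#' @return A validated `miril_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(miril_config, y)
}

#' Run the full synthetic-study eQTL pipeline
#'
#' Executes simulate -> expression-marker genotyping -> scan -> permutation
#' threshold -> peak calling -> cis/trans classification -> trans-band
#' detection -> replication -> enrichment, writing each stage's TSV and a
#' JSON run report under `config$out_dir`. Deterministic given the config
#' seed: rerunning with the same config reproduces byte-identical outputs.
#'
#' @param config A `miril_config`.
#' @return The run report (list), invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "miril_config")) stop_("config must be a miril_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  out <- function(f) file.path(config$out_dir, f)

  study <- stage("simulate", simulate_miril_study(
    seed = config$seed, n_lines = config$n_lines,
    n_features = config$n_features))
  write_genotypes(study$geno, out("genotypes_truth.tsv"))
  write_expression(study$expr, out("expression.tsv"))
  write_tsv(study$arch$effects, out("architecture_truth.tsv"))
  write_tsv(study$panel, out("reference_cis_panel.tsv"))

  emap <- stage("genotype", {
    centered <- center_on_parents(study$expr)
    calls <- call_expression_markers(centered, study$panel,
                                     window = config$window,
                                     call_threshold = config$call_threshold)
    calls <- qc_filter_markers(calls, min_fraction_called = config$min_fraction,
                               qc_threshold = config$qc_threshold)
    impute_and_extend(calls)
  })
  write_genotypes(emap, out("genotypes_expression_markers.tsv"))

  geno_map <- if (config$map_source == "expression") {
    prune_informative_markers(emap, config$min_minor_freq)
  } else {
    study$geno_informative
  }
  write_genotypes(geno_map, out("genotypes_informative.tsv"))

  scanm <- stage("scan", eqtl_scan(study$expr, geno_map))
  thr <- stage("threshold", {
    if (!is.null(config$threshold)) {
      list(threshold = config$threshold, fixed = TRUE)
    } else {
      permutation_threshold(study$expr, geno_map, q = config$q,
                            n_perm = config$n_perm,
                            seed = sub_seed(config$seed, 101),
                            scan_obs = scanm)
    }
  })
  records <- stage("peaks", call_peaks(scanm, threshold = thr$threshold,
                                       ci_drop = config$ci_drop))
  records <- stage("classify",
                   classify_cis_trans(records, cis_window = config$cis_window))
  write_tsv(records, out("eqtl_records.tsv"))
  counts <- summarize_counts(records)
  write_tsv(counts, out("eqtl_counts.tsv"))

  bands <- stage("hotspots", detect_trans_bands(
    records[records$class == "trans", , drop = FALSE],
    bin_size = config$bin_size, sig_level = config$sig_level))
  write_tsv(bands, out("trans_bands.tsv"))

  repl <- stage("replication", replication_overlap(records, study$ref_eqtl))
  band_repl <- if (nrow(bands) > 0) {
    transband_replication(bands, records, repl)
  } else bands
  write_tsv(band_repl, out("trans_band_replication.tsv"))

  enr <- stage("enrich", {
    universe <- unique(study$arch$features$gene_id)
    query <- intersect(unique(records$gene_id[records$class == "trans"]),
                       universe)
    enrich(query, study$annotation, universe, alpha = config$alpha)
  })
  write_tsv(enr, out("enrichment_trans.tsv"))

  report <- list(
    package_version = as.character(utils::packageVersion("mirilqtl")),
    parameters = unclass(config),
    seed = config$seed,
    threshold = thr$threshold,
    n_markers_map = ncol(geno_map$calls),
    n_expression_markers = ncol(emap$calls),
    counts = counts,
    n_eqtl_records = nrow(records),
    n_trans_bands = nrow(bands),
    lambda_per_occupied_bin = attr(bands, "lambda"),
    replication = list(cis_rate = repl$cis_rate,
                       trans_rate = repl$trans_rate),
    n_enriched_categories = sum(enr$pass))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
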