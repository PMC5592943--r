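#' Simulate genotypes for a mutation-introgressed RIL (miRIL) population
#'
#' Emulates the construction of miRILs: an F1 between two fully homozygous
#' parents (P1 = N2-like, P2 = CB4856-like) is selfed to F2, F2 individuals are
#' selected to be homozygous P1 at the introgressed locus (emulating selection
#' for a mutation such as \emph{let-60(gf)} at IV: 11.7 Mb), and lines are then
#' driven to homozygosity by repeated selfing with the selected locus kept
#' fixed. Meiosis draws a Poisson number of crossovers per chromosome with
#' uniformly distributed breakpoints.
#'
#' @param n_lines Number of inbred lines to simulate (>= 2).
#' @param chromosomes Data frame with columns `chrom`, `length_bp`.
#' @param marker_spacing Distance between adjacent simulated markers, bp.
#' @param selected_locus Length-2 list/vector `(chrom, pos_bp)` of the locus
#'   kept homozygous P1 from the F2 on, or `NULL` for no selection.
#' @param recomb_rate Expected crossovers per chromosome per meiosis.
#' @param n_selfing Number of selfing generations after the F2.
#' @param seed Integer seed; the simulation is fully reproducible.
#'
#' @return An object of class `miril_geno`: a list with `calls` (strains x
#'   markers integer matrix, 1 = P1, 0 = P2, `NA` = missing), `map` (data frame
#'   `marker`, `chrom`, `pos`), and `selected_locus`.
#' @export
simulate_miril_genotypes <- function(n_lines,
                                     chromosomes = celegans_chromosomes(),
                                     marker_spacing = 2e5,
                                     selected_locus = list("IV", 11.7e6),
                                     recomb_rate = 1,
                                     n_selfing = 10,
                                     seed = 1) {
  if (n_lines < 2) stop_("n_lines must be >= 2, got %d", n_lines)
  if (any(floor(chromosomes$length_bp / marker_spacing) < 1)) {
    stop_("marker_spacing %g leaves zero markers on at least one chromosome",
          marker_spacing)
  }
  map <- do.call(rbind, lapply(seq_len(nrow(chromosomes)), function(i) {
    pos <- seq(marker_spacing, chromosomes$length_bp[i], by = marker_spacing)
    data.frame(chrom = chromosomes$chrom[i], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  map <- data.frame(marker = marker_id(map$chrom, map$pos), map,
                    stringsAsFactors = FALSE)

  sel_idx <- NULL
  if (!is.null(selected_locus)) {
    sc <- as.character(selected_locus[[1]])
    sp <- as.numeric(selected_locus[[2]])
    ci <- match(sc, chromosomes$chrom)
    if (is.na(ci)) stop_("selected locus chromosome '%s' not declared", sc)
    if (sp < 0 || sp > chromosomes$length_bp[ci]) {
      stop_("selected locus %s:%g outside chromosome bounds", sc, sp)
    }
    on_chr <- which(map$chrom == sc)
    sel_idx <- on_chr[which.min(abs(map$pos[on_chr] - sp))]
  }

  chrom_index <- split(seq_len(nrow(map)), chrom_factor(map$chrom, chromosomes))
  chrom_len <- stats::setNames(chromosomes$length_bp, chromosomes$chrom)

  gamete <- function(h1, h2) {
    out <- integer(nrow(map))
    for (cn in names(chrom_index)) {
      idx <- chrom_index[[cn]]
      nxo <- stats::rpois(1L, recomb_rate)
      seg <- if (nxo > 0L) {
        findInterval(map$pos[idx], sort(stats::runif(nxo, 0, chrom_len[[cn]])))
      } else rep.int(0L, length(idx))
      use1 <- (seg %% 2L) == 0L
      if (stats::runif(1) < 0.5) use1 <- !use1
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
    out
  }

  calls <- with_seed(seed, {
    t(vapply(seq_len(n_lines), function(l) {
      # F1 is heterozygous everywhere; self to F2, selecting at the locus
      f1 <- list(rep.int(1L, nrow(map)), rep.int(0L, nrow(map)))
      repeat {
        h1 <- gamete(f1[[1]], f1[[2]])
        h2 <- gamete(f1[[1]], f1[[2]])
        if (is.null(sel_idx) || (h1[sel_idx] == 1L && h2[sel_idx] == 1L)) break
      }
      for (g in seq_len(n_selfing)) {
        n1 <- gamete(h1, h2)
        n2 <- gamete(h1, h2)
        h1 <- n1
        h2 <- n2
      }
      # force residual heterozygous runs to one of the parental segments
      het <- h1 != h2
      if (any(het)) {
        for (cn in names(chrom_index)) {
          idx <- chrom_index[[cn]]
          r <- rle(het[idx])
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1L
          for (k in which(r$values)) {
            span <- idx[starts[k]:ends[k]]
            if (stats::runif(1) < 0.5) h1[span] <- h2[span] else h2[span] <- h1[span]
          }
        }
      }
      h1
    }, integer(nrow(map))))
  })
  dimnames(calls) <- list(sprintf("miRIL_%03d", seq_len(n_lines)), map$marker)

  structure(list(calls = calls, map = map,
                 selected_locus = if (is.null(sel_idx)) NULL else
                   list(chrom = map$chrom[sel_idx], pos = map$pos[sel_idx],
                        marker = map$marker[sel_idx])),
            class = "miril_geno")
}

#' @export
print.miril_geno <- function(x, ...) {
  cat(sprintf("miril_geno: %d strains x %d markers on %d chromosomes\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  if (!is.null(x$selected_locus)) {
    cat(sprintf("  selected locus: %s:%d (marker %s)\n",
                x$selected_locus$chrom, x$selected_locus$pos,
                x$selected_locus$marker))
  }
  invisible(x)
}

#' Define a planted eQTL architecture for simulated expression data
#'
#' Builds the truth table used by [simulate_expression()]: feature positions
#' and a set of planted genetic effects in noise-SD units. Cis effects target
#' the marker nearest the feature's own position; trans effects target a marker
#' on another chromosome; trans-band effects share a single regulator marker so
#' their eQTL cluster in one genomic bin. Effect sizes are on the scale where,
#' at a balanced marker with unit noise, a peak size of 1 explains 20% of the
#' variance.
#'
#' @param genotypes A `miril_geno` object supplying the marker map.
#' @param n_features Total number of array spots to simulate.
#' @param n_panel_cis Number of features given strong cis effects that also
#'   form the reference cis-eQTL panel used for expression-marker genotyping.
#' @param n_cis_extra Additional cis-regulated features (weaker, mixed sizes).
#' @param n_trans Number of isolated trans-regulated features.
#' @param band_spots Integer vector: planted trans-band sizes in spots.
#' @param cis_pos_frac Fraction of cis effects positive (higher in P1/N2).
#' @param band_pos_frac Fraction of band effects positive.
#' @param frac_dup_gene Fraction of genes represented by two spots.
#' @param noise_sd Residual SD of simulated log2 intensities.
#' @param seed Integer seed.
#'
#' @return An object of class `miril_arch`: list with `features` (spot_id,
#'   gene_id, chrom, pos), `effects` (spot_id, marker, effect, class, band_id),
#'   `bands` (band_id, chrom, bin start/end in bp, regulator marker),
#'   `noise_sd`, `seed`.
#' @export
simulate_architecture <- function(genotypes,
                                  n_features = 5000,
                                  n_panel_cis = 1200,
                                  n_cis_extra = 200,
                                  n_trans = 250,
                                  band_spots = c(200, 120, 60),
                                  cis_pos_frac = 0.7,
                                  band_pos_frac = 0.3,
                                  frac_dup_gene = 0.08,
                                  noise_sd = 1,
                                  seed = 1) {
  map <- genotypes$map
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(cn) max(map$pos[map$chrom == cn]), 0)

  with_seed(seed, {
    n_genes <- round(n_features / (1 + frac_dup_gene))
    gc <- sample(chroms, n_genes, replace = TRUE,
                 prob = chrom_len / sum(chrom_len))
    gp <- as.integer(floor(stats::runif(n_genes, 1, chrom_len[gc])))
    genes <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
                        chrom = gc, pos = gp, stringsAsFactors = FALSE)
    dup <- sample(n_genes, min(n_genes, n_features - n_genes))
    features <- rbind(genes, genes[dup, , drop = FALSE])
    features <- features[order(chrom_factor(features$chrom,
                                            data.frame(chrom = chroms)),
                               features$pos), , drop = FALSE]
    features <- data.frame(spot_id = sprintf("spot_%05d", seq_len(nrow(features))),
                           features, row.names = NULL, stringsAsFactors = FALSE)

    nearest_marker <- function(chrom, pos) {
      vapply(seq_along(chrom), function(i) {
        on_chr <- which(map$chrom == chrom[i])
        map$marker[on_chr[which.min(abs(map$pos[on_chr] - pos[i]))]]
      }, "")
    }

    total_planted <- n_panel_cis + n_cis_extra + n_trans + sum(band_spots)
    if (total_planted > nrow(features)) {
      stop_("planted effects (%d) exceed n_features (%d)", total_planted,
            nrow(features))
    }
    # one planted effect per spot: draw disjoint spot sets
    pool <- sample(nrow(features))
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }

    eff <- list()
    if (n_panel_cis > 0) {
      i <- take(n_panel_cis)
      eff$panel <- data.frame(
        spot_id = features$spot_id[i],
        marker = nearest_marker(features$chrom[i], features$pos[i]),
        effect = stats::runif(n_panel_cis, 2, 4) *
          ifelse(stats::runif(n_panel_cis) < cis_pos_frac, 1, -1),
        class = "cis", band_id = NA_character_, stringsAsFactors = FALSE)
    }
    if (n_cis_extra > 0) {
      i <- take(n_cis_extra)
      eff$cis <- data.frame(
        spot_id = features$spot_id[i],
        marker = nearest_marker(features$chrom[i], features$pos[i]),
        effect = stats::runif(n_cis_extra, 0.5, 2.5) *
          ifelse(stats::runif(n_cis_extra) < cis_pos_frac, 1, -1),
        class = "cis", band_id = NA_character_, stringsAsFactors = FALSE)
    }
    if (n_trans > 0) {
      i <- take(n_trans)
      tm <- vapply(i, function(f) {
        sample(which(map$chrom != features$chrom[f]), 1L)
      }, 0L)
      eff$trans <- data.frame(
        spot_id = features$spot_id[i],
        marker = map$marker[tm],
        effect = stats::runif(n_trans, 0.5, 2.5) *
          ifelse(stats::runif(n_trans) < 0.5, 1, -1),
        class = "trans", band_id = NA_character_, stringsAsFactors = FALSE)
    }
    bands <- NULL
    if (length(band_spots) > 0) {
      # place each band in its own 1-Mb bin, away from the selected chromosome
      # (selection strips informative markers there)
      sel_chrom <- if (is.null(genotypes$selected_locus)) "" else
        genotypes$selected_locus$chrom
      cand_chroms <- setdiff(chroms, sel_chrom)
      bch <- sample(cand_chroms, length(band_spots),
                    replace = length(band_spots) > length(cand_chroms))
      bands <- do.call(rbind, lapply(seq_along(band_spots), function(b) {
        on_chr <- which(map$chrom == bch[b])
        reg <- sample(on_chr[map$pos[on_chr] > 1e6 &
                               map$pos[on_chr] < chrom_len[bch[b]] - 1e6], 1L)
        bin <- floor((map$pos[reg] - 1) / 1e6)
        data.frame(band_id = sprintf("band_%d", b), chrom = bch[b],
                   bin_start = as.integer(bin * 1e6 + 1),
                   bin_end = as.integer((bin + 1) * 1e6),
                   marker = map$marker[reg], n_spots = band_spots[b],
                   stringsAsFactors = FALSE)
      }))
      eff$bands <- do.call(rbind, lapply(seq_len(nrow(bands)), function(b) {
        # band members live on other chromosomes so every member is trans
        elig <- pool[features$chrom[pool] != bands$chrom[b]]
        i <- elig[seq_len(bands$n_spots[b])]
        pool <<- setdiff(pool, i)
        data.frame(
          spot_id = features$spot_id[i],
          marker = bands$marker[b],
          effect = stats::runif(length(i), 1.5, 3) *
            ifelse(stats::runif(length(i)) < band_pos_frac, 1, -1),
          class = "transband", band_id = bands$band_id[b],
          stringsAsFactors = FALSE)
      }))
    }
    effects <- do.call(rbind, eff)
    if (is.null(effects)) {
      effects <- data.frame(spot_id = character(), marker = character(),
                            effect = numeric(), class = character(),
                            band_id = character(), stringsAsFactors = FALSE)
    }
    row.names(effects) <- NULL

    structure(list(features = features, effects = effects, bands = bands,
                   noise_sd = noise_sd, seed = seed),
              class = "miril_arch")
  })
}

#' Simulate log2 expression data from genotypes and a planted architecture
#'
#' Each feature's value is `baseline + sum(effect * [genotype at target marker
#' == P1]) + N(0, noise_sd)`. Parental replicate profiles are generated from
#' pure-P1 and pure-P2 genotype rows with the same noise model; they drive the
#' parental-mean centering and QC steps of expression-marker genotyping.
#'
#' @param genotypes A `miril_geno`.
#' @param architecture A `miril_arch` from [simulate_architecture()].
#' @param baseline Scalar baseline log2 intensity added to every value.
#' @param n_parent_reps Number of replicate arrays per parental strain.
#' @param seed Integer seed; defaults to the architecture's seed + 1.
#'
#' @return An object of class `miril_expr`: list with `values` (features x
#'   strains), `features` (spot_id, gene_id, chrom, pos), and `parents`
#'   (list of two features x replicate matrices, `P1` and `P2`).
#' @export
simulate_expression <- function(genotypes, architecture, baseline = 10,
                                n_parent_reps = 4,
                                seed = architecture$seed + 1) {
  ef <- architecture$effects
  if (!all(ef$marker %in% genotypes$map$marker)) {
    bad <- setdiff(ef$marker, genotypes$map$marker)
    stop_("architecture references unknown marker(s): %s",
          paste(utils::head(bad, 3), collapse = ", "))
  }
  feats <- architecture$features
  n_f <- nrow(feats)
  n_s <- nrow(genotypes$calls)

  # feature x strain matrix of planted genetic signal
  signal_for <- function(geno_row_matrix) {
    # geno_row_matrix: strains x markers (0/1); returns features x strains
    sig <- matrix(0, n_f, nrow(geno_row_matrix))
    if (nrow(ef) > 0) {
      fi <- match(ef$spot_id, feats$spot_id)
      mi <- match(ef$marker, colnames(geno_row_matrix))
      for (k in seq_len(nrow(ef))) {
        g <- geno_row_matrix[, mi[k]]
        g[is.na(g)] <- 0L
        sig[fi[k], ] <- sig[fi[k], ] + ef$effect[k] * g
      }
    }
    sig
  }

  with_seed(seed, {
    values <- baseline + signal_for(genotypes$calls) +
      matrix(stats::rnorm(n_f * n_s, 0, architecture$noise_sd), n_f, n_s)
    colnames(values) <- rownames(genotypes$calls)
    rownames(values) <- feats$spot_id

    pure <- function(allele) {
      m <- matrix(allele, n_parent_reps, ncol(genotypes$calls),
                  dimnames = list(NULL, colnames(genotypes$calls)))
      baseline + signal_for(m) +
        matrix(stats::rnorm(n_f * n_parent_reps, 0, architecture$noise_sd),
               n_f, n_parent_reps)
    }
    parents <- list(P1 = pure(1L), P2 = pure(0L))
    rownames(parents$P1) <- rownames(parents$P2) <- feats$spot_id
    colnames(parents$P1) <- sprintf("P1_rep%d", seq_len(n_parent_reps))
    colnames(parents$P2) <- sprintf("P2_rep%d", seq_len(n_parent_reps))

    structure(list(values = values, features = feats, parents = parents),
              class = "miril_expr")
  })
}

#' @export
print.miril_expr <- function(x, ...) {
  cat(sprintf("miril_expr: %d features x %d strains%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$parents)) "" else
                sprintf(" (+%d parental replicates each)",
                        ncol(x$parents$P1))))
  invisible(x)
}

#' Simulate a standalone reference cis-eQTL effect panel
#'
#' Generates a position-sorted table of genes with signed cis-eQTL effects
#' (positive = higher expression on the P1/N2 allele), emulating the published
#' cis-eQTL effect panels used as a genotyping reference. For a panel that is
#' consistent with a simulated expression data set, use the one returned by
#' [simulate_miril_study()], which shares the planted cis architecture.
#'
#' @param genotypes A `miril_geno` supplying chromosome extents.
#' @param n_genes Number of panel genes (>= 1).
#' @param effect_scale Scale of effect magnitudes (must be > 0).
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `chrom`, `pos`, `effect`, sorted by position
#'   within chromosome.
#' @export
simulate_reference_cis_panel <- function(genotypes, n_genes, effect_scale = 1,
                                         seed = 1) {
  if (n_genes < 1) stop_("n_genes must be >= 1, got %d", n_genes)
  if (!is.finite(effect_scale) || effect_scale <= 0) {
    stop_("effect_scale must be positive (panel effects are nonzero by definition)")
  }
  map <- genotypes$map
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(cn) max(map$pos[map$chrom == cn]), 0)
  with_seed(seed, {
    gc <- sample(chroms, n_genes, replace = TRUE,
                 prob = chrom_len / sum(chrom_len))
    gp <- as.integer(floor(stats::runif(n_genes, 1, chrom_len[gc])))
    effect <- effect_scale * stats::runif(n_genes, 0.5, 2) *
      ifelse(stats::runif(n_genes) < 0.5, 1, -1)
    panel <- data.frame(gene_id = sprintf("refgene_%05d", seq_len(n_genes)),
                        chrom = gc, pos = gp, effect = effect,
                        stringsAsFactors = FALSE)
    panel <- panel[order(chrom_factor(panel$chrom, data.frame(chrom = chroms)),
                         panel$pos), , drop = FALSE]
    row.names(panel) <- NULL
    panel
  })
}

# Reference panel aligned with an architecture's planted panel-cis genes:
# the "prior experiment" measured the same cis effects, with attenuation noise.
panel_from_architecture <- function(architecture, effect_jitter_sd = 0.25,
                                    seed = architecture$seed + 2) {
  ef <- architecture$effects
  pc <- ef[ef$class == "cis" & abs(ef$effect) >= 1.5, , drop = FALSE]
  fi <- match(pc$spot_id, architecture$features$spot_id)
  with_seed(seed, {
    panel <- data.frame(
      gene_id = architecture$features$gene_id[fi],
      chrom = architecture$features$chrom[fi],
      pos = architecture$features$pos[fi],
      effect = pc$effect + stats::rnorm(nrow(pc), 0, effect_jitter_sd),
      stringsAsFactors = FALSE)
    panel <- panel[!duplicated(panel$gene_id), , drop = FALSE]
    panel$effect[panel$effect == 0] <- 1e-6
    panel <- panel[order(chrom_factor(panel$chrom,
                                      data.frame(chrom = unique(architecture$features$chrom))),
                         panel$pos), , drop = FALSE]
    row.names(panel) <- NULL
    panel
  })
}

#' Synthesize a reference eQTL result table for replication analysis
#'
#' Builds the kind of table a prior eQTL study would contribute: one row per
#' gene-eQTL with gene id, class and eQTL chromosome. Cis rows are taken from
#' the architecture's planted cis genes (a configurable share, emulating that
#' cis effects replicate well across studies); trans rows replicate a
#' configurable share of the planted trans genes on the same chromosome, with
#' the remainder of the reference made of unrelated genes. Synthetic: this is
#' not derived from any published eQTL table.
#'
#' @param architecture A `miril_arch`.
#' @param genotypes The `miril_geno` the architecture targets.
#' @param cis_share Fraction of planted cis genes present in the reference.
#' @param trans_share Fraction of planted isolated-trans genes whose
#'   trans-eQTL the reference replicates on the same chromosome.
#' @param band_trans_share Fraction of planted trans-band member genes the
#'   reference replicates; low by default because the bands emulate
#'   regulation specific to the sensitizing mutation, which a reference
#'   study without that mutation would largely miss.
#' @param n_background Unrelated reference genes to add.
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `class`, `chrom`.
#' @export
simulate_reference_eqtl_table <- function(architecture, genotypes,
                                          cis_share = 0.75,
                                          trans_share = 0.238,
                                          band_trans_share = 0.05,
                                          n_background = 500,
                                          seed = architecture$seed + 3) {
  ef <- architecture$effects
  feats <- architecture$features
  map <- genotypes$map
  with_seed(seed, {
    cis_genes <- unique(feats$gene_id[match(ef$spot_id[ef$class == "cis"],
                                            feats$spot_id)])
    cis_keep <- sample(cis_genes, round(cis_share * length(cis_genes)))
    cis_tab <- data.frame(
      gene_id = cis_keep, class = "cis",
      chrom = feats$chrom[match(cis_keep, feats$gene_id)],
      stringsAsFactors = FALSE)

    tr <- ef[ef$class %in% c("trans", "transband"), , drop = FALSE]
    tr_genes <- unique(data.frame(
      gene_id = feats$gene_id[match(tr$spot_id, feats$spot_id)],
      chrom = map$chrom[match(tr$marker, map$marker)],
      in_band = tr$class == "transband",
      stringsAsFactors = FALSE))
    share <- ifelse(tr_genes$in_band, band_trans_share, trans_share)
    keep <- which(stats::runif(nrow(tr_genes)) < share)
    tr_tab <- if (length(keep) > 0) {
      data.frame(gene_id = tr_genes$gene_id[keep], class = "trans",
                 chrom = tr_genes$chrom[keep], stringsAsFactors = FALSE)
    } else NULL

    bg <- data.frame(
      gene_id = sprintf("refonly_%05d", seq_len(n_background)),
      class = sample(c("cis", "trans"), n_background, replace = TRUE),
      chrom = sample(unique(map$chrom), n_background, replace = TRUE),
      stringsAsFactors = FALSE)
    out <- rbind(cis_tab, tr_tab, bg)
    row.names(out) <- NULL
    out
  })
}

#' Synthesize an annotation catalogue for enrichment testing
#'
#' Produces a two-column (category_id, gene_id) table over the simulated
#' platform. A configurable number of categories are enriched in the members of
#' each planted trans-band (so enrichment is detectable by construction); the
#' rest are random draws from the universe.
#'
#' @param architecture A `miril_arch`.
#' @param n_random Number of random categories.
#' @param size_range Category size range for random categories.
#' @param band_frac Fraction of each planted band's genes placed into that
#'   band's dedicated category.
#' @param seed Integer seed.
#' @return Data frame `category_id`, `gene_id`.
#' @export
simulate_annotation <- function(architecture, n_random = 40,
                                size_range = c(5, 80), band_frac = 0.6,
                                seed = architecture$seed + 4) {
  feats <- architecture$features
  genes <- unique(feats$gene_id)
  with_seed(seed, {
    rand <- do.call(rbind, lapply(seq_len(n_random), function(k) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      data.frame(category_id = sprintf("CAT_rand_%03d", k),
                 gene_id = sample(genes, sz), stringsAsFactors = FALSE)
    }))
    band_cat <- NULL
    if (!is.null(architecture$bands)) {
      ef <- architecture$effects
      band_cat <- do.call(rbind, lapply(architecture$bands$band_id, function(b) {
        g <- unique(feats$gene_id[match(ef$spot_id[!is.na(ef$band_id) &
                                                     ef$band_id == b],
                                        feats$spot_id)])
        data.frame(category_id = sprintf("CAT_%s", b),
                   gene_id = sample(g, round(band_frac * length(g))),
                   stringsAsFactors = FALSE)
      }))
    }
    out <- rbind(band_cat, rand)
    out <- out[!duplicated(out[c("category_id", "gene_id")]), , drop = FALSE]
    row.names(out) <- NULL
    out
  })
}

#' Simulate a complete miRIL eQTL study
#'
#' One-call generator for the full set of inputs the pipeline consumes, under
#' the emulated study conditions: 33 miRILs over 6 chromosomes with a selected
#' homozygous locus at IV: 11.7 Mb, a marker grid dense enough to yield a few
#' hundred informative markers after pruning, and an expression architecture
#' with N2-biased cis effects, isolated trans effects, clustered trans-bands
#' and unit Gaussian noise.
#'
#' @param seed Integer master seed; all component seeds derive from it.
#' @param n_lines,n_features Study dimensions.
#' @param ... Passed to [simulate_architecture()].
#' @return List with `geno` (true marker genotypes), `geno_informative`
#'   (pruned informative truth map), `arch`, `expr`, `panel` (reference
#'   cis-eQTL panel consistent with the architecture), `ref_eqtl` (list of
#'   synthetic reference eQTL tables), `annotation`.
#' @export
simulate_miril_study <- function(seed = 1, n_lines = 33, n_features = 5000,
                                 ...) {
  geno <- simulate_miril_genotypes(n_lines, seed = sub_seed(seed, 1))
  arch <- simulate_architecture(geno, n_features = n_features,
                                seed = sub_seed(seed, 2), ...)
  expr <- simulate_expression(geno, arch, seed = sub_seed(seed, 3))
  panel <- panel_from_architecture(arch, seed = sub_seed(seed, 4))
  ref1 <- simulate_reference_eqtl_table(arch, geno, seed = sub_seed(seed, 5))
  ref2 <- simulate_reference_eqtl_table(arch, geno, cis_share = 0.6,
                                        trans_share = 0.15,
                                        seed = sub_seed(seed, 6))
  ann <- simulate_annotation(arch, seed = sub_seed(seed, 7))
  gi <- prune_informative_markers(geno)
  list(geno = geno, geno_informative = gi, arch = arch, expr = expr,
       panel = panel, ref_eqtl = list(ref1, ref2), annotation = ann,
       seed = seed)
}
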