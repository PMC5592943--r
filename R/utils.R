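#' @keywords internal
"_PACKAGE"

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# Every stochastic operation in the package routes through this so nothing
# depends on (or perturbs) global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + k * 12347L) %% 2147483587)
}

#' Chromosome sizes emulating the C. elegans nuclear genome
#'
#' Six chromosomes (I-V and X) with lengths in base pairs close to the
#' reference assembly, used as the default genome for all simulations.
#'
#' @return A data frame with columns `chrom` and `length_bp`.
#' @export
celegans_chromosomes <- function() {
  data.frame(
    chrom = c("I", "II", "III", "IV", "V", "X"),
    length_bp = c(15072434, 15279421, 13783801, 17493829, 20924180, 17718942),
    stringsAsFactors = FALSE
  )
}

# Order chromosome labels as they appear in the genome table (not alphabetic).
chrom_factor <- function(chrom, chromosomes) {
  factor(chrom, levels = unique(chromosomes$chrom))
}

marker_id <- function(chrom, pos) sprintf("%s_%09d", chrom, as.integer(pos))

row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
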