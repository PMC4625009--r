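#' Genome-wide LOD threshold from the effective number of tests
#'
#' A genome scan makes many correlated tests; the effective number of
#' independent tests is approximated as `M_eff = density_factor * genome
#' length (cM)`. The per-test type-I error is then `alpha_p = alpha_g /
#' M_eff` and the LOD threshold is the upper-`alpha_p` quantile of the
#' chi-squared distribution with `df` degrees of freedom divided by
#' `2 ln 10`. For a four-way cross scan the mixture fit has 3 free effect
#' contrasts, so `df = 3`. The default `density_factor = 0.072` is
#' calibrated for marker spacing near 10 cM; at the reference genome length
#' of 1799.03 cM and `alpha_g = 0.05` the threshold is 3.97.
#'
#' @param genome_length_cM Total map length in cM (> 0).
#' @param alpha_g Genome-wide type-I error rate, in (0, 1).
#' @param df Degrees of freedom of the scan test (3 for four-way crosses).
#' @param density_factor Effective tests per cM.
#' @return The LOD threshold (numeric scalar).
#' @examples
#' lod_threshold_formula(1799.03)          # 3.97
#' @export
lod_threshold_formula <- function(genome_length_cM, alpha_g = 0.05, df = 3,
                                  density_factor = 0.072) {
  stopifnot(genome_length_cM > 0, alpha_g > 0, alpha_g < 1,
            df >= 1, density_factor > 0)
  m_eff <- density_factor * genome_length_cM
  alpha_p <- alpha_g / m_eff
  if (alpha_p >= 1) {
    stop("per-test error alpha_g / M_eff = ", signif(alpha_p, 3),
         " is not below 1; genome length or density factor is implausible",
         call. = FALSE)
  }
  stats::qchisq(alpha_p, df, lower.tail = FALSE) / (2 * log(10))
}

#' Genome-wide LOD threshold by permutation
#'
#' Breaks the genotype-phenotype relationship by shuffling the phenotype
#' vector against the genotype rows, re-runs the full scan (including
#' cofactor selection) for each permutation, records the genome-wide
#' maximum LOD, and returns the empirical `(1 - alpha_g)` quantile of those
#' maxima. Shuffling preserves the phenotype distribution, so for
#' non-normal traits the permuted data are not a clean no-QTL null and the
#' permutation threshold tends to exceed the normal-theory formula value.
#'
#' @param phenotypes,genotypes,map As in [icim_scan()].
#' @param n_perm Number of permutations (>= 100, and `n_perm * alpha_g`
#'   must be at least 1 for the quantile to be estimable).
#' @param alpha_g Genome-wide type-I error rate.
#' @param seed Integer seed fixing the shuffles.
#' @param step,env,p_enter,p_remove,window,map_function As in [icim_scan()].
#' @return A list of class `perm_threshold`: `threshold`, `alpha_g`,
#'   `n_perm`, and the audit vector `max_lods`.
#' @export
lod_threshold_permutation <- function(phenotypes, genotypes, map,
                                      n_perm = 1000, alpha_g = 0.05, seed,
                                      step = 1, env = "mean",
                                      p_enter = 0.001, p_remove = 0.002,
                                      window = 10, map_function = "haldane") {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for permutation thresholds", call. = FALSE)
  }
  if (n_perm < 100) stop("need at least 100 permutations", call. = FALSE)
  if (n_perm * alpha_g < 1) {
    stop("n_perm = ", n_perm, " is too small to estimate the upper ",
         alpha_g, " quantile", call. = FALSE)
  }
  ph <- line_phenotypes(phenotypes, env)
  keep_lines <- genotypes$line[genotypes$line %in% ph$line]
  y <- ph$value[match(keep_lines, ph$line)]
  obs <- !is.na(y)
  keep_lines <- keep_lines[obs]
  y <- y[obs]
  geno <- genotypes[genotypes$line %in% keep_lines, , drop = FALSE]
  design <- build_scan_design(geno, map, step = step, window = window,
                              map_function = map_function)
  X <- encode_design(geno, map)
  n <- length(y)
  set.seed(seed)
  max_lods <- vapply(seq_len(n_perm), function(p) {
    yp <- y[sample.int(n)]
    cof <- stepwise_select(yp, X, p_enter = p_enter, p_remove = p_remove)
    max(scan_profile(yp, rep(TRUE, n), design, cof)$lod)
  }, numeric(1))
  sorted <- sort(max_lods)
  idx <- max(1L, ceiling((1 - alpha_g) * n_perm))
  structure(list(threshold = sorted[idx], alpha_g = alpha_g,
                 n_perm = n_perm, max_lods = max_lods),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("Permutation LOD threshold: %.2f (alpha_g = %g, %d permutations)\n",
              x$threshold, x$alpha_g, x$n_perm))
  invisible(x)
}
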