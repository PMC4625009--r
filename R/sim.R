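#' Simulate a four-way cross marker map
#'
#' Builds a marker framework emulating the SSR map of a maize four-way cross
#' study design: by default 10 chromosomes carrying 221 markers
#' (25, 28, 25, 25, 21, 19, 18, 17, 25, 18 per chromosome), a genome of
#' 1799.03 cM (so mean marker interval 8.53 cM), and the study's mix of
#' information categories per chromosome. Markers are evenly spaced within a
#' chromosome; categories are shuffled over positions with the supplied seed.
#'
#' @param n_markers Integer vector, markers per chromosome.
#' @param genome_length Total map length in cM, split across chromosomes in
#'   proportion to their interval counts so spacing is uniform genome-wide.
#' @param category_counts Integer matrix (chromosomes x 5 categories, columns
#'   `ABCD`, `A=B`, `C=D`, `A=CB=D`, `A=DB=C`); row sums must equal
#'   `n_markers`. Defaults to the study layout (see
#'   [study_category_counts()]).
#' @param seed Integer seed fixing the category placement.
#'
#' @return A genetic map: tibble with columns `marker`, `chrom`, `pos_cM`,
#'   `category`, `a`, `b`, `c`, `d` (founder alleles).
#'
#' @examples
#' map <- sim_map(seed = 1)
#' dplyr::count(map, chrom)
#' @export
sim_map <- function(n_markers = NULL, genome_length = 1799.03,
                    category_counts = NULL, seed = 1) {
  if (is.null(category_counts)) category_counts <- study_category_counts()
  category_counts <- as.matrix(category_counts[, MARKER_CATEGORIES])
  if (is.null(n_markers)) n_markers <- rowSums(category_counts)
  stopifnot(length(n_markers) == nrow(category_counts),
            all(rowSums(category_counts) == n_markers),
            all(n_markers >= 2))
  n_chr <- length(n_markers)
  intervals <- n_markers - 1L
  chr_len <- genome_length * intervals / sum(intervals)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    m <- n_markers[ch]
    cats <- rep(MARKER_CATEGORIES, times = category_counts[ch, ])
    cats <- sample(cats)
    tibble::tibble(
      marker = sprintf("c%02dm%02d", ch, seq_len(m)),
      chrom = ch,
      pos_cM = seq(0, chr_len[ch], length.out = m),
      category = cats
    ) |>
      dplyr::bind_cols(category_founder_alleles(cats))
  })
}

#' Per-chromosome marker category counts of the reference study design
#'
#' The 221-marker layout used as the simulator default: counts of the five
#' information categories on each of the 10 maize chromosomes (totals
#' 83 ABCD, 61 A=B, 50 C=D, 17 A=CB=D, 10 A=DB=C).
#'
#' @return A tibble with columns `chrom`, `ABCD`, `A=B`, `C=D`, `A=CB=D`,
#'   `A=DB=C`.
#' @export
study_category_counts <- function() {
  tibble::tibble(
    chrom = 1:10,
    "ABCD"   = c(8L, 8L, 14L, 8L, 10L, 6L, 7L, 3L, 10L, 9L),
    "A=B"    = c(6L, 9L, 5L, 11L, 5L, 6L, 6L, 2L, 8L, 3L),
    "C=D"    = c(6L, 9L, 3L, 3L, 4L, 5L, 4L, 8L, 5L, 3L),
    "A=CB=D" = c(2L, 1L, 3L, 3L, 2L, 0L, 1L, 2L, 2L, 1L),
    "A=DB=C" = c(3L, 1L, 0L, 0L, 0L, 2L, 0L, 2L, 0L, 2L)
  )
}

#' Reference QTL effect set for calibrated simulations
#'
#' The 14 leaf-angle QTL of the reference study (chromosome, position, two
#' additive effects `a_F`, `a_M` and dominance `d` on the F1 scale, in
#' degrees), optionally rescaled so that the closed-form genetic variance of
#' selfed-family means (see [expected_genetic_variance()]) matches a target
#' genotypic variance. With `sigma2_g = 29.0` the set reproduces the study's
#' combined-ANOVA genotypic variance.
#'
#' @param sigma2_g Target genotypic variance of family means, or `NULL` to
#'   return the effects unscaled.
#' @param map Genetic map used to place the QTL (positions are clamped to
#'   chromosome ends); defaults to [sim_map()] with seed 1.
#' @param map_function Map function for the linkage covariance terms.
#'
#' @return A tibble with columns `qtl`, `chrom`, `pos_cM`, `a_F`, `a_M`, `d`.
#' @examples
#' qtl <- study_qtl_effects(sigma2_g = 29.0)
#' sum(qtl$a_F^2 + qtl$a_M^2 + (qtl$d / 2)^2)  # unlinked part of the variance
#' @export
study_qtl_effects <- function(sigma2_g = 29.0, map = NULL,
                              map_function = "haldane") {
  eff <- tibble::tribble(
    ~qtl,     ~chrom, ~pos_cM, ~a_F,  ~a_M,  ~d,
    "qLA1-1",  1,      18,     -0.74,  0.43,  0.27,
    "qLA1-2",  1,      98,     -1.06,  0.53,  0.16,
    "qLA1-3",  1,     144,     -1.28,  0.18,  0.04,
    "qLA2-1",  2,      17,     -1.12, -0.02,  0.28,
    "qLA2-2",  2,      23,     -0.05, -1.54,  0.20,
    "qLA2-3",  2,      79,     -0.29,  1.23,  0.11,
    "qLA4-1",  4,      70,     -1.07,  1.40, -0.14,
    "qLA4-2",  4,      89,     -1.14,  0.28, -0.18,
    "qLA5-1",  5,      66,      0.04,  1.34, -0.01,
    "qLA7-1",  7,      94,     -1.37,  0.07, -0.06,
    "qLA7-2",  7,     124,      0.11, -0.89, -0.06,
    "qLA8-1",  8,      19,      0.23, -0.98,  0.07,
    "qLA8-2",  8,      67,      1.46, -0.52, -0.22,
    "qLA9-1",  9,      47,      0.17, -1.08, -0.03
  )
  if (is.null(map)) map <- sim_map(seed = 1)
  chr_end <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(end = max(.data$pos_cM), .groups = "drop")
  eff <- eff |>
    dplyr::left_join(chr_end, by = "chrom") |>
    dplyr::mutate(pos_cM = pmin(.data$pos_cM, .data$end)) |>
    dplyr::select(-"end")
  if (!is.null(sigma2_g)) {
    v0 <- expected_genetic_variance(eff, map_function = map_function)
    s <- sqrt(sigma2_g / v0)
    eff <- dplyr::mutate(eff, a_F = .data$a_F * s, a_M = .data$a_M * s,
                         d = .data$d * s)
  }
  eff
}

#' Closed-form genetic variance of selfed-family means under a QTL set
#'
#' For lines from a four-way cross scored as selfed-family means, each QTL
#' contributes `a_F*x_F + a_M*x_M + (d/2)*x_F*x_M` with `x_F, x_M = +/-1`
#' equally likely and independent across the two meioses. Between two linked
#' QTL with recombination fraction `r`, `E(x x') = 1 - 2r`, so the variance is
#' the sum of per-QTL terms `a_F^2 + a_M^2 + (d/2)^2` plus linkage
#' covariances `2[a_F a_F' rho + a_M a_M' rho + (d/2)(d'/2) rho^2]` with
#' `rho = 1 - 2r` from the map distance between the QTL.
#'
#' @param qtl Tibble with columns `chrom`, `pos_cM`, `a_F`, `a_M`, `d`.
#' @param map_function Map function converting cM gaps to `r`.
#' @return The genetic variance (squared trait units).
#' @export
expected_genetic_variance <- function(qtl, map_function = "haldane") {
  v <- sum(qtl$a_F^2 + qtl$a_M^2 + (qtl$d / 2)^2)
  if (nrow(qtl) > 1) {
    for (i in seq_len(nrow(qtl) - 1)) {
      for (j in (i + 1):nrow(qtl)) {
        if (qtl$chrom[i] != qtl$chrom[j]) next
        rho <- 1 - 2 * map_rf(abs(qtl$pos_cM[i] - qtl$pos_cM[j]), map_function)
        v <- v + 2 * (qtl$a_F[i] * qtl$a_F[j] * rho +
                      qtl$a_M[i] * qtl$a_M[j] * rho +
                      (qtl$d[i] / 2) * (qtl$d[j] / 2) * rho^2)
      }
    }
  }
  v
}

#' Simulate one gamete from a phased diploid along a chromosome
#'
#' Meiosis without interference: the transmitted haplotype starts from either
#' parental strand with probability 1/2 and switches strands between adjacent
#' loci independently, with probability equal to the recombination fraction
#' implied by the interval length under the chosen map function.
#'
#' @param haplotypes A 2 x m matrix (rows = the two parental strands,
#'   columns = loci in map order) of allele labels.
#' @param pos_cM Numeric vector of locus positions, strictly increasing.
#' @param map_function Map function for interval lengths.
#'
#' @return A vector of m transmitted alleles. Uses the current RNG state.
#' @examples
#' set.seed(42)
#' simulate_gamete(rbind(rep("A", 5), rep("B", 5)), seq(0, 40, by = 10))
#' @export
simulate_gamete <- function(haplotypes, pos_cM, map_function = "haldane") {
  m <- length(pos_cM)
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) == 2, ncol(haplotypes) == m)
  if (m > 1 && any(diff(pos_cM) <= 0)) {
    stop("locus positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  r <- if (m > 1) map_rf(diff(pos_cM), map_function) else numeric(0)
  start <- sample.int(2L, 1L)
  switches <- stats::runif(m - 1) < r
  strand <- (cumsum(c(start - 1L, switches))) %% 2L + 1L
  haplotypes[cbind(strand, seq_len(m))]
}

#' Expected selfed-family mean of a heterozygous F1 at one locus
#'
#' Selfing a heterozygote gives progeny genotypes in a 1:2:1 ratio with
#' genotypic values `mu + a`, `mu + d`, `mu - a`, so the family mean is
#' `0.25(mu + a) + 0.5(mu + d) + 0.25(mu - a) = mu + 0.5 d`: the additive
#' effect survives intact in expectation while the dominance effect is
#' halved. This is why family-mean phenotypes of a four-way cross estimate
#' `d/2` rather than `d` unless the coding compensates.
#'
#' @param mu Mid-parent value (trait units).
#' @param a Additive effect.
#' @param d Dominance effect.
#' @return `mu + 0.5 * d`, computed through the 1:2:1 enumeration.
#' @examples
#' selfed_family_mean(0, 5, 4)   # 2
#' @export
selfed_family_mean <- function(mu, a, d) {
  0.25 * (mu + a) + 0.5 * (mu + d) + 0.25 * (mu - a)
}

#' Simulate a four-way cross population with phenotypes
#'
#' Generates `n` four-way F1 individuals by simulating one meiosis in the
#' A x B single-cross F1 (transmitting A or B at each locus) and one in the
#' C x D F1 (transmitting C or D), with QTL carried as extra loci on the same
#' gametes. Phenotypes are simulated at the selfed-family-mean scale the
#' analysis sees: the genetic value of line i is
#' `mu + sum_q [a_F x_F + a_M x_M + (d/2) x_F x_M]` (dominance pre-halved by
#' the 1:2:1 selfing argument), and the plot value for (line, environment,
#' replicate) adds a fixed environment effect, a genotype-by-environment
#' deviation with variance `sigma2_ge`, and residual noise with variance
#' `sigma2_e`. Observed marker codes are the category-collapsed classes with
#' missing values inserted uniformly at random.
#'
#' @param map Genetic map from [sim_map()] (or same layout).
#' @param qtl Tibble of true QTL (`chrom`, `pos_cM`, `a_F`, `a_M`, `d`), or
#'   `NULL` for a null population.
#' @param n Number of lines.
#' @param n_env,n_rep Environments and replicates per environment.
#' @param mu Population mean (trait units).
#' @param env_effects Fixed environment offsets (length `n_env`); default
#'   spreads `+/-5.1` trait units across environments, emulating the two
#'   study locations.
#' @param sigma2_ge,sigma2_e Genotype-by-environment and residual (plot)
#'   variances.
#' @param missing_rate Probability an observed genotype call is missing.
#' @param map_function Map function for meiosis.
#' @param seed Integer seed; mandatory so the population is reproducible.
#'
#' @return An object of class `fourway_pop`: a list with tibbles `map`,
#'   `qtl`, `genotypes` (line x marker observed codes, wide), `latent`
#'   (line x marker true genotypes, wide), `qtl_genotypes`, `genetic_values`
#'   (`line`, `g`), `phenotypes` (long: `line`, `env`, `rep`, `value`), and
#'   the simulation parameters.
#'
#' @examples
#' pop <- sim_cross(sim_map(seed = 1), study_qtl_effects(29.0), n = 50, seed = 7)
#' pop$phenotypes
#' @export
sim_cross <- function(map, qtl = NULL, n = 277, n_env = 2, n_rep = 3,
                      mu = 33.2, env_effects = NULL,
                      sigma2_ge = 5.1, sigma2_e = 10.7,
                      missing_rate = 0.02, map_function = "haldane",
                      seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to simulate a population", call. = FALSE)
  }
  stopifnot(n >= 2, n_env >= 1, n_rep >= 1,
            sigma2_ge >= 0, sigma2_e >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(qtl) && nrow(qtl) > 0) {
    chr_rng <- map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(lo = min(.data$pos_cM), hi = max(.data$pos_cM),
                       .groups = "drop")
    chk <- dplyr::left_join(qtl, chr_rng, by = "chrom")
    if (any(is.na(chk$lo)) || any(chk$pos_cM < chk$lo | chk$pos_cM > chk$hi)) {
      stop("QTL positions must lie within the map", call. = FALSE)
    }
  }
  if (is.null(env_effects)) {
    env_effects <- if (n_env == 1) 0 else seq(-5.1, 5.1, length.out = n_env)
  }
  stopifnot(length(env_effects) == n_env)
  set.seed(seed)

  qtl <- if (is.null(qtl)) tibble::tibble(qtl = character(), chrom = integer(),
                                          pos_cM = numeric(), a_F = numeric(),
                                          a_M = numeric(), d = numeric())
         else qtl
  if (!"qtl" %in% names(qtl)) {
    qtl <- dplyr::mutate(qtl, qtl = sprintf("Q%d", dplyr::row_number()),
                         .before = 1)
  }

  # per chromosome: merge marker and QTL loci, simulate both meioses
  chroms <- unique(map$chrom)
  pat <- matrix(NA_character_, n, nrow(map))  # A/B per marker
  mat <- matrix(NA_character_, n, nrow(map))  # C/D per marker
  qpat <- matrix(NA_character_, n, nrow(qtl))
  qmat <- matrix(NA_character_, n, nrow(qtl))
  for (ch in chroms) {
    mk_idx <- which(map$chrom == ch)
    q_idx <- which(qtl$chrom == ch)
    pos <- c(map$pos_cM[mk_idx], qtl$pos_cM[q_idx])
    # jitter exact ties between a QTL and a marker by an epsilon offset
    ord <- order(pos)
    pos_s <- pos[ord]
    dup <- which(diff(pos_s) <= 0)
    while (length(dup)) {
      pos_s[dup + 1] <- pos_s[dup] + 1e-6
      dup <- which(diff(pos_s) <= 0)
    }
    is_marker <- c(rep(TRUE, length(mk_idx)), rep(FALSE, length(q_idx)))[ord]
    hapAB <- rbind(rep("A", length(pos_s)), rep("B", length(pos_s)))
    hapCD <- rbind(rep("C", length(pos_s)), rep("D", length(pos_s)))
    for (i in seq_len(n)) {
      gp <- simulate_gamete(hapAB, pos_s, map_function)
      gm <- simulate_gamete(hapCD, pos_s, map_function)
      pat[i, mk_idx] <- gp[is_marker][order(order(map$pos_cM[mk_idx]))]
      mat[i, mk_idx] <- gm[is_marker][order(order(map$pos_cM[mk_idx]))]
      if (length(q_idx)) {
        qpat[i, q_idx] <- gp[!is_marker][order(order(qtl$pos_cM[q_idx]))]
        qmat[i, q_idx] <- gm[!is_marker][order(order(qtl$pos_cM[q_idx]))]
      }
    }
  }
  latent <- matrix(paste0(pat, mat), n, nrow(map))
  colnames(latent) <- map$marker
  observed <- vapply(seq_len(nrow(map)), function(j) {
    collapse_observed(map$category[j], latent[, j])
  }, character(n))
  colnames(observed) <- map$marker
  if (missing_rate > 0) {
    observed[matrix(stats::runif(length(observed)) < missing_rate,
                    nrow(observed))] <- NA_character_
  }

  line_id <- sprintf("L%03d", seq_len(n))
  g <- rep(mu, n)
  if (nrow(qtl) > 0) {
    xF <- ifelse(qpat == "A", 1, -1)
    xM <- ifelse(qmat == "C", 1, -1)
    g <- g + as.vector(xF %*% qtl$a_F + xM %*% qtl$a_M +
                       (xF * xM) %*% (qtl$d / 2))
  }
  ge <- matrix(stats::rnorm(n * n_env, 0, sqrt(sigma2_ge)), n, n_env)
  pheno <- tidyr::expand_grid(line = line_id, env = sprintf("E%d", seq_len(n_env)),
                              rep = seq_len(n_rep)) |>
    dplyr::mutate(
      value = g[match(.data$line, line_id)] +
        env_effects[match(.data$env, sprintf("E%d", seq_len(n_env)))] +
        ge[cbind(match(.data$line, line_id),
                 match(.data$env, sprintf("E%d", seq_len(n_env))))] +
        stats::rnorm(dplyr::n(), 0, sqrt(sigma2_e))
    )

  structure(list(
    map = map,
    qtl = qtl,
    genotypes = dplyr::bind_cols(tibble::tibble(line = line_id),
                                 tibble::as_tibble(observed)),
    latent = dplyr::bind_cols(tibble::tibble(line = line_id),
                              tibble::as_tibble(latent)),
    qtl_genotypes = if (nrow(qtl) > 0) {
      qg <- matrix(paste0(qpat, qmat), n, nrow(qtl))
      colnames(qg) <- qtl$qtl
      dplyr::bind_cols(tibble::tibble(line = line_id), tibble::as_tibble(qg))
    } else tibble::tibble(line = line_id),
    genetic_values = tibble::tibble(line = line_id, g = g),
    phenotypes = pheno,
    params = list(n = n, n_env = n_env, n_rep = n_rep, mu = mu,
                  env_effects = env_effects, sigma2_ge = sigma2_ge,
                  sigma2_e = sigma2_e, missing_rate = missing_rate,
                  map_function = map_function, seed = seed)
  ), class = "fourway_pop")
}

#' @export
print.fourway_pop <- function(x, ...) {
  cat("Four-way cross population: ", x$params$n, " lines, ",
      nrow(x$map), " markers on ", length(unique(x$map$chrom)),
      " chromosomes, ", nrow(x$qtl), " QTL\n", sep = "")
  cat("Phenotypes: ", x$params$n_env, " environment(s) x ",
      x$params$n_rep, " replicate(s)\n", sep = "")
  invisible(x)
}
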