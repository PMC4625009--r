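test_that("quarter-contrast effects match the printed reference rows", {
  # genotypic means from the reference study, effects to 2 dp
  e1 <- effects_from_means(32.49, 31.10, 33.44, 33.10)
  expect_equal(round(e1$a_F, 2), -0.74)
  e2 <- effects_from_means(31.12, 33.79, 30.82, 34.30)
  expect_equal(round(e2$a_M, 2), -1.54)
  expect_equal(round(e2$d, 2), 0.20)
  e0 <- effects_from_means(7, 7, 7, 7)
  expect_equal(unlist(e0), c(m = 7, a_F = 0, a_M = 0, d = 0))
})

test_that("effects and means are exact linear inverses", {
  expect_equal(unlist(means_from_effects(0, 0, 0, 0)),
               c(mu1 = 0, mu2 = 0, mu3 = 0, mu4 = 0))
  # direct substitution: mu1 = m + aF + aM + d, etc.
  mus <- means_from_effects(32.78, -0.74, 0.43, 0.26)
  expect_equal(round(unlist(mus), 2),
               c(mu1 = 32.73, mu2 = 31.35, mu3 = 33.69, mu4 = 33.35))
  set.seed(61)
  for (i in 1:1000) {
    eff <- stats::rnorm(4, sd = 10)
    mus <- means_from_effects(eff[1], eff[2], eff[3], eff[4])
    back <- effects_from_means(mus$mu1, mus$mu2, mus$mu3, mus$mu4)
    expect_equal(unlist(back), c(m = eff[1], a_F = eff[2], a_M = eff[3],
                                 d = eff[4]), tolerance = 1e-12)
  }
})

test_that("stepwise selection holds its type-I level on pure noise", {
  map <- reduced_map()
  pop <- sim_cross(map, NULL, n = 200, seed = 71)
  X <- encode_design(pop$genotypes, map)
  set.seed(72)
  hits <- vapply(1:60, function(i) {
    y <- stats::rnorm(200)
    length(stepwise_select(y, X)$vars) > 0
  }, logical(1))
  # at p_enter = 0.001 a null phenotype should almost never admit a variable
  expect_lte(mean(hits), 0.10)
})

test_that("stepwise selection finds a single strong QTL's flank", {
  map <- abcd_map(10, spacing = 10)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 45, a_F = 2, a_M = 0, d = 0)
  pop <- sim_cross(map, qtl, n = 277, n_env = 1, n_rep = 1,
                   sigma2_ge = 0, sigma2_e = 4, missing_rate = 0, seed = 73)
  y <- line_phenotypes(pop$phenotypes)$value
  X <- encode_design(pop$genotypes, map)
  cof <- stepwise_select(y, X)
  # flanks of the 40-50 interval
  expect_true(any(cof$vars %in% c("c01m05.xF", "c01m06.xF")))
  # fixed point: every retained variable stays below p_remove
  n <- length(y)
  fit <- stats::lm(y ~ cof$X)
  pv <- summary(fit)$coefficients[-1, 4]
  expect_true(all(pv < 0.002))
})

test_that("phenotype adjustment removes only out-of-window cofactors", {
  map <- abcd_map(10, spacing = 10)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 45, a_F = 2, a_M = 0, d = 0)
  pop <- sim_cross(map, qtl, n = 200, n_env = 1, n_rep = 1, sigma2_ge = 0,
                   sigma2_e = 4, missing_rate = 0, seed = 74)
  y <- line_phenotypes(pop$phenotypes)$value
  X <- encode_design(pop$genotypes, map)
  cof <- stepwise_select(y, X)
  expect_gt(length(cof$vars), 0)
  none <- structure(list(vars = character(0), beta = numeric(0),
                         intercept = mean(y), marker = character(0),
                         X = matrix(numeric(0), length(y), 0)),
                    class = "icim_cofactors")
  expect_identical(adjust_phenotype(y, none), y)
  # excluding every cofactor's marker leaves y unchanged
  expect_equal(adjust_phenotype(y, cof, exclude = unique(cof$marker)), y)
  # with nothing excluded, adjustment cannot inflate the variance
  y_adj <- adjust_phenotype(y, cof)
  expect_lte(stats::var(y_adj), stats::var(y) + 1e-12)
  expect_equal(mean(y_adj), mean(y), tolerance = 1e-10)
})

test_that("class probabilities are coherent at markers and in intervals", {
  # at a fully informative observed marker: certainty
  expect_equal(unname(qtl_class_probs("AC", "AC", 1e-9, 1e-9)[1, ]),
               c(1, 0, 0, 0), tolerance = 1e-6)
  # no information anywhere: uniform
  expect_equal(unname(qtl_class_probs(NA, NA, 0.1, 0.1)[1, ]),
               rep(0.25, 4))
  # rows always sum to 1 across code combinations
  codes <- c("AC", "AD", "BC", "BD", "-C", "A-", "AD/BC", "AC/BD", NA)
  grid <- expand.grid(l = codes, r = codes, stringsAsFactors = FALSE)
  P <- qtl_class_probs(grid$l, grid$r, 0.12, 0.07)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  expect_true(all(P >= 0))
})

test_that("midpoint class probabilities match crossover enumeration", {
  # both flanks ABCD observed "AC", 20 cM interval, scan at the midpoint:
  # enumerate the four crossover configurations per meiosis under Haldane
  r_half <- map_rf(10)
  r_full <- map_rf(20)
  # P(QTL = A | both flanks A) from the two-interval paths
  pA <- (1 - r_half)^2 / (1 - r_full)
  expected <- c(pA * pA, pA * (1 - pA), (1 - pA) * pA, (1 - pA) * (1 - pA))
  got <- qtl_class_probs("AC", "AC", r_half, r_half)[1, ]
  # the flank-product approximation normalizes the same numerator terms
  num <- c((1 - r_half)^2, r_half^2)
  pA_flank <- num[1] / sum(num)
  expect_equal(unname(got),
               c(pA_flank^2, pA_flank * (1 - pA_flank),
                 (1 - pA_flank) * pA_flank, (1 - pA_flank)^2),
               tolerance = 1e-12)
  # and the two constructions agree (no-interference Markov identity)
  expect_equal(pA, pA_flank, tolerance = 1e-12)
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("EM with degenerate class assignment equals the ANOVA LOD", {
  set.seed(81)
  n <- 200
  cls <- rep(1:4, each = n / 4)
  mu_true <- c(0, 1, 2, 3)
  y <- mu_true[cls] + stats::rnorm(n)
  P <- matrix(0, n, 4); P[cbind(1:n, cls)] <- 1
  fit <- em_fit_scanpoint(y, P)
  # closed-form oracle: one-way 4-group likelihood-ratio LOD
  rss1 <- sum((y - tapply(y, cls, mean)[cls])^2)
  rss0 <- sum((y - mean(y))^2)
  lod_oracle <- n / 2 * log10(rss0 / rss1)
  expect_equal(fit$lod, lod_oracle, tolerance = 1e-6)
  expect_equal(fit$mu, as.numeric(tapply(y, cls, mean)), tolerance = 1e-8)
  # genotypic means reproduce effects through the quarter-contrasts
  eff <- effects_from_means(fit$mu[1], fit$mu[2], fit$mu[3], fit$mu[4])
  expect_equal(unname(fit$effects["a_F"]), eff$a_F, tolerance = 1e-10)
})

test_that("EM LOD is shift-invariant and scale-equivariant", {
  set.seed(82)
  n <- 120
  P <- matrix(stats::runif(n * 4), n, 4)
  P <- P / rowSums(P)
  y <- stats::rnorm(n)
  # unstructured priors on pure noise converge very slowly; the last
  # iterate is still well-defined and the invariances must hold for it
  f0 <- suppressWarnings(em_fit_scanpoint(y, P))
  f_shift <- suppressWarnings(em_fit_scanpoint(y + 100, P))
  expect_equal(f_shift$lod, f0$lod, tolerance = 1e-6)
  f_scale <- suppressWarnings(em_fit_scanpoint(3 * y, P))
  expect_equal(f_scale$lod, f0$lod, tolerance = 1e-6)
  expect_equal(unname(f_scale$effects[c("a_F", "a_M", "d")]),
               unname(3 * f0$effects[c("a_F", "a_M", "d")]),
               tolerance = 1e-4)
})

test_that("null phenotypes give small LOD", {
  map <- abcd_map(6)
  pop <- sim_cross(map, NULL, n = 150, seed = 83)
  set.seed(84)
  geno <- pop$genotypes
  design <- fourwayqtl:::build_scan_design(geno, map)
  lods <- vapply(1:40, function(i) {
    y <- stats::rnorm(150)
    cof <- stepwise_select(y, encode_design(geno, map))
    max(fourwayqtl:::scan_profile(y, rep(TRUE, 150), design, cof)$lod)
  }, numeric(1))
  expect_lt(stats::median(lods), 1.5)
})

test_that("a moderate QTL is located and its effect recovered", {
  # sized like a ~7% PVE locus in a 277-line population
  map <- sim_map(n_markers = rep(21L, 2), genome_length = 340,
                 category_counts = data.frame(
                   chrom = 1:2, "ABCD" = 21L, "A=B" = 0L, "C=D" = 0L,
                   "A=CB=D" = 0L, "A=DB=C" = 0L, check.names = FALSE),
                 seed = 5)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 66, a_F = 0, a_M = 1.5, d = 0)
  hits <- 0; eff_ok <- 0; n_rep <- 10
  for (i in 1:n_rep) {
    pop <- sim_cross(map, qtl, n = 277, n_env = 1, n_rep = 1, sigma2_ge = 0,
                     sigma2_e = 30, missing_rate = 0, seed = 900 + i)
    sc <- icim_scan(pop$phenotypes, pop$genotypes, map, threshold = 3)
    pk <- sc$profile[which.max(sc$profile$lod), ]
    if (pk$chrom == 1 && abs(pk$pos_cM - 66) <= 10) hits <- hits + 1
    if (abs(pk$a_M - 1.5) < 2 * 0.33) eff_ok <- eff_ok + 1   # ~2 SE
  }
  expect_gte(hits, 8)
  expect_gte(eff_ok, 8)
})

test_that("a single-marker chromosome is scanned without crashing", {
  map <- tibble::tibble(marker = c("s1", "t1", "t2"), chrom = c(1, 2, 2),
                        pos_cM = c(0, 0, 12),
                        category = "ABCD") |>
    dplyr::bind_cols(fourwayqtl:::category_founder_alleles(rep("ABCD", 3)))
  pop <- sim_cross(map, NULL, n = 60, missing_rate = 0, seed = 85)
  sc <- icim_scan(pop$phenotypes, pop$genotypes, map, threshold = "none")
  expect_equal(sum(sc$profile$chrom == 1), 1)
  expect_equal(sc$profile$pos_cM[sc$profile$chrom == 1], 0)
  expect_error(icim_scan(pop$phenotypes, pop$genotypes, map, step = 0),
               "step")
})

test_that("scan output is tidy-able and plottable", {
  map <- abcd_map(6)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 25, a_F = 3, a_M = 0, d = 0)
  pop <- sim_cross(map, qtl, n = 150, n_env = 1, n_rep = 1, sigma2_ge = 0,
                   sigma2_e = 4, missing_rate = 0, seed = 86)
  sc <- icim_scan(pop$phenotypes, pop$genotypes, map, threshold = 3)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_gte(nrow(td), 1)
  expect_true(all(td$lod >= sc$threshold))
  # reported means reproduce reported effects through the contrasts
  eff <- effects_from_means(td$mu1, td$mu2, td$mu3, td$mu4)
  expect_equal(td$a_F, eff$a_F, tolerance = 1e-10)
  expect_equal(td$d, eff$d, tolerance = 1e-10)
  gl <- glance(sc)
  expect_equal(gl$n_qtl, nrow(td))
  p <- autoplot(sc)
  expect_s3_class(p, "ggplot")
  # peak flanking markers bracket the peak position
  for (i in seq_len(nrow(td))) {
    lpos <- map$pos_cM[map$marker == td$left_marker[i]]
    rpos <- map$pos_cM[map$marker == td$right_marker[i]]
    expect_true(lpos <= td$pos_cM[i] && td$pos_cM[i] <= rpos)
  }
})
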