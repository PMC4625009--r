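test_that("gamete simulation reproduces the inverse map function", {
  hap <- rbind(rep("A", 2), rep("B", 2))
  pos <- c(0, 10)
  set.seed(101)
  rec <- mean(replicate(10000, {
    g <- simulate_gamete(hap, pos)
    g[1] != g[2]
  }))
  r_true <- 0.5 * (1 - exp(-0.2))   # Haldane inverse of 10 cM
  se <- sqrt(r_true * (1 - r_true) / 10000)
  expect_lt(abs(rec - r_true), 3 * se)
  expect_error(simulate_gamete(hap, c(10, 0)), "increasing")
})

test_that("alleles on different chromosomes are inherited independently", {
  map2 <- tibble::tibble(marker = c("x1", "y1"), chrom = c(1, 2),
                         pos_cM = c(0, 0), category = "ABCD") |>
    dplyr::bind_cols(fourwayqtl:::category_founder_alleles(c("ABCD", "ABCD")))
  pop <- sim_cross(map2, NULL, n = 4000, n_env = 1, n_rep = 1,
                   missing_rate = 0, seed = 7)
  pat1 <- substr(pop$latent$x1, 1, 1)
  pat2 <- substr(pop$latent$y1, 1, 1)
  rec <- mean(pat1 != pat2)
  expect_lt(abs(rec - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("selfing a heterozygote halves the dominance effect exactly", {
  # 1:2:1 enumeration oracle, independent of the implementation
  enum_mean <- function(mu, a, d) mean(c(mu + a, mu + d, mu + d, mu - a))
  grid <- expand.grid(mu = c(-10, 0, 10), a = c(-3, 0, 5), d = c(-4, 0, 4))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      expect_identical(selfed_family_mean(mu, a, d), enum_mean(mu, a, d))
      expect_identical(selfed_family_mean(mu, a, d), mu + 0.5 * d)
    })
  }
  expect_equal(selfed_family_mean(10, 3, 0), 10)
  expect_equal(selfed_family_mean(0, 5, 4), 2)
})

test_that("genetic variance of family means follows the variance algebra", {
  # unlinked QTL on separate chromosomes: Vg = sum aF^2 + aM^2 + (d/2)^2
  cc <- data.frame(chrom = 1:3, "ABCD" = 2L, "A=B" = 0L, "C=D" = 0L,
                   "A=CB=D" = 0L, "A=DB=C" = 0L, check.names = FALSE)
  map <- sim_map(n_markers = rep(2L, 3), genome_length = 30,
                 category_counts = cc, seed = 1)
  qtl <- tibble::tibble(chrom = 1:3, pos_cM = 5,
                        a_F = c(2, -1, 0.5), a_M = c(1, 0.8, -1.2),
                        d = c(1, -0.6, 0.4))
  v_expected <- sum(qtl$a_F^2 + qtl$a_M^2 + (qtl$d / 2)^2)
  expect_equal(expected_genetic_variance(qtl), v_expected)
  pop <- sim_cross(map, qtl, n = 10000, n_env = 1, n_rep = 1,
                   sigma2_ge = 0, sigma2_e = 1, missing_rate = 0, seed = 42)
  v_emp <- stats::var(pop$genetic_values$g)
  expect_lt(abs(v_emp - v_expected) / v_expected, 0.05)
})

test_that("linked QTL add covariance through the map function", {
  qtl <- tibble::tibble(chrom = c(1, 1), pos_cM = c(0, 50),
                        a_F = c(1, 1), a_M = c(0, 0), d = c(0, 0))
  rho <- 1 - 2 * map_rf(50)
  expect_equal(expected_genetic_variance(qtl), 2 + 2 * rho)
})

test_that("observed codes are the collapsed latent genotypes with masking", {
  map <- reduced_map()
  pop <- sim_cross(map, NULL, n = 60, missing_rate = 0.1, seed = 13)
  for (mk in sample(map$marker, 5)) {
    ct <- map$category[map$marker == mk]
    expected <- collapse_observed(ct, pop$latent[[mk]])
    obs <- pop$genotypes[[mk]]
    ok <- !is.na(obs)
    expect_equal(obs[ok], expected[ok])
  }
  miss <- mean(is.na(as.matrix(pop$genotypes[, map$marker])))
  expect_lt(abs(miss - 0.1), 0.02)
})

test_that("a fixed seed reproduces the population bit for bit", {
  map <- abcd_map(5)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 15, a_F = 1, a_M = 0.5, d = 0.2)
  p1 <- sim_cross(map, qtl, n = 40, seed = 99)
  p2 <- sim_cross(map, qtl, n = 40, seed = 99)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$phenotypes, p2$phenotypes)
  p3 <- sim_cross(map, qtl, n = 40, seed = 100)
  expect_false(identical(p1$phenotypes, p3$phenotypes))
  expect_error(sim_cross(map, qtl, n = 40), "seed")
})

test_that("QTL outside the map and bad configs are rejected", {
  map <- abcd_map(5)
  qtl <- tibble::tibble(chrom = 1, pos_cM = 100, a_F = 1, a_M = 0, d = 0)
  expect_error(sim_cross(map, qtl, n = 40, seed = 1), "within the map")
  expect_error(sim_cross(map, NULL, n = 1, seed = 1))
})

test_that("the study QTL set is rescaled to the target genetic variance", {
  qtl <- study_qtl_effects(sigma2_g = 29.0)
  expect_equal(expected_genetic_variance(qtl), 29.0, tolerance = 1e-8)
  expect_equal(nrow(qtl), 14)
  raw <- study_qtl_effects(sigma2_g = NULL)
  # rescaling preserves relative effect sizes
  expect_equal(qtl$a_F / raw$a_F, rep(qtl$a_F[1] / raw$a_F[1], 14))
})
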