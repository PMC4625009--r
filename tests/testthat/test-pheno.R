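balanced_pheno <- function(g, e, r, env_eff = NULL, ge = NULL, noise = NULL) {
  n <- length(g)
  if (is.null(env_eff)) env_eff <- rep(0, e)
  if (is.null(ge)) ge <- matrix(0, n, e)
  tidyr::expand_grid(line = sprintf("L%03d", seq_len(n)),
                     env = sprintf("E%d", seq_len(e)), rep = seq_len(r)) |>
    dplyr::mutate(
      value = g[match(line, sprintf("L%03d", seq_len(n)))] +
        env_eff[match(env, sprintf("E%d", seq_len(e)))] +
        ge[cbind(match(line, sprintf("L%03d", seq_len(n))),
                 match(env, sprintf("E%d", seq_len(e))))] +
        (if (is.null(noise)) 0 else noise)
    )
}

test_that("noise-free balanced data recover the genotypic variance exactly", {
  set.seed(111)
  g <- stats::rnorm(50, 30, 4)
  ph <- balanced_pheno(g, e = 2, r = 3, env_eff = c(-2, 2))
  vc <- anova_components(ph)
  # population (MS-based) genotypic variance of the g draw
  expect_equal(vc$sigma2_g, stats::var(g), tolerance = 1e-8)
  expect_equal(vc$sigma2_ge, 0, tolerance = 1e-8)
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-8)
})

test_that("ANOVA sums of squares add to the total in the balanced case", {
  set.seed(112)
  g <- stats::rnorm(40, 0, 3)
  ge <- matrix(stats::rnorm(80, 0, 1.5), 40, 2)
  ph <- balanced_pheno(g, 2, 3, env_eff = c(-1, 1), ge = ge,
                       noise = stats::rnorm(240, 0, 2))
  fit <- stats::aov(value ~ env + env:rep + line + env:line,
                    data = dplyr::mutate(ph, dplyr::across(c(line, env, rep),
                                                           factor)))
  tab <- summary(fit)[[1]]
  total <- sum((ph$value - mean(ph$value))^2)
  expect_equal(sum(tab[["Sum Sq"]]), total, tolerance = 1e-8 * total)
})

test_that("calibrated simulation recovers the study variance components", {
  map <- reduced_map()
  qtl <- tibble::tibble(chrom = 1:2, pos_cM = c(40, 60),
                        a_F = c(2.6, 2.0), a_M = c(2.2, -2.4), d = c(0.5, -0.5))
  vg <- expected_genetic_variance(qtl)
  ests <- t(vapply(1:6, function(i) {
    pop <- sim_cross(map, qtl, n = 277, sigma2_ge = 5.1, sigma2_e = 10.7,
                     seed = 400 + i)
    vc <- anova_components(pop$phenotypes)
    c(vc$sigma2_g, vc$sigma2_ge, vc$sigma2_e, heritability(vc))
  }, numeric(4)))
  avg <- colMeans(ests)
  expect_lt(abs(avg[1] - vg) / vg, 0.15)
  expect_lt(abs(avg[2] - 5.1) / 5.1, 0.25)
  expect_lt(abs(avg[3] - 10.7) / 10.7, 0.10)
})

test_that("heritability follows the entry-mean formula", {
  expect_equal(round(heritability(29.0, 5.1, 10.7, e = 2, r = 3), 2), 0.87)
  expect_equal(heritability(10, 0, 0, e = 2, r = 3), 1)
  # strictly decreasing in the residual variance
  H <- vapply(c(0, 5, 10, 20, 40), function(s2e)
    heritability(29, 5.1, s2e, e = 2, r = 3), numeric(1))
  expect_true(all(diff(H) < 0))
  # single environment variant
  expect_equal(heritability(10, NA, 5, e = 1, r = 2), 10 / 12.5)
  expect_error(heritability(0, 0, 0, e = 2, r = 3), "undefined")
})

test_that("variance components tidy and glance into tibbles", {
  set.seed(113)
  g <- stats::rnorm(40, 0, 3)
  ph <- balanced_pheno(g, 2, 3, ge = matrix(stats::rnorm(80), 40, 2),
                       noise = stats::rnorm(240))
  vc <- anova_components(ph)
  td <- tidy(vc)
  expect_equal(td$component, c("sigma2_g", "sigma2_ge", "sigma2_e"))
  expect_true(all(!is.na(td$p_value[1:2])))
  gl <- glance(vc)
  expect_equal(gl$H, heritability(vc))
})

test_that("describe_phenotypes reports per-environment and combined stats", {
  ph <- tibble::tibble(line = rep(c("a", "b"), each = 4),
                       env = rep(rep(c("E1", "E2"), each = 2), 2),
                       rep = rep(1:2, 4),
                       value = c(10, 12, 20, 22, 14, 16, 24, 26))
  d <- describe_phenotypes(ph)
  expect_equal(d$env, c("E1", "E2", "combined"))
  expect_equal(d$mean, c(13, 23, 18))
  comb <- d[d$env == "combined", ]
  # range equals a brute-force scan of the line means
  lm_ <- c(mean(c(11, 21)), mean(c(15, 25)))
  expect_equal(c(comb$min, comb$max), range(lm_))
  expect_false(any(d$degenerate))
  one <- describe_phenotypes(tibble::tibble(line = "a", env = "E1",
                                            rep = 1, value = 5))
  expect_true(one$degenerate[1])
  expect_true(is.na(one$sd[1]))
})

test_that("normality test behaves as a Shapiro-Wilk wrapper should", {
  set.seed(114)
  # null: p-values roughly uniform
  pvals <- vapply(1:200, function(i) test_normality(stats::rnorm(277))$p_value,
                  numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  # power: heavy right skew is detected essentially always
  skewed <- vapply(1:50, function(i)
    test_normality(stats::rexp(277))$p_value, numeric(1))
  expect_gte(mean(skewed < 0.01), 0.99)
  expect_error(test_normality(rep(1, 10)), "identical")
  expect_error(test_normality(stats::rnorm(2)), "between")
})

test_that("NIL contrasts report the pair difference and its significance", {
  # the reference pair means: effect is their absolute difference
  pair <- tibble::tibble(line = rep(c("M02-1-1", "M02-1-2"), each = 3),
                         value = c(28.5, 28.5, 28.5, 47.5, 47.5, 47.5) +
                           rep(c(-0.3, 0, 0.3), 2))
  ct <- nil_contrast(pair, favorable_parent = "D276")
  expect_equal(ct$effect, 19.0, tolerance = 1e-10)
  expect_true(ct$significant)
  expect_equal(ct$favorable_parent, "D276")
  # identical samples: zero effect, not significant
  same <- tibble::tibble(line = rep(c("x", "y"), each = 3),
                         value = rep(c(1, 2, 3), 2))
  ct0 <- nil_contrast(same)
  expect_equal(ct0$effect, 0)
  expect_false(ct0$significant)
  # single replicate: effect only
  single <- tibble::tibble(line = c("x", "y"), value = c(10, 15))
  ct1 <- nil_contrast(single)
  expect_equal(ct1$effect, 5)
  expect_true(is.na(ct1$p_value))
  expect_error(nil_contrast(tibble::tibble(line = "x", value = 1)), "two lines")
})

test_that("a true 10-degree NIL difference is nearly always significant", {
  set.seed(115)
  hits <- vapply(1:100, function(i) {
    pair <- tibble::tibble(line = rep(c("p", "q"), each = 6),
                           value = c(stats::rnorm(6, 30, 2),
                                     stats::rnorm(6, 40, 2)))
    nil_contrast(pair)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
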