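#' Multi-environment ANOVA variance components
#'
#' Fits the fixed-effects model with environment, replicate within
#' environment, genotype (line) and genotype-by-environment terms to a
#' balanced long phenotype table, and extracts variance components by
#' equating observed to expected mean squares:
#' `sigma2_e = MS_error`, `sigma2_ge = (MS_ge - MS_error) / r`,
#' `sigma2_g = (MS_g - MS_ge) / (e * r)`, where `e` is the number of
#' environments and `r` the replicates per environment. Replicate (block)
#' variation is removed by the replicate-within-environment term and its
#' remainder folds into `MS_error`. Negative component estimates are
#' truncated at zero and flagged. F-tests use `MS_g / MS_ge` for genotype
#' and `MS_ge / MS_error` for the interaction. With a single environment
#' the model reduces to replicate + genotype and `sigma2_ge` is undefined.
#'
#' @param phenotypes Long tibble: `line`, `env`, `rep`, `value`.
#' @return An object of class `variance_components`: list with
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, `e`, `r`, `truncated` (which
#'   components were raised to 0), and `tests` (a tibble of F statistics
#'   and p-values).
#' @examples
#' pop <- sim_cross(sim_map(seed = 1), study_qtl_effects(29.0), n = 120, seed = 5)
#' vc <- anova_components(pop$phenotypes)
#' heritability(vc)
#' @export
anova_components <- function(phenotypes) {
  stopifnot(all(c("line", "env", "rep", "value") %in% names(phenotypes)))
  ph <- phenotypes[!is.na(phenotypes$value), ]
  ph$line <- factor(ph$line)
  ph$env <- factor(ph$env)
  ph$rep <- factor(ph$rep)
  e <- nlevels(ph$env)
  cell <- table(ph$line, ph$env)
  if (any(cell == 0)) {
    warning("unbalanced design: some lines are missing from an environment; ",
            "components are method-of-moments on sequential sums of squares",
            call. = FALSE)
  }
  r <- round(mean(cell[cell > 0]))

  if (e > 1) {
    fit <- stats::aov(value ~ env + env:rep + line + env:line, data = ph)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    ms <- stats::setNames(tab[["Mean Sq"]], rn)
    df <- stats::setNames(tab[["Df"]], rn)
    ms_g <- ms[["line"]]; ms_ge <- ms[["env:line"]]; ms_e <- ms[["Residuals"]]
    s2e <- ms_e
    s2ge <- (ms_ge - ms_e) / r
    s2g <- (ms_g - ms_ge) / (e * r)
    tests <- tibble::tibble(
      term = c("genotype", "genotype x environment"),
      statistic = c(ms_g / ms_ge, ms_ge / ms_e),
      df1 = c(df[["line"]], df[["env:line"]]),
      df2 = c(df[["env:line"]], df[["Residuals"]]),
      p_value = c(
        stats::pf(ms_g / ms_ge, df[["line"]], df[["env:line"]], lower.tail = FALSE),
        stats::pf(ms_ge / ms_e, df[["env:line"]], df[["Residuals"]], lower.tail = FALSE)
      )
    )
  } else {
    fit <- stats::aov(value ~ rep + line, data = ph)
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    ms <- stats::setNames(tab[["Mean Sq"]], rn)
    df <- stats::setNames(tab[["Df"]], rn)
    ms_g <- ms[["line"]]; ms_e <- ms[["Residuals"]]
    s2e <- ms_e
    s2ge <- NA_real_
    s2g <- (ms_g - ms_e) / r
    tests <- tibble::tibble(
      term = "genotype",
      statistic = ms_g / ms_e,
      df1 = df[["line"]], df2 = df[["Residuals"]],
      p_value = stats::pf(ms_g / ms_e, df[["line"]], df[["Residuals"]],
                          lower.tail = FALSE)
    )
  }
  truncated <- character(0)
  if (!is.na(s2g) && s2g < 0) { s2g <- 0; truncated <- c(truncated, "sigma2_g") }
  if (!is.na(s2ge) && s2ge < 0) { s2ge <- 0; truncated <- c(truncated, "sigma2_ge") }
  structure(list(sigma2_g = unname(s2g), sigma2_ge = unname(s2ge),
                 sigma2_e = unname(s2e), e = e, r = r,
                 truncated = truncated, tests = tests),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (e = %d, r = %d):\n", x$e, x$r))
  cat(sprintf("  sigma2_g  = %.3f\n  sigma2_ge = %s\n  sigma2_e  = %.3f\n",
              x$sigma2_g,
              if (is.na(x$sigma2_ge)) "-" else sprintf("%.3f", x$sigma2_ge),
              x$sigma2_e))
  if (length(x$truncated)) {
    cat("  (truncated at 0: ", paste(x$truncated, collapse = ", "), ")\n",
        sep = "")
  }
  cat(sprintf("  H = %.3f\n", heritability(x)))
  invisible(x)
}

#' Tidy variance components
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return A tibble with one row per component and the associated F-test
#'   where defined.
#' @exportS3Method generics::tidy
tidy.variance_components <- function(x, ...) {
  comp <- tibble::tibble(
    component = c("sigma2_g", "sigma2_ge", "sigma2_e"),
    estimate = c(x$sigma2_g, x$sigma2_ge, x$sigma2_e),
    truncated = c("sigma2_g", "sigma2_ge", "sigma2_e") %in% x$truncated
  )
  tests <- dplyr::bind_rows(
    dplyr::mutate(x$tests, component = c("sigma2_g", "sigma2_ge")[seq_len(nrow(x$tests))])
  )
  dplyr::left_join(comp, tests[, c("component", "statistic", "p_value")],
                   by = "component")
}

#' @rdname tidy.variance_components
#' @exportS3Method generics::glance
glance.variance_components <- function(x, ...) {
  tibble::tibble(sigma2_g = x$sigma2_g, sigma2_ge = x$sigma2_ge,
                 sigma2_e = x$sigma2_e, e = x$e, r = x$r,
                 H = heritability(x))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H = sigma2_g / (sigma2_g + sigma2_ge / e + sigma2_e / (e * r))` across
#' `e` environments with `r` replicates each; with a single environment the
#' interaction is not separable and `H = sigma2_g / (sigma2_g +
#' sigma2_e / r)`.
#'
#' @param components A `variance_components` object, or a numeric
#'   `sigma2_g` when the remaining arguments are given directly.
#' @param sigma2_ge,sigma2_e,e,r Components and design constants when not
#'   passing an object.
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(29.0, 5.1, 10.7, e = 2, r = 3)   # 0.87
#' @export
heritability <- function(components, sigma2_ge = NULL, sigma2_e = NULL,
                         e = NULL, r = NULL) {
  if (inherits(components, "variance_components")) {
    s2g <- components$sigma2_g; s2ge <- components$sigma2_ge
    s2e <- components$sigma2_e; e <- components$e; r <- components$r
  } else {
    s2g <- components; s2ge <- sigma2_ge; s2e <- sigma2_e
  }
  stopifnot(e >= 1, r >= 1)
  if (e == 1 || is.na(s2ge)) {
    denom <- s2g + s2e / r
  } else {
    denom <- s2g + s2ge / e + s2e / (e * r)
  }
  if (denom <= 0) {
    stop("all variance components are zero; heritability is undefined",
         call. = FALSE)
  }
  s2g / denom
}

#' Descriptive phenotype statistics per environment and combined
#'
#' Summarises line means (the entry-mean scale of the analysis): for each
#' environment, and combined across environments, the mean, standard
#' deviation, and range over lines. Groups with a single value get `NA`
#' standard deviation and are flagged.
#'
#' @param phenotypes Long tibble: `line`, `env`, `rep`, `value`.
#' @return A tibble: `env` (environment name or `"combined"`), `n_lines`,
#'   `mean`, `sd`, `min`, `max`, `degenerate`.
#' @export
describe_phenotypes <- function(phenotypes) {
  stopifnot(nrow(phenotypes) > 0)
  line_env <- phenotypes |>
    dplyr::group_by(line = .data$line, env = .data$env) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  per_env <- line_env |>
    dplyr::group_by(env = .data$env) |>
    dplyr::summarise(
      n_lines = dplyr::n(),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )
  comb <- line_env |>
    dplyr::group_by(line = .data$line) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  combined <- tibble::tibble(
    env = "combined", n_lines = nrow(comb),
    mean = mean(comb$value), sd = stats::sd(comb$value),
    min = min(comb$value), max = max(comb$value)
  )
  dplyr::bind_rows(per_env, combined) |>
    dplyr::mutate(degenerate = .data$n_lines < 2)
}

#' Shapiro-Wilk normality test for a phenotype vector
#'
#' Thin wrapper used to annotate scan reports: permutation thresholds
#' assume the shuffled phenotype is a plausible no-QTL sample, which fails
#' for clearly non-normal traits.
#'
#' @param values Numeric vector, `3 <= n <= 5000` after removing `NA`.
#' @return A tibble: `statistic` (W), `p_value`, `n`.
#' @examples
#' test_normality(rnorm(100))
#' @export
test_normality <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk test needs between 3 and 5000 values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("all values are identical; normality test is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  tibble::tibble(statistic = unname(sw$statistic),
                 p_value = sw$p.value, n = length(x))
}

#' Contrast a pair of near-isogenic lines at a target QTL
#'
#' The QTL effect in a NIL pair is the difference between the two line
#' means; significance comes from a two-sample t-test on the replicate
#' values, at the 0.01 level. The favorable-allele parent annotates the
#' direction (its allele decreases the trait).
#'
#' @param pair Tibble with columns `line` (exactly two distinct lines) and
#'   `value` (replicate measurements), plus optionally `qtl`.
#' @param favorable_parent Name of the parent carrying the favorable
#'   (trait-decreasing) allele.
#' @param alpha Significance level (default 0.01).
#' @return A one-row tibble: `qtl`, `favorable_parent`, line names and
#'   means, `effect` (absolute difference), `p_value`, `significant`.
#' @examples
#' pair <- tibble::tibble(line = rep(c("M02-1-1", "M02-1-2"), each = 3),
#'                        value = c(28.1, 28.6, 28.8, 47.2, 47.9, 47.4))
#' nil_contrast(pair, "D276")
#' @export
nil_contrast <- function(pair, favorable_parent = NA_character_,
                         alpha = 0.01) {
  stopifnot(all(c("line", "value") %in% names(pair)))
  lines <- unique(pair$line)
  if (length(lines) != 2) {
    stop("a NIL contrast needs exactly two lines, got ", length(lines),
         call. = FALSE)
  }
  v1 <- pair$value[pair$line == lines[1]]
  v2 <- pair$value[pair$line == lines[2]]
  eff <- abs(mean(v1) - mean(v2))
  if (length(v1) >= 2 && length(v2) >= 2 &&
      (stats::sd(v1) > 0 || stats::sd(v2) > 0)) {
    p <- stats::t.test(v1, v2)$p.value
  } else {
    p <- NA_real_
  }
  tibble::tibble(
    qtl = if ("qtl" %in% names(pair)) pair$qtl[1] else NA_character_,
    favorable_parent = favorable_parent,
    line_1 = lines[1], mean_1 = mean(v1),
    line_2 = lines[2], mean_2 = mean(v2),
    effect = eff, p_value = p,
    significant = !is.na(p) & p < alpha
  )
}
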