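#' Genetic effects from four-way genotypic means, and back
#'
#' In a four-way cross (A x B) x (C x D) the four QTL genotype classes AC,
#' AD, BC, BD have means `mu1..mu4`, and the genetic effects are defined as
#' quarter-contrasts: `a_F = (mu1 + mu2 - mu3 - mu4)/4` (additive effect of
#' the first single cross, A vs B), `a_M = (mu1 - mu2 + mu3 - mu4)/4`
#' (additive effect of the second single cross, C vs D), and
#' `d = (mu1 - mu2 - mu3 + mu4)/4` (dominance between the two single
#' crosses), with `m` the plain mean of the four. `means_from_effects()` is
#' the exact linear inverse: `mu1 = m + a_F + a_M + d`,
#' `mu2 = m + a_F - a_M - d`, `mu3 = m - a_F + a_M - d`,
#' `mu4 = m - a_F - a_M + d`.
#'
#' @param mu1,mu2,mu3,mu4 Genotypic means of classes AC, AD, BC, BD.
#' @param m,a_F,a_M,d Mean and genetic effects.
#' @return A tibble with columns `m`, `a_F`, `a_M`, `d` (or `mu1..mu4`).
#' @examples
#' effects_from_means(32.49, 31.10, 33.44, 33.10)   # a_F = -0.7375
#' means_from_effects(0, 1, 0.5, 0.25)
#' @export
effects_from_means <- function(mu1, mu2, mu3, mu4) {
  stopifnot(is.finite(mu1), is.finite(mu2), is.finite(mu3), is.finite(mu4))
  tibble::tibble(
    m   = (mu1 + mu2 + mu3 + mu4) / 4,
    a_F = (mu1 + mu2 - mu3 - mu4) / 4,
    a_M = (mu1 - mu2 + mu3 - mu4) / 4,
    d   = (mu1 - mu2 - mu3 + mu4) / 4
  )
}

#' @rdname effects_from_means
#' @export
means_from_effects <- function(m, a_F, a_M, d) {
  tibble::tibble(
    mu1 = m + a_F + a_M + d,
    mu2 = m + a_F - a_M - d,
    mu3 = m - a_F + a_M - d,
    mu4 = m - a_F - a_M + d
  )
}

#' Encode observed marker classes as regression design variables
#'
#' Builds the inclusive linear-model design used for background control:
#' for every marker, `xF` (+1 paternal A, -1 paternal B, 0 unobservable),
#' `xM` (+1 maternal C, -1 maternal D, 0) and the interaction `z = xF * xM`
#' adjusted so ambiguous classes carry their within-class expectation (see
#' the category coding in the package vignette). Under this coding the
#' regression coefficients on `xF`, `xM`, `z` of a fully informative marker
#' are exactly `a_F`, `a_M`, `d`.
#'
#' @param genotypes Wide genotype tibble (`line` plus marker columns).
#' @param map Genetic map tibble defining marker order and categories.
#' @return A numeric matrix (lines x 3 * markers) with columns named
#'   `<marker>.xF`, `<marker>.xM`, `<marker>.z` and attributes `marker`
#'   (marker of each column) and `line` (row order).
#' @export
encode_design <- function(genotypes, map) {
  stopifnot(all(map$marker %in% names(genotypes)))
  n <- nrow(genotypes)
  cols <- vector("list", nrow(map))
  for (j in seq_len(nrow(map))) {
    codes <- genotypes[[map$marker[j]]]
    valid <- observed_codes(map$category[j])
    bad <- setdiff(stats::na.omit(unique(codes)), valid)
    if (length(bad)) {
      stop("marker ", map$marker[j], " (category ", map$category[j],
           ") has invalid code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    xyz <- matrix(0, n, 3)
    ok <- !is.na(codes)
    if (any(ok)) {
      xyz[ok, ] <- do.call(rbind, DESIGN_CODE_TABLE[codes[ok]])
    }
    colnames(xyz) <- paste(map$marker[j], c("xF", "xM", "z"), sep = ".")
    cols[[j]] <- xyz
  }
  X <- do.call(cbind, cols)
  attr(X, "marker") <- rep(map$marker, each = 3)
  attr(X, "line") <- genotypes$line
  X
}

# least squares through QR; returns list(beta, rss, rank, qr)
fit_ls <- function(X, y) {
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  res <- qr.resid(qr_x, y)
  list(beta = beta, rss = sum(res^2), rank = qr_x$rank, qr = qr_x, resid = res)
}

#' Select background marker cofactors by stepwise regression
#'
#' Two-threshold stepwise selection on the encoded marker variables (each
#' marker's `xF`, `xM`, `z` enter independently): repeatedly add the
#' candidate with the smallest partial-F p-value while it is below
#' `p_enter`, then drop the selected variable with the largest partial-F
#' p-value while it is above `p_remove`, to a fixed point. Collinear
#' additions are skipped; if a selected variable becomes collinear its
#' later-entering member is dropped with a warning.
#'
#' @param y Phenotype vector (one value per line, `NA` dropped upstream).
#' @param design Design matrix from [encode_design()].
#' @param p_enter,p_remove Entry and removal probabilities (defaults 0.001
#'   and 0.002, the reference operating point).
#' @return An object of class `icim_cofactors`: list with `vars` (selected
#'   column names), `beta` (their joint least-squares coefficients),
#'   `intercept`, `marker` (marker of each selected variable), and `X`
#'   (the selected columns).
#' @export
stepwise_select <- function(y, design, p_enter = 0.001, p_remove = 0.002) {
  n <- length(y)
  stopifnot(nrow(design) == n)
  keep_cols <- which(apply(design, 2, function(col) stats::var(col) > 0))
  C <- design[, keep_cols, drop = FALSE]
  sel <- integer(0)
  max_vars <- max(0L, n - 3L)

  repeat {
    added <- FALSE
    if (length(sel) < max_vars) {
      Xcur <- cbind(1, C[, sel, drop = FALSE])
      qr_x <- qr(Xcur)
      ry <- qr.resid(qr_x, y)
      rss <- sum(ry^2)
      cand <- setdiff(seq_len(ncol(C)), sel)
      if (length(cand) && rss > 1e-12) {
        RC <- qr.resid(qr_x, C[, cand, drop = FALSE])
        ssq <- colSums(RC^2)
        num <- colSums(RC * ry)^2
        usable <- ssq > 1e-10
        rss_new <- ifelse(usable, rss - num / ssq, rss)
        df2 <- n - length(sel) - 2
        fstat <- (rss - rss_new) / pmax(rss_new / df2, 1e-300)
        pval <- stats::pf(fstat, 1, df2, lower.tail = FALSE)
        pval[!usable] <- 1
        best <- which.min(pval)
        if (pval[best] < p_enter) {
          sel <- c(sel, cand[best])
          added <- TRUE
        }
      }
    }
    removed <- FALSE
    while (length(sel) > 0) {
      Xs <- cbind(1, C[, sel, drop = FALSE])
      fit <- fit_ls(Xs, y)
      if (anyNA(fit$beta)) {
        dropi <- max(which(is.na(fit$beta)) - 1L)
        warning("dropping collinear cofactor ", colnames(C)[sel[dropi]],
                call. = FALSE)
        sel <- sel[-dropi]
        next
      }
      df2 <- n - length(sel) - 1
      xtxi <- chol2inv(qr.R(fit$qr))
      se2 <- diag(xtxi) * fit$rss / df2
      tstat2 <- fit$beta^2 / pmax(se2, 1e-300)
      pvals <- stats::pf(tstat2[-1], 1, df2, lower.tail = FALSE)
      worst <- which.max(pvals)
      if (pvals[worst] > p_remove) {
        sel <- sel[-worst]
        removed <- TRUE
      } else break
    }
    if (!added && !removed) break
  }

  if (length(sel) == 0) {
    return(structure(list(vars = character(0), beta = numeric(0),
                          intercept = mean(y), marker = character(0),
                          X = matrix(numeric(0), n, 0)),
                     class = "icim_cofactors"))
  }
  Xs <- C[, sel, drop = FALSE]
  fit <- fit_ls(cbind(1, Xs), y)
  structure(list(
    vars = colnames(Xs),
    beta = stats::setNames(fit$beta[-1], colnames(Xs)),
    intercept = fit$beta[1],
    marker = sub("\\.(xF|xM|z)$", "", colnames(Xs)),
    X = Xs
  ), class = "icim_cofactors")
}

#' @export
print.icim_cofactors <- function(x, ...) {
  cat("ICIM background cofactors: ", length(x$vars), " variable(s)",
      if (length(x$vars)) paste0(" [", paste(x$vars, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Adjust the phenotype for background cofactors
#'
#' Subtracts the fitted contributions of the selected cofactors, excluding
#' every variable belonging to a marker in `exclude` (the flanking markers
#' of the current scan interval plus any marker inside the exclusion
#' window), then re-centres so the adjusted phenotype keeps the mean of `y`.
#'
#' @param y Phenotype vector.
#' @param cofactors An `icim_cofactors` object.
#' @param exclude Character vector of marker names whose variables must not
#'   be adjusted for.
#' @return The adjusted phenotype vector.
#' @export
adjust_phenotype <- function(y, cofactors, exclude = character(0)) {
  keep <- !(cofactors$marker %in% exclude)
  if (!any(keep)) return(y)
  contrib <- cofactors$X[, keep, drop = FALSE] %*% cofactors$beta[keep]
  y_adj <- y - as.vector(contrib)
  y_adj - mean(y_adj) + mean(y)
}

#' QTL genotype class probabilities from flanking markers
#'
#' At a scan position inside a marker interval, the paternal allele
#' probability P(A vs B) is computed from the paternal information of the
#' two flanking markers under no interference (each flank weighs in with
#' `1 - r` for agreement and `r` for disagreement; confounded or ambiguous
#' flank codes are uninformative), and likewise the maternal P(C vs D). The
#' two meioses are independent, so the four class probabilities are the
#' products, ordered AC, AD, BC, BD.
#'
#' @param code_left,code_right Observed class codes of the flanking markers
#'   (NA for missing; `code_right = NULL` for a degenerate interval with a
#'   single flank).
#' @param r_left,r_right Recombination fractions between the scan position
#'   and the left/right flanking markers.
#' @return A numeric matrix (individuals x 4) with columns AC, AD, BC, BD;
#'   rows sum to 1.
#' @examples
#' qtl_class_probs("AC", "AC", 0.05, 0.05)
#' qtl_class_probs(NA, NA, 0.1, 0.1)   # no information: all 1/4
#' @export
qtl_class_probs <- function(code_left, code_right = NULL, r_left, r_right) {
  n <- length(code_left)
  flank <- function(codes) {
    pat <- rep(NA_character_, n)
    mat <- rep(NA_character_, n)
    ok <- !is.na(codes)
    if (any(ok)) {
      info <- do.call(rbind, FLANK_INFO_TABLE[codes[ok]])
      pat[ok] <- info[, "pat"]
      mat[ok] <- info[, "mat"]
    }
    list(pat = pat, mat = mat)
  }
  # weight contributed by one flank to the "first allele" hypothesis
  wgt <- function(state, first, second, r) {
    ifelse(is.na(state), 1, ifelse(state == first, 1 - r, r))
  }
  r_left <- min(max(r_left, 1e-9), 0.5)
  fl <- flank(code_left)
  wA <- wgt(fl$pat, "A", "B", r_left)
  wB <- wgt(fl$pat, "B", "A", r_left)
  wC <- wgt(fl$mat, "C", "D", r_left)
  wD <- wgt(fl$mat, "D", "C", r_left)
  if (!is.null(code_right)) {
    r_right <- min(max(r_right, 1e-9), 0.5)
    fr <- flank(code_right)
    wA <- wA * wgt(fr$pat, "A", "B", r_right)
    wB <- wB * wgt(fr$pat, "B", "A", r_right)
    wC <- wC * wgt(fr$mat, "C", "D", r_right)
    wD <- wD * wgt(fr$mat, "D", "C", r_right)
  }
  pA <- ifelse(wA + wB > 0, wA / (wA + wB), 0.5)
  pC <- ifelse(wC + wD > 0, wC / (wC + wD), 0.5)
  out <- cbind(AC = pA * pC, AD = pA * (1 - pC),
               BC = (1 - pA) * pC, BD = (1 - pA) * (1 - pC))
  out
}

#' Fit the four-component mixture at one scan position
#'
#' EM fit of a four-component normal mixture with common variance, in which
#' each individual's component prior is its QTL class probability vector
#' from the flanking markers. The null model is a single normal. LOD is the
#' log10 likelihood ratio; effects come from the quarter-contrasts of the
#' fitted class means; PVE is `100 * (1 - sigma2_1 / sigma2_0)` against the
#' null variance of the (adjusted) phenotype.
#'
#' @param y Adjusted phenotype vector (no NA).
#' @param probs Class probability matrix (individuals x 4, columns AC, AD,
#'   BC, BD).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return A list: `mu` (length-4 class means), `sigma2`, `lod`, `pve`,
#'   `effects` (named numeric vector `m`, `a_F`, `a_M`, `d`), `loglik`,
#'   `loglik0`, `converged`, `n_iter`.
#' @export
em_fit_scanpoint <- function(y, probs, max_iter = 100, tol = 1e-6) {
  n <- length(y)
  stopifnot(nrow(probs) == n, ncol(probs) == 4)
  if (sum(rowSums(probs) > 0) < 20) {
    stop("need at least 20 individuals with nonzero class probability mass",
         call. = FALSE)
  }
  ybar <- mean(y)
  s20 <- mean((y - ybar)^2)
  if (s20 < 1e-12) s20 <- 1e-12
  csum <- colSums(probs)
  mu <- colSums(probs * y) / pmax(csum, 1e-12)
  mu[csum <= 1e-8] <- ybar
  s2 <- s20
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  ll <- NA_real_
  sqdev <- function(mu) {
    cbind((y - mu[1])^2, (y - mu[2])^2, (y - mu[3])^2, (y - mu[4])^2)
  }
  while (iter < max_iter) {
    iter <- iter + 1
    dens <- exp(-0.5 * sqdev(mu) / s2) / sqrt(2 * pi * s2)
    W <- probs * dens
    L <- rowSums(W)
    ll <- sum(log(pmax(L, 1e-300)))
    # EM guarantee: the observed-data log-likelihood never decreases
    stopifnot(ll >= ll_old - 1e-6)
    w <- W / pmax(L, 1e-300)
    csum <- colSums(w)
    mu <- colSums(w * y) / pmax(csum, 1e-12)
    mu[csum <= 1e-8] <- ybar
    s2 <- max(sum(w * sqdev(mu)) / n, 1e-12)
    if (ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) {
    warning("EM did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  ll0 <- sum(stats::dnorm(y, ybar, sqrt(s20), log = TRUE))
  mu <- unname(mu)
  list(mu = mu, sigma2 = s2,
       lod = max((ll - ll0) / log(10), 0),
       pve = 100 * (1 - s2 / s20),
       effects = c(m = mean(mu),
                   a_F = (mu[1] + mu[2] - mu[3] - mu[4]) / 4,
                   a_M = (mu[1] - mu[2] + mu[3] - mu[4]) / 4,
                   d = (mu[1] - mu[2] - mu[3] + mu[4]) / 4),
       loglik = ll, loglik0 = ll0, converged = converged, n_iter = iter)
}

#' Collapse a long phenotype table to one value per line
#'
#' @param phenotypes Long tibble (`line`, `env`, `rep`, `value`) or a tibble
#'   already holding one `value` per `line`.
#' @param env Environment name to analyse, or `"mean"` for the across-
#'   environment line mean.
#' @return A tibble `line`, `value`.
#' @export
line_phenotypes <- function(phenotypes, env = "mean") {
  stopifnot(all(c("line", "value") %in% names(phenotypes)))
  ph <- phenotypes
  if ("env" %in% names(ph) && !identical(env, "mean")) {
    if (!env %in% ph$env) stop("environment not found: ", env, call. = FALSE)
    ph <- ph[ph$env == env, ]
  }
  ph |>
    dplyr::group_by(line = .data$line) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

# Precompute everything about the scan that does not depend on the
# phenotype: per-point class probabilities, interval flanks and the
# exclusion set for the cofactor adjustment. Reused across permutations.
build_scan_design <- function(genotypes, map, step = 1, window = 10,
                              map_function = "haldane") {
  points <- list()
  intervals <- list()
  for (ch in unique(map$chrom)) {
    mk <- map[map$chrom == ch, ]
    mk <- mk[order(mk$pos_cM), ]
    mpos <- mk$pos_cM
    m <- nrow(mk)
    pos <- unique(c(seq(mpos[1], mpos[m], by = step), mpos[m]))
    left <- pmin(pmax(findInterval(pos, mpos), 1L), m)
    right <- pmin(left + 1L, m)
    at_end <- pos >= mpos[m] - 1e-9
    right[at_end] <- left[at_end] <- m
    key <- paste(ch, left, right)
    for (i in seq_along(pos)) {
      k <- key[i]
      if (is.null(intervals[[k]])) {
        lo <- mpos[left[i]] - window
        hi <- mpos[right[i]] + window
        intervals[[k]] <- list(
          chrom = ch,
          exclude = mk$marker[mpos >= lo - 1e-9 & mpos <= hi + 1e-9]
        )
      }
      degenerate <- left[i] == right[i]
      codesL <- genotypes[[mk$marker[left[i]]]]
      probs <- qtl_class_probs(
        code_left = codesL,
        code_right = if (degenerate) NULL else genotypes[[mk$marker[right[i]]]],
        r_left = map_rf(pos[i] - mpos[left[i]], map_function),
        r_right = if (degenerate) NULL
                  else map_rf(mpos[right[i]] - pos[i], map_function)
      )
      points[[length(points) + 1L]] <- list(
        chrom = ch, pos = pos[i], interval = k,
        left_marker = mk$marker[left[i]], right_marker = mk$marker[right[i]],
        probs = probs
      )
    }
  }
  list(points = points, intervals = intervals,
       genome_length = sum(tapply(map$pos_cM, map$chrom, function(p) diff(range(p)))))
}

# Scan a phenotype vector over a prebuilt design. keep = logical mask of
# lines with observed phenotype (rows of the probability matrices).
scan_profile <- function(y, keep, design, cofactors) {
  y_adj_cache <- list()
  np <- length(design$points)
  num <- matrix(NA_real_, np, 9,
                dimnames = list(NULL, c("pos_cM", "lod", "a_F", "a_M", "d",
                                        "pve", "mu1", "mu2", "mu3")))
  mu4 <- numeric(np)
  chrom <- vector(mode = typeof(design$points[[1]]$chrom), np)
  lmk <- character(np); rmk <- character(np)
  all_kept <- all(keep)
  for (i in seq_len(np)) {
    pt <- design$points[[i]]
    k <- pt$interval
    if (is.null(y_adj_cache[[k]])) {
      y_adj_cache[[k]] <- adjust_phenotype(
        y, cofactors, exclude = design$intervals[[k]]$exclude)
    }
    probs <- if (all_kept) pt$probs else pt$probs[keep, , drop = FALSE]
    fit <- em_fit_scanpoint(y_adj_cache[[k]], probs)
    mu <- fit$mu
    num[i, ] <- c(pt$pos, fit$lod,
                  (mu[1] + mu[2] - mu[3] - mu[4]) / 4,
                  (mu[1] - mu[2] + mu[3] - mu[4]) / 4,
                  (mu[1] - mu[2] - mu[3] + mu[4]) / 4,
                  fit$pve, mu[1], mu[2], mu[3])
    mu4[i] <- mu[4]
    chrom[i] <- pt$chrom
    lmk[i] <- pt$left_marker; rmk[i] <- pt$right_marker
  }
  out <- tibble::as_tibble(as.data.frame(num))
  dplyr::bind_cols(tibble::tibble(chrom = chrom), out,
                   tibble::tibble(mu4 = mu4, left_marker = lmk,
                                  right_marker = rmk)) |>
    dplyr::relocate("mu4", .after = "mu3")
}

# Local LOD maxima above the threshold, separated by >= peak_sep cM or by a
# LOD valley at least peak_lod_drop below the lower of the two peaks.
call_peaks <- function(profile, threshold, peak_sep = 20, peak_lod_drop = 1) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, ]
    pr <- pr[order(pr$pos_cM), ]
    lod <- pr$lod
    np <- nrow(pr)
    is_max <- vapply(seq_len(np), function(i) {
      lod[i] >= threshold &&
        (i == 1 || lod[i] >= lod[i - 1]) &&
        (i == np || lod[i] >= lod[i + 1])
    }, logical(1))
    cand <- which(is_max)
    cand <- cand[order(-lod[cand], pr$pos_cM[cand])]
    accepted <- integer(0)
    for (i in cand) {
      ok <- TRUE
      for (a in accepted) {
        if (abs(pr$pos_cM[i] - pr$pos_cM[a]) >= peak_sep) next
        span <- sort(c(i, a))
        valley <- min(lod[span[1]:span[2]])
        if (valley <= min(lod[i], lod[a]) - peak_lod_drop) next
        ok <- FALSE
        break
      }
      if (ok) accepted <- c(accepted, i)
    }
    if (length(accepted)) {
      out[[length(out) + 1L]] <- pr[sort(accepted), ]
    }
  }
  if (!length(out)) {
    return(dplyr::mutate(profile[0, ], qtl = character(0), .before = 1))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$chrom, .data$pos_cM) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(qtl = sprintf("q%s-%d", .data$chrom, dplyr::row_number()),
                  .before = 1) |>
    dplyr::ungroup()
}

#' Inclusive composite interval mapping scan for a four-way cross
#'
#' The two-step ICIM procedure: (1) select background marker cofactors once
#' by stepwise regression on the encoded marker variables; (2) walk the
#' genome at `step` cM, and at each position adjust the phenotype for all
#' cofactors outside the current interval's exclusion window, compute QTL
#' class probabilities from the flanking markers, and fit the four-component
#' normal mixture by EM, yielding LOD, the effects `a_F`, `a_M`, `d`, PVE
#' and the four genotypic means. QTL are called at local LOD maxima at or
#' above the threshold, with nearby maxima merged unless separated by at
#' least `peak_sep` cM or a LOD drop of `peak_lod_drop`.
#'
#' @param phenotypes Long phenotype tibble (`line`, `env`, `rep`, `value`)
#'   or per-line values (`line`, `value`). Lines missing a phenotype are
#'   dropped listwise.
#' @param genotypes Wide genotype tibble (`line` plus marker columns).
#' @param map Genetic map tibble.
#' @param step Scan step in cM (> 0).
#' @param env Environment to analyse, or `"mean"` (default) for the
#'   across-environment line means.
#' @param p_enter,p_remove Stepwise entry/removal probabilities.
#' @param threshold Numeric LOD threshold, or `"formula"` (default) for the
#'   effective-test-count formula at this map's genome length, or `"none"`.
#' @param window Cofactor exclusion window around the scan interval, cM.
#' @param alpha_g,density_factor Passed to [lod_threshold_formula()] when
#'   `threshold = "formula"`.
#' @param peak_sep,peak_lod_drop Peak separation rules.
#' @param map_function Map function.
#'
#' @return An object of class `icim_scan`: list with `profile` (per-cM scan
#'   tibble), `qtl` (called QTL tibble), `threshold`, `cofactors`, `env`,
#'   `n_lines`.
#'
#' @examples
#' map <- sim_map(n_markers = c(8, 8), genome_length = 140,
#'                category_counts = data.frame(chrom = 1:2,
#'                  "ABCD" = c(8L, 8L), "A=B" = 0L, "C=D" = 0L,
#'                  "A=CB=D" = 0L, "A=DB=C" = 0L, check.names = FALSE),
#'                seed = 1)
#' qtl <- data.frame(chrom = 1, pos_cM = 35, a_F = 3, a_M = 0, d = 0)
#' pop <- sim_cross(map, qtl, n = 120, sigma2_ge = 0, sigma2_e = 4, seed = 2)
#' scan <- icim_scan(pop$phenotypes, pop$genotypes, map, threshold = 3)
#' tidy(scan)
#' @export
icim_scan <- function(phenotypes, genotypes, map, step = 1, env = "mean",
                      p_enter = 0.001, p_remove = 0.002,
                      threshold = "formula", window = 10,
                      alpha_g = 0.05, density_factor = 0.072,
                      peak_sep = 20, peak_lod_drop = 1,
                      map_function = "haldane") {
  if (!is.numeric(step) || step <= 0) {
    stop("scan step must be a positive number of cM", call. = FALSE)
  }
  ph <- line_phenotypes(phenotypes, env)
  keep_lines <- genotypes$line[genotypes$line %in% ph$line]
  y <- ph$value[match(keep_lines, ph$line)]
  obs <- !is.na(y)
  keep_lines <- keep_lines[obs]
  y <- y[obs]
  keep <- genotypes$line %in% keep_lines
  geno <- genotypes[keep, , drop = FALSE]

  design <- build_scan_design(geno, map, step = step, window = window,
                              map_function = map_function)
  thr <- if (is.numeric(threshold)) {
    threshold
  } else if (identical(threshold, "formula")) {
    lod_threshold_formula(design$genome_length, alpha_g = alpha_g,
                          density_factor = density_factor)
  } else if (identical(threshold, "none")) {
    Inf
  } else stop("threshold must be numeric, \"formula\" or \"none\"",
              call. = FALSE)

  X <- encode_design(geno, map)
  cof <- stepwise_select(y, X, p_enter = p_enter, p_remove = p_remove)
  profile <- scan_profile(y, rep(TRUE, length(y)), design, cof)
  qtl <- call_peaks(profile, thr, peak_sep, peak_lod_drop)
  structure(list(profile = profile, qtl = qtl, threshold = thr,
                 cofactors = cof, env = env, n_lines = length(y),
                 step = step),
            class = "icim_scan")
}

#' @export
print.icim_scan <- function(x, ...) {
  cat("ICIM genome scan (", x$env, " phenotype, ", x$n_lines, " lines, step ",
      x$step, " cM)\n", sep = "")
  cat("LOD threshold ", round(x$threshold, 2), "; ", nrow(x$qtl),
      " QTL called\n", sep = "")
  if (nrow(x$qtl)) {
    print(dplyr::mutate(x$qtl, dplyr::across(dplyr::where(is.numeric),
                                             ~ round(.x, 2))))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the QTL calls of an ICIM scan
#'
#' @param x An `icim_scan` object.
#' @param ... Unused.
#' @return A tibble with one row per called QTL: name, location, flanking
#'   markers, LOD, effects, PVE and genotypic means.
#' @exportS3Method generics::tidy
tidy.icim_scan <- function(x, ...) {
  x$qtl
}

#' One-row summary of an ICIM scan
#'
#' @param x An `icim_scan` object.
#' @param ... Unused.
#' @return A tibble: lines scanned, scan points, threshold, maximum LOD and
#'   QTL count.
#' @exportS3Method generics::glance
glance.icim_scan <- function(x, ...) {
  tibble::tibble(
    n_lines = x$n_lines,
    n_points = nrow(x$profile),
    n_cofactors = length(x$cofactors$vars),
    threshold = x$threshold,
    max_lod = max(x$profile$lod),
    n_qtl = nrow(x$qtl)
  )
}

#' LOD profile plot for an ICIM scan
#'
#' @param object An `icim_scan` object.
#' @param ... Unused.
#' @return A ggplot: LOD against position, faceted by chromosome, with the
#'   threshold as a dashed line and called QTL marked.
#' @exportS3Method ggplot2::autoplot
autoplot.icim_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (is.finite(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed", colour = "grey40")
  }
  if (nrow(object$qtl)) {
    p <- p + ggplot2::geom_point(data = object$qtl, colour = "firebrick")
  }
  p
}
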