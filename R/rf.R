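# Latent two-locus configuration table: 16 combinations of paternal pair
# (A/B at locus i and j) and maternal pair (C/D), with the number of
# recombinant meioses (0, 1, or 2). Joint probability under recombination
# fraction r (same r for both meioses, no interference):
# (1/4) * (1-r)^(2-k) * r^k.
latent_two_locus <- function() {
  g <- expand.grid(pi = c("A", "B"), pj = c("A", "B"),
                   mi = c("C", "D"), mj = c("C", "D"),
                   stringsAsFactors = FALSE)
  g$k <- (g$pi != g$pj) + (g$mi != g$mj)
  g
}

#' Estimate the recombination fraction between two markers by ML
#'
#' Maximizes the multinomial log-likelihood of the observed two-marker class
#' counts over `r` in `[0, 0.5]`. The class probabilities are built from the
#' 16 latent two-locus configurations (two independent meioses, each
#' recombinant with probability `r`, no interference) projected through both
#' markers' category code tables, so partially informative markers contribute
#' exactly the information their collapsed classes retain. A pair in which
#' one marker carries only paternal information (`C=D`) and the other only
#' maternal (`A=B`) has a likelihood that is constant in `r` and is flagged
#' inestimable.
#'
#' @param obs_i,obs_j Character vectors of observed class codes (NA allowed;
#'   pairwise complete cases are used).
#' @param cat_i,cat_j The two markers' information categories.
#' @param min_informative Minimum number of jointly non-missing individuals.
#'
#' @return A one-row tibble: `r_hat`, `loglik`, `lod` (linkage LOD vs
#'   `r = 0.5`), `estimable`, `n_used`. Inestimable pairs carry `NA` for
#'   `r_hat` and `lod`.
#'
#' @examples
#' map <- sim_map(seed = 1)
#' pop <- sim_cross(map, n = 100, missing_rate = 0, seed = 3)
#' estimate_rf(pop$genotypes$c01m01, pop$genotypes$c01m02, "ABCD", "ABCD")
#' @export
estimate_rf <- function(obs_i, obs_j, cat_i, cat_j, min_informative = 30) {
  keep <- !is.na(obs_i) & !is.na(obs_j)
  n_used <- sum(keep)
  if (n_used < min_informative) {
    stop("only ", n_used, " individuals have both markers observed (need >= ",
         min_informative, ")", call. = FALSE)
  }
  lat <- latent_two_locus()
  code_i <- collapse_observed(cat_i, paste0(lat$pi, lat$mi))
  code_j <- collapse_observed(cat_j, paste0(lat$pj, lat$mj))
  cls <- paste(code_i, code_j, sep = "|")
  obs <- paste(obs_i[keep], obs_j[keep], sep = "|")
  bad <- setdiff(unique(obs), unique(cls))
  if (length(bad)) {
    stop("observed codes inconsistent with categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(obs)
  cls_levels <- names(counts)
  # membership matrix: observed class x latent configuration
  memb <- vapply(cls_levels, function(cl) cls == cl, logical(nrow(lat)))
  nvec <- as.numeric(counts)
  k <- lat$k
  loglik <- function(r) {
    pr_lat <- 0.25 * (1 - r)^(2 - k) * r^k
    p <- as.numeric(crossprod(memb, pr_lat))
    sum(nvec * log(pmax(p, 1e-300)))
  }
  # flat likelihood <=> no meiosis informative at both markers
  if (abs(loglik(0.1) - loglik(0.4)) < 1e-9 * max(1, abs(loglik(0.25)))) {
    return(tibble::tibble(r_hat = NA_real_, loglik = loglik(0.25),
                          lod = NA_real_, estimable = FALSE, n_used = n_used))
  }
  opt <- stats::optimize(loglik, c(0, 0.5), maximum = TRUE, tol = 1e-8)
  r_hat <- opt$maximum
  ll <- opt$objective
  # snap to the boundaries when they dominate (optimize never lands exactly)
  for (b in c(0, 0.5)) {
    llb <- loglik(b)
    if (llb >= ll - 1e-10) { r_hat <- b; ll <- llb }
  }
  tibble::tibble(r_hat = r_hat, loglik = ll,
                 lod = (ll - loglik(0.5)) / log(10),
                 estimable = TRUE, n_used = n_used)
}

#' Pairwise recombination fractions for all within-chromosome marker pairs
#'
#' Applies [estimate_rf()] to every unordered pair of markers assigned to the
#' same chromosome by the anchor information in `map` (de novo grouping is
#' not attempted; markers are anchored as in the study design). Pairs with
#' too few jointly observed individuals or with flat likelihoods are
#' returned with `estimable = FALSE`.
#'
#' @param genotypes Wide genotype tibble (`line` column plus one column per
#'   marker of observed class codes).
#' @param map Marker table with `marker`, `chrom`, `category` (positions not
#'   required).
#' @param min_informative Per-pair floor on jointly observed individuals.
#'
#' @return A tibble with one row per pair: `chrom`, `marker_i`, `marker_j`,
#'   `r_hat`, `loglik`, `lod`, `estimable`, `n_used`.
#' @export
rf_pairs <- function(genotypes, map, min_informative = 30) {
  stopifnot(all(map$marker %in% names(genotypes)))
  purrr::map_dfr(unique(map$chrom), function(ch) {
    mk <- map[map$chrom == ch, ]
    if (nrow(mk) < 2) return(NULL)
    pairs <- utils::combn(nrow(mk), 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      est <- tryCatch(
        estimate_rf(genotypes[[mk$marker[i]]], genotypes[[mk$marker[j]]],
                    mk$category[i], mk$category[j], min_informative),
        error = function(e) tibble::tibble(r_hat = NA_real_, loglik = NA_real_,
                                           lod = NA_real_, estimable = FALSE,
                                           n_used = NA_integer_)
      )
      dplyr::bind_cols(
        tibble::tibble(chrom = ch, marker_i = mk$marker[i],
                       marker_j = mk$marker[j]),
        est
      )
    })
  })
}

#' Convert pairwise estimates to a symmetric recombination matrix
#'
#' @param pairs Output of [rf_pairs()] (one chromosome's rows).
#' @param fill Value for inestimable pairs (default 0.5, the unlinked limit).
#' @return A symmetric numeric matrix with marker dimnames; diagonal 0.
#' @export
rf_matrix <- function(pairs, fill = 0.5) {
  markers <- sort(unique(c(pairs$marker_i, pairs$marker_j)))
  m <- matrix(fill, length(markers), length(markers),
              dimnames = list(markers, markers))
  diag(m) <- 0
  for (row in seq_len(nrow(pairs))) {
    r <- pairs$r_hat[row]
    if (is.na(r)) next
    m[pairs$marker_i[row], pairs$marker_j[row]] <- r
    m[pairs$marker_j[row], pairs$marker_i[row]] <- r
  }
  m
}
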