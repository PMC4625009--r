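# Shared fixtures and independent oracles used across test files.

# All permutations of 1..n (tiny n only), for exhaustive ordering oracles.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Exhaustive minimum SARF over all open tours of a distance matrix.
exhaustive_sarf <- function(dmat) {
  m <- nrow(dmat)
  perms <- all_permutations(m)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    s <- sum(dmat[cbind(p[-m], p[-1])])
    if (s < best) best <- s
  }
  best
}

# Independent two-marker log-likelihood: explicit enumeration of the 16
# latent configurations with scalar loops (no shared code with the
# estimator beyond the category code tables).
oracle_pair_loglik <- function(obs_i, obs_j, cat_i, cat_j, r) {
  keep <- !is.na(obs_i) & !is.na(obs_j)
  obs_i <- obs_i[keep]; obs_j <- obs_j[keep]
  ll <- 0
  pats <- c("A", "B"); mats <- c("C", "D")
  for (idx in seq_along(obs_i)) {
    p <- 0
    for (pi in pats) for (pj in pats) for (mi in mats) for (mj in mats) {
      pr <- 0.25 * (if (pi == pj) 1 - r else r) * (if (mi == mj) 1 - r else r)
      ci <- collapse_observed(cat_i, paste0(pi, mi))
      cj <- collapse_observed(cat_j, paste0(pj, mj))
      if (ci == obs_i[idx] && cj == obs_j[idx]) p <- p + pr
    }
    ll <- ll + log(max(p, 1e-300))
  }
  ll
}

# Grid-search ML over r for the oracle likelihood.
oracle_pair_mle <- function(obs_i, obs_j, cat_i, cat_j,
                            grid = seq(0, 0.5, by = 0.001)) {
  lat <- expand.grid(pi = c("A", "B"), pj = c("A", "B"),
                     mi = c("C", "D"), mj = c("C", "D"),
                     stringsAsFactors = FALSE)
  ci <- collapse_observed(cat_i, paste0(lat$pi, lat$mi))
  cj <- collapse_observed(cat_j, paste0(lat$pj, lat$mj))
  k <- (lat$pi != lat$pj) + (lat$mi != lat$mj)
  keep <- !is.na(obs_i) & !is.na(obs_j)
  counts <- table(paste(obs_i[keep], obs_j[keep]))
  cls <- paste(ci, cj)
  lls <- vapply(grid, function(r) {
    pr <- 0.25 * (1 - r)^(2 - k) * r^k
    p_cls <- vapply(names(counts), function(cl) sum(pr[cls == cl]), numeric(1))
    sum(as.numeric(counts) * log(pmax(p_cls, 1e-300)))
  }, numeric(1))
  grid[which.max(lls)]
}

# Simulate observed codes for a single marker pair with true recombination
# fraction r under the two-meiosis model (independent of sim_cross).
sim_marker_pair <- function(n, r, cat_i, cat_j) {
  pat1 <- sample(c("A", "B"), n, replace = TRUE)
  pat2 <- ifelse(stats::runif(n) < r, c(A = "B", B = "A")[pat1], pat1)
  mat1 <- sample(c("C", "D"), n, replace = TRUE)
  mat2 <- ifelse(stats::runif(n) < r, c(C = "D", D = "C")[mat1], mat1)
  list(obs_i = collapse_observed(cat_i, paste0(pat1, mat1)),
       obs_j = collapse_observed(cat_j, paste0(pat2, mat2)))
}

# A small all-ABCD map: one chromosome, m markers, given spacing.
abcd_map <- function(m = 8, spacing = 10, chrom = 1) {
  cc <- data.frame(chrom = chrom, "ABCD" = as.integer(m), "A=B" = 0L,
                   "C=D" = 0L, "A=CB=D" = 0L, "A=DB=C" = 0L,
                   check.names = FALSE)
  sim_map(n_markers = m, genome_length = spacing * (m - 1),
          category_counts = cc, seed = 1)
}

# The reduced null-scan map: 3 chromosomes x 20 markers at 10 cM spacing,
# the marker density for which the default effective-test factor is stated.
reduced_map <- function(seed = 2) {
  cc <- data.frame(chrom = 1:3, "ABCD" = c(8L, 7L, 7L), "A=B" = c(5L, 5L, 5L),
                   "C=D" = c(5L, 5L, 5L), "A=CB=D" = c(1L, 2L, 2L),
                   "A=DB=C" = c(1L, 1L, 1L), check.names = FALSE)
  sim_map(n_markers = rep(20L, 3), genome_length = 10 * 57,
          category_counts = cc, seed = seed)
}
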