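sarf <- function(order, dmat) {
  if (length(order) < 2) return(0)
  sum(dmat[cbind(order[-length(order)], order[-1])])
}

# connected components on the estimability graph; returns integer labels
estimable_components <- function(markers, pairs) {
  comp <- stats::setNames(seq_along(markers), markers)
  est <- pairs[pairs$estimable %in% TRUE, , drop = FALSE]
  for (row in seq_len(nrow(est))) {
    ci <- comp[[est$marker_i[row]]]
    cj <- comp[[est$marker_j[row]]]
    if (ci != cj) comp[comp == cj] <- ci
  }
  comp
}

#' Order markers along a chromosome by nearest neighbor plus 2-opt
#'
#' Treats ordering as an open traveling-salesman tour minimizing the sum of
#' adjacent recombination fractions (SARF). A greedy nearest-neighbor tour is
#' built from every possible start marker, and each is refined by 2-opt
#' segment reversals (first improvement, deterministic scan order) until no
#' reversal lowers the SARF. The best tour over all starts is returned, ties
#' broken by the lexicographically smallest marker sequence, and orientation
#' is normalized so the first marker name sorts at or before the last.
#'
#' @param pairs Pairwise estimates for one chromosome ([rf_pairs()] rows), or
#'   a symmetric distance matrix with marker dimnames. When a pairs tibble is
#'   given, the estimability graph must be connected: markers unlinkable
#'   through any chain of estimable pairs are reported by name as an error.
#'   Inestimable pairs inside a connected graph are completed by the
#'   shortest chain of estimable pairs on the map-distance scale before the
#'   tour search.
#'
#' @return Character vector of marker names in tour order, with the achieved
#'   SARF in attribute `"sarf"`.
#'
#' @examples
#' d <- matrix(0.5, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
#' d["x", "y"] <- d["y", "x"] <- 0.1
#' d["y", "z"] <- d["z", "y"] <- 0.1
#' d["x", "z"] <- d["z", "x"] <- 0.18
#' order_markers(d)
#' @export
order_markers <- function(pairs) {
  if (is.matrix(pairs)) {
    dmat <- pairs
  } else {
    markers <- sort(unique(c(pairs$marker_i, pairs$marker_j)))
    comp <- estimable_components(markers, pairs)
    if (length(unique(comp)) > 1) {
      tab <- table(comp)
      main <- names(tab)[which.max(tab)]
      stray <- names(comp)[comp != as.integer(main)]
      stop("markers cannot be linked to the rest of the group: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
    dmat <- map_rf(bridged_cM_matrix(pairs))
  }
  m <- nrow(dmat)
  markers <- rownames(dmat)
  if (m <= 2) {
    out <- markers
    attr(out, "sarf") <- sarf(seq_len(m), dmat)
    return(out)
  }

  two_opt <- function(path) {
    repeat {
      improved <- FALSE
      # 2-opt: reverse the segment [i, j]
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          if (i == 1 && j == m) next  # full reversal leaves SARF unchanged
          old <- 0; new <- 0
          if (i > 1) {
            old <- old + dmat[path[i - 1], path[i]]
            new <- new + dmat[path[i - 1], path[j]]
          }
          if (j < m) {
            old <- old + dmat[path[j], path[j + 1]]
            new <- new + dmat[path[i], path[j + 1]]
          }
          if (new < old - 1e-12) {
            path[i:j] <- path[j:i]
            improved <- TRUE
          }
        }
      }
      # or-opt: relocate a short segment (length 1-3, either orientation)
      # elsewhere in the tour, escaping local optima that segment reversal
      # alone cannot leave
      cur <- sarf(path, dmat)
      for (len in 1:3) {
        if (len >= m) next
        for (i in seq_len(m - len + 1)) {
          seg <- path[i:(i + len - 1)]
          rest <- path[-(i:(i + len - 1))]
          for (j in 0:length(rest)) {
            for (s_or in if (len > 1) list(seg, rev(seg)) else list(seg)) {
              cand <- append(rest, s_or, after = j)
              s <- sarf(cand, dmat)
              if (s < cur - 1e-12) {
                path <- cand
                cur <- s
                improved <- TRUE
              }
            }
          }
        }
      }
      if (!improved) return(path)
    }
  }

  best <- NULL
  best_sarf <- Inf
  for (start in seq_len(m)) {
    path <- integer(m)
    path[1] <- start
    left <- rep(TRUE, m); left[start] <- FALSE
    for (step in 2:m) {
      cand <- which(left)
      nxt <- cand[which.min(dmat[path[step - 1], cand])]
      path[step] <- nxt
      left[nxt] <- FALSE
    }
    path <- two_opt(path)
    s <- sarf(path, dmat)
    seq_names <- markers[path]
    if (seq_names[1] > seq_names[m]) seq_names <- rev(seq_names)
    if (s < best_sarf - 1e-12 ||
        (abs(s - best_sarf) <= 1e-12 && !is.null(best) &&
         paste(seq_names, collapse = "\r") < paste(best, collapse = "\r"))) {
      best <- seq_names
      best_sarf <- s
    }
  }
  out <- best
  attr(out, "sarf") <- best_sarf
  out
}

# Pairwise cM distances with inestimable entries completed through third
# markers. On a linear map, for any marker k outside the interval (i, j),
# |d(i,k) - d(j,k)| equals d(i,j); a missing entry is filled from the
# nearest such k (smallest d(i,k) + d(j,k)), which keeps truly adjacent but
# mutually uninformative markers (one A=B, one C=D) at their real short
# distance instead of a detour. Entries still missing afterwards fall back
# to shortest estimable chains. Estimates at or above 0.5 are capped just
# below before conversion.
bridged_cM_matrix <- function(pairs, map_function = "haldane", cap = 0.49) {
  markers <- sort(unique(c(pairs$marker_i, pairs$marker_j)))
  m <- length(markers)
  d <- matrix(NA_real_, m, m, dimnames = list(markers, markers))
  diag(d) <- 0
  est <- pairs[pairs$estimable %in% TRUE & !is.na(pairs$r_hat), , drop = FALSE]
  d[cbind(est$marker_i, est$marker_j)] <-
    map_distance(pmin(est$r_hat, cap), map_function)
  d[cbind(est$marker_j, est$marker_i)] <-
    map_distance(pmin(est$r_hat, cap), map_function)
  direct <- d
  miss <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  for (row in seq_len(nrow(miss))) {
    i <- miss[row, 1]; j <- miss[row, 2]
    k <- which(!is.na(direct[i, ]) & !is.na(direct[j, ]))
    if (!length(k)) next
    k_best <- k[which.min(direct[i, k] + direct[j, k])]
    d[i, j] <- d[j, i] <- abs(direct[i, k_best] - direct[j, k_best])
  }
  # remaining gaps: shortest chains over what is known
  if (anyNA(d)) {
    w <- d
    w[is.na(w)] <- Inf
    for (k in seq_len(m)) {
      wk <- outer(w[, k], w[k, ], `+`)
      better <- wk < w
      w[better] <- wk[better]
    }
    d[is.na(d)] <- w[is.na(d)]
  }
  if (any(!is.finite(d))) {
    stop("marker distance graph is disconnected", call. = FALSE)
  }
  d
}

#' Accumulate map positions along an ordered chromosome
#'
#' Converts the adjacent-pair recombination fractions of an ordered marker
#' list into cumulative cM positions through the map function; the first
#' marker sits at 0. By default an adjacent pair whose recombination
#' fraction is inestimable is an error; with `bridge = TRUE` such gaps are
#' filled by the shortest chain of estimable pairs.
#'
#' @param order Character vector of markers in map order.
#' @param pairs Pairwise estimates covering the adjacent pairs.
#' @param map_function Map function for the conversion.
#' @param bridge Bridge inestimable adjacent pairs through estimable chains.
#' @return A tibble `marker`, `pos_cM`.
#' @export
build_map_positions <- function(order, pairs, map_function = "haldane",
                                bridge = FALSE) {
  if (length(order) == 1) return(tibble::tibble(marker = order, pos_cM = 0))
  if (bridge) {
    d <- bridged_cM_matrix(pairs, map_function)
    gaps <- d[cbind(order[-length(order)], order[-1])]
    return(tibble::tibble(marker = order, pos_cM = c(0, cumsum(gaps))))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- stats::setNames(pairs$r_hat, key(pairs$marker_i, pairs$marker_j))
  est <- stats::setNames(pairs$estimable, key(pairs$marker_i, pairs$marker_j))
  adj <- key(order[-length(order)], order[-1])
  if (any(!adj %in% names(lut)) || any(!est[adj]) || any(is.na(lut[adj]))) {
    bad <- adj[!adj %in% names(lut) | !est[adj] | is.na(lut[adj])]
    stop("adjacent marker pair(s) without an estimable recombination ",
         "fraction: ", paste(gsub("\r", " - ", bad), collapse = ", "),
         call. = FALSE)
  }
  r <- pmin(unname(lut[adj]), 0.4999)  # r_hat = 0.5 would be infinitely long
  tibble::tibble(marker = order,
                 pos_cM = c(0, cumsum(map_distance(r, map_function))))
}

#' Build a genetic map from genotypes and anchored markers
#'
#' The full map-construction pipeline: estimate all within-chromosome
#' pairwise recombination fractions, order the markers of each chromosome by
#' nearest neighbor + 2-opt on SARF, and accumulate cM positions through the
#' map function. Chromosome assignment comes from the anchor table (as when
#' markers are anchored to a physical map); de novo linkage grouping is
#' available separately via [group_markers()].
#'
#' @param genotypes Wide genotype tibble (`line` plus marker columns).
#' @param anchors Marker table with `marker`, `chrom`, `category`.
#' @param min_informative Per-pair floor on jointly observed individuals.
#' @param map_function Map function.
#' @param drop_unlinked If `TRUE`, markers that cannot be linked to their
#'   chromosome's main group are dropped with a warning instead of raising
#'   an error.
#'
#' @return A genetic map tibble: `marker`, `chrom`, `pos_cM`, `category`.
#' @export
construct_map <- function(genotypes, anchors, min_informative = 30,
                          map_function = "haldane", drop_unlinked = FALSE) {
  pairs <- rf_pairs(genotypes, anchors, min_informative)
  purrr::map_dfr(unique(anchors$chrom), function(ch) {
    mk <- anchors[anchors$chrom == ch, ]
    if (nrow(mk) == 1) {
      return(tibble::tibble(marker = mk$marker, chrom = ch, pos_cM = 0,
                            category = mk$category))
    }
    pp <- pairs[pairs$chrom == ch, ]
    if (drop_unlinked) {
      comp <- estimable_components(sort(mk$marker), pp)
      tab <- table(comp)
      main <- as.integer(names(tab)[which.max(tab)])
      stray <- names(comp)[comp != main]
      if (length(stray)) {
        warning("dropping unlinkable marker(s) on chromosome ", ch, ": ",
                paste(stray, collapse = ", "), call. = FALSE)
        mk <- mk[!mk$marker %in% stray, ]
        pp <- pp[!(pp$marker_i %in% stray | pp$marker_j %in% stray), ]
      }
    }
    ord <- as.vector(order_markers(pp))
    pos <- build_map_positions(ord, pp, map_function, bridge = TRUE)
    dplyr::left_join(pos, mk[, c("marker", "category")], by = "marker") |>
      dplyr::mutate(chrom = ch, .after = "marker")
  })
}

#' Group markers into linkage groups by single linkage
#'
#' De novo grouping for unanchored markers: two markers join the same group
#' when linked by a chain of pairwise estimates with linkage LOD at or above
#' the threshold. Provided as a diagnostic; chromosome anchoring through an
#' anchor table is the default analysis path.
#'
#' @param pairs Pairwise estimates over the markers to group.
#' @param min_lod Linkage LOD threshold for an edge (default 3).
#' @return A tibble `marker`, `group` (integer labels, largest group first).
#' @export
group_markers <- function(pairs, min_lod = 3) {
  linked <- pairs[pairs$estimable %in% TRUE & !is.na(pairs$lod) &
                    pairs$lod >= min_lod, , drop = FALSE]
  markers <- sort(unique(c(pairs$marker_i, pairs$marker_j)))
  linked$estimable <- TRUE
  comp <- estimable_components(markers, linked)
  sizes <- sort(table(comp), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  tibble::tibble(marker = markers,
                 group = as.integer(relabel[as.character(comp)]))
}

#' Restrict a combined four-way map to one single cross
#'
#' The AB sub-map (the D276 x D72 single cross in the reference design)
#' cannot contain `A=B` markers, which are monomorphic in that cross;
#' likewise the CD sub-map drops `C=D` markers. Positions of the retained
#' markers are re-accumulated: from the recombination fractions of the new
#' adjacent pairs when `pairs` is supplied, otherwise from the combined
#' map's cM gaps (each chromosome restarting at 0).
#'
#' @param map A genetic map tibble (`marker`, `chrom`, `pos_cM`, `category`).
#' @param cross `"AB"` or `"CD"`.
#' @param pairs Optional [rf_pairs()] output for re-accumulation.
#' @param map_function Map function when `pairs` is used.
#' @return A genetic map tibble for the sub-cross.
#' @examples
#' map <- sim_map(seed = 1)
#' nrow(subset_map(map, "AB"))   # 221 - 61 = 160
#' @export
subset_map <- function(map, cross = c("AB", "CD"), pairs = NULL,
                       map_function = "haldane") {
  cross <- match.arg(cross)
  drop_cat <- if (cross == "AB") "A=B" else "C=D"
  purrr::map_dfr(unique(map$chrom), function(ch) {
    mk <- map[map$chrom == ch, ]
    mk <- mk[order(mk$pos_cM), ]
    keep <- mk[mk$category != drop_cat, ]
    if (nrow(keep) < 2) {
      warning("chromosome ", ch, " has fewer than 2 markers in the ", cross,
              " sub-map", call. = FALSE)
      if (nrow(keep) == 1) keep$pos_cM <- 0
      return(keep)
    }
    if (is.null(pairs)) {
      keep$pos_cM <- keep$pos_cM - keep$pos_cM[1]
    } else {
      pos <- build_map_positions(keep$marker, pairs[pairs$chrom == ch, ],
                                 map_function)
      keep$pos_cM <- pos$pos_cM[match(keep$marker, pos$marker)]
    }
    keep
  })
}

#' Summarise a genetic map
#'
#' Overall and per-chromosome statistics in the layout of a map-description
#' table: marker counts by information category, chromosome lengths, total
#' genome length, and the mean marker interval, defined as total length
#' divided by (markers - chromosomes), i.e. length per interval.
#'
#' @param map A genetic map tibble.
#' @param digits Rounding for the reported (not stored) positions.
#' @return A list of class `map_summary` with tibbles `overall` and
#'   `by_chrom`.
#' @examples
#' map_summary(sim_map(seed = 1))
#' @export
map_summary <- function(map, digits = 2) {
  stopifnot(nrow(map) > 0)
  by_chrom <- map |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_cM = max(.data$pos_cM) - min(.data$pos_cM),
      .groups = "drop"
    )
  cats <- map |>
    dplyr::count(.data$chrom, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  for (ct in MARKER_CATEGORIES) if (!ct %in% names(cats)) cats[[ct]] <- 0L
  by_chrom <- dplyr::left_join(by_chrom, cats[, c("chrom", MARKER_CATEGORIES)],
                               by = "chrom")
  n_mark <- nrow(map)
  n_chr <- nrow(by_chrom)
  total <- sum(by_chrom$length_cM)
  overall <- tibble::tibble(
    n_markers = n_mark,
    n_chromosomes = n_chr,
    total_length_cM = total,
    mean_interval_cM = if (n_mark > n_chr) total / (n_mark - n_chr) else NA_real_
  )
  structure(list(overall = overall, by_chrom = by_chrom, digits = digits),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Genetic map: %d markers on %d chromosomes, %.*f cM (mean interval %.*f cM)\n",
              o$n_markers, o$n_chromosomes, x$digits, o$total_length_cM,
              x$digits, o$mean_interval_cM))
  print(dplyr::mutate(x$by_chrom,
                      length_cM = round(.data$length_cM, x$digits)), ...)
  invisible(x)
}
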