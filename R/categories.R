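#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# The five marker information categories of a four-way cross (A x B) x (C x D).
# Which founder alleles are confounded determines which of the four genotype
# classes AC, AD, BC, BD can be told apart at the marker.
MARKER_CATEGORIES <- c("ABCD", "A=B", "C=D", "A=CB=D", "A=DB=C")

GENOTYPE_CLASSES <- c("AC", "AD", "BC", "BD")

# Observed-class code table: for each category, the observed code emitted by
# each latent ordered genotype. Codes use "-" for a confounded haplotype and
# "X/Y" for a genuinely ambiguous class.
OBSERVED_CODE_TABLE <- list(
  "ABCD"   = c(AC = "AC", AD = "AD", BC = "BC", BD = "BD"),
  "A=B"    = c(AC = "-C", AD = "-D", BC = "-C", BD = "-D"),
  "C=D"    = c(AC = "A-", AD = "A-", BC = "B-", BD = "B-"),
  "A=CB=D" = c(AC = "AC", AD = "AD/BC", BC = "AD/BC", BD = "BD"),
  "A=DB=C" = c(AC = "AC/BD", AD = "AD", BC = "BC", BD = "AC/BD")
)

# Design-variable coding per observed code: x_F (+1 paternal A, -1 paternal B,
# 0 unobservable), x_M (+1 maternal C, -1 maternal D, 0), and the interaction
# z. For ambiguous classes the codes are within-class expectations under the
# 1:1:1:1 genotype frequencies of a four-way cross, so that m + aF*xF + aM*xM
# + d*z stays an unbiased working regression (e.g. class {AD, BC} has
# E(xF) = E(xM) = 0 but xF*xM = -1 for both members, hence z = -1).
DESIGN_CODE_TABLE <- list(
  "AC"    = c(xF =  1, xM =  1, z =  1),
  "AD"    = c(xF =  1, xM = -1, z = -1),
  "BC"    = c(xF = -1, xM =  1, z = -1),
  "BD"    = c(xF = -1, xM = -1, z =  1),
  "-C"    = c(xF =  0, xM =  1, z =  0),
  "-D"    = c(xF =  0, xM = -1, z =  0),
  "A-"    = c(xF =  1, xM =  0, z =  0),
  "B-"    = c(xF = -1, xM =  0, z =  0),
  "AD/BC" = c(xF =  0, xM =  0, z = -1),
  "AC/BD" = c(xF =  0, xM =  0, z =  1)
)

# Haplotype information carried by each observed code, used when computing
# QTL genotype probabilities from flanking markers: paternal allele ("A",
# "B" or NA when confounded/ambiguous) and maternal allele ("C", "D" or NA).
FLANK_INFO_TABLE <- list(
  "AC"    = c(pat = "A", mat = "C"),
  "AD"    = c(pat = "A", mat = "D"),
  "BC"    = c(pat = "B", mat = "C"),
  "BD"    = c(pat = "B", mat = "D"),
  "-C"    = c(pat = NA,  mat = "C"),
  "-D"    = c(pat = NA,  mat = "D"),
  "A-"    = c(pat = "A", mat = NA),
  "B-"    = c(pat = "B", mat = NA),
  "AD/BC" = c(pat = NA,  mat = NA),
  "AC/BD" = c(pat = NA,  mat = NA)
)

#' Classify a marker into its information category from founder alleles
#'
#' In a four-way cross (A x B) x (C x D), a marker is useful only if its four
#' founder alleles fall into one of five confounding patterns: `ABCD` (all
#' four alleles distinct, fully informative), `A=B` (female-side parents
#' share an allele, only the maternal C/D haplotype is observable), `C=D`
#' (male-side parents share an allele, only the paternal A/B haplotype is
#' observable), `A=CB=D` and `A=DB=C` (cross-confounded patterns in which one
#' genotype class pair is indistinguishable). Any other pattern (monomorphic,
#' `A=B` and `C=D` simultaneously, three parents sharing an allele, ...)
#' segregates in neither single cross the way the model requires and is
#' rejected.
#'
#' @param founders A data frame with one row per marker and columns `a`, `b`,
#'   `c`, `d` holding allele identifiers (integers or strings) for the four
#'   founders in cross order, plus optionally `marker`; or a length-4 vector
#'   for a single marker.
#'
#' @return A tibble with columns `marker` (if supplied) and `category`
#'   (character, one of the five category labels).
#'
#' @examples
#' classify_marker(c(1, 2, 3, 4))          # ABCD
#' classify_marker(c(1, 1, 2, 3))          # A=B
#' classify_marker(c(1, 2, 2, 1))          # A=DB=C
#' @export
classify_marker <- function(founders) {
  if (is.atomic(founders)) {
    if (length(founders) != 4L) {
      stop("a single marker needs exactly four founder alleles", call. = FALSE)
    }
    founders <- tibble::tibble(
      a = founders[[1]], b = founders[[2]], c = founders[[3]], d = founders[[4]]
    )
  }
  stopifnot(all(c("a", "b", "c", "d") %in% names(founders)))
  cat_one <- function(a, b, c, d) {
    if (any(is.na(c(a, b, c, d)))) {
      stop("founder alleles must all be present", call. = FALSE)
    }
    ab <- a == b; cd <- c == d; ac <- a == c; bd <- b == d
    ad <- a == d; bc <- b == c
    if (ab && cd && ac) {
      stop("unusable marker: monomorphic across all four parents", call. = FALSE)
    }
    if (!ab && !cd && !ac && !bd && !ad && !bc) return("ABCD")
    if (ab && !cd && !ac && !ad) return("A=B")
    if (cd && !ab && !ac && !bc) return("C=D")
    if (ac && bd && !ab) return("A=CB=D")
    if (ad && bc && !ab) return("A=DB=C")
    pat <- paste0(a, "/", b, "/", c, "/", d)
    stop("unusable marker: allele pattern ", pat,
         " segregates in neither single cross under the five-category model",
         call. = FALSE)
  }
  out <- tibble::tibble(
    category = purrr::pmap_chr(
      list(founders$a, founders$b, founders$c, founders$d), cat_one
    )
  )
  if ("marker" %in% names(founders)) {
    out <- dplyr::bind_cols(tibble::tibble(marker = founders$marker), out)
  }
  out
}

#' Collapse latent four-way genotypes into observed marker classes
#'
#' Given a marker's information category, maps the latent ordered genotype
#' (paternal allele from \{A, B\}, maternal from \{C, D\}) to the class a
#' genotyping assay can actually distinguish. Fully informative markers keep
#' all four classes; `A=B` and `C=D` markers collapse to two classes; the
#' cross-confounded categories collapse one pair of genotypes into an
#' ambiguous class (`"AD/BC"` or `"AC/BD"`).
#'
#' @param category Character vector of marker categories (recycled).
#' @param genotype Character vector of latent genotypes, each one of
#'   `"AC"`, `"AD"`, `"BC"`, `"BD"`.
#'
#' @return Character vector of observed class codes. `NA` inputs give `NA`.
#'
#' @examples
#' collapse_observed("ABCD", "AC")      # "AC"
#' collapse_observed("A=B", "AD")       # "-D": maternal D seen, paternal lost
#' collapse_observed("A=DB=C", "AC")    # "AC/BD": ambiguous
#' @export
collapse_observed <- function(category, genotype) {
  n <- max(length(category), length(genotype))
  category <- rep_len(category, n)
  genotype <- rep_len(genotype, n)
  bad_cat <- !is.na(category) & !(category %in% MARKER_CATEGORIES)
  if (any(bad_cat)) {
    stop("unknown marker category: ", paste(unique(category[bad_cat]), collapse = ", "),
         call. = FALSE)
  }
  bad_gen <- !is.na(genotype) & !(genotype %in% GENOTYPE_CLASSES)
  if (any(bad_gen)) {
    stop("latent genotype must be one of AC, AD, BC, BD", call. = FALSE)
  }
  out <- rep(NA_character_, n)
  ok <- !is.na(category) & !is.na(genotype)
  out[ok] <- purrr::map2_chr(category[ok], genotype[ok],
                             ~ OBSERVED_CODE_TABLE[[.x]][[.y]])
  out
}

#' Observed codes that are valid for a category
#'
#' @param category A single marker category.
#' @return Character vector of the observed class codes the category can emit.
#' @examples
#' observed_codes("A=CB=D")
#' @export
observed_codes <- function(category) {
  if (!category %in% MARKER_CATEGORIES) {
    stop("unknown marker category: ", category, call. = FALSE)
  }
  unique(unname(OBSERVED_CODE_TABLE[[category]]))
}

#' Founder allele patterns realising each category
#'
#' Returns a canonical founder-allele assignment (small integers) for a
#' marker of the given category, used by the simulator.
#'
#' @param category Character vector of categories.
#' @return A tibble with columns `a`, `b`, `c`, `d`.
#' @keywords internal
category_founder_alleles <- function(category) {
  tab <- list(
    "ABCD"   = c(1L, 2L, 3L, 4L),
    "A=B"    = c(1L, 1L, 2L, 3L),
    "C=D"    = c(1L, 2L, 3L, 3L),
    "A=CB=D" = c(1L, 2L, 1L, 2L),
    "A=DB=C" = c(1L, 2L, 2L, 1L)
  )
  m <- do.call(rbind, lapply(category, function(ct) tab[[ct]]))
  tibble::tibble(a = m[, 1], b = m[, 2], c = m[, 3], d = m[, 4])
}
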