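#' Read and write the package's file dialects
#'
#' Plain-text formats with `NA` as the missing sentinel: the marker map is a
#' TSV (`marker`, `chrom`, `pos_cM`, `category`, optionally founder allele
#' columns `a`..`d`), genotypes are a CSV with lines as rows and markers as
#' columns of observed class codes, phenotypes are a long CSV (`line`,
#' `env`, `rep`, `value`), and the simulation truth file is a TSV of true
#' QTL. Loaders validate structure (unique marker names, genotype columns
#' present in the map, codes legal for each marker's category) and name the
#' offending cell on failure; write-then-read round-trips are exact.
#'
#' @param path File path.
#' @param map Genetic map tibble (for genotype validation on read, and as
#'   the object written by `write_map()`).
#' @param genotypes,phenotypes,qtl Objects to write.
#' @return The read functions return tibbles; the write functions return
#'   the path invisibly.
#' @name fourway_io
NULL

#' @rdname fourway_io
#' @export
read_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("marker", "chrom", "pos_cM", "category")
  if (!all(need %in% names(map))) {
    stop("map file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- map$marker[duplicated(map$marker)]
  if (length(dup)) {
    stop("duplicate marker name(s) in map: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(map$category), MARKER_CATEGORIES)
  if (length(bad)) {
    stop("unknown category string(s) in map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (any(diff(p) < 0)) {
      stop("positions are not non-decreasing on chromosome ", ch, call. = FALSE)
    }
  }
  map
}

#' @rdname fourway_io
#' @export
write_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' @rdname fourway_io
#' @export
read_genotypes <- function(path, map = NULL) {
  geno <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          na = "NA")
  if (!"line" %in% names(geno)) {
    stop("genotype file must have a 'line' column", call. = FALSE)
  }
  geno <- dplyr::mutate(geno, dplyr::across(-"line", as.character))
  if (!is.null(map)) {
    extra <- setdiff(names(geno), c("line", map$marker))
    if (length(extra)) {
      stop("genotype column(s) not in map: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    for (j in seq_len(nrow(map))) {
      mk <- map$marker[j]
      if (!mk %in% names(geno)) next
      valid <- observed_codes(map$category[j])
      bad <- which(!is.na(geno[[mk]]) & !(geno[[mk]] %in% valid))
      if (length(bad)) {
        stop("invalid code '", geno[[mk]][bad[1]], "' for marker ", mk,
             " (category ", map$category[j], ") at row ", bad[1],
             call. = FALSE)
      }
    }
  }
  geno
}

#' @rdname fourway_io
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_csv(genotypes, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname fourway_io
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("line", "env", "rep", "value")
  if (!all(need %in% names(ph))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ph
}

#' @rdname fourway_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_csv(phenotypes, path, progress = FALSE)
  invisible(path)
}

#' @rdname fourway_io
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname fourway_io
#' @export
write_truth <- function(qtl, path) {
  readr::write_tsv(qtl, path, progress = FALSE)
  invisible(path)
}

#' Write a simulated population to a directory
#'
#' Emits the four files of the documented dialects: `genotypes.csv`,
#' `map.tsv`, `phenotypes.csv` and `truth.tsv`.
#'
#' @param pop A `fourway_pop` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_population <- function(pop, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_map(pop$map, file.path(dir, "map.tsv"))
  write_genotypes(pop$genotypes, file.path(dir, "genotypes.csv"))
  write_phenotypes(pop$phenotypes, file.path(dir, "phenotypes.csv"))
  write_truth(pop$qtl, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Load a run configuration
#'
#' A declarative YAML file with paths (`map`, `genotypes`, `phenotypes`,
#' optionally `anchors`, `truth`), the analysis parameters (`seed`,
#' `map_function`, `step`, `p_enter`, `p_remove`, `threshold`, `alpha_g`,
#' `density_factor`, `env`, `n_perm`) and `out_dir`. A seed is mandatory
#' whenever a stochastic stage (`threshold: permutation`) is enabled, and
#' all referenced files must exist at load.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return The validated configuration as a named list.
#' @export
read_run_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(map_function = "haldane", step = 1, p_enter = 0.001,
                   p_remove = 0.002, threshold = "formula", alpha_g = 0.05,
                   density_factor = 0.072, env = "mean", n_perm = 1000,
                   out_dir = ".", report_digits = 2)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("map", "genotypes", "phenotypes", "anchors", "truth")) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      stop("configured ", nm, " file does not exist: ", config[[nm]],
           call. = FALSE)
    }
  }
  if (identical(config$threshold, "permutation") && is.null(config$seed)) {
    stop("a seed is required in the config when permutation thresholds are ",
         "enabled", call. = FALSE)
  }
  config
}

#' Run the full four-way QTL pipeline from a configuration
#'
#' Executes describe -> ANOVA/heritability -> map summary -> threshold ->
#' ICIM scan, logging each stage, and writes rounded report tables plus
#' full-precision companions to the configured output directory. Outputs
#' are deterministic given the configuration (including its seed).
#'
#' @param config A YAML path or named list accepted by [read_run_config()].
#' @param quiet Suppress stage messages.
#' @return A list of class `fourway_run`: `describe`, `components`,
#'   `heritability`, `map_summary`, `threshold`, `scan`, `config`,
#'   invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  say <- function(...) if (!quiet) message("[fourwayqtl] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  dg <- config$report_digits

  say("reading inputs")
  map <- stage("read", read_map(config$map))
  geno <- stage("read", read_genotypes(config$genotypes, map))
  pheno <- stage("read", read_phenotypes(config$phenotypes))

  say("describing phenotypes")
  desc <- stage("describe", describe_phenotypes(pheno))
  readr::write_tsv(dplyr::mutate(desc, dplyr::across(dplyr::where(is.numeric),
                                                     ~ round(.x, dg))),
                   file.path(out, "phenotype_summary.tsv"), progress = FALSE)
  readr::write_tsv(desc, file.path(out, "phenotype_summary_full.tsv"),
                   progress = FALSE)

  multi_env <- length(unique(pheno$env)) > 1
  vc <- NULL; H <- NA_real_
  if (multi_env || length(unique(pheno$rep)) > 1) {
    say("estimating variance components")
    vc <- stage("anova", anova_components(pheno))
    H <- heritability(vc)
    readr::write_tsv(dplyr::mutate(glance(vc),
                                   dplyr::across(dplyr::where(is.numeric),
                                                 ~ round(.x, dg))),
                     file.path(out, "variance_components.tsv"),
                     progress = FALSE)
  }

  say("summarising map")
  ms <- stage("map-summary", map_summary(map, digits = dg))
  readr::write_tsv(ms$by_chrom, file.path(out, "map_by_chromosome.tsv"),
                   progress = FALSE)
  readr::write_tsv(ms$overall, file.path(out, "map_overall.tsv"),
                   progress = FALSE)

  say("determining LOD threshold (", config$threshold, ")")
  thr <- stage("threshold", {
    if (identical(config$threshold, "permutation")) {
      pt <- lod_threshold_permutation(
        pheno, geno, map, n_perm = config$n_perm, alpha_g = config$alpha_g,
        seed = config$seed, step = config$step, env = config$env,
        p_enter = config$p_enter, p_remove = config$p_remove,
        map_function = config$map_function)
      readr::write_tsv(tibble::tibble(max_lod = pt$max_lods),
                       file.path(out, "permutation_max_lods.tsv"),
                       progress = FALSE)
      pt$threshold
    } else if (identical(config$threshold, "formula")) {
      "formula"
    } else as.numeric(config$threshold)
  })

  say("running ICIM scan (step ", config$step, " cM, env ", config$env, ")")
  scan <- stage("scan", icim_scan(
    pheno, geno, map, step = config$step, env = config$env,
    p_enter = config$p_enter, p_remove = config$p_remove,
    threshold = thr, alpha_g = config$alpha_g,
    density_factor = config$density_factor,
    map_function = config$map_function))
  readr::write_tsv(scan$profile, file.path(out, "scan_profile.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::mutate(scan$qtl,
                                 dplyr::across(dplyr::where(is.numeric),
                                               ~ round(.x, dg))),
                   file.path(out, "qtl_calls.tsv"), progress = FALSE)
  readr::write_tsv(scan$qtl, file.path(out, "qtl_calls_full.tsv"),
                   progress = FALSE)

  say("done: ", nrow(scan$qtl), " QTL at LOD >= ", round(scan$threshold, dg))
  invisible(structure(list(describe = desc, components = vc,
                           heritability = H, map_summary = ms,
                           threshold = scan$threshold, scan = scan,
                           config = config),
                      class = "fourway_run"))
}
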