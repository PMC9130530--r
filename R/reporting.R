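#' Frequency and taxon report for an age-structured survey
#'
#' Assembles the published-table-shaped frequency output (family, species,
#' AF/RF/CRF per age class, ordered by total AF descending) together with a
#' taxon summary: species, genus and family counts, native percentage and
#' age-class-exclusive species counts. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param adult,juvenile `incidence` objects over the same site set.
#' @param traits Optional species trait tibble (see [read_traits_csv()]);
#'   without it the origin-based summary fields are `NA` and a warning is
#'   given.
#' @return A list with `frequency` (tibble in the 11-column table layout)
#'   and `summary` (one-row tibble).
#' @export
report_frequency <- function(adult, juvenile, traits = NULL) {
  total <- merge_age_classes(adult, juvenile)
  n_sites <- ncol(total)
  sp <- rownames(total)
  af <- function(m) {
    v <- setNames(integer(length(sp)), sp)
    v[rownames(m)] <- rowSums(m)
    v
  }
  freq <- tibble(species = sp, AF_total = af(total), AF_adult = af(adult),
                 AF_juv = af(juvenile)) %>%
    arrange(desc(.data$AF_total))
  for (cls in c("total", "adult", "juv")) {
    rf <- 100 * freq[[paste0("AF_", cls)]] / n_sites
    freq[[paste0("RF_", cls)]] <- round_half_up(rf)
    freq[[paste0("CRF_", cls)]] <- cumsum(rf)
  }
  if (!is.null(traits)) {
    freq <- left_join(freq, select(traits, "species", "family"),
                      by = "species")
    tx <- taxon_counts(traits)
  } else {
    warn("no traits table supplied; origin- and family-based summary fields are NA")
    freq$family <- NA_character_
    tx <- tibble(species = length(sp), genera = NA_integer_,
                 families = NA_integer_, pct_native = NA_real_,
                 pct_native_pct = NA_real_)
  }
  freq <- select(freq, "family", "species",
                 "AF_total", "RF_total", "CRF_total",
                 "AF_adult", "RF_adult", "CRF_adult",
                 "AF_juv", "RF_juv", "CRF_juv")
  excl <- count_exclusive_species(adult, juvenile)
  singletons <- sum(freq$AF_total == 1)
  list(frequency = freq,
       summary = dplyr::bind_cols(
         tx, excl,
         tibble(n_sites = n_sites, singleton_species = singletons,
                pct_singletons = 100 * singletons / length(sp))))
}

#' EMS report across age classes
#'
#' Runs [ems_analyze()] on each supplied age-class matrix (typically adult,
#' juvenile and total) with a common null-model configuration. A degenerate
#' matrix records an error entry for its age class and the run continues.
#'
#' @param matrices Named list of `incidence` objects (names are age-class
#'   labels).
#' @param iterations,seed,alpha,direction,method Passed to [ems_analyze()];
#'   each age class uses an independent sub-seed derived from `seed`.
#' @param coords Optional site coordinate tibble (`site`, `latitude`,
#'   `longitude`).
#' @return A list with `results` (named list of `ems_result` or error
#'   condition), `summary` (tibble: one row per successful age class) and
#'   `scores` (tibble in the site-score table layout: `site`, coordinates if
#'   given, one score column per age class).
#' @export
report_ems <- function(matrices, iterations = 1000, seed = NULL, alpha = 0.05,
                       direction = "rowcol", method = "normal",
                       coords = NULL) {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  results <- list()
  for (i in seq_along(matrices)) {
    nm <- names(matrices)[i]
    sub_seed <- if (is.null(seed)) NULL else seed + i - 1L
    results[[nm]] <- tryCatch(
      ems_analyze(matrices[[i]], iterations = iterations, seed = sub_seed,
                  alpha = alpha, direction = direction, method = method,
                  coords = coords),
      error = function(e) e)
  }
  ok <- !vapply(results, inherits, logical(1), "condition")
  summary <- purrr::map_dfr(results[ok], glance, .id = "matrix")
  scores <- NULL
  for (nm in names(results)[ok]) {
    sc <- rename(results[[nm]]$site_scores, !!paste0("score_", nm) := "score")
    scores <- if (is.null(scores)) sc else {
      left_join(scores, select(sc, "site", dplyr::starts_with("score_")),
                by = "site")
    }
  }
  list(results = results, summary = summary, scores = scores)
}

#' Landscape metric report over multiple scenes
#'
#' Applies [summarize_buffer()] to each raster and stacks the rows in the
#' per-site metric table layout. A raster that fails to process yields a row
#' of `NA` metrics with the error message recorded.
#'
#' @param rasters Named list of [landscape_raster()] objects (names become
#'   site ids).
#' @param focal_patch_ids Optional vector of focal patch ids, recycled.
#' @param exclude Classes excluded before analysis (see
#'   [summarize_buffer()]).
#' @return A tibble with columns `ID`, the 14 metric columns, and `error`.
#' @export
report_landscape <- function(rasters, focal_patch_ids = NULL,
                             exclude = c("water", "urban")) {
  stopifnot(length(rasters) >= 1, !is.null(names(rasters)))
  purrr::map_dfr(seq_along(rasters), function(i) {
    out <- tryCatch(
      summarize_buffer(rasters[[i]],
                       focal_patch_id = if (is.null(focal_patch_ids)) NULL
                                        else focal_patch_ids[[i]],
                       exclude = exclude),
      error = function(e) e)
    if (inherits(out, "condition")) {
      na_row <- as.list(rep(NA_real_, 14))
      names(na_row) <- c("NP", "LSI", "SHEI", "AI", "P_NF", "P_GL", "P_TF",
                         "P_C", "N_NF", "IJI", "ENN", "AREA", "PARA", "SHAPE")
      dplyr::bind_cols(tibble(ID = names(rasters)[i]), as_tibble(na_row),
                       tibble(error = conditionMessage(out)))
    } else {
      dplyr::bind_cols(tibble(ID = names(rasters)[i]), out,
                       tibble(error = NA_character_))
    }
  })
}

#' Write report tables
#'
#' CSV/JSON writers for the report objects: the frequency table keeps the
#' 11-column layout; the EMS report writes the summary as JSON and the
#' site scores as CSV; the landscape table keeps the metric column order.
#'
#' @param report A [report_frequency()] / [report_ems()] result, or the
#'   [report_landscape()] tibble.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, prefix = "emsland") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  if (is.data.frame(report)) {                       # landscape table
    p <- file.path(dir, paste0(prefix, "_landscape.csv"))
    readr::write_csv(report, p, na = "NA"); add(p)
  } else if (!is.null(report$frequency)) {           # frequency report
    p1 <- file.path(dir, paste0(prefix, "_frequency.csv"))
    readr::write_csv(report$frequency, p1, na = ""); add(p1)
    p2 <- file.path(dir, paste0(prefix, "_taxon_summary.json"))
    jsonlite::write_json(as.list(report$summary), p2, auto_unbox = TRUE,
                         digits = NA); add(p2)
  } else if (!is.null(report$results)) {             # EMS report
    p1 <- file.path(dir, paste0(prefix, "_ems_summary.json"))
    jsonlite::write_json(report$summary, p1, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA); add(p1)
    if (!is.null(report$scores)) {
      p2 <- file.path(dir, paste0(prefix, "_ems_scores.csv"))
      readr::write_csv(report$scores, p2); add(p2)
    }
  } else {
    abort("unrecognized report object")
  }
  invisible(paths)
}
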