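#' Species frequency table (absolute, relative, cumulative relative)
#'
#' For each species, AF is the number of occupied sites (row sum), RF the
#' relative frequency `100 * AF / n_sites`, and CRF the running sum of the
#' unrounded RF down the AF-descending order (ties keep input order). RF is
#' reported both unrounded and rounded half-up to integer percent, the
#' rounding used in frequency tables of this kind (31/32 -> 97, 30/32 -> 94,
#' 29/32 -> 91).
#'
#' @param m An [incidence_matrix()].
#' @return A tibble sorted AF-descending with columns `species`, `AF`, `RF`
#'   (unrounded), `RF_pct` (half-up integer percent) and `CRF`.
#' @examples
#' m <- incidence_matrix(matrix(c(1, 1, 1, 0), 2, 2,
#'   dimnames = list(c("a", "b"), c("s1", "s2"))))
#' frequency_table(m)
#' @export
frequency_table <- function(m) {
  if (ncol(m) < 1) abort("need at least one site")
  af <- unname(rowSums(m))
  tibble(species = rownames(m), AF = as.integer(af),
         RF = 100 * af / ncol(m)) %>%
    mutate(RF_pct = round_half_up(.data$RF)) %>%
    arrange(desc(.data$AF)) %>%
    mutate(CRF = cumsum(.data$RF))
}

round_half_up <- function(x) floor(x + 0.5)

#' Age-class-exclusive and single-site species counts
#'
#' Cross-tabulates which species occur only among adults, only in the
#' regeneration (juvenile) layer, and which occur at a single site in one or
#' both layers.
#'
#' @param adult,juvenile `incidence` objects over the same site set.
#' @return A tibble with one row and columns `adult_only`, `juvenile_only`,
#'   `single_site_both`, `single_site_adult`, `single_site_juvenile`.
#'   `adult_only` counts species with at least one adult record and no
#'   juvenile record (symmetrically for `juvenile_only`); the `single_site_*`
#'   counts classify species whose total (union) range is exactly one site by
#'   the layers recorded there.
#' @export
count_exclusive_species <- function(adult, juvenile) {
  if (!setequal(colnames(adult), colnames(juvenile))) {
    abort("adult and juvenile matrices must share the same site set")
  }
  juvenile <- juvenile[, colnames(adult), drop = FALSE]
  sp <- union(rownames(adult), rownames(juvenile))
  af_a <- setNames(integer(length(sp)), sp)
  af_j <- af_a
  af_a[rownames(adult)] <- rowSums(adult)
  af_j[rownames(juvenile)] <- rowSums(juvenile)
  # union AF without materializing the merged matrix
  tot <- merge_age_classes(adult, juvenile)
  af_t <- setNames(rowSums(tot)[sp], sp)
  single <- af_t == 1
  tibble(
    adult_only = sum(af_a >= 1 & af_j == 0),
    juvenile_only = sum(af_j >= 1 & af_a == 0),
    single_site_both = sum(single & af_a >= 1 & af_j >= 1),
    single_site_adult = sum(single & af_a >= 1 & af_j == 0),
    single_site_juvenile = sum(single & af_j >= 1 & af_a == 0)
  )
}

#' Counts of species, genera, families and native percentage
#'
#' Genus is the first whitespace-delimited token of the binomial. Synonymous
#' names are not collapsed: counts follow the table as given.
#'
#' @param records Data frame of species records with at least `species` and
#'   `family` columns; an `origin` column (native/exotic) enables
#'   `pct_native`.
#' @return A one-row tibble: `species`, `genera`, `families`, `pct_native`
#'   (unrounded percent; `NA` when origin is absent) and `pct_native_pct`
#'   (half-up integer).
#' @export
taxon_counts <- function(records) {
  if (nrow(records) == 0) abort("records must be nonempty")
  pct <- if ("origin" %in% names(records)) {
    100 * sum(records$origin == "native") / nrow(records)
  } else NA_real_
  tibble(
    species = length(unique(records$species)),
    genera = length(unique(sub("\\s.*$", "", records$species))),
    families = length(unique(records$family)),
    pct_native = pct,
    pct_native_pct = round_half_up(pct)
  )
}

#' Per-group site richness summary
#'
#' Site richness is the column sum of the incidence matrix. Groups (for
#' example forest types) are summarized by min, max, mean and sample standard
#' deviation (denominator n - 1; `NA` for single-site groups).
#'
#' @param m An [incidence_matrix()].
#' @param groups Named character vector or single label: `groups[site]` gives
#'   the group of each site. Unnamed scalars label all sites alike.
#' @return A tibble with one row per group: `group`, `n_sites`, `min`, `max`,
#'   `mean`, `sd`.
#' @export
richness_summary <- function(m, groups = "all") {
  rich <- colSums(m)
  if (length(groups) == 1 && is.null(names(groups))) {
    groups <- setNames(rep(groups, ncol(m)), colnames(m))
  }
  miss <- setdiff(colnames(m), names(groups))
  if (length(miss)) abort(paste("unlabeled sites:", paste(miss, collapse = ", ")))
  tibble(site = colnames(m), richness = as.integer(rich),
         group = unname(groups[colnames(m)])) %>%
    group_by(.data$group) %>%
    summarise(n_sites = n(),
              min = min(.data$richness), max = max(.data$richness),
              mean = mean(.data$richness),
              sd = if (n() > 1) sd(.data$richness) else NA_real_,
              .groups = "drop")
}
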