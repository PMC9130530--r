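#' Incidence matrices of species occurrences across sites
#'
#' An `incidence` object stores a boolean species-by-sites occupancy matrix
#' together with an age-class tag. Rows are species, columns are sites; this
#' orientation is fixed throughout the package. Surveys that record woody
#' plants in two size classes keep one matrix per class (`"adult"`: dbh >= 5
#' cm, `"juvenile"`: dbh < 5 cm) plus their union (`"total"`).
#'
#' @param data A data frame whose first column holds species names and whose
#'   remaining columns are sites with 0/1 (or logical) occupancy, or a logical
#'   matrix with species as rownames and sites as colnames.
#' @param age_class One of `"adult"`, `"juvenile"`, `"total"`.
#'
#' @return An object of class `incidence`: a logical matrix with `species` on
#'   rows, `site` on columns and an `age_class` attribute.
#' @examples
#' df <- tibble::tibble(species = c("sp A", "sp B"), s1 = c(1, 0), s2 = c(0, 1))
#' incidence_matrix(df, "total")
#' @export
incidence_matrix <- function(data, age_class = c("total", "adult", "juvenile")) {
  age_class <- match.arg(age_class)
  if (is.matrix(data)) {
    occ <- data
    if (is.numeric(occ)) {
      bad <- !(occ %in% c(0, 1))
      if (any(bad)) {
        ij <- which(bad, arr.ind = TRUE)[1, ]
        abort(sprintf("non-binary value at (%s, %s)",
                      rownames(occ)[ij[1]] %||% ij[1],
                      colnames(occ)[ij[2]] %||% ij[2]))
      }
      occ <- occ == 1
    }
    if (is.null(rownames(occ))) rownames(occ) <- paste0("sp", seq_len(nrow(occ)))
    if (is.null(colnames(occ))) colnames(occ) <- paste0("site", seq_len(ncol(occ)))
  } else {
    data <- as.data.frame(data)
    if (ncol(data) < 2) abort("need a species column plus at least one site column")
    species <- as.character(data[[1]])
    cells <- data[, -1, drop = FALSE]
    occ <- matrix(FALSE, nrow(cells), ncol(cells),
                  dimnames = list(species, colnames(cells)))
    for (j in seq_along(cells)) {
      v <- cells[[j]]
      if (is.logical(v)) { occ[, j] <- v; next }
      v_num <- suppressWarnings(as.numeric(as.character(v)))
      bad <- is.na(v_num) | !(v_num %in% c(0, 1))
      if (any(bad)) {
        abort(sprintf("non-binary value at (%s, %s)",
                      species[which(bad)[1]], colnames(cells)[j]))
      }
      occ[, j] <- v_num == 1
    }
  }
  if (anyDuplicated(rownames(occ))) abort("duplicate species ids")
  if (anyDuplicated(colnames(occ))) abort("duplicate site ids")
  structure(occ, class = c("incidence", "matrix"), age_class = age_class)
}

#' @export
print.incidence <- function(x, ...) {
  cat(sprintf("<incidence> %d species x %d sites (%s), fill %.2f\n",
              nrow(x), ncol(x), age_class(x), mean(x)))
  invisible(x)
}

#' @rdname incidence_matrix
#' @param x An `incidence` object.
#' @export
age_class <- function(x) attr(x, "age_class") %||% "total"

#' @export
as_tibble.incidence <- function(x, ...) {
  out <- tibble(species = rownames(x))
  for (j in colnames(x)) out[[j]] <- as.integer(x[, j])
  out
}

#' Read and write incidence matrices as CSV
#'
#' The CSV dialect has a header row of site ids, a first column `species`, and
#' 0/1 cells. Reading preserves input order; empty rows and columns are kept
#' (downstream analyses decide whether to drop them).
#'
#' @param path File path.
#' @param age_class Age class tag for the matrix read.
#' @return `read_incidence_csv()` returns an [incidence_matrix()];
#'   `write_incidence_csv()` returns `path` invisibly.
#' @export
read_incidence_csv <- function(path, age_class = c("total", "adult", "juvenile")) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        comment = "#")
  incidence_matrix(df, match.arg(age_class))
}

#' @rdname read_incidence_csv
#' @param m An `incidence` object.
#' @export
write_incidence_csv <- function(m, path) {
  readr::write_csv(as_tibble(m), path)
  invisible(path)
}

#' Merge adult and juvenile incidence matrices into a total matrix
#'
#' The total layer is the element-wise OR over the union of the two species
#' lists; both inputs must cover exactly the same sites. Species present in
#' only one layer appear in the union with implicit absences in the other.
#'
#' @param adult,juvenile `incidence` objects sharing a site set.
#' @return An `incidence` with `age_class = "total"`. Species order: adult
#'   species first (input order), then juvenile-only species.
#' @export
merge_age_classes <- function(adult, juvenile) {
  if (!setequal(colnames(adult), colnames(juvenile)) ||
      ncol(adult) != ncol(juvenile)) {
    abort("adult and juvenile matrices must share the same site set")
  }
  juvenile <- juvenile[, colnames(adult), drop = FALSE]
  sp <- union(rownames(adult), rownames(juvenile))
  occ <- matrix(FALSE, length(sp), ncol(adult),
                dimnames = list(sp, colnames(adult)))
  occ[rownames(adult), ] <- adult
  occ[rownames(juvenile), ] <- occ[rownames(juvenile), , drop = FALSE] |
    unclass(juvenile)
  incidence_matrix(occ, "total")
}

#' Read a species trait table
#'
#' Expected columns: `species`, `family`, `growth_form` (tree, shrub, both,
#' mistletoe, liana), `origin` (native/exotic), `priority` (logical
#' conservation-priority flag) and optionally `dispersal` (zoochore,
#' anemochore, autochore, unknown). The genus of a species is its first
#' whitespace-delimited name token.
#'
#' @param path CSV file path.
#' @return A tibble of species records.
#' @export
read_traits_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        comment = "#")
  need <- c("species", "family")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste("traits table missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(df$species)) abort("duplicate species in traits table")
  if (!"dispersal" %in% names(df)) df$dispersal <- "unknown"
  df
}
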