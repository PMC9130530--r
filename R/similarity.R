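#' Jaccard similarity between two communities
#'
#' `J = shared / (shared + unique_a + unique_b)` over species presences.
#' Two empty communities are defined as identical (`J = 1`).
#'
#' @param a,b Logical or 0/1 vectors over the same species list.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Morisita-Horn overlap between two communities
#'
#' `C = 2 * sum(a_i b_i) / ((d_a + d_b) * N_a * N_b)` with
#' `d = sum(x^2) / N^2`. The Morisita-Horn form is used because incidence
#' (0/1) data carry no integer abundances; it equals 1 for identical
#' communities and 0 for disjoint ones.
#'
#' @param a,b Nonnegative count vectors (incidence treated as 0/1 counts)
#'   over the same species list, each with positive total.
#' @return Overlap in `[0, 1]`.
#' @export
morisita_overlap <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  na <- sum(a); nb <- sum(b)
  if (na == 0 || nb == 0) abort("zero-sum community vector")
  da <- sum(a^2) / na^2
  db <- sum(b^2) / nb^2
  2 * sum(a * b) / ((da + db) * na * nb)
}

#' Great-circle distance between two coordinates
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p,q Numeric `c(latitude, longitude)` in decimal degrees.
#' @return Kilometers.
#' @export
great_circle_km <- function(p, q) {
  chk <- function(x) {
    if (abs(x[1]) > 90 || abs(x[2]) > 180) abort("coordinates out of range")
  }
  chk(p); chk(q)
  # geosphere expects (lon, lat)
  geosphere::distHaversine(c(p[2], p[1]), c(q[2], q[1]), r = 6371000) / 1000
}

#' Distance-overlap matrix between sites
#'
#' Builds the square site-by-site summary matrix used to inspect distance
#' decay of community similarity: great-circle distances (km) in the lower
#' triangle, Morisita-Horn overlap of incidence in the upper triangle, and
#' an empty diagonal. Rows/columns are ordered by increasing distance from a
#' reference site.
#'
#' @param m An [incidence_matrix()] (typically the total age class).
#' @param coords Data frame with columns `site`, `latitude`, `longitude`
#'   covering every site of `m`.
#' @param reference_site Site id anchoring the ordering (default: first site
#'   of `m`).
#' @return An object of class `pairwise_matrix`: numeric matrix with `NA`
#'   diagonal and a `site_order` attribute.
#' @export
distance_overlap_matrix <- function(m, coords, reference_site = NULL) {
  sites <- colnames(m)
  coords <- as.data.frame(coords)
  miss <- setdiff(sites, coords$site)
  if (length(miss)) abort(paste("missing coordinates for:",
                                paste(miss, collapse = ", ")))
  rownames(coords) <- coords$site
  reference_site <- reference_site %||% sites[1]
  n <- length(sites)
  dk <- matrix(0, n, n, dimnames = list(sites, sites))
  ov <- dk
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dk[i, j] <- great_circle_km(
      unlist(coords[sites[i], c("latitude", "longitude")]),
      unlist(coords[sites[j], c("latitude", "longitude")]))
    ov[i, j] <- morisita_overlap(m[, i], m[, j])
  }
  ord <- order(dk[reference_site, ])
  dk <- dk[ord, ord]; ov <- ov[ord, ord]
  out <- dk
  out[upper.tri(out)] <- ov[upper.tri(ov)]
  diag(out) <- NA_real_
  structure(out, class = c("pairwise_matrix", "matrix"),
            site_order = colnames(out), reference_site = reference_site)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %d sites (lower: km, upper: overlap), ref %s\n",
              nrow(x), attr(x, "reference_site")))
  print(round(unclass(x), 2))
  invisible(x)
}

#' @rdname distance_overlap_matrix
#' @param x A `pairwise_matrix`.
#' @param ... Unused.
#' @return `tidy()` returns a long tibble with one row per ordered site pair
#'   and columns `site_a`, `site_b`, `distance_km`, `overlap`.
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  sites <- colnames(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  tibble(site_a = sites[idx[, "col"]], site_b = sites[idx[, "row"]],
         distance_km = x[idx],
         overlap = x[cbind(idx[, "col"], idx[, "row"])])
}

#' Write a distance-overlap matrix as CSV
#'
#' Mirrors the printed layout: first column `ID`, one column per site,
#' distances (km, 1 decimal) below the diagonal, overlap (2 decimals) above,
#' empty diagonal cells.
#'
#' @param pm A [distance_overlap_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_csv <- function(pm, path) {
  n <- nrow(pm)
  chr <- matrix("", n, n)
  chr[lower.tri(chr)] <- sprintf("%.1f", pm[lower.tri(pm)])
  chr[upper.tri(chr)] <- sprintf("%.2f", pm[upper.tri(pm)])
  df <- as.data.frame(chr)
  names(df) <- colnames(pm)
  df <- cbind(ID = rownames(pm), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}
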