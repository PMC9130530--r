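#' Categorical land-use rasters
#'
#' A `landscape_raster` wraps an integer matrix of land-use class codes on a
#' square-cell lattice. The default class map follows a six-type land-use
#' legend: 1 native_forest, 2 grassland, 3 timber, 4 crops, 5 water,
#' 6 urban.
#'
#' @param grid Integer matrix of class codes (`NA` or `nodata` = no data).
#' @param cell_size Cell edge length in meters (> 0).
#' @param nodata Reserved no-data code (converted to `NA` internally).
#' @param class_names Named character vector mapping codes to labels.
#' @return An object of class `landscape_raster`.
#' @export
landscape_raster <- function(grid, cell_size = 30,
                             nodata = NA_integer_,
                             class_names = default_class_names()) {
  stopifnot(is.matrix(grid), cell_size > 0)
  grid <- matrix(as.integer(grid), nrow(grid), ncol(grid))
  if (!is.na(nodata)) grid[grid == nodata] <- NA_integer_
  if (all(is.na(grid))) abort("raster contains no valid cells")
  codes <- sort(unique(grid[!is.na(grid)]))
  unknown <- setdiff(codes, as.integer(names(class_names)))
  if (length(unknown)) {
    class_names <- c(class_names,
                     setNames(paste0("class_", unknown), unknown))
  }
  structure(list(grid = grid, cell_size = cell_size,
                 class_names = class_names),
            class = "landscape_raster")
}

#' @rdname landscape_raster
#' @export
default_class_names <- function() {
  c(`1` = "native_forest", `2` = "grassland", `3` = "timber",
    `4` = "crops", `5` = "water", `6` = "urban")
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("<landscape_raster> %d x %d cells @ %g m, classes: %s\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              paste(x$class_names[as.character(present_codes(x))],
                    collapse = ", ")))
  invisible(x)
}

present_codes <- function(r) sort(unique(r$grid[!is.na(r$grid)]))

#' @rdname landscape_raster
#' @param object A `landscape_raster`.
#' @param ... Unused.
#' @method autoplot landscape_raster
#' @export
autoplot.landscape_raster <- function(object, ...) {
  g <- object$grid
  df <- tidyr::expand_grid(row = seq_len(nrow(g)), col = seq_len(ncol(g)))
  df$class <- object$class_names[as.character(as.vector(t(g))[
    (df$row - 1) * ncol(g) + df$col])]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "land use") +
    ggplot2::theme_void()
}

#' Read and write ESRI ASCII grids
#'
#' Minimal reader/writer for the ASCII grid interchange format (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` header
#' followed by row-major cell values, first row = northernmost).
#'
#' @param path File path.
#' @param class_names Passed to [landscape_raster()].
#' @return `read_asc()` returns a [landscape_raster()]; `write_asc()` returns
#'   `path` invisibly.
#' @export
read_asc <- function(path, class_names = default_class_names()) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) abort(paste("ASCII grid header missing", k))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort("ASCII grid cell count does not match header")
  }
  g <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols,
              byrow = TRUE)
  landscape_raster(g, cell_size = hdr$cellsize,
                   nodata = if (is.null(hdr$nodata_value)) NA_integer_
                            else as.integer(hdr$nodata_value),
                   class_names = class_names)
}

#' @rdname read_asc
#' @param r A `landscape_raster`.
#' @param nodata No-data code to write.
#' @export
write_asc <- function(r, path, nodata = -9999L) {
  g <- r$grid
  g[is.na(g)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %g", r$cell_size),
           sprintf("NODATA_value %d", nodata))
  body <- apply(g, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Label patches (connected components) of a categorical raster
#'
#' Patches are maximal 8-connected sets of same-class cells. Per-patch area
#' is `cells * cell_size^2`; perimeter counts every cell edge adjacent to a
#' different class, to no-data, or to the raster boundary, times
#' `cell_size`.
#'
#' @param r A [landscape_raster()].
#' @return An object of class `patch_set`: list with the source `raster` and
#'   a `patches` tibble (`patch_id`, `class`, `class_name`, `n_cells`,
#'   `area`, `perimeter`, `cells` list-column of cell indices).
#' @export
label_patches <- function(r) {
  g <- r$grid
  nr <- nrow(g); nc <- ncol(g)
  valid <- which(!is.na(g))
  if (!length(valid)) abort("raster contains no valid cells")
  # same-class 8-neighbour adjacency as an igraph edge list
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  shifts <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr); c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    r2 <- r1 + dr; c2 <- c1 + dc
    a <- idx[r1, c1]; b <- idx[r2, c2]
    same <- !is.na(g[a]) & !is.na(g[b]) & g[a] == g[b]
    edges[[length(edges) + 1]] <- cbind(a[same], b[same])
  }
  el <- do.call(rbind, edges)
  gr <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (nrow(el)) gr <- igraph::add_edges(gr, t(el))
  memb <- igraph::components(gr)$membership
  memb[-valid] <- NA
  comp_ids <- unique(memb[valid])
  # perimeter per cell: 4 minus like-class rook neighbours
  per_cell <- perimeter_cells(g)
  patches <- purrr::map_dfr(seq_along(comp_ids), function(i) {
    cells <- which(memb == comp_ids[i])
    tibble(patch_id = i, class = g[cells[1]],
           n_cells = length(cells),
           perim_edges = sum(per_cell[cells]),
           cells = list(cells))
  })
  patches <- patches %>%
    mutate(class_name = r$class_names[as.character(.data$class)],
           area = .data$n_cells * r$cell_size^2,
           perimeter = .data$perim_edges * r$cell_size) %>%
    select("patch_id", "class", "class_name", "n_cells", "area",
           "perimeter", "cells")
  structure(list(raster = r, patches = patches), class = "patch_set")
}

# per-cell count of exposed rook edges (different class, NA, or boundary)
perimeter_cells <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(NA_integer_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  expo <- matrix(0L, nr, nc)
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + s[1], 2:(nc + 1) + s[2]]
    expo <- expo + (is.na(nb) | nb != core)
  }
  expo[is.na(core)] <- 0L
  expo
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches over %d classes\n",
              nrow(x$patches), length(unique(x$patches$class))))
  invisible(x)
}

landscape_area <- function(ps) {
  sum(!is.na(ps$raster$grid)) * ps$raster$cell_size^2
}

resolve_class <- function(ps, class) {
  cn <- ps$raster$class_names
  if (is.character(class)) {
    code <- as.integer(names(cn)[cn == class])
    if (!length(code)) return(NA_integer_)
    code[1]
  } else as.integer(class)
}

#' Proportion of the landscape occupied by a class
#'
#' `P_i = 100 * sum(a_ij) / A` where `A` is the total valid-cell area.
#' An absent class yields 0.
#'
#' @param ps A [label_patches()] result.
#' @param class Class code or name.
#' @return Percent in `[0, 100]`.
#' @export
class_proportion <- function(ps, class) {
  code <- resolve_class(ps, class)
  a <- sum(ps$patches$area[ps$patches$class == code], na.rm = TRUE)
  100 * a / landscape_area(ps)
}

# tally of rook edges: like joins per class, unlike joins per class pair,
# and exposed (boundary / nodata) edges, all in cell-edge units
edge_tallies <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  pairs_a <- integer(0); pairs_b <- integer(0)
  for (s in list(c(1, 0), c(0, 1))) {
    r1 <- seq_len(nr - s[1]); c1 <- seq_len(nc - s[2])
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + s[1], c1 + s[2], drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    pairs_a <- c(pairs_a, a[keep]); pairs_b <- c(pairs_b, b[keep])
  }
  like <- pairs_a == pairs_b
  like_joins <- table(factor(pairs_a[like]))
  unlike <- !like
  ek <- tibble(i = pmin(pairs_a[unlike], pairs_b[unlike]),
               k = pmax(pairs_a[unlike], pairs_b[unlike])) %>%
    dplyr::count(.data$i, .data$k, name = "edges")
  exposed <- sum(perimeter_cells(g)) - 2 * sum(unlike)  # boundary/NA edges
  list(like = like_joins, between = ek, exposed = exposed,
       internal_unlike = sum(unlike))
}

#' Landscape shape index
#'
#' `LSI = 0.25 * E* / sqrt(A)` where `E*` is the total edge length in the
#' landscape: by default every class-to-class edge plus the raster boundary
#' and edges against no-data. A maximally compact single-class square scores
#' 1.
#'
#' @param ps A [label_patches()] result.
#' @param include_boundary Count raster boundary / no-data edges in `E*`
#'   (default `TRUE`).
#' @return LSI >= 1.
#' @export
lsi <- function(ps, include_boundary = TRUE) {
  g <- ps$raster$grid
  et <- edge_tallies(g)
  e_star <- et$internal_unlike + if (include_boundary) et$exposed else 0
  0.25 * e_star * ps$raster$cell_size / sqrt(landscape_area(ps))
}

#' Shannon's evenness index of class proportions
#'
#' `SHEI = -sum(p_i ln p_i) / ln(m)` over the `m` classes present; defined
#' as 0 for a single-class landscape. Bounded in `[0, 1]`, with 1 for equal
#' class proportions.
#'
#' @param ps A [label_patches()] result.
#' @return SHEI in `[0, 1]`.
#' @export
shei <- function(ps) {
  tot <- tapply(ps$patches$area, ps$patches$class, sum)
  p <- tot / sum(tot)
  if (length(p) <= 1) return(0)
  -sum(p * log(p)) / log(length(p))
}

ai_max_joins <- function(a) {
  n <- floor(sqrt(a)); m <- a - n^2
  if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
}

#' Aggregation index
#'
#' Class-level `AI = 100 * g_ii / max_g_ii` where `g_ii` is the number of
#' like-class rook joins and `max_g_ii` the joins of the maximally compact
#' arrangement of the same number of cells. A single-cell class (max 0
#' joins) is defined as fully aggregated (100). Landscape-level AI is the
#' area-weighted mean of class values.
#'
#' @param ps A [label_patches()] result.
#' @param class Class code or name, or `"landscape"` for the area-weighted
#'   landscape value.
#' @return Percent in `[0, 100]`.
#' @export
ai <- function(ps, class = "landscape") {
  g <- ps$raster$grid
  et <- edge_tallies(g)
  class_ai <- function(code) {
    ncells <- sum(ps$patches$n_cells[ps$patches$class == code])
    if (ncells == 0) return(NA_real_)
    maxg <- ai_max_joins(ncells)
    if (maxg == 0) return(100)
    gii <- et$like[as.character(code)]
    100 * (if (is.na(gii)) 0 else as.numeric(gii)) / maxg
  }
  if (identical(class, "landscape")) {
    codes <- sort(unique(ps$patches$class))
    w <- vapply(codes, function(cd)
      sum(ps$patches$area[ps$patches$class == cd]), numeric(1))
    vals <- vapply(codes, class_ai, numeric(1))
    sum(vals * w) / sum(w)
  } else {
    class_ai(resolve_class(ps, class))
  }
}

#' Interspersion and juxtaposition index of a focal class
#'
#' Evenness of the focal class's edge apportionment among the other classes:
#' `IJI = -sum((e_ik / E) ln(e_ik / E)) / ln(m - 1) * 100` over the classes
#' `k != i` that share edge with the focal class, where `m` is the number of
#' classes present in the landscape. Undefined (`NA`) when fewer than three
#' classes are present or the focal class has no inter-class edge.
#'
#' @param ps A [label_patches()] result.
#' @param class Focal class code or name (default native forest).
#' @return Percent in `[0, 100]`, or `NA`.
#' @export
iji <- function(ps, class = "native_forest") {
  code <- resolve_class(ps, class)
  m <- length(unique(ps$patches$class))
  if (m < 3) return(NA_real_)
  et <- edge_tallies(ps$raster$grid)
  eik <- et$between %>%
    filter(.data$i == code | .data$k == code) %>%
    mutate(other = ifelse(.data$i == code, .data$k, .data$i)) %>%
    group_by(.data$other) %>% summarise(edges = sum(.data$edges), .groups = "drop")
  tot <- sum(eik$edges)
  if (tot == 0) return(NA_real_)
  p <- eik$edges / tot
  100 * (-sum(p * log(p))) / log(m - 1)
}

#' Mean Euclidean nearest-neighbor distance among patches of a class
#'
#' For each patch the distance `h` to its nearest same-class patch, measured
#' center-to-center between cells, averaged over patches. Requires at least
#' two patches of the class (`NA` otherwise).
#'
#' @param ps A [label_patches()] result.
#' @param class Class code or name.
#' @return Meters, or `NA`.
#' @export
enn_mn <- function(ps, class = "native_forest") {
  code <- resolve_class(ps, class)
  pp <- ps$patches[ps$patches$class == code, ]
  if (nrow(pp) < 2) return(NA_real_)
  nr <- nrow(ps$raster$grid)
  cs <- ps$raster$cell_size
  coords <- lapply(pp$cells, function(cells) {
    cbind(row = (cells - 1) %% nr + 1, col = (cells - 1) %/% nr + 1)
  })
  h <- vapply(seq_len(nrow(pp)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(pp))[-i]) {
      d2 <- outer(coords[[i]][, 1], coords[[j]][, 1], "-")^2 +
        outer(coords[[i]][, 2], coords[[j]][, 2], "-")^2
      best <- min(best, min(d2))
    }
    sqrt(best) * cs
  }, numeric(1))
  mean(h)
}

#' Perimeter-area ratio of a patch
#'
#' `PARA = P_ij / a_ij` in inverse meters. Scale-dependent: the same shape
#' at a larger cell size has a smaller PARA.
#'
#' @param patch One row of the `patches` tibble of a [label_patches()]
#'   result (or any list with `perimeter` and `area`).
#' @return Ratio (1/m).
#' @export
para <- function(patch) {
  stopifnot(patch$area > 0)
  patch$perimeter / patch$area
}

#' Shape (compactness) index of a patch
#'
#' `SHAPE = 0.25 * P_ij / sqrt(a_ij)`, the raster-normalized compactness:
#' 1 for a square block of cells, larger for more elongated or convoluted
#' patches, and invariant under cell-size rescaling.
#'
#' @inheritParams para
#' @return SHAPE >= 1.
#' @export
shape_index <- function(patch) {
  stopifnot(patch$area > 0)
  0.25 * patch$perimeter / sqrt(patch$area)
}

#' Circular buffer mask
#'
#' Sets to no-data every cell whose center lies farther than `radius` from
#' the given center cell's center. Used to clip a scene to the 3-km analysis
#' buffer around a monitoring site.
#'
#' @param r A [landscape_raster()].
#' @param center `c(row, col)` of the buffer center cell (default: raster
#'   center).
#' @param radius Buffer radius in meters (default 3000).
#' @return A clipped `landscape_raster`.
#' @export
buffer_mask <- function(r, center = NULL, radius = 3000) {
  g <- r$grid
  if (is.null(center)) center <- c(nrow(g) / 2 + 0.5, ncol(g) / 2 + 0.5)
  d <- sqrt(outer((seq_len(nrow(g)) - center[1])^2,
                  (seq_len(ncol(g)) - center[2])^2, "+")) * r$cell_size
  g[d > radius] <- NA_integer_
  landscape_raster(g, r$cell_size, class_names = r$class_names)
}

#' Full landscape metric report for one scene
#'
#' Computes the per-site metric set at the three levels: landscape (`NP`
#' patches, `LSI`, `SHEI`, `AI`), class (percentages `P_NF`, `P_GL`, `P_TF`,
#' `P_C` of native forest, grassland, timber and crops; native-forest patch
#' count `N_NF`, `IJI`, `ENN`) and focal native-forest patch (`AREA`,
#' `PARA`, `SHAPE`). Water and urban cells are treated as background
#' (no data) by default, mirroring analyses that exclude those uses.
#'
#' @param r A [landscape_raster()].
#' @param focal_patch_id Optional patch id (as in [label_patches()], after
#'   exclusion) of the focal native-forest patch; default: the largest
#'   native-forest patch. `NA` metrics if the class is absent.
#' @param exclude Class names removed before analysis (default water,
#'   urban).
#' @return A one-row tibble with columns `NP, LSI, SHEI, AI, P_NF, P_GL,
#'   P_TF, P_C, N_NF, IJI, ENN, AREA, PARA, SHAPE`.
#' @export
summarize_buffer <- function(r, focal_patch_id = NULL,
                             exclude = c("water", "urban")) {
  if (length(exclude)) {
    drop_codes <- as.integer(names(r$class_names)[r$class_names %in% exclude])
    g <- r$grid
    g[g %in% drop_codes] <- NA_integer_
    r <- landscape_raster(g, r$cell_size, class_names = r$class_names)
  }
  ps <- label_patches(r)
  nf <- ps$patches[ps$patches$class_name == "native_forest", ]
  if (!is.null(focal_patch_id)) {
    if (!focal_patch_id %in% nf$patch_id) {
      abort("focal patch id not found among native-forest patches")
    }
    focal <- nf[nf$patch_id == focal_patch_id, ]
  } else {
    focal <- if (nrow(nf)) nf[which.max(nf$area), ] else NULL
  }
  tibble(
    NP = nrow(ps$patches),
    LSI = lsi(ps),
    SHEI = shei(ps),
    AI = ai(ps, "landscape"),
    P_NF = class_proportion(ps, "native_forest"),
    P_GL = class_proportion(ps, "grassland"),
    P_TF = class_proportion(ps, "timber"),
    P_C = class_proportion(ps, "crops"),
    N_NF = nrow(nf),
    IJI = iji(ps, "native_forest"),
    ENN = enn_mn(ps, "native_forest"),
    AREA = if (is.null(focal)) NA_real_ else focal$area,
    PARA = if (is.null(focal)) NA_real_ else para(focal),
    SHAPE = if (is.null(focal)) NA_real_ else shape_index(focal)
  )
}
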