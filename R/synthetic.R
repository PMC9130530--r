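#' Generate an incidence matrix with a known idealized structure
#'
#' Emulates the idealized species-distribution patterns used to benchmark
#' metacommunity classification. Matrices are built in their "ideal" row and
#' column order, cell noise is applied, and rows and columns are then
#' randomly permuted (so analyses must rediscover the order by ordination).
#'
#' Generator conventions:
#' * `checkerboard` — the anti-coherent extreme: starting from a random
#'   matrix at `fill`, margin-preserving 2x2 swaps are hill-climbed to
#'   maximize post-ordination embedded absences, producing the mutually
#'   segregated occupancy pattern that no site ordering can make coherent;
#' * `clementsian` — discrete compartments: contiguous site blocks, each
#'   species occupying every site of its block;
#' * `gleasonian` — contiguous ranges of random width at random positions;
#' * `evenly_spaced` — equal-width contiguous ranges with maximally
#'   staggered boundaries;
#' * `nested_clumped` / `nested_random` / `nested_evenly_spaced` — ranges
#'   anchored at the first site with widths drawn from a few shared levels
#'   (clumped boundaries), uniformly at random, or evenly spread;
#' * `random` — iid Bernoulli occupancy at `fill`.
#'
#' @param kind One of the eight non-quasi structure labels above.
#' @param n_species,n_sites Matrix dimensions (>= 2 each).
#' @param n_compartments Number of Clementsian compartments (default 3).
#' @param noise Probability of flipping any cell after construction
#'   (`[0, 0.5)`).
#' @param fill Bernoulli occupancy probability for `kind = "random"` and the
#'   starting fill for `kind = "checkerboard"`.
#' @param sweeps Swap proposals for the checkerboard hill-climb (default
#'   2500).
#' @param seed Optional integer seed.
#' @param shuffle Randomly permute rows and columns before returning
#'   (default `TRUE`).
#' @return An [incidence_matrix()] with `age_class = "total"`.
#' @examples
#' m <- make_structure("nested_random", 15, 10, seed = 4)
#' @export
make_structure <- function(kind = c("clementsian", "gleasonian",
                                    "evenly_spaced", "nested_clumped",
                                    "nested_random", "nested_evenly_spaced",
                                    "checkerboard", "random"),
                           n_species, n_sites, n_compartments = 3,
                           noise = 0, fill = 0.35, seed = NULL,
                           shuffle = TRUE, sweeps = 2500) {
  kind <- match.arg(kind)
  stopifnot(n_species >= 2, n_sites >= 2, noise >= 0, noise < 0.5)
  if (!is.null(seed)) set.seed(seed)
  s <- n_species; n <- n_sites
  x <- matrix(FALSE, s, n)
  range_rows <- function(starts, widths) {
    ends <- pmin(starts + widths - 1L, n)
    (col(x) >= starts) & (col(x) <= ends)
  }
  if (kind == "clementsian") {
    if (n_compartments > min(s, n)) abort("more compartments than species or sites")
    site_block <- sort(rep_len(seq_len(n_compartments), n))
    sp_block <- sort(rep_len(seq_len(n_compartments), s))
    x <- outer(sp_block, site_block, "==")
  } else if (kind == "gleasonian") {
    # each range = unordered pair of uniform cut points, so every boundary
    # position is marginally uniform (individualistic range placement)
    for (tries in 1:200) {
      ends <- t(replicate(s, sort(sample.int(n, 2))))
      x <- (col(x) >= ends[, 1]) & (col(x) <= ends[, 2])
      if (all(colSums(x) > 0)) break
    }
  } else if (kind == "evenly_spaced") {
    # width n/2 makes the 2S staggered boundary events tile the site axis
    # at uniform density (narrower widths double-stack starts and ends in
    # the interior)
    w <- max(2L, round(n / 2))
    st <- 1L + round((seq_len(s) - 1) * (n - w) / (s - 1))
    x <- range_rows(as.integer(st), rep(w, s))
  } else if (kind == "nested_clumped") {
    levels <- unique(pmax(2L, round(seq(n, n / 4, length.out = 4))))
    w <- sort(rep_len(levels, s), decreasing = TRUE)
    w[1] <- n
    x <- range_rows(rep(1L, s), w)
  } else if (kind == "nested_random") {
    w <- sample.int(n, s, replace = TRUE)
    w[1] <- n
    w <- sort(w, decreasing = TRUE)
    x <- range_rows(rep(1L, s), w)
  } else if (kind == "nested_evenly_spaced") {
    w <- sort(pmax(1L, round(seq(n, 1, length.out = s))), decreasing = TRUE)
    w[1] <- n
    x <- range_rows(rep(1L, s), as.integer(w))
  } else if (kind == "checkerboard") {
    x <- anti_coherent_matrix(s, n, fill = 0.5, sweeps = sweeps)
  } else if (kind == "random") {
    x <- matrix(stats::runif(s * n) < fill, s, n)
  }
  if (noise > 0) {
    flips <- matrix(stats::runif(s * n) < noise, s, n)
    x <- xor(x, flips)
  }
  dimnames(x) <- list(sprintf("sp%02d", seq_len(s)),
                      sprintf("site%02d", seq_len(n)))
  if (shuffle) {
    x <- x[sample.int(s), sample.int(n), drop = FALSE]
  }
  incidence_matrix(x, "total")
}

# Hill-climbed anti-coherent occupancy: margin-preserving 2x2 swaps accepted
# when they do not decrease the embedded-absence count of the re-ordinated
# matrix. The fixed margins keep the result comparable to its own null.
anti_coherent_matrix <- function(s, n, fill = 0.5, sweeps = 2500) {
  ea_of <- function(x) {
    o <- tryCatch(ra_orders(x), error = function(e) NULL)
    if (is.null(o)) return(NA_integer_)
    xo <- x[o$rows, o$cols, drop = FALSE]
    gap_count(xo) + gap_count(t(xo))
  }
  x <- matrix((stats::runif(s * n) < fill) * 1L, s, n)
  cur <- ea_of(x)
  for (it in seq_len(sweeps)) {
    i <- sample.int(s, 2); j <- sample.int(n, 2)
    sub <- x[i, j]
    if (abs(sub[1, 1] + sub[2, 2] - sub[1, 2] - sub[2, 1]) == 2L) {
      x[i, j] <- 1L - sub
      new <- ea_of(x)
      if (!is.na(new) && !is.na(cur) && new >= cur) cur <- new
      else x[i, j] <- sub
    }
  }
  x == 1L
}

#' Generate a toy categorical raster scene
#'
#' Deterministic scene assembly from a base class plus rectangular regions
#' (later regions overwrite earlier ones), with optional seeded random
#' speckle. Designed so the landscape metrics of the scene have closed
#' forms.
#'
#' @param nrow,ncol Raster dimensions.
#' @param cell_size Cell edge (m).
#' @param base_class Class code filling the scene.
#' @param regions List of `list(class =, rows =, cols =)` rectangles.
#' @param speckle Fraction of cells reassigned to random classes.
#' @param speckle_classes Codes used for speckle.
#' @param seed Optional seed (speckle only).
#' @param class_names Code-to-label map.
#' @return A [landscape_raster()].
#' @examples
#' sc <- make_scene(8, 8, base_class = 2,
#'   regions = list(list(class = 1, rows = 3:6, cols = 3:6)))
#' @export
make_scene <- function(nrow, ncol, cell_size = 30, base_class = 2,
                       regions = list(), speckle = 0,
                       speckle_classes = c(1, 2, 3, 4), seed = NULL,
                       class_names = default_class_names()) {
  g <- matrix(as.integer(base_class), nrow, ncol)
  for (reg in regions) {
    if (max(reg$rows) > nrow || max(reg$cols) > ncol || min(reg$rows) < 1 ||
        min(reg$cols) < 1) abort("region outside raster bounds")
    g[reg$rows, reg$cols] <- as.integer(reg$class)
  }
  if (speckle > 0) {
    if (!is.null(seed)) set.seed(seed)
    pick <- which(stats::runif(length(g)) < speckle)
    g[pick] <- as.integer(sample(speckle_classes, length(pick), replace = TRUE))
  }
  landscape_raster(g, cell_size, class_names = class_names)
}

#' Packaged woody-species frequency and trait fixture
#'
#' Loads the transcription of the published frequency table for the 101
#' woody species recorded at 32 permanent monitoring plots in Uruguayan
#' native forests: family, growth form, origin (native/exotic),
#' conservation-priority flag, and absolute frequency per age class (total,
#' adult, juvenile).
#'
#' @return A list with `traits` (tibble of species records) and `frequency`
#'   (tibble with `AF_*`, half-up integer `RF_*` and cumulative `CRF_*`
#'   columns per age class, ordered by total AF descending).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_woody_species.csv",
                      package = "emsland", mustWork = TRUE)
  d <- readr::read_csv(path, comment = "#", col_types = readr::cols(),
                       progress = FALSE)
  n_sites <- 32
  freq <- d %>%
    select("family", "species", "AF_total", "AF_adult", "AF_juv") %>%
    arrange(desc(.data$AF_total))
  for (cls in c("total", "adult", "juv")) {
    af <- freq[[paste0("AF_", cls)]]
    rf <- 100 * af / n_sites
    freq[[paste0("RF_", cls)]] <- round_half_up(rf)
    freq[[paste0("CRF_", cls)]] <- cumsum(rf)
  }
  freq <- select(freq, "family", "species",
                 "AF_total", "RF_total", "CRF_total",
                 "AF_adult", "RF_adult", "CRF_adult",
                 "AF_juv", "RF_juv", "CRF_juv")
  list(traits = select(d, "species", "family", "growth_form", "origin",
                       "priority", "dispersal"),
       frequency = freq)
}

#' Synthetic incidence realization of the packaged frequency fixture
#'
#' Builds adult and juvenile incidence matrices over the 32 survey sites
#' whose per-species occupied-site counts match the fixture's absolute
#' frequencies exactly (including the union counts of the total layer).
#' Site assignments are otherwise random: this is a synthetic realization
#' consistent with the published frequencies, not the original survey
#' matrix (which is deposited externally).
#'
#' @param seed Integer seed for the site assignment.
#' @return A list of `incidence` objects: `adult`, `juvenile`, `total`.
#' @export
table1_matrices <- function(seed = 1) {
  d <- readr::read_csv(
    system.file("extdata", "table1_woody_species.csv", package = "emsland",
                mustWork = TRUE),
    comment = "#", col_types = readr::cols(), progress = FALSE)
  set.seed(seed)
  n <- 32
  sites <- sprintf("site%02d", seq_len(n))
  a_m <- matrix(FALSE, nrow(d), n, dimnames = list(d$species, sites))
  j_m <- a_m
  for (i in seq_len(nrow(d))) {
    t_ <- d$AF_total[i]; a_ <- d$AF_adult[i]; j_ <- d$AF_juv[i]
    stopifnot(t_ >= max(a_, j_), t_ <= a_ + j_, t_ <= n)
    o <- a_ + j_ - t_           # sites shared by both layers
    adult_sites <- sample.int(n, a_)
    shared <- adult_sites[sample.int(length(adult_sites), o)]
    free <- setdiff(seq_len(n), adult_sites)
    juv_new <- free[sample.int(length(free), j_ - o)]
    a_m[i, adult_sites] <- TRUE
    j_m[i, c(shared, juv_new)] <- TRUE
  }
  adult <- incidence_matrix(a_m, "adult")
  juvenile <- incidence_matrix(j_m, "juvenile")
  list(adult = adult, juvenile = juvenile,
       total = merge_age_classes(adult, juvenile))
}
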