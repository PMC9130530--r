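#' Embedded absences (coherence statistic)
#'
#' Counts the 0-cells lying strictly between the first and last presence of
#' each species along the ordinated site order and, by default, of each site
#' along the ordinated species order; the statistic is the sum of both
#' tallies. Fewer embedded absences than expected under the null model means
#' positive coherence.
#'
#' @param o An `ra_ordination` (from [reciprocal_averaging()]) or an already
#'   ordinated `incidence` matrix.
#' @param direction `"rowcol"` (default: species rows plus site columns, the
#'   convention of the Matlab EMS script lineage) or `"row"` (species rows
#'   only).
#' @return Integer count.
#' @export
embedded_absences <- function(o, direction = c("rowcol", "row")) {
  direction <- match.arg(direction)
  x <- ordinated_matrix(o)
  n <- gap_count(x)
  if (direction == "rowcol") n <- n + gap_count(t(x))
  n
}

ordinated_matrix <- function(o) {
  if (inherits(o, "ra_ordination")) unclass(o$ordinated) * 1L
  else unclass(o) * 1L
}

# total gaps within row ranges of a 0/1 matrix; all-zero rows contribute 0
gap_count <- function(x) {
  occ <- rowSums(x)
  keep <- occ > 0
  if (!any(keep)) return(0L)
  x <- x[keep, , drop = FALSE]
  first <- max.col(x, ties.method = "first")
  last <- ncol(x) + 1L - max.col(x[, rev(seq_len(ncol(x))), drop = FALSE],
                                 ties.method = "first")
  as.integer(sum((last - first + 1L) - occ[keep]))
}

row_range <- function(x) {
  first <- max.col(x, ties.method = "first")
  last <- ncol(x) + 1L - max.col(x[, rev(seq_len(ncol(x))), drop = FALSE],
                                 ties.method = "first")
  cbind(first = first, last = last)
}

#' Fill species ranges to contiguity
#'
#' Sets to presence every absence lying inside a species' range (between its
#' first and last occupied site in the ordinated order). Turnover and
#' boundary statistics are computed on this range-filled matrix.
#'
#' @inheritParams embedded_absences
#' @return An ordinated `incidence` matrix with contiguous rows.
#' @export
fill_ranges <- function(o) {
  x <- ordinated_matrix(o)
  rng <- row_range(x)
  filled <- (col(x) >= rng[, "first"]) & (col(x) <= rng[, "last"]) &
    rowSums(x) > 0
  incidence_matrix(matrix(filled, nrow(x), dimnames = dimnames(x)),
                   if (inherits(o, "ra_ordination")) age_class(o$ordinated)
                   else age_class(o))
}

#' Species replacements (turnover statistic)
#'
#' On the range-filled ordinated matrix, counts, over every unordered pair of
#' species and unordered pair of sites, the configurations in which one
#' species is present at exactly one site of the pair and the other species
#' at exactly the other (a mutual replacement). Nested distributions have
#' zero replacements.
#'
#' @inheritParams embedded_absences
#' @return Integer (stored as double; the count can exceed `.Machine$integer.max`
#'   on large matrices).
#' @export
replacements <- function(o) {
  xf <- unclass(fill_ranges(o)) * 1
  a <- tcrossprod(xf, 1 - xf)   # a[i,j] = #sites with i present, j absent
  sum(a * t(a)) / 2
}

#' Range-boundary counts per site
#'
#' For each site position of the ordinated, range-filled matrix, counts the
#' species ranges that start or end there. A species occupying a single site
#' contributes two boundary counts (start = end) at that site.
#'
#' @inheritParams embedded_absences
#' @return Integer vector, one count per site (in ordinated site order).
#' @export
boundary_counts <- function(o) {
  x <- unclass(fill_ranges(o))
  rng <- row_range(x * 1L)
  keep <- rowSums(x) > 0
  tabulate(c(rng[keep, "first"], rng[keep, "last"]), nbins = ncol(x))
}

#' Morisita index of boundary clumping
#'
#' Morisita's index of dispersion over per-site boundary counts `b_j`:
#' `MI = n * sum(b_j (b_j - 1)) / (B (B - 1))` with `B = sum(b_j)` and `n`
#' sites. `MI > 1` indicates clumped range boundaries (Clementsian),
#' `MI < 1` over-dispersed (evenly spaced) boundaries. Significance comes
#' from the chi-square statistic `sum((b_j - B/n)^2 / (B/n))` with
#' `df = n - 1`, evaluated in the tail matching the observed direction
#' (upper tail when `MI >= 1`, lower tail when `MI < 1`, so that
#' under-dispersion is detectable).
#'
#' @param counts Integer vector of boundary counts per site (see
#'   [boundary_counts()]).
#' @return A one-row tibble: `MI`, `chisq`, `df`, `p`.
#' @examples
#' morisita_boundary_index(c(4, 0, 0, 0))  # MI = 4, strongly clumped
#' @export
morisita_boundary_index <- function(counts) {
  n <- length(counts)
  if (n < 2) abort("need counts for at least 2 sites")
  b <- sum(counts)
  if (b < 2) abort("too few boundaries")
  mi <- n * sum(counts * (counts - 1)) / (b * (b - 1))
  chisq <- sum((counts - b / n)^2 / (b / n))
  p <- if (mi >= 1) pchisq(chisq, df = n - 1, lower.tail = FALSE)
       else pchisq(chisq, df = n - 1, lower.tail = TRUE)
  tibble(MI = mi, chisq = chisq, df = n - 1, p = p)
}

#' Null incidence matrices with fixed site richness, equiprobable species
#'
#' The "random 0" null model: every simulated matrix keeps each site's
#' (column's) observed species richness and fills the column by drawing that
#' many species uniformly without replacement from the full species pool.
#' Column sums are therefore identical to the observed matrix, while each
#' species' expected occupancy is `sum(k_j) / S`.
#'
#' @param m An [incidence_matrix()].
#' @param n Number of null matrices.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `incidence` objects.
#' @export
null_matrices <- function(m, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- nrow(m)
  k <- colSums(m)
  if (any(k > s)) abort("site richness exceeds species pool")
  dn <- dimnames(m)
  ac <- age_class(m)
  lapply(seq_len(n), function(i) {
    x <- matrix(FALSE, s, ncol(m), dimnames = dn)
    for (j in seq_along(k)) if (k[j] > 0) x[sample.int(s, k[j]), j] <- TRUE
    incidence_matrix(x, ac)
  })
}

# bare-matrix variant used in hot loops (no class, no names)
null_fill <- function(s, k) {
  x <- matrix(FALSE, s, length(k))
  for (j in seq_along(k)) if (k[j] > 0) x[sample.int(s, k[j]), j] <- TRUE
  x
}

#' Monte-Carlo z test of an observed statistic against null values
#'
#' `z = (obs - mean(nulls)) / sd(nulls)`; the default p-value is the
#' two-tailed normal approximation `2 * (1 - Phi(|z|))`. For coherence,
#' negative z (fewer embedded absences than the null) corresponds to
#' "positive coherence" in the classification tree; for turnover, positive z
#' means more replacements than the null. `method = "empirical"` gives the
#' exact two-tailed permutation p-value `2 * min(Pr(null <= obs),
#' Pr(null >= obs))` (capped at 1) counting the observation itself.
#'
#' @param observed Observed statistic.
#' @param nulls Numeric vector of null statistics (length >= 2, sd > 0).
#' @param method `"normal"` (default) or `"empirical"`.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `z`, `p`.
#' @export
montecarlo_test <- function(observed, nulls, method = c("normal", "empirical")) {
  method <- match.arg(method)
  if (length(nulls) < 2) abort("need at least 2 null values")
  mu <- mean(nulls); sdev <- sd(nulls)
  if (sdev == 0) abort("degenerate null: zero variance")
  z <- (observed - mu) / sdev
  p <- if (method == "normal") {
    2 * pnorm(abs(z), lower.tail = FALSE)
  } else {
    lo <- (sum(nulls <= observed) + 1) / (length(nulls) + 1)
    hi <- (sum(nulls >= observed) + 1) / (length(nulls) + 1)
    min(1, 2 * min(lo, hi))
  }
  tibble(observed = observed, null_mean = mu, null_sd = sdev, z = z, p = p)
}

#' Type-I error calibration of the coherence test
#'
#' Draws observed matrices from the fixed-richness equiprobable-species
#' null itself and measures how often the two-tailed coherence test rejects
#' at `alpha`. A calibrated test rejects at rate `alpha`. Site richnesses
#' are drawn per replicate as Binomial(`n_species`, `fill`), truncated to
#' at least 1.
#'
#' @param n_reps Number of simulated observed matrices.
#' @param iterations Null iterations per test (default 99).
#' @param n_species,n_sites Matrix dimensions.
#' @param fill Expected site occupancy proportion.
#' @param alpha Nominal level.
#' @param seed Optional seed.
#' @param direction Gap counting direction (see [embedded_absences()]).
#' @return A one-row tibble: `n_reps`, `rejections`, `rate`.
#' @export
calibrate_coherence <- function(n_reps = 1000, iterations = 99,
                                n_species = 15, n_sites = 10, fill = 0.4,
                                alpha = 0.05, seed = NULL,
                                direction = c("rowcol", "row")) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  rowcol <- direction == "rowcol"
  ea_of <- function(x) {
    x <- x[rowSums(x) > 0, , drop = FALSE]
    ob <- tryCatch(ra_orders(x), error = function(e) NULL)
    if (is.null(ob)) return(NA_integer_)
    xo <- x[ob$rows, ob$cols, drop = FALSE]
    gap_count(xo) + if (rowcol) gap_count(t(xo)) else 0L
  }
  rej <- 0L; used <- 0L
  for (r in seq_len(n_reps)) {
    k <- pmax(1L, stats::rbinom(n_sites, n_species, fill))
    obs <- ea_of(null_fill(n_species, k) * 1L)
    if (is.na(obs)) next
    nulls <- vapply(seq_len(iterations),
                    function(i) ea_of(null_fill(n_species, k) * 1L),
                    numeric(1))
    nulls <- nulls[!is.na(nulls)]
    if (length(nulls) < 2 || sd(nulls) == 0) next
    used <- used + 1L
    z <- (obs - mean(nulls)) / sd(nulls)
    if (2 * pnorm(abs(z), lower.tail = FALSE) < alpha) rej <- rej + 1L
  }
  tibble(n_reps = used, rejections = rej, rate = rej / used)
}

ems_structure_labels <- c(
  "checkerboard", "random", "clementsian", "gleasonian", "evenly_spaced",
  "nested_clumped", "nested_random", "nested_evenly_spaced",
  "quasi_clementsian", "quasi_gleasonian", "quasi_evenly_spaced",
  "quasi_nested_clumped", "quasi_nested_random", "quasi_nested_evenly_spaced")

#' Classify a metacommunity from its EMS statistics
#'
#' Implements the three-step decision tree. Step 1 (coherence): a
#' significant excess of embedded absences gives a checkerboard; a
#' non-significant test gives a random structure; a significant deficit
#' (positive coherence) continues. Step 2 (turnover): significantly more
#' replacements than the null leads to the Clementsian / Gleasonian / evenly
#' spaced branch; significantly fewer to the nested branch; a
#' non-significant turnover yields the quasi-variant chosen by the sign of
#' its z. Step 3 (boundary clumping): a significant Morisita chi-square with
#' `MI > 1` selects the clumped label (clementsian / nested_clumped),
#' with `MI < 1` the evenly spaced label; a non-significant chi-square
#' selects gleasonian / nested_random.
#'
#' @param coherence,turnover One-row data frames from [montecarlo_test()].
#' @param morisita One-row data frame from [morisita_boundary_index()] or a
#'   Monte-Carlo equivalent; an optional logical column `clumped` overrides
#'   the default direction rule `MI > 1` (used when clumping is judged
#'   against a null-ensemble reference rather than against 1).
#' @param alpha Significance level (default 0.05).
#' @return Single character label (see `ems_structure_labels`).
#' @export
classify_structure <- function(coherence, turnover, morisita, alpha = 0.05) {
  if (coherence$p >= alpha) return("random")
  if (coherence$z > 0) return("checkerboard")
  clumped <- if ("clumped" %in% names(morisita)) morisita$clumped
             else morisita$MI > 1
  clump <- function(base) {
    if (morisita$p < alpha) {
      if (clumped) paste0(base, c("clementsian", "clumped")[1 + (base == "nested_")])
      else paste0(base, "evenly_spaced")
    } else {
      if (base == "nested_") "nested_random" else "gleasonian"
    }
  }
  if (turnover$p < alpha) {
    if (turnover$z > 0) clump("") else clump("nested_")
  } else {
    paste0("quasi_", if (turnover$z > 0) clump("") else clump("nested_"))
  }
}

#' Elements of Metacommunity Structure analysis
#'
#' Runs the full EMS workflow on one incidence matrix: drops empty rows and
#' columns, ordinates by reciprocal averaging, computes observed embedded
#' absences and replacements, simulates `iterations` null matrices under the
#' fixed-richness equiprobable-species ("random 0") null — each null is
#' re-ordinated before counting — tests both statistics, evaluates boundary
#' clumping with Morisita's index, and classifies the structure.
#'
#' Boundary clumping is evaluated on the interior site positions (the first
#' and last ordinated sites are excluded, `boundary = "interior"`). Range
#' limits falling on the extreme sites are structurally forced — any
#' coherent range reaching the edge ends there, and in a nested pattern
#' every species' range is anchored at the richest site — so they carry no
#' information about whether boundaries clump; including them would swamp
#' the index (and push every nested metacommunity to "clumped").
#'
#' @param m An [incidence_matrix()].
#' @param iterations Null-model iterations (default 1000).
#' @param seed Integer seed for the null stream (recommended).
#' @param alpha Significance level for classification (default 0.05).
#' @param direction Coherence gap counting, see [embedded_absences()].
#' @param method P-value method for the Monte-Carlo tests, see
#'   [montecarlo_test()].
#' @param boundary `"interior"` (default) evaluates Morisita's index on
#'   boundary counts at interior site positions; `"all"` uses every
#'   position.
#' @param clump_test `"montecarlo"` (default) judges boundary clumping by a
#'   range-shuffle null: every species' range is re-placed with its free
#'   boundaries drawn independently and uniformly over the site positions,
#'   while boundaries pinned at the ordination's extreme positions stay
#'   pinned (a range limit at the first or last site is structural — in a
#'   nested pattern every range is anchored at the richest site). Each
#'   shuffled matrix is re-ordinated and the interior Morisita index
#'   recomputed; the observed index is compared with this distribution by
#'   empirical two-tailed tail probabilities (clumped when significantly
#'   above the null mean, evenly spaced when significantly below). This is
#'   the direct question boundary clumping asks — are range limits more
#'   coincident than independently placed ranges would produce — and it
#'   absorbs the clumping that reciprocal averaging itself induces
#'   (near-tied site scores are ordered arbitrarily), which the fixed
#'   multinomial reference of the chi-square does not. `"chisq"` uses the
#'   classical directional chi-square test of the boundary counts against
#'   uniformity (vs `MI = 1`).
#' @param coords Optional data frame `site`, `latitude`, `longitude` merged
#'   into the site-score table.
#' @return An object of class `ems_result` with elements `stats` (tibble:
#'   one row each for coherence and turnover), `morisita`, `label`,
#'   `ordination`, `site_scores` (tibble: `site`, optional coordinates,
#'   `score`), `dropped_species`, `dropped_sites` and the call parameters.
#'   [tidy()], [glance()] and [autoplot()] methods are provided.
#' @examples
#' m <- make_structure("clementsian", n_species = 18, n_sites = 12, seed = 2)
#' res <- ems_analyze(m, iterations = 50, seed = 9)
#' res$label
#' @export
ems_analyze <- function(m, iterations = 1000, seed = NULL, alpha = 0.05,
                        direction = c("rowcol", "row"),
                        method = c("normal", "empirical"),
                        boundary = c("interior", "all"),
                        clump_test = c("montecarlo", "chisq"),
                        coords = NULL) {
  direction <- match.arg(direction); method <- match.arg(method)
  boundary <- match.arg(boundary); clump_test <- match.arg(clump_test)
  stopifnot(iterations >= 2, alpha > 0, alpha < 1)
  ord <- reciprocal_averaging(m)
  obs_ea <- embedded_absences(ord, direction)
  obs_rp <- replacements(ord)
  interior <- function(b) {
    if (boundary == "interior" && length(b) >= 4) b[2:(length(b) - 1)] else b
  }
  raw_mi <- function(counts) {
    b <- sum(counts)
    if (b < 2) return(NA_real_)
    length(counts) * sum(counts * (counts - 1)) / (b * (b - 1))
  }
  bc <- interior(boundary_counts(ord))
  mor_chisq <- morisita_boundary_index(bc)

  x <- unclass(ord$ordinated)
  s <- nrow(x); k <- colSums(x)
  if (!is.null(seed)) set.seed(seed)
  null_ea <- numeric(iterations); null_rp <- numeric(iterations)
  for (i in seq_len(iterations)) {
    nm <- null_fill(s, k)
    nm <- nm[rowSums(nm) > 0, , drop = FALSE]
    ob <- tryCatch(ra_orders(nm * 1L), error = function(e) NULL)
    if (is.null(ob)) { null_ea[i] <- NA; null_rp[i] <- NA; next }
    no <- nm[ob$rows, ob$cols, drop = FALSE] * 1L
    null_ea[i] <- gap_count(no) +
      if (direction == "rowcol") gap_count(t(no)) else 0L
    rng <- row_range(no)
    nf <- ((col(no) >= rng[, "first"]) & (col(no) <= rng[, "last"])) * 1
    a <- tcrossprod(nf, 1 - nf)
    null_rp[i] <- sum(a * t(a)) / 2
  }
  ok <- !is.na(null_ea)
  coh <- montecarlo_test(obs_ea, null_ea[ok], method)
  tur <- montecarlo_test(obs_rp, null_rp[ok], method)
  mor <- if (clump_test == "montecarlo") {
    # range-shuffle null: free boundaries uniform, edge-pinned boundaries
    # kept, re-ordinated through the same pipeline
    rng0 <- row_range(x)
    keep0 <- rowSums(x) > 0
    f0 <- rng0[keep0, "first"]; l0 <- rng0[keep0, "last"]
    n_sites <- ncol(x); n_sp <- length(f0)
    null_mi <- numeric(iterations)
    for (i in seq_len(iterations)) {
      f <- f0; l <- l0
      free_l <- f0 == 1L & l0 < n_sites        # anchored left, free right end
      l[free_l] <- sample.int(n_sites, sum(free_l), replace = TRUE)
      free_f <- l0 == n_sites & f0 > 1L        # anchored right, free left end
      f[free_f] <- sample.int(n_sites, sum(free_f), replace = TRUE)
      both <- f0 > 1L & l0 < n_sites           # fully free range
      if (any(both)) {
        a <- sample.int(n_sites, sum(both), replace = TRUE)
        b <- sample.int(n_sites, sum(both), replace = TRUE)
        single <- f0[both] == l0[both]
        f[both] <- ifelse(single, a, pmin(a, b))
        l[both] <- ifelse(single, a, pmax(a, b))
      }
      nm <- matrix(FALSE, n_sp, n_sites)
      nm <- (col(nm) >= f) & (col(nm) <= l)
      nm <- nm[, colSums(nm) > 0, drop = FALSE]
      ob <- tryCatch(ra_orders(nm * 1L), error = function(e) NULL)
      if (is.null(ob)) { null_mi[i] <- NA; next }
      rng <- row_range(nm[ob$rows, ob$cols, drop = FALSE] * 1L)
      null_mi[i] <- raw_mi(interior(tabulate(c(rng), nbins = ncol(nm))))
    }
    mi_ok <- !is.na(null_mi)
    # empirical tail probabilities: the null MI distribution is right-skewed
    # (tied site scores are ordered arbitrarily), so a normal approximation
    # would under-reject evenly spaced boundaries
    mc <- montecarlo_test(mor_chisq$MI, null_mi[mi_ok], "empirical")
    tibble(MI = mor_chisq$MI, null_mean = mc$null_mean, z = mc$z,
           p = mc$p, clumped = mc$z > 0)
  } else {
    mor_chisq
  }
  label <- classify_structure(coh, tur, mor, alpha)

  scores <- tibble(site = names(ord$site_scores),
                   score = unname(ord$site_scores))
  if (!is.null(coords)) {
    scores <- left_join(scores, as_tibble(coords), by = "site") %>%
      relocate("score", .after = dplyr::last_col())
  }
  structure(list(
    stats = bind_rows(
      mutate(coh, element = "coherence", .before = 1),
      mutate(tur, element = "turnover", .before = 1)),
    morisita = mor, label = label, ordination = ord,
    site_scores = arrange(scores, match(.data$site, colnames(m))),
    dropped_species = ord$dropped_species, dropped_sites = ord$dropped_sites,
    age_class = age_class(m), iterations = iterations, alpha = alpha,
    seed = seed, direction = direction, method = method, boundary = boundary,
    clump_test = clump_test,
    n_null_used = sum(ok)
  ), class = "ems_result")
}

#' @export
print.ems_result <- function(x, ...) {
  cat(sprintf("<ems_result> %s structure (%s age class)\n", x$label, x$age_class))
  cat(sprintf("  coherence: obs %.0f, null %.1f +/- %.2f, z = %.2f, p = %.3g\n",
              x$stats$observed[1], x$stats$null_mean[1], x$stats$null_sd[1],
              x$stats$z[1], x$stats$p[1]))
  cat(sprintf("  turnover : obs %.0f, null %.1f +/- %.2f, z = %.2f, p = %.3g\n",
              x$stats$observed[2], x$stats$null_mean[2], x$stats$null_sd[2],
              x$stats$z[2], x$stats$p[2]))
  cat(sprintf("  boundary clumping: MI = %.3f, p = %.3g (%s)\n",
              x$morisita$MI, x$morisita$p,
              x$clump_test %||% "chisq"))
  invisible(x)
}

#' @rdname ems_analyze
#' @param x An `ems_result`.
#' @param ... Unused.
#' @method tidy ems_result
#' @export
tidy.ems_result <- function(x, ...) {
  bind_rows(
    select(x$stats, "element", statistic = "observed", "null_mean",
           "null_sd", "z", "p"),
    tibble(element = "boundary_clumping", statistic = x$morisita$MI,
           null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
           p = x$morisita$p))
}

#' @rdname ems_analyze
#' @method glance ems_result
#' @export
glance.ems_result <- function(x, ...) {
  tibble(label = x$label, age_class = x$age_class,
         coherence_z = x$stats$z[1], coherence_p = x$stats$p[1],
         turnover_z = x$stats$z[2], turnover_p = x$stats$p[2],
         morisita = x$morisita$MI, morisita_p = x$morisita$p,
         n_species = length(x$ordination$species_scores),
         n_sites = length(x$ordination$site_scores),
         iterations = x$iterations)
}

#' @rdname ems_analyze
#' @param object An `ems_result`.
#' @method autoplot ems_result
#' @export
autoplot.ems_result <- function(object, ...) {
  x <- unclass(object$ordination$ordinated)
  df <- tidyr::expand_grid(species = factor(rownames(x), levels = rev(rownames(x))),
                           site = factor(colnames(x), levels = colnames(x)))
  df$present <- as.vector(t(x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$species,
                                   fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c("TRUE" = "grey20", "FALSE" = "white"),
                               guide = "none") +
    ggplot2::labs(title = sprintf("Ordinated incidence matrix: %s", object$label),
                  x = "sites (first CA axis order)",
                  y = "species (first CA axis order)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
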