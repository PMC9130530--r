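# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious path so that the vectorized implementations are
# checked against something written differently.

# bare occupancy matrix: class and tag attributes stripped for comparisons
occ <- function(m) {
  a <- unclass(m)
  attr(a, "age_class") <- NULL
  a
}

# build an incidence object from a plain 0/1 matrix
inc <- function(m, age_class = "total") {
  if (is.null(rownames(m))) rownames(m) <- paste0("sp", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("site", seq_len(ncol(m)))
  incidence_matrix(m == 1, age_class)
}

# gap counting by explicit iteration over rows and columns
brute_embedded_absences <- function(x, direction = "rowcol") {
  x <- unclass(x) * 1
  count_line <- function(v) {
    w <- which(v == 1)
    if (length(w) < 2) return(0)
    sum(v[min(w):max(w)] == 0)
  }
  total <- sum(apply(x, 1, count_line))
  if (direction == "rowcol") total <- total + sum(apply(x, 2, count_line))
  total
}

# replacements by the quadruple loop over species pairs x site pairs,
# applied to an already range-filled matrix
brute_replacements <- function(xf) {
  xf <- unclass(xf) * 1
  s <- nrow(xf); n <- ncol(xf)
  total <- 0
  for (i in seq_len(s - 1)) for (j in (i + 1):s) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      ia <- xf[i, a]; ib <- xf[i, b]; ja <- xf[j, a]; jb <- xf[j, b]
      if ((ia == 1 && ib == 0 && ja == 0 && jb == 1) ||
          (ia == 0 && ib == 1 && ja == 1 && jb == 0)) total <- total + 1
    }
  }
  total
}

# range filling by explicit loop
brute_fill <- function(x) {
  x <- unclass(x) * 1
  for (i in seq_len(nrow(x))) {
    w <- which(x[i, ] == 1)
    if (length(w) >= 2) x[i, min(w):max(w)] <- 1
  }
  x
}

# first non-trivial axis of the site-averaging operator by dense eigen
# decomposition: M = Dc^-1 X' Dr^-1 X, trivial eigenvector is constant
oracle_site_scores <- function(x) {
  x <- unclass(x) * 1
  r <- rowSums(x); c <- colSums(x)
  m <- diag(1 / c) %*% t(x) %*% diag(1 / r) %*% x
  e <- eigen(m)
  v <- Re(e$vectors[, 2])
  list(scores = v,
       gap = abs(Re(e$values[2]) - Re(e$values[3])),
       gap_trivial = abs(1 - Re(e$values[2])))
}

# a random non-degenerate binary matrix: no empty rows/cols, the bipartite
# graph is connected (second eigenvalue strictly below the trivial 1) and
# the first non-trivial eigenvalue is well separated from the next, so the
# axis is numerically stable
random_nondegenerate <- function(s, n, fill = 0.4, need_gap = 0,
                                 distinct_scores = FALSE) {
  repeat {
    x <- matrix(stats::runif(s * n) < fill, s, n) * 1
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    ok <- tryCatch({
      orc <- oracle_site_scores(x)
      good <- orc$gap > need_gap && orc$gap_trivial > 1e-4
      if (good && distinct_scores) {
        o <- reciprocal_averaging(incidence_matrix(x == 1))
        good <- all(diff(sort(o$site_scores)) > 1e-9) &&
          all(diff(sort(o$species_scores)) > 1e-9)
      }
      good
    }, error = function(e) FALSE)
    if (ok) return(x)
  }
}

# landscape: direct like-join counting by scanning all rook pairs
brute_like_joins <- function(g, code) {
  n <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    if (is.na(g[i, j]) || g[i, j] != code) next
    if (i < nrow(g) && !is.na(g[i + 1, j]) && g[i + 1, j] == code) n <- n + 1
    if (j < ncol(g) && !is.na(g[i, j + 1]) && g[i, j + 1] == code) n <- n + 1
  }
  n
}
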