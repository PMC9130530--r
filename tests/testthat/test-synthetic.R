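kinds <- c("clementsian", "gleasonian", "evenly_spaced", "nested_clumped",
           "nested_random", "nested_evenly_spaced", "checkerboard", "random")

test_that("generators honor dimensions and are seed-reproducible", {
  for (k in kinds) {
    m1 <- make_structure(k, 14, 9, seed = 42, sweeps = 200)
    m2 <- make_structure(k, 14, 9, seed = 42, sweeps = 200)
    m3 <- make_structure(k, 14, 9, seed = 43, sweeps = 200)
    expect_equal(dim(m1), c(14, 9))
    expect_identical(unclass(m1), unclass(m2))
    expect_false(identical(unclass(m1), unclass(m3)))
  }
})

test_that("nested generators are perfectly coherent at zero noise", {
  for (k in c("nested_clumped", "nested_random", "nested_evenly_spaced")) {
    m <- make_structure(k, 15, 10, seed = 1)
    ord <- suppressMessages(reciprocal_averaging(m))
    expect_equal(embedded_absences(ord), 0)
    expect_equal(replacements(ord), 0)   # nested ranges never replace
  }
})

test_that("clementsian compartments are recovered end to end", {
  m <- make_structure("clementsian", 30, 20, n_compartments = 3, seed = 6)
  r <- suppressMessages(ems_analyze(m, iterations = 150, seed = 60))
  expect_equal(r$label, "clementsian")
  expect_lt(r$stats$z[1], 0)            # coherent
  expect_gt(r$stats$z[2], 0)            # high turnover
  expect_gt(r$morisita$MI, 1)
})

test_that("the checkerboard generator is anti-coherent", {
  m <- make_structure("checkerboard", 20, 14, seed = 3, sweeps = 1200)
  ord <- suppressMessages(reciprocal_averaging(m))
  obs <- embedded_absences(ord)
  # random matrices with the same margins have fewer embedded absences
  set.seed(99)
  nulls <- replicate(60, {
    nm <- emsland:::null_fill(nrow(m), colSums(m))
    nm <- nm[rowSums(nm) > 0, , drop = FALSE]
    ob <- emsland:::ra_orders(nm * 1L)
    no <- nm[ob$rows, ob$cols] * 1L
    emsland:::gap_count(no) + emsland:::gap_count(t(no))
  })
  expect_gt((obs - mean(nulls)) / sd(nulls), 1)
})

test_that("noise flips cells at the requested rate", {
  m0 <- make_structure("clementsian", 40, 30, seed = 5, shuffle = FALSE)
  m1 <- make_structure("clementsian", 40, 30, seed = 5, noise = 0.1,
                       shuffle = FALSE)
  flips <- mean(unclass(m0) != unclass(m1))
  expect_gt(flips, 0.05); expect_lt(flips, 0.16)
})

test_that("infeasible specs are rejected", {
  expect_error(make_structure("clementsian", 10, 4, n_compartments = 6),
               "compartments")
  expect_error(make_structure("random", 1, 5), "n_species")
})

test_that("scenes assemble deterministically with later regions winning", {
  sc <- make_scene(6, 6, base_class = 2, regions = list(
    list(class = 1, rows = 1:4, cols = 1:4),
    list(class = 3, rows = 3:6, cols = 3:6)))
  expect_equal(sc$grid[4, 4], 3L)       # overwritten by the later region
  expect_equal(sc$grid[1, 1], 1L)

  s1 <- make_scene(8, 8, speckle = 0.3, seed = 10)
  s2 <- make_scene(8, 8, speckle = 0.3, seed = 10)
  expect_identical(s1$grid, s2$grid)

  expect_error(make_scene(4, 4, regions = list(
    list(class = 1, rows = 1:9, cols = 1:2))), "outside")
})

test_that("toy scenes reproduce the closed-form metrics", {
  block <- make_scene(8, 8, base_class = 2,
                      regions = list(list(class = 1, rows = 3:6, cols = 3:6)))
  ps <- label_patches(block)
  nf <- ps$patches[ps$patches$class == 1, ]
  expect_equal(shape_index(nf), 1)

  even <- make_scene(6, 8, base_class = 2,
                     regions = list(list(class = 1, rows = 1:3, cols = 1:8)))
  expect_equal(shei(label_patches(even)), 1)
})

test_that("the packaged frequency fixture matches its published margins", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$frequency), 101)
  expect_equal(length(unique(fx$traits$family)), 41)
  expect_equal(max(fx$frequency$AF_total), 31)
  expect_equal(fx$frequency$RF_total[1:3], c(97, 94, 91))
  expect_false(is.unsorted(rev(fx$frequency$AF_total)))
  for (cls in c("total", "adult", "juv")) {
    crf <- fx$frequency[[paste0("CRF_", cls)]]
    expect_false(is.unsorted(crf))
  }
})

test_that("synthetic survey matrices reproduce the fixture frequencies", {
  fx <- table1_fixture()
  mm <- table1_matrices(seed = 2)
  expect_equal(age_class(mm$adult), "adult")
  expect_equal(unname(rowSums(mm$total)[fx$frequency$species]),
               fx$frequency$AF_total)
  expect_equal(unname(rowSums(mm$adult)[fx$frequency$species]),
               fx$frequency$AF_adult)
  expect_equal(unname(rowSums(mm$juvenile)[fx$frequency$species]),
               fx$frequency$AF_juv)
})
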