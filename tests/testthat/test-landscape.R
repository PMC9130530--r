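solid_block <- function(n = 4, cell = 1) {
  landscape_raster(matrix(1L, n, n), cell_size = cell)
}

test_that("patch labeling uses 8-connectivity and computes geometry", {
  g <- matrix(2L, 4, 4)
  g[1, 1] <- 1L; g[2, 2] <- 1L        # diagonal cells join into one patch
  ps <- label_patches(landscape_raster(g, 1))
  expect_equal(sum(ps$patches$class == 1), 1)

  ps_block <- label_patches(solid_block(4, 1))
  expect_equal(ps_block$patches$area, 16)
  expect_equal(ps_block$patches$perimeter, 16)

  three <- make_scene(9, 9, base_class = 2, regions = list(
    list(class = 1, rows = 1:2, cols = 1:2),
    list(class = 1, rows = 5:6, cols = 5:6),
    list(class = 3, rows = 8:9, cols = 1:3)))
  ps3 <- label_patches(three)
  expect_equal(nrow(ps3$patches), 4)  # 2 forest + 1 timber + 1 background
  expect_equal(sum(ps3$patches$class == 1), 2)
})

test_that("class proportions sum to 100 and handle absent classes", {
  sc <- make_scene(10, 10, base_class = 2,
                   regions = list(list(class = 1, rows = 1:5, cols = 1:5)))
  ps <- label_patches(sc)
  expect_equal(class_proportion(ps, "native_forest"), 25)
  expect_equal(class_proportion(ps, "crops"), 0)
  codes <- unique(ps$patches$class)
  expect_equal(sum(vapply(codes, function(cd) class_proportion(ps, cd),
                          numeric(1))), 100)
})

test_that("LSI equals its closed forms and grows with internal edge", {
  ps <- label_patches(solid_block(8, 1))
  expect_equal(lsi(ps), 1)

  split <- landscape_raster(cbind(matrix(1L, 8, 4), matrix(2L, 8, 4)), 1)
  expect_equal(lsi(label_patches(split)), 1.25)

  more <- landscape_raster(cbind(matrix(1L, 8, 3), matrix(2L, 8, 2),
                                 matrix(1L, 8, 3)), 1)
  expect_gt(lsi(label_patches(more)), 1.25)
})

test_that("Shannon evenness follows the formula with the single-class convention", {
  even <- landscape_raster(cbind(matrix(1L, 6, 3), matrix(2L, 6, 3)), 1)
  expect_equal(shei(label_patches(even)), 1)
  expect_equal(shei(label_patches(solid_block())), 0)

  # 70 / 20 / 10 proportions
  g <- matrix(1L, 10, 10)
  g[1:2, ] <- 2L; g[3, ] <- 3L
  p <- c(0.7, 0.2, 0.1)
  expect_equal(shei(label_patches(landscape_raster(g, 1))),
               -sum(p * log(p)) / log(3))
})

test_that("aggregation index matches join counting and stays in [0, 100]", {
  ps <- label_patches(solid_block(4, 1))
  expect_equal(ai(ps, 1), 100)

  # perfectly interleaved classes: no like-joins at all
  g <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1L, 2L))
  ps2 <- label_patches(landscape_raster(g, 1))
  expect_equal(ai(ps2, 1), 0)
  expect_equal(ai(ps2, 2), 0)

  set.seed(12)
  for (rep in 1:10) {
    g <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    ps3 <- label_patches(landscape_raster(g, 1))
    vals <- c(ai(ps3, 1), ai(ps3, 2), ai(ps3, 3), ai(ps3, "landscape"))
    expect_true(all(vals >= 0 & vals <= 100))
    # like joins agree with the brute-force scan (class 1)
    n1 <- sum(g == 1)
    maxg <- emsland:::ai_max_joins(n1)
    if (maxg > 0) {
      expect_equal(ai(ps3, 1), 100 * brute_like_joins(g, 1) / maxg)
    }
  }

  single <- landscape_raster(rbind(c(1L, 2L), c(2L, 2L)), 1)
  expect_equal(ai(label_patches(single), 1), 100)   # single-cell convention
})

test_that("IJI measures edge evenness and is NA when undefined", {
  # focal class 1 strip between classes 2 and 3: equal edge shares, m = 3
  g <- rbind(matrix(2L, 3, 6), matrix(1L, 2, 6), matrix(3L, 3, 6))
  expect_equal(iji(label_patches(landscape_raster(g, 1)), 1), 100)

  # all focal edge with one neighbor class (m = 3 via an isolated corner)
  g2 <- rbind(matrix(2L, 3, 6), matrix(1L, 2, 6), matrix(2L, 3, 6))
  g2[1, 1] <- 3L
  expect_equal(iji(label_patches(landscape_raster(g2, 1)), 1), 0)

  two <- landscape_raster(cbind(matrix(1L, 4, 2), matrix(2L, 4, 2)), 1)
  expect_true(is.na(iji(label_patches(two), 1)))
})

test_that("nearest-neighbor distances use cell centers and per-patch minima", {
  g <- matrix(2L, 5, 7)
  g[3, 2] <- 1L; g[3, 5] <- 1L        # centers 3 cells apart
  ps <- label_patches(landscape_raster(g, cell_size = 30))
  expect_equal(enn_mn(ps, 1), 90)

  g2 <- matrix(2L, 5, 9)
  g2[3, c(1, 4, 9)] <- 1L             # collinear at 0, 3, 8
  ps2 <- label_patches(landscape_raster(g2, cell_size = 10))
  # per-patch minima: 30, 30, 50 -> mean
  expect_equal(enn_mn(ps2, 1), mean(c(30, 30, 50)))

  one <- label_patches(landscape_raster(matrix(c(1L, 2L), 1, 2), 1))
  expect_true(is.na(enn_mn(one, 1)))
})

test_that("PARA and SHAPE follow the patch closed forms", {
  p1 <- label_patches(solid_block(4, 1))$patches
  expect_equal(para(p1), 1)
  expect_equal(shape_index(p1), 1)

  p2 <- label_patches(solid_block(4, 2))$patches
  expect_equal(para(p2), 0.5)          # PARA is scale dependent
  expect_equal(shape_index(p2), 1)     # SHAPE is not

  strip <- label_patches(landscape_raster(matrix(1L, 1, 4), 1))$patches
  expect_equal(shape_index(strip), 0.25 * 10 / 2)

  # at fixed area the square minimizes PARA over rectangles
  paras <- sapply(list(c(4, 4), c(2, 8), c(1, 16)), function(d) {
    para(label_patches(landscape_raster(matrix(1L, d[1], d[2]), 1))$patches)
  })
  expect_equal(which.min(paras), 1)
})

test_that("metrics are invariant under rotation and translation", {
  set.seed(77)
  g <- matrix(sample(1:3, 120, replace = TRUE), 10, 12)
  r1 <- landscape_raster(g, 1)
  r2 <- landscape_raster(t(g)[ncol(g):1, ], 1)       # 90 degree rotation
  for (f in list(function(ps) lsi(ps), function(ps) shei(ps),
                 function(ps) ai(ps, "landscape"),
                 function(ps) class_proportion(ps, 1),
                 function(ps) iji(ps, 1))) {
    expect_equal(f(label_patches(r1)), f(label_patches(r2)))
  }
})

test_that("buffer reports carry the full metric column set", {
  sc <- make_scene(12, 12, cell_size = 30, base_class = 2, regions = list(
    list(class = 1, rows = 3:6, cols = 3:6),
    list(class = 3, rows = 9:12, cols = 1:4),
    list(class = 4, rows = 1:2, cols = 9:12)))
  rep <- summarize_buffer(sc)
  expect_named(rep, c("NP", "LSI", "SHEI", "AI", "P_NF", "P_GL", "P_TF",
                      "P_C", "N_NF", "IJI", "ENN", "AREA", "PARA", "SHAPE"))
  expect_equal(rep$N_NF, 1)
  expect_true(is.na(rep$ENN))          # single native-forest patch
  expect_equal(rep$SHAPE, 1)           # 4x4 block is maximally compact
  expect_equal(rep$P_NF + rep$P_GL + rep$P_TF + rep$P_C, 100)

  # water and urban cells are treated as background by default
  sc2 <- make_scene(12, 12, base_class = 2, regions = list(
    list(class = 1, rows = 3:6, cols = 3:6),
    list(class = 5, rows = 1:12, cols = 11:12)))
  rep2 <- summarize_buffer(sc2)
  expect_equal(rep2$P_NF, 100 * 16 / (144 - 24))

  expect_error(summarize_buffer(sc, focal_patch_id = 999), "not found")
})

test_that("ASCII grid round trip preserves the raster", {
  sc <- make_scene(7, 9, cell_size = 30, base_class = 2,
                   regions = list(list(class = 1, rows = 2:4, cols = 3:5)),
                   speckle = 0.1, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_asc(sc, tmp)
  back <- read_asc(tmp)
  expect_identical(back$grid, sc$grid)
  expect_equal(back$cell_size, 30)
})

test_that("circular buffers clip by cell-center distance", {
  r <- landscape_raster(matrix(1L, 21, 21), cell_size = 10)
  b <- buffer_mask(r, center = c(11, 11), radius = 50)
  expect_true(is.na(b$grid[1, 1]))
  expect_false(is.na(b$grid[11, 11]))
  expect_false(is.na(b$grid[11, 16]))  # exactly 50 m away
  expect_true(is.na(b$grid[11, 17]))
})
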