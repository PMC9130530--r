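mc_row <- function(z, p) tibble::tibble(observed = NA, null_mean = NA,
                                        null_sd = NA, z = z, p = p)
mi_row <- function(mi, p, clumped = NULL) {
  out <- tibble::tibble(MI = mi, p = p)
  if (!is.null(clumped)) out$clumped <- clumped
  out
}

test_that("the decision tree reproduces the canonical branch outcomes", {
  coh_pos <- mc_row(-4, 1e-4)   # fewer embedded absences: positive coherence
  coh_neg <- mc_row(4, 1e-4)    # more absences
  coh_ns <- mc_row(0.5, 0.6)
  turn_pos <- mc_row(3, 0.01)
  turn_neg <- mc_row(-3, 0.01)

  expect_equal(classify_structure(coh_neg, turn_pos, mi_row(2, 0.01)),
               "checkerboard")
  expect_equal(classify_structure(coh_ns, turn_pos, mi_row(2, 0.01)),
               "random")
  expect_equal(classify_structure(coh_pos, turn_pos, mi_row(2.5, 0.001)),
               "clementsian")
  expect_equal(classify_structure(coh_pos, turn_pos, mi_row(0.4, 0.001)),
               "evenly_spaced")
  expect_equal(classify_structure(coh_pos, turn_pos, mi_row(1.3, 0.4)),
               "gleasonian")
  expect_equal(classify_structure(coh_pos, turn_neg, mi_row(2.5, 0.001)),
               "nested_clumped")
  expect_equal(classify_structure(coh_pos, turn_neg, mi_row(0.4, 0.001)),
               "nested_evenly_spaced")
  expect_equal(classify_structure(coh_pos, turn_neg, mi_row(1.1, 0.5)),
               "nested_random")
})

test_that("non-significant turnover yields quasi-variants by its sign", {
  coh_pos <- mc_row(-4, 1e-4)
  turn_up <- mc_row(1.2, 0.23)
  turn_down <- mc_row(-0.8, 0.4)
  expect_equal(classify_structure(coh_pos, turn_up, mi_row(2.5, 0.001)),
               "quasi_clementsian")
  expect_equal(classify_structure(coh_pos, turn_up, mi_row(0.5, 0.001)),
               "quasi_evenly_spaced")
  expect_equal(classify_structure(coh_pos, turn_up, mi_row(1, 0.7)),
               "quasi_gleasonian")
  expect_equal(classify_structure(coh_pos, turn_down, mi_row(2.5, 0.001)),
               "quasi_nested_clumped")
  expect_equal(classify_structure(coh_pos, turn_down, mi_row(0.5, 0.001)),
               "quasi_nested_evenly_spaced")
  expect_equal(classify_structure(coh_pos, turn_down, mi_row(1, 0.7)),
               "quasi_nested_random")
})

test_that("an explicit clumped flag overrides the MI > 1 rule", {
  coh_pos <- mc_row(-4, 1e-4)
  turn_pos <- mc_row(3, 0.01)
  # MI above 1 but below its null reference: evenly spaced
  expect_equal(classify_structure(coh_pos, turn_pos,
                                  mi_row(1.2, 0.01, clumped = FALSE)),
               "evenly_spaced")
})

test_that("analysis results are reproducible under a fixed seed", {
  m <- make_structure("clementsian", 18, 12, seed = 3)
  r1 <- suppressMessages(ems_analyze(m, iterations = 100, seed = 5))
  r2 <- suppressMessages(ems_analyze(m, iterations = 100, seed = 5))
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$label, r2$label)
  expect_identical(r1$morisita, r2$morisita)
})

test_that("reversing the site order does not change the label", {
  for (s in 1:3) {
    m <- make_structure("clementsian", 20, 12, seed = s)
    rev_m <- incidence_matrix(unclass(m)[, rev(seq_len(ncol(m)))],
                              age_class(m))
    l1 <- suppressMessages(ems_analyze(m, iterations = 150, seed = 7))$label
    l2 <- suppressMessages(ems_analyze(rev_m, iterations = 150, seed = 7))$label
    expect_equal(l1, l2)
  }
})

test_that("tidy and glance expose the statistics tables", {
  m <- make_structure("nested_random", 16, 10, seed = 2)
  r <- suppressMessages(ems_analyze(m, iterations = 60, seed = 8))
  td <- tidy(r)
  expect_setequal(td$element, c("coherence", "turnover", "boundary_clumping"))
  gl <- glance(r)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("label", "coherence_z", "turnover_z", "morisita",
                    "iterations") %in% names(gl)))
  expect_s3_class(autoplot(r), "ggplot")
})
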