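test_that("percentile color classes follow the published scheme", {
  # identical values: one class everywhere
  S <- matrix(0.3, 4, 3)
  cc <- percentile_colorcode(S)
  expect_length(unique(as.vector(cc$classes)), 1)
  # one dominant cell in a 78 x 1 column: exactly one top-class cell
  v <- matrix(c(0.9, rep(1e-5, 77)), 78, 1)
  cc <- percentile_colorcode(v)
  expect_identical(sum(cc$classes == "red"), 1L)
  expect_identical(cc$classes[1, 1], "red")
  expect_true(all(cc$classes[-1, 1] == "green"))
})

test_that("columns uniformly above the matrix median are flagged", {
  S <- cbind(runif(20, 0, 0.3), runif(20, 0.6, 1))
  colnames(S) <- c("low", "high")
  cc <- percentile_colorcode(S)
  expect_false(cc$above_median_columns[["low"]])
  expect_true(cc$above_median_columns[["high"]])
})

test_that("degenerate inputs are rejected", {
  expect_error(percentile_colorcode(matrix(numeric(0), 0, 0)), "empty")
  expect_error(percentile_colorcode(matrix(c(0.1, NA), 1)), "finite")
  expect_error(percentile_colorcode(matrix(c(0.5, 1.2), 1)), "0, 1")
})

test_that("heatmap rendering runs on a sensitivity-shaped matrix", {
  S <- matrix(runif(78 * 23, 0, 1), 78, 23,
              dimnames = list(fast_parameter_names(), state_info()$name))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 400, height = 400)
  cc <- plot_sensitivity_heatmap(S)
  grDevices::dev.off()
  expect_true(file.exists(f))
  expect_identical(dim(cc$classes), dim(S))
})
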