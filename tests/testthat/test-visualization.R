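# Fan-plot and nomogram layouts plus rendering.

test_that("fan layout places factors at (1/P, beta_ave) with slope = approx PAF", {
  tab <- data.frame(factor = "hypertension", prevalence = 0.474,
                    beta_ave = 1.093)
  fl <- fan_layout(tab)
  p <- fl$points
  expect_equal(p$x, 1 / 0.474, tolerance = 1e-9)
  expect_equal(p$y, 1.093)
  expect_equal(p$slope, 0.474 * 1.093, tolerance = 1e-12)
  expect_equal(p$intercept, p$slope)
  expect_equal(round(p$intercept, 3), 0.518)

  # P = 1: the point sits on the left axis and y equals the intercept
  f1 <- fan_layout(data.frame(factor = "cont", prevalence = 1,
                              beta_ave = 0.7))
  expect_equal(f1$points$x, 1)
  expect_equal(f1$points$y, f1$points$intercept, tolerance = 1e-12)

  # equal approximate PAFs: identical slopes, distinct points
  f2 <- fan_layout(data.frame(factor = c("a", "b"),
                              prevalence = c(0.5, 0.25),
                              beta_ave = c(0.4, 0.8)))
  expect_equal(f2$points$slope[1], f2$points$slope[2], tolerance = 1e-12)
  expect_false(f2$points$x[1] == f2$points$x[2])
})

test_that("fan intercept identity holds for random inputs", {
  set.seed(101)
  p <- runif(1000, 0.01, 1)
  b <- runif(1000, 0.01, 2)
  fl <- suppressWarnings(
    fan_layout(data.frame(factor = paste0("f", 1:1000),
                          prevalence = p, beta_ave = b)))
  # slope evaluated at x = 1 equals the left-axis intercept = P * beta
  expect_true(all(abs(fl$points$slope * 1 - fl$points$intercept) < 1e-12))
  expect_true(all(abs(fl$points$intercept - p * b) < 1e-12))
  expect_true(all(fl$points$x >= 1))
})

test_that("published table ranks hypertension first and diabetes last", {
  fl <- fan_layout(stroke_table())
  pts <- fl$points[order(fl$points$rank), ]
  expect_equal(pts$rank, 1:10)
  expect_equal(pts$factor[1], "High blood pressure")
  expect_equal(pts$factor[10], "Diabetes")
})

test_that("layouts refuse invalid inputs with informative messages", {
  # negative beta_ave warns in the formula layer, then the layout
  # refuses and names the offending factor
  expect_error(suppressWarnings(
    fan_layout(data.frame(factor = "bad", prevalence = 0.5,
                          beta_ave = -0.1))), "bad")
  expect_error(fan_layout(list()), "no risk factors")
  expect_error(nomogram_layout(data.frame(factor = "x", prevalence = 1.4,
                                          beta_ave = 0.5)),
               "\\(0, 1\\]")
  w <- capture_warnings(nomogram_layout(data.frame(factor = "x",
                                                   prevalence = 0.9,
                                                   beta_ave = 1.5)))
  expect_true(any(grepl(">= 1", w)))
})

test_that("nomogram points are collinear across 1000 random inputs", {
  set.seed(103)
  p <- runif(1000, 0.02, 0.99)
  b <- runif(1000, 0.01, 2)
  for (ord in c("prevalence-left", "or-left")) {
    nl <- suppressWarnings(
      nomogram_layout(data.frame(factor = paste0("f", 1:1000),
                                 prevalence = p, beta_ave = b),
                      ordering = ord))
    f <- nl$factors
    # cross product of the two segment vectors along the line
    cross <- 0.5 * (f$y_right - f$y_left) - 1 * (f$y_mid - f$y_left)
    expect_true(all(abs(cross) < 1e-10))
  }
})

test_that("identical (P, beta) pairs map to identical nomogram lines", {
  tab <- data.frame(factor = c("a", "b"), prevalence = c(0.3, 0.3),
                    beta_ave = c(0.6, 0.6))
  nl <- nomogram_layout(tab)
  expect_equal(nl$factors$y_left[1], nl$factors$y_left[2])
  expect_equal(nl$factors$y_mid[1], nl$factors$y_mid[2])
  expect_equal(nl$factors$y_right[1], nl$factors$y_right[2])
})

test_that("the right-axis ordinate is the same under both orderings", {
  tab <- stroke_table()
  n1 <- nomogram_layout(tab, ordering = "prevalence-left")
  n2 <- nomogram_layout(tab, ordering = "or-left")
  expect_equal(n1$factors$y_right, n2$factors$y_right, tolerance = 1e-12)
  # equal approximate PAFs intersect the right axis at the same ordinate
  t2 <- data.frame(factor = c("a", "b"), prevalence = c(0.5, 0.25),
                   beta_ave = c(0.4, 0.8))
  nn <- nomogram_layout(t2)
  expect_equal(nn$factors$y_right[1], nn$factors$y_right[2],
               tolerance = 1e-12)
})

test_that("tilting pivots about the left-axis point at a new prevalence", {
  tab <- stroke_table()
  nl <- nomogram_layout(tab, ordering = "or-left",
                        tilts = c(Smoking = 0.302))
  tl <- nl$tilts
  expect_equal(tl$approx_paf, 0.302 * 0.513, tolerance = 1e-9)
  expect_equal(round(tl$approx_paf, 3), 0.155)
  i <- match("Smoking", nl$factors$factor)
  expect_equal(tl$y_left, nl$factors$y_left[i])  # shared pivot
  expect_equal(tl$type, "alternative-population")

  # tilt back to the original prevalence coincides with the original line
  nl0 <- nomogram_layout(tab, ordering = "or-left",
                         tilts = c(Smoking = 0.224))
  expect_equal(nl0$tilts$y_mid, nl0$factors$y_mid[i], tolerance = 1e-12)
  expect_equal(nl0$tilts$y_right, nl0$factors$y_right[i], tolerance = 1e-12)

  # halving hypertension is an intervention tilt
  nh <- nomogram_layout(tab, ordering = "or-left",
                        tilts = c(`High blood pressure` = 0.237))
  expect_equal(nh$tilts$type, "intervention")
  expect_error(nomogram_layout(tab, ordering = "prevalence-left",
                               tilts = c(Smoking = 0.3)),
               "or-left")
  expect_error(nomogram_layout(tab, ordering = "or-left",
                               tilts = c(nonexistent = 0.3)),
               "nonexistent")
})

test_that("rendering is deterministic and supports svg and png", {
  tab <- stroke_table()
  fl <- fan_layout(tab)
  nl <- nomogram_layout(tab, ordering = "or-left",
                        tilts = c(`High blood pressure` = 0.237))
  for (layout in list(fl, nl)) {
    p1 <- withr::local_tempfile(fileext = ".svg")
    p2 <- withr::local_tempfile(fileext = ".svg")
    render(layout, p1)
    render(layout, p2)
    expect_gt(file.size(p1), 0)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
  png_path <- withr::local_tempfile(fileext = ".png")
  render(fl, png_path, format = "png")
  expect_gt(file.size(png_path), 0)
  expect_error(render(fl, "/nonexistent-dir/x.svg"), "nonexistent-dir")
})

test_that("bias heatmaps render to file", {
  s <- bias_surface(prevalence_grid = seq(0.1, 0.9, 0.1),
                    or_grid = seq(1.1, 3, 0.1))
  for (w in c("b_abs", "b_r")) {
    path <- withr::local_tempfile(fileext = ".svg")
    bias_heatmap(s, w, path = path)
    expect_gt(file.size(path), 0)
  }
})

test_that("layouts export to JSON with axes and coordinates", {
  nl <- nomogram_layout(stroke_table())
  js <- layout_json(nl)
  obj <- jsonlite::fromJSON(js)
  expect_equal(length(obj$factors$factor), 10)
  expect_equal(obj$axes$left$x, 0)
  expect_equal(obj$axes$right$x, 1)
  path <- withr::local_tempfile(fileext = ".json")
  layout_json(fan_layout(stroke_table()), path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$points$slope, fan_layout(stroke_table())$points$slope,
               tolerance = 1e-9)
})
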