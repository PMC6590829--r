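test_that("attribute, comment and data lines are classified correctly", {
  txt <- paste("# a comment line",
               "temperature 293.15",
               "sample bovine serum",
               "vecattr 1 2 3",
               "1 0.5",
               "2 0.25",
               sep = "\n")
  dc <- read_dat(text = txt)
  expect_length(dc, 1)
  ds <- dc[[1]]
  expect_identical(ds_attr(ds, "temperature"), 293.15)
  expect_identical(ds_attr(ds, "sample"), "bovine serum")
  expect_identical(ds_attr(ds, "vecattr"), c(1, 2, 3))
  expect_identical(ds$comments, "a comment line")
  expect_identical(dim(ds$data), c(2L, 2L))
})

test_that("comment-only input gives an empty collection", {
  dc <- read_dat(text = "just words here\n# more words\n")
  expect_length(dc, 0)
  expect_length(read_dat(text = ""), 0)
})

test_that("blank lines and post-data attributes start new blocks", {
  txt <- "q 0.5\n1 1\n2 2\n\nq 1.0\n1 3\n2 4\n"
  dc <- read_dat(text = txt)
  expect_length(dc, 2)
  expect_identical(dc_attr(dc, "q"), c(0.5, 1.0))
  # without blank line: attribute after data rows also splits
  txt2 <- "q 0.5\n1 1\n2 2\nq 1.0\n1 3\n2 4\n"
  expect_length(read_dat(text = txt2), 2)
})

test_that("ragged rows raise an error naming the line", {
  expect_error(read_dat(text = "1 2\n3 4 5\n"), "line 2")
})

test_that("parse options work: replacement map, columns, block keyword", {
  dc <- read_dat(text = "1,5 2,5\n3,5 4,5\n", replace = c("," = "."))
  expect_equal(dc[[1]]$data[1, ], c(1.5, 2.5))
  dc2 <- read_dat(text = "1 2 3\n4 5 6\n", columns = c(1, 3))
  expect_equal(dc2[[1]]$data, matrix(c(1, 4, 3, 6), 2, 2))
  dc3 <- read_dat(text = "1 1\n2 2\nNEXT x\n3 3\n4 4\n", block = "NEXT")
  expect_length(dc3, 2)
})

test_that("write -> parse round trips randomized dataSets exactly", {
  for (seed in 1:40) {
    ds <- random_dataset(seed)
    back <- read_dat(text = write_dat(dataCollection(ds)))
    expect_length(back, 1)
    expect_identical(back[[1]]$data, unname(ds$data))
    expect_identical(back[[1]]$attributes, ds$attributes)
    expect_identical(back[[1]]$comments, ds$comments)
    expect_identical(back[[1]]$roles, ds$roles)
  }
})

test_that("multi-set files and vector attributes round trip", {
  dc <- dataCollection(lapply(1:3, random_dataset))
  f <- tempfile(fileext = ".dat")
  write_dat(dc, f)
  back <- read_dat(f)
  expect_length(back, 3)
  for (i in 1:3) expect_identical(back[[i]]$attributes, dc[[i]]$attributes)
  # one-row data block stays data, vector attribute stays attribute
  one <- dataSet(matrix(c(1, 2, 3), 1, 3),
                 attributes = list(v = c(1, 2, 3)))
  b1 <- read_dat(text = write_dat(dataCollection(one)))[[1]]
  expect_identical(dim(b1$data), c(1L, 3L))
  expect_identical(b1$attributes$v, c(1, 2, 3))
  # empty collection -> empty file
  expect_identical(write_dat(dataCollection()), "")
})

test_that("filter_collection selects by attributes and composes", {
  dc <- dataCollection(lapply(c(280, 300, 320), function(Tv)
    dataSet(cbind(1:3, 1:3), attributes = list(temperature = Tv))))
  hot <- filter_collection(dc, function(a) a$temperature > 300)
  expect_length(hot, 1)
  expect_length(filter_collection(dc, function(a) TRUE), 3)
  expect_length(filter_collection(dc, function(a) FALSE), 0)
  # composition p then q == p & q
  p <- function(a) a$temperature > 280
  q <- function(a) a$temperature < 320
  both <- filter_collection(filter_collection(dc, p), q)
  joint <- filter_collection(dc, function(a) p(a) && q(a))
  expect_identical(dc_attr(both, "temperature"), dc_attr(joint, "temperature"))
  # predicate error on missing attribute excludes the item with a warning
  dc2 <- dataCollection(list(dc[[1]],
                             dataSet(cbind(1, 1))))
  expect_warning(kept <- filter_collection(dc2, function(a)
    if (is.null(a$temperature)) stop("missing") else TRUE))
  expect_length(kept, 1)
})

test_that("dc_attr returns NA for missing attributes", {
  dc <- dataCollection(list(
    dataSet(cbind(1, 1), attributes = list(q = 0.5)),
    dataSet(cbind(1, 1))))
  expect_identical(dc_attr(dc, "q"), c(0.5, NA))
})

test_that("prune averages in bins and propagates uncertainties", {
  x <- 1:100
  y <- sin(x / 7)
  ds <- dataSet(cbind(x, y))
  pr <- prune(ds, 10)
  expect_identical(nrow(pr$data), 10L)
  # direct averaging oracle: equal-population bins of 10
  oracle_y <- colMeans(matrix(y, 10, 10))
  expect_close(ds_y(pr), oracle_y, 1e-12)
  oracle_x <- colMeans(matrix(as.numeric(x), 10, 10))
  expect_close(ds_x(pr), oracle_x, 1e-12)
  # global mean conserved for equal-population bins
  expect_lt(abs(mean(ds_y(pr)) - mean(y)), 1e-12)
  # n_bins = n distinct rows reproduces the input
  pr2 <- prune(ds, 100)
  expect_close(ds_y(pr2), y, 1e-12)
  # constant Y gives eY = 0
  pc <- prune(dataSet(cbind(x, rep(2, 100))), 10)
  expect_true(all(ds_ey(pc) == 0))
  expect_true(all(ds_y(pc) == 2))
  # input eY propagates as sqrt(sum(e^2))/n
  dse <- dataSet(cbind(x, y, rep(0.2, 100)))
  pre <- prune(dse, 10)
  expect_close(ds_ey(pre), rep(sqrt(10 * 0.04) / 10, 10), 1e-12)
  # log scale demands positive X
  expect_error(prune(dataSet(cbind(-1:5, 0:6)), 2, scale = "log"), "positive")
  expect_warning(prune(ds, 200), "n_bins")
})

test_that("interpolation methods reproduce knots and exact polynomials", {
  ds <- dataSet(cbind(0:5, 2 * (0:5)))
  # knot identity and linearity
  expect_close(ds_y(ds_interpolate(ds, c(0, 2, 5))), c(0, 4, 10), 1e-12)
  expect_equal(ds_y(ds_interpolate(ds, 1.5)), 3)
  # quadratic through Y = X^2 exact at midpoints
  x <- 0:6
  dq <- dataSet(cbind(x, x^2))
  mid <- x[-1] - 0.5
  yq <- ds_y(ds_interpolate(dq, mid, method = "polynomial", degree = 2))
  expect_close(yq, mid^2, 1e-10)
  # bspline passes through the knots
  yb <- ds_y(ds_interpolate(dq, x, method = "bspline"))
  expect_close(yb, x^2, 1e-10)
  # out-of-range errors unless allowed
  expect_error(ds_interpolate(ds, 7), "extrapolate")
  expect_silent(ds_interpolate(ds, 7, extrapolate = TRUE))
  # attributes survive
  dsa <- dataSet(cbind(0:5, 0:5), attributes = list(q = 1))
  expect_identical(ds_attr(ds_interpolate(dsa, 2.5), "q"), 1)
})
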