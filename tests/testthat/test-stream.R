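# CrystFEL-stream writing/parsing and unit-cell statistics.

make_cells <- function(n, a = 45.3, sd = 0.1, seed = 1) {
  set.seed(seed)
  data.frame(a = stats::rnorm(n, a, sd), b = stats::rnorm(n, a, sd),
             c = stats::rnorm(n, 183.9, 0.2),
             al = stats::rnorm(n, 90, 0.1), be = stats::rnorm(n, 90, 0.1),
             ga = stats::rnorm(n, 120.1, 0.1),
             resolution_limit = stats::runif(n, 1.9, 3.5))
}

test_that("an empty fixture parses to an empty record set", {
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream_fixture(make_cells(0)[0, ], path)
  rec <- parse_stream(path)
  expect_equal(nrow(rec), 0)
})

test_that("a single cell round-trips exactly to printed precision", {
  path <- withr::local_tempfile(fileext = ".stream")
  cells <- data.frame(a = 45.3, b = 45.3, c = 183.9,
                      al = 90, be = 90, ga = 120.1,
                      resolution_limit = 2.3)
  write_stream_fixture(cells, path)
  rec <- parse_stream(path)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$a, 45.3, tolerance = 1e-9)
  expect_equal(rec$ga, 120.1, tolerance = 1e-9)
  expect_equal(rec$resolution_limit, 2.3, tolerance = 1e-9)
})

test_that("parsed sample means match the generating distribution", {
  n <- 1400
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream_fixture(make_cells(n, a = 47.0, sd = 1.0, seed = 2), path)
  rec <- parse_stream(path)
  expect_equal(nrow(rec), n)
  expect_lt(abs(mean(rec$a) - 47.0), 3 * 1.0 / sqrt(n))
})

test_that("unindexed and malformed chunks are skipped", {
  path <- withr::local_tempfile(fileext = ".stream")
  writeLines(c("CrystFEL stream format 2.3",
               "----- Begin chunk -----",
               "Image filename: nohit.h5",
               "----- End chunk -----",
               "----- Begin chunk -----",
               "Cell parameters garbage here",
               "----- End chunk -----",
               "----- Begin chunk -----",
               "--- Begin crystal",
               "Cell parameters 4.53000 4.53000 18.39000 nm, 90.00 90.00 120.10 deg",
               "--- End crystal",
               "----- End chunk -----"), path)
  expect_warning(rec <- parse_stream(path), "malformed")
  expect_equal(nrow(rec), 1)
  expect_equal(rec$chunk, 3)
  expect_error(suppressWarnings(parse_stream(path, strict = TRUE)),
               "malformed")
})

test_that("cell volume matches a vector-algebra evaluation", {
  # independent oracle: build the lattice vectors explicitly and take the
  # determinant of the cell matrix
  vol_oracle <- function(a, b, c, al, be, ga) {
    alr <- al * pi / 180; ber <- be * pi / 180; gar <- ga * pi / 180
    va <- c(a, 0, 0)
    vb <- c(b * cos(gar), b * sin(gar), 0)
    cx <- c * cos(ber)
    cy <- c * (cos(alr) - cos(ber) * cos(gar)) / sin(gar)
    cz <- sqrt(c^2 - cx^2 - cy^2)
    abs(det(rbind(va, vb, c(cx, cy, cz))))
  }
  cases <- list(c(45.3, 45.3, 183.9, 90, 90, 120.1),
                c(47.0, 47.2, 183.5, 90.2, 89.9, 120.9),
                c(10, 12, 14, 80, 95, 102))
  for (p in cases) {
    expect_equal(cell_volume(p[1], p[2], p[3], p[4], p[5], p[6]),
                 vol_oracle(p[1], p[2], p[3], p[4], p[5], p[6]),
                 tolerance = 1e-9)
  }
  expect_error(cell_volume(-1, 2, 3, 90, 90, 90))
  expect_error(cell_volume(1, 2, 3, 190, 90, 90))
})

test_that("constant cells give exactly zero volume trend", {
  rec <- data.frame(chunk = 1:50, a = 45.3, b = 45.3, c = 183.9,
                    al = 90, be = 90, ga = 120.1,
                    resolution_limit = 2.3)
  rec$cell_volume <- cell_volume(rec$a, rec$b, rec$c, rec$al, rec$be, rec$ga)
  cs <- cell_summary(rec, time_bins = 5)
  expect_identical(cs$trend$slope[cs$trend$quantity == "cell_volume"], 0)
  expect_equal(nrow(cs$bins), 5)
  expect_true(all(cs$bins$cell_volume_sd == 0))
})

test_that("an injected volume drift is recovered within 2 SE", {
  n <- 500
  set.seed(6)
  a0 <- 45.3
  drift <- 1e-4  # relative volume change per chunk
  rec <- data.frame(chunk = 1:n,
                    a = a0 * (1 + drift / 3 * (1:n)) + stats::rnorm(n, 0, 0.05),
                    b = a0, c = 183.9, al = 90, be = 90, ga = 120.1,
                    resolution_limit = 2.3)
  rec$cell_volume <- cell_volume(rec$a, rec$b, rec$c, rec$al, rec$be, rec$ga)
  true_slope <- stats::coef(stats::lm(
    cell_volume(a0 * (1 + drift / 3 * (1:n)), a0, 183.9, 90, 90, 120.1)
    ~ seq_len(n)))[2]
  cs <- cell_summary(rec, time_bins = 10)
  tr <- cs$trend[cs$trend$quantity == "cell_volume", ]
  expect_lt(abs(tr$slope - true_slope), 2 * tr$slope_se)
  # sd undefined in single-record bins is reported missing
  one <- cell_summary(rec[1, ], time_bins = 1)
  expect_true(is.na(one$bins$a_sd))
})

test_that("fixtures from the generator survive a 1e4-cell round trip", {
  n <- 1e4
  cells <- make_cells(n, seed = 3)
  path <- withr::local_tempfile(fileext = ".stream")
  write_stream_fixture(cells, path)
  rec <- parse_stream(path)
  expect_equal(nrow(rec), n)
  # printed precision: 1e-5 nm = 1e-4 Angstrom, 0.01 degrees
  expect_lt(max(abs(rec$a - cells$a)), 5.1e-5)
  expect_lt(max(abs(rec$c - cells$c)), 5.1e-5)
  expect_lt(max(abs(rec$ga - cells$ga)), 5.1e-3)
  expect_lt(max(abs(rec$resolution_limit - cells$resolution_limit)), 5.1e-3)
})
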