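test_that("construction validates counts, drops zero lines, and keeps labels unique", {
  wide <- matrix(c(2, 1, 0, 0, 3, 0), nrow = 3,
                 dimnames = list(c("h1", "h2", "h3"), c("A", "B")))
  expect_warning(m <- interaction_matrix(wide), "h3")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(rownames(m), c("h1", "h2"))

  long <- tibble::tibble(
    hollow = c("h1", "h2", "h2"), species = c("A", "A", "B"),
    count = c(2L, 1L, 3L)
  )
  m2 <- interaction_matrix(long)
  expect_equal(as.matrix(m2)[rownames(m), colnames(m)], as.matrix(m))

  neg <- wide; neg[1, 1] <- -1
  expect_error(interaction_matrix(neg), "h1.*A|A.*h1")
  dup <- wide; rownames(dup) <- c("h1", "h1", "h3")
  expect_error(interaction_matrix(dup), "Duplicate")
  expect_error(
    suppressWarnings(interaction_matrix(matrix(0L, 2, 2,
      dimnames = list(c("a", "b"), c("x", "y"))))),
    "no positive"
  )
})

test_that("wide and long files round-trip through disk identically", {
  m <- as_im(random_count_matrix(5, 7))
  for (fmt in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_interaction_matrix(m, path, format = fmt)
    back <- read_interaction_matrix(path)
    expect_equal(as.matrix(back)[rownames(m), colnames(m)], as.matrix(m),
                 info = fmt)
  }
})

test_that("reader errors name the offending cell and normalizes orientation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hollow,A,B", "h1,2,x", "h2,1,3"), path)
  expect_error(read_interaction_matrix(path), "B")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,h1,h2", "A,2,1", "B,0,3"), path2)
  m <- read_interaction_matrix(path2, orientation = "species_as_rows")
  expect_equal(rownames(m), c("h1", "h2"))
  expect_equal(as.vector(as.matrix(m)["h2", ]), c(1, 3))
})

test_that("summary tables round-trip and tolerate empty input", {
  summ <- tibble::tibble(
    site = c("riparian", "park"), year = c("t1", "t1"),
    nodf = c(15.754321, 10.63), RR = c(0.9012345678, 0.84)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(summ, path)
  back <- read_summary_table(path)
  expect_equal(back$metric, c("nodf", "RR"))
  expect_identical(back$riparian_t1[1], summ$nodf[1])
  expect_identical(back$park_t1[2], summ$RR[2])

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(summ[0, ], path2)
  expect_equal(nrow(read_summary_table(path2)), 0)
})

test_that("pooling concatenates hollows and unions species", {
  a <- interaction_matrix(
    matrix(c(1L, 2L), 1, 2, dimnames = list("h1", c("A", "B"))),
    site = "s1", year = "t1", quiet = TRUE
  )
  b <- interaction_matrix(
    matrix(c(3L, 4L), 1, 2, dimnames = list("h1", c("B", "C"))),
    site = "s2", year = "t1", quiet = TRUE
  )
  park <- pool_networks(list(a, b))
  expect_equal(nrow(park), 2)
  expect_setequal(colnames(park), c("A", "B", "C"))
  expect_equal(sum(park), sum(a) + sum(b))
  expect_equal(as.matrix(park)["s2.h1", "B"], 3L)
})
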