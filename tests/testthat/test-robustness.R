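two_hollow <- local({
  m <- matrix(0L, 2, 4, dimnames = list(c("H1", "H2"), c("A", "B", "C", "D")))
  m["H1", ] <- 1L
  m["H2", "A"] <- 1L
  as_im(m)
})

test_that("removal sequences follow degree/abundance orders with tie-breaks", {
  m <- as_im(matrix(c(5L, 3L, 2L, 0L, 1L, 0L, 0L, 1L, 0L, 2L, 0L, 3L), nrow = 3,
                    dimnames = list(c("h1", "h2", "h3"), paste0("s", 1:4))))
  # degrees: h1 = 2, h2 = 3, h3 = 2; abundances: h1 = 7, h2 = 5, h3 = 5;
  # degree ties fall back on abundance and vice versa
  expect_equal(extinction_sequence(m, "most_connected_first"), c("h2", "h1", "h3"))
  expect_equal(extinction_sequence(m, "least_first", variant = "degree"),
               c("h3", "h1", "h2"))
  expect_equal(extinction_sequence(m, "least_first", variant = "abundance"),
               c("h3", "h2", "h1"))
  expect_identical(extinction_sequence(m, "random", seed = 4),
                   extinction_sequence(m, "random", seed = 4))

  # abundance ties broken by degree
  tie <- as_im(matrix(c(10L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 1L, 10L, 0L, 2L),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("h1", "h2", "h3"), paste0("s", 1:4))))
  # abundances 10, 3, 13; degrees 1, 1, 3
  expect_equal(extinction_sequence(tie, "least_first", variant = "abundance")[1], "h2")
})

test_that("extinction curves cascade secondary extinctions correctly", {
  c1 <- extinction_curve(two_hollow, c("H1", "H2"))
  expect_equal(c1$removed_frac, c(0, 0.5, 1))
  expect_equal(c1$surviving_frac, c(1, 0.25, 0))
  c2 <- extinction_curve(two_hollow, c("H2", "H1"))
  expect_equal(c2$surviving_frac, c(1, 1, 0))

  single <- as_im(matrix(c(1L, 2L), 1, 2, dimnames = list("h1", c("A", "B"))))
  cs <- extinction_curve(single, "h1")
  expect_equal(cs$surviving_frac, c(1, 0))
  expect_error(extinction_curve(two_hollow, c("H1", "H1")), "permutation")
})

test_that("robustness areas match the trapezoid hand values", {
  expect_equal(robustness(extinction_curve(two_hollow, c("H1", "H2"))), 0.375)
  expect_equal(robustness(extinction_curve(two_hollow, c("H2", "H1"))), 0.75)
  rs <- robustness_suite(two_hollow)
  expect_equal(rs$summary$RR, 0.5625)
  expect_identical(rs$summary$rr_mode, "exhaustive")
  expect_equal(rs$summary$RM, 0.375) # H1 is the most connected
  expect_equal(rs$summary$RL, 0.75)
})

test_that("Monte-Carlo RR converges to the exhaustive average", {
  set.seed(60)
  m <- as_im(random_count_matrix(5, 10, 0.35))
  exact <- robustness_suite(m, exhaustive_max = 6)$summary$RR
  expect_equal(exact, rr_oracle(m), tolerance = 1e-12)
  mc <- robustness_suite(m, random_reps = 1000, seed = 8, exhaustive_max = 0)
  se <- sd(mc$rr_values) / sqrt(length(mc$rr_values))
  expect_lt(abs(mc$summary$RR - exact), 3 * se + 1e-9)
})

test_that("curves are monotone and R bounded on random webs", {
  set.seed(61)
  for (i in 1:20) {
    m <- as_im(random_count_matrix(sample(3:8, 1), sample(4:12, 1), 0.4))
    cur <- extinction_curve(m, extinction_sequence(m, "random", seed = i))
    expect_equal(cur$surviving_frac[1], 1)
    expect_equal(cur$surviving_frac[nrow(cur)], 0)
    expect_true(all(diff(cur$surviving_frac) <= 1e-12))
    r <- robustness(cur)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})
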