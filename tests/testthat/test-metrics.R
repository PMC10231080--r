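worked <- interaction_matrix(
  matrix(c(2L, 1L, 0L, 3L), 2, dimnames = list(c("h1", "h2"), c("A", "B"))),
  quiet = TRUE
)

test_that("species strength follows the dependency formula and conserves totals", {
  ns <- node_scores(worked)
  expect_equal(ns$strength[ns$node == "h1"], 2 / 3)
  expect_equal(ns$strength[ns$node == "h2"], 4 / 3)

  one_hollow <- as_im(matrix(c(1L, 2L, 5L), 1, dimnames = list("h1", c("A", "B", "C"))))
  expect_equal(node_scores(one_hollow)$strength[1], 3)

  d4 <- diag(4L) * 3L
  dimnames(d4) <- list(paste0("h", 1:4), paste0("s", 1:4))
  diag4 <- as_im(d4)
  expect_true(all(node_scores(diag4)$strength == 1))

  set.seed(42)
  for (i in 1:25) {
    m <- as_im(random_count_matrix(sample(2:8, 1), sample(2:8, 1)))
    ns <- node_scores(m)
    expect_equal(sum(ns$strength[ns$level == "hollow"]), ncol(m))
    expect_equal(sum(ns$strength[ns$level == "beetle"]), nrow(m))
  }
})

test_that("connectance and links per species count positive cells", {
  b <- basic_metrics(worked)
  expect_equal(b$links, 3L)
  expect_equal(b$connectance, 0.75)
  expect_equal(b$links_per_species, 0.75)

  full <- as_im(matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(basic_metrics(full)$connectance, 1)
  expect_equal(basic_metrics(full)$links_per_species, 1)

  single <- as_im(matrix(2L, 1, 1, dimnames = list("a", "x")))
  expect_equal(basic_metrics(single)$connectance, 1)
  expect_equal(basic_metrics(single)$links_per_species, 0.5)
})

test_that("linkage density is the Bersier weighted partner diversity", {
  expect_equal(linkage_density(as_im(diag(c(5L, 5L)) |>
    `dimnames<-`(list(c("h1", "h2"), c("A", "B"))))), 1)
  expect_equal(linkage_density(as_im(matrix(1L, 2, 2,
    dimnames = list(c("h1", "h2"), c("A", "B"))))), 2)
  # direct evaluation of the formula on the worked 2x2 example
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  expected <- 0.5 * (
    (3 / 6) * 2^h(c(2, 1) / 3) + (3 / 6) * 1 +  # columns A, B
      (2 / 6) * 1 + (4 / 6) * 2^h(c(1, 3) / 4)  # rows h1, h2
  )
  expect_equal(linkage_density(worked), expected)
  expect_equal(linkage_density(worked), 1.474059, tolerance = 1e-6)
})

test_that("interaction evenness spans [0, 1] with both denominators", {
  uniform <- as_im(matrix(4L, 3, 3, dimnames = list(paste0("h", 1:3), paste0("s", 1:3))))
  expect_equal(interaction_evenness(uniform, "prod"), 1)
  expect_equal(interaction_evenness(uniform, "sum"), 1)
  single <- as_im(matrix(7L, 1, 1, dimnames = list("h", "s")))
  expect_equal(interaction_evenness(single), 0)
  expect_equal(interaction_evenness(worked, "prod"), 1.011404 / log(4), tolerance = 1e-6)
  expect_equal(interaction_evenness(worked, "prod") * log(4),
               -sum(c(2, 1, 3) / 6 * log(c(2, 1, 3) / 6)))
  expect_gt(interaction_evenness(worked, "sum"), interaction_evenness(worked, "prod"))
})

test_that("H2' hits its extremes and stays inside its entropy bounds", {
  diag2 <- as_im(matrix(c(5L, 0L, 0L, 5L), 2, dimnames = list(c("h1", "h2"), c("A", "B"))))
  expect_equal(h2prime(diag2), 1)
  ones <- as_im(matrix(1L, 3, 4, dimnames = list(paste0("h", 1:3), paste0("s", 1:4))))
  expect_equal(h2prime(ones), 0)
  outer_prop <- as_im(outer(c(1L, 2L), c(2L, 3L, 5L)) |>
    `dimnames<-`(list(c("h1", "h2"), c("A", "B", "C"))))
  expect_lt(h2prime(outer_prop), 0.05)

  set.seed(7)
  for (i in 1:300) {
    m <- as_im(random_count_matrix(4, 4))
    val <- h2prime(m)
    expect_gte(val, 0)
    expect_lte(val, 1)
  }
})

test_that("V-ratio matches its hand example and needs two hollows", {
  expect_equal(variance_ratio(worked), 0.4)
  same <- as_im(matrix(rep(c(1L, 2L), each = 2), 2, byrow = FALSE,
                       dimnames = list(c("h1", "h2"), c("A", "B"))))
  # two identical rows: Var of totals is 0
  ident <- as_im(matrix(c(1L, 1L, 2L, 2L), 2, dimnames = list(c("h1", "h2"), c("A", "B"))))
  expect_equal(variance_ratio(ident), 0)
  expect_error(variance_ratio(as_im(matrix(1L, 1, 2, dimnames = list("h", c("A", "B"))))),
               "2 hollows")
})

test_that("every summary metric is invariant to row/column permutation", {
  set.seed(11)
  m <- random_count_matrix(6, 9)
  perm <- m[sample(nrow(m)), sample(ncol(m))]
  for (f in list(nodf, linkage_density, interaction_evenness, h2prime,
                 variance_ratio, function(x) basic_metrics(x)$connectance)) {
    expect_equal(f(as_im(perm)), f(as_im(m)))
  }
})
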