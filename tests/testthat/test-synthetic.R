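test_that("generated networks satisfy the container invariants", {
  for (s in 1:5) {
    net <- generate_network(synthetic_spec(n_hollows = 10, n_species = 30, seed = s))
    m <- as.matrix(net)
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
    expect_true(all(rowSums(m) > 0))
    expect_true(all(colSums(m) > 0))
    expect_true(all(m[m > 0] >= 1))
  }
})

test_that("saturation and determinism of the generator", {
  full <- generate_network(synthetic_spec(n_hollows = 5, n_species = 8,
                                          target_connectance = 1, seed = 2))
  expect_equal(sum(full > 0), 40)
  a <- generate_network(synthetic_spec(seed = 99))
  b <- generate_network(synthetic_spec(seed = 99))
  expect_identical(as.matrix(a), as.matrix(b))
})

test_that("realized connectance tracks the target under random fill", {
  # binomial oracle: expected links = C * R * S, se from Bernoulli cells
  spec <- synthetic_spec(n_hollows = 16, n_species = 60, nestedness_shape = 0,
                         target_connectance = 0.2)
  reps <- 60
  set.seed(7)
  conn <- vapply(seq_len(reps), function(i) {
    spec$seed <- i
    m <- as.matrix(generate_network(spec))
    mean(m > 0)
  }, numeric(1))
  cells <- 16 * 60
  se <- sqrt(0.2 * 0.8 / cells / reps)
  expect_lt(abs(mean(conn) - 0.2), 3 * se + 0.01) # small allowance: empty-line resampling
})

test_that("the nestedness gradient raises NODF at fixed connectance", {
  set.seed(8)
  steep <- flat <- numeric(12)
  for (i in seq_along(steep)) {
    steep[i] <- nodf(generate_network(synthetic_spec(16, 60, nestedness_shape = 8,
                                                     target_connectance = 0.15,
                                                     seed = 1000 + i)))
    flat[i] <- nodf(generate_network(synthetic_spec(16, 60, nestedness_shape = 0,
                                                    target_connectance = 0.15,
                                                    seed = 2000 + i)))
  }
  expect_gt(mean(steep), mean(flat))
})

test_that("temporal pairs honor the identity, turnover, and labeling contracts", {
  base <- generate_network(synthetic_spec(12, 40, seed = 3), year = "t1")
  id <- generate_temporal_pair(base, temporal_spec(0, 0, 1, seed = 1))
  expect_identical(as.matrix(id$t1), as.matrix(id$t2))

  half <- generate_temporal_pair(base, temporal_spec(turnover = 0.5, rewiring = 0,
                                                     seed = 2))
  shared <- intersect(colnames(half$t1), colnames(half$t2))
  expect_equal(length(shared), 40 - ceiling(0.5 * 40), tolerance = 0.1)
  # hollow labels persist (a hollow vacated by turnover may drop out, but
  # none is ever relabeled)
  expect_true(all(rownames(half$t2) %in% rownames(half$t1)))
  expect_gte(length(intersect(rownames(half$t1), rownames(half$t2))), 10)

  rel <- generate_temporal_pair(base, temporal_spec(0.2, 0.2, seed = 4),
                                relabel_hollows = TRUE)
  expect_length(intersect(rownames(rel$t1), rownames(rel$t2)), 0)
})

test_that("rewiring preserves each retained species' degree", {
  base <- generate_network(synthetic_spec(12, 40, seed = 5))
  pr <- generate_temporal_pair(base, temporal_spec(turnover = 0, rewiring = 0.5,
                                                   seed = 6))
  expect_identical(colnames(pr$t1), colnames(pr$t2))
  expect_equal(colSums(as.matrix(pr$t2) > 0)[colnames(pr$t1)],
               colSums(as.matrix(pr$t1) > 0))
})

test_that("turnover recovery: measured species replacement tracks tau", {
  base <- generate_network(synthetic_spec(14, 50, seed = 10))
  taus <- seq(0.1, 0.9, by = 0.2)
  reps <- 10
  measured <- vapply(taus, function(tau) {
    mean(vapply(seq_len(reps), function(r) {
      pr <- generate_temporal_pair(base, temporal_spec(turnover = tau, rewiring = 0,
                                                       seed = 100 * tau + r))
      1 - length(intersect(colnames(pr$t1), colnames(pr$t2))) / ncol(base)
    }, numeric(1)))
  }, numeric(1))
  fit <- stats::lm(measured ~ taus)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("the study bundle has the design's shape and pools the park", {
  bundle <- generate_study_bundle(seed = 42)
  expect_equal(nrow(bundle), 8)
  expect_setequal(unique(bundle$site), c("park", "deciduous", "riparian", "sclerophyllous"))
  site_rows <- bundle[bundle$site != "park", ]
  expect_true(all(vapply(site_rows$network, nrow, integer(1)) == 16))

  for (yr in c("t1", "t2")) {
    park <- bundle$network[bundle$site == "park" & bundle$year == yr][[1]]
    sites <- site_rows$network[site_rows$year == yr]
    expect_equal(nrow(park), sum(vapply(sites, nrow, integer(1))))
    expect_setequal(colnames(park),
                    unique(unlist(lapply(sites, colnames))))
  }
  again <- generate_study_bundle(seed = 42)
  expect_identical(lapply(bundle$network, as.matrix),
                   lapply(again$network, as.matrix))
  other <- generate_study_bundle(seed = 43)
  expect_false(identical(as.matrix(bundle$network[[1]]), as.matrix(other$network[[1]])))
})
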