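star <- local({
  m <- rbind(
    h1 = c(1L, 1L, 1L, 1L, 1L),
    h2 = c(1L, 0L, 0L, 0L, 0L),
    h3 = c(0L, 1L, 0L, 0L, 0L),
    h4 = c(0L, 0L, 1L, 0L, 0L)
  )
  colnames(m) <- LETTERS[1:5]
  as_im(m)
})

test_that("Gc standardizes degrees with the population sd", {
  prof <- core_profile(star)
  expect_equal(prof$degree, c(5L, 1L, 1L, 1L))
  expect_equal(prof$gc, c(3, -1, -1, -1) / sqrt(3))
  expect_equal(prof$hollow[prof$qualitative_core], "h1")
  expect_equal(sum(prof$gc), 0)

  # relabeling hollows permutes but does not change Gc values
  mm <- as.matrix(star)
  rownames(mm) <- c("z4", "z3", "z2", "z1")
  prof2 <- core_profile(as_im(mm))
  expect_setequal(round(prof2$gc, 10), round(prof$gc, 10))
})

test_that("equal degrees give no qualitative core, with a warning", {
  flat <- as_im(matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("h1", "h2"), c("A", "B"))))
  expect_warning(prof <- core_profile(flat), "sigma_k")
  expect_true(all(prof$gc == 0))
  expect_false(any(prof$qualitative_core))
})

test_that("strength tiers are nested and capture the all-individuals case", {
  # h1 holds every individual of six species plus a share of a seventh:
  # strength just above 6, so it sits in the top tier (and hence also > 4)
  m <- rbind(h1 = c(rep(3L, 6), 1L), h2 = c(rep(0L, 6), 5L))
  colnames(m) <- paste0("s", 1:7)
  prof <- core_profile(as_im(m))
  h1 <- prof[prof$hollow == "h1", ]
  expect_equal(h1$strength, 6 + 1 / 6)
  expect_identical(h1$strength_tier, "gt5")
  expect_identical(prof$strength_tier[prof$hollow == "h2"], "none")
  # tiers nest: everything above 5 is above 4
  expect_true(all(prof$strength[prof$strength_tier == "gt5"] > 4))
})

test_that("core transform replaces rows by worst donors and only shrinks the web", {
  m <- rbind(
    h1 = c(2L, 3L, 1L, 4L, 1L, 2L),
    h2 = c(1L, 2L, 0L, 0L, 0L, 0L),
    h3 = c(0L, 0L, 2L, 1L, 0L, 0L),
    h4 = c(5L, 0L, 0L, 0L, 0L, 0L)
  )
  colnames(m) <- paste0("s", 1:6)
  im <- as_im(m)
  tr <- suppressMessages(transform_cores(im, "h1"))
  expect_equal(as.vector(as.matrix(tr)["h1", colnames(tr)]),
               as.vector(as.matrix(im)["h4", colnames(tr)]))
  expect_equal(attr(tr, "replacements")$donor, "h4")
  expect_true(all(c("s5", "s6") %in% attr(tr, "dropped_species")))
  expect_lte(ncol(tr), ncol(im))
  expect_lte(sum(tr), sum(im))
  # non-core rows untouched
  expect_equal(as.matrix(tr)["h2", colnames(tr)], as.matrix(im)["h2", colnames(tr)])

  expect_warning(ident <- transform_cores(im, character(0)), "identity")
  expect_equal(as.matrix(ident), as.matrix(im))
  expect_error(suppressWarnings(transform_cores(as_im(m[1:2, 1:2]), c("h1", "h2"))),
               "donor")
})

test_that("transform is idempotent when the donor pool is unchanged", {
  m <- rbind(
    h1 = c(1L, 1L, 1L, 1L, 1L, 1L),
    h2 = c(1L, 1L, 0L, 0L, 0L, 0L),
    h3 = c(1L, 0L, 0L, 0L, 0L, 0L),
    h4 = c(0L, 1L, 0L, 0L, 0L, 0L)
  )
  colnames(m) <- paste0("s", 1:6)
  im <- as_im(m)
  core <- core_profile(im)$hollow[core_profile(im)$qualitative_core]
  t1 <- suppressMessages(transform_cores(im, core))
  t2 <- suppressMessages(transform_cores(t1, core))
  expect_equal(as.matrix(t2), as.matrix(t1))
})

test_that("scenario suite degrades or preserves and reports full summaries", {
  set.seed(90)
  net <- generate_network(synthetic_spec(n_hollows = 10, n_species = 30,
                                         nestedness_shape = 6,
                                         target_connectance = 0.25, seed = 13))
  ss <- suppressMessages(scenario_suite(net, null_replicates = 50,
                                        robustness_reps = 30, seed = 5))
  expect_setequal(ss$summaries$scenario, c("A_qualitative", "B_quantitative"))
  expect_true(all(c("nodf", "h2prime", "RR", "RM", "RL") %in% names(ss$summaries)))
  expect_true(all(ss$summaries$n_species <= ncol(net)))
  expect_true(all(ss$summaries$n_individuals <= sum(net)))

  # no core by either criterion: both scenarios equal the original
  flat <- as_im(matrix(c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L), 3,
                       dimnames = list(paste0("h", 1:3), paste0("s", 1:3))))
  prof <- suppressWarnings(core_profile(flat))
  expect_false(any(prof$qualitative_core | prof$strength > 4))
  ss2 <- suppressWarnings(scenario_suite(flat, null_replicates = 20,
                                         robustness_reps = 10, seed = 2))
  expect_equal(as.matrix(ss2$A), as.matrix(flat))
  expect_equal(as.matrix(ss2$B), as.matrix(flat))
})
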