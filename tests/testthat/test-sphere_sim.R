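test_that("sphere sampling puts points exactly on the sphere, uniformly", {
  expect_equal(nrow(sample_sphere_points(0, 5000)), 0L)
  expect_error(sample_sphere_points(-1, 5000), "n must be")
  expect_error(sample_sphere_points(10, 0), "radius")

  set.seed(11)
  p <- sample_sphere_points(1000, 5000)
  expect_true(all(abs(sqrt(rowSums(p^2)) - 5000) < 1e-9 * 5000))

  # Monte-Carlo check against the uniform-sphere closed form: z/R is
  # uniform on [-1, 1), so mean(z) = 0 and P(z > 0) = 1/2
  set.seed(12)
  n <- 200000
  z <- sample_sphere_points(n, 5000)[, "z"]
  se_mean <- 5000 / sqrt(3) / sqrt(n)
  expect_lt(abs(mean(z)), 3 * se_mean)
  expect_lt(abs(mean(z > 0) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("negative binomial draws have the documented mean-variance law", {
  expect_error(sample_nb_count(5, -1), "mean")
  expect_identical(sample_nb_count(10, 0), integer(10))
  # p_NB = (1 + mean/n_nb)^-1 as printed; implied by the mu/size form
  expect_equal(1 / (1 + 1000 / 1.5), 1.4978e-3, tolerance = 1e-4)

  set.seed(13)
  x <- sample_nb_count(50000, 20, 1.5)
  v_target <- 20 + 20^2 / 1.5
  expect_lt(abs(mean(x) - 20), 3 * sqrt(v_target / 50000))
  expect_lt(abs(var(x) - v_target) / v_target, 0.05)
})

test_that("cell realization obeys the configured counts and couplings", {
  cfg <- sim_config(probe_a_means = 10, probe_b_means = 10,
                    variance_mode = "none", n_cells = 1)
  set.seed(1)
  cell <- realize_cell(cfg)
  expect_identical(cell$drawn_a, 10L)
  expect_identical(cell$drawn_b, 10L)
  expect_identical(sum(cell$drawn_c), 0L)

  # complexes add one coincident A and B point each
  cfg2 <- sim_config(probe_a_means = 4, complex_means = matrix(5, 1, 1),
                     variance_mode = "none", n_cells = 1)
  set.seed(2)
  cell2 <- realize_cell(cfg2)
  expect_identical(length(cell2$a$protein), 9L)   # 4 monomer + 5 complex
  cx_a <- cell2$a$xyz[cell2$a$pair > 0, ]
  cx_b <- cell2$b$xyz[cell2$b$pair > 0, ]
  expect_identical(cx_a, cx_b)

  # B(t) = (B/A) * A(t) coupling, exact up to integer rounding
  cfg3 <- sim_config(probe_a_means = 1000, probe_b_means = 500,
                     n_cells = 1)
  for (s in 1:30) {
    set.seed(s)
    cell3 <- realize_cell(cfg3)
    expect_lte(abs(cell3$drawn_b - 0.5 * cell3$drawn_a), 0.5)
  }

  expect_error(sim_config(probe_a_means = 0, probe_b_means = 5),
               "coupling is undefined")
  expect_error(sim_config(probe_a_means = 10, ligation_distance = 6000),
               "ligation_distance")
  expect_error(sim_config(probe_a_means = -1), ">= 0")
})

test_that("ligation matches coincident pairs and resolves competition", {
  p0 <- matrix(c(0, 0, 5000), 1, 3)
  cell <- make_cell(p0, 1L, p0, 1L, 1L)
  set.seed(1)
  lig <- ligate(cell, 50)
  expect_identical(lig$x[1, 1], 1L)
  expect_identical(lig$np_a[1], 0L)
  expect_identical(lig$np_b[1], 0L)

  # one probe A within d of two probes B: exactly one PLA product and one
  # leftover non-proximal probe B
  b2 <- rbind(c(10, 0, 4999.99), c(-10, 0, 4999.99))
  cell2 <- make_cell(p0, 1L, b2, c(1L, 1L), 1L)
  for (s in 1:20) {
    set.seed(s)
    lig2 <- ligate(cell2, 50)
    expect_identical(lig2$x[1, 1], 1L)
    expect_identical(lig2$np_b[1], 1L)
  }
})

test_that("probe counts are conserved and each probe ligates at most once", {
  cm <- matrix(c(15, 5, 0, 10), 2, 2)
  cfg <- sim_config(probe_a_means = c(400, 300), probe_b_means = c(350, 250),
                    complex_means = cm, n_cells = 6, seed = 21)
  sim <- simulate_population(cfg)
  for (t in seq_len(cfg$n_cells)) {
    set.seed(proxsim:::cell_seed(cfg$seed, t))
    cell <- realize_cell(cfg)
    lig <- ligate(cell, cfg$ligation_distance)
    # conservation: ligated + non-proximal = drawn, per protein and probe
    expect_identical(rowSums(lig$x) + lig$np_a,
                     unname(cell$drawn_a) + rowSums(cell$drawn_c))
    expect_identical(colSums(lig$x) + lig$np_b,
                     unname(cell$drawn_b) + colSums(cell$drawn_c))
    # single use
    expect_lte(sum(lig$x), min(length(cell$a$protein),
                               length(cell$b$protein)))
    # categories partition the counts
    expect_identical(lig$both_specific + lig$one_specific + lig$nonspecific,
                     lig$x)
  }
})

test_that("spatially indexed matching is identical to the brute-force oracle", {
  cm <- matrix(c(10, 0, 5, 0), 2, 2)
  cfg <- sim_config(probe_a_means = c(500, 300), complex_means = cm,
                    n_cells = 8, seed = 33)
  s_binned <- simulate_population(cfg)
  s_brute <- simulate_population(cfg, matching = "brute")
  expect_identical(s_binned$pla, s_brute$pla)
  expect_identical(s_binned$nonproximal, s_brute$nonproximal)
  expect_identical(s_binned$categories, s_brute$categories)

  # the adaptive x-subdivision path returns the same candidate set too
  set.seed(5)
  a <- sample_sphere_points(2000, 5000)
  b <- sample_sphere_points(2000, 5000)
  expect_identical(
    proxsim:::find_candidate_pairs(a, b, 200, "binned", dense_limit = 50),
    proxsim:::find_candidate_pairs(a, b, 200, "brute"))
})

test_that("populations are reproducible and extensible by cell substreams", {
  cfg <- sim_config(probe_a_means = c(300, 200), n_cells = 5, seed = 7)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1, s2)

  cfg10 <- cfg
  cfg10$n_cells <- 10L
  s10 <- simulate_population(cfg10)
  expect_identical(s10$pla[1:5, ], s1$pla)
})

test_that("nonspecific flags produce the three binding categories", {
  cfg <- sim_config(probe_a_means = c(300, 300, 300),
                    complex_means = diag(c(30, 30, 30)),
                    nonspecific_prob = c(0.2, 0.1, 0.05),
                    n_cells = 30, seed = 17)
  sim <- simulate_population(cfg)
  tot <- vapply(sim$categories, sum, 0)
  # both-specific >> one-specific >> nonspecific for specific targets
  expect_gt(tot["both_specific"], tot["one_specific"])
  expect_gt(tot["one_specific"], tot["nonspecific"])
  # p_ns = 0 gives only both-specific products
  cfg0 <- sim_config(probe_a_means = c(300, 300), n_cells = 5, seed = 2)
  sim0 <- simulate_population(cfg0)
  expect_identical(sim0$categories$both_specific, sim0$pla)
  expect_true(all(sim0$truth == 0))
})
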