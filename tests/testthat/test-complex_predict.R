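test_that("protein abundance sums PLA appearances, homodimers twice", {
  x <- rep_cells(c(10, 0, 0, 0), 2)
  expect_equal(unname(protein_abundance(x)[1, ]), c(20, 0))
  x2 <- rep_cells(c(0, 7, 0, 0), 2)
  expect_equal(unname(protein_abundance(x2)[1, ]), c(7, 7))
})

test_that("expected PLA counts preserve the observed margins", {
  x <- rep_cells(c(10, 0, 0, 10), 1)
  e <- expected_pla_count(x)
  expect_equal(e[1, "P1:P1"], 5)
  # a single nonzero entry is its own expectation
  x1 <- rep_cells(c(0, 9, 0, 0), 1)
  expect_equal(expected_pla_count(x1)[1, ], x1[1, ])

  # margin preservation on random panels (3 proteins)
  panel3 <- as.vector(t(outer(paste0("P", 1:3), paste0("P", 1:3),
                              paste, sep = ":")))
  set.seed(8)
  for (rep in 1:10) {
    m <- matrix(rpois(9, 20), 1, dimnames = list("c1", panel3))
    e <- expected_pla_count(m)
    em <- matrix(e, 3, 3, byrow = TRUE)
    xm <- matrix(m, 3, 3, byrow = TRUE)
    expect_equal(rowSums(em), rowSums(xm))
    expect_equal(colSums(em), colSums(xm))
  }

  # all-zero cells are flagged and get E = 0
  z <- rep_cells(c(0, 0, 0, 0), 1)
  ez <- expected_pla_count(z)
  expect_true(all(ez == 0))
  expect_identical(attr(ez, "zero_cells"), 1L)
})

test_that("iterative recurrence starts at X - E and converges idempotently", {
  x <- rep_cells(c(10, 0, 0, 10), 3)
  one <- iterative_predict(x, iterative_settings(max_iterations = 1))
  # first iteration from zero init: Y11 = 10 - 10*10/20 = 5
  expect_equal(unname(one$y[1, ]), c(5, 0, 0, 5))
  expect_identical(one$iterations, 1L)

  # diagonal X means every count is complex-derived: iteration climbs to X
  full <- iterative_predict(x)
  expect_true(full$converged)
  expect_equal(unname(full$y[1, c(1, 4)]), c(10, 10), tolerance = 0.01)
  expect_equal(unname(full$y[1, c(2, 3)]), c(0, 0))
  expect_identical(unname(which(full$detected)), c(1L, 4L))

  # idempotence at the fixed point: re-running from the converged state
  # moves by less than the tolerance in one step
  again <- iterative_predict(x, iterative_settings(max_iterations = 1,
                                                   init = full$y))
  expect_lt(max(abs(colMeans(again$y) - colMeans(full$y))), 0.01)
})

test_that("iterative symmetry rule fills the failing partner", {
  # P1:P2 is strongly positive and P2:P1 absent; a well-expressed P3:P3
  # keeps the margins from absorbing the heterodimer (rank-one degeneracy)
  set.seed(30)
  n <- 40
  panel3 <- as.vector(t(outer(paste0("P", 1:3), paste0("P", 1:3),
                              paste, sep = ":")))
  x <- matrix(0L, n, 9, dimnames = list(sprintf("cell%d", 1:n), panel3))
  x[, "P1:P1"] <- rpois(n, 0.3)
  x[, "P1:P2"] <- rpois(n, 60) + 20
  x[, "P2:P1"] <- rpois(n, 0.5)
  x[, "P3:P3"] <- rpois(n, 60)
  # a single update isolates the rule from the margin feedback that the
  # filled partner exerts on later iterations
  fit <- iterative_predict(x, iterative_settings(max_iterations = 1))
  expect_true(fit$detected["P1:P2"])
  expect_true(fit$detected["P2:P1"])
  expect_false(fit$detected["P1:P1"])
  expect_equal(fit$y[, "P2:P1"], fit$y[, "P1:P2"])  # sym_weight = 1
  half <- iterative_predict(x, iterative_settings(max_iterations = 1,
                                                  sym_weight = 0.5))
  expect_equal(half$y[, "P2:P1"], 0.5 * half$y[, "P1:P2"])
})

test_that("LR fits recover exact intercepts and reject pure noise", {
  set.seed(9)
  n <- 30
  ap <- rpois(n, 200) + 50
  bp <- rpois(n, 150) + 50
  np <- cbind("P1:free_oligo_B" = ap, "free_oligo_A:P1" = bp)
  rownames(np) <- sprintf("cell%d", 1:n)

  # constant response: beta0 = X, beta1 = 0, Y = X
  x_const <- matrix(9, n, 1, dimnames = list(rownames(np), "P1:P1"))
  fit <- lr_predict(x_const, np)
  expect_equal(fit$coefficients$beta0, 9)
  expect_equal(fit$coefficients$beta1, 0)
  expect_true(fit$detected["P1:P1"])
  expect_equal(unname(fit$y[, 1]), rep(9, n))

  # exact proportionality to the interaction term: beta0 = 0, undetected
  x_noise <- matrix(2e-5 * ap * bp, n, 1,
                    dimnames = list(rownames(np), "P1:P1"))
  fit2 <- lr_predict(x_noise, np)
  expect_equal(fit2$coefficients$beta0, 0, tolerance = 1e-10)
  expect_equal(fit2$coefficients$beta1, 2e-5, tolerance = 1e-10)
  expect_false(fit2$detected["P1:P1"])
  expect_true(all(fit2$y == 0))

  # all-zero interaction terms: product skipped and flagged
  np0 <- np; np0[, 1] <- 0
  fit3 <- lr_predict(x_const, np0)
  expect_false(fit3$detected["P1:P1"])
  expect_match(fit3$coefficients$flag, "skipped")
})

test_that("LR slope is invariant to the automatic interaction rescaling", {
  set.seed(10)
  n <- 50
  ap <- round(runif(n, 5000, 20000))
  bp <- round(runif(n, 5000, 20000))
  np <- cbind("P1:free_oligo_B" = ap, "free_oligo_A:P1" = bp)
  rownames(np) <- sprintf("cell%d", 1:n)
  x <- matrix(rpois(n, 2.5e-5 * ap * bp / 200), n, 1,
              dimnames = list(rownames(np), "P1:P1"))
  # median interaction (~1e8) >> 1e3 * median response: rescaling triggers
  f1 <- lr_predict(x, np, lr_settings(interaction_scale = 1e6))
  f2 <- lr_predict(x, np, lr_settings(interaction_scale = 1))
  expect_equal(f1$coefficients$beta1, f2$coefficients$beta1,
               tolerance = 1e-8)
  expect_equal(f1$y, f2$y, tolerance = 1e-8)
})

test_that("ensemble reduces to the default iterative run on a zero LR init", {
  set.seed(14)
  n <- 25
  ap <- rpois(n, 300); bp <- rpois(n, 300)
  np <- cbind("P1:free_oligo_B" = ap, "free_oligo_A:P1" = bp)
  rownames(np) <- sprintf("cell%d", 1:n)
  x <- matrix(rpois(n, 2.5e-5 * ap * bp), n, 1,
              dimnames = list(rownames(np), "P1:P1"))
  lr <- lr_predict(x, np)
  expect_true(all(lr$y == 0))          # pure noise: LR output is zero
  en <- ensemble_predict(x, np)
  it <- iterative_predict(x)
  expect_equal(en$y, it$y)
  expect_identical(en$detected, it$detected)
  expect_identical(en$method, "ensemble")
})

test_that("Fisher per-cell p-values equal the hypergeometric tail oracle", {
  x <- rep_cells(c(20, 5, 5, 20), 1)
  fit <- fisher_detect(x)
  p_raw <- c(fisher_tail_oracle(20, 5, 5, 20),
             fisher_tail_oracle(5, 20, 20, 5),
             fisher_tail_oracle(5, 20, 20, 5),
             fisher_tail_oracle(20, 5, 5, 20))
  expect_equal(unname(fit$p_adj[1, ]), p.adjust(p_raw, "BH"))

  # zero observed count is never called
  x0 <- rep_cells(c(0, 8, 3, 9), 2)
  f0 <- fisher_detect(x0)
  expect_equal(unname(f0$p_adj[, "P1:P1"]), c(1, 1))

  # 100 random tables against the brute-force tail sum and fisher.test
  set.seed(15)
  for (i in 1:100) {
    tb <- matrix(rpois(4, 15) + 1, 2)
    x <- matrix(c(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]), 1,
                dimnames = list("c1", panel2))
    praw <- phyper(tb[1, 1] - 1, sum(tb[1, ]), sum(tb[2, ]), sum(tb[, 1]),
                   lower.tail = FALSE)
    expect_equal(praw, fisher_tail_oracle(tb[1, 1], tb[1, 2], tb[2, 1],
                                          tb[2, 2]), tolerance = 1e-12)
    if (i <= 5)
      expect_equal(praw,
                   stats::fisher.test(tb, alternative = "greater")$p.value,
                   tolerance = 1e-9)
  }
})

test_that("BH adjustment agrees exactly with the step-up oracle", {
  set.seed(16)
  for (len in c(1, 3, 7, 12, 20)) {
    p <- runif(len)
    # exact up to floating-point association order
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("no complexes are called on a null simulation", {
  cfg <- sim_config(probe_a_means = c(600, 400, 200), n_cells = 60,
                    seed = 19)
  sim <- simulate_population(cfg)
  expect_equal(sum(iterative_predict(sim$pla)$detected), 0L)
  expect_equal(sum(lr_predict(sim$pla, sim$nonproximal)$detected), 0L)
  expect_equal(sum(ensemble_predict(sim$pla, sim$nonproximal)$detected), 0L)
  fi <- fisher_detect(sim$pla)
  expect_equal(sum(fi$detected), 0L)
  # per-cell false-call rate stays near the nominal level
  expect_lt(mean(rowSums(fi$calls) > 0), 0.1)
})
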