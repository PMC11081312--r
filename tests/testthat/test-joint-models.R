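test_that("the barking-dog tree reproduces every caption anchor", {
  ct <- carol_tree()
  expect_equal(sum(ct$counts), 100)
  expect_equal(joint_prob(ct, list(A = "1", B = "1", C = "1")), 3 / 100)
  expect_equal(conditional(ct, "C", list(A = "0"))[["0"]], 40 / 50)
  expect_equal(conditional(ct, "C")[["1"]], 0.4)            # prior
  expect_equal(conditional(ct, "B")[["1"]], 0.4)
  expect_equal(joint_prob(ct, list(A = "1", B = "1")), 0.15)
  # barking depends only on Carol's presence, not on the time
  expect_equal(conditional(ct, "B", list(A = "1", C = "1"))[["1"]], 0.1)
  expect_equal(conditional(ct, "B", list(A = "0", C = "1"))[["1"]], 0.1)
  expect_equal(conditional(ct, "B", list(C = "1"))[["1"]], 0.1)
  # ... but A and B are unconditionally dependent
  expect_false(isTRUE(all.equal(joint_prob(ct, list(A = "1", B = "1")),
                                0.4 * 0.5)))
})

test_that("conditional() normalizes and reassembles the marginal", {
  ct <- carol_tree()
  marg_b <- conditional(ct, "B")
  p_c <- conditional(ct, "C")
  rebuilt <- p_c[["1"]] * as.numeric(conditional(ct, "B", list(C = "1"))) +
    p_c[["0"]] * as.numeric(conditional(ct, "B", list(C = "0")))
  expect_equal(rebuilt, as.numeric(marg_b), tolerance = 1e-14)
  expect_equal(sum(conditional(ct, "A", list(B = "1", C = "0"))), 1)
  expect_error(conditional(ct, "C", list(C = "1")), "distinct")
  expect_error(conditional(ct, "Z"), "not in table")
})

test_that("zero conditioning mass is an error, not an imputation", {
  counts <- array(c(5L, 0L, 0L, 0L, 3L, 2L, 0L, 1L), dim = c(2, 2, 2),
                  dimnames = list(A = c("0", "1"), B = c("0", "1"),
                                  C = c("0", "1")))
  tab <- joint_count_table(counts)
  expect_error(conditional(tab, "C", list(A = "0", B = "1")),
               "zero conditioning mass")
})

test_that("count-table construction rejects malformed input", {
  expect_error(joint_count_table(1:4), "array")
  arr <- array(1:8, dim = c(2, 2, 2))
  expect_error(joint_count_table(arr), "dimnames")
  dimnames(arr) <- list(A = c("0", "1"), B = c("0", "1"), C = c("0", "1"))
  arr2 <- arr; arr2[1] <- -1
  expect_error(joint_count_table(arr2), "nonnegative")
  arr3 <- arr; arr3[1] <- 0.5
  expect_error(joint_count_table(arr3), "nonnegative integers")
})

test_that("CI check: exact on the tree, passes on constructed products", {
  ct <- carol_tree()
  rep_ <- check_conditional_independence(ct, "A", "B", "C")
  expect_lt(rep_$max_abs_deviation, 1e-12)
  expect_true(rep_$passes)
  expect_equal(as.numeric(rep_$g_values), rep(1, 4), tolerance = 1e-12)

  # any product-constructed table passes at 1e-12
  set.seed(11)
  p_c <- c(0.3, 0.7)
  p_a_c <- cbind(rand_simplex(3), rand_simplex(3))
  p_b_c <- cbind(rand_simplex(2), rand_simplex(2))
  joint <- array(0, dim = c(3, 2, 2),
                 dimnames = list(A = paste0("a", 1:3), B = c("b1", "b2"),
                                 C = c("c1", "c2")))
  for (i in 1:3) for (j in 1:2) for (k in 1:2) {
    joint[i, j, k] <- round(1e7 * p_c[k] * p_a_c[i, k] * p_b_c[j, k])
  }
  tab <- joint_count_table(joint)
  rep2 <- check_conditional_independence(tab, "A", "B", "C", tol = 1e-6)
  expect_lt(rep2$max_abs_deviation, 1e-6)
})

test_that("CI check flags correlated tables and perturbed cells", {
  # correlated repeats generate a conditionally dependent (T1, T2 | D)
  set.seed(22)
  n <- 20000
  d <- rbinom(n, 1, 0.5)
  p <- ifelse(d == 1, 0.7, 0.2)
  # per-subject correlated test pair with disease-dependent marginal
  eta <- runif(n); u1 <- runif(n); u2 <- runif(n)
  r1 <- ifelse(runif(n) < 0.5, eta, u1); r2 <- ifelse(runif(n) < 0.5, eta, u2)
  t1 <- as.integer(r1 < p); t2 <- as.integer(r2 < p)
  counts <- table(T1 = t1, T2 = t2, D = d)
  tab <- joint_count_table(array(as.integer(counts), dim = dim(counts),
                                 dimnames = dimnames(counts)))
  rep_ <- check_conditional_independence(tab, "T1", "T2", "D", tol = 1e-9)
  expect_false(rep_$passes)
  expect_gt(rep_$max_abs_deviation, 0.01)

  # single perturbed count breaks g = 1
  ct <- carol_tree()
  pert <- ct$counts; pert["1", "1", "1"] <- pert["1", "1", "1"] + 5L
  g <- g_factor(joint_count_table(pert), "A", "B", "C")
  expect_gt(max(abs(g - 1)), 1e-3)
  expect_error(
    check_conditional_independence(ct, "A", "B", "Z"), "not in table"
  )
})

test_that("identifiability condition compares state counts", {
  expect_true(identifiability_condition(2, 2, 2))
  expect_false(identifiability_condition(4, 4, 2))
  expect_true(identifiability_condition(5, 2, 2))
  expect_error(identifiability_condition(1, 2, 2))
})

test_that("predicted-vs-measured sits on the diagonal exactly for CI tables", {
  ct <- carol_tree()
  pm <- predicted_vs_measured(ct, "A", "B", "C")
  expect_equal(pm$measured, pm$predicted, tolerance = 1e-12)
  # the (A=1, B=0) cell is the hand-computed 27/35
  cell <- pm[pm$a == "1" & pm$b == "0" & pm$c_state == "1", ]
  expect_equal(cell$measured, 27 / 35, tolerance = 1e-12)
  expect_equal(cell$predicted, 27 / 35, tolerance = 1e-12)

  # random CI-constructed tables: diagonal to 1e-10
  set.seed(33)
  for (i in 1:20) {
    n_e <- sample(2:4, 2, replace = TRUE)
    n_c <- sample(2:4, 1)
    joint <- rand_ci_joint(n_e, n_c)
    counts <- round(joint * 1e9)
    dimnames(counts) <- list(A = paste0("a", seq_len(n_e[1])),
                             B = paste0("b", seq_len(n_e[2])),
                             C = paste0("c", seq_len(n_c)))
    pm <- predicted_vs_measured(joint_count_table(counts), "A", "B", "C")
    expect_lt(max(abs(pm$measured - pm$predicted)), 1e-7)
  }
})

test_that("long-CSV round trip preserves tables and prob vectors", {
  ct <- carol_tree()
  f <- withr::local_tempfile(fileext = ".csv")
  write_joint_table(ct, f, meta = c(source = "unit-test"))
  back <- read_joint_table(f)
  expect_equal(back$counts, ct$counts)

  pv <- prob_vector(c("1" = 0.4, "0" = 0.6))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_prob_vector(pv, f2, meta = c(seed = "1"))
  expect_equal(as.numeric(read_prob_vector(f2)[names(pv)]),
               as.numeric(pv))
})
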