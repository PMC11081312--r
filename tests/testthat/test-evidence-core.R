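test_that("probability vectors validate, renormalize and match by label", {
  pv <- prob_vector(c(a = 0.25, b = 0.75))
  expect_s3_class(pv, "prob_vector")
  expect_equal(sum(pv), 1)

  expect_error(prob_vector(c(0.5, 0.5)), "named")
  expect_error(prob_vector(c(a = 0.5, a = 0.5)), "unique")
  expect_error(prob_vector(c(a = 1)), "2 states")
  expect_error(prob_vector(c(a = 0.6, b = 0.6)), "sum to 1")
  expect_error(prob_vector(c(a = 1.2, b = -0.2)), "0, 1")

  # combination is label-driven: permuting entries changes nothing
  prior <- prob_vector(c("1" = 0.4, "0" = 0.6))
  pa <- prob_vector(c("1" = 0.6, "0" = 0.4))
  pa_rev <- prob_vector(c("0" = 0.4, "1" = 0.6))
  r1 <- combine_two(pa, pa, prior)$posterior
  r2 <- combine_two(pa_rev, pa, prior)$posterior
  expect_equal(r1[["1"]], r2[["1"]])
  expect_error(
    combine_two(pa, prob_vector(c(x = 0.6, y = 0.4)), prior),
    "state-set mismatch"
  )
})

test_that("the frequency-tree worked example combines to 27/35", {
  prior <- prob_vector(c("1" = 0.4, "0" = 0.6))
  post <- prob_vector(c("1" = 0.6, "0" = 0.4))
  res <- combine_two(post, post, prior)
  expect_equal(res$posterior[["1"]], 27 / 35, tolerance = 1e-12)
  # normalization of f_values is what defines the posterior
  expect_equal(as.numeric(res$posterior),
               as.numeric(res$f_values / sum(res$f_values)))
  # odds form agrees: 27/8
  expect_equal(posterior_odds(post, post, prior, "1", "0"), 27 / 8)
  # linear approximation: prior + 0.2 + 0.2
  expect_equal(linear_approx(0.6, 0.6, 0.4), 0.8)
})

test_that("an uninformative source cancels out", {
  prior <- prob_vector(c(a = 0.3, b = 0.5, c = 0.2))
  post <- prob_vector(c(a = 0.6, b = 0.1, c = 0.3))
  res <- combine_two(post, prior, prior)
  expect_equal(as.numeric(res$posterior), as.numeric(post),
               tolerance = 1e-14)
  expect_equal(posterior_odds(post, prior, prior, "a", "b"),
               post[["a"]] / post[["b"]])
  # uniform prior, two identical binary posts: odds square
  upr <- prob_vector(c("1" = 0.5, "0" = 0.5))
  p6 <- prob_vector(c("1" = 0.6, "0" = 0.4))
  expect_equal(posterior_odds(p6, p6, upr, "1", "0"), 1.5^2)
})

test_that("combination is symmetric and combine_many reduces correctly", {
  set.seed(101)
  for (i in 1:20) {
    prior <- pv_named(rand_simplex(3))
    pa <- pv_named(rand_simplex(3))
    pb <- pv_named(rand_simplex(3))
    ab <- combine_two(pa, pb, prior)$posterior
    ba <- combine_two(pb, pa, prior)$posterior
    expect_identical(as.numeric(ab), as.numeric(ba))
    many <- combine_many(list(pa, pb), prior)$posterior
    expect_equal(as.numeric(ab), as.numeric(many), tolerance = 1e-15)
  }
  # N = 1: no combination happens
  prior <- pv_named(rand_simplex(4))
  pa <- pv_named(rand_simplex(4))
  expect_equal(as.numeric(combine_many(list(pa), prior)$posterior),
               as.numeric(pa), tolerance = 1e-15)
  expect_error(combine_many(list(), prior), "non-empty")
})

test_that("binary N-source formula matches the general multi-state one", {
  # the binary special case written out longhand, vs combine_many
  set.seed(202)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    posts <- replicate(n, runif(1, 0.05, 0.95))
    prior <- runif(1, 0.05, 0.95)
    longhand <- prod(posts) /
      (prod(posts) + prod(1 - posts) * (prior / (1 - prior))^(n - 1))
    pvs <- lapply(posts, function(p) prob_vector(c("1" = p, "0" = 1 - p)))
    res <- combine_many(pvs, prob_vector(c("1" = prior, "0" = 1 - prior)))
    expect_equal(res$posterior[["1"]], longhand, tolerance = 1e-12)
  }
})

test_that("combination matches brute-force conditionals on CI joints", {
  # two evidence variables, random dimensions <= 5
  set.seed(303)
  for (i in 1:200) {
    n_e <- sample(2:5, 2, replace = TRUE)
    n_c <- sample(2:5, 1)
    joint <- rand_ci_joint(n_e, n_c)
    prior <- pv_named(prior_c(joint))
    e_idx <- vapply(n_e, function(m) sample.int(m, 1), 0L)
    posts <- lapply(1:2, function(q) {
      pv_named(marginal_posterior_c(joint, q, e_idx[q]))
    })
    direct <- direct_conditional_c(joint, e_idx)
    got <- combine_two(posts[[1]], posts[[2]], prior)$posterior
    expect_equal(as.numeric(got), direct, tolerance = 1e-10)
  }
  # three evidence variables through combine_many
  for (i in 1:50) {
    n_e <- sample(2:4, 3, replace = TRUE)
    n_c <- sample(2:4, 1)
    joint <- rand_ci_joint(n_e, n_c)
    prior <- pv_named(prior_c(joint))
    e_idx <- vapply(n_e, function(m) sample.int(m, 1), 0L)
    posts <- lapply(1:3, function(q) {
      pv_named(marginal_posterior_c(joint, q, e_idx[q]))
    })
    direct <- direct_conditional_c(joint, e_idx)
    got <- combine_many(posts, prior)$posterior
    expect_equal(as.numeric(got), direct, tolerance = 1e-10)
  }
})

test_that("a vanishing prior drives the combined posterior to 0, not 1", {
  # family of consistent CI tables indexed by a shrinking prior: the
  # conditionals shrink with it, so the combined value stays bounded
  for (pr1 in 10^seq(-2, -12, by = -2)) {
    # P(E=1|C=1)=0.9, P(E=1|C=0)=0.1 for both sources
    pa1 <- 0.9 * pr1 / (0.9 * pr1 + 0.1 * (1 - pr1))
    prior <- prob_vector(c("1" = pr1, "0" = 1 - pr1))
    pa <- prob_vector(c("1" = pa1, "0" = 1 - pa1))
    comb <- combine_two(pa, pa, prior)$posterior[["1"]]
    expect_gte(comb, 0); expect_lte(comb, 1)
    # exact value from the joint: odds multiply
    exact <- 1 / (1 + (0.1 / 0.9)^2 * (1 - pr1) / pr1)
    expect_equal(comb, exact, tolerance = 1e-9)
  }
  # and in the limit it vanishes
  pr1 <- 1e-12
  pa1 <- 0.9 * pr1 / (0.9 * pr1 + 0.1 * (1 - pr1))
  comb <- combine_two(prob_vector(c("1" = pa1, "0" = 1 - pa1)),
                      prob_vector(c("1" = pa1, "0" = 1 - pa1)),
                      prob_vector(c("1" = pr1, "0" = 1 - pr1)))
  expect_lt(comb$posterior[["1"]], 1e-9)
})

test_that("linear approximation error is second order in the deviations", {
  for (prior1 in c(0.2, 0.4, 0.6, 0.8)) {
    for (eps_a in c(-0.05, -0.01, 0.01, 0.05)) {
      for (eps_b in c(-0.05, 0.02, 0.05)) {
        exact <- combine_two(
          prob_vector(c("1" = prior1 + eps_a, "0" = 1 - prior1 - eps_a)),
          prob_vector(c("1" = prior1 + eps_b, "0" = 1 - prior1 - eps_b)),
          prob_vector(c("1" = prior1, "0" = 1 - prior1))
        )$posterior[["1"]]
        approx <- linear_approx(prior1 + eps_a, prior1 + eps_b, prior1)
        # K = 10 comfortably bounds the curvature on this prior range
        expect_lt(abs(exact - approx), 10 * (abs(eps_a) + abs(eps_b))^2)
      }
    }
  }
  # opposite deviations cancel exactly in the approximation
  expect_equal(linear_approx(0.41, 0.39, 0.4), 0.4)
})

test_that("degenerate and inconsistent evidence raise labeled errors", {
  prior0 <- prob_vector(c(a = 0, b = 1))
  ev <- prob_vector(c(a = 0.5, b = 0.5))
  expect_error(combine_two(ev, ev, prior0), "zero-prior")
  # jointly contradictory: each source certain of a different state
  pa <- prob_vector(c(a = 1, b = 0))
  pb <- prob_vector(c(a = 0, b = 1))
  pr <- prob_vector(c(a = 0.5, b = 0.5))
  expect_error(combine_two(pa, pb, pr), "degenerate evidence")
  expect_error(
    posterior_odds(pa, pa, pr, "a", "b"),
    "zero probability"
  )
})

test_that("exclusive-condition combination handles cue-integration cases", {
  expect_equal(combine_exclusive(0.75, 0.75, 0.5), 0.9)
  # uninformative visual cue: auditory performance unchanged
  expect_equal(combine_exclusive(0.8, 0.5, 0.5), 0.8)
  # certain visual cue absorbs
  expect_equal(combine_exclusive(0.6, 1, 0.5), 1)
  # never below the better cue when both are at or above chance
  set.seed(404)
  for (i in 1:100) {
    ch <- runif(1, 0.1, 0.9)
    pa <- runif(1, ch, 1)
    pv <- runif(1, ch, 1)
    got <- combine_exclusive(pa, pv, ch)
    expect_gte(got, max(pa, pv) - 1e-12)
    expect_lte(got, 1)
  }
  expect_error(combine_exclusive(0.7, 0.7, 0), "p_chance")
  expect_error(combine_exclusive(0.7, 0.7, 1), "p_chance")
})

test_that("exclusive form is the two-source rule on the no-cue tables", {
  # build the equivalent probability tables with chance as the prior and
  # run combine_two on them: the algebra must agree
  set.seed(505)
  for (i in 1:50) {
    ch <- runif(1, 0.2, 0.8)
    pa <- runif(1, 0.05, 0.95)
    pv <- runif(1, 0.05, 0.95)
    direct <- combine_exclusive(pa, pv, ch)
    via_two <- combine_two(
      prob_vector(c("1" = pa, "0" = 1 - pa)),
      prob_vector(c("1" = pv, "0" = 1 - pv)),
      prob_vector(c("1" = ch, "0" = 1 - ch))
    )$posterior[["1"]]
    expect_equal(direct, via_two, tolerance = 1e-12)
  }
})
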