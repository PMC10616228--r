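K_true <- c("s1", "s3", "s4", "s7", "s8")

test_that("half-split scores and selection reproduce the worked example", {
  ks <- ktol_structure()
  L0 <- uniform_likelihood(ks)
  score <- function(q) abs(2 * mass_containing(L0, q) - 1)
  expect_equal(score("s4"), 1 / 11, tolerance = 1e-12)      # .091
  expect_equal(score("s1"), 3 / 11, tolerance = 1e-12)      # .273
  expect_equal(score("s3"), 3 / 11, tolerance = 1e-12)
  expect_equal(score("s7"), 3 / 11, tolerance = 1e-12)
  expect_equal(score("s8"), 9 / 11, tolerance = 1e-12)      # .818
  expect_identical(half_split_select(L0, ks$domain, seed = 1), "s4")
  # concentrated likelihood: every problem ties, any may be returned
  Lc <- uniform_likelihood(ks, weights = c(rep(0, 10), 1))
  expect_true(half_split_select(Lc, ks$domain, seed = 2) %in% ks$domain)
  expect_error(half_split_select(L0, character(0)), "no problems")
})

test_that("likelihood mass on containing states matches direct summation", {
  ks <- ktol_structure()
  withr::with_seed(8, {
    for (rep in 1:10) {
      w <- stats::runif(ks$n_states)
      L <- uniform_likelihood(ks, weights = w)
      q <- sample(ks$domain, 1)
      direct <- sum((w / sum(w))[states_containing(ks, q)])
      expect_equal(mass_containing(L, q), direct, tolerance = 1e-14)
    }
  })
})

test_that("one Bayesian update reproduces the worked posterior", {
  ks <- ktol_structure()
  L1 <- cmp_update(uniform_likelihood(ks), "s4", 1, 0.02, 4e-5)
  inq <- states_containing(ks, "s4")
  expect_equal(unique(round(L1$weights[inq], 2)), 0.17)
  expect_equal(L1$weights[inq][1], 0.98 / 5.8802, tolerance = 1e-9)
  # non-containing states drop to 4e-5 / 5.8802
  expect_equal(L1$weights[setdiff(1:11, inq)][1], 4e-5 / 5.8802, tolerance = 1e-9)
  expect_equal(sum(L1$weights), 1, tolerance = 1e-12)
})

test_that("an uninformative item leaves the prior unchanged", {
  ks <- ktol_structure()
  L <- uniform_likelihood(ks, weights = stats::runif(11))
  L2 <- cmp_update(L, "s4", 1, 0.5, 0.5)  # P(r|K) equal across states
  expect_equal(L2$weights, L$weights, tolerance = 1e-12)
  L3 <- multiplicative_update(L, "s4", 1, 1, 1)
  expect_equal(L3$weights, L$weights, tolerance = 1e-12)
})

test_that("Bayesian and multiplicative rules agree under the conversion", {
  ks <- ktol_structure()
  withr::with_seed(21, {
    for (rep in 1:50) {
      w <- stats::runif(ks$n_states)
      q <- sample(ks$domain, 1)
      b <- stats::runif(1, 0.001, 0.3)
      e <- stats::runif(1, 0.001, 0.3)
      r <- sample(0:1, 1)
      L <- uniform_likelihood(ks, weights = w)
      bayes <- cmp_update(L, q, r, b, e)
      mult <- multiplicative_update(L, q, r, (1 - b) / e, (1 - e) / b)
      expect_equal(bayes$weights, mult$weights, tolerance = 1e-12)
    }
  })
  # the worked example's zeta: beta .02, eta 4e-5 -> 24,500
  expect_equal((1 - 0.02) / 4e-5, 24500)
})

test_that("move-by-move updates reproduce the worked MSP example", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  pars <- table4_params()
  L <- uniform_likelihood(ks)
  proc1 <- c("s4", "s6", "s8", "s9")
  for (k in 1:3) L <- msp_update(L, "s4", proc1[k], proc1[k + 1], pars, "msp3", gs)
  both <- intersect(states_containing(ks, "s4"), states_containing(ks, "s8"))
  expect_equal(unique(round(L$weights[both], 2)), 0.17)
  proc2 <- c("s1", "s3", "s5", "s7", "s8", "s9")
  for (k in 1:5) L <- msp_update(L, "s1", proc2[k], proc2[k + 1], pars, "msp3", gs)
  sets <- state_sets(ks)
  at <- function(s) which(vapply(sets, function(x) setequal(x, s), TRUE))
  expect_equal(round(L$weights[at(c("s1", "s4", "s7", "s8"))], 2), 0.07)
  expect_equal(round(L$weights[at(c("s1", "s4", "s8"))], 2), 0.01)
  expect_gte(L$weights[at(K_true)], 0.9)
  expect_equal(which.max(L$weights), at(K_true))
  expect_equal(sum(L$weights), 1, tolerance = 1e-12)
})

test_that("a move with equal beta and eta leaves the prior unchanged", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  pars <- transition_params(data.frame(i = "s8", j = "s9", beta = 0.4, eta = 0.4))
  L <- uniform_likelihood(ks, weights = stats::runif(11))
  L2 <- msp_update(L, "s8", "s8", "s9", pars, "msp3", gs)
  expect_equal(L2$weights, L$weights, tolerance = 1e-12)
})

test_that("Eq-9 updating equals its multiplicative form under the rate condition", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  withr::with_seed(77, {
    for (rep in 1:100) {
      pars <- random_theorem_params(gs, seed = sample.int(1e6, 1))
      ep <- elementary_pairs(gs)
      k <- sample.int(nrow(ep), 1)
      s0 <- sample(gs$domain$initial, 1)
      a <- sample(c("msp1", "msp2", "msp3"), 1)
      L <- uniform_likelihood(ks, weights = stats::runif(11))
      bayes <- msp_update(L, s0, ep$i[k], ep$j[k], pars, a, gs)
      mult <- msp_multiplicative_update(L, s0, ep$i[k], ep$j[k], pars, a, gs)
      expect_equal(bayes$weights, mult$weights, tolerance = 1e-12)
    }
  })
})

test_that("the CMP example runs end to end: sequence (s4, s1, s3), state recovered", {
  ks <- ktol_structure()
  rec <- run_assessment(ks, list(s1 = 1L, s3 = 1L, s4 = 1L, s7 = 1L, s8 = 1L),
                        engine = "cmp", item_params = example1_item_params(),
                        seed = 1)
  expect_identical(rec$administered$problem, c("s4", "s1", "s3"))
  expect_setequal(estimated_state(rec), K_true)
  expect_true(rec$terminated)
  expect_equal(rec$n_questions, 3)
  # the intermediate likelihood after two correct answers is about one third
  expect_equal(round(rec$administered$max_likelihood[2], 2), 0.33)
})

test_that("the MSP example terminates after two problems with the true modal state", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  procs <- list(s4 = c("s4", "s6", "s8", "s9"),
                s1 = c("s1", "s3", "s5", "s7", "s8", "s9"))
  rec <- run_assessment(ks, function(q) procs[[q]], engine = "msp3", gs = gs,
                        params = table4_params(), threshold = 0.5, seed = 1)
  expect_identical(rec$administered$problem, c("s4", "s1"))
  expect_equal(rec$n_questions, 2)
  expect_setequal(estimated_state(rec), K_true)
  expect_gte(max(rec$likelihood$weights), 0.9)
})

test_that("threshold 1 with noiseless responses exhausts the domain", {
  ks <- ktol_structure()
  rec <- run_assessment(ks, list(s1 = 1L, s3 = 1L, s4 = 1L, s7 = 1L, s8 = 1L),
                        engine = "cmp", item_params = example1_item_params(),
                        threshold = 1, seed = 1)
  expect_equal(rec$n_questions, 5)
  expect_false(rec$terminated)
  expect_setequal(estimated_state(rec), K_true)
})

test_that("noiseless process data uncovers the latent state at a strict threshold", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  pars <- noiseless_params(gs)
  for (idx in c(1, 5, 11)) {
    K0 <- state_sets(ks)[[idx]]
    responses <- lapply(stats::setNames(ks$domain, ks$domain), function(q) {
      sp <- simulate_process(gs, pars, q, K0, "msp3", seed = 1)
      sp$visited
    })
    rec <- run_assessment(ks, responses, engine = "msp3", gs = gs, params = pars,
                          threshold = 0.9, seed = 2)
    expect_setequal(estimated_state(rec), K0)
  }
})

test_that("CMP results agree between scripted binaries and dichotomized processes", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  pars <- generate_params(gs, 0.01, seed = 14)
  cohort <- simulate_cohort(gs, pars, list(K_true, c("s4", "s8")), "msp3", seed = 5)
  ip <- example1_item_params()
  for (w in 1:2) {
    rows <- cohort[cohort$subject == w, ]
    from_binary <- run_assessment(ks, stats::setNames(as.list(rows$correct), rows$problem),
                                  engine = "cmp", item_params = ip, seed = 3)
    redich <- lapply(stats::setNames(rows$visited, rows$problem),
                     function(v) dichotomize(v, gs))
    from_proc <- run_assessment(ks, redich, engine = "cmp", item_params = ip, seed = 3)
    expect_identical(from_binary$administered, from_proc$administered)
  }
})

test_that("likelihood mass on path-consistent states never decreases on correct processes", {
  ks <- ktol_structure()
  gs <- fig2_goal_space()
  pars <- random_theorem_params(gs, seed = 31)
  L <- uniform_likelihood(ks)
  proc <- c("s1", "s3", "s5", "s7", "s8", "s9")
  # states containing s1 and all its observed sub-solved problems s3, s7, s8
  consistent <- Reduce(intersect, lapply(c("s1", "s3", "s7", "s8"),
                                         function(q) states_containing(ks, q)))
  before <- sum(L$weights[consistent])
  for (k in 1:5) {
    L <- msp_update(L, "s1", proc[k], proc[k + 1], pars, "msp3", gs)
    now <- sum(L$weights[consistent])
    expect_gte(now, before - 1e-12)
    before <- now
  }
})
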