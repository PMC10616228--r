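K_full <- c("s1", "s3", "s4", "s7", "s8")

test_that("transition probabilities dispatch per the planning assumptions", {
  gs <- fig2_goal_space()
  pars <- table4_params()
  # s0 = s1 (in K), i = s4 (in K): beta under all three
  K <- c("s1", "s4", "s8")
  for (a in c("msp1", "msp2", "msp3")) {
    expect_equal(transition_prob(pars, "s4", "s6", "s1", K, a, gs), 0.99)
  }
  # s0 in K, i = s3 not in K: beta / eta / eta
  expect_equal(transition_prob(pars, "s3", "s5", "s1", K, "msp1", gs), 0.99)
  expect_equal(transition_prob(pars, "s3", "s5", "s1", K, "msp2", gs), 0.08)
  expect_equal(transition_prob(pars, "s3", "s5", "s1", K, "msp3", gs), 0.08)
  # s0 = s3 not in K, i = s4 in K: eta / beta / eta
  expect_equal(transition_prob(pars, "s4", "s6", "s3", K, "msp1", gs), 0.01)
  expect_equal(transition_prob(pars, "s4", "s6", "s3", K, "msp2", gs), 0.99)
  expect_equal(transition_prob(pars, "s4", "s6", "s3", K, "msp3", gs), 0.01)
  # s0 not in K, i not in K: eta under all three
  for (a in c("msp1", "msp2", "msp3")) {
    expect_equal(transition_prob(pars, "s5", "s7", "s3", K, a, gs), 0.09)
  }
  # an intermediate state outside the domain is never in K
  expect_equal(transition_prob(pars, "s6", "s8", "s4", K_full, "msp3", gs), 0.09)
  # non-elementary pairs are rejected
  expect_error(transition_prob(pars, "s1", "s8", "s1", K, "msp1", gs),
               "not an elementary pair")
})

test_that("the assumptions coincide when K contains all or none of the problems", {
  gs <- fig2_goal_space()
  pars <- table4_params()
  ep <- elementary_pairs(gs)
  # with K empty every dispatch is eta; with K equal to the whole domain the
  # dispatches agree on transitions whose current state is a domain problem
  for (k in seq_len(nrow(ep))) {
    ps <- vapply(c("msp1", "msp2", "msp3"), function(a) {
      transition_prob(pars, ep$i[k], ep$j[k], "s4", character(0), a, gs)
    }, 0)
    expect_equal(max(ps) - min(ps), 0)
  }
  K_all <- gs$domain$initial
  for (k in seq_len(nrow(ep))) {
    ps <- vapply(c("msp1", "msp2", "msp3"), function(a) {
      transition_prob(pars, ep$i[k], ep$j[k], "s4", K_all, a, gs)
    }, 0)
    expect_equal(max(ps) - min(ps), 0)
  }
})

test_that("implied transition rows are stochastic", {
  gs <- fig2_goal_space()
  pars <- generate_params(gs, 0.2, seed = 3)
  for (i in names(gs$dist)[gs$dist >= 1]) {
    succs <- c(gs$edges$to[gs$edges$from == i], gs$failure)
    for (K in list(K_full, character(0), c("s4", "s8"))) {
      for (a in c("msp1", "msp2", "msp3")) {
        total <- sum(vapply(succs, function(j) {
          transition_prob(pars, i, j, "s1", K, a, gs)
        }, 0))
        expect_equal(total, 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("parameter generation respects the error-level intervals", {
  gs <- fig2_goal_space()
  for (x in c(0.01, 0.2)) {
    pars <- generate_params(gs, x, seed = 42)
    bf <- attr(pars, "beta_fail")
    ef <- attr(pars, "eta_fail")
    expect_true(all(bf > 0 & bf <= x + 1e-12))
    # lucky-guess mass per move is bounded by x as well
    expect_true(all(ef >= 1 - x - 1e-12 & ef < 1))
    bsum <- tapply(pars$beta, pars$i, sum)
    expect_equal(as.numeric(bsum + bf[names(bsum)]), rep(1, length(bsum)), tolerance = 1e-12)
  }
  expect_identical(generate_params(gs, 0.01, seed = 7),
                   generate_params(gs, 0.01, seed = 7))
  expect_error(generate_params(gs, 1.5), "must lie in")
})

test_that("simulated move frequencies match the transition probabilities", {
  gs <- fig2_goal_space()
  pars <- table4_params()
  n <- 2000
  firsts <- vapply(seq_len(n), function(k) {
    simulate_process(gs, pars, "s4", K_full, "msp1", seed = k)$visited[2]
  }, "")
  p <- 0.99  # beta_46; the residual .01 goes to failure
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(firsts == "s6") - p), 3 * se + 1e-9)
})

test_that("degenerate parameter rows give deterministic or immediately failing processes", {
  gs <- fig2_goal_space()
  # beta mass 1 along the single path from s4: process equals the path
  det <- transition_params(data.frame(
    i = c("s4", "s6", "s8"), j = c("s6", "s8", "s9"),
    beta = c(1, 1, 1), eta = c(0.5, 0.5, 0.5)
  ))
  sp <- simulate_process(gs, det, "s4", K_full, "msp1", seed = 1)
  expect_identical(sp$visited, c("s4", "s6", "s8", "s9"))
  expect_identical(sp$terminal, "goal")
  # eta failure mass near 1 and empty K: failure in one step
  fail <- transition_params(data.frame(
    i = c("s4", "s6", "s8"), j = c("s6", "s8", "s9"),
    beta = c(0.9, 0.9, 0.9), eta = c(1e-9, 1e-9, 1e-9)
  ))
  out <- vapply(1:50, function(k) {
    p <- simulate_process(gs, fail, "s4", character(0), "msp1", seed = k)
    length(p$visited) == 2 && p$terminal == "failure"
  }, TRUE)
  expect_true(all(out))
})

test_that("goal-terminated processes are never shorter than the minimum", {
  gs <- fig2_goal_space()
  pars <- generate_params(gs, 0.2, seed = 9)
  for (k in 1:40) {
    sp <- simulate_process(gs, pars, "s1", K_full, "msp3", seed = k)
    if (sp$terminal == "goal") expect_gte(length(sp$visited) - 1, 5)
  }
})

test_that("dichotomization marks goal-terminated processes correct", {
  gs <- fig2_goal_space()
  expect_equal(dichotomize(c("s1", "s3", "s5", "s7", "s8", "s9"), gs), 1L)
  expect_equal(dichotomize(c("s4", gs$failure), gs), 0L)
  expect_error(dichotomize(c("s4", "s6"), gs), "not terminal")
})

test_that("higher careless error lowers the mean dichotomized score", {
  gs <- fig2_goal_space()
  lo <- generate_params(gs, 0.01, seed = 5)
  mean_score <- function(pars) {
    mean(vapply(1:150, function(k) {
      dichotomize(simulate_process(gs, pars, "s1", K_full, "msp1",
                                   seed = k), gs)
    }, 0L))
  }
  # same table with beta rows rescaled to put .5 mass on failure
  hi_tab <- as.data.frame(lo)
  bsum <- tapply(hi_tab$beta, hi_tab$i, sum)
  hi_tab$beta <- hi_tab$beta / bsum[hi_tab$i] * 0.5
  hi <- transition_params(hi_tab)
  expect_gt(mean_score(lo), mean_score(hi))
})

test_that("state sampling follows the generated distribution", {
  ks <- ktol_structure()
  draw <- sample_states(ks, 20000, seed = 12)
  obs <- tabulate(draw$states, nbins = ks$n_states)
  gof <- suppressWarnings(stats::chisq.test(obs, p = draw$distribution))
  expect_gt(gof$p.value, 1e-3)
  expect_length(sample_states(ks, 0, seed = 1)$states, 0)
  # forced equal weights: uniform sampling
  u <- sample_states(ks, 5000, seed = 3, weights = rep(1, ks$n_states))
  expect_equal(u$distribution, rep(1 / 11, 11))
  expect_gt(suppressWarnings(stats::chisq.test(
    tabulate(u$states, 11))$p.value), 1e-3)
})
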