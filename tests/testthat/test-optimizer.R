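test_that("Levy steps are reproducible, truncated, and heavy-tailed", {
  set.seed(1); a <- levy_step(1.5, 1000)
  set.seed(1); b <- levy_step(1.5, 1000)
  expect_identical(a, b)
  expect_true(all(a >= 0.01))
  expect_error(levy_step(1, 10), "lambda")
  expect_error(levy_step(2.5, 10), "lambda")

  # Hill-estimator oracle on the upper tail recovers the stability index
  set.seed(123)
  x <- levy_step(1.5, 1e5)
  xs <- sort(x, decreasing = TRUE)
  k <- 1000
  hill <- 1 / mean(log(xs[1:k] / xs[k + 1]))
  expect_lt(abs(hill - 1.5), 0.2)
})

test_that("pollination moves follow the printed update rules", {
  expect_equal(global_pollination(c(1, 2), c(1, 2), c(3, 9)), c(1, 2))
  expect_equal(global_pollination(c(1, 0), c(0, 0), c(0.5, 0.5)), c(1.5, 0))
  expect_equal(global_pollination(c(1, 2), c(0, 1), 0), c(1, 2))
  expect_error(global_pollination(1:2, 1:3, 1), "equal length")

  expect_equal(local_pollination(c(1, 2), c(3, 3), c(3, 3), 0.7), c(1, 2))
  expect_equal(local_pollination(c(1, 2), c(9, 9), c(0, 0), 0), c(1, 2))
  expect_equal(local_pollination(c(0, 0), c(1, 0), c(0, 1), 0.5), c(0.5, -0.5))
  expect_error(local_pollination(1:2, 1:2, 1:3, 0.5), "equal length")
})

test_that("binarization thresholds the sigmoid against delta", {
  expect_true(binarize(0, 0.4, "printed"))
  expect_true(binarize(0, 0.4, "standard"))
  expect_false(binarize(0, 0.6, "printed"))
  expect_false(binarize(10, 0.5, "printed"))   # S(10) ~ 4.5e-5 under 1/(1+e^x)
  expect_true(binarize(10, 0.5, "standard"))
})

test_that("elite search rewrites only the leading window", {
  m <- c(TRUE, FALSE, TRUE)
  expect_equal(elite_search(m, m, 2 / 3), m)
  mask <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  g <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(elite_search(mask, g, 2 / 3),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(elite_search(mask, g, 0.01),
               c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(elite_search(mask, g[1:3], 0.5), "equal length")
})

test_that("fitness evaluates the confusion-based closed form", {
  gs <- synthetic_gold(18, 12)
  gold_mask <- gs$gold_mask
  fit <- mask_fitness(gold_mask, gs, alpha = 0.8)
  expect_equal(fit$fitness, 0.8 + 0.2 / 12, tolerance = 1e-12)
  expect_equal(unname(fit$counts), c(12, 0, 6, 0))

  ones <- mask_fitness(rep(TRUE, 18), gs, alpha = 0.8)
  expect_equal(ones$fitness, 0.8 * (12 / 18) + 0.2 / 18, tolerance = 1e-12)
  expect_equal(sum(ones$counts), 18)

  some <- rep(c(TRUE, FALSE), 9)
  expect_equal(mask_fitness(some, gs, alpha = 1)$fitness,
               (sum(some & gold_mask) + sum(!some & !gold_mask)) / 18)
  empty <- mask_fitness(rep(FALSE, 18), gs, 0.8)
  expect_equal(empty$fitness, -1)
})

test_that("exhaustive search returns the brute-force optimum", {
  gs <- synthetic_gold(10, 6)
  orc <- exhaustive_oracle(gs, alpha = 0.8)
  expect_equal(unname(orc$mask), gs$gold_mask)
  expect_equal(orc$fitness, 0.8 + 0.2 / 6, tolerance = 1e-12)

  orc0 <- exhaustive_oracle(gs, alpha = 0)
  expect_equal(unname(which(orc0$mask)), 1L)  # tie-break: first enumerated mask
  expect_equal(orc0$fitness, 1.0)

  gs1 <- synthetic_gold(1, 1)
  expect_equal(unname(exhaustive_oracle(gs1, 0.8)$mask), TRUE)
  expect_error(exhaustive_oracle(synthetic_gold(21, 10)), "20")
})

test_that("gold mask optimality matches its exact characterization", {
  # the best competitor of the full gold set is a single gold feature, so
  # the gold mask is the unique optimum iff m = 1 or alpha/fn > (1-alpha)/m
  set.seed(11)
  for (i in 1:30) {
    fn <- sample(3:12, 1)
    m <- sample(seq_len(fn), 1)
    alpha <- runif(1, 0.3, 0.95)
    gs <- synthetic_gold(fn, m, seed = i)
    orc <- exhaustive_oracle(gs, alpha)
    predicted <- m == 1 || alpha / fn > (1 - alpha) / m
    expect_equal(identical(unname(orc$mask), gs$gold_mask), predicted,
                 info = sprintf("fn=%d m=%d alpha=%.3f", fn, m, alpha))
  }
})

test_that("population initialization is deterministic and well-formed", {
  gs <- synthetic_gold(18, 12)
  cfg <- esfpa_config(seed = 9, population_size = 20)
  s1 <- initialize_population(gs, cfg)
  s2 <- initialize_population(gs, cfg)
  expect_identical(s1, s2)
  expect_length(s1$population, 20)
  expect_true(all(vapply(s1$population, function(p) length(p$position), 0L) == 18))
  expect_true(all(vapply(s1$population,
                         function(p) all(abs(p$position) <= 1), TRUE)))
  expect_gte(s1$global_best$fitness,
             max(vapply(s1$population, `[[`, 0, "fitness")) - 1e-15)

  gs1 <- synthetic_gold(1, 1)
  expect_length(initialize_population(gs1, cfg)$population[[1]]$mask, 1)
})

test_that("the optimizer is deterministic, monotone, and converges", {
  tab <- random_table(40, 8, seed = 3)
  cfg <- esfpa_config(seed = 5, max_iterations = 200)
  r1 <- esfpa_run(tab, cfg)
  r2 <- esfpa_run(tab, cfg)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace) >= 0))

  gs <- gold_standard(tab, 2 / 3)
  orc <- exhaustive_oracle(gs, cfg$alpha)
  expect_equal(unname(r1$mask), unname(orc$mask))

  r0 <- esfpa_run(tab, esfpa_config(seed = 5, max_iterations = 0))
  init <- initialize_population(gs, esfpa_config(seed = 5, max_iterations = 0))
  expect_equal(r0$fitness, init$global_best$fitness)

  # selected features reported in original column order
  expect_equal(r1$selected_features,
               intersect(feature_names(tab), names(r1$mask)[r1$mask]))
})
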