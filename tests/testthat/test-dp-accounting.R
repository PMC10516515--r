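# Laplace-mechanism accounting: epsilon arithmetic, sensitivity formulas,
# composition, enforcement, and the budget/accuracy trade-off.

test_that("epsilon_for_query is the sensitivity/scale ratio", {
  expect_identical(epsilon_for_query(1, 1), 1)
  expect_identical(epsilon_for_query(0.5, 5), 0.1)
  expect_error(epsilon_for_query(0, 1), class = "invalid_parameter")
  expect_error(epsilon_for_query(1, -1), class = "invalid_parameter")
})

test_that("Laplace noise has the mechanism's distribution", {
  set.seed(123)
  b <- 2.5
  draws <- rlaplace(1e5, scale = b)
  expect_lt(abs(var(draws) / (2 * b^2) - 1), 0.05)
  ks <- suppressWarnings(ks.test(draws, function(q) covleak:::plaplace(q, b)))
  expect_gt(ks$p.value, 0.01)
})

test_that("attack_budget composes per-query epsilons additively", {
  expect_identical(attack_budget(numeric(0), 0), 0)
  expect_equal(attack_budget(c(0.1, 0.1, 0.1), 0.05), 0.35, tolerance = 1e-12)
  expect_error(attack_budget(c(-0.1), 0), class = "invalid_parameter")
  for (n in c(7, 50, 250)) {
    expect_equal(attack_budget(rep(0.02, n), 0.01), n * 0.02 + 0.01,
                 tolerance = 1e-12)
  }
})

test_that("allowed_iterations floors the budget ratio", {
  expect_identical(allowed_iterations(log(3), log(3)), 1L)
  expect_identical(allowed_iterations(log(3), 2 * log(3)), 0L)
  expect_identical(allowed_iterations(1, 0.3), 3L)
  expect_error(allowed_iterations(1, 0), class = "invalid_parameter")
})

test_that("covariance sensitivity is the exact corner bound", {
  # enumerate all corner datasets and corner replacements at n = 3
  w <- 1.7
  n <- 3
  corners <- expand.grid(rep(list(c(0, w)), n))
  worst <- 0
  for (i in seq_len(nrow(corners))) {
    for (j in seq_len(nrow(corners))) {
      x <- as.numeric(corners[i, ])
      y <- as.numeric(corners[j, ])
      for (s in 1:n) {
        for (xs in c(0, w)) {
          for (ys in c(0, w)) {
            x2 <- x; x2[s] <- xs
            y2 <- y; y2[s] <- ys
            worst <- max(worst, abs(cov(x2, y2) - cov(x, y)))
          }
        }
      }
    }
  }
  expect_equal(worst, cov_sensitivity(w, w, n), tolerance = 1e-12)

  # random one-record perturbations never exceed the bound
  set.seed(17)
  for (k in 1:300) {
    n <- sample(3:10, 1)
    wx <- runif(1, 0.5, 3)
    wy <- runif(1, 0.5, 3)
    x <- runif(n, 0, wx)
    y <- runif(n, 0, wy)
    s <- sample(n, 1)
    x2 <- x; y2 <- y
    x2[s] <- runif(1, 0, wx)
    y2[s] <- runif(1, 0, wy)
    expect_lte(abs(cov(x2, y2) - cov(x, y)),
               cov_sensitivity(wx, wy, n) + 1e-12)
  }
})

test_that("probe covariance sensitivity is exact for a public probe", {
  set.seed(18)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    w <- runif(1, 0.5, 3)
    y <- rnorm(n)
    x <- runif(n, 0, w)
    s <- sample(n, 1)
    x2 <- x
    x2[s] <- runif(1, 0, w)
    expect_lte(abs(cov(x2, y) - cov(x, y)), probe_cov_sensitivity(w, y) + 1e-12)
  }
  # achieved exactly by a full-width move at the extreme probe entry
  y <- c(-2, 0.5, 1, 0.3)
  s <- which.max(abs(y - mean(y)))
  x <- c(0, 0, 0, 0)
  x2 <- x
  x2[s] <- 1
  expect_equal(abs(cov(x2, y) - cov(x, y)), probe_cov_sensitivity(1, y),
               tolerance = 1e-12)
})

test_that("mean sensitivity matches a one-record replacement", {
  expect_identical(mean_sensitivity(2, 8), 0.25)
  x <- runif(8)
  x2 <- x
  x2[3] <- x[3] + 2 # full clip-width move
  expect_equal(abs(mean(x2) - mean(x)), mean_sensitivity(2, 8), tolerance = 1e-14)
})

test_that("the accountant composes, records, and refuses before answering", {
  acct <- privacy_accountant(1, clip_bounds = list(x = c(0, 10)))
  acct_charge(acct, "q1", sensitivity = 0.4, noise_scale = 1)
  acct_charge(acct, "q2", sensitivity = 0.5, noise_scale = 1)
  expect_equal(acct$consumed, 0.9, tolerance = 1e-12)
  expect_error(acct_charge(acct, "q3", sensitivity = 0.2, noise_scale = 1),
               class = "budget_exhausted")
  expect_equal(acct$consumed, 0.9, tolerance = 1e-12) # refused charge not booked
  led <- acct_ledger(acct)
  expect_identical(nrow(led), 2L)
  expect_equal(led$cumulative, cumsum(led$eps))
  expect_true(all(diff(led$cumulative) >= 0))
})

test_that("accounted endpoints charge the ledger and the refused query is unanswered", {
  set.seed(20)
  x <- runif(20, 15, 50)
  acct <- privacy_accountant(0.05, clip_bounds = list(x = c(15, 50)))
  fed <- make_fed(x = x, accountant = acct,
                  noise = noise_policy(mean_noise_sd = 100, cov_noise_sd = 100,
                                       distribution = "laplace"))
  m <- query_mean(fed, "s1", "x")
  expect_equal(acct$consumed, mean_sensitivity(35, 20) / (100 / sqrt(2)),
               tolerance = 1e-12)
  expect_error(query_cov(fed, "s1", "x", "x"), class = "budget_exhausted")
  lg <- query_log(fed)
  expect_identical(lg$status, c("ok", "budget_exhausted"))
  # probe-only releases are free: broadcast vectors are client-known
  broadcast(fed, "s1", "p", matrix(rnorm(40), 20, 2))
  before <- acct$consumed
  query_mean(fed, "s1", "p[1]")
  query_cov(fed, "s1", "p[1]", "p[2]")
  expect_identical(acct$consumed, before)
})

test_that("the accountant requires Laplace noise with positive sd", {
  x <- runif(10, 0, 1)
  acct <- privacy_accountant(10, clip_bounds = list(x = c(0, 1)))
  fed <- make_fed(x = x, accountant = acct, noise = noise_policy(1, 1, "gaussian"))
  expect_error(query_mean(fed, "s1", "x"), class = "invalid_parameter")
})

test_that("ledger total of a logged attack equals the composed attack budget", {
  set.seed(22)
  n <- 12
  x <- runif(n, 15, 50)
  acct <- privacy_accountant(1e6, clip_bounds = list(x = c(15, 50)))
  fed <- make_fed(x = x, accountant = acct,
                  noise = noise_policy(50, 50, "laplace"))
  probes <- generate_probes(n, seed = 2)
  reconstruct_variable(fed, "s1", "x", probes = probes)
  eps <- covleak:::attack_iteration_epsilons(35, probes$Y, 50)
  expect_equal(acct$consumed, attack_budget(eps$eps_cov, eps$eps_mean),
               tolerance = 1e-10)
})

test_that("allowed_iterations equals what a live accountant admits", {
  set.seed(23)
  n <- 10
  x <- runif(n, 15, 50)
  probes <- generate_probes(n, seed = 3)
  for (sd_l in c(2000, 8000)) {
    eps <- covleak:::attack_iteration_epsilons(35, probes$Y, sd_l)
    eps_att <- attack_budget(eps$eps_cov, eps$eps_mean)
    budget <- log(3)
    acct <- privacy_accountant(budget, clip_bounds = list(x = c(15, 50)))
    fed <- make_fed(x = x, accountant = acct,
                    noise = noise_policy(sd_l, sd_l, "laplace"))
    fed$log_enabled <- FALSE
    admitted <- 0L
    repeat {
      done <- tryCatch({
        attack_noisy_once(fed, "s1", "x", probes = probes)
        FALSE
      }, budget_exhausted = function(e) TRUE)
      if (done) break
      admitted <- admitted + 1L
    }
    expect_identical(admitted, allowed_iterations(budget, eps_att))
  }
})

test_that("standard descriptive analysis exhausts the budget under tight noise", {
  spec <- federation_spec(n_servers = 1, n_per_server = 100, seed = 9)
  fed <- generate_federation(spec)
  metric <- cnsim_like_variables()
  metric_names <- metric$name[metric$kind == "continuous"]
  clip <- stats::setNames(
    lapply(metric_names, function(nm) {
      v <- metric[metric$name == nm, ]
      c(v$lower, v$upper)
    }), metric_names)
  rep <- run_standard_analysis_budget(fed, "server1", metric_names,
                                      noise_sds = c(5, 5000), clip_bounds = clip)
  tight <- rep$summary[rep$summary$noise_sd == 5, ]
  # a single covariance of BMI-scale variables costs (35*35/100)/(5/sqrt(2))
  # ~ 3.5 epsilon >> ln(3): nothing beyond the cheap means completes
  expect_true(all(!tight$completed))
  # pairwise covariances among 5 metric variables flag exhaustion early
  pw <- tight[tight$scenario == "pairwise_covariances", ]
  expect_lt(pw$answered, pw$queries)
  # ledger consistency: summary consumption equals the ledger sum
  for (nm in names(rep$ledgers)) {
    led <- rep$ledgers[[nm]]
    sc <- sub("@sd.*", "", nm)
    sd_l <- as.numeric(sub(".*@sd", "", nm))
    row <- rep$summary[rep$summary$scenario == sc & rep$summary$noise_sd == sd_l, ]
    expect_equal(row$consumed, sum(led$eps), tolerance = 1e-12)
  }
})

test_that("the budget/accuracy trade-off runs and moves in the right directions", {
  fed <- bmi_fed(15, policy = disclosure_policy(enabled = FALSE))
  exp <- run_dp_attack_experiment(fed, "server1", "bmi",
                                  clip_bounds = c(15, 50),
                                  budgets = c(log(1.01), log(1.5), log(3)),
                                  noise_sds = c(800, 4000),
                                  replicates = 8L, seed = 31)
  s <- exp$summary
  # more noise admits at least as many iterations at fixed budget
  for (b in unique(s$budget)) {
    sb <- s[s$budget == b, ]
    sb <- sb[order(sb$noise_sd), ]
    expect_true(all(diff(sb$iterations) >= 0))
  }
  # zero-iteration cells carry no reconstruction
  expect_true(all(is.na(exp$results$rel_mse[exp$results$iterations == 0])))
  expect_true(all(!is.na(exp$results$rel_mse[exp$results$iterations > 0])))
})
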