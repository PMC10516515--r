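# Epsilon-differential-privacy accounting over the summary-statistic
# endpoints. The Laplace mechanism with scale b applied to a release of
# sensitivity D satisfies eps = D / b differential privacy; sequential
# composition charges the sum of per-release epsilons against a total budget.
# Sensitivities assume records clipped to configured per-variable bounds
# [a, b] (width w = b - a):
#   mean:                        D = w / n
#   covariance, both private:    D = w_x * w_y / n      (exact corner bound)
#   covariance vs public probe:  D = w_x * max_s |y_s - mean(y)| / (n - 1)
# Probe-only releases are charged eps = 0: differential privacy protects the
# dataset, and broadcast vectors are client-known public inputs.

#' Privacy accountant with additive composition
#'
#' Tracks consumed epsilon across releases; a query whose charge would push
#' consumption above `total_budget` is refused (error class
#' `budget_exhausted`) before being answered.
#'
#' @param total_budget total epsilon > 0.
#' @param clip_bounds named list of `c(lower, upper)` clip bounds per private
#'   variable; required to compute sensitivities.
#' @return an environment of class `privacy_accountant` with fields
#'   `total_budget`, `consumed`, `clip_bounds` and `ledger`.
#' @export
privacy_accountant <- function(total_budget, clip_bounds = list()) {
  if (!is.numeric(total_budget) || total_budget <= 0) {
    fl_stop("invalid_parameter", "total_budget must be > 0")
  }
  a <- new.env(parent = emptyenv())
  a$total_budget <- total_budget
  a$consumed <- 0
  a$clip_bounds <- clip_bounds
  a$ledger <- list()
  class(a) <- "privacy_accountant"
  a
}

#' @export
print.privacy_accountant <- function(x, ...) {
  cat(sprintf("<privacy_accountant> consumed %.6g of %.6g over %d release(s)\n",
              x$consumed, x$total_budget, length(x$ledger)))
  invisible(x)
}

#' Charge the accountant for one release
#'
#' @param acct a [privacy_accountant()].
#' @param query description string.
#' @param sensitivity release sensitivity (> 0).
#' @param noise_scale Laplace scale of the added noise (> 0).
#' @return the epsilon charged, invisibly.
#' @export
acct_charge <- function(acct, query, sensitivity, noise_scale) {
  eps <- epsilon_for_query(sensitivity, noise_scale)
  if (acct$consumed + eps > acct$total_budget + 1e-12) {
    fl_stop("budget_exhausted",
            "release refused: charge %.4g would exceed remaining budget %.4g",
            eps, acct$total_budget - acct$consumed)
  }
  acct$ledger[[length(acct$ledger) + 1L]] <- list(query = query,
                                                  sensitivity = sensitivity,
                                                  noise_scale = noise_scale,
                                                  eps = eps)
  acct$consumed <- acct$consumed + eps
  invisible(eps)
}

#' Ledger of a privacy accountant as a data frame
#' @param acct a [privacy_accountant()].
#' @return data frame with columns `query`, `sensitivity`, `noise_scale`,
#'   `eps`, `cumulative`.
#' @export
acct_ledger <- function(acct) {
  if (!length(acct$ledger)) {
    return(data.frame(query = character(), sensitivity = numeric(),
                      noise_scale = numeric(), eps = numeric(),
                      cumulative = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(acct$ledger, function(r) {
    data.frame(query = r$query, sensitivity = r$sensitivity,
               noise_scale = r$noise_scale, eps = r$eps,
               stringsAsFactors = FALSE)
  }))
  df$cumulative <- cumsum(df$eps)
  df
}

#' Epsilon consumed by one Laplace-mechanism release
#'
#' @param sensitivity worst-case change of the released statistic under one
#'   record's replacement (> 0).
#' @param noise_scale Laplace scale b (> 0).
#' @return `sensitivity / noise_scale`.
#' @export
epsilon_for_query <- function(sensitivity, noise_scale) {
  if (!is.numeric(sensitivity) || !is.numeric(noise_scale) ||
      sensitivity <= 0 || noise_scale <= 0) {
    fl_stop("invalid_parameter", "sensitivity and noise_scale must be > 0")
  }
  sensitivity / noise_scale
}

#' Sensitivity of a clipped sample mean
#' @param width clip-box width (upper - lower).
#' @param n sample size.
#' @return `width / n`.
#' @export
mean_sensitivity <- function(width, n) {
  if (width <= 0 || n < 1) fl_stop("invalid_parameter", "need width > 0 and n >= 1")
  width / n
}

#' Sensitivity of a sample covariance of two clipped private variables
#'
#' Exact worst-case change of the `n - 1`-denominator sample covariance when
#' one record `(x_s, y_s)` is replaced within the clip box; the maximum is
#' attained at box corners and equals `w_x * w_y / n`.
#'
#' @param width_x,width_y clip-box widths of the two variables.
#' @param n sample size.
#' @return `width_x * width_y / n`.
#' @export
cov_sensitivity <- function(width_x, width_y, n) {
  if (width_x <= 0 || width_y <= 0 || n < 2) {
    fl_stop("invalid_parameter", "need positive widths and n >= 2")
  }
  width_x * width_y / n
}

#' Sensitivity of a covariance against a public probe vector
#'
#' When `y` is client-known (a broadcast probe), replacing record `x_s` by
#' `x_s + d` changes the covariance by exactly `d (y_s - mean(y)) / (n - 1)`,
#' so the worst case is `width * max_s |y_s - mean(y)| / (n - 1)`.
#'
#' @param width clip-box width of the private variable.
#' @param y the public probe vector.
#' @return the sensitivity.
#' @export
probe_cov_sensitivity <- function(width, y) {
  n <- length(y)
  if (width <= 0 || n < 2) fl_stop("invalid_parameter", "need width > 0 and n >= 2")
  width * max(abs(y - mean(y))) / (n - 1)
}

#' Budget consumed by one full single-variable attack
#'
#' Sequential composition: the sum of the per-covariance charges plus the
#' mean charge.
#'
#' @param eps_cov numeric vector of per-covariance epsilons (length `n_j`).
#' @param eps_mean epsilon of the mean release.
#' @return the total epsilon.
#' @export
attack_budget <- function(eps_cov, eps_mean) {
  if (any(eps_cov < 0) || eps_mean < 0) {
    fl_stop("invalid_parameter", "epsilons must be >= 0")
  }
  sum(eps_cov) + eps_mean
}

# Per-query epsilons of one attack iteration under a Laplace noise sd.
attack_iteration_epsilons <- function(width, Y, noise_sd) {
  scale <- noise_sd / sqrt(2)
  n <- nrow(Y)
  eps_cov <- vapply(seq_len(n), function(i) {
    epsilon_for_query(probe_cov_sensitivity(width, Y[, i]), scale)
  }, numeric(1))
  list(eps_cov = eps_cov,
       eps_mean = epsilon_for_query(mean_sensitivity(width, n), scale))
}

#' Number of attack iterations a budget admits
#'
#' @param total_budget total epsilon (>= 0).
#' @param per_iteration_budget epsilon consumed by one full attack iteration
#'   (> 0).
#' @return `floor(total_budget / per_iteration_budget)` as an integer.
#' @export
allowed_iterations <- function(total_budget, per_iteration_budget) {
  if (!is.numeric(per_iteration_budget) || per_iteration_budget <= 0) {
    fl_stop("invalid_parameter", "per_iteration_budget must be > 0")
  }
  if (total_budget < 0) fl_stop("invalid_parameter", "total_budget must be >= 0")
  # guard against 1 ulp under an exact multiple
  as.integer(floor(total_budget / per_iteration_budget * (1 + 1e-12)))
}

#' Privacy-budget versus attack-accuracy experiment
#'
#' For each noise sd and total budget in the grid, computes the per-iteration
#' attack cost from the probe sensitivities, the number of admitted
#' iterations, and the relative MSE of the noise-averaging estimator run for
#' exactly that many iterations (Laplace noise). Within a replicate the
#' estimators across budgets are nested prefixes of one noise stream, so a
#' larger budget never sees a worse draw by construction. Zero-iteration
#' cells are recorded with `rel_mse = NA` (no reconstruction possible).
#'
#' @param fed a [federation()]; the target column must be fully observed.
#' @param server_id,variable attack target.
#' @param clip_bounds `c(lower, upper)` public clip bounds of the target.
#' @param budgets epsilon grid, default 6 points from `log(1.01)` to `log(3)`.
#' @param noise_sds Laplace noise sds (applied to mean and covariance
#'   endpoints), default `c(500, 1500, 5000)`.
#' @param replicates replicates per cell (default 200).
#' @param seed base seed.
#' @return object of class `dp_experiment`: `results` (noise_sd, budget,
#'   replicate, eps_per_iteration, iterations, rel_mse) and `summary`
#'   (median iterations and median relative MSE per cell, where a replicate
#'   admitting zero iterations counts as infinite error -- no reconstruction
#'   is worse than any reconstruction).
#' @export
run_dp_attack_experiment <- function(fed, server_id, variable, clip_bounds,
                                     budgets = seq(log(1.01), log(3), length.out = 6),
                                     noise_sds = c(500, 1500, 5000),
                                     replicates = 200L, seed = 1L) {
  srv <- fed_server(fed, server_id)
  x_true <- srv$X[, variable]
  if (anyNA(x_true)) fl_stop("incomplete_target", "target variable has missing values")
  n <- length(x_true)
  width <- diff(range(clip_bounds))
  old_log <- fed$log_enabled
  old_noise <- fed$noise
  fed$log_enabled <- FALSE
  on.exit({
    fed$log_enabled <- old_log
    fed$noise <- old_noise
  })
  rows <- list()
  for (si in seq_along(noise_sds)) {
    sd_l <- noise_sds[si]
    fed$noise <- noise_policy(mean_noise_sd = sd_l, cov_noise_sd = sd_l,
                              distribution = "laplace")
    for (rep_i in seq_len(replicates)) {
      s <- sub_seed(seed, si * 1000000L + rep_i)
      probes <- generate_probes(n, s)
      eps <- attack_iteration_epsilons(width, probes$Y, sd_l)
      eps_att <- attack_budget(eps$eps_cov, eps$eps_mean)
      iters <- vapply(budgets, allowed_iterations,
                      integer(1), per_iteration_budget = eps_att)
      Rmax <- max(iters)
      X <- if (Rmax >= 1L) {
        with_seed(s + 1, noisy_batch(fed, server_id, variable, probes, Rmax)$X)
      } else {
        NULL
      }
      for (bi in seq_along(budgets)) {
        R <- iters[bi]
        rel <- if (R >= 1L) {
          est <- rowMeans(X[, seq_len(R), drop = FALSE])
          mean((est - x_true)^2) / stats::var(x_true)
        } else {
          NA_real_
        }
        rows[[length(rows) + 1L]] <-
          data.frame(noise_sd = sd_l, budget = budgets[bi], replicate = rep_i,
                     eps_per_iteration = eps_att, iterations = R, rel_mse = rel)
      }
    }
  }
  results <- do.call(rbind, rows)
  # infeasible replicates (0 admitted iterations) score as infinite error
  med <- function(v) stats::median(ifelse(is.na(v), Inf, v))
  summary <- stats::aggregate(cbind(iterations, rel_mse) ~ noise_sd + budget,
                              results, med, na.action = stats::na.pass)
  summary <- summary[order(summary$noise_sd, summary$budget), ]
  structure(list(results = results, summary = summary), class = "dp_experiment")
}

#' @export
print.dp_experiment <- function(x, ...) {
  cat("<dp_experiment> median iterations and relative MSE by noise sd and budget:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Privacy budget consumed by routine descriptive analysis
#'
#' For each noise sd, charges a fresh accountant for (a) the standard
#' workflow on the first two variables -- two means, two variances, one
#' covariance -- and (b) all pairwise covariances among the given metric
#' variables, reporting per-query and cumulative epsilon (display-capped at
#' the total budget) and whether each workflow completed before budget
#' exhaustion.
#'
#' @param fed a [federation()].
#' @param server_id server to query.
#' @param variables character vector of at least two metric (continuous)
#'   variables.
#' @param noise_sds Laplace noise sds to evaluate.
#' @param clip_bounds named list of per-variable `c(lower, upper)` bounds.
#' @param total_budget total epsilon, default `log(3)`.
#' @return object of class `budget_report_set`: `summary` (one row per noise
#'   sd and scenario) and `ledgers` (per-query charge tables).
#' @export
run_standard_analysis_budget <- function(fed, server_id, variables, noise_sds,
                                         clip_bounds, total_budget = log(3)) {
  if (length(variables) < 2L) {
    fl_stop("invalid_parameter", "need at least two metric variables")
  }
  v1 <- variables[1]
  v2 <- variables[2]
  pairs <- utils::combn(variables, 2L, simplify = FALSE)
  scenarios <- list(
    standard_two_variable = c(
      list(c("mean", v1), c("mean", v2), c("cov", v1, v1), c("cov", v2, v2),
           c("cov", v1, v2))
    ),
    pairwise_covariances = lapply(pairs, function(p) c("cov", p))
  )
  old_noise <- fed$noise
  old_acct <- fed$accountant
  on.exit({
    fed$noise <- old_noise
    fed$accountant <- old_acct
  })
  rows <- list()
  ledgers <- list()
  for (sd_l in noise_sds) {
    fed$noise <- noise_policy(mean_noise_sd = sd_l, cov_noise_sd = sd_l,
                              distribution = "laplace")
    for (sc in names(scenarios)) {
      acct <- privacy_accountant(total_budget, clip_bounds)
      fed$accountant <- acct
      queries <- scenarios[[sc]]
      answered <- 0L
      completed <- TRUE
      for (q in queries) {
        ans <- tryCatch({
          if (q[1] == "mean") {
            query_mean(fed, server_id, q[2])
          } else {
            query_cov(fed, server_id, q[2], q[3])
          }
          TRUE
        }, budget_exhausted = function(e) FALSE)
        if (!ans) {
          completed <- FALSE
          break
        }
        answered <- answered + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        noise_sd = sd_l, scenario = sc, queries = length(queries),
        answered = answered, consumed = acct$consumed,
        consumed_capped = min(acct$consumed, total_budget),
        completed = completed, stringsAsFactors = FALSE
      )
      ledgers[[sprintf("%s@sd%g", sc, sd_l)]] <- acct_ledger(acct)
    }
  }
  structure(list(summary = do.call(rbind, rows), ledgers = ledgers,
                 total_budget = total_budget),
            class = "budget_report_set")
}

#' @export
print.budget_report_set <- function(x, ...) {
  cat(sprintf("<budget_report_set> total budget %.4g\n", x$total_budget))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
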