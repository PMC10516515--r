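# Noise robustness of the attack. When the server adds zero-mean noise
# (eps to each covariance, gamma to the mean), the client observes
#   x_noisy = x + (n-1) (Y')^{-1} eps + n (Y')^{-1} mt gamma,
# so the noisy reconstruction is unbiased and the mean of R independent runs
# converges in probability to x at rate sqrt(R) (MSE proportional to 1/R).
# Probes are held fixed across repetitions: the estimator averages over
# noise, not probes.

#' One noisy reconstruction
#'
#' [reconstruct_variable()] under an explicit noise policy; with both sds 0
#' it reduces exactly to the noiseless attack.
#'
#' @inheritParams reconstruct_variable
#' @param noise a [noise_policy()]; defaults to the federation's.
#' @return a `reconstruction_result`.
#' @export
attack_noisy_once <- function(fed, server_id, variable, probes = NULL,
                              noise = NULL, seed = NULL, probe_name = NULL) {
  if (!is.null(noise)) {
    old <- fed$noise
    fed$noise <- noise
    on.exit(fed$noise <- old)
  }
  reconstruct_variable(fed, server_id, variable, probes = probes, seed = seed,
                       probe_name = probe_name)
}

# R noisy reconstructions with fixed probes and a single broadcast/QR
# factorization; returns an n x R matrix of reconstructions plus the context.
noisy_batch <- function(fed, server_id, variable, probes, R, probe_name = NULL) {
  ctx <- attack_context(fed, server_id, variable, probes, probe_name)
  X <- matrix(0, ctx$n, R)
  for (r in seq_len(R)) {
    X[, r] <- attack_once(fed, server_id, variable, ctx)$x_hat
  }
  list(ctx = ctx, X = X)
}

#' Noise-averaging estimator
#'
#' Runs `R` independent noisy reconstructions (fresh server-side noise per
#' run, probes fixed) and returns their componentwise mean. With `R = 1` this
#' is a single noisy attack; with noise sd 0 it is exact for any `R`.
#'
#' @inheritParams attack_noisy_once
#' @param R number of repetitions (>= 1).
#' @param seed optional seed for the noise draws (client-side RNG).
#' @return a `reconstruction_result` whose `x_hat` is the averaged estimator;
#'   carries `R` and, as `runs`, the `n x R` matrix of individual
#'   reconstructions.
#' @export
averaged_attack <- function(fed, server_id, variable, probes, noise = NULL,
                            R = 1L, seed = NULL, probe_name = NULL) {
  if (R < 1L) fl_stop("invalid_parameter", "R must be >= 1")
  if (!is.null(noise)) {
    old <- fed$noise
    fed$noise <- noise
    on.exit(fed$noise <- old)
  }
  run_batch <- function() noisy_batch(fed, server_id, variable, probes, R, probe_name)
  batch <- if (is.null(seed)) run_batch() else with_seed(seed, run_batch())
  x_bar <- rowMeans(batch$X)
  new_reconstruction_result(
    list(x_hat = x_bar, V_tilde = rep(NA_real_, batch$ctx$n), mean_x = NA_real_),
    batch$ctx, server_id, variable, "covariance",
    extra = list(R = R, runs = batch$X)
  )
}

#' Noise-robustness experiment (relative MSE versus repetitions)
#'
#' For each noise level and replicate, draws fresh probes, runs
#' `max(R_values)` noisy reconstructions and scores the averaging estimator
#' at each requested `R` (nested prefixes of one noise stream, so estimators
#' across `R` are comparable within a replicate). The relative MSE is the
#' mean squared error divided by the sample variance of the true vector.
#'
#' @param fed a [federation()].
#' @param server_id,variable attack target.
#' @param R_values numbers of repetitions to score (default 1, 10, 100).
#' @param noise_levels numeric vector of noise sds applied to both the mean
#'   and covariance endpoints; default `c(0.01, 0.1, 1, 10) * sd(x)`.
#' @param replicates independent replicates per level (default 200).
#' @param seed base seed.
#' @param distribution noise distribution, default Gaussian.
#' @return object of class `noise_experiment`: `results` (one row per level,
#'   R, replicate) and `summary` (median and 5th/95th percentile of the
#'   relative MSE per level and R).
#' @export
run_noise_experiment <- function(fed, server_id, variable,
                                 R_values = c(1L, 10L, 100L),
                                 noise_levels = NULL, replicates = 200L,
                                 seed = 1L, distribution = "gaussian") {
  srv <- fed_server(fed, server_id)
  x_true <- srv$X[, variable]
  n <- length(x_true)
  if (is.null(noise_levels)) {
    noise_levels <- c(0.01, 0.1, 1, 10) * stats::sd(x_true)
  }
  R_values <- sort(as.integer(R_values))
  Rmax <- max(R_values)
  old_log <- fed$log_enabled
  old_noise <- fed$noise
  fed$log_enabled <- FALSE
  on.exit({
    fed$log_enabled <- old_log
    fed$noise <- old_noise
  })
  rows <- vector("list", length(noise_levels) * replicates * length(R_values))
  k <- 0L
  for (li in seq_along(noise_levels)) {
    sd_l <- noise_levels[li]
    fed$noise <- noise_policy(mean_noise_sd = sd_l, cov_noise_sd = sd_l,
                              distribution = distribution)
    for (rep_i in seq_len(replicates)) {
      s <- sub_seed(seed, li * 100000L + rep_i)
      probes <- generate_probes(n, s)
      batch <- with_seed(s + 1, noisy_batch(fed, server_id, variable, probes, Rmax))
      for (R in R_values) {
        est <- rowMeans(batch$X[, seq_len(R), drop = FALSE])
        k <- k + 1L
        rows[[k]] <- data.frame(noise_sd = sd_l, R = R, replicate = rep_i,
                                rel_mse = mean((est - x_true)^2) / stats::var(x_true))
      }
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarize_noise_results(results)),
            class = "noise_experiment")
}

summarize_noise_results <- function(results) {
  agg <- function(f) stats::aggregate(rel_mse ~ noise_sd + R, results, f)
  s <- agg(stats::median)
  names(s)[3] <- "median"
  s$q05 <- agg(function(v) stats::quantile(v, 0.05))$rel_mse
  s$q95 <- agg(function(v) stats::quantile(v, 0.95))$rel_mse
  s[order(s$noise_sd, s$R), ]
}

#' @export
print.noise_experiment <- function(x, ...) {
  cat("<noise_experiment> median relative MSE by noise sd and R:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
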