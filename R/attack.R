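# The covariance-based reconstruction attack. A private server-side vector
# x (length n) satisfies, for any client-known probe vector y_i,
#   Cov(x, y_i) = (1/(n-1)) y_i' x - (n/(n-1)) Mean(x) Mean(y_i),
# so n linearly independent probes give a linear system whose solution is
#   x = (n-1) (Y')^{-1} Vt + n Mean(x) (Y')^{-1} mt,
# with Vt the vector of returned covariances and mt the client-side probe
# means. The implementation solves the system by QR factorization with one
# step of iterative refinement rather than forming the inverse.

#' Generate a client-known probe matrix
#'
#' Draws an `n x n` matrix of independent standard-normal entries, which is
#' almost surely of full rank and whose columns almost surely satisfy the
#' dichotomous-level disclosure check (all entries distinct). Numerical rank
#' is verified; on the (probability ~0) event of rank deficiency the matrix is
#' redrawn with a derived sub-seed, up to `max_redraws` times.
#'
#' @param n number of observations on the target server.
#' @param seed integer seed; the same seed always yields the same probes.
#' @param max_redraws bounded retries before failing with class
#'   `probe_degenerate`.
#' @return object of class `probe_matrix` with fields `Y`, `seed`,
#'   `condition_estimate` and `redraws`.
#' @export
generate_probes <- function(n, seed, max_redraws = 10L) {
  if (n < 1L) fl_stop("invalid_parameter", "n must be >= 1")
  s <- seed
  for (k in 0:max_redraws) {
    Y <- with_seed(s, matrix(stats::rnorm(n * n), n, n))
    if (qr(Y, tol = 1e-8)$rank == n) {
      return(structure(list(Y = Y, seed = seed,
                            condition_estimate = kappa(Y, exact = FALSE),
                            redraws = k),
                       class = "probe_matrix"))
    }
    s <- sub_seed(seed, k + 1L)
  }
  fl_stop("probe_degenerate", "could not draw a full-rank %d x %d probe matrix", n, n)
}

#' Wrap an explicit matrix as a probe matrix
#'
#' Validates linear independence of the columns (numerical full rank at
#' relative tolerance 1e-8).
#'
#' @param Y square numeric matrix; column `i` is probe `y_i`.
#' @param seed optional provenance seed, stored as metadata only.
#' @return object of class `probe_matrix`.
#' @export
probe_matrix <- function(Y, seed = NA_integer_) {
  Y <- as.matrix(Y)
  if (nrow(Y) != ncol(Y)) fl_stop("shape_mismatch", "probe matrix must be square")
  if (qr(Y, tol = 1e-8)$rank < ncol(Y)) {
    fl_stop("probe_degenerate", "probe columns are not linearly independent")
  }
  structure(list(Y = Y, seed = seed,
                 condition_estimate = kappa(Y, exact = FALSE), redraws = 0L),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix> %d x %d, seed %s, condition estimate %.3g\n",
              nrow(x$Y), ncol(x$Y), format(x$seed), x$condition_estimate))
  invisible(x)
}

# QR solve of Y' xhat = rhs with one iterative-refinement step.
solve_probe_system <- function(qrA, A, rhs) {
  x0 <- qr.coef(qrA, rhs)
  r <- rhs - A %*% x0
  drop(x0 + qr.coef(qrA, r))
}

# Shared setup: validate the target column, broadcast probes if needed, and
# factor Y'. Returns everything the per-iteration attack body needs.
attack_context <- function(fed, server_id, variable, probes, probe_name) {
  srv <- fed_server(fed, server_id)
  if (!(variable %in% colnames(srv$X))) {
    fl_stop("unknown_variable", "no variable '%s' on server '%s'", variable, server_id)
  }
  x_true <- srv$X[, variable]
  if (anyNA(x_true)) {
    fl_stop("incomplete_target",
            "variable '%s' has missing values; reconstruct from a complete-case load",
            variable)
  }
  n <- length(x_true)
  if (!inherits(probes, "probe_matrix")) probes <- probe_matrix(probes)
  if (nrow(probes$Y) != n) {
    fl_stop("shape_mismatch", "probe matrix is %d x %d but server '%s' holds %d observations",
            nrow(probes$Y), ncol(probes$Y), server_id, n)
  }
  if (is.null(probe_name)) {
    fed$probe_counter <- fed$probe_counter + 1L
    probe_name <- sprintf(".probe%d", fed$probe_counter)
    broadcast(fed, server_id, probe_name, probes$Y)
  } else if (is.null(fed$servers[[server_id]]$broadcast[[probe_name]])) {
    broadcast(fed, server_id, probe_name, probes$Y)
  }
  A <- t(probes$Y)
  qrA <- qr(A)
  if (qrA$rank < n) fl_stop("singular_probe", "probe system is rank deficient")
  list(srv = srv, x_true = x_true, n = n, probes = probes,
       probe_name = probe_name, A = A, qrA = qrA, mt = colMeans(probes$Y))
}

# One pass of covariance collection + solve; `ctx` from attack_context().
attack_once <- function(fed, server_id, variable, ctx, channel = "covariance") {
  n <- ctx$n
  Vt <- numeric(n)
  if (channel == "covariance") {
    for (i in seq_len(n)) {
      Vt[i] <- query_cov(fed, server_id, variable, sprintf("%s[%d]", ctx$probe_name, i))
    }
  } else {
    for (i in seq_len(n)) {
      beta <- query_regression_coefficient(fed, server_id, variable,
                                           sprintf("%s[%d]", ctx$probe_name, i))
      Vt[i] <- covariance_from_regression(beta, stats::var(ctx$probes$Y[, i]))
    }
  }
  mean_x <- query_mean(fed, server_id, variable)
  # The mean term n * Mean(x) * (Y')^{-1} mt collapses exactly to Mean(x) * 1,
  # since mt = Y' 1 / n; evaluating it that way avoids amplifying rounding of
  # the large n * Mean(x) * mt entries through the solve.
  x_hat <- solve_probe_system(ctx$qrA, ctx$A, (n - 1) * Vt) + mean_x
  list(x_hat = x_hat, V_tilde = Vt, mean_x = mean_x)
}

#' Reconstruct one private variable from summary-statistic queries
#'
#' Runs the covariance-based attack against one server: broadcasts the probe
#' matrix (unless `probe_name` names an existing broadcast), issues the `n_j`
#' covariance queries `Cov(x, y_i)` and one mean query `Mean(x)`, computes the
#' probe means client-side, and solves the resulting linear system. With
#' `channel = "regression"` the covariances are sourced from the linear-model
#' coefficient endpoint instead (`Cov = beta_hat * Var(y_i)`), demonstrating
#' the attack on platforms that expose only model fits.
#'
#' @param fed a [federation()].
#' @param server_id target server.
#' @param variable target column name.
#' @param probes a [probe_matrix()] (or plain matrix); generated from `seed`
#'   when omitted.
#' @param seed probe seed used when `probes` is missing.
#' @param probe_name reuse an already-broadcast probe matrix under this name.
#' @param channel `"covariance"` (default) or `"regression"`.
#' @return object of class `reconstruction_result`: `x_hat`, `V_tilde`,
#'   `m_tilde`, `mean_x`, `server_id`, `variable`, `n`, `probe_seed`,
#'   `channel` and `metrics` (max abs error, relative MSE, Pearson r against
#'   the server-side truth).
#' @export
reconstruct_variable <- function(fed, server_id, variable, probes = NULL,
                                 seed = NULL, probe_name = NULL,
                                 channel = c("covariance", "regression")) {
  channel <- match.arg(channel)
  if (is.null(probes)) {
    if (is.null(seed)) fl_stop("invalid_parameter", "either probes or seed must be given")
    srv <- fed_server(fed, server_id)
    probes <- generate_probes(nrow(srv$X), seed)
  }
  ctx <- attack_context(fed, server_id, variable, probes, probe_name)
  run <- attack_once(fed, server_id, variable, ctx, channel)
  new_reconstruction_result(run, ctx, server_id, variable, channel)
}

new_reconstruction_result <- function(run, ctx, server_id, variable, channel,
                                      extra = list()) {
  res <- c(list(x_hat = run$x_hat, V_tilde = run$V_tilde, m_tilde = ctx$mt,
                mean_x = run$mean_x, server_id = server_id, variable = variable,
                n = ctx$n, probe_seed = ctx$probes$seed, channel = channel,
                metrics = reconstruction_metrics(ctx$x_true, run$x_hat)),
           extra)
  structure(res, class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %s/%s (n=%d, channel=%s)\n",
              x$server_id, x$variable, x$n, x$channel))
  cat(sprintf("  max abs error %.3g, relative MSE %.3g, Pearson r %.10f\n",
              x$metrics$max_abs_error, x$metrics$rel_mse, x$metrics$pearson_r))
  invisible(x)
}

#' Client-side covariance from a regression coefficient
#'
#' The model-fit side channel: given `beta_hat = Cov(x, y) / Var(y)` and the
#' client-known `Var(y)`, returns `Cov(x, y) = beta_hat * Var(y)`.
#'
#' @param beta_hat returned coefficient.
#' @param var_y sample variance of the client-known probe; must be > 0.
#' @return the implied covariance.
#' @export
covariance_from_regression <- function(beta_hat, var_y) {
  if (!is.numeric(var_y) || var_y <= 0) {
    fl_stop("degenerate_probe", "probe variance must be > 0, got %s", format(var_y))
  }
  beta_hat * var_y
}

#' Sweep the attack over every server and variable
#'
#' Reuses one probe matrix (and one broadcast) per server when
#' `probe_reuse = TRUE`; variables refused by the disclosure policy are
#' recorded, not fatal.
#'
#' @param fed a [federation()].
#' @param probe_reuse reuse probes across a server's variables (default TRUE).
#' @param seed base seed for probe generation.
#' @param channel passed to [reconstruct_variable()].
#' @return object of class `attack_report`: `results` (list of
#'   `reconstruction_result`), `summary` (one row per server/variable with
#'   error metrics or refusal reason), `refusals`.
#' @export
reconstruct_all <- function(fed, probe_reuse = TRUE, seed = 1L,
                            channel = c("covariance", "regression")) {
  channel <- match.arg(channel)
  results <- list()
  rows <- list()
  for (sid in names(fed$servers)) {
    srv <- fed$servers[[sid]]
    n <- nrow(srv$X)
    probes <- NULL
    pname <- NULL
    if (probe_reuse) {
      probes <- generate_probes(n, sub_seed(seed, match(sid, names(fed$servers))))
      pname <- paste0(".sweep_", sid)
    }
    for (v in colnames(srv$X)) {
      row <- data.frame(server_id = sid, variable = v, n = n, refused = FALSE,
                        reason = NA_character_, max_abs_error = NA_real_,
                        rel_mse = NA_real_, pearson_r = NA_real_,
                        stringsAsFactors = FALSE)
      res <- tryCatch(
        reconstruct_variable(fed, sid, v,
                             probes = if (probe_reuse) probes else NULL,
                             seed = if (probe_reuse) NULL else
                               sub_seed(seed, 1000L + length(rows)),
                             probe_name = pname, channel = channel),
        disclosure_refused = function(e) e,
        incomplete_target = function(e) e
      )
      if (inherits(res, "reconstruction_result")) {
        results[[paste(sid, v, sep = "/")]] <- res
        row$max_abs_error <- res$metrics$max_abs_error
        row$rel_mse <- res$metrics$rel_mse
        row$pearson_r <- res$metrics$pearson_r
      } else {
        row$refused <- TRUE
        row$reason <- conditionMessage(res)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  summary <- do.call(rbind, rows)
  structure(list(results = results, summary = summary,
                 refusals = summary[summary$refused, , drop = FALSE]),
            class = "attack_report")
}

#' @export
print.attack_report <- function(x, ...) {
  ok <- !x$summary$refused
  cat(sprintf("<attack_report> %d variable(s) reconstructed, %d refused\n",
              sum(ok), sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  worst max abs error %.3g, worst Pearson r %.10f\n",
                max(x$summary$max_abs_error[ok]), min(x$summary$pearson_r[ok])))
  }
  invisible(x)
}
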