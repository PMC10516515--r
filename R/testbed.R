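# Mock federated infrastructure: data-owner servers exposing only sample
# means, sample covariances and a client-to-server broadcast, under
# disclosure-control rules, optional additive output noise and an optional
# differential-privacy accountant. Everything is in-process; there is no
# networking. The federation object is an environment so that the query log,
# broadcast store and accountant mutate in place, as a real server would.

#' One data owner's dataset
#'
#' Wraps a numeric matrix `X` (rows = observations, columns = variables)
#' together with per-variable metadata. A variable is classified as
#' dichotomous iff it takes exactly two distinct non-missing values; the
#' classification can be overridden with `kinds`.
#'
#' @param X numeric matrix or data frame; must have column names.
#' @param server_id identifier string.
#' @param kinds optional character vector (`"continuous"`/`"dichotomous"`),
#'   one per column; defaults to automatic detection.
#' @return an object of class `server_dataset`.
#' @export
server_dataset <- function(X, server_id = "server1", kinds = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L || ncol(X) < 1L) {
    fl_stop("spec_invalid", "server dataset must have at least one row and one column")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  }
  detected <- vapply(seq_len(ncol(X)), function(j) {
    if (n_distinct_finite(X[, j]) == 2L) "dichotomous" else "continuous"
  }, character(1))
  if (is.null(kinds)) {
    kinds <- detected
  } else {
    if (length(kinds) != ncol(X) || !all(kinds %in% c("continuous", "dichotomous"))) {
      fl_stop("spec_invalid", "kinds must be one of continuous/dichotomous per column")
    }
    bad <- which(kinds == "dichotomous" & detected != "dichotomous")
    if (length(bad)) {
      fl_stop("spec_invalid",
              "column(s) %s declared dichotomous but do not take exactly two distinct values",
              paste(colnames(X)[bad], collapse = ", "))
    }
  }
  structure(
    list(server_id = server_id,
         X = X,
         variables = data.frame(name = colnames(X), kind = kinds,
                                stringsAsFactors = FALSE),
         broadcast = list()),
    class = "server_dataset"
  )
}

n_distinct_finite <- function(v) length(unique(v[!is.na(v)]))

#' @export
print.server_dataset <- function(x, ...) {
  cat(sprintf("<server_dataset '%s'> %d observations x %d variables (%d dichotomous)\n",
              x$server_id, nrow(x$X), ncol(x$X),
              sum(x$variables$kind == "dichotomous")))
  invisible(x)
}

#' Disclosure-control policy for summary-statistic endpoints
#'
#' Mirrors the answer rules of DataSHIELD-style platforms: a mean is released
#' only when the (complete-case) sample size strictly exceeds `mean_min_n`, a
#' covariance only when it strictly exceeds `cov_min_n` (C1), and any
#' dichotomous vector involved in a release must have each of its two levels
#' occurring at least `dichotomous_min_level_count` times (C2). With
#' `enabled = FALSE` every check passes.
#'
#' @param mean_min_n sample size that must be exceeded for a mean (default 3).
#' @param cov_min_n sample size that must be exceeded for a covariance
#'   (default 6).
#' @param dichotomous_min_level_count minimum per-level count (default 3).
#' @param enabled logical.
#' @return object of class `disclosure_policy`.
#' @export
disclosure_policy <- function(mean_min_n = 3L, cov_min_n = 6L,
                              dichotomous_min_level_count = 3L,
                              enabled = TRUE) {
  if (any(c(mean_min_n, cov_min_n, dichotomous_min_level_count) < 0)) {
    fl_stop("invalid_parameter", "disclosure thresholds must be >= 0")
  }
  structure(list(mean_min_n = as.integer(mean_min_n),
                 cov_min_n = as.integer(cov_min_n),
                 dichotomous_min_level_count = as.integer(dichotomous_min_level_count),
                 enabled = isTRUE(enabled)),
            class = "disclosure_policy")
}

#' Additive output-noise policy
#'
#' Zero-mean noise added server-side to every released mean (`mean_noise_sd`)
#' and covariance (`cov_noise_sd`), parameterized by standard deviation for
#' both supported distributions. For `distribution = "laplace"` the scale is
#' `sd / sqrt(2)` so the variance is `sd^2` in both cases. `sd = 0` reproduces
#' noiseless answers bit-for-bit (no RNG draw is consumed). When `rng_seed` is
#' given, the federation keeps a private RNG stream for noise so that endpoint
#' noise is reproducible independently of client-side randomness.
#'
#' @param mean_noise_sd,cov_noise_sd nonnegative standard deviations.
#' @param distribution `"gaussian"` (noise-robustness experiments) or
#'   `"laplace"` (required by the differential-privacy accountant).
#' @param rng_seed optional integer seed for a dedicated noise stream.
#' @return object of class `noise_policy`.
#' @export
noise_policy <- function(mean_noise_sd = 0, cov_noise_sd = 0,
                         distribution = c("gaussian", "laplace"),
                         rng_seed = NULL) {
  distribution <- match.arg(distribution)
  if (mean_noise_sd < 0 || cov_noise_sd < 0) {
    fl_stop("invalid_parameter", "noise standard deviations must be >= 0")
  }
  structure(list(mean_noise_sd = mean_noise_sd,
                 cov_noise_sd = cov_noise_sd,
                 distribution = distribution,
                 rng_seed = rng_seed),
            class = "noise_policy")
}

#' Assemble an in-process federation
#'
#' @param servers a `server_dataset` or list of them.
#' @param policy a [disclosure_policy()].
#' @param noise a [noise_policy()].
#' @param accountant optional [privacy_accountant()]; when set, every release
#'   computed on private data is charged epsilon before being answered and the
#'   noise policy must be Laplace with positive sd.
#' @param log_queries keep a full per-query transcript (default TRUE).
#' @return an environment of class `federation`.
#' @export
federation <- function(servers, policy = disclosure_policy(),
                       noise = noise_policy(), accountant = NULL,
                       log_queries = TRUE) {
  if (inherits(servers, "server_dataset")) servers <- list(servers)
  if (!length(servers) || !all(vapply(servers, inherits, logical(1), "server_dataset"))) {
    fl_stop("spec_invalid", "servers must be server_dataset objects")
  }
  names(servers) <- vapply(servers, `[[`, character(1), "server_id")
  if (anyDuplicated(names(servers))) {
    fl_stop("spec_invalid", "duplicate server_id in federation")
  }
  fed <- new.env(parent = emptyenv())
  fed$servers <- servers
  fed$policy <- policy
  fed$noise <- noise
  fed$accountant <- accountant
  fed$log_enabled <- isTRUE(log_queries)
  fed$log <- new.env(parent = emptyenv())
  fed$log$records <- vector("list", 64L)
  fed$log$n <- 0L
  fed$truth <- list()
  fed$probe_counter <- 0L
  fed$trace_noise <- FALSE
  fed$noise_trace <- list()
  fed$noise_rng <- NULL
  if (!is.null(noise$rng_seed)) {
    fed$noise_rng <- with_seed(noise$rng_seed, get(".Random.seed", envir = globalenv()))
  }
  class(fed) <- "federation"
  fed
}

#' @export
print.federation <- function(x, ...) {
  ns <- vapply(x$servers, function(s) nrow(s$X), integer(1))
  cat(sprintf("<federation> %d server(s): %s\n", length(x$servers),
              paste(sprintf("%s (n=%d)", names(x$servers), ns), collapse = ", ")))
  cat(sprintf("  disclosure checks %s; noise sd (mean %g, cov %g, %s); accountant %s; %d logged queries\n",
              if (x$policy$enabled) "on" else "off",
              x$noise$mean_noise_sd, x$noise$cov_noise_sd, x$noise$distribution,
              if (is.null(x$accountant)) "none" else
                sprintf("eps %.4g/%.4g", x$accountant$consumed, x$accountant$total_budget),
              x$log$n))
  invisible(x)
}

#' Access one server of a federation
#' @param fed a [federation()].
#' @param server_id identifier.
#' @return the `server_dataset`.
#' @export
fed_server <- function(fed, server_id) {
  srv <- fed$servers[[server_id]]
  if (is.null(srv)) fl_stop("unknown_variable", "no server '%s' in federation", server_id)
  srv
}

# Resolve a vector reference on a server: a data column by name, or a
# broadcast column as "name[i]" (or "name" for single-column broadcasts).
# Broadcast vectors are client-known, hence flagged public.
resolve_vector <- function(server, ref) {
  if (ref %in% colnames(server$X)) {
    return(list(values = server$X[, ref], probe = FALSE, name = ref))
  }
  m <- regmatches(ref, regexec("^(.+)\\[([0-9]+)\\]$", ref))[[1]]
  if (length(m) == 3L) {
    B <- server$broadcast[[m[2]]]
    i <- as.integer(m[3])
    if (!is.null(B) && i >= 1L && i <= ncol(B)) {
      return(list(values = B[, i], probe = TRUE, name = ref))
    }
  }
  B <- server$broadcast[[ref]]
  if (!is.null(B) && ncol(B) == 1L) {
    return(list(values = B[, 1], probe = TRUE, name = ref))
  }
  fl_stop("unknown_variable", "no variable or broadcast vector '%s' on server '%s'",
          ref, server$server_id)
}

# --- query transcript ------------------------------------------------------

log_query <- function(fed, server_id, endpoint, args, eps = 0, status = "ok") {
  if (!fed$log_enabled) return(invisible(NULL))
  lg <- fed$log
  lg$n <- lg$n + 1L
  if (lg$n > length(lg$records)) length(lg$records) <- 2L * length(lg$records)
  lg$records[[lg$n]] <- list(server_id = server_id, endpoint = endpoint,
                             args = args, eps = eps, status = status)
  invisible(NULL)
}

#' The append-only query log of a federation
#'
#' One record per endpoint call (including refused calls, with
#' `status != "ok"`), supporting query-count audits: a full single-variable
#' attack must show exactly `n_j` covariance queries plus one mean query.
#'
#' @param fed a [federation()].
#' @return data frame with columns `server_id`, `endpoint`, `args`, `eps`,
#'   `status`.
#' @export
query_log <- function(fed) {
  recs <- fed$log$records[seq_len(fed$log$n)]
  data.frame(
    server_id = vapply(recs, `[[`, character(1), "server_id"),
    endpoint = vapply(recs, `[[`, character(1), "endpoint"),
    args = vapply(recs, `[[`, character(1), "args"),
    eps = vapply(recs, `[[`, numeric(1), "eps"),
    status = vapply(recs, `[[`, character(1), "status"),
    stringsAsFactors = FALSE
  )
}

#' Export the query log as JSON lines
#' @param fed a [federation()].
#' @param path output file; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_query_log <- function(fed, path) {
  recs <- fed$log$records[seq_len(fed$log$n)]
  lines <- vapply(recs, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Reset the query transcript
#' @param fed a [federation()].
#' @export
clear_query_log <- function(fed) {
  fed$log$records <- vector("list", 64L)
  fed$log$n <- 0L
  invisible(fed)
}

# --- disclosure checks -----------------------------------------------------

# C2: any dichotomous vector must have each level at least k times.
passes_c2 <- function(v, policy) {
  v <- v[!is.na(v)]
  u <- unique(v)
  if (length(u) != 2L) return(TRUE)
  min(tabulate(match(v, u))) >= policy$dichotomous_min_level_count
}

check_mean_disclosure <- function(v, policy) {
  if (!policy$enabled) return(invisible(TRUE))
  n <- sum(!is.na(v))
  if (n <= policy$mean_min_n) {
    fl_stop("disclosure_refused",
            "mean refused: sample size %d does not exceed threshold %d", n, policy$mean_min_n)
  }
  if (!passes_c2(v, policy)) {
    fl_stop("disclosure_refused",
            "mean refused: a dichotomous level occurs fewer than %d times",
            policy$dichotomous_min_level_count)
  }
  invisible(TRUE)
}

check_cov_disclosure <- function(a, b, n, policy) {
  if (!policy$enabled) return(invisible(TRUE))
  if (n <= policy$cov_min_n) {
    fl_stop("disclosure_refused",
            "covariance refused: sample size %d does not exceed threshold %d",
            n, policy$cov_min_n)
  }
  if (!passes_c2(a, policy) || !passes_c2(b, policy)) {
    fl_stop("disclosure_refused",
            "covariance refused: a dichotomous level occurs fewer than %d times",
            policy$dichotomous_min_level_count)
  }
  invisible(TRUE)
}

# --- server-side noise -----------------------------------------------------

draw_noise <- function(fed, sd) {
  if (is.null(sd) || sd <= 0) return(0)
  swap <- !is.null(fed$noise_rng)
  if (swap) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    saved <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", fed$noise_rng, envir = globalenv())
  }
  x <- if (fed$noise$distribution == "laplace") {
    rlaplace(1L, scale = sd / sqrt(2))
  } else {
    stats::rnorm(1L, mean = 0, sd = sd)
  }
  if (swap) {
    fed$noise_rng <- get(".Random.seed", envir = globalenv())
    if (is.null(saved)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", saved, envir = globalenv())
    }
  }
  if (fed$trace_noise) fed$noise_trace[[length(fed$noise_trace) + 1L]] <- x
  x
}

# Charge the accountant for a release on private data; returns eps (0 when no
# accountant or the release involves only client-known broadcast vectors).
charge_if_accounted <- function(fed, server_id, query, sensitivity, private) {
  if (is.null(fed$accountant) || !private) return(0)
  sd <- if (startsWith(query, "mean")) fed$noise$mean_noise_sd else fed$noise$cov_noise_sd
  if (fed$noise$distribution != "laplace" || sd <= 0) {
    fl_stop("invalid_parameter",
            "the privacy accountant requires Laplace output noise with positive sd")
  }
  acct_charge(fed$accountant, query, sensitivity, sd / sqrt(2))
}

# --- endpoints -------------------------------------------------------------

#' Server endpoint: sample mean
#'
#' Returns the arithmetic mean of the referenced vector over its complete
#' cases, plus one zero-mean noise draw with sd `mean_noise_sd`. The call is
#' appended to the query log. Refused (error class `disclosure_refused`) when
#' the complete-case sample size does not exceed the policy's `mean_min_n`, or
#' a dichotomous level occurs fewer than `dichotomous_min_level_count` times.
#'
#' @param fed a [federation()].
#' @param server_id server identifier.
#' @param ref a data column name or broadcast reference (`"name[i]"`).
#' @param policy,noise overrides of the federation's policies (rarely needed).
#' @return the (possibly noisy) sample mean, a single number.
#' @export
query_mean <- function(fed, server_id, ref, policy = fed$policy, noise = fed$noise) {
  srv <- fed_server(fed, server_id)
  rv <- resolve_vector(srv, ref)
  v <- rv$values[!is.na(rv$values)]
  refuse <- function(e) {
    log_query(fed, server_id, "mean", ref, status = class(e)[1])
    stop(e)
  }
  tryCatch({
    check_mean_disclosure(rv$values, policy)
    eps <- charge_if_accounted(fed, server_id, paste0("mean(", ref, ")"),
                               mean_sensitivity(clip_width_for(fed, rv), length(v)),
                               private = !rv$probe)
    value <- mean(v) + draw_noise_with(fed, noise, noise$mean_noise_sd)
    log_query(fed, server_id, "mean", ref, eps = eps)
    value
  }, covleak_error = refuse)
}

#' Server endpoint: sample covariance
#'
#' Returns the sample covariance (denominator `n - 1`) of the two referenced
#' vectors over their listwise complete cases, plus one zero-mean noise draw
#' with sd `cov_noise_sd`. Both vectors must pass the disclosure checks (C1
#' with `cov_min_n`, C2 for dichotomous vectors).
#'
#' @inheritParams query_mean
#' @param ref_a,ref_b vector references (data columns or broadcast vectors).
#' @return the (possibly noisy) sample covariance, a single number.
#' @export
query_cov <- function(fed, server_id, ref_a, ref_b, policy = fed$policy, noise = fed$noise) {
  srv <- fed_server(fed, server_id)
  ra <- resolve_vector(srv, ref_a)
  rb <- resolve_vector(srv, ref_b)
  if (length(ra$values) != length(rb$values)) {
    fl_stop("length_mismatch", "vectors '%s' (%d) and '%s' (%d) differ in length",
            ref_a, length(ra$values), ref_b, length(rb$values))
  }
  ok <- !is.na(ra$values) & !is.na(rb$values)
  a <- ra$values[ok]
  b <- rb$values[ok]
  args <- paste0(ref_a, ",", ref_b)
  refuse <- function(e) {
    log_query(fed, server_id, "cov", args, status = class(e)[1])
    stop(e)
  }
  tryCatch({
    check_cov_disclosure(a, b, length(a), policy)
    eps <- charge_if_accounted(fed, server_id, paste0("cov(", args, ")"),
                               cov_release_sensitivity(fed, ra, rb, a, b),
                               private = !(ra$probe && rb$probe))
    value <- stats::cov(a, b) + draw_noise_with(fed, noise, noise$cov_noise_sd)
    log_query(fed, server_id, "cov", args, eps = eps)
    value
  }, covleak_error = refuse)
}

# Honor an endpoint-level noise override while keeping the federation's
# distribution/stream machinery.
draw_noise_with <- function(fed, noise, sd) {
  if (identical(noise, fed$noise)) return(draw_noise(fed, sd))
  old <- fed$noise
  fed$noise <- noise
  on.exit(fed$noise <- old)
  draw_noise(fed, sd)
}

#' Server endpoint: broadcast a client matrix
#'
#' Installs the columns of a client-known matrix `M` as addressable
#' server-side vectors under `name[i]`; the identical matrix stays
#' client-known. This is the client-to-server transfer (e.g. `ds.dmtC2S` in
#' DataSHIELD, `federated_broadcast` in TensorFlow Federated) that makes the
#' probe-based attack possible.
#'
#' @inheritParams query_mean
#' @param name identifier under which columns are addressable.
#' @param M numeric matrix with `n_j` rows.
#' @return `name`, invisibly.
#' @export
broadcast <- function(fed, server_id, name, M) {
  srv <- fed_server(fed, server_id)
  M <- as.matrix(M)
  if (nrow(M) != nrow(srv$X)) {
    fl_stop("shape_mismatch", "broadcast matrix has %d rows but server '%s' holds %d observations",
            nrow(M), server_id, nrow(srv$X))
  }
  fed$servers[[server_id]]$broadcast[[name]] <- M
  log_query(fed, server_id, "broadcast", sprintf("%s[%dx%d]", name, nrow(M), ncol(M)))
  invisible(name)
}

#' Server endpoint: simple linear-model coefficient
#'
#' Fits `x = y beta + e` server-side and returns
#' `beta_hat = Cov(x, y) / Var(y)`. On platforms that expose only model fits
#' (not covariances), this is the side channel from which the client recovers
#' `Cov(x, y) = beta_hat * Var(y)` because `y` is client-known. Computed on
#' listwise complete cases; errors with class `degenerate_probe` when
#' `Var(y) = 0`.
#'
#' @inheritParams query_mean
#' @param response_ref data column name (the private variable).
#' @param probe_ref broadcast-vector reference (the client-known regressor).
#' @return `beta_hat`, a single number.
#' @export
query_regression_coefficient <- function(fed, server_id, response_ref, probe_ref) {
  srv <- fed_server(fed, server_id)
  rx <- resolve_vector(srv, response_ref)
  ry <- resolve_vector(srv, probe_ref)
  if (length(rx$values) != length(ry$values)) {
    fl_stop("length_mismatch", "response and probe differ in length")
  }
  ok <- !is.na(rx$values) & !is.na(ry$values)
  x <- rx$values[ok]
  y <- ry$values[ok]
  if (length(x) < 2L) {
    fl_stop("invalid_parameter", "regression requires at least 2 complete cases")
  }
  vy <- stats::var(y)
  if (vy == 0) {
    log_query(fed, server_id, "regression", paste0(response_ref, "~", probe_ref),
              status = "degenerate_probe")
    fl_stop("degenerate_probe", "probe '%s' has zero sample variance", probe_ref)
  }
  eps <- charge_if_accounted(fed, server_id,
                             paste0("beta(", response_ref, "~", probe_ref, ")"),
                             cov_release_sensitivity(fed, rx, ry, x, y) / vy,
                             private = !rx$probe)
  value <- stats::cov(x, y) / vy
  log_query(fed, server_id, "regression", paste0(response_ref, "~", probe_ref), eps = eps)
  value
}

# Sensitivity of a covariance release, depending on which inputs are private.
cov_release_sensitivity <- function(fed, ra, rb, a, b) {
  if (is.null(fed$accountant)) return(0)
  n <- length(a)
  if (ra$probe && rb$probe) return(0)
  if (!ra$probe && !rb$probe) {
    return(cov_sensitivity(clip_width_for(fed, ra), clip_width_for(fed, rb), n))
  }
  if (ra$probe) {
    probe_cov_sensitivity(clip_width_for(fed, rb), a)
  } else {
    probe_cov_sensitivity(clip_width_for(fed, ra), b)
  }
}

clip_width_for <- function(fed, rv) {
  if (is.null(fed$accountant) || rv$probe) return(0)
  bounds <- fed$accountant$clip_bounds[[rv$name]]
  if (is.null(bounds)) {
    fl_stop("invalid_parameter", "no clip bounds configured for variable '%s'", rv$name)
  }
  diff(range(bounds))
}
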