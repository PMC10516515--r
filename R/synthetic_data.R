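# CNSIM-like synthetic federations: 3 servers, 11 obesity-related variables
# (5 continuous "metric" lab/anthropometric columns, 6 dichotomous columns),
# optional MCAR missingness. The generator mimics only the structure of the
# DataSHIELD tutorial federation; distribution parameters are this package's
# own choices and are fully configurable.

#' Default CNSIM-like variable table
#'
#' Five continuous variables (BMI-like and lab-like normals, clipped to
#' plausible ranges) and six dichotomous variables with fixed prevalences.
#'
#' @return data frame with columns `name`, `kind`, `mean`, `sd`, `lower`,
#'   `upper`, `prob`.
#' @export
cnsim_like_variables <- function() {
  data.frame(
    name = c("bmi", "chol_total", "triglycerides", "hdl", "glucose",
             "gender", "diabetes", "stroke", "mi", "lipid_med", "smoker"),
    kind = c(rep("continuous", 5), rep("dichotomous", 6)),
    mean = c(27, 5.9, 1.7, 1.5, 5.4, rep(NA, 6)),
    sd = c(4, 1.1, 0.9, 0.4, 1.2, rep(NA, 6)),
    lower = c(15, 2, 0.3, 0.3, 2, rep(NA, 6)),
    upper = c(50, 12, 10, 3.5, 15, rep(NA, 6)),
    prob = c(rep(NA, 5), 0.49, 0.06, 0.04, 0.05, 0.12, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic federation
#'
#' Defaults emulate the structure of the CNSIM demonstration federation:
#' three servers totalling 9379 observations of 11 variables.
#'
#' @param n_servers number of servers (default 3).
#' @param n_per_server integer vector of per-server sample sizes.
#' @param variables variable table as in [cnsim_like_variables()].
#' @param missingness_rate MCAR cell-missingness probability in `[0, 1)`.
#' @param seed integer seed; the same spec generates an identical federation.
#' @return object of class `federation_spec`.
#' @export
federation_spec <- function(n_servers = 3L,
                            n_per_server = c(2163L, 3088L, 4128L),
                            variables = cnsim_like_variables(),
                            missingness_rate = 0, seed = 1L) {
  if (n_servers < 1L || length(n_per_server) != n_servers || any(n_per_server < 1L)) {
    fl_stop("spec_invalid", "n_per_server must give a positive size for each of %d servers",
            n_servers)
  }
  need <- c("name", "kind")
  if (!is.data.frame(variables) || !all(need %in% names(variables)) ||
      !all(variables$kind %in% c("continuous", "dichotomous"))) {
    fl_stop("spec_invalid", "variables must be a data frame with name and kind columns")
  }
  if (missingness_rate < 0 || missingness_rate >= 1) {
    fl_stop("spec_invalid", "missingness_rate must be in [0, 1)")
  }
  structure(list(n_servers = as.integer(n_servers),
                 n_per_server = as.integer(n_per_server),
                 variables = variables,
                 missingness_rate = missingness_rate,
                 seed = as.integer(seed)),
            class = "federation_spec")
}

draw_column <- function(v, n) {
  if (v$kind == "continuous") {
    pmin(pmax(stats::rnorm(n, v$mean, v$sd), v$lower), v$upper)
  } else {
    x <- stats::rbinom(n, 1L, v$prob)
    # guarantee the C2 disclosure condition (each level >= 3) by construction
    # whenever the sample size permits
    if (n >= 6L) {
      for (level in c(0, 1)) {
        short <- 3L - sum(x == level)
        if (short > 0L) {
          pool <- which(x != level)
          x[pool[sample.int(length(pool), short)]] <- level
        }
      }
    }
    as.numeric(x)
  }
}

#' Generate a synthetic federation
#'
#' Draws every server's data matrix from the spec (continuous columns from
#' clipped normals, dichotomous columns Bernoulli with each level forced to
#' occur at least three times when `n_j >= 6`), keeps the complete matrices
#' as ground truth, then injects MCAR missingness into the served copies.
#' Optionally writes one CSV per server (empty cell = missing), one
#' ground-truth CSV per server and a JSON spec echo to `dir`.
#'
#' @param spec a [federation_spec()].
#' @param dir optional output directory for CSV/JSON artifacts.
#' @param policy,noise,accountant passed to [federation()].
#' @return a [federation()] whose `truth` field holds the per-server
#'   ground-truth matrices.
#' @export
generate_federation <- function(spec, dir = NULL, policy = disclosure_policy(),
                                noise = noise_policy(), accountant = NULL) {
  if (!inherits(spec, "federation_spec")) fl_stop("spec_invalid", "spec must be a federation_spec")
  vars <- spec$variables
  out <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_servers), function(j) {
      n <- spec$n_per_server[j]
      X <- vapply(seq_len(nrow(vars)), function(k) draw_column(vars[k, ], n),
                  numeric(n))
      X <- matrix(X, nrow = n, dimnames = list(NULL, vars$name))
      truth <- X
      if (spec$missingness_rate > 0) {
        mask <- matrix(stats::runif(length(X)) < spec$missingness_rate,
                       nrow = n)
        X[mask] <- NA_real_
      }
      list(X = X, truth = truth)
    })
  })
  ids <- sprintf("server%d", seq_len(spec$n_servers))
  servers <- lapply(seq_along(out), function(j) {
    server_dataset(out[[j]]$X, server_id = ids[j])
  })
  fed <- federation(servers, policy = policy, noise = noise, accountant = accountant)
  fed$truth <- stats::setNames(lapply(out, `[[`, "truth"), ids)
  if (!is.null(dir)) write_federation_csv(fed, dir, spec)
  fed
}

#' Write a federation's data, ground truth and spec echo to disk
#'
#' @param fed a [federation()] as returned by [generate_federation()].
#' @param dir output directory (created if needed).
#' @param spec the generating [federation_spec()], echoed as JSON.
#' @return character vector of the data CSV paths, invisibly.
#' @export
write_federation_csv <- function(fed, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(fed$servers), function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    utils::write.csv(as.data.frame(fed$servers[[id]]$X), p,
                     row.names = FALSE, na = "")
    truth <- fed$truth[[id]]
    if (!is.null(truth)) {
      utils::write.csv(as.data.frame(truth),
                       file.path(dir, paste0(id, "_truth.csv")),
                       row.names = FALSE, na = "")
    }
    p
  }, character(1))
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(paths)
}

#' Load CNSIM-style CSV exports as server datasets
#'
#' Reads one CSV per server (header row, empty cell or `NA` = missing),
#' encodes non-numeric columns as 0-based integer level codes, and applies
#' listwise complete-case filtering on `complete_case_vars`. This is the
#' route for auditing the real CNSIM export of the DSData package, which the
#' user supplies; no data are bundled.
#'
#' @param paths character vector of CSV files, one per server.
#' @param complete_case_vars variables whose complete cases define the rows
#'   kept (empty: keep all rows).
#' @param server_ids identifiers, default file names without extension.
#' @return list of `server_dataset` objects (pass to [federation()]).
#' @export
load_cnsim_csv <- function(paths, complete_case_vars = character(),
                           server_ids = NULL) {
  if (is.null(server_ids)) {
    server_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  mapply(function(path, id) {
    if (!file.exists(path)) fl_stop("format_error", "file not found: %s", path)
    df <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
    if (!ncol(df) || is.null(names(df)) || any(names(df) == "")) {
      fl_stop("format_error", "%s has no usable header row", path)
    }
    missing_vars <- setdiff(complete_case_vars, names(df))
    if (length(missing_vars)) {
      fl_stop("format_error", "%s lacks column(s): %s", path,
              paste(missing_vars, collapse = ", "))
    }
    for (nm in names(df)) {
      if (!is.numeric(df[[nm]])) {
        df[[nm]] <- as.numeric(factor(df[[nm]])) - 1
      }
    }
    if (length(complete_case_vars)) {
      keep <- stats::complete.cases(df[, complete_case_vars, drop = FALSE])
      df <- df[keep, , drop = FALSE]
    }
    if (!nrow(df)) fl_stop("format_error", "%s: no rows left after complete-case filtering", path)
    server_dataset(as.matrix(df), server_id = id)
  }, paths, server_ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
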