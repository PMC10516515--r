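# Shared fixtures, built in code.

# A single-server federation holding the given columns (list of vectors).
make_fed <- function(..., server_id = "s1", policy = disclosure_policy(enabled = FALSE),
                     noise = noise_policy(), accountant = NULL) {
  cols <- list(...)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  federation(server_dataset(X, server_id = server_id),
             policy = policy, noise = noise, accountant = accountant)
}

# Independent textbook oracle for the sample covariance (direct formula,
# naive accumulation -- deliberately not stats::cov).
oracle_cov <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - mx) * (y[i] - my)
  s / (n - 1)
}

# Naively summed mean oracle.
oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

# One BMI-like continuous column as a 1-server federation of size n.
bmi_fed <- function(n, data_seed = 11, policy = disclosure_policy(),
                    noise = noise_policy()) {
  spec <- federation_spec(n_servers = 1, n_per_server = n,
                          variables = cnsim_like_variables()[1, , drop = FALSE],
                          seed = data_seed)
  generate_federation(spec, policy = policy, noise = noise)
}
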