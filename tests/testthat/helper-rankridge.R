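# Shared fixtures, built in code at test time.

# Centred design with n^{-1} X'X = I_p exactly (orthonormal-scaled): the
# closed forms for X(k) and R_n(k) hold exactly under it.
ortho_design <- function(n, p) {
  M <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  sqrt(n) * qr.Q(qr(M))[, seq_len(p), drop = FALSE]
}

# A small random regression instance (correlation-form design).
rand_instance <- function(n, p, gamma = 0.3, sd_noise = 0.5, beta = NULL,
                          seed = NULL) {
  X <- gen_design(n, p, gamma, seed = seed)
  if (is.null(beta)) beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = sd_noise)
  list(data = prepare_data(X, y, standardize = FALSE), beta = beta,
       X = X, y = y)
}

ls_coef <- function(data) {
  drop(data$v %*% (crossprod(data$u, data$y) / data$d))
}
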