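# Small numeric helpers shared by the VAE and GNN.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

log_sigmoid <- function(x) {
  # numerically safe log sigma(x), clamped away from -Inf
  log(pmax(sigmoid(x), 1e-9))
}

l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / ifelse(nrm > 0, nrm, 1)
}

cosine_distance_to <- function(m_unit, v_unit) {
  # m_unit: rows unit-norm; v_unit: unit vector -> 1 - cosine similarity
  1 - as.numeric(m_unit %*% v_unit)
}

# Glorot-uniform weight init, one matrix
glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -r, r), n_in, n_out)
}

# Adam optimizer over a named list of parameter matrices
adam_init <- function(params) {
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Derive stage-specific RNG seeds from one run seed, kept in 32-bit range
derive_seed <- function(seed, stage) {
  offsets <- c(vae = 101L, gnn = 211L, cluster = 307L, synth = 401L,
               sample = 503L)
  (as.integer(seed) * 7L + offsets[[stage]]) %% 2147483587L
}
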