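# Variational auto-encoder over contig composition + abundance features.
# Written directly in matrix algebra with hand-derived gradients and Adam;
# rows are observations throughout.

#' VAE hyper-parameters
#'
#' The reconstruction loss is split between the composition block and the
#' abundance block with weights 0.1 / 0.9, so the multi-sample abundance
#' signal dominates reconstruction. `kl_weight = NULL` defaults to
#' `1 / (4 * latent_dim)`, ramped linearly from 0 over the first 10% of
#' epochs; stronger KL pressure tends to collapse the weak many-dimension
#' composition signal before it is encoded.
#'
#' @param latent_dim Latent embedding dimension (default 32).
#' @param hidden_dims Encoder hidden layer widths (decoder mirrors them).
#' @param composition_weight,abundance_weight Reconstruction weights; must
#'   sum to 1.
#' @param kl_weight Weight of the KL term, or `NULL` for
#'   `1/(4*latent_dim)`.
#' @param epochs,batch_size,learning_rate Optimization settings.
#' @param seed RNG seed governing init, shuffling and reparameterization.
#' @return A `vae_config` list.
#' @export
vae_config <- function(latent_dim = 32, hidden_dims = c(512, 512),
                       composition_weight = 0.1, abundance_weight = 0.9,
                       kl_weight = NULL, epochs = 300, batch_size = 64,
                       learning_rate = 1e-3, seed = 1) {
  stopifnot(abs(composition_weight + abundance_weight - 1) < 1e-12,
            latent_dim > 0, all(hidden_dims > 0), epochs >= 0)
  structure(list(latent_dim = latent_dim, hidden_dims = hidden_dims,
                 composition_weight = composition_weight,
                 abundance_weight = abundance_weight,
                 kl_weight = kl_weight %||% 1 / (4 * latent_dim),
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed),
            class = "vae_config")
}

#' VAE loss with split reconstruction and closed-form KL
#'
#' `loss = w_c * MSE(composition block) + w_a * MSE(abundance block)
#'  + kl_weight * KL(N(mu, exp(logvar)) || N(0, I))`, where each MSE is the
#' mean squared error over the entries of its feature block and the KL term
#' is the closed form `-1/2 * sum(1 + logvar - mu^2 - exp(logvar))`,
#' averaged over observations.
#'
#' @param x,reconstruction Input and reconstructed feature matrices
#'   (observations x features).
#' @param mu,logvar Latent Gaussian parameters (observations x latent).
#' @param composition_cols,abundance_cols Column indices of the two blocks.
#' @param composition_weight,abundance_weight,kl_weight Loss weights.
#' @return List: `total`, `recon_composition`, `recon_abundance`, `kl`.
#' @export
vae_loss <- function(x, reconstruction, mu, logvar,
                     composition_cols, abundance_cols,
                     composition_weight = 0.1, abundance_weight = 0.9,
                     kl_weight = 1) {
  if (!all(is.finite(x)) || !all(is.finite(reconstruction)) ||
      !all(is.finite(mu)) || !all(is.finite(logvar)))
    abort("non-finite inputs to vae_loss")
  err <- reconstruction - x
  mse_c <- mean(err[, composition_cols, drop = FALSE]^2)
  mse_a <- mean(err[, abundance_cols, drop = FALSE]^2)
  kl <- mean(-0.5 * rowSums(1 + logvar - mu^2 - exp(logvar)))
  list(total = composition_weight * mse_c + abundance_weight * mse_a +
         kl_weight * kl,
       recon_composition = mse_c, recon_abundance = mse_a, kl = kl)
}

vae_init_params <- function(d_in, hidden, latent) {
  p <- list()
  dims <- c(d_in, hidden)
  for (i in seq_along(hidden)) {
    p[[paste0("enc_W", i)]] <- glorot(dims[i], dims[i + 1])
    p[[paste0("enc_b", i)]] <- matrix(0, 1, dims[i + 1])
  }
  last <- tail(dims, 1)
  p$W_mu <- glorot(last, latent);  p$b_mu <- matrix(0, 1, latent)
  p$W_lv <- glorot(last, latent);  p$b_lv <- matrix(0, 1, latent)
  ddims <- c(latent, rev(hidden))
  for (i in seq_along(hidden)) {
    p[[paste0("dec_W", i)]] <- glorot(ddims[i], ddims[i + 1])
    p[[paste0("dec_b", i)]] <- matrix(0, 1, ddims[i + 1])
  }
  p$W_out <- glorot(tail(ddims, 1), d_in); p$b_out <- matrix(0, 1, d_in)
  p
}

add_bias <- function(m, b) sweep(m, 2, as.numeric(b), "+")

vae_encode <- function(p, x, n_hidden) {
  hs <- list(x)
  h <- x
  for (i in seq_len(n_hidden)) {
    h <- relu(add_bias(h %*% p[[paste0("enc_W", i)]], p[[paste0("enc_b", i)]]))
    hs[[i + 1]] <- h
  }
  list(hs = hs,
       mu = add_bias(h %*% p$W_mu, p$b_mu),
       logvar = add_bias(h %*% p$W_lv, p$b_lv))
}

vae_decode <- function(p, z, n_hidden) {
  hs <- list(z)
  h <- z
  for (i in seq_len(n_hidden)) {
    h <- relu(add_bias(h %*% p[[paste0("dec_W", i)]], p[[paste0("dec_b", i)]]))
    hs[[i + 1]] <- h
  }
  list(hs = hs, xhat = add_bias(h %*% p$W_out, p$b_out))
}

#' Train the VAE and embed contigs
#'
#' Trains encoder and decoder jointly with Adam on mini-batches; the
#' embedding returned for each contig is the posterior mean `mu` (not a
#' sample), so downstream clustering is deterministic. Fully reproducible
#' under the config seed.
#'
#' @param features A `contig_features` object from [contig_features()].
#' @param config A [vae_config()].
#' @return A `vae_fit`: list with `embedding` (matrix contigs x latent,
#'   rownames = contig ids), `params`, `trace` (per-epoch loss tibble),
#'   `config`, `contig_ids`.
#' @export
train_vae <- function(features, config = vae_config()) {
  x <- features$features
  n <- nrow(x)
  stopifnot(n >= 1)
  set.seed(derive_seed(config$seed, "vae"))
  nh <- length(config$hidden_dims)
  p <- vae_init_params(ncol(x), config$hidden_dims, config$latent_dim)
  opt <- adam_init(p)
  bs <- min(config$batch_size, n)
  warmup <- max(1, floor(config$epochs * 0.1))
  cc <- features$composition_cols; ac <- features$abundance_cols
  wc <- config$composition_weight; wa <- config$abundance_weight

  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    klw <- config$kl_weight * min(1, epoch / warmup)
    idx <- sample.int(n)
    ep <- c(total = 0, recon_composition = 0, recon_abundance = 0, kl = 0)
    nb <- 0
    for (start in seq(1, n, by = bs)) {
      b <- idx[start:min(start + bs - 1, n)]
      xb <- x[b, , drop = FALSE]
      m <- nrow(xb)
      enc <- vae_encode(p, xb, nh)
      eps <- matrix(rnorm(m * config$latent_dim), m)
      sdv <- exp(0.5 * enc$logvar)
      z <- enc$mu + eps * sdv
      dec <- vae_decode(p, z, nh)
      ls <- vae_loss(xb, dec$xhat, enc$mu, enc$logvar, cc, ac, wc, wa, klw)
      if (!is.finite(ls$total))
        abort(sprintf("non-finite VAE loss at epoch %d (batch starting %d)",
                      epoch, start))
      g <- vae_gradients(p, xb, enc, dec, z, eps, sdv, cc, ac, wc, wa, klw, nh)
      upd <- adam_step(p, g, opt, config$learning_rate)
      p <- upd$params; opt <- upd$state
      ep <- ep + unlist(ls)[names(ep)]; nb <- nb + 1
    }
    trace[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep[["total"]] / nb,
      recon_composition = ep[["recon_composition"]] / nb,
      recon_abundance = ep[["recon_abundance"]] / nb, kl = ep[["kl"]] / nb)
  }

  emb <- vae_encode(p, x, nh)$mu
  rownames(emb) <- features$contig_ids
  structure(list(embedding = emb, params = p,
                 trace = dplyr::bind_rows(trace), config = config,
                 contig_ids = features$contig_ids),
            class = "vae_fit")
}

vae_gradients <- function(p, xb, enc, dec, z, eps, sdv, cc, ac, wc, wa, klw, nh) {
  m <- nrow(xb)
  g <- purrr::map(p, ~ .x * 0)
  # reconstruction gradient, block-weighted MSE
  dxhat <- dec$xhat - xb
  dxhat[, cc] <- dxhat[, cc] * (2 * wc / (m * length(cc)))
  dxhat[, ac] <- dxhat[, ac] * (2 * wa / (m * length(ac)))
  # decoder output layer
  hlast <- dec$hs[[nh + 1]]
  g$W_out <- t(hlast) %*% dxhat
  g$b_out <- matrix(colSums(dxhat), 1)
  dh <- dxhat %*% t(p$W_out)
  for (i in rev(seq_len(nh))) {
    dh <- dh * (dec$hs[[i + 1]] > 0)
    g[[paste0("dec_W", i)]] <- t(dec$hs[[i]]) %*% dh
    g[[paste0("dec_b", i)]] <- matrix(colSums(dh), 1)
    dh <- dh %*% t(p[[paste0("dec_W", i)]])
  }
  dz <- dh
  # KL gradients plus reparameterization path
  dmu <- dz + klw * enc$mu / m
  dlv <- dz * 0.5 * eps * sdv + klw * 0.5 * (exp(enc$logvar) - 1) / m
  henc <- enc$hs[[nh + 1]]
  g$W_mu <- t(henc) %*% dmu; g$b_mu <- matrix(colSums(dmu), 1)
  g$W_lv <- t(henc) %*% dlv; g$b_lv <- matrix(colSums(dlv), 1)
  dh <- dmu %*% t(p$W_mu) + dlv %*% t(p$W_lv)
  for (i in rev(seq_len(nh))) {
    dh <- dh * (enc$hs[[i + 1]] > 0)
    g[[paste0("enc_W", i)]] <- t(enc$hs[[i]]) %*% dh
    g[[paste0("enc_b", i)]] <- matrix(colSums(dh), 1)
    dh <- dh %*% t(p[[paste0("enc_W", i)]])
  }
  g
}

#' @export
print.vae_fit <- function(x, ...) {
  cat(sprintf("<vae_fit> %d contigs -> %d latent dims, %d epochs, final loss %.4g\n",
              nrow(x$embedding), ncol(x$embedding), nrow(x$trace),
              if (nrow(x$trace)) tail(x$trace$loss, 1) else NA))
  invisible(x)
}

#' @rdname tidy.gnn_fit
#' @method tidy vae_fit
#' @export
tidy.vae_fit <- function(x, ...) embedding_tibble(x$embedding, "vae")

#' @rdname glance.gnn_fit
#' @method glance vae_fit
#' @export
glance.vae_fit <- function(x, ...) {
  tibble::tibble(n_contigs = nrow(x$embedding), latent_dim = ncol(x$embedding),
                 epochs = nrow(x$trace),
                 final_loss = if (nrow(x$trace)) tail(x$trace$loss, 1) else NA_real_)
}

embedding_tibble <- function(emb, prefix) {
  colnames(emb) <- paste0(prefix, seq_len(ncol(emb)))
  dplyr::bind_cols(tibble::tibble(contig_id = rownames(emb)),
                   tibble::as_tibble(emb))
}
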