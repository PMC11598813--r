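# Training of the binarized network with the straight-through estimator
# (STE): real-valued latent weights are binarized (>0) in every forward
# pass, gradients are passed straight through the binarization inside the
# clip window, and latent weights are clipped to [-1, 1] after each Adam
# step. Batch norm uses batch statistics during training and tracked
# running statistics for inference and folding.

.bn_bwd <- function(x, dy, gamma, m, v, eps) {
  n <- length(x)
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - m) * inv
  dgamma <- sum(dy * xhat)
  dbeta <- sum(dy)
  dxhat <- dy * gamma
  dx <- inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.adam_step <- function(st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  st$x <- st$x - lr * mh / (sqrt(vh) + eps)
  st
}

.adam_init <- function(x) list(x = x, m = x * 0, v = x * 0, t = 0L)

.state_to_weights <- function(st, cfg, log = NULL) {
  bnify <- function(bn) data.frame(gamma = bn$gamma, beta = bn$beta,
                                   mu = bn$r_mu, sigma = sqrt(bn$r_var))
  .new_weights(cfg,
               conv1 = binarize(st$lc$x), dw = binarize(st$ldw$x),
               pw = binarize(st$lpw$x),
               bn_dsc = bnify(st$bn3), fc1 = binarize(st$l1$x),
               bn_fc1 = bnify(st$bn4), fc2 = binarize(st$l2$x),
               bn_fc2 = bnify(st$bn5), log = log)
}

.new_bn_state <- function(n) {
  # running stats are seeded from the first batch, then tracked with
  # momentum, so short trainings still fold with calibrated statistics
  list(gamma = rep(1, n), beta = rep(0, n), r_mu = rep(0, n),
       r_var = rep(1, n), seen = FALSE,
       g_m = rep(0, n), g_v = rep(0, n), b_m = rep(0, n), b_v = rep(0, n),
       t = 0L)
}

.bn_adam <- function(bn, dgamma, dbeta, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  bn$t <- bn$t + 1L
  bn$g_m <- b1 * bn$g_m + (1 - b1) * dgamma
  bn$g_v <- b2 * bn$g_v + (1 - b2) * dgamma^2
  bn$b_m <- b1 * bn$b_m + (1 - b1) * dbeta
  bn$b_v <- b2 * bn$b_v + (1 - b2) * dbeta^2
  corr1 <- 1 - b1^bn$t; corr2 <- 1 - b2^bn$t
  bn$gamma <- bn$gamma - lr * (bn$g_m / corr1) / (sqrt(bn$g_v / corr2) + eps)
  bn$beta <- bn$beta - lr * (bn$b_m / corr1) / (sqrt(bn$b_v / corr2) + eps)
  bn
}

.dataset_xy <- function(ds, cfg) {
  list(X = ds$images, RR = ds$rr_bits,
       y = match(ds$label, beat_classes()))
}

# cross-entropy and accuracy of the reference forward on a dataset
.eval_ref <- function(w, X, RR, y) {
  res <- .forward_ref_batch(X, RR, w)
  p <- res$scores[cbind(seq_along(y), y)]
  list(loss = -mean(log(pmax(p, 1e-12))), acc = mean(res$pred == y))
}

#' Train the binarized network
#'
#' Straight-through-estimator training of the full model: latent real
#' weights binarized (threshold 0) in each forward pass, gradients passed
#' through the binarization inside the unit clip window, latents clipped to
#' `[-1, 1]`; Adam with a cosine learning-rate decay from `lr_start` to
#' `lr_end`; cross-entropy loss on the softmax output; early stopping on
#' validation loss with the given patience, restoring the best weights.
#' Batch-norm layers sit after the separable convolution and both fully
#' connected layers (the first convolution has none -- its activation
#' threshold is exactly 0, which is what licenses the merged
#' convolution-pooling rewrite at deployment).
#'
#' @param train_set,val_set `beat_dataset` objects (see [build_dataset()]).
#' @param cfg A `bdscnn_config`.
#' @param rng_seed Integer seed controlling initialization and shuffling.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param lr_start,lr_end Cosine-decayed learning-rate endpoints.
#' @param verbose Print per-epoch progress.
#' @return A `bdscnn_weights` object whose `log` field is a data frame with
#'   per-epoch training loss and validation loss/accuracy.
#' @export
train_bdscnn <- function(train_set, val_set, cfg = bdscnn_config(),
                         rng_seed = 1L, epochs = 40L, batch_size = 128L,
                         patience = 10L, lr_start = 1e-3, lr_end = 1e-4,
                         verbose = FALSE) {
  stopifnot(inherits(train_set, "beat_dataset"),
            inherits(val_set, "beat_dataset"))
  tr <- .dataset_xy(train_set, cfg)
  va <- .dataset_xy(val_set, cfg)
  if (length(tr$y) == 0L) stop("empty training set")
  n <- length(tr$y)
  idx <- .geometry_indices(cfg)
  npos <- cfg$dsc_side^2

  with_seed(rng_seed, {
    # latents start near zero so early gradient steps can flip weight signs
    runi <- function(nr, nc) matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
    st <- list(lc = .adam_init(runi(cfg$KO^2, cfg$K)),
               ldw = .adam_init(runi(cfg$KD^2, cfg$K)),
               lpw = .adam_init(runi(cfg$K, cfg$KP)),
               l1 = .adam_init(runi(cfg$fc1_inputs, cfg$F1)),
               l2 = .adam_init(runi(cfg$F1, cfg$C)),
               bn3 = .new_bn_state(cfg$KP), bn4 = .new_bn_state(cfg$F1),
               bn5 = .new_bn_state(cfg$C))
    mom <- 0.9
    best <- list(loss = Inf, st = st, epoch = 0L)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_acc = numeric())
    wait <- 0L

    for (ep in seq_len(epochs)) {
      lr <- lr_end + 0.5 * (lr_start - lr_end) *
        (1 + cos(pi * (ep - 1) / max(epochs - 1, 1)))
      ord <- sample(n)
      ep_loss <- 0; n_batches <- 0L
      for (b0 in seq(1L, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, n)]
        B <- length(bi)
        Xb <- tr$X[bi, , drop = FALSE]
        RRb <- tr$RR[bi, , drop = FALSE]
        yb <- tr$y[bi]

        Wc <- binarize(st$lc$x); Wdw <- binarize(st$ldw$x)
        Wpw <- binarize(st$lpw$x); W1 <- binarize(st$l1$x)
        W2 <- binarize(st$l2$x)

        # ---- forward ----
        A1 <- H1 <- M1 <- Pool <- Route <- A2 <- vector("list", cfg$K)
        for (ch in seq_len(cfg$K)) {
          a1 <- conv_batch(Xb, Wc[, ch], idx$conv)
          h1 <- (a1 > 0) * 1L
          M1[[ch]] <- a1 <= 1
          # OR-pool with argmax routing to the first window cell at the max
          vals <- lapply(seq_len(ncol(idx$pool)),
                         function(t) h1[, idx$pool[, t], drop = FALSE])
          pooled <- Reduce(pmax, vals)
          taken <- matrix(FALSE, B, ncol(pooled))
          route <- vector("list", length(vals))
          for (t in seq_along(vals)) {
            hit <- (vals[[t]] == pooled) & !taken
            route[[t]] <- hit
            taken <- taken | hit
          }
          A1[[ch]] <- a1; H1[[ch]] <- h1; Pool[[ch]] <- pooled
          Route[[ch]] <- route
          A2[[ch]] <- conv_batch(pooled, Wdw[, ch], idx$dw)
        }
        S3 <- H3 <- M3 <- vector("list", cfg$KP)
        bnst3 <- vector("list", cfg$KP)
        first3 <- !st$bn3$seen
        for (p in seq_len(cfg$KP)) {
          s <- matrix(0, B, npos)
          for (ch in which(Wpw[, p] != 0)) s <- s + A2[[ch]]
          m <- mean(s); v <- mean((s - m)^2)
          y3 <- st$bn3$gamma[p] * (s - m) / sqrt(v + cfg$eps) + st$bn3$beta[p]
          S3[[p]] <- s; H3[[p]] <- (y3 > 0) * 1L; M3[[p]] <- abs(y3) <= 1
          bnst3[[p]] <- c(m, v)
          if (first3) {
            st$bn3$r_mu[p] <- m; st$bn3$r_var[p] <- v
          } else {
            st$bn3$r_mu[p] <- mom * st$bn3$r_mu[p] + (1 - mom) * m
            st$bn3$r_var[p] <- mom * st$bn3$r_var[p] + (1 - mom) * v
          }
        }
        st$bn3$seen <- TRUE
        Z <- matrix(0L, B, npos * cfg$KP)
        for (p in seq_len(cfg$KP)) {
          Z[, (p - 1L) * npos + seq_len(npos)] <- H3[[p]]
        }
        Zf <- cbind(Z, RRb)
        S4 <- Zf %*% W1
        m4 <- colMeans(S4); v4 <- colMeans(sweep(S4, 2, m4)^2)
        Y4 <- sweep(sweep(S4, 2, m4), 2, sqrt(v4 + cfg$eps), "/")
        Y4 <- sweep(sweep(Y4, 2, st$bn4$gamma, "*"), 2, st$bn4$beta, "+")
        H4 <- (Y4 > 0) * 1L; M4 <- abs(Y4) <= 1
        if (!st$bn4$seen) {
          st$bn4$r_mu <- m4; st$bn4$r_var <- v4; st$bn4$seen <- TRUE
        } else {
          st$bn4$r_mu <- mom * st$bn4$r_mu + (1 - mom) * m4
          st$bn4$r_var <- mom * st$bn4$r_var + (1 - mom) * v4
        }
        S5 <- H4 %*% W2
        m5 <- colMeans(S5); v5 <- colMeans(sweep(S5, 2, m5)^2)
        Y5 <- sweep(sweep(S5, 2, m5), 2, sqrt(v5 + cfg$eps), "/")
        Y5 <- sweep(sweep(Y5, 2, st$bn5$gamma, "*"), 2, st$bn5$beta, "+")
        if (!st$bn5$seen) {
          st$bn5$r_mu <- m5; st$bn5$r_var <- v5; st$bn5$seen <- TRUE
        } else {
          st$bn5$r_mu <- mom * st$bn5$r_mu + (1 - mom) * m5
          st$bn5$r_var <- mom * st$bn5$r_var + (1 - mom) * v5
        }
        sm <- exp(Y5 - apply(Y5, 1, max))
        sm <- sm / rowSums(sm)
        loss <- -mean(log(pmax(sm[cbind(seq_len(B), yb)], 1e-12)))
        if (!is.finite(loss)) stop("training diverged (non-finite loss)")
        ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L

        # ---- backward ----
        dY5 <- sm
        dY5[cbind(seq_len(B), yb)] <- dY5[cbind(seq_len(B), yb)] - 1
        dY5 <- dY5 / B
        dS5 <- matrix(0, B, cfg$C)
        dg5 <- db5 <- numeric(cfg$C)
        for (cl in seq_len(cfg$C)) {
          bb <- .bn_bwd(S5[, cl], dY5[, cl], st$bn5$gamma[cl], m5[cl], v5[cl],
                        cfg$eps)
          dS5[, cl] <- bb$dx; dg5[cl] <- bb$dgamma; db5[cl] <- bb$dbeta
        }
        dW2 <- crossprod(H4, dS5)
        dH4 <- dS5 %*% t(W2)
        dY4 <- dH4 * M4
        dS4 <- matrix(0, B, cfg$F1)
        dg4 <- db4 <- numeric(cfg$F1)
        for (u in seq_len(cfg$F1)) {
          bb <- .bn_bwd(S4[, u], dY4[, u], st$bn4$gamma[u], m4[u], v4[u],
                        cfg$eps)
          dS4[, u] <- bb$dx; dg4[u] <- bb$dgamma; db4[u] <- bb$dbeta
        }
        dW1 <- crossprod(Zf, dS4)
        dZ <- dS4 %*% t(W1)
        dA2 <- lapply(seq_len(cfg$K), function(ch) matrix(0, B, npos))
        dWpw <- matrix(0, cfg$K, cfg$KP)
        dg3 <- db3 <- numeric(cfg$KP)
        for (p in seq_len(cfg$KP)) {
          dH3 <- dZ[, (p - 1L) * npos + seq_len(npos), drop = FALSE]
          dY3 <- dH3 * M3[[p]]
          bb <- .bn_bwd(as.vector(S3[[p]]), as.vector(dY3), st$bn3$gamma[p],
                        bnst3[[p]][1], bnst3[[p]][2], cfg$eps)
          dS3 <- matrix(bb$dx, B, npos)
          dg3[p] <- bb$dgamma; db3[p] <- bb$dbeta
          for (ch in seq_len(cfg$K)) {
            if (Wpw[ch, p] != 0) dA2[[ch]] <- dA2[[ch]] + dS3
            dWpw[ch, p] <- sum(dS3 * A2[[ch]])
          }
        }
        dWdw <- matrix(0, cfg$KD^2, cfg$K)
        dWc <- matrix(0, cfg$KO^2, cfg$K)
        for (ch in seq_len(cfg$K)) {
          dPool <- matrix(0, B, cfg$pool_side^2)
          for (t in seq_len(ncol(idx$dw))) {
            dWdw[t, ch] <- sum(dA2[[ch]] * Pool[[ch]][, idx$dw[, t]])
            if (Wdw[t, ch] != 0) {
              dPool[, idx$dw[, t]] <- dPool[, idx$dw[, t]] + dA2[[ch]]
            }
          }
          dH1 <- matrix(0, B, cfg$conv_side^2)
          for (t in seq_len(ncol(idx$pool))) {
            dH1[, idx$pool[, t]] <- dH1[, idx$pool[, t]] +
              dPool * Route[[ch]][[t]]
          }
          dA1 <- dH1 * M1[[ch]]
          for (t in seq_len(ncol(idx$conv))) {
            dWc[t, ch] <- sum(dA1 * Xb[, idx$conv[, t]])
          }
        }

        # ---- updates (STE: latent gradient = binary-weight gradient) ----
        st$lc <- .adam_step(st$lc, dWc, lr)
        st$ldw <- .adam_step(st$ldw, dWdw, lr)
        st$lpw <- .adam_step(st$lpw, dWpw, lr)
        st$l1 <- .adam_step(st$l1, dW1, lr)
        st$l2 <- .adam_step(st$l2, dW2, lr)
        for (nm in c("lc", "ldw", "lpw", "l1", "l2")) {
          st[[nm]]$x <- pmin(pmax(st[[nm]]$x, -1), 1)
        }
        st$bn3 <- .bn_adam(st$bn3, dg3, db3, lr)
        st$bn4 <- .bn_adam(st$bn4, dg4, db4, lr)
        st$bn5 <- .bn_adam(st$bn5, dg5, db5, lr)
      }

      w_now <- .state_to_weights(st, cfg)
      vl <- if (length(va$y)) .eval_ref(w_now, va$X, va$RR, va$y)
            else list(loss = ep_loss / n_batches, acc = NA_real_)
      log <- rbind(log, data.frame(epoch = ep,
                                   train_loss = ep_loss / n_batches,
                                   val_loss = vl$loss, val_acc = vl$acc))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f, val %.4f (acc %.3f)", ep,
                        ep_loss / n_batches, vl$loss, vl$acc))
      }
      if (vl$loss < best$loss - 1e-6) {
        best <- list(loss = vl$loss, st = st, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    .state_to_weights(best$st, cfg, log = log)
  })
}
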