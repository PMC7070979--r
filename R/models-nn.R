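# Shallow networks: one satlins hidden layer, purelin output, trained by
# full-batch iRprop- on the squared error to 0/1 targets with MATLAB-style
# stopping (epoch cap + consecutive validation failures). The recurrent
# variant adds a single hidden-to-hidden path with a delay of one step and is
# trained by backpropagation through time over whole windows.

#' Symmetric saturating-linear activation
#'
#' `satlins(x) = min(max(x, -1), 1)`; cheap to evaluate on an embedded
#' target, and its quantized counterpart is a clamp at +/-1024.
#' @param z numeric input.
#' @export
satlins <- function(z) pmin(pmax(z, -1), 1)

.nn_init <- function(p, H, seed, recurrent = FALSE) {
  with_seed(seed, {
    w <- list(W1 = matrix(runif(p * H, -1, 1) / sqrt(p), p, H),
              b1 = runif(H, -0.1, 0.1),
              W2 = matrix(runif(H, -1, 1) / sqrt(H), H, 1),
              b2 = 0)
    if (recurrent) w$Wr <- matrix(runif(H * H, -1, 1) / (2 * sqrt(H)), H, H)
    w
  })
}

# one iRprop- update over a named list of parameter arrays. Full-batch
# resilient backpropagation makes near-monotone progress per epoch, so the
# "six consecutive validation failures" stopping rule carries the same
# meaning as with a second-order batch optimizer.
.rprop_state <- function(w, delta0 = 0.01) {
  list(delta = lapply(w, function(x) x * 0 + delta0),
       gprev = lapply(w, function(x) x * 0))
}

.rprop_step <- function(w, g, st, dmin = 1e-6, dmax = 1) {
  for (nm in names(g)) {
    sgn <- sign(g[[nm]] * st$gprev[[nm]])
    st$delta[[nm]] <- pmin(pmax(
      st$delta[[nm]] * ifelse(sgn > 0, 1.2, ifelse(sgn < 0, 0.5, 1)),
      dmin), dmax)
    g[[nm]][sgn < 0] <- 0  # iRprop-: forget the gradient after a sign flip
    w[[nm]] <- w[[nm]] - sign(g[[nm]]) * st$delta[[nm]]
    st$gprev[[nm]] <- g[[nm]]
  }
  list(w = w, st = st)
}

.nn_forward <- function(w, X) {
  Z <- sweep(X %*% w$W1, 2, w$b1, "+")
  H1 <- satlins(Z)
  list(Z = Z, H = H1, y = drop(H1 %*% w$W2) + w$b2)
}

#' Train the feed-forward satlins/purelin network
#'
#' Full-batch gradient training of the squared error to 0/1 targets, with
#' early stopping after `patience` consecutive epochs without improvement of
#' the validation loss (the best weights are restored).
#'
#' @param X,y normalized training features (rows = samples) and binary
#'   targets.
#' @param hidden_units hidden layer width.
#' @param Xval,yval validation set driving early stopping.
#' @param max_epochs epoch cap.
#' @param patience consecutive validation failures allowed.
#' @param lr initial per-weight step size of the resilient-backpropagation
#'   update.
#' @param seed weight initialization seed.
#' @return Parameter list `W1`, `b1`, `W2`, `b2` plus the best validation
#'   loss and the number of epochs run.
#' @export
train_nn <- function(X, y, hidden_units = 9L, Xval, yval,
                     max_epochs = 1000L, patience = 6L, lr = 0.01, seed = 1L) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  w <- .nn_init(ncol(X), hidden_units, seed)
  st <- .rprop_state(w, lr)
  best <- list(loss = Inf, w = w)
  fails <- 0
  for (epoch in seq_len(max_epochs)) {
    fw <- .nn_forward(w, X)
    dy <- matrix(2 * (fw$y - y) / n, ncol = 1)
    dZ <- (dy %*% t(w$W2)) * (abs(fw$Z) < 1)
    g <- list(W1 = t(X) %*% dZ, b1 = colSums(dZ),
              W2 = t(fw$H) %*% dy, b2 = sum(dy))
    up <- .rprop_step(w, g, st)
    w <- up$w; st <- up$st
    vl <- mean((.nn_forward(w, Xval)$y - yval)^2)
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, w = w)
      fails <- 0
    } else {
      fails <- fails + 1
      if (fails >= patience) break
    }
  }
  c(best$w, list(val_loss = best$loss, epochs = epoch))
}

# pad a list of sequences into per-time-step matrices for batched BPTT
.pack_seqs <- function(seqs) {
  B <- length(seqs)
  p <- ncol(seqs[[1]]$X)
  Tl <- vapply(seqs, function(s) nrow(s$X), integer(1))
  Tmax <- max(Tl)
  Xt <- lapply(seq_len(Tmax), function(t) {
    M <- matrix(0, B, p)
    live <- which(Tl >= t)
    for (b in live) M[b, ] <- seqs[[b]]$X[t, ]
    M
  })
  list(Xt = Xt, y = vapply(seqs, function(s) s$y, numeric(1)),
       mask = outer(Tl, seq_len(Tmax), ">="), Tl = Tl, B = B, p = p,
       Tmax = Tmax, ntot = sum(Tl))
}

.rnn_loss <- function(w, pk) {
  H <- ncol(w$W1)
  h <- matrix(0, pk$B, H)
  loss <- 0
  for (t in seq_len(pk$Tmax)) {
    h <- satlins(pk$Xt[[t]] %*% w$W1 + h %*% w$Wr +
                 matrix(w$b1, pk$B, H, byrow = TRUE))
    yh <- drop(h %*% w$W2) + w$b2
    loss <- loss + sum(((yh - pk$y)^2)[pk$mask[, t]])
  }
  loss / pk$ntot
}

#' Train the delay-1 recurrent network
#'
#' Same architecture and stopping rules as [train_nn()] plus one recurrent
#' hidden-to-hidden path applied to the hidden state delayed by one step
#' (`h_i = satlins(W1 x_i + Wr h_{i-1} + b1)`, `h_{-1} = 0`). Trained by
#' backpropagation through time over whole window sequences (each window is
#' one sequence with a constant target).
#'
#' @param seqs,val_seqs lists of `list(X, y)` sequences (normalized features
#'   in time order; `y` the window class).
#' @inheritParams train_nn
#' @return Parameter list `W1`, `b1`, `Wr`, `W2`, `b2` plus validation loss
#'   and epochs.
#' @export
train_rnn <- function(seqs, val_seqs, hidden_units = 9L, max_epochs = 100L,
                      patience = 6L, lr = 0.01, seed = 1L) {
  pk <- .pack_seqs(seqs)
  pkv <- .pack_seqs(val_seqs)
  H <- hidden_units
  w <- .nn_init(pk$p, H, seed, recurrent = TRUE)
  st <- .rprop_state(w, lr)
  best <- list(loss = Inf, w = w)
  fails <- 0
  for (epoch in seq_len(max_epochs)) {
    # forward, storing pre-activations and hidden states
    Zs <- Hs <- vector("list", pk$Tmax)
    h <- matrix(0, pk$B, H)
    for (t in seq_len(pk$Tmax)) {
      Z <- pk$Xt[[t]] %*% w$W1 + h %*% w$Wr + matrix(w$b1, pk$B, H, byrow = TRUE)
      h <- satlins(Z)
      Zs[[t]] <- Z
      Hs[[t]] <- h
    }
    # backward through time
    g <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = 0,
              Wr = w$Wr * 0)
    carry <- matrix(0, pk$B, H)
    for (t in rev(seq_len(pk$Tmax))) {
      yh <- drop(Hs[[t]] %*% w$W2) + w$b2
      dy <- matrix(2 * (yh - pk$y) * pk$mask[, t] / pk$ntot, ncol = 1)
      g$W2 <- g$W2 + t(Hs[[t]]) %*% dy
      g$b2 <- g$b2 + sum(dy)
      dH <- dy %*% t(w$W2) + carry
      dZ <- dH * (abs(Zs[[t]]) < 1) * pk$mask[, t]
      g$W1 <- g$W1 + t(pk$Xt[[t]]) %*% dZ
      g$b1 <- g$b1 + colSums(dZ)
      hprev <- if (t > 1) Hs[[t - 1]] else matrix(0, pk$B, H)
      g$Wr <- g$Wr + t(hprev) %*% dZ
      carry <- dZ %*% t(w$Wr)
    }
    up <- .rprop_step(w, g, st)
    w <- up$w; st <- up$st
    vl <- .rnn_loss(w, pkv)
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, w = w)
      fails <- 0
    } else {
      fails <- fails + 1
      if (fails >= patience) break
    }
  }
  c(best$w, list(val_loss = best$loss, epochs = epoch))
}
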