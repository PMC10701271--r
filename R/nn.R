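# Minimal 3D neural-network layer library with reverse-mode gradients.
#
# Layers are environments exposing forward()/backward() closures; each
# caches what its backward pass needs and accumulates parameter gradients
# in $grads. Tensors are single-sample arrays (X, Y, Z, C); convolutions
# are im2col gathers feeding BLAS gemm, which is where the compute lives.

new_layer <- function(type, params = list()) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  ly$params <- params
  ly$grads <- lapply(params, function(p) p * 0)  # zeros, same shape class
  class(ly) <- "nn_layer"
  ly
}

zero_grads <- function(layers) {
  for (ly in layers)
    ly$grads <- lapply(ly$params, function(p) p * 0)
  invisible(NULL)
}

# Kaiming-normal initialization for a fan-in of n.
kaiming <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# --- 3D convolution (kernel 3 with same-padding, or pointwise kernel 1) --

nn_conv3d <- function(cin, cout, ksize = 3L) {
  stopifnot(ksize %in% c(1L, 3L))
  kvol <- ksize^3
  ly <- new_layer("conv3d",
                  list(W = kaiming(kvol * cin, cout, kvol * cin),
                       b = rep(0, cout)))
  ly$cin <- cin; ly$cout <- cout; ly$ksize <- ksize
  ly$shape_cache <- new.env(parent = emptyenv())
  ly$forward <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(d[4] == cin)
    N <- prod(d[1:3])
    if (ksize == 1L) {
      xm <- matrix(x, N, cin)
      y <- xm %*% ly$params$W
      ly$cache <- list(xcol = xm, dims = d)
    } else {
      key <- paste(d[1:3], collapse = "x")
      sc <- ly$shape_cache[[key]]
      if (is.null(sc)) {
        pd <- d[1:3] + 2L
        i <- rep(seq_len(d[1]), times = d[2] * d[3])
        j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
        kk <- rep(seq_len(d[3]), each = d[1] * d[2])
        base <- i + (j - 1L) * pd[1] + (kk - 1L) * pd[1] * pd[2]
        offs <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
        off_lin <- offs[, 1] + offs[, 2] * pd[1] + offs[, 3] * pd[1] * pd[2]
        sc <- list(pd = pd, base = base, off_lin = off_lin,
                   pvol = prod(pd))
        # full gather-index matrix; columns ordered (channel, offset).
        # skipped for large tensors where its memory would dominate.
        if (N * 27 * cin <= 2e7) {
          IDX <- matrix(0L, N, 27L * cin)
          for (ch in seq_len(cin)) {
            choff <- (ch - 1L) * sc$pvol
            for (o in 1:27) {
              IDX[, (ch - 1L) * 27L + o] <-
                as.integer(base + off_lin[o] + choff)
            }
          }
          sc$IDX <- IDX
        }
        ly$shape_cache[[key]] <- sc
      }
      xp <- array(0, c(sc$pd, cin))
      xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), ] <- x
      xpv <- as.numeric(xp)
      if (!is.null(sc$IDX)) {
        xcol <- xpv[sc$IDX]
        dim(xcol) <- c(N, 27L * cin)
      } else {
        xcol <- matrix(0, N, 27L * cin)
        for (ch in seq_len(cin)) {
          choff <- (ch - 1L) * sc$pvol
          for (o in 1:27) {
            xcol[, (ch - 1L) * 27L + o] <-
              xpv[sc$base + sc$off_lin[o] + choff]
          }
        }
      }
      y <- xcol %*% ly$params$W
      ly$cache <- list(xcol = xcol, dims = d, sc = sc)
    }
    y <- sweep(y, 2, ly$params$b, "+")
    array(y, c(d[1:3], cout))
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    d <- ca$dims
    N <- prod(d[1:3])
    dym <- matrix(dy, N, cout)
    ly$grads$W <- ly$grads$W + crossprod(ca$xcol, dym)
    ly$grads$b <- ly$grads$b + colSums(dym)
    dxcol <- tcrossprod(dym, ly$params$W)
    if (ksize == 1L) return(array(dxcol, c(d[1:3], cin)))
    sc <- ca$sc
    dxp <- numeric(sc$pvol * cin)
    if (!is.null(sc$IDX)) {
      # per kernel offset the indices are unique, so 27 vectorized
      # scatter-adds cover every channel at once
      for (o in 1:27) {
        cols <- (seq_len(cin) - 1L) * 27L + o
        ids <- sc$IDX[, cols]
        dxp[ids] <- dxp[ids] + dxcol[, cols]
      }
    } else {
      for (ch in seq_len(cin)) {
        choff <- (ch - 1L) * sc$pvol
        for (o in 1:27) {
          ids <- sc$base + sc$off_lin[o] + choff
          dxp[ids] <- dxp[ids] + dxcol[, (ch - 1L) * 27L + o]
        }
      }
    }
    dxp <- array(dxp, c(sc$pd, cin))
    dxp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), , drop = FALSE]
  }
  ly
}

# --- batch normalization over spatial positions, per channel -------------

nn_batchnorm <- function(c_ch, eps = 1e-5, momentum = 0.1) {
  ly <- new_layer("batchnorm", list(gamma = rep(1, c_ch),
                                    beta = rep(0, c_ch)))
  ly$eps <- eps
  ly$run_mean <- rep(0, c_ch)
  ly$run_var <- rep(1, c_ch)
  ly$momentum <- momentum
  ly$forward <- function(x, train = TRUE) {
    d <- dim(x)
    N <- prod(d[1:3])
    xm <- matrix(x, N, d[4])
    if (train) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      va <- colMeans(xc^2)
      ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
      ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * va
    } else {
      mu <- ly$run_mean
      va <- ly$run_var
      xc <- sweep(xm, 2, mu)
    }
    ivar <- 1 / sqrt(va + ly$eps)
    xhat <- sweep(xc, 2, ivar, "*")
    y <- sweep(sweep(xhat, 2, ly$params$gamma, "*"), 2, ly$params$beta, "+")
    ly$cache <- list(xhat = xhat, ivar = ivar, dims = d, train = train)
    array(y, d)
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    d <- ca$dims
    N <- prod(d[1:3])
    dym <- matrix(dy, N, d[4])
    ly$grads$gamma <- ly$grads$gamma + colSums(dym * ca$xhat)
    ly$grads$beta <- ly$grads$beta + colSums(dym)
    dxhat <- sweep(dym, 2, ly$params$gamma, "*")
    if (!ca$train) {
      dx <- sweep(dxhat, 2, ca$ivar, "*")
      return(array(dx, d))
    }
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * ca$xhat)
    dx <- sweep(dxhat, 2, s1 / N) - sweep(ca$xhat, 2, s2 / N, "*")
    dx <- sweep(dx, 2, ca$ivar, "*")
    array(dx, d)
  }
  ly
}

# --- ReLU ---------------------------------------------------------------

nn_relu <- function() {
  ly <- new_layer("relu")
  ly$forward <- function(x, train = TRUE) {
    ly$cache <- x > 0
    x * ly$cache
  }
  ly$backward <- function(dy) dy * ly$cache
  ly
}

# --- 2x2x2 max pooling --------------------------------------------------

nn_maxpool <- function() {
  ly <- new_layer("maxpool")
  ly$forward <- function(x, train = TRUE) {
    d <- dim(x)
    if (any(d[1:3] %% 2 != 0))
      stop("maxpool input spatial shape must be even, got ",
           paste(d[1:3], collapse = "x"))
    subs <- expand.grid(dx = 0:1, dy = 0:1, dz = 0:1)
    best <- NULL; argm <- NULL
    for (m in 1:8) {
      s <- x[seq(1 + subs$dx[m], d[1], 2), seq(1 + subs$dy[m], d[2], 2),
             seq(1 + subs$dz[m], d[3], 2), , drop = FALSE]
      if (m == 1) {
        best <- s
        argm <- array(1L, dim(s))
      } else {
        upd <- s > best
        best[upd] <- s[upd]
        argm[upd] <- m
      }
    }
    ly$cache <- list(argm = argm, dims = d, subs = subs)
    best
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    d <- ca$dims
    dx <- array(0, d)
    for (m in 1:8) {
      sel <- (ca$argm == m) * dy
      dx[seq(1 + ca$subs$dx[m], d[1], 2), seq(1 + ca$subs$dy[m], d[2], 2),
         seq(1 + ca$subs$dz[m], d[3], 2), ] <-
        dx[seq(1 + ca$subs$dx[m], d[1], 2), seq(1 + ca$subs$dy[m], d[2], 2),
           seq(1 + ca$subs$dz[m], d[3], 2), , drop = FALSE] + sel
    }
    dx
  }
  ly
}

# --- 2x nearest-neighbour upsampling ------------------------------------

nn_upsample <- function() {
  ly <- new_layer("upsample")
  ly$forward <- function(x, train = TRUE) {
    d <- dim(x)
    ly$cache <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
      rep(seq_len(d[3]), each = 2), , drop = FALSE]
  }
  ly$backward <- function(dy) {
    d <- ly$cache
    dd <- dim(dy)
    dx <- array(0, d)
    for (dx_ in 0:1) for (dy_ in 0:1) for (dz_ in 0:1) {
      dx <- dx + dy[seq(1 + dx_, dd[1], 2), seq(1 + dy_, dd[2], 2),
                    seq(1 + dz_, dd[3], 2), , drop = FALSE]
    }
    dx
  }
  ly
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# --- multi-head cross attention -----------------------------------------
# Query from the structure features, Key/Value from the CT features; every
# spatial position is one token. Scores are (optionally scaled) dot
# products, softmax-normalized per query row; heads are concatenated and
# linearly projected back to c_out channels.

nn_mha <- function(c_q, c_kv, n_heads, head_dim, c_out, scale = TRUE) {
  E <- n_heads * head_dim
  ly <- new_layer("mha", list(
    Wq = kaiming(c_q, E, c_q), Wk = kaiming(c_kv, E, c_kv),
    Wv = kaiming(c_kv, E, c_kv), Wo = kaiming(E, c_out, E),
    bo = rep(0, c_out)))
  ly$n_heads <- n_heads; ly$head_dim <- head_dim
  ly$scale <- if (scale) 1 / sqrt(head_dim) else 1
  ly$forward <- function(s, ct, train = TRUE) {
    d <- dim(s)
    if (!identical(d[1:3], dim(ct)[1:3]))
      stop("structure and CT feature blocks must share spatial shape")
    N <- prod(d[1:3])
    S <- matrix(s, N, d[4])
    C <- matrix(ct, N, dim(ct)[4])
    Q <- S %*% ly$params$Wq
    K <- C %*% ly$params$Wk
    V <- C %*% ly$params$Wv
    O <- matrix(0, N, E)
    A_list <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * head_dim + seq_len(head_dim)
      A <- row_softmax(tcrossprod(Q[, cols, drop = FALSE],
                                  K[, cols, drop = FALSE]) * ly$scale)
      A_list[[h]] <- A
      O[, cols] <- A %*% V[, cols, drop = FALSE]
    }
    Y <- sweep(O %*% ly$params$Wo, 2, ly$params$bo, "+")
    ly$cache <- list(S = S, C = C, Q = Q, K = K, V = V, A = A_list, O = O,
                     dims_s = d, dims_ct = dim(ct))
    array(Y, c(d[1:3], c_out))
  }
  ly$backward <- function(dy) {
    ca <- ly$cache
    N <- nrow(ca$S)
    dY <- matrix(dy, N, ncol(ly$params$Wo))
    ly$grads$Wo <- ly$grads$Wo + crossprod(ca$O, dY)
    ly$grads$bo <- ly$grads$bo + colSums(dY)
    dO <- tcrossprod(dY, ly$params$Wo)
    dQ <- matrix(0, N, E); dK <- matrix(0, N, E); dV <- matrix(0, N, E)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * head_dim + seq_len(head_dim)
      A <- ca$A[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dA <- tcrossprod(dOh, ca$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dOh)
      dSc <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- (dSc %*% ca$K[, cols, drop = FALSE]) * ly$scale
      dK[, cols] <- (crossprod(dSc, ca$Q[, cols, drop = FALSE])) * ly$scale
    }
    ly$grads$Wq <- ly$grads$Wq + crossprod(ca$S, dQ)
    ly$grads$Wk <- ly$grads$Wk + crossprod(ca$C, dK)
    ly$grads$Wv <- ly$grads$Wv + crossprod(ca$C, dV)
    dS <- tcrossprod(dQ, ly$params$Wq)
    dC <- tcrossprod(dK, ly$params$Wk) + tcrossprod(dV, ly$params$Wv)
    list(ds = array(dS, ca$dims_s), dct = array(dC, ca$dims_ct))
  }
  ly
}

# --- sequential helpers -------------------------------------------------

seq_forward <- function(layers, x, train = TRUE) {
  for (ly in layers) x <- ly$forward(x, train)
  x
}

seq_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$backward(dy)
  dy
}

# --- Adam optimizer -----------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(ly)
    list(m = lapply(ly$params, function(p) p * 0),
         v = lapply(ly$params, function(p) p * 0)))
}

adam_step <- function(layers, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      state[[i]]$m[[nm]] <- beta1 * state[[i]]$m[[nm]] + (1 - beta1) * g
      state[[i]]$v[[nm]] <- beta2 * state[[i]]$v[[nm]] + (1 - beta2) * g^2
      mhat <- state[[i]]$m[[nm]] / (1 - beta1^t)
      vhat <- state[[i]]$v[[nm]] / (1 - beta2^t)
      ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  state
}
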