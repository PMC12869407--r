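# Minimal layer framework for the 3D convolutional VAE.
#
# Volume batches are arrays with dim (C, d1, d2, d3, B); feature batches are
# matrices (features x B). Each layer is a plain list carrying its parameters;
# `layer_forward()` returns the output plus a cache, `layer_backward()`
# consumes the cache and returns the input gradient and parameter gradients.
# Heavy lifting is one gemm per convolution against an im2col patch matrix
# built in C++.

conv_out_dim <- function(n, k, s, p) floor((n + 2 * p - k) / s) + 1L

convt_out_dim <- function(n, k, s, p, op) (n - 1L) * s - 2L * p + k + op

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv3d <- function(in_ch, out_ch, k, stride, pad, in_sp) {
  out_sp <- conv_out_dim(in_sp, k, stride, pad)
  if (any(out_sp < 1L))
    stop("conv3d: kernel ", k, " stride ", stride, " pad ", pad,
         " empties a ", paste(in_sp, collapse = "x"), " input")
  list(type = "conv3d", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad, in_sp = in_sp, out_sp = out_sp,
       params = list(W = he_init(in_ch * k^3, out_ch, in_ch * k^3),
                     b = numeric(out_ch)))
}

layer_convt3d <- function(in_ch, out_ch, k, stride, pad, out_pad, in_sp) {
  out_sp <- convt_out_dim(in_sp, k, stride, pad, out_pad)
  if (!all(conv_out_dim(out_sp, k, stride, pad) == in_sp))
    stop("convt3d: shape arithmetic does not close for kernel ", k,
         " stride ", stride, " pad ", pad, " output_padding ", out_pad)
  list(type = "convt3d", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad, in_sp = in_sp, out_sp = out_sp,
       params = list(W = he_init(out_ch * k^3, in_ch, in_ch * k^3),
                     b = numeric(out_ch)))
}

layer_dense <- function(n_in, n_out, w_sd = NULL) {
  W <- if (is.null(w_sd)) he_init(n_in, n_out, n_in)
       else matrix(stats::rnorm(n_in * n_out, sd = w_sd), n_in, n_out)
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = W, b = numeric(n_out)))
}

layer_relu <- function() list(type = "relu", params = list())

layer_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       buffers = list(run_mean = numeric(ch), run_var = rep(1, ch)))
}

layer_flatten <- function(in_ch, in_sp) {
  list(type = "flatten", in_ch = in_ch, in_sp = in_sp,
       n_out = in_ch * prod(in_sp), params = list())
}

layer_reshape <- function(out_ch, out_sp) {
  list(type = "reshape", out_ch = out_ch, out_sp = out_sp, params = list())
}

layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    conv3d = {
      out <- .conv3d_fwd(x, l$params$W, l$params$b, l$k, l$stride, l$pad)
      list(out = out, cache = list(x = x), layer = l)
    },
    convt3d = {
      out <- .convt3d_fwd(x, l$params$W, l$params$b, l$out_sp,
                          l$k, l$stride, l$pad)
      list(out = out, cache = list(u = x), layer = l)
    },
    dense = {
      out <- crossprod(l$params$W, x) + l$params$b
      list(out = out, cache = list(x = x), layer = l)
    },
    relu = {
      list(out = .relu_fwd(x), cache = list(x = x), layer = l)
    },
    batchnorm = {
      if (training) {
        mo <- .channel_moments(x, l$ch)
        mu <- mo$mean
        va <- mo$var
        m <- l$momentum
        l$buffers$run_mean <- (1 - m) * l$buffers$run_mean + m * mu
        l$buffers$run_var  <- (1 - m) * l$buffers$run_var  + m * va
      } else {
        mu <- l$buffers$run_mean
        va <- l$buffers$run_var
      }
      istd <- 1 / sqrt(va + l$eps)
      a <- l$params$gamma * istd
      out <- .channel_affine(x, a, l$params$beta - a * mu)
      list(out = out, cache = list(x = x, mu = mu, istd = istd), layer = l)
    },
    flatten = {
      dims <- dim(x)
      dim(x) <- c(prod(dims[-length(dims)]), dims[length(dims)])
      list(out = x, cache = list(dims = dims), layer = l)
    },
    reshape = {
      B <- ncol(x)
      dim(x) <- c(l$out_ch, l$out_sp, B)
      list(out = x, cache = list(), layer = l)
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, cache, dout, want_dx = TRUE) {
  switch(l$type,
    conv3d = {
      bw <- .conv3d_bwd(cache$x, l$params$W, dout, l$k, l$stride, l$pad,
                        want_dx)
      list(dx = if (want_dx) bw$dx else NULL,
           grads = list(W = bw$dW, b = bw$db))
    },
    convt3d = {
      bw <- .convt3d_bwd(cache$u, l$params$W, dout, l$out_sp,
                         l$k, l$stride, l$pad)
      list(dx = bw$du, grads = list(W = bw$dW, b = bw$db))
    },
    dense = {
      dW <- cache$x %*% t(dout)
      db <- rowSums(dout)
      dx <- l$params$W %*% dout
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = .relu_bwd(cache$x, dout), grads = list()),
    batchnorm = {
      bw <- .bn_bwd(cache$x, dout, cache$mu, cache$istd, l$params$gamma)
      list(dx = bw$dx, grads = list(gamma = bw$dgamma, beta = bw$dbeta))
    },
    flatten = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = list())
    },
    reshape = {
      d <- dim(dout)
      dim(dout) <- c(prod(d[-length(d)]), d[length(d)])
      list(dx = dout, grads = list())
    },
    stop("unknown layer type: ", l$type)
  )
}

# Run a chain of layers; returns output, per-layer caches, and the (possibly
# updated, for batch-norm running stats) layers.
chain_forward <- function(layers, x, training = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
    layers[[i]] <- fw$layer
  }
  list(out = x, caches = caches, layers = layers)
}

# `need_dx = FALSE` skips the input gradient of the first layer (nothing
# upstream consumes it), which matters for the wide first convolution.
chain_backward <- function(layers, caches, dout, need_dx = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dout,
                         want_dx = need_dx || i > 1L)
    dout <- bw$dx
    grads[[i]] <- bw$grads
  }
  list(dx = dout, grads = grads)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
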