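# Minimal CNN engine: feature maps, im2col convolutions, batch norm,
# pooling, fully connected layers and squeeze-and-excitation blocks, each
# with a hand-derived backward pass. Built for the small, exactly-seeded
# networks this package trains on CPU; everything is plain matrix algebra.
#
# Feature-map representation: list(x, H, W, N) where x is an
# (H*W*N) x C matrix. Rows are image-major: row = (n-1)*H*W + p with
# spatial position p = (w-1)*H + h (column-major, as R arrays).

fm <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

fm_from_images <- function(images) {
  # images: list of H x W x C arrays (equal dims), values already scaled
  d <- dim(images[[1]])
  x <- do.call(rbind, lapply(images, function(a) matrix(a, d[1] * d[2], d[3])))
  fm(x, d[1], d[2], length(images))
}

fm_to_array <- function(f) array(f$x, c(f$H, f$W, ncol(f$x)))
fm_from_array <- function(a) fm(matrix(a, dim(a)[1] * dim(a)[2], dim(a)[3]),
                                dim(a)[1], dim(a)[2], 1L)

# --- im2col geometry, cached per layer on (H, W, N) ---------------------

conv_geom <- function(H, W, N, kh, kw, stride, pad) {
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  P <- Ho * Wo
  ho <- rep(seq_len(Ho), Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  h0 <- (ho - 1) * stride + 1 - pad
  w0 <- (wo - 1) * stride + 1 - pad
  idx0 <- matrix(NA_integer_, P, kh * kw)
  for (j in seq_len(kw)) for (i in seq_len(kh)) {
    h <- h0 + (i - 1); w <- w0 + (j - 1)
    ok <- h >= 1 & h <= H & w >= 1 & w <= W
    col <- i + (j - 1) * kh
    idx0[ok, col] <- (w[ok] - 1) * H + h[ok]
  }
  idx <- idx0[rep(seq_len(P), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * H * W, each = P)
  idx[is.na(idx)] <- H * W * N + 1L
  list(Ho = Ho, Wo = Wo, idx = idx, k = kh * kw)
}

get_geom <- function(layer, H, W, N) {
  key <- paste(H, W, N, sep = "x")
  g <- layer$geom[[key]]
  if (is.null(g)) {
    g <- conv_geom(H, W, N, layer$kh, layer$kw, layer$stride, layer$pad)
    layer$geom[[key]] <- g
  }
  g
}

# Gather the im2col patch matrix: (P*N) x (k*C), pad rows read `fill`.
gather_patches <- function(x, g, fill = 0) {
  xp <- rbind(x, fill)
  M <- xp[as.vector(g$idx), , drop = FALSE]
  dim(M) <- c(nrow(g$idx), g$k * ncol(x))
  M
}

# Scatter-add patch gradients back to input rows. dM: (P*N) x (k*C).
scatter_patches <- function(dM, g, n_rows, n_ch) {
  dX <- matrix(0, n_rows, n_ch)
  for (o in seq_len(g$k)) {
    rows <- g$idx[, o]
    ok <- rows <= n_rows
    cols <- o + (seq_len(n_ch) - 1L) * g$k
    dX[rows[ok], ] <- dX[rows[ok], , drop = FALSE] + dM[ok, cols, drop = FALSE]
  }
  dX
}

# --- layer constructors -------------------------------------------------
# Weight layout for conv: (k*C_in) x C_out, rows ordered offset-fastest
# (matching gather_patches). He-normal initialization; call under a seeded
# RNG (build_network seeds once for the whole model).

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = FALSE) {
  sd <- sqrt(2 / (k * k * in_ch))
  params <- list(W = matrix(rnorm(k * k * in_ch * out_ch, 0, sd), k * k * in_ch, out_ch))
  if (bias) params$b <- numeric(out_ch)
  list(type = "conv", kh = k, kw = k, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch, params = params, geom = new.env(parent = emptyenv()))
}

layer_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", ch = ch, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       buffers = list(mean = numeric(ch), var = rep(1, ch)))
}

layer_relu <- function() list(type = "relu")

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  list(type = "maxpool", kh = k, kw = k, stride = stride, pad = pad,
       geom = new.env(parent = emptyenv()))

layer_avgpool <- function(k = 2L, stride = 2L)
  list(type = "avgpool", kh = k, kw = k, stride = stride, pad = 0L,
       geom = new.env(parent = emptyenv()))

layer_gap <- function() list(type = "gap")

layer_fc <- function(in_dim, out_dim, bias = TRUE) {
  sd <- sqrt(2 / in_dim)
  params <- list(W = matrix(rnorm(in_dim * out_dim, 0, sd), in_dim, out_dim))
  if (bias) params$b <- numeric(out_dim)
  list(type = "fc", in_dim = in_dim, out_dim = out_dim, params = params)
}

layer_se <- function(ch, r = 16L, optimized = TRUE, zero_init = FALSE) {
  bott <- ch %/% r
  if (bott < 1) {
    warnf("SE bottleneck %d/%d < 1; clamped to 1", ch, r)
    bott <- 1L
  }
  in_dim <- if (optimized) 3L * ch else ch
  sd1 <- sqrt(2 / in_dim); sd2 <- sqrt(2 / bott)
  mk <- function(n, s) if (zero_init) numeric(n) else rnorm(n, 0, s)
  list(type = "se", ch = ch, r = r, bottleneck = bott, optimized = optimized,
       kh = 2L, kw = 2L, stride = 2L, pad = 0L,   # local-pool geometry
       params = list(W1 = matrix(mk(in_dim * bott, sd1), in_dim, bott),
                     b1 = numeric(bott),
                     W2 = matrix(mk(bott * ch, sd2), bott, ch),
                     b2 = numeric(ch)),
       geom = new.env(parent = emptyenv()))
}

layer_seq <- function(children, name = "seq") list(type = "seq", name = name, children = children)

# Dense block: each child layer is BN-ReLU-conv1x1(4k)-BN-ReLU-conv3x3(k)
# applied to the concatenation of the block input and all previous child
# outputs; the block output is the full concatenation.
dense_layer <- function(in_ch, k) {
  layer_seq(list(layer_bn(in_ch), layer_relu(), layer_conv(in_ch, 4L * k, 1L),
                 layer_bn(4L * k), layer_relu(),
                 layer_conv(4L * k, k, 3L, stride = 1L, pad = 1L)),
            name = "dense_layer")
}

dense_block_module <- function(in_ch, n_layers, k) {
  children <- vector("list", n_layers)
  ch <- in_ch
  for (l in seq_len(n_layers)) {
    children[[l]] <- dense_layer(ch, k)
    ch <- ch + k
  }
  list(type = "dense_block", in_ch = in_ch, k = k, out_ch = ch, children = children)
}

transition_module <- function(in_ch, compression) {
  out_ch <- max(1L, floor(in_ch * compression))
  m <- layer_seq(list(layer_bn(in_ch), layer_relu(), layer_conv(in_ch, out_ch, 1L),
                      layer_avgpool(2L, 2L)),
                 name = "transition")
  m$out_ch <- out_ch
  m
}

# --- forward ------------------------------------------------------------
# net_forward returns list(mod, out, cache): mod carries updated BN
# running statistics, cache everything backward needs.

net_forward <- function(mod, f, training = FALSE) {
  switch(mod$type,
    seq = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- net_forward(mod$children[[i]], f, training)
        mod$children[[i]] <- r$mod
        f <- r$out
        caches[[i]] <- r$cache
      }
      list(mod = mod, out = f, cache = caches)
    },
    dense_block = {
      caches <- vector("list", length(mod$children))
      for (i in seq_along(mod$children)) {
        r <- net_forward(mod$children[[i]], f, training)
        mod$children[[i]] <- r$mod
        caches[[i]] <- r$cache
        f <- fm(cbind(f$x, r$out$x), f$H, f$W, f$N)
      }
      list(mod = mod, out = f, cache = caches)
    },
    conv = forward_conv(mod, f),
    bn = forward_bn(mod, f, training),
    relu = {
      mask <- f$x > 0
      list(mod = mod, out = fm(f$x * mask, f$H, f$W, f$N), cache = list(mask = mask))
    },
    maxpool = forward_maxpool(mod, f),
    avgpool = forward_avgpool(mod, f),
    gap = {
      grp <- rep(seq_len(f$N), each = f$H * f$W)
      out <- rowsum(f$x, grp, reorder = FALSE) / (f$H * f$W)
      rownames(out) <- NULL
      list(mod = mod, out = fm(out, 1L, 1L, f$N), cache = list(H = f$H, W = f$W, N = f$N))
    },
    fc = {
      out <- f$x %*% mod$params$W
      if (!is.null(mod$params$b)) out <- sweep(out, 2, mod$params$b, "+")
      list(mod = mod, out = fm(out, 1L, 1L, f$N), cache = list(x = f$x))
    },
    se = forward_se(mod, f),
    stopf("unknown module type: %s", mod$type))
}

forward_conv <- function(mod, f) {
  g <- get_geom(mod, f$H, f$W, f$N)
  M <- gather_patches(f$x, g, fill = 0)
  out <- M %*% mod$params$W
  if (!is.null(mod$params$b)) out <- sweep(out, 2, mod$params$b, "+")
  list(mod = mod, out = fm(out, g$Ho, g$Wo, f$N),
       cache = list(M = M, g = g, n_rows = nrow(f$x), in_ch = ncol(f$x)))
}

forward_bn <- function(mod, f, training) {
  x <- f$x
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc * xc)
    mom <- mod$momentum
    mod$buffers$mean <- (1 - mom) * mod$buffers$mean + mom * mu
    mod$buffers$var <- (1 - mom) * mod$buffers$var + mom * v
  } else {
    mu <- mod$buffers$mean
    v <- mod$buffers$var
    xc <- sweep(x, 2, mu)
  }
  invstd <- 1 / sqrt(v + mod$eps)
  xhat <- sweep(xc, 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, mod$params$gamma, "*"), 2, mod$params$beta, "+")
  list(mod = mod, out = fm(y, f$H, f$W, f$N),
       cache = list(xhat = xhat, invstd = invstd, training = training))
}

forward_maxpool <- function(mod, f) {
  g <- get_geom(mod, f$H, f$W, f$N)
  C <- ncol(f$x)
  A <- gather_patches(f$x, g, fill = -Inf)
  dim(A) <- c(nrow(g$idx), g$k, C)
  cur <- matrix(A[, 1, ], nrow(g$idx), C)
  arg <- matrix(1L, nrow(g$idx), C)
  for (o in seq_len(g$k)[-1]) {
    s <- A[, o, ]
    m <- s > cur
    arg[m] <- o
    cur[m] <- s[m]
  }
  list(mod = mod, out = fm(cur, g$Ho, g$Wo, f$N),
       cache = list(g = g, arg = arg, n_rows = nrow(f$x), in_ch = C))
}

forward_avgpool <- function(mod, f) {
  # clamp the kernel on maps smaller than it (degenerates to identity)
  key <- paste(f$H, f$W, f$N, sep = "x")
  g <- mod$geom[[key]]
  if (is.null(g)) {
    g <- conv_geom(f$H, f$W, f$N, min(mod$kh, f$H), min(mod$kw, f$W), mod$stride, 0L)
    mod$geom[[key]] <- g
  }
  C <- ncol(f$x)
  A <- gather_patches(f$x, g, fill = 0)
  dim(A) <- c(nrow(g$idx), g$k, C)
  out <- matrix(A[, 1, ], nrow(g$idx), C)
  for (o in seq_len(g$k)[-1]) out <- out + A[, o, ]
  out <- out / g$k
  list(mod = mod, out = fm(out, g$Ho, g$Wo, f$N),
       cache = list(g = g, n_rows = nrow(f$x), in_ch = C))
}

# Squeeze statistics per channel and image: global mean, max over the
# 2x2-average-pooled (stride 2) map, population spatial variance.
forward_se <- function(mod, f) {
  x <- f$x; C <- ncol(x); N <- f$N; HW <- f$H * f$W
  grp <- rep(seq_len(N), each = HW)
  gm <- rowsum(x, grp, reorder = FALSE) / HW
  if (mod$optimized) {
    ex2 <- rowsum(x * x, grp, reorder = FALSE) / HW
    v <- ex2 - gm * gm
    vmask <- v > 0
    v <- pmax(v, 0)
    if (f$H >= 2 && f$W >= 2) {
      g <- get_geom(mod, f$H, f$W, N)
      A <- gather_patches(x, g, fill = 0)
      dim(A) <- c(nrow(g$idx), g$k, C)
      P <- matrix(A[, 1, ], nrow(g$idx), C)
      for (o in seq_len(g$k)[-1]) P <- P + A[, o, ]
      P <- P / g$k
      PHW <- g$Ho * g$Wo
    } else {
      g <- NULL; P <- x; PHW <- HW
    }
    dim(P) <- c(PHW, N * C)
    cur <- P[1, ]
    argp <- rep(1L, N * C)
    for (p in seq_len(PHW)[-1]) {
      s <- P[p, ]
      m <- s > cur
      argp[m] <- p
      cur[m] <- s[m]
    }
    lm <- matrix(cur, N, C)
    S <- cbind(gm, lm, v)
  } else {
    vmask <- NULL; argp <- NULL; g <- NULL; PHW <- NULL
    S <- gm
  }
  z1 <- sweep(S %*% mod$params$W1, 2, mod$params$b1, "+")
  a1 <- z1 * (z1 > 0)
  z2 <- sweep(a1 %*% mod$params$W2, 2, mod$params$b2, "+")
  G <- 1 / (1 + exp(-z2))
  y <- x * G[grp, , drop = FALSE]
  list(mod = mod, out = fm(y, f$H, f$W, f$N),
       cache = list(x = x, gm = gm, S = S, a1 = a1, G = G, grp = grp, HW = HW,
                    vmask = vmask, argp = argp, g = g, PHW = PHW, C = C, N = N))
}

# --- backward -----------------------------------------------------------
# net_backward returns list(dx, grads) with grads mirroring the module
# tree: list(params = <list like mod$params>, children = list(...)).

net_backward <- function(mod, cache, df) {
  switch(mod$type,
    seq = {
      grads <- vector("list", length(mod$children))
      for (i in rev(seq_along(mod$children))) {
        r <- net_backward(mod$children[[i]], cache[[i]], df)
        df <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = df, grads = list(children = grads))
    },
    dense_block = {
      n <- length(mod$children)
      grads <- vector("list", n)
      d <- df   # gradient w.r.t. the full running concatenation
      for (i in rev(seq_len(n))) {
        c_in <- mod$in_ch + (i - 1L) * mod$k
        dy_i <- d[, (c_in + 1L):(c_in + mod$k), drop = FALSE]
        r <- net_backward(mod$children[[i]], cache[[i]], dy_i)
        grads[[i]] <- r$grads
        d <- d[, seq_len(c_in), drop = FALSE] + r$dx
      }
      list(dx = d, grads = list(children = grads))
    },
    conv = {
      dW <- crossprod(cache$M, df)
      grads <- list(params = list(W = dW))
      if (!is.null(mod$params$b)) grads$params$b <- colSums(df)
      dM <- tcrossprod(df, mod$params$W)
      list(dx = scatter_patches(dM, cache$g, cache$n_rows, cache$in_ch), grads = grads)
    },
    bn = {
      xhat <- cache$xhat
      dxh <- sweep(df, 2, mod$params$gamma, "*")
      grads <- list(params = list(gamma = colSums(df * xhat), beta = colSums(df)))
      if (cache$training) {
        n <- nrow(xhat)
        dx <- dxh - matrix(colSums(dxh) / n, n, ncol(xhat), byrow = TRUE) -
          sweep(xhat, 2, colSums(dxh * xhat) / n, "*")
        dx <- sweep(dx, 2, cache$invstd, "*")
      } else {
        dx <- sweep(dxh, 2, cache$invstd, "*")
      }
      list(dx = dx, grads = grads)
    },
    relu = list(dx = df * cache$mask, grads = NULL),
    maxpool = {
      g <- cache$g
      dX <- matrix(0, cache$n_rows, cache$in_ch)
      for (o in seq_len(g$k)) {
        m <- cache$arg == o
        if (!any(m)) next
        contrib <- df * m
        rows <- g$idx[, o]
        ok <- rows <= cache$n_rows
        dX[rows[ok], ] <- dX[rows[ok], , drop = FALSE] + contrib[ok, , drop = FALSE]
      }
      list(dx = dX, grads = NULL)
    },
    avgpool = {
      g <- cache$g
      dX <- matrix(0, cache$n_rows, cache$in_ch)
      dshare <- df / g$k
      for (o in seq_len(g$k)) {
        rows <- g$idx[, o]
        ok <- rows <= cache$n_rows
        dX[rows[ok], ] <- dX[rows[ok], , drop = FALSE] + dshare[ok, , drop = FALSE]
      }
      list(dx = dX, grads = NULL)
    },
    gap = {
      HW <- cache$H * cache$W
      list(dx = df[rep(seq_len(cache$N), each = HW), , drop = FALSE] / HW, grads = NULL)
    },
    fc = {
      grads <- list(params = list(W = crossprod(cache$x, df)))
      if (!is.null(mod$params$b)) grads$params$b <- colSums(df)
      list(dx = tcrossprod(df, mod$params$W), grads = grads)
    },
    se = backward_se(mod, cache, df),
    stopf("unknown module type: %s", mod$type))
}

backward_se <- function(mod, cache, df) {
  x <- cache$x; G <- cache$G; grp <- cache$grp; HW <- cache$HW
  C <- cache$C; N <- cache$N
  Gexp <- G[grp, , drop = FALSE]
  dx <- df * Gexp
  dG <- rowsum(df * x, grp, reorder = FALSE)
  dz2 <- dG * G * (1 - G)
  dW2 <- crossprod(cache$a1, dz2)
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, mod$params$W2)
  dz1 <- da1 * (cache$a1 > 0)
  dW1 <- crossprod(cache$S, dz1)
  db1 <- colSums(dz1)
  dS <- tcrossprod(dz1, mod$params$W1)
  if (mod$optimized) {
    dgm_s <- dS[, seq_len(C), drop = FALSE]
    dlm <- dS[, C + seq_len(C), drop = FALSE]
    dv <- dS[, 2L * C + seq_len(C), drop = FALSE] * cache$vmask
    # variance path: v = E[x^2] - gm^2
    dx <- dx + (dv[grp, , drop = FALSE] * 2 * (x - cache$gm[grp, , drop = FALSE]) +
                dgm_s[grp, , drop = FALSE]) / HW
    # local-max path: route to the argmax pooled cell, then through the
    # 2x2 average pool (or directly when the map was too small to pool)
    PHW <- cache$PHW
    m <- seq_len(N * C)
    nvec <- ((m - 1L) %% N) + 1L
    cvec <- ((m - 1L) %/% N) + 1L
    lin <- (cvec - 1L) * (PHW * N) + (nvec - 1L) * PHW + cache$argp
    dP <- numeric(PHW * N * C)
    dP[lin] <- as.vector(dlm)
    dim(dP) <- c(PHW * N, C)
    if (!is.null(cache$g)) {
      g <- cache$g
      dshare <- dP / g$k
      for (o in seq_len(g$k)) {
        rows <- g$idx[, o]
        ok <- rows <= nrow(x)
        dx[rows[ok], ] <- dx[rows[ok], , drop = FALSE] + dshare[ok, , drop = FALSE]
      }
    } else {
      dx <- dx + dP
    }
  } else {
    dx <- dx + dS[grp, , drop = FALSE] / HW
  }
  list(dx = dx,
       grads = list(params = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

# --- parameter bookkeeping ----------------------------------------------

flatten_params <- function(mod) {
  out <- if (!is.null(mod$params)) unname(mod$params) else list()
  for (ch in mod$children) out <- c(out, flatten_params(ch))
  out
}

flatten_grads <- function(g) {
  if (is.null(g)) return(list())
  out <- if (!is.null(g$params)) unname(g$params) else list()
  for (ch in g$children) out <- c(out, flatten_grads(ch))
  out
}

assign_params <- function(mod, flat, i = 1L) {
  if (!is.null(mod$params)) {
    for (j in seq_along(mod$params)) {
      mod$params[[j]] <- flat[[i]]
      i <- i + 1L
    }
  }
  for (k in seq_along(mod$children)) {
    r <- assign_params(mod$children[[k]], flat, i)
    mod$children[[k]] <- r$mod
    i <- r$i
  }
  list(mod = mod, i = i)
}
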