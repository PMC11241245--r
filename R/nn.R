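# Minimal feed-forward network framework with exact backward passes.
#
# Tensors are column-major arrays (H, W, C, N); fully connected activations
# are (D, N) matrices. Each layer is a plain list: `type`, optional `name`,
# `params` (named arrays), `grads` (filled by backward), and layer-specific
# buffers. `nn_forward()` returns list(y, cache, layer); `nn_backward()`
# returns list(dx, layer). The functional style keeps models serializable.

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)

ly_conv <- function(cin, cout, k, stride = 1L, groups = 1L, name = NULL) {
  pad <- k %/% 2L
  w <- he_init(c(k, k, cin %/% groups, cout), k * k * cin / groups)
  list(type = "conv", name = name, k = k, stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups),
       cin = cin, cout = cout, params = list(w = w), grads = NULL)
}

ly_bn <- function(c, name = NULL) {
  list(type = "bn", name = name, c = c, eps = 1e-5, momentum = 0.1,
       params = list(gamma = rep(1, c), beta = rep(0, c)),
       running_mean = rep(0, c), running_var = rep(1, c), grads = NULL)
}

ly_act <- function(fun = c("silu", "relu", "sigmoid"), name = NULL) {
  list(type = "act", name = name, fun = match.arg(fun))
}

ly_linear <- function(din, dout, name = NULL) {
  list(type = "linear", name = name, din = din, dout = dout,
       params = list(w = array(stats::rnorm(dout * din, 0, sqrt(1 / din)),
                               dim = c(dout, din)),
                     b = rep(0, dout)), grads = NULL)
}

ly_gap <- function(name = NULL) list(type = "gap", name = name)

ly_dropout <- function(p, name = NULL) list(type = "dropout", name = name, p = p)

ly_se <- function(c_exp, c_base, ratio = 0.25, name = NULL) {
  cse <- max(1L, as.integer(round(c_base * ratio)))
  list(type = "se", name = name, c = c_exp, cse = cse,
       params = list(w1 = he_init(c(cse, c_exp), c_exp), b1 = rep(0, cse),
                     w2 = he_init(c(c_exp, cse), cse), b2 = rep(0, c_exp)),
       grads = NULL)
}

ly_cbam <- function(c, reduction_ratio = 16L, spatial_kernel = 7L, name = NULL) {
  if (spatial_kernel %% 2L == 0L)
    abort("Spatial attention kernel must be odd.", class = "ecsanet_config_error")
  ch <- max(1L, c %/% as.integer(reduction_ratio))
  list(type = "cbam", name = name, c = c, ch = ch,
       k_sp = as.integer(spatial_kernel),
       params = list(w1 = he_init(c(ch, c), c), b1 = rep(0, ch),
                     w2 = he_init(c(c, ch), ch), b2 = rep(0, c),
                     w_sp = he_init(c(spatial_kernel, spatial_kernel, 2L, 1L),
                                    spatial_kernel^2 * 2),
                     b_sp = 0),
       grads = NULL)
}

ly_seq <- function(layers, name = NULL) list(type = "seq", name = name, layers = layers)

ly_block <- function(body, use_res, name = NULL)
  list(type = "block", name = name, body = body, use_res = isTRUE(use_res))

# ---- activation helpers -----------------------------------------------------

sigmoid_ <- function(x) 1 / (1 + exp(-x))
silu_ <- function(x) x * sigmoid_(x)
dsilu_ <- function(x) { s <- sigmoid_(x); s * (1 + x * (1 - s)) }

# broadcast a (C, N) matrix over spatial positions of an (H, W, C, N) array
bcast_cn <- function(m, d) array(rep(m, each = d[1] * d[2]), dim = d)

# ---- forward ----------------------------------------------------------------

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = {
      y <- conv2d_fwd(x, layer$params$w, layer$stride, layer$pad, layer$groups)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x); C <- d[3]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N, C)
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean + layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var + layer$momentum * v
      } else {
        mu <- layer$running_mean; v <- layer$running_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, invstd, "*")
      ym <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
      y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
      list(y = y, cache = list(xhat = xhat, invstd = invstd, d = d,
                               training = training), layer = layer)
    },
    act = {
      y <- switch(layer$fun, silu = silu_(x), relu = pmax(x, 0), sigmoid = sigmoid_(x))
      list(y = y, cache = list(x = x, y = y), layer = layer)
    },
    linear = {
      y <- layer$params$w %*% x + layer$params$b
      list(y = y, cache = list(x = x), layer = layer)
    },
    gap = {
      d <- dim(x); hw <- d[1] * d[2]
      p <- matrix(colMeans(matrix(x, nrow = hw)), nrow = d[3])  # (C, N)
      list(y = p, cache = list(d = d), layer = layer)
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- (array(stats::runif(length(x)), dim = dim(x)) >= layer$p) / (1 - layer$p)
        list(y = x * mask, cache = list(mask = mask), layer = layer)
      } else list(y = x, cache = list(mask = NULL), layer = layer)
    },
    se = {
      d <- dim(x); hw <- d[1] * d[2]
      p <- matrix(colMeans(matrix(x, nrow = hw)), nrow = d[3])
      z1 <- layer$params$w1 %*% p + layer$params$b1
      a1 <- silu_(z1)
      z2 <- layer$params$w2 %*% a1 + layer$params$b2
      s <- sigmoid_(z2)
      y <- x * bcast_cn(s, d)
      list(y = y, cache = list(x = x, p = p, z1 = z1, a1 = a1, s = s, d = d),
           layer = layer)
    },
    cbam = cbam_forward(layer, x),
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- nn_forward(layer$layers[[i]], x, training)
        x <- r$y; caches[[i]] <- r$cache; layer$layers[[i]] <- r$layer
      }
      list(y = x, cache = caches, layer = layer)
    },
    block = {
      r <- nn_forward(layer$body, x, training)
      y <- if (layer$use_res) r$y + x else r$y
      layer$body <- r$layer
      list(y = y, cache = r$cache, layer = layer)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type)))
}

# ---- CBAM forward/backward --------------------------------------------------

col_max_idx <- function(m) {
  # per-column max and argmax of a matrix
  idx <- integer(ncol(m)); mx <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) { i <- which.max(m[, j]); idx[j] <- i; mx[j] <- m[i, j] }
  list(max = mx, idx = idx)
}

cbam_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; hw <- H * W
  xm <- matrix(x, nrow = hw)                       # (HW, C*N)
  pa <- matrix(colMeans(xm), nrow = C)             # (C, N)
  mm <- col_max_idx(xm)
  pm <- matrix(mm$max, nrow = C)
  z1a <- layer$params$w1 %*% pa + layer$params$b1
  z1m <- layer$params$w1 %*% pm + layer$params$b1
  h_a <- pmax(z1a, 0); h_m <- pmax(z1m, 0)
  za <- layer$params$w2 %*% h_a + layer$params$b2
  zm <- layer$params$w2 %*% h_m + layer$params$b2
  mc <- sigmoid_(za + zm)                          # (C, N)
  f1 <- x * bcast_cn(mc, d)
  # spatial attention on the channel-refined map
  sa <- array(0, dim = c(H, W, N)); sm <- f1[, , 1, , drop = TRUE]
  sm <- array(sm, dim = c(H, W, N)); widx <- array(1L, dim = c(H, W, N))
  for (c in seq_len(C)) {
    plane <- array(f1[, , c, , drop = TRUE], dim = c(H, W, N))
    sa <- sa + plane
    if (c > 1) { upd <- plane > sm; sm[upd] <- plane[upd]; widx[upd] <- c }
  }
  sa <- sa / C
  stack2 <- array(0, dim = c(H, W, 2, N))
  stack2[, , 1, ] <- sa; stack2[, , 2, ] <- sm
  zsp <- conv2d_fwd(stack2, layer$params$w_sp, 1L, layer$k_sp %/% 2L, 1L) +
    layer$params$b_sp
  ms <- sigmoid_(zsp)                              # (H, W, 1, N)
  msr <- ms[, , rep(1L, C), , drop = FALSE]
  y <- f1 * msr
  list(y = y,
       cache = list(x = x, d = d, pa = pa, pm = pm, amax = mm$idx,
                    z1a = z1a, z1m = z1m, h_a = h_a, h_m = h_m, mc = mc,
                    f1 = f1, widx = widx, stack2 = stack2, ms = ms, msr = msr),
       layer = layer)
}

cbam_backward <- function(layer, dout, cache) {
  d <- cache$d; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; hw <- H * W
  p <- layer$params
  # y = f1 * ms
  df1 <- dout * cache$msr
  dms <- array(0, dim = c(H, W, N))
  prod_df <- dout * cache$f1
  for (c in seq_len(C))
    dms <- dms + array(prod_df[, , c, , drop = TRUE], dim = c(H, W, N))
  ms3 <- array(cache$ms, dim = c(H, W, N))
  dzsp <- array(dms * ms3 * (1 - ms3), dim = c(H, W, 1, N))
  bw <- conv2d_bwd(cache$stack2, p$w_sp, dzsp, 1L, layer$k_sp %/% 2L, 1L)
  dw_sp <- bw$dw; db_sp <- sum(dzsp)
  dsa <- array(bw$dx[, , 1, , drop = TRUE], dim = c(H, W, N))
  dsm <- array(bw$dx[, , 2, , drop = TRUE], dim = c(H, W, N))
  # channel mean / channel max backward into f1
  for (c in seq_len(C)) {
    add <- dsa / C
    sel <- cache$widx == c
    add[sel] <- add[sel] + dsm[sel]
    df1[, , c, ] <- array(df1[, , c, , drop = TRUE], dim = c(H, W, N)) + add
  }
  # f1 = x * mc
  dx <- df1 * bcast_cn(cache$mc, d)
  dmc <- matrix(colSums(matrix(df1 * cache$x, nrow = hw)), nrow = C)
  dz <- dmc * cache$mc * (1 - cache$mc)            # shared for both branches
  dw2 <- dz %*% t(cache$h_a) + dz %*% t(cache$h_m)
  db2 <- 2 * rowSums(dz)
  dha <- t(p$w2) %*% dz; dhm <- t(p$w2) %*% dz
  dz1a <- dha * (cache$z1a > 0); dz1m <- dhm * (cache$z1m > 0)
  dw1 <- dz1a %*% t(cache$pa) + dz1m %*% t(cache$pm)
  db1 <- rowSums(dz1a) + rowSums(dz1m)
  dpa <- t(p$w1) %*% dz1a; dpm <- t(p$w1) %*% dz1m
  dx <- dx + bcast_cn(dpa, d) / hw
  dxm <- matrix(0, nrow = hw, ncol = C * N)
  dxm[cbind(cache$amax, seq_len(C * N))] <- as.numeric(dpm)
  dx <- dx + array(dxm, dim = d)
  layer$grads <- list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2,
                      w_sp = dw_sp, b_sp = db_sp)
  list(dx = dx, layer = layer)
}

# ---- backward ---------------------------------------------------------------

nn_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd(cache$x, layer$params$w, dout, layer$stride, layer$pad,
                      layer$groups)
      layer$grads <- list(w = r$dw)
      list(dx = r$dx, layer = layer)
    },
    bn = {
      d <- cache$d; C <- d[3]
      dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
      m <- nrow(dm)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      dxhat <- sweep(dm, 2, layer$params$gamma, "*")
      if (cache$training) {
        t1 <- sweep(dxhat, 2, colMeans(dxhat))
        t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
        dxm <- sweep(t1 - t2, 2, cache$invstd, "*")
      } else {
        dxm <- sweep(dxhat, 2, cache$invstd, "*")
      }
      dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
      layer$grads <- list(gamma = dgamma, beta = dbeta)
      list(dx = dx, layer = layer)
    },
    act = {
      dx <- switch(layer$fun,
        silu = dout * dsilu_(cache$x),
        relu = dout * (cache$x > 0),
        sigmoid = dout * cache$y * (1 - cache$y))
      list(dx = dx, layer = layer)
    },
    linear = {
      layer$grads <- list(w = dout %*% t(cache$x), b = rowSums(dout))
      list(dx = t(layer$params$w) %*% dout, layer = layer)
    },
    gap = {
      d <- cache$d; hw <- d[1] * d[2]
      list(dx = bcast_cn(dout, d) / hw, layer = layer)
    },
    dropout = {
      list(dx = if (is.null(cache$mask)) dout else dout * cache$mask, layer = layer)
    },
    se = {
      d <- cache$d; hw <- d[1] * d[2]; p <- layer$params
      ds <- matrix(colSums(matrix(dout * cache$x, nrow = hw)), nrow = d[3])
      dxf <- dout * bcast_cn(cache$s, d)
      dz2 <- ds * cache$s * (1 - cache$s)
      dw2 <- dz2 %*% t(cache$a1); db2 <- rowSums(dz2)
      da1 <- t(p$w2) %*% dz2
      dz1 <- da1 * dsilu_(cache$z1)
      dw1 <- dz1 %*% t(cache$p); db1 <- rowSums(dz1)
      dp <- t(p$w1) %*% dz1
      dx <- dxf + bcast_cn(dp, d) / hw
      layer$grads <- list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2)
      list(dx = dx, layer = layer)
    },
    cbam = cbam_backward(layer, dout, cache),
    seq = {
      for (i in rev(seq_along(layer$layers))) {
        r <- nn_backward(layer$layers[[i]], dout, cache[[i]])
        dout <- r$dx; layer$layers[[i]] <- r$layer
      }
      list(dx = dout, layer = layer)
    },
    block = {
      r <- nn_backward(layer$body, dout, cache)
      layer$body <- r$layer
      dx <- if (layer$use_res) r$dx + dout else r$dx
      list(dx = dx, layer = layer)
    },
    abort(sprintf("Unknown layer type '%s'.", layer$type)))
}

# ---- parameter traversal ----------------------------------------------------

# fn(param_array, grad_array, velocity_array_or_NULL, path) -> list(param, velocity)
walk_params <- function(layer, fn, path = "") {
  if (!is.null(layer$params)) {
    for (nm in names(layer$params)) {
      g <- if (!is.null(layer$grads)) layer$grads[[nm]] else NULL
      v <- if (!is.null(layer$vel)) layer$vel[[nm]] else NULL
      r <- fn(layer$params[[nm]], g, v, paste0(path, "/", nm))
      layer$params[[nm]] <- r$param
      if (!is.null(r$velocity)) {
        if (is.null(layer$vel)) layer$vel <- list()
        layer$vel[[nm]] <- r$velocity
      }
    }
  }
  if (!is.null(layer$layers))
    for (i in seq_along(layer$layers))
      layer$layers[[i]] <- walk_params(layer$layers[[i]], fn,
                                       paste0(path, "/", i))
  if (!is.null(layer$body))
    layer$body <- walk_params(layer$body, fn, paste0(path, "/body"))
  layer
}

n_params <- function(layer) {
  total <- 0
  walk_params(layer, function(p, g, v, path) {
    total <<- total + length(p)
    list(param = p, velocity = v)
  })
  total
}
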