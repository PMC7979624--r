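# Minimal computational-graph engine for the segmentation networks.
#
# Tensors are numeric 4D arrays (z, y, x, channel). A graph is a list of
# nodes evaluated in insertion (topological) order; backward traverses the
# reverse order. Parameters live in a flat list shared by the graph; the
# model stores shapes always and values only when initialized, so very large
# configurations can be inspected (parameter counts, topology) without
# allocating weights.

nn_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$param_shapes <- list()
  env
}

nb_node <- function(nb, node) {
  nb$nodes[[length(nb$nodes) + 1L]] <- node
  length(nb$nodes)
}

nb_param <- function(nb, name, shape) {
  nb$param_shapes[[name]] <- shape
  name
}

nb_input <- function(nb, ch) nb_node(nb, list(op = "input", ch = ch))

# 3x3x3 or 1x1x1 convolution, no bias, followed by instance norm + ReLU
# unless norm/act are disabled (the final classifier conv uses neither).
nb_conv <- function(nb, input, k, cin, cout, name, norm = TRUE, act = TRUE) {
  wname <- nb_param(nb, paste0(name, ".w"), c(k, k, k, cin, cout))
  id <- nb_node(nb, list(op = "conv", inputs = input, k = k, cin = cin,
                         cout = cout, w = wname, ch = cout))
  if (norm) {
    gname <- nb_param(nb, paste0(name, ".gamma"), cout)
    bname <- nb_param(nb, paste0(name, ".beta"), cout)
    id <- nb_node(nb, list(op = "inorm", inputs = id, ch = cout,
                           gamma = gname, beta = bname))
  }
  if (act) id <- nb_node(nb, list(op = "relu", inputs = id, ch = cout))
  id
}

nb_pool <- function(nb, input, ch)
  nb_node(nb, list(op = "pool", inputs = input, ch = ch))

nb_upsample <- function(nb, input, ch, factors = c(2L, 2L, 2L))
  nb_node(nb, list(op = "up", inputs = input, ch = ch, factors = factors))

nb_concat <- function(nb, a, b, ch_a, ch_b)
  nb_node(nb, list(op = "concat", inputs = c(a, b), ch_a = ch_a, ch_b = ch_b,
                   ch = ch_a + ch_b))

nb_add <- function(nb, a, b, ch, act = TRUE) {
  id <- nb_node(nb, list(op = "add", inputs = c(a, b), ch = ch))
  if (act) id <- nb_node(nb, list(op = "relu", inputs = id, ch = ch))
  id
}

nb_softmax <- function(nb, input, ch)
  nb_node(nb, list(op = "softmax", inputs = input, ch = ch))

BC_INORM_EPS <- 1e-5

nn_init_params <- function(shapes, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    if (grepl("\\.w$", nm)) {
      # He initialization for ReLU networks: sd = sqrt(2 / fan_in)
      fan_in <- prod(sh[1:4])
      params[[nm]] <- array(rnorm(prod(sh), 0, sqrt(2 / fan_in)), sh)
    } else if (grepl("\\.gamma$", nm)) {
      params[[nm]] <- rep(1, sh)
    } else {
      params[[nm]] <- rep(0, sh)
    }
  }
  params
}

channel_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

nn_softmax_apply <- function(x) {
  d <- dim(x)
  m <- channel_mat(x)
  mx <- m[, 1]
  for (c in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, c])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# Forward pass. Returns list(out, vals, caches); vals/caches retained only
# when train = TRUE (needed by nn_backward).
nn_forward <- function(model, x, train = FALSE) {
  nodes <- model$nodes
  params <- model$params
  if (is.null(params)) bc_stop("model has no initialized weights; build with init_weights = TRUE")
  vals <- vector("list", length(nodes))
  caches <- if (train) vector("list", length(nodes)) else NULL
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    vals[[i]] <- switch(nd$op,
      input = {
        if (dim(x)[4] != nd$ch) bc_stop("input has ", dim(x)[4],
                                        " channels; model expects ", nd$ch)
        x
      },
      conv = {
        a <- vals[[nd$inputs]]
        d <- dim(a)
        w <- params[[nd$w]]
        # im2col + GEMM; weight layout (k, k, k, cin, cout) flattens
        # column-major to exactly the unfolded column order. A 1x1x1 conv
        # is a plain channel mixing, no unfolding needed.
        cols <- if (nd$k == 1L) matrix(a, ncol = nd$cin)
                else .im2col3d(as.numeric(a), d[1:3], nd$k, nd$cin)
        if (train) caches[[i]] <- cols
        y <- cols %*% matrix(w, ncol = nd$cout)
        dim(y) <- c(d[1:3], nd$cout)
        y
      },
      inorm = {
        a <- vals[[nd$inputs]]
        d <- dim(a)
        m <- channel_mat(a)
        mu <- colMeans(m)
        gam <- params[[nd$gamma]]
        bet <- params[[nd$beta]]
        xhat <- m
        istd <- numeric(ncol(m))
        y <- m
        for (j in seq_len(ncol(m))) {
          cj <- m[, j] - mu[j]
          istd[j] <- 1 / sqrt(sum(cj * cj) / nrow(m) + BC_INORM_EPS)
          xj <- cj * istd[j]
          xhat[, j] <- xj
          y[, j] <- xj * gam[j] + bet[j]
        }
        if (train) caches[[i]] <- list(xhat = xhat, istd = istd)
        dim(y) <- d
        y
      },
      relu = {
        a <- vals[[nd$inputs]]
        a[a < 0] <- 0
        a
      },
      pool = {
        a <- vals[[nd$inputs]]
        d <- dim(a)
        if (any(d[1:3] %% 2L != 0L))
          bc_stop("spatial dims (", paste(d[1:3], collapse = "x"),
                  ") not divisible by 2 at a pooling stage")
        r <- .maxpool3d_fw(as.numeric(a), d[1:3], d[4])
        if (train) caches[[i]] <- list(argmax = r$argmax, n_in = length(a), d_in = d)
        array(r$out, c(d[1:3] %/% 2L, d[4]))
      },
      up = {
        a <- vals[[nd$inputs]]
        d <- dim(a)
        f <- nd$factors
        y <- .upsample3d_fw(as.numeric(a), d[1:3], d[4], f[1], f[2], f[3])
        array(y, c(d[1:3] * f, d[4]))
      },
      concat = {
        a <- vals[[nd$inputs[1]]]
        b <- vals[[nd$inputs[2]]]
        d <- dim(a)
        array(c(a, b), c(d[1:3], d[4] + dim(b)[4]))
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      softmax = nn_softmax_apply(vals[[nd$inputs]]),
      bc_stop("unknown op ", nd$op))
  }
  out <- vals[[model$out_id]]
  if (!train) return(list(out = out))
  list(out = out, vals = vals, caches = caches)
}

# Backward pass. g_out is dLoss/d(output of out_id node). Returns gradients
# as a named list parallel to model$params.
nn_backward <- function(model, fw, g_out) {
  nodes <- model$nodes
  params <- model$params
  vals <- fw$vals
  caches <- fw$caches
  grads_n <- vector("list", length(nodes))
  pgrads <- list()
  acc <- function(i, g) {
    grads_n[[i]] <<- if (is.null(grads_n[[i]])) g else grads_n[[i]] + g
  }
  acc(model$out_id, g_out)
  for (i in rev(seq_along(nodes))) {
    g <- grads_n[[i]]
    if (is.null(g)) next
    nd <- nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        d <- dim(vals[[nd$inputs]])
        w <- params[[nd$w]]
        wm <- matrix(w, ncol = nd$cout)
        gm <- matrix(g, ncol = nd$cout)
        cols <- caches[[i]]
        pg <- crossprod(cols, gm)
        dim(pg) <- dim(w)
        gi <- tcrossprod(gm, wm)
        if (nd$k > 1L) gi <- .col2im3d(gi, d[1:3], nd$k, nd$cin)
        dim(gi) <- d
        pgrads[[nd$w]] <- if (is.null(pgrads[[nd$w]])) pg else pgrads[[nd$w]] + pg
        acc(nd$inputs, gi)
      },
      inorm = {
        cc <- caches[[i]]
        d <- dim(vals[[nd$inputs]])
        gm <- channel_mat(g)
        gam <- params[[nd$gamma]]
        C <- ncol(gm)
        dgamma <- numeric(C); dbeta <- numeric(C)
        dx <- gm
        n <- nrow(gm)
        for (j in seq_len(C)) {
          gj <- gm[, j]; xj <- cc$xhat[, j]
          dgamma[j] <- sum(gj * xj)
          dbeta[j] <- sum(gj)
          dxh <- gj * gam[j]
          dx[, j] <- (dxh - mean(dxh) - xj * (sum(dxh * xj) / n)) * cc$istd[j]
        }
        for (nm in c("gamma", "beta")) {
          pg <- if (nm == "gamma") dgamma else dbeta
          key <- nd[[nm]]
          pgrads[[key]] <- if (is.null(pgrads[[key]])) pg else pgrads[[key]] + pg
        }
        dim(dx) <- d
        acc(nd$inputs, dx)
      },
      relu = {
        a <- vals[[nd$inputs]]
        g[a <= 0] <- 0
        acc(nd$inputs, g)
      },
      pool = {
        cc <- caches[[i]]
        gi <- .maxpool3d_bw(as.numeric(g), cc$argmax, cc$n_in)
        acc(nd$inputs, array(gi, cc$d_in))
      },
      up = {
        d_out <- dim(g)
        f <- nd$factors
        d_in <- c(d_out[1:3] %/% f, d_out[4])
        gi <- .upsample3d_bw(as.numeric(g), d_in[1:3], d_in[4], f[1], f[2], f[3])
        acc(nd$inputs, array(gi, d_in))
      },
      concat = {
        d <- dim(g)
        ca <- nd$ch_a
        ga <- g[, , , seq_len(ca), drop = FALSE]
        gb <- g[, , , ca + seq_len(nd$ch_b), drop = FALSE]
        acc(nd$inputs[1], ga)
        acc(nd$inputs[2], gb)
      },
      add = {
        acc(nd$inputs[1], g)
        acc(nd$inputs[2], g)
      },
      softmax = {
        p <- vals[[i]]
        d <- dim(p)
        pm <- channel_mat(p)
        gm <- channel_mat(g)
        s <- rowSums(gm * pm)
        dz <- pm * (gm - s)
        acc(nd$inputs, array(dz, d))
      })
    grads_n[[i]] <- NULL  # free
  }
  pgrads
}

# Decoupled-weight-decay Adam (AdamW).
adamw_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7, weight_decay = 1e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
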