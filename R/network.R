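# A compact 3D convolutional network engine.
#
# Networks are directed acyclic graphs of a handful of node types:
#   conv     3D convolution ("same" padding) + per-channel spatial
#            normalization + leaky ReLU (0.1); stride 1 or 2
#   head     3D convolution with bias, linear activation, no normalization
#   add      elementwise residual sum of two nodes
#   upsample nearest-neighbor x2 upsampling
#   concat   channel concatenation of two nodes
#
# Forward activations, analytic gradients and the Adam update are exact;
# convolutions run as chunked im2col + BLAS gemm in C++. Arrays are
# (X, Y, Z, C) for a single sample; mini-batches are accumulated by looping
# over samples and summing parameter gradients.

nn_node <- function(name, op, from, k = 3L, stride = 1L, cout = NULL) {
  list(name = name, op = op, from = from, k = as.integer(k),
       stride = as.integer(stride), cout = cout)
}

# Kaiming-style initialization for leaky-ReLU fan-in.
init_params <- function(nodes, cin_map, seed = NULL) {
  with_seed(seed, {
    params <- list()
    for (nd in nodes) {
      if (!nd$op %in% c("conv", "head")) next
      cin <- cin_map[[nd$name]]
      fan_in <- nd$k^3 * cin
      gain <- sqrt(2 / (1 + 0.1^2))
      w <- matrix(rnorm(fan_in * nd$cout, sd = gain / sqrt(fan_in)), fan_in, nd$cout)
      p <- list(w = w)
      if (nd$op == "conv") {
        p$gamma <- rep(1, nd$cout); p$beta <- rep(0, nd$cout)
      } else {
        p$b <- rep(0, nd$cout)
      }
      params[[nd$name]] <- p
    }
    params
  })
}

# Resolve per-node input channel counts and output shapes symbolically.
trace_shapes <- function(nodes, input_dim) {
  shapes <- list(.input = input_dim)
  cin_map <- list()
  for (nd in nodes) {
    ins <- lapply(nd$from, function(f) shapes[[f]])
    if (any(vapply(ins, is.null, TRUE))) stop("unknown input node for ", nd$name)
    s <- ins[[1]]
    if (nd$op %in% c("conv", "head")) {
      cin_map[[nd$name]] <- s[4]
      sp <- if (nd$stride == 2) s[1:3] %/% 2L else s[1:3]
      shapes[[nd$name]] <- c(sp, nd$cout)
    } else if (nd$op == "add") {
      s2 <- ins[[2]]
      if (!identical(s, s2)) stop("residual add shape mismatch at ", nd$name)
      shapes[[nd$name]] <- s
    } else if (nd$op == "upsample") {
      shapes[[nd$name]] <- c(s[1:3] * 2L, s[4])
    } else if (nd$op == "concat") {
      s2 <- ins[[2]]
      if (!identical(s[1:3], s2[1:3])) stop("concat spatial mismatch at ", nd$name)
      shapes[[nd$name]] <- c(s[1:3], s[4] + s2[4])
    } else stop("unknown op ", nd$op)
  }
  list(shapes = shapes, cin_map = cin_map)
}

new_network <- function(nodes, outputs, input_dim, seed = NULL, cfg = NULL) {
  tr <- trace_shapes(nodes, input_dim)
  structure(list(nodes = nodes, outputs = outputs, input_dim = input_dim,
                 shapes = tr$shapes, cfg = cfg,
                 params = init_params(nodes, tr$cin_map, seed)),
            class = "spineplane_net")
}

#' @export
print.spineplane_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) sum(vapply(p, length, 1L)), 1L))
  cat("<spineplane_net> ", length(x$nodes), " nodes, ",
      format(np, big.mark = ","), " parameters\n", sep = "")
  cat("input ", paste(x$input_dim, collapse = "x"), " -> outputs: ",
      paste(vapply(x$outputs, function(o)
        paste(paste(x$shapes[[o]], collapse = "x")), ""), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Forward pass. When cache = TRUE all intermediates needed for the backward
# pass are retained; otherwise activations are freed as soon as no remaining
# node consumes them.
net_forward <- function(net, x, cache = FALSE) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a 3D or 4D array")
  if (length(d) == 3) dim(x) <- c(d, 1L)
  stopifnot(identical(as.integer(dim(x)), as.integer(net$input_dim)))
  acts <- new.env(parent = emptyenv())
  assign(".input", x, acts)
  caches <- if (cache) list()
  last_use <- last_use_index(net)
  for (i in seq_along(net$nodes)) {
    nd <- net$nodes[[i]]
    ins <- lapply(nd$from, function(f) get(f, acts))
    a <- ins[[1]]
    if (nd$op %in% c("conv", "head")) {
      p <- net$params[[nd$name]]
      pad <- (nd$k - 1L) %/% 2L
      pre <- conv3d_fw_cpp(a, dim(a), p$w, if (nd$op == "head") p$b else numeric(0),
                           nd$k, nd$stride, pad)
      if (nd$op == "conv") {
        nrm <- instnorm_fw_cpp(pre, dim(pre), p$gamma, p$beta, 1e-5)
        out <- leaky_fw_cpp(nrm$y, 0.1)
        dim(out) <- dim(pre)
        if (cache) caches[[nd$name]] <- list(pre = pre, mu = nrm$mu,
                                             invstd = nrm$invstd, post = nrm$y)
      } else {
        out <- pre
      }
    } else if (nd$op == "add") {
      out <- a + ins[[2]]
    } else if (nd$op == "upsample") {
      out <- upsample2_fw_cpp(a, dim(a))
    } else if (nd$op == "concat") {
      out <- c(a, ins[[2]])
      dim(out) <- c(dim(ins[[1]])[1:3], dim(ins[[1]])[4] + dim(ins[[2]])[4])
    }
    assign(nd$name, out, acts)
    if (!cache) {
      for (f in nd$from) if (last_use[[f]] <= i && f != ".input") rm(list = f, envir = acts)
    }
  }
  outs <- lapply(net$outputs, function(o) get(o, acts))
  names(outs) <- net$outputs
  list(outputs = outs, acts = if (cache) acts, caches = caches)
}

last_use_index <- function(net) {
  lu <- list()
  keep <- c(net$outputs, ".input")
  for (i in seq_along(net$nodes)) for (f in net$nodes[[i]]$from) lu[[f]] <- i
  for (k in keep) lu[[k]] <- length(net$nodes) + 1L
  lu
}

# Backward pass from gradients w.r.t. the output nodes.
# Returns list(grads = per-parameter gradients). Requires a cached forward.
net_backward <- function(net, fwd, gout) {
  acts <- fwd$acts
  caches <- fwd$caches
  gacc <- new.env(parent = emptyenv())
  addg <- function(name, g) {
    if (exists(name, gacc)) assign(name, get(name, gacc) + g, gacc)
    else assign(name, g, gacc)
  }
  for (o in names(gout)) addg(o, gout[[o]])
  grads <- list()
  for (i in rev(seq_along(net$nodes))) {
    nd <- net$nodes[[i]]
    if (!exists(nd$name, gacc)) next
    g <- get(nd$name, gacc)
    rm(list = nd$name, envir = gacc)
    a <- get(nd$from[[1]], acts)
    if (nd$op %in% c("conv", "head")) {
      p <- net$params[[nd$name]]
      pad <- (nd$k - 1L) %/% 2L
      need_gx <- nd$from[[1]] != ".input"
      if (nd$op == "conv") {
        cc <- caches[[nd$name]]
        g <- leaky_bw_cpp(cc$post, g, 0.1)
        nb <- instnorm_bw_cpp(cc$pre, dim(cc$pre), p$gamma, cc$mu, cc$invstd, g)
        cb <- conv3d_bw_cpp(a, dim(a), p$w, nb$gx, nd$k, nd$stride, pad, need_gx)
        grads[[nd$name]] <- list(w = cb$gw, gamma = nb$dgamma, beta = nb$dbeta)
      } else {
        cb <- conv3d_bw_cpp(a, dim(a), p$w, g, nd$k, nd$stride, pad, need_gx)
        grads[[nd$name]] <- list(w = cb$gw, b = cb$gb)
      }
      if (need_gx) { dim(cb$gx) <- dim(a); addg(nd$from[[1]], cb$gx) }
    } else if (nd$op == "add") {
      addg(nd$from[[1]], g)
      addg(nd$from[[2]], g)
    } else if (nd$op == "upsample") {
      addg(nd$from[[1]], upsample2_bw_cpp(g, dim(g)))
    } else if (nd$op == "concat") {
      c1 <- dim(a)[4]
      n1 <- prod(dim(a))
      g1 <- g[seq_len(n1)]; dim(g1) <- dim(a)
      b <- get(nd$from[[2]], acts)
      g2 <- g[-seq_len(n1)]; dim(g2) <- dim(b)
      addg(nd$from[[1]], g1)
      addg(nd$from[[2]], g2)
    }
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Adam -------------------------------------------------------------------

adam_init <- function(net) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(net$params)) {
    st$m[[nm]] <- lapply(net$params[[nm]], function(p) p * 0)
    st$v[[nm]] <- lapply(net$params[[nm]], function(p) p * 0)
  }
  st
}

adam_step <- function(net, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (weight_decay > 0 && pn == "w") g <- g + weight_decay * net$params[[nm]][[pn]]
      state$m[[nm]][[pn]] <- beta1 * state$m[[nm]][[pn]] + (1 - beta1) * g
      state$v[[nm]][[pn]] <- beta2 * state$v[[nm]][[pn]] + (1 - beta2) * g * g
      upd <- (state$m[[nm]][[pn]] / bc1) / (sqrt(state$v[[nm]][[pn]] / bc2) + eps)
      net$params[[nm]][[pn]] <- net$params[[nm]][[pn]] - lr * upd
    }
  }
  list(net = net, state = state)
}

# SGD with momentum (used by the segmentation pipeline).
sgd_init <- function(net) {
  v <- list()
  for (nm in names(net$params)) v[[nm]] <- lapply(net$params[[nm]], function(p) p * 0)
  list(v = v)
}

sgd_step <- function(net, grads, state, lr, momentum = 0.99, weight_decay = 0) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (weight_decay > 0 && pn == "w") g <- g + weight_decay * net$params[[nm]][[pn]]
      state$v[[nm]][[pn]] <- momentum * state$v[[nm]][[pn]] + g
      net$params[[nm]][[pn]] <- net$params[[nm]][[pn]] - lr * state$v[[nm]][[pn]]
    }
  }
  list(net = net, state = state)
}
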