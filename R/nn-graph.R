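# Compact CNN engine: a directed acyclic graph of layer nodes with manual
# reverse-mode differentiation and an Adam optimizer. Tensors are dense R
# arrays, dim (H, W, C, N) for feature maps and (units, N) for feature
# vectors; convolution and pooling run through the C++ kernels in src/.
#
# The builder guarantees topological order (a node may only consume nodes
# created before it), so forward is a single left-to-right sweep and
# backward a right-to-left sweep with gradient accumulation at fan-outs.

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$input <- NA_integer_
  g$output <- NA_integer_
  class(g) <- "nn_graph"
  g
}

# Adds a node and returns its id. Tracks (size, channels) for 4-D nodes and
# `units` for vector nodes so parameter shapes are known at build time.
nn_add <- function(g, op, inputs = integer(0), ...) {
  inputs <- as.integer(inputs)  # force before id: inputs may be nested calls
  cfg <- list(...)
  id <- length(g$nodes) + 1L
  ins <- lapply(inputs, function(i) g$nodes[[i]])
  node <- list(id = id, op = op, inputs = inputs, cfg = cfg)

  node[c("kind", "size", "channels", "units")] <- switch(op,
    input = list("4d", cfg$size, cfg$channels, NULL),
    conv = {
      stopifnot(ins[[1]]$kind == "4d")
      node$cfg$cin <- ins[[1]]$channels
      if (is.null(cfg$groups)) node$cfg$groups <- 1L
      if (node$cfg$cin %% node$cfg$groups != 0L)
        stop("conv: input channels not divisible by groups")
      list("4d", ins[[1]]$size, cfg$cout, NULL)
    },
    maxpool = {
      s <- ins[[1]]$size
      so <- (s + 2L * cfg$pad - cfg$k) %/% cfg$stride + 1L
      list("4d", so, ins[[1]]$channels, NULL)
    },
    upsample2 = list("4d", ins[[1]]$size * 2L, ins[[1]]$channels, NULL),
    concat = {
      kinds <- vapply(ins, `[[`, "", "kind")
      if (all(kinds == "4d")) {
        sizes <- vapply(ins, `[[`, 0L, "size")
        if (length(unique(sizes)) != 1L)
          stop("concat: spatial sizes differ")
        list("4d", sizes[1],
             sum(vapply(ins, `[[`, 0L, "channels")), NULL)
      } else {
        list("mat", NULL, NULL, sum(vapply(ins, `[[`, 0L, "units")))
      }
    },
    add = list(ins[[1]]$kind, ins[[1]]$size, ins[[1]]$channels,
               ins[[1]]$units),
    flatten = list("mat", NULL, NULL,
                   ins[[1]]$size^2 * ins[[1]]$channels),
    gap = list("mat", NULL, NULL, ins[[1]]$channels),
    dense = {
      node$cfg$nin <- ins[[1]]$units
      list("mat", NULL, NULL, cfg$units)
    },
    relu = , swish = , sigmoid = , dropout =
      list(ins[[1]]$kind, ins[[1]]$size, ins[[1]]$channels, ins[[1]]$units),
    stop("unknown op: ", op)
  )
  g$nodes[[id]] <- node
  if (op == "input") g$input <- id
  g$output <- id
  id
}

# He-normal initialization for conv and dense weights; zero biases.
nn_init <- function(g, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- vector("list", length(g$nodes))
  for (nd in g$nodes) {
    if (nd$op == "conv") {
      k <- nd$cfg$k
      cg <- nd$cfg$cin %/% nd$cfg$groups
      fan_in <- k * k * cg
      params[[nd$id]] <- list(
        W = array(stats::rnorm(k * k * cg * nd$cfg$cout,
                               sd = sqrt(2 / fan_in)),
                  dim = c(k, k, cg, nd$cfg$cout)),
        b = numeric(nd$cfg$cout))
    } else if (nd$op == "dense") {
      params[[nd$id]] <- list(
        W = matrix(stats::rnorm(nd$cfg$units * nd$cfg$nin,
                                sd = sqrt(2 / nd$cfg$nin)),
                   nd$cfg$units, nd$cfg$nin),
        b = numeric(nd$cfg$units))
    }
  }
  params
}

nn_count_params <- function(params) {
  sum(vapply(params, function(p)
    if (is.null(p)) 0L else length(p$W) + length(p$b), 0L))
}

nn_forward <- function(g, params, x, train = FALSE) {
  cache <- vector("list", length(g$nodes))
  for (nd in g$nodes) {
    id <- nd$id
    xin <- if (length(nd$inputs)) cache[[nd$inputs[1]]]$out
    cache[[id]] <- switch(nd$op,
      input = list(out = x),
      conv = list(out = cpp_conv2d_fw(xin, params[[id]]$W, params[[id]]$b,
                                      nd$cfg$k, (nd$cfg$k - 1L) %/% 2L,
                                      nd$cfg$groups)),
      relu = list(out = { y <- xin; y[y < 0] <- 0; y }),
      swish = {
        s <- 1 / (1 + exp(-xin))
        list(out = xin * s, s = s)
      },
      sigmoid = list(out = 1 / (1 + exp(-xin))),
      maxpool = {
        r <- cpp_maxpool_fw(xin, nd$cfg$k, nd$cfg$stride, nd$cfg$pad)
        list(out = r$out, argmax = r$argmax, in_dim = dim(xin))
      },
      upsample2 = {
        d <- dim(xin)
        list(out = xin[rep(seq_len(d[1]), each = 2),
                       rep(seq_len(d[2]), each = 2), , , drop = FALSE])
      },
      concat = {
        parts <- lapply(nd$inputs, function(i) cache[[i]]$out)
        if (nd$kind == "4d") {
          d <- dim(parts[[1]])
          cs <- vapply(parts, function(p) dim(p)[3], 0)
          out <- array(0, c(d[1], d[2], sum(cs), d[4]))
          at <- 0L
          for (p in parts) {
            out[, , at + seq_len(dim(p)[3]), ] <- p
            at <- at + dim(p)[3]
          }
          list(out = out, sizes = cs)
        } else {
          list(out = do.call(rbind, parts),
               sizes = vapply(parts, nrow, 0))
        }
      },
      add = list(out = xin + cache[[nd$inputs[2]]]$out),
      flatten = {
        d <- dim(xin)
        y <- xin
        dim(y) <- c(prod(d[1:3]), d[4])
        list(out = y, in_dim = d)
      },
      gap = {
        d <- dim(xin)
        y <- xin
        dim(y) <- c(d[1] * d[2], d[3] * d[4])
        list(out = matrix(colMeans(y), d[3], d[4]), in_dim = d)
      },
      dense = list(out = params[[id]]$W %*% xin + params[[id]]$b),
      dropout = {
        if (train && nd$cfg$rate > 0) {
          m <- (stats::runif(length(xin)) >= nd$cfg$rate) /
            (1 - nd$cfg$rate)
          dim(m) <- dim(xin)
          list(out = xin * m, mask = m)
        } else list(out = xin)
      })
  }
  list(out = cache[[g$output]]$out, cache = cache)
}

nn_backward <- function(g, params, cache, dout) {
  n <- length(g$nodes)
  dacc <- vector("list", n)
  grads <- vector("list", n)
  dacc[[g$output]] <- dout
  push <- function(i, d) {
    dacc[[i]] <<- if (is.null(dacc[[i]])) d else dacc[[i]] + d
  }
  for (id in rev(seq_len(n))) {
    d <- dacc[[id]]
    if (is.null(d)) next
    nd <- g$nodes[[id]]
    cc <- cache[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        xin <- cache[[nd$inputs[1]]]$out
        r <- cpp_conv2d_bw(xin, params[[id]]$W, d, nd$cfg$k,
                           (nd$cfg$k - 1L) %/% 2L, nd$cfg$groups)
        grads[[id]] <- list(W = r$dW, b = as.numeric(r$db))
        push(nd$inputs[1], r$dx)
      },
      relu = {
        dx <- d
        dx[cache[[nd$inputs[1]]]$out < 0] <- 0
        push(nd$inputs[1], dx)
      },
      swish = {
        xin <- cache[[nd$inputs[1]]]$out
        s <- cc$s
        push(nd$inputs[1], d * (s + xin * s * (1 - s)))
      },
      sigmoid = push(nd$inputs[1], d * cc$out * (1 - cc$out)),
      maxpool = push(nd$inputs[1],
                     cpp_maxpool_bw(d, cc$argmax, cc$in_dim[1],
                                    cc$in_dim[2])),
      upsample2 = {
        dd <- dim(d)
        t1 <- d[seq(1, dd[1], 2), , , , drop = FALSE] +
          d[seq(2, dd[1], 2), , , , drop = FALSE]
        push(nd$inputs[1],
             t1[, seq(1, dd[2], 2), , , drop = FALSE] +
               t1[, seq(2, dd[2], 2), , , drop = FALSE])
      },
      concat = {
        at <- 0L
        for (t in seq_along(nd$inputs)) {
          sz <- cc$sizes[t]
          if (nd$kind == "4d") {
            push(nd$inputs[t], d[, , at + seq_len(sz), , drop = FALSE])
          } else {
            push(nd$inputs[t], d[at + seq_len(sz), , drop = FALSE])
          }
          at <- at + sz
        }
      },
      add = {
        push(nd$inputs[1], d)
        push(nd$inputs[2], d)
      },
      flatten = {
        dx <- d
        dim(dx) <- cc$in_dim
        push(nd$inputs[1], dx)
      },
      gap = {
        di <- cc$in_dim
        dx <- array(rep(d, each = di[1] * di[2]) / (di[1] * di[2]), di)
        push(nd$inputs[1], dx)
      },
      dense = {
        xin <- cache[[nd$inputs[1]]]$out
        grads[[id]] <- list(W = d %*% t(xin), b = rowSums(d))
        push(nd$inputs[1], t(params[[id]]$W) %*% d)
      },
      dropout = push(nd$inputs[1],
                     if (is.null(cc$mask)) d else d * cc$mask))
  }
  grads
}

adam_init <- function(params) {
  st <- list(t = 0L,
             m = lapply(params, function(p)
               if (is.null(p)) NULL else lapply(p, function(x) x * 0)),
             v = lapply(params, function(p)
               if (is.null(p)) NULL else lapply(p, function(x) x * 0)))
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in names(params[[i]])) {
      gmat <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * gmat
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] +
        (1 - beta2) * gmat^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) /
          (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
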