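# Minimal reverse-mode automatic differentiation on a define-by-run tape.
# Values are numeric scalars, matrices or H x W x C arrays. Nodes are
# immutable lists; gradients are accumulated in a per-backward-pass list
# keyed by node id, so the tape itself is never mutated after creation.
# Internal machinery: none of this is exported.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = list(), backward = NULL,
                    rg = NULL, name = NULL) {
  if (is.null(rg)) rg <- any(vapply(parents, function(p) isTRUE(p$rg), logical(1)))
  id <- tape$n + 1L
  if (id > length(tape$nodes)) length(tape$nodes) <- 2L * length(tape$nodes)
  node <- list(id = id, value = value, parents = parents,
               backward = backward, rg = rg, name = name, tape = tape)
  tape$nodes[[id]] <- node
  tape$n <- id
  node
}

ag_const <- function(tape, v) ag_node(tape, v, rg = FALSE)
ag_param <- function(tape, v, name) ag_node(tape, v, rg = TRUE, name = name)

is_ag <- function(x) is.list(x) && !is.null(x$tape) && !is.null(x$id)

# wrap plain numerics appearing as operands
ag_wrap <- function(tape, x) if (is_ag(x)) x else ag_const(tape, x)

# Gradient accumulation tolerant of H x W vs H x W x 1 shape differences
# arising when one node feeds both 2-D and 3-D consumers.
add_grad <- function(a, b) {
  if (is.null(a)) return(b)
  if (!identical(dim(a), dim(b)) && length(a) == length(b)) dim(b) <- dim(a)
  a + b
}

# Run backward from a scalar loss node. Returns list(by_id = grads indexed by
# node id, params = named list of gradients for ag_param leaves).
ag_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", loss$id)
  grads[[loss$id]] <- 1
  pgrads <- list()
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (!isTRUE(node$rg)) next
    if (length(g) == length(node$value) && !identical(dim(g), dim(node$value)))
      dim(g) <- dim(node$value)
    if (!is.null(node$name)) {
      pgrads[[node$name]] <- add_grad(pgrads[[node$name]], g)
    }
    if (is.null(node$backward)) next
    pg <- node$backward(g, node)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (!isTRUE(p$rg) || is.null(pg[[k]])) next
      gk <- pg[[k]]
      grads[[p$id]] <- add_grad(grads[[p$id]], gk)
    }
  }
  list(by_id = grads, params = pgrads)
}

ag_grad_of <- function(bw, node) bw$by_id[[node$id]]

# ---- elementwise binary ops (length-1 operands broadcast) ------------------

bcast_reduce <- function(g, target_len) if (target_len == 1L && length(g) > 1L) sum(g) else g

ag_add <- function(a, b) {
  tape <- if (is_ag(a)) a$tape else b$tape
  a <- ag_wrap(tape, a); b <- ag_wrap(tape, b)
  ag_node(tape, a$value + b$value, list(a, b), function(g, node) {
    list(bcast_reduce(g, length(node$parents[[1]]$value)),
         bcast_reduce(g, length(node$parents[[2]]$value)))
  })
}

ag_sub <- function(a, b) {
  tape <- if (is_ag(a)) a$tape else b$tape
  a <- ag_wrap(tape, a); b <- ag_wrap(tape, b)
  ag_node(tape, a$value - b$value, list(a, b), function(g, node) {
    list(bcast_reduce(g, length(node$parents[[1]]$value)),
         bcast_reduce(-g, length(node$parents[[2]]$value)))
  })
}

ag_mul <- function(a, b) {
  tape <- if (is_ag(a)) a$tape else b$tape
  a <- ag_wrap(tape, a); b <- ag_wrap(tape, b)
  ag_node(tape, a$value * b$value, list(a, b), function(g, node) {
    av <- node$parents[[1]]$value; bv <- node$parents[[2]]$value
    list(bcast_reduce(g * bv, length(av)), bcast_reduce(g * av, length(bv)))
  })
}

ag_div <- function(a, b) {
  tape <- if (is_ag(a)) a$tape else b$tape
  a <- ag_wrap(tape, a); b <- ag_wrap(tape, b)
  ag_node(tape, a$value / b$value, list(a, b), function(g, node) {
    av <- node$parents[[1]]$value; bv <- node$parents[[2]]$value
    list(bcast_reduce(g / bv, length(av)),
         bcast_reduce(-g * av / (bv * bv), length(bv)))
  })
}

ag_adds <- function(a, s) ag_node(a$tape, a$value + s, list(a), function(g, node) list(g))
ag_muls <- function(a, s) ag_node(a$tape, a$value * s, list(a),
                                  local({ ss <- s; function(g, node) list(g * ss) }))

# ---- elementwise unary ops -------------------------------------------------

ag_relu <- function(a) ag_node(a$tape, pmax(a$value, 0), list(a), function(g, node) {
  list(g * (node$parents[[1]]$value > 0))
})

ag_lrelu <- function(a, alpha = 0.2) {
  ag_node(a$tape, ifelse(a$value > 0, a$value, alpha * a$value), list(a),
          local({ al <- alpha; function(g, node) {
            list(g * ifelse(node$parents[[1]]$value > 0, 1, al))
          } }))
}

ag_tanh <- function(a) {
  y <- tanh(a$value)
  ag_node(a$tape, y, list(a), local({ yy <- y; function(g, node) list(g * (1 - yy * yy)) }))
}

ag_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(a$tape, y, list(a), local({ yy <- y; function(g, node) list(g * yy * (1 - yy)) }))
}

ag_abs <- function(a) ag_node(a$tape, abs(a$value), list(a), function(g, node) {
  list(g * sign(node$parents[[1]]$value))
})

# x assumed > 0 where p is non-integer
ag_pow_s <- function(a, p) {
  ag_node(a$tape, a$value^p, list(a), local({ pp <- p; function(g, node) {
    list(g * pp * node$parents[[1]]$value^(pp - 1))
  } }))
}

ag_mean <- function(a) ag_node(a$tape, mean(a$value), list(a), function(g, node) {
  v <- node$parents[[1]]$value
  list(array(g / length(v), dim(v) %||% length(v)))
})

ag_sum <- function(a) ag_node(a$tape, sum(a$value), list(a), function(g, node) {
  v <- node$parents[[1]]$value
  list(array(g, dim(v) %||% length(v)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- structural ops --------------------------------------------------------

as3d <- function(x) if (length(dim(x)) == 3L) x else array(x, c(dim(x) %||% c(length(x), 1L), 1L))

ag_concat_c <- function(a, b) {
  av <- as3d(a$value); bv <- as3d(b$value)
  y <- array(c(av, bv), c(dim(av)[1:2], dim(av)[3] + dim(bv)[3]))
  ag_node(a$tape, y, list(a, b), local({
    ca <- dim(av)[3]
    function(g, node) {
      g <- as3d(g)
      list(g[, , seq_len(ca), drop = FALSE],
           g[, , -seq_len(ca), drop = FALSE])
    }
  }))
}

acc_rows <- function(g, idx, H) {
  d <- dim(g)
  m <- matrix(g, d[1], prod(d) / d[1])
  rs <- rowsum(m, idx)
  out <- matrix(0, H, ncol(m))
  out[as.integer(rownames(rs)), ] <- rs
  array(out, c(H, d[-1]))
}

pad_indices <- function(H, p, mode) {
  switch(mode,
         reflect = c(seq(p + 1L, 2L), seq_len(H), seq(H - 1L, H - p)),
         replicate = c(rep(1L, p), seq_len(H), rep(H, p)),
         stop("unknown pad mode: ", mode))
}

ag_pad <- function(a, p, mode = "reflect") {
  if (p == 0L) return(a)
  v <- as3d(a$value)
  H <- dim(v)[1]; W <- dim(v)[2]
  if (mode == "zero") {
    y <- array(0, c(H + 2 * p, W + 2 * p, dim(v)[3]))
    y[p + seq_len(H), p + seq_len(W), ] <- v
    return(ag_node(a$tape, y, list(a), local({ pp <- p; Hh <- H; Ww <- W
      function(g, node) list(as3d(g)[pp + seq_len(Hh), pp + seq_len(Ww), , drop = FALSE]) })))
  }
  ri <- pad_indices(H, p, mode); ci <- pad_indices(W, p, mode)
  y <- v[ri, ci, , drop = FALSE]
  ag_node(a$tape, y, list(a), local({ rii <- ri; cii <- ci; Hh <- H; Ww <- W
    function(g, node) {
      g <- acc_rows(as3d(g), rii, Hh)
      g <- aperm(acc_rows(aperm(g, c(2, 1, 3)), cii, Ww), c(2, 1, 3))
      list(g)
    } }))
}

ag_conv2d <- function(x, w, b, kh, kw, stride = 1L) {
  y <- cpp_conv2d(as3d(x$value), w$value, as.numeric(b$value), kh, kw, stride)
  ag_node(x$tape, y, list(x, w, b), local({
    khh <- kh; kww <- kw; ss <- stride
    function(g, node) {
      xv <- as3d(node$parents[[1]]$value); wv <- node$parents[[2]]$value
      bw <- cpp_conv2d_backward(xv, wv, as3d(g), khh, kww, ss)
      list(bw$dx, bw$dw, as.numeric(bw$db))
    } }))
}

ag_upsample2 <- function(a) {
  v <- as3d(a$value)
  H <- dim(v)[1]; W <- dim(v)[2]
  y <- v[rep(seq_len(H), each = 2L), rep(seq_len(W), each = 2L), , drop = FALSE]
  ag_node(a$tape, y, list(a), function(g, node) {
    g <- as3d(g)
    o <- seq(1L, dim(g)[1], 2L); e <- o + 1L
    oc <- seq(1L, dim(g)[2], 2L); ec <- oc + 1L
    list(g[o, oc, , drop = FALSE] + g[o, ec, , drop = FALSE] +
           g[e, oc, , drop = FALSE] + g[e, ec, , drop = FALSE])
  })
}

ag_avgpool2 <- function(a) {
  v <- as3d(a$value)
  o <- seq(1L, dim(v)[1] - 1L, 2L); oc <- seq(1L, dim(v)[2] - 1L, 2L)
  y <- (v[o, oc, , drop = FALSE] + v[o + 1L, oc, , drop = FALSE] +
          v[o, oc + 1L, , drop = FALSE] + v[o + 1L, oc + 1L, , drop = FALSE]) / 4
  ag_node(a$tape, y, list(a), local({ dd <- dim(v); function(g, node) {
    g <- as3d(g)
    gx <- array(0, dd)
    gi <- g[rep(seq_len(dim(g)[1]), each = 2L), rep(seq_len(dim(g)[2]), each = 2L), ,
            drop = FALSE] / 4
    gx[seq_len(2L * dim(g)[1]), seq_len(2L * dim(g)[2]), ] <- gi
    list(gx)
  } }))
}

# Instance normalization without affine parameters (per-channel over H x W).
ag_instnorm <- function(a, eps = 1e-5) {
  v <- as3d(a$value)
  d <- dim(v); n <- d[1] * d[2]
  m <- matrix(v, n, d[3])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  s <- sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, s, "/")
  ag_node(a$tape, array(xhat, d), list(a), local({
    xh <- xhat; sd_ <- s; dd <- d; nn <- n
    function(g, node) {
      gm <- matrix(g, nn, dd[3])
      gmean <- colMeans(gm)
      gxmean <- colMeans(gm * xh)
      # (g - mean(g) - xhat * mean(g * xhat)) / s
      dx <- sweep(gm, 2, gmean) - sweep(xh, 2, gxmean, "*")
      dx <- sweep(dx, 2, sd_, "/")
      list(array(dx, dd))
    } }))
}

# Weighted sum over channels (e.g. RGB -> luma). w is a plain numeric vector.
ag_chanwsum <- function(a, w) {
  v <- as3d(a$value)
  y <- matrix(0, dim(v)[1], dim(v)[2])
  for (c in seq_along(w)) y <- y + w[c] * v[, , c]
  ag_node(a$tape, y, list(a), local({ ww <- w; dd <- dim(v); function(g, node) {
    gx <- array(0, dd)
    for (c in seq_along(ww)) gx[, , c] <- ww[c] * g
    list(gx)
  } }))
}

# ---- clamped integer shift and bilinear sampling (for LBP neighbours) ------

shift_clamp <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

adj_shift_clamp <- function(g, dy, dx) {
  H <- nrow(g); W <- ncol(g)
  ri <- pmin(pmax(seq_len(H) + dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1L), W)
  out <- matrix(0, H, W)
  rs <- rowsum(g, ri)
  out[as.integer(rownames(rs)), ] <- rs
  t2 <- matrix(0, W, H)
  cs <- rowsum(t(out), ci)
  t2[as.integer(rownames(cs)), ] <- cs
  t(t2)
}

# Bilinear sample of a single-channel image at fixed fractional offset
# (dy, dx), border replicated. Linear in x, so the adjoint reuses the weights.
ag_shift_bilinear <- function(a, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  wts <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
  offs <- list(c(y0, x0), c(y0, x0 + 1), c(y0 + 1, x0), c(y0 + 1, x0 + 1))
  keep <- which(wts > 1e-12)
  v <- a$value
  y <- matrix(0, nrow(v), ncol(v))
  for (k in keep) y <- y + wts[k] * shift_clamp(v, offs[[k]][1], offs[[k]][2])
  ag_node(a$tape, y, list(a), local({ ww <- wts; oo <- offs; kk <- keep
    function(g, node) {
      gx <- matrix(0, nrow(g), ncol(g))
      for (k in kk) gx <- gx + ww[k] * adj_shift_clamp(g, oo[[k]][1], oo[[k]][2])
      list(gx)
    } }))
}
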