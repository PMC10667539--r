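# Minimal CPU neural-network engine.
#
# All forward and backward passes are expressed as dense matrix products
# (BLAS) plus gather/scatter index operations. Convolutions use the im2col
# construction: patches of the zero-padded input are gathered into a
# (positions x kernel*channels) matrix and multiplied by a weight matrix;
# "same" padding uses ceiling division, so a stride-2 layer maps side s to
# ceiling(s / 2) (104 -> 52 -> 26 -> 13). Transposed convolutions are the
# exact adjoint (scatter-add of the same geometry). Feature maps travel as
# (H*W x channels) matrices in pixel column-major order; dense activations
# as 1 x n row vectors.

# --- layer specs -------------------------------------------------------------

#' Neural-network layer specifications
#'
#' Constructors for the layer types used by the VAE and the CNN classifiers.
#' A network is a list of these specs compiled by [nn_build()].
#'
#' @param filters,units layer width.
#' @param kernel square kernel side.
#' @param stride stride (same padding, ceiling division).
#' @param activation `"relu"`, `"linear"` or `"sigmoid"`.
#' @param rate dropout rate in `[0, 1)`.
#' @param h,w,c target shape of a reshape layer.
#' @param name optional layer name.
#' @return a layer spec list.
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
layer_conv <- function(filters, kernel = 3, stride = 2, activation = "relu",
                       name = NULL) {
  list(type = "conv", filters = filters, kernel = kernel, stride = stride,
       activation = activation, name = name)
}

#' @rdname nn_layers
#' @export
layer_conv_transpose <- function(filters, kernel = 3, stride = 2,
                                 activation = "relu", name = NULL) {
  list(type = "conv_transpose", filters = filters, kernel = kernel,
       stride = stride, activation = activation, name = name)
}

#' @rdname nn_layers
#' @export
layer_dense <- function(units, activation = "relu", name = NULL) {
  list(type = "dense", units = units, activation = activation, name = name)
}

#' @rdname nn_layers
#' @export
layer_flatten <- function(name = NULL) list(type = "flatten", name = name)

#' @rdname nn_layers
#' @export
layer_reshape <- function(h, w, c, name = NULL) {
  list(type = "reshape", h = h, w = w, c = c, name = name)
}

#' @rdname nn_layers
#' @export
layer_dropout <- function(rate, name = NULL) {
  list(type = "dropout", rate = rate, name = name)
}

#' @rdname nn_layers
#' @export
layer_gap <- function(name = NULL) list(type = "gap", name = name)

# --- geometry ----------------------------------------------------------------

conv_geom <- function(h, w, k, stride) {
  out_h <- ceiling(h / stride); out_w <- ceiling(w / stride)
  pad_h <- max((out_h - 1) * stride + k - h, 0)
  pad_w <- max((out_w - 1) * stride + k - w, 0)
  pt <- pad_h %/% 2; pl <- pad_w %/% 2
  hp <- h + pad_h; wp <- w + pad_w
  inner_idx <- as.vector(outer(seq_len(h) + pt, (seq_len(w) + pl - 1) * hp, `+`))
  npos <- out_h * out_w; kk <- k * k
  pr <- rep((seq_len(out_h) - 1) * stride, times = out_w)
  pc <- rep((seq_len(out_w) - 1) * stride, each = out_h)
  gather <- matrix(0L, npos, kk)
  for (dw in seq_len(k)) for (dh in seq_len(k)) {
    j <- dh + (dw - 1) * k
    gather[, j] <- (pr + dh) + (pc + dw - 1) * hp
  }
  # trivial geometry: 1x1 kernel at stride 1 is a plain per-pixel matmul
  trivial <- k == 1 && stride == 1
  list(h = h, w = w, hp = hp, wp = wp, out_h = out_h, out_w = out_w,
       pad_top = pt, pad_left = pl, npos = npos, kk = kk,
       inner_idx = inner_idx, gather_idx = as.vector(gather),
       gather_mat = gather, trivial = trivial)
}

# Precomputed linear-index scatter maps: the adjoint of the patch gather.
# For kernel element j, patch entries of the f-channel (npos*kk x f) matrix
# land on distinct pixels of the unpadded h x w plane (entries falling into
# the padding are dropped), so the scatter is kk disjoint vector additions.
make_scatter <- function(g, f) {
  lapply(seq_len(g$kk), function(j) {
    idx <- g$gather_mat[, j]
    r0 <- (idx - 1) %% g$hp + 1 - g$pad_top
    c0 <- (idx - 1) %/% g$hp + 1 - g$pad_left
    valid <- which(r0 >= 1 & r0 <= g$h & c0 >= 1 & c0 <= g$w)
    dst <- r0[valid] + (c0[valid] - 1) * g$h
    list(
      src = as.integer(outer(valid + (j - 1) * g$npos,
                             (seq_len(f) - 1) * (g$npos * g$kk), `+`)),
      dst = as.integer(outer(dst, (seq_len(f) - 1) * (g$h * g$w), `+`)))
  })
}

# e: (npos*kk x f) patch-entry matrix -> (h*w x f) accumulated plane
scatter_add <- function(e, scatter, n_pix, f) {
  out <- numeric(n_pix * f)
  for (s in scatter) out[s$dst] <- out[s$dst] + e[s$src]
  dim(out) <- c(n_pix, f)
  out
}

glorot <- function(n_row, n_col, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
}

# --- build -------------------------------------------------------------------

#' Compile a network from layer specs
#'
#' Resolves the shape chain from `input_shape`, precomputes convolution
#' geometries, and initializes parameters (Glorot uniform, seeded).
#'
#' @param specs list of layer specs (see [nn_layers]).
#' @param input_shape `c(h, w, channels)` for spatial input or a single
#'   integer for vector input.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `kv_nn` with `layers` (specs + parameters +
#'   geometry) and a `summary` data frame of per-layer output shapes and
#'   parameter counts.
#' @export
nn_build <- function(specs, input_shape, seed = 1) {
  with_seed(seed, {
    spatial <- length(input_shape) == 3
    h <- if (spatial) input_shape[1] else NA
    w <- if (spatial) input_shape[2] else NA
    c_in <- if (spatial) input_shape[3] else input_shape[1]
    layers <- list()
    rows <- list()
    for (i in seq_along(specs)) {
      l <- specs[[i]]
      if (is.null(l$name)) l$name <- sprintf("%s_%d", l$type, i)
      n_par <- 0
      if (l$type == "conv") {
        kv_assert(spatial, "conv layer on non-spatial input")
        l$geom <- conv_geom(h, w, l$kernel, l$stride)
        l$c_in <- c_in
        if (!l$geom$trivial) l$scatter <- make_scatter(l$geom, c_in)
        kkc <- l$kernel^2 * c_in
        l$W <- glorot(kkc, l$filters, kkc, l$kernel^2 * l$filters)
        l$b <- numeric(l$filters)
        n_par <- length(l$W) + l$filters
        h <- l$geom$out_h; w <- l$geom$out_w; c_in <- l$filters
      } else if (l$type == "conv_transpose") {
        kv_assert(spatial, "conv_transpose layer on non-spatial input")
        oh <- h * l$stride; ow <- w * l$stride
        l$geom <- conv_geom(oh, ow, l$kernel, l$stride)
        kv_assert(l$geom$npos == h * w,
                  "conv_transpose geometry does not close")
        l$scatter <- make_scatter(l$geom, l$filters)
        l$c_in <- c_in
        kkf <- l$kernel^2 * l$filters
        l$W <- glorot(kkf, c_in, l$kernel^2 * c_in, kkf)
        l$b <- numeric(l$filters)
        n_par <- length(l$W) + l$filters
        h <- oh; w <- ow; c_in <- l$filters
      } else if (l$type == "dense") {
        n_in <- if (spatial) h * w * c_in else c_in
        kv_assert(!spatial, "flatten before a dense layer")
        l$W <- glorot(n_in, l$units, n_in, l$units)
        l$b <- numeric(l$units)
        n_par <- length(l$W) + l$units
        c_in <- l$units
      } else if (l$type == "flatten") {
        kv_assert(spatial, "flatten on non-spatial input")
        c_in <- h * w * c_in
        l$from <- c(h, w)
        spatial <- FALSE; h <- NA; w <- NA
      } else if (l$type == "reshape") {
        kv_assert(!spatial && c_in == l$h * l$w * l$c,
                  "reshape size does not match input width")
        spatial <- TRUE; h <- l$h; w <- l$w; c_in <- l$c
      } else if (l$type == "dropout") {
        # shape unchanged
      } else if (l$type == "gap") {
        kv_assert(spatial, "gap on non-spatial input")
        spatial <- FALSE; h <- NA; w <- NA
      } else kv_error(sprintf("unknown layer type '%s'", l$type),
                      "kv_argument_error")
      rows[[i]] <- data.frame(
        layer = l$name, type = l$type,
        output_shape = if (spatial) sprintf("%d x %d x %d", h, w, c_in)
                       else sprintf("%d", c_in),
        n_params = n_par)
      layers[[i]] <- l
    }
    structure(list(layers = layers, input_shape = input_shape,
                   output_units = c_in, output_spatial = spatial,
                   summary = do.call(rbind, rows)),
              class = "kv_nn")
  })
}

#' @export
print.kv_nn <- function(x, ...) {
  cat("<kv_nn>\n"); print(x$summary, row.names = FALSE); invisible(x)
}

# --- activations -------------------------------------------------------------

act_fwd <- function(z, act) {
  switch(act, relu = (z + abs(z)) * 0.5, linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         kv_error(sprintf("unknown activation '%s'", act), "kv_argument_error"))
}

act_bwd <- function(d, z, act) {
  switch(act,
         relu = d * (z > 0),
         linear = d,
         sigmoid = { s <- 1 / (1 + exp(-z)); d * s * (1 - s) })
}

# --- forward / backward ------------------------------------------------------

as_val <- function(x) {
  if (is.list(x)) return(x)
  if (is.matrix(x) || length(dim(x)) == 0) {
    if (is.matrix(x) && nrow(x) == 1) return(list(mat = x, h = NA, w = NA))
    return(list(mat = matrix(x, 1), h = NA, w = NA))
  }
  d <- dim(x)
  list(mat = matrix(as.vector(x), d[1] * d[2], d[3]), h = d[1], w = d[2])
}

val_to_array <- function(val) {
  array(as.vector(val$mat), c(val$h, val$w, ncol(val$mat)))
}

#' Forward pass
#'
#' @param net a compiled [nn_build()] network.
#' @param x input: an `H x W x C` array, a numeric vector, or a `val` list.
#' @param training apply dropout (`TRUE`) or run it as identity (`FALSE`).
#' @return list with `out` (output value), `caches` (per-layer caches for
#'   [nn_backward()]).
#' @export
nn_forward <- function(net, x, training = FALSE) {
  val <- as_val(x)
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      g <- l$geom
      if (g$trivial) {
        p <- val$mat
      } else {
        xp <- matrix(0, g$hp * g$wp, l$c_in)
        xp[g$inner_idx, ] <- val$mat
        p <- xp[g$gather_idx, , drop = FALSE]
        dim(p) <- c(g$npos, g$kk * l$c_in)
      }
      z <- p %*% l$W + rep(l$b, each = g$npos)
      val <- list(mat = act_fwd(z, l$activation), h = g$out_h, w = g$out_w)
      caches[[i]] <- list(p = p, z = z, out = val$mat)
    } else if (l$type == "conv_transpose") {
      g <- l$geom
      x_in <- val$mat
      e <- tcrossprod(x_in, l$W)              # npos x kk*F
      z <- scatter_add(e, l$scatter, g$h * g$w, l$filters) +
        rep(l$b, each = g$h * g$w)
      val <- list(mat = act_fwd(z, l$activation), h = g$h, w = g$w)
      caches[[i]] <- list(x = x_in, z = z, out = val$mat)
    } else if (l$type == "dense") {
      z <- val$mat %*% l$W + rep(l$b, each = nrow(val$mat))
      caches[[i]] <- list(x = val$mat, z = z, out = NULL)
      val <- list(mat = act_fwd(z, l$activation), h = NA, w = NA)
      caches[[i]]$out <- val$mat
    } else if (l$type == "flatten") {
      caches[[i]] <- list(h = val$h, w = val$w, c = ncol(val$mat))
      val <- list(mat = matrix(as.vector(val$mat), 1), h = NA, w = NA)
    } else if (l$type == "reshape") {
      val <- list(mat = matrix(as.vector(val$mat), l$h * l$w, l$c),
                  h = l$h, w = l$w)
      caches[[i]] <- list()
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- (matrix(runif(length(val$mat)), nrow(val$mat)) >= l$rate) /
          (1 - l$rate)
        val$mat <- val$mat * mask
        caches[[i]] <- list(mask = mask)
      } else caches[[i]] <- list(mask = NULL)
    } else if (l$type == "gap") {
      caches[[i]] <- list(npos = nrow(val$mat))
      val <- list(mat = matrix(colMeans(val$mat), 1), h = NA, w = NA)
    }
  }
  list(out = val, caches = caches)
}

#' Backward pass
#'
#' Propagates a gradient from the network output back to its input,
#' collecting parameter gradients.
#'
#' @param net compiled network.
#' @param caches caches from [nn_forward()].
#' @param dout gradient with respect to the network output (same shape as
#'   the output `mat`).
#' @param capture optional layer index: the gradient with respect to that
#'   layer's *output* is returned as `captured` (used by Grad-CAM).
#' @return list with `grads` (per layer, `list(W, b)` or `NULL`), `dinput`,
#'   and `captured`.
#' @export
nn_backward <- function(net, caches, dout, capture = NULL) {
  grads <- vector("list", length(net$layers))
  captured <- NULL
  d <- dout
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    if (!is.null(capture) && i == capture) captured <- d
    if (l$type == "conv") {
      g <- l$geom
      dz <- act_bwd(d, cache$z, l$activation)
      grads[[i]] <- list(W = crossprod(cache$p, dz), b = colSums(dz))
      dp <- tcrossprod(dz, l$W)
      d <- if (g$trivial) dp else
        scatter_add(dp, l$scatter, g$h * g$w, l$c_in)
    } else if (l$type == "conv_transpose") {
      g <- l$geom
      dz <- act_bwd(d, cache$z, l$activation)
      db <- colSums(dz)
      dyp <- matrix(0, g$hp * g$wp, l$filters)
      dyp[g$inner_idx, ] <- dz
      de <- dyp[g$gather_idx, , drop = FALSE]      # npos*kk x F
      dim(de) <- c(g$npos, g$kk * l$filters)
      grads[[i]] <- list(W = crossprod(de, cache$x), b = db)
      d <- de %*% l$W
    } else if (l$type == "dense") {
      dz <- act_bwd(d, cache$z, l$activation)
      grads[[i]] <- list(W = crossprod(cache$x, dz), b = colSums(dz))
      d <- tcrossprod(dz, l$W)
    } else if (l$type == "flatten") {
      d <- matrix(as.vector(d), cache$h * cache$w, cache$c)
    } else if (l$type == "reshape") {
      d <- matrix(as.vector(d), 1)
    } else if (l$type == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
    } else if (l$type == "gap") {
      d <- matrix(rep(d / cache$npos, each = cache$npos), cache$npos)
    }
  }
  list(grads = grads, dinput = d, captured = captured)
}

# --- optimizers --------------------------------------------------------------

#' Gradient-descent optimizers
#'
#' RMSprop (squared-gradient moving average, decay 0.9 — the from-scratch
#' training optimizer) and Adam (the transfer-learning optimizer). State is
#' kept in an environment keyed by layer/parameter.
#'
#' @param kind `"rmsprop"` or `"adam"`.
#' @param lr learning rate.
#' @param rho RMSprop decay.
#' @param beta1,beta2 Adam moment decays.
#' @param eps numerical stabilizer.
#' @return an optimizer object for [opt_step()].
#' @export
make_optimizer <- function(kind = c("rmsprop", "adam"), lr = 1e-4, rho = 0.9,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, rho = rho, beta1 = beta1,
                 beta2 = beta2, eps = eps, state = new.env(parent = emptyenv()),
                 t = new.env(parent = emptyenv())),
            class = "kv_optimizer")
}

opt_update <- function(opt, key, p, g) {
  st <- opt$state
  if (opt$kind == "rmsprop") {
    v <- if (exists(key, st)) get(key, st) else p * 0
    v <- opt$rho * v + (1 - opt$rho) * g^2
    assign(key, v, st)
    p - opt$lr * g / (sqrt(v) + opt$eps)
  } else {
    mk <- paste0(key, ".m"); vk <- paste0(key, ".v"); tk <- paste0(key, ".t")
    m <- if (exists(mk, st)) get(mk, st) else p * 0
    v <- if (exists(vk, st)) get(vk, st) else p * 0
    t <- if (exists(tk, st)) get(tk, st) + 1 else 1
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    assign(mk, m, st); assign(vk, v, st); assign(tk, t, st)
    mh <- m / (1 - opt$beta1^t); vh <- v / (1 - opt$beta2^t)
    p - opt$lr * mh / (sqrt(vh) + opt$eps)
  }
}

#' @rdname make_optimizer
#' @param opt optimizer object.
#' @param net compiled network.
#' @param grads per-layer gradients from [nn_backward()].
#' @param prefix state key prefix (distinguishes multiple networks sharing
#'   one optimizer).
#' @param trainable optional integer vector of layer indices to update;
#'   `NULL` updates every parameterized layer.
#' @return the updated network.
#' @export
opt_step <- function(opt, net, grads, prefix = "net", trainable = NULL) {
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    if (!is.null(trainable) && !(i %in% trainable)) next
    l <- net$layers[[i]]
    l$W <- opt_update(opt, sprintf("%s.%d.W", prefix, i), l$W, grads[[i]]$W)
    l$b <- opt_update(opt, sprintf("%s.%d.b", prefix, i), l$b, grads[[i]]$b)
    net$layers[[i]] <- l
  }
  net
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    acc[[i]]$W <- acc[[i]]$W + g[[i]]$W
    acc[[i]]$b <- acc[[i]]$b + g[[i]]$b
  }
  acc
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    if (is.null(g[[i]])) next
    g[[i]]$W <- g[[i]]$W * s
    g[[i]]$b <- g[[i]]$b * s
  }
  g
}

# --- losses ------------------------------------------------------------------

# binary cross-entropy from a logit; returns loss and d(loss)/d(logit)
bce_logit <- function(logit, y) {
  # log(1 + exp(l)) - y * l, numerically stable
  loss <- sum(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
  list(loss = loss, dlogit = 1 / (1 + exp(-logit)) - y)
}

#' Save / load a compiled network or model
#'
#' Plain RDS round-trip of the parameter lists; reloading reproduces
#' forward passes bit-exactly.
#' @param model any model object from this package.
#' @param path file path.
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
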