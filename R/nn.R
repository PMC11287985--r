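## Minimal 3D CNN engine: channel-first tensors, hand-derived backprop.
## Layers: 3x3x3 / 1x1x1 convolution (zero padding, stride 1), instance
## normalization, ReLU, 2x2x2 max pooling, nearest-neighbor upsampling,
## channel concatenation, dense layers, sigmoid head, soft-Dice + BCE loss,
## Adam.  Correctness is pinned by finite-difference gradient checks in the
## test suite.

IN_EPS <- 1e-5

he_conv <- function(co, ci, k) {
  array(rnorm(co * ci * k^3, 0, sqrt(2 / (ci * k^3))), dim = c(co, ci, k, k, k))
}
he_dense <- function(out, inp) {
  matrix(rnorm(out * inp, 0, sqrt(2 / inp)), out, inp)
}

cb_init <- function(ci, co, norm = TRUE) {
  p <- list(W = he_conv(co, ci, 3), b = numeric(co))
  if (norm) { p$gamma <- rep(1, co); p$beta <- numeric(co) }
  p
}

## conv -> instance norm -> ReLU -----------------------------------------------
cb_fwd <- function(p, x) {
  z <- conv3d_fwd_cpp(x, p$W, p$b)
  if (!is.null(p$gamma)) {
    nc <- in_fwd(z, p$gamma, p$beta)
    a <- pmax(nc$y, 0)
    list(out = a, cache = list(x = x, incache = nc, a = a))
  } else {
    a <- pmax(z, 0)
    list(out = a, cache = list(x = x, a = a))
  }
}

cb_bwd <- function(p, cache, ga) {
  g <- ga * (cache$a > 0)
  if (!is.null(p$gamma)) {
    nb <- in_bwd(g, cache$incache, p$gamma)
    cv <- conv3d_bwd_cpp(cache$x, p$W, nb$gx)
    list(gx = cv$gx, grads = list(W = cv$gw, b = cv$gb,
                                  gamma = nb$ggamma, beta = nb$gbeta))
  } else {
    cv <- conv3d_bwd_cpp(cache$x, p$W, g)
    list(gx = cv$gx, grads = list(W = cv$gw, b = cv$gb))
  }
}

in_fwd <- function(z, gamma, beta) {
  d <- dim(z)
  M <- matrix(z, nrow = d[1])
  m <- rowMeans(M)
  v <- rowMeans(M * M) - m * m
  inv <- 1 / sqrt(pmax(v, 0) + IN_EPS)
  xh <- (M - m) * inv
  y <- array(gamma * xh + beta, d)
  list(y = y, xhat = xh, inv = inv, d = d)
}

in_bwd <- function(gy, cache, gamma) {
  gyM <- matrix(gy, nrow = cache$d[1])
  gbeta <- rowSums(gyM)
  ggamma <- rowSums(gyM * cache$xhat)
  gxh <- gyM * gamma
  gx <- cache$inv * (gxh - rowMeans(gxh) -
                       cache$xhat * rowMeans(gxh * cache$xhat))
  list(gx = array(gx, cache$d), ggamma = ggamma, gbeta = gbeta)
}

## sequential stack of conv blocks ---------------------------------------------
stack_init <- function(ci, co, n_convs) {
  lapply(seq_len(n_convs), function(i) cb_init(if (i == 1) ci else co, co))
}

stack_fwd <- function(plist, x) {
  caches <- vector("list", length(plist))
  for (i in seq_along(plist)) {
    r <- cb_fwd(plist[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

stack_bwd <- function(plist, caches, g) {
  grads <- vector("list", length(plist))
  for (i in rev(seq_along(plist))) {
    r <- cb_bwd(plist[[i]], caches[[i]], g)
    grads[[i]] <- r$grads
    g <- r$gx
  }
  list(gx = g, grads = grads)
}

## nearest-neighbor x2 upsampling ----------------------------------------------
up_fwd <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2),
    rep(seq_len(d[4]), each = 2), drop = FALSE]
}

up_bwd <- function(g) {
  d <- dim(g)
  o <- lapply(2:4, function(ax) seq(1, d[ax], by = 2))
  e <- lapply(2:4, function(ax) seq(2, d[ax], by = 2))
  acc <- g[, o[[1]], o[[2]], o[[3]], drop = FALSE]
  for (i in 0:7) {
    if (i == 0) next
    ix <- if (bitwAnd(i, 1L)) e[[1]] else o[[1]]
    iy <- if (bitwAnd(i, 2L)) e[[2]] else o[[2]]
    iz <- if (bitwAnd(i, 4L)) e[[3]] else o[[3]]
    acc <- acc + g[, ix, iy, iz, drop = FALSE]
  }
  acc
}

concat_ch <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[-1]
  cs <- vapply(parts, function(p) dim(p)[1], 0L)
  out <- array(0, dim = c(sum(cs), d))
  at <- 0L
  for (p in parts) {
    out[(at + 1):(at + dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

split_ch <- function(g, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    part <- g[(at + 1):(at + s), , , , drop = FALSE]
    at <<- at + s
    part
  })
}

## dense (MLP) stack ------------------------------------------------------------
mlp_init <- function(widths, n_in) {
  lapply(seq_along(widths), function(i) {
    list(W = he_dense(widths[i], if (i == 1) n_in else widths[i - 1]),
         b = numeric(widths[i]))
  })
}

## activation: ReLU between layers; `final` selects the last layer's
## activation ("relu" for feature heads, "sigmoid" for scalar members).
mlp_fwd <- function(plist, x, final = c("relu", "sigmoid")) {
  final <- match.arg(final)
  n <- length(plist)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    z <- as.vector(plist[[i]]$W %*% x + plist[[i]]$b)
    a <- if (i < n || final == "relu") pmax(z, 0) else 1 / (1 + exp(-z))
    caches[[i]] <- list(x = x, z = z, a = a)
    x <- a
  }
  list(out = x, caches = caches)
}

mlp_bwd <- function(plist, caches, g, final = c("relu", "sigmoid"),
                    grad_is_logit = FALSE) {
  final <- match.arg(final)
  n <- length(plist)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    c_ <- caches[[i]]
    gz <- if (i < n || final == "relu") g * (c_$a > 0)
          else if (grad_is_logit) g
          else g * c_$a * (1 - c_$a)
    grads[[i]] <- list(W = outer(gz, c_$x), b = gz)
    g <- as.vector(crossprod(plist[[i]]$W, gz))
  }
  list(gx = g, grads = grads)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## soft-Dice + binary cross-entropy (equal weights), gradient wrt logits.
## p and g are arrays of identical shape; returns loss and dL/dlogit.
seg_loss <- function(p, g, smooth = 1) {
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  dice <- 1 - num / den
  gbce <- (p - g) / n
  gdice_p <- -(2 * g * den - num) / den^2
  glogit <- gbce + gdice_p * p * (1 - p)
  list(loss = bce + dice, glogit = glogit, bce = bce, dice = dice)
}

## Adam ------------------------------------------------------------------------
adam_state <- function(params) rapply(params, function(x) NULL, how = "list")

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s %||% vector("list", length(p))
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], out_s[[i]])
        out_p[[i]] <- r$p; out_s[[i]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  walk(params, grads, state)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(mapply(grads_add, a, b, SIMPLIFY = FALSE))
  a + b
}

grads_scale <- function(a, s) rapply(a, function(x) x * s, how = "replace")

n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
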