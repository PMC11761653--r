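# Minimal dense-network engine: linear / ELU / LayerNorm / ReLU ops with
# reverse-mode gradients and decoupled-weight-decay Adam. Written in plain
# matrix code; gradient correctness is pinned by finite-difference tests.

nn_linear <- function(din, dout) {
  s <- sqrt(6 / (din + dout))
  list(kind = "linear",
       W = matrix(stats::runif(din * dout, -s, s), din, dout),
       b = numeric(dout))
}

nn_linear_identity <- function(d) {
  list(kind = "linear", W = diag(d), b = numeric(d))
}

nn_elu <- function() list(kind = "elu")
nn_relu <- function() list(kind = "relu")

nn_layernorm <- function(d, eps = 1e-5) {
  list(kind = "layernorm", gamma = rep(1, d), beta = numeric(d), eps = eps)
}

# flatten a (B*P) x H activation into B x (P*H), position-major per sample
nn_flatten <- function(P) list(kind = "flatten", P = P)

nn_forward <- function(ops, x, cache = FALSE) {
  caches <- if (cache) vector("list", length(ops)) else NULL
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    if (op$kind == "linear") {
      if (cache) caches[[i]] <- x
      x <- x %*% op$W
      x <- x + rep(op$b, each = nrow(x))
    } else if (op$kind == "elu") {
      if (cache) caches[[i]] <- x
      neg <- x < 0
      x[neg] <- expm1(x[neg])
    } else if (op$kind == "relu") {
      if (cache) caches[[i]] <- x
      x <- pmax(x, 0)
    } else if (op$kind == "layernorm") {
      mu <- rowMeans(x)
      xc <- x - mu
      va <- rowMeans(xc * xc)
      isd <- 1 / sqrt(va + op$eps)
      xhat <- xc * isd
      if (cache) caches[[i]] <- list(xhat = xhat, isd = isd)
      n <- nrow(xhat)
      x <- xhat * rep(op$gamma, each = n) + rep(op$beta, each = n)
    } else if (op$kind == "flatten") {
      if (cache) caches[[i]] <- dim(x)
      B <- nrow(x) / op$P
      x <- matrix(as.vector(t(x)), nrow = B, byrow = TRUE)
    } else stop("unknown op kind: ", op$kind)
  }
  if (cache) list(out = x, caches = caches) else x
}

# Backward pass; returns list(grads = per-op parameter grads, dx = input grad)
nn_backward <- function(ops, caches, dy) {
  grads <- vector("list", length(ops))
  for (i in rev(seq_along(ops))) {
    op <- ops[[i]]
    if (op$kind == "linear") {
      x <- caches[[i]]
      grads[[i]] <- list(W = crossprod(x, dy), b = colSums(dy))
      dy <- dy %*% t(op$W)
    } else if (op$kind == "elu") {
      x <- caches[[i]]
      neg <- x < 0
      dy[neg] <- dy[neg] * exp(x[neg])
    } else if (op$kind == "relu") {
      x <- caches[[i]]
      dy <- dy * (x > 0)
    } else if (op$kind == "layernorm") {
      cc <- caches[[i]]
      xhat <- cc$xhat; isd <- cc$isd
      grads[[i]] <- list(gamma = colSums(dy * xhat), beta = colSums(dy))
      dxhat <- dy * rep(op$gamma, each = nrow(dy))
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      dy <- (dxhat - m1 - xhat * m2) * isd
    } else if (op$kind == "flatten") {
      dims <- caches[[i]]
      H <- dims[2]
      dy <- matrix(as.vector(t(dy)), ncol = H, byrow = TRUE)
    }
  }
  list(grads = grads, dx = dy)
}

# --- AdamW -------------------------------------------------------------

adamw_init <- function(ops, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state <- lapply(ops, function(op) {
    ps <- intersect(names(op), c("W", "b", "gamma", "beta"))
    setNames(lapply(ps, function(p) list(m = op[[p]] * 0, v = op[[p]] * 0)), ps)
  })
  list(state = state, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, weight_decay = weight_decay)
}

adamw_step <- function(ops, grads, opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (i in seq_along(ops)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- opt$state[[i]][[p]]
      st$m <- b1 * st$m + (1 - b1) * g[[p]]
      st$v <- b2 * st$v + (1 - b2) * g[[p]]^2
      opt$state[[i]][[p]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
      ops[[i]][[p]] <- ops[[i]][[p]] - lr * upd -
        lr * opt$weight_decay * ops[[i]][[p]]
    }
  }
  list(ops = ops, opt = opt)
}

# --- losses ------------------------------------------------------------

# mean over rows of (1 - cos(u_i, v_i)); returns loss and gradient wrt pred
cosine_loss <- function(pred, target) {
  nu <- sqrt(rowSums(pred^2))
  nv <- sqrt(rowSums(target^2))
  if (any(nu == 0) || any(nv == 0)) stop("zero vector in cosine loss")
  dot <- rowSums(pred * target)
  cs <- dot / (nu * nv)
  B <- nrow(pred)
  grad <- -(target / (nu * nv) - pred * (dot / (nu^3 * nv))) / B
  list(loss = mean(1 - cs), grad = grad)
}

# softmax cross-entropy with integer labels; returns loss and logit gradient
ce_loss <- function(logits, labels) {
  B <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  ll <- -log(pmax(p[cbind(seq_len(B), labels)], 1e-12))
  grad <- p
  grad[cbind(seq_len(B), labels)] <- grad[cbind(seq_len(B), labels)] - 1
  list(loss = mean(ll), grad = grad / B)
}
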