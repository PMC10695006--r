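# Minimal neural-network kernels: dense layers, GRU cells and sequence
# backpropagation-through-time, written as batch-major base-R matrix code.
# All gradients are analytic and are verified against central finite
# differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.nn_mat <- function(nin, nout, scale = sqrt(1 / nin)) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

.nn_zeros <- function(n) numeric(n)

# softmax over rows, numerically stabilised
.softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# masked categorical cross-entropy.
# logits: B x K, target: integer in 1..K, mask: 0/1 weights.
# Returns summed loss and dlogits for loss_scale * sum(mask * ce).
.ce_forward <- function(logits, target, mask = NULL) {
  B <- nrow(logits)
  if (is.null(mask)) mask <- rep(1, B)
  p <- .softmax(logits)
  picked <- p[cbind(seq_len(B), target)]
  loss <- sum(mask * -log(pmax(picked, 1e-12)))
  grad <- p
  grad[cbind(seq_len(B), target)] <- grad[cbind(seq_len(B), target)] - 1
  grad <- grad * mask
  list(loss = loss, dlogits = grad)
}

# one GRU cell step. x: B x in, h_prev: B x h.
# Wi: in x 3h, Wh: h x 3h, blocks ordered [reset | update | candidate].
.gru_cell <- function(x, h_prev, Wi, Wh, bi, bh) {
  h <- ncol(h_prev)
  Ai <- sweep(x %*% Wi, 2L, bi, "+")
  Ah <- sweep(h_prev %*% Wh, 2L, bh, "+")
  ir <- 1:h; iz <- (h + 1):(2 * h); inn <- (2 * h + 1):(3 * h)
  r <- .sigmoid(Ai[, ir, drop = FALSE] + Ah[, ir, drop = FALSE])
  z <- .sigmoid(Ai[, iz, drop = FALSE] + Ah[, iz, drop = FALSE])
  hn <- Ah[, inn, drop = FALSE]
  n <- tanh(Ai[, inn, drop = FALSE] + r * hn)
  h_new <- (1 - z) * n + z * h_prev
  list(h = h_new, cache = list(x = x, h_prev = h_prev, r = r, z = z,
                               n = n, hn = hn))
}

# backward through one GRU cell.
# dh: gradient w.r.t. h_new. Returns dx, dh_prev and parameter grads.
.gru_cell_backward <- function(dh, cache, Wi, Wh) {
  r <- cache$r; z <- cache$z; n <- cache$n; hn <- cache$hn
  h_prev <- cache$h_prev; x <- cache$x
  dz <- dh * (h_prev - n) * z * (1 - z)
  dn <- dh * (1 - z) * (1 - n^2)
  dh_prev <- dh * z
  dhn <- dn * r
  dr <- dn * hn * r * (1 - r)
  da_i <- cbind(dr, dz, dn)
  da_h <- cbind(dr, dz, dhn)
  dx <- da_i %*% t(Wi)
  dh_prev <- dh_prev + da_h %*% t(Wh)
  list(dx = dx,
       dh_prev = dh_prev,
       dWi = t(x) %*% da_i,
       dWh = t(h_prev) %*% da_h,
       dbi = colSums(da_i),
       dbh = colSums(da_h))
}

# forward over a whole sequence. xs: list over time of B x in matrices.
.gru_seq_forward <- function(xs, h0, Wi, Wh, bi, bh) {
  L <- length(xs)
  hs <- vector("list", L)
  caches <- vector("list", L)
  h <- h0
  for (t in seq_len(L)) {
    step <- .gru_cell(xs[[t]], h, Wi, Wh, bi, bh)
    h <- step$h
    hs[[t]] <- h
    caches[[t]] <- step$cache
  }
  list(hs = hs, h_final = h, caches = caches)
}

# backward through time. dhs: list of per-step external gradients on h_t
# (NULL entries allowed); dh_final: extra gradient on the last state.
.gru_seq_backward <- function(dhs, dh_final, fw, Wi, Wh) {
  L <- length(fw$caches)
  dWi <- matrix(0, nrow(Wi), ncol(Wi))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dbi <- numeric(ncol(Wi)); dbh <- numeric(ncol(Wh))
  dxs <- vector("list", L)
  dh <- if (is.null(dh_final)) 0 else dh_final
  for (t in rev(seq_len(L))) {
    dht <- dh
    if (!is.null(dhs) && !is.null(dhs[[t]])) dht <- dht + dhs[[t]]
    bk <- .gru_cell_backward(dht, fw$caches[[t]], Wi, Wh)
    dxs[[t]] <- bk$dx
    dh <- bk$dh_prev
    dWi <- dWi + bk$dWi; dWh <- dWh + bk$dWh
    dbi <- dbi + bk$dbi; dbh <- dbh + bk$dbh
  }
  list(dxs = dxs, dh0 = dh, dWi = dWi, dWh = dWh, dbi = dbi, dbh = dbh)
}

# accumulate embedding gradients for one timestep of token rows
.emb_grad_add <- function(dE, idx, dX) {
  agg <- rowsum(dX, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  dE[rows, ] <- dE[rows, , drop = FALSE] + agg
  dE
}

# inverted dropout; returns scaled mask (1/(1-p) kept, 0 dropped)
.dropout_mask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  keep <- matrix(stats::runif(dim1 * dim2) >= p, dim1, dim2)
  keep / (1 - p)
}

# Adam optimiser state and update over a flat named list of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
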