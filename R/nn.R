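# Native neural-network engine.
#
# Activations are numeric arrays of dim (H, W, B, C) (rows, columns, batch,
# channels). This layout lets every hot operation reshape with `dim<-`
# instead of `aperm`: a 3x3 valid convolution is evaluated as nine
# shifted-slice matrix multiplications accumulated into the output (one
# BLAS GEMM per kernel offset), batch normalisation folds (H, W, B) into
# rows of a single matrix, and global average pooling is one colMeans.
# Kernel weights for a layer are stored as a (9*C_in) x C_out matrix whose
# row order is (kernel offset within input channel block).

conv_out_len <- function(n, stride) (n - 3L) %/% stride + 1L

# X: (h, w, B, C_in); Wmat: (9*C_in) x C_out, row r = 9*c + j for input
# channel c and kernel offset j (dy fastest). Returns Y: (oh, ow, B, C_out).
conv_forward <- function(X, Wmat, stride) {
  .conv3_forward(X, dim(X), Wmat, as.integer(stride))
}

conv_backward <- function(dY, X, Wmat, stride) {
  .conv3_backward(dY, X, dim(X), Wmat, as.integer(stride))
}

relu_forward <- function(X) .relu_fwd(X)

relu_backward <- function(dY, Y) .relu_bwd(dY, Y)

# 2x2 max-pooling; ties are routed to the first cell in the scan order
# (top-left, bottom-left, top-right, bottom-right).
maxpool_forward <- function(X) {
  d <- dim(X)
  mp <- .maxpool_fwd(X, d)
  list(Y = mp$Y, which = mp$which, in_dim = d)
}

maxpool_backward <- function(dY, fwd) {
  .maxpool_bwd(dY, fwd$which, fwd$in_dim)
}

# Batch normalisation over (H, W, B) per channel. In training mode the
# biased batch variance normalises the activations and the running
# statistics are updated with momentum (unbiased variance stored); in
# evaluation mode the stored running statistics are used, making inference
# deterministic.
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  C <- d[4]
  n <- prod(d[1:3])
  M <- X
  dim(M) <- c(n, C)
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M * M) - mu * mu
    va[va < 0] <- 0
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va * n / max(n - 1, 1)
  } else {
    mu <- run_mean
    va <- run_var
  }
  invstd <- 1 / sqrt(va + eps)
  ap <- .bn_apply(M, mu, invstd, gamma, beta)
  Y <- ap$Y
  dim(Y) <- d
  list(Y = Y, xhat = ap$xhat, invstd = invstd, n = n, dims = d,
       run_mean = run_mean, run_var = run_var, training = training)
}

# Returns the input gradient only; the (cheap) gamma/beta gradients are
# taken directly from xhat by the caller.
bn_backward <- function(dY, fwd, gamma) {
  d <- fwd$dims
  dYm <- dY
  dim(dYm) <- c(fwd$n, d[4])
  dM <- .bn_input_grad(dYm, fwd$xhat, fwd$invstd, gamma, fwd$training)
  dim(dM) <- d
  dM
}

# Global average pooling: (H, W, B, C) -> (C, B) matrix of spatial means.
gap_forward <- function(X) {
  d <- dim(X)
  M <- X
  dim(M) <- c(d[1] * d[2], d[3] * d[4])
  t(matrix(colMeans(M), d[3], d[4]))
}

gap_backward <- function(dPooled, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  array(rep(as.vector(t(dPooled)), each = hw) / hw, in_dim)
}

softmax_cols <- function(Z) {
  Z <- Z - rep(apply(Z, 2, max), each = nrow(Z))
  E <- exp(Z)
  E / rep(colSums(E), each = nrow(E))
}

# Mean cross-entropy over a batch; labels are 0-based grades.
cross_entropy <- function(logits, labels) {
  P <- softmax_cols(logits)
  idx <- cbind(labels + 1L, seq_along(labels))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- P
  G[idx] <- G[idx] - 1
  list(loss = loss, dlogits = G / length(labels))
}
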