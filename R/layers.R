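# Differentiable building blocks for the segmentation network. Each layer has
# a forward returning (out, cache) and a backward mapping the upstream
# gradient and cache to input/parameter gradients. Feature maps are (H, W, C)
# arrays; convolution weights are (k*k*Cin) x Cout matrices acting on im2col
# patches, so the heavy lifting is a single BLAS gemm per layer.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA  <- 1.6732632423543772

conv_forward <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], k, stride, pad)
  out <- cols %*% W
  out <- sweep(out, 2, b, `+`)
  Ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  dim(out) <- c(Ho, Wo, length(b))
  list(out = out, cache = list(cols = cols, W = W, dims = d,
                               k = k, stride = stride, pad = pad))
}

conv_backward <- function(dout, cache) {
  d3 <- dim(dout)[3]
  dmat <- matrix(dout, ncol = d3)
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, cache$W)
  dx <- col2im_cpp(dcols, cache$dims[1], cache$dims[2], cache$dims[3],
                   cache$k, cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

selu_forward <- function(x) {
  out <- ifelse(x > 0, SELU_LAMBDA * x, SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1))
  list(out = out, cache = x)
}

selu_backward <- function(dout, cache) {
  dout * ifelse(cache > 0, SELU_LAMBDA, SELU_LAMBDA * SELU_ALPHA * exp(cache))
}

# Alpha Dropout: dropped activations are set to the SELU saturation value
# alpha' = -lambda*alpha, then an affine correction restores zero mean / unit
# variance in expectation. Identity when rate = 0 or active = FALSE.
alpha_dropout_forward <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(out = x, cache = NULL))
  ap <- -SELU_LAMBDA * SELU_ALPHA
  q <- 1 - rate
  a <- (q * (1 + rate * ap^2))^(-0.5)
  b <- -a * ap * rate
  keep <- array(runif(length(x)) >= rate, dim(x))
  out <- a * (x * keep + ap * !keep) + b
  list(out = out, cache = list(keep = keep, a = a))
}

alpha_dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * cache$keep * cache$a
}

# Separable bilinear interpolation matrix mapping n_in samples to n_out
# (half-pixel-center convention, clamped at the borders).
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  f <- n_out / n_in
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) / f - 0.5
    s <- min(max(s, 0), n_in - 1)
    lo <- floor(s)
    hi <- min(lo + 1, n_in - 1)
    wh <- s - lo
    A[i, lo + 1] <- A[i, lo + 1] + (1 - wh)
    A[i, hi + 1] <- A[i, hi + 1] + wh
  }
  A
}

upsample_forward <- function(x, H, W) {
  d <- dim(x)
  A <- interp_matrix(H, d[1])
  B <- interp_matrix(W, d[2])
  out <- array(0, c(H, W, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- A %*% x[, , c] %*% t(B)
  list(out = out, cache = list(A = A, B = B, dims = d))
}

upsample_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- array(0, d)
  for (c in seq_len(d[3])) dx[, , c] <- crossprod(cache$A, dout[, , c]) %*% cache$B
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Gradient of L wrt logits given dL/dp and the softmax output p (rowwise).
softmax_backprop <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}
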