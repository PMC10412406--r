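.sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform weight matrix; draws from the caller's RNG stream.
.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

#' Initialize highway-encoder parameters
#'
#' A linear input projection p -> l followed by `nLayers` highway blocks of
#' width l. Each block holds an affine transform H (ReLU) and an affine
#' sigmoid gate T whose bias starts at -1, so training begins carry-biased
#' (output close to the projected input). Weights are Glorot-uniform; the
#' caller controls the RNG state.
#'
#' @param p input feature count.
#' @param l encoder width.
#' @param nLayers number of highway blocks (3 by default).
#' @return a nested parameter list with elements `W0`, `b0` and `blocks`.
#' @export
initHighwayParams <- function(p, l, nLayers = 3L) {
  blocks <- lapply(seq_len(nLayers), function(i)
    list(Wh = .glorot(l, l), bh = numeric(l),
         Wt = .glorot(l, l), bt = rep(-1, l)))
  list(W0 = .glorot(p, l), b0 = numeric(l), blocks = blocks)
}

#' Highway-encoder forward pass
#'
#' Projects the input to width l and applies the highway blocks
#' \deqn{x_{out} = H(x_{in}) \odot T(x_{in}) + x_{in} \odot (1 - T(x_{in}))}
#' with `H(x) = relu(x Wh + bh)` and gate `T(x) = sigmoid(x Wt + bt)`.
#'
#' @param x n-by-p input matrix.
#' @param params parameters from [initHighwayParams()].
#' @param cache if `TRUE`, also return the intermediates needed for the
#'   backward pass.
#' @return n-by-l output matrix, or `list(out, cache)` when `cache = TRUE`.
#' @export
highwayForward <- function(x, params, cache = FALSE) {
  if (ncol(x) != nrow(params$W0))
    stop("input width ", ncol(x), " does not match projection input dim ",
         nrow(params$W0))
  cur <- x %*% params$W0
  cur <- sweep(cur, 2, params$b0, "+")
  caches <- vector("list", length(params$blocks))
  for (i in seq_along(params$blocks)) {
    b <- params$blocks[[i]]
    preH <- sweep(cur %*% b$Wh, 2, b$bh, "+")
    h <- pmax(preH, 0)
    preT <- sweep(cur %*% b$Wt, 2, b$bt, "+")
    tg <- .sigmoid(preT)
    out <- h * tg + cur * (1 - tg)
    if (cache) caches[[i]] <- list(xin = cur, preH = preH, h = h, tg = tg)
    cur <- out
  }
  if (cache) list(out = cur, cache = caches) else cur
}

# Backward pass of the highway encoder. Returns gradients mirroring the
# parameter structure; the gradient w.r.t. the (fixed) input is not needed.
.highwayBackward <- function(dout, x, params, caches) {
  gBlocks <- vector("list", length(params$blocks))
  d <- dout
  for (i in rev(seq_along(params$blocks))) {
    b <- params$blocks[[i]]
    cc <- caches[[i]]
    dh <- d * cc$tg
    dtg <- d * (cc$h - cc$xin)
    dxin <- d * (1 - cc$tg)
    dPreH <- dh * (cc$preH > 0)
    dPreT <- dtg * cc$tg * (1 - cc$tg)
    gBlocks[[i]] <- list(Wh = crossprod(cc$xin, dPreH), bh = colSums(dPreH),
                         Wt = crossprod(cc$xin, dPreT), bt = colSums(dPreT))
    dxin <- dxin + tcrossprod(dPreH, b$Wh) + tcrossprod(dPreT, b$Wt)
    d <- dxin
  }
  list(W0 = crossprod(x, d), b0 = colSums(d), blocks = gBlocks)
}

#' Initialize factorized-bilinear-model parameters
#'
#' Two order-3 tensors `U`, `V` of shape l x d x m whose slices define the m
#' rank-d bilinear cross-omics features.
#'
#' @param l encoder width.
#' @param d factor rank of each bilinear slice.
#' @param m number of cross-omics features.
#' @return list with arrays `U` and `V` (dim `c(l, d, m)`).
#' @export
initFBMParams <- function(l, d, m) {
  one <- function() {
    a <- array(0, dim = c(l, d, m))
    for (j in seq_len(m)) a[, , j] <- .glorot(l, d)
    a
  }
  list(U = one(), V = one())
}

#' Factorized bilinear cross-omics features
#'
#' For each sample with encoded views `z1`, `z2` and each j in 1..m, the j-th
#' cross feature is the bilinear form \eqn{z_1^T U_j V_j^T z_2}, computed as
#' the inner product of the rank-d projections `z1 U_j` and `z2 V_j`; the
#' l-by-l matrix \eqn{U_j V_j^T} is never materialized.
#'
#' @param z1,z2 n-by-l encoded feature matrices.
#' @param params parameters from [initFBMParams()].
#' @param cache if `TRUE`, also return the projections for the backward pass.
#' @return n-by-m matrix, or `list(out, cache)` when `cache = TRUE`.
#' @export
fbmForward <- function(z1, z2, params, cache = FALSE) {
  dims <- dim(params$U)
  if (!identical(dim(z1), dim(z2)))
    stop("z1 and z2 must have identical shape")
  if (ncol(z1) != dims[1])
    stop("encoder width ", ncol(z1), " does not match FBM l = ", dims[1])
  m <- dims[3]
  n <- nrow(z1)
  out <- matrix(0, n, m)
  proj <- if (cache) vector("list", m) else NULL
  for (j in seq_len(m)) {
    a <- z1 %*% params$U[, , j]
    b <- z2 %*% params$V[, , j]
    out[, j] <- rowSums(a * b)
    if (cache) proj[[j]] <- list(a = a, b = b)
  }
  if (cache) list(out = out, cache = proj) else out
}

.fbmBackward <- function(dout, z1, z2, params, proj) {
  dims <- dim(params$U)
  m <- dims[3]
  dU <- array(0, dims)
  dV <- array(0, dims)
  dz1 <- matrix(0, nrow(z1), ncol(z1))
  dz2 <- matrix(0, nrow(z2), ncol(z2))
  for (j in seq_len(m)) {
    da <- proj[[j]]$b * dout[, j]
    db <- proj[[j]]$a * dout[, j]
    dU[, , j] <- crossprod(z1, da)
    dV[, , j] <- crossprod(z2, db)
    dz1 <- dz1 + tcrossprod(da, params$U[, , j])
    dz2 <- dz2 + tcrossprod(db, params$V[, , j])
  }
  list(U = dU, V = dV, dz1 = dz1, dz2 = dz2)
}

#' Concatenation feature fusion
#'
#' Low-level fusion is the elementwise sum `zLow = z1 + z2`; the final fused
#' representation concatenates it with the cross-omics features:
#' `z = cbind(zLow, zCross)`.
#'
#' @param z1,z2 n-by-l encoded views.
#' @param zCross n-by-m cross-omics features.
#' @return a [FusedFeatures-class].
#' @export
fuseFeatures <- function(z1, z2, zCross) {
  if (!identical(dim(z1), dim(z2)))
    stop("z1 and z2 must have identical shape")
  if (nrow(zCross) != nrow(z1))
    stop("zCross must be row-aligned with z1/z2")
  zLow <- z1 + z2
  new("FusedFeatures", z1 = z1, z2 = z2, zLow = zLow, zCross = zCross,
      z = cbind(zLow, zCross))
}
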