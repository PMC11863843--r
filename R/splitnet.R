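#' Split-network configuration
#'
#' Configuration of the two-head architecture. An IR spectrum carries
#' distinct information in its fingerprint region (dense, overlapping,
#' molecule-specific bands at low wavenumbers) and its functional-group
#' region (cleaner, characteristic group stretches at high wavenumbers).
#' The network encodes the two regions with separate fully connected heads
#' and only then joins the learned features, enforcing an inductive bias:
#' y = f_joint(h1, h2) with h1 = f_FP(x_FP), h2 = f_FG(x_FG).
#'
#' Each head is dense(input -> input size) + batch norm + rectifier +
#' dropout 0.2, then dense(-> 256) + batch norm + rectifier + dropout 0.3.
#' The concatenated 512-wide feature vector passes through one dense layer
#' of size 512 (no batch norm) and a 17-unit logistic output layer.
#'
#' @param boundary Wavenumber splitting the two regions; grid points at or
#'   below it form the fingerprint segment. Default 1800 1/cm.
#' @param head_hidden Second head layer width (default 256).
#' @param dropout_in,dropout_hidden Dropout rates after the first and
#'   second head layers.
#' @param concat_size Width of the post-concatenation dense layer.
#' @param n_outputs Number of functional groups (17).
#' @param threshold Decision threshold on output probabilities.
#' @param seed Seed for parameter initialization.
#' @return A `splitnet_config` list.
#' @export
splitnet_config <- function(boundary = 1800, head_hidden = 256,
                            dropout_in = 0.2, dropout_hidden = 0.3,
                            concat_size = 512, n_outputs = 17,
                            threshold = 0.5, seed = 42L) {
  stopifnot(head_hidden > 0, concat_size > 0, n_outputs > 0,
            dropout_in >= 0, dropout_in < 1,
            dropout_hidden >= 0, dropout_hidden < 1)
  structure(list(boundary = boundary, head_hidden = head_hidden,
                 dropout_in = dropout_in, dropout_hidden = dropout_hidden,
                 concat_size = concat_size, n_outputs = n_outputs,
                 threshold = threshold, seed = as.integer(seed)),
            class = "splitnet_config")
}

#' Split a spectrum at the region boundary
#'
#' @param spectrum An `ir_spectrum`.
#' @param boundary Wavenumber strictly inside the grid range; points at or
#'   below it go to the fingerprint segment.
#' @return List with `x_fp` and `x_fg`; their concatenation is the full
#'   intensity vector.
#' @export
split_spectrum <- function(spectrum, boundary = 1800) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  g <- spectrum$grid
  if (boundary <= g[1] || boundary >= g[length(g)]) {
    stop("boundary must lie strictly inside the grid range", call. = FALSE)
  }
  fp <- g <= boundary
  list(x_fp = spectrum$intensities[fp], x_fg = spectrum$intensities[!fp])
}

split_indices <- function(grid, boundary) {
  if (boundary <= grid[1] || boundary >= grid[length(grid)]) {
    stop("boundary must lie strictly inside the grid range", call. = FALSE)
  }
  which(grid <= boundary)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

new_dense <- function(n_in, n_out) list(W = glorot(n_in, n_out),
                                        b = rep(0, n_out))

new_bn <- function(d) list(gamma = rep(1, d), beta = rep(0, d),
                           rmean = rep(0, d), rvar = rep(1, d))

#' Initialize split-network parameters
#'
#' Uniform fan-based (Glorot) weight initialization with an explicit seed,
#' so parameters are bit-reproducible across runs on the same platform.
#'
#' @param config A [splitnet_config()].
#' @param grid The analysis wavenumber grid the model will consume.
#' @return A `splitnet_params` object holding the weight collections of the
#'   two heads and the joint classifier, the grid, the config, and the
#'   functional-group catalog hash.
#' @export
splitnet_init <- function(config = splitnet_config(), grid = fg_grid()) {
  ifp <- split_indices(grid, config$boundary)
  n_fp <- length(ifp)
  n_fg <- length(grid) - n_fp
  stopifnot(n_fp > 0, n_fg > 0,
            config$concat_size == 2 * config$head_hidden)
  set.seed(config$seed)
  h <- config$head_hidden
  structure(list(
    config = config,
    grid = grid,
    n_fp = n_fp,
    n_fg = n_fg,
    catalog_hash = fg_catalog_hash(),
    fp1 = new_dense(n_fp, n_fp), fp1_bn = new_bn(n_fp),
    fp2 = new_dense(n_fp, h),    fp2_bn = new_bn(h),
    fg1 = new_dense(n_fg, n_fg), fg1_bn = new_bn(n_fg),
    fg2 = new_dense(n_fg, h),    fg2_bn = new_bn(h),
    joint = new_dense(config$concat_size, config$concat_size),
    out = new_dense(config$concat_size, config$n_outputs)
  ), class = "splitnet_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# row-broadcast column vector ops; cheaper than sweep() in the hot loop
addc <- function(z, a) z + matrix(a, nrow(z), ncol(z), byrow = TRUE)
subc <- function(z, a) z - matrix(a, nrow(z), ncol(z), byrow = TRUE)
mulc <- function(z, a) z * matrix(a, nrow(z), ncol(z), byrow = TRUE)

bn_apply <- function(z, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(z)
    zc <- subc(z, mu)
    va <- colMeans(zc * zc)
    inv <- 1 / sqrt(va + eps)
    xh <- mulc(zc, inv)
    out <- addc(mulc(xh, bn$gamma), bn$beta)
    bn$rmean <- (1 - momentum) * bn$rmean + momentum * mu
    bn$rvar <- (1 - momentum) * bn$rvar + momentum * va
    list(out = out, xh = xh, inv = inv, bn = bn)
  } else {
    inv <- 1 / sqrt(bn$rvar + eps)
    xh <- mulc(subc(z, bn$rmean), inv)
    out <- addc(mulc(xh, bn$gamma), bn$beta)
    list(out = out, bn = bn)
  }
}

bn_backward <- function(dout, cache, gamma) {
  m <- nrow(cache$xh)
  dgamma <- colSums(dout * cache$xh)
  dbeta <- colSums(dout)
  dxh <- mulc(dout, gamma)
  # dz = inv/m * (m*dxh - colSums(dxh) - xh * colSums(dxh*xh))
  t2 <- matrix(colSums(dxh), m, ncol(dxh), byrow = TRUE)
  t3 <- mulc(cache$xh, colSums(dxh * cache$xh))
  dz <- mulc(m * dxh - t2 - t3, cache$inv / m)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

dense_apply <- function(X, layer) {
  addc(X %*% layer$W, layer$b)
}

head_forward <- function(X, d1, bn1, d2, bn2, p1, p2, training) {
  cache <- list(X = X)
  z1 <- dense_apply(X, d1)
  b1 <- bn_apply(z1, bn1, training)
  a1 <- pmax(b1$out, 0)
  if (training && p1 > 0) {
    m1 <- matrix(stats::runif(length(a1)) >= p1, nrow(a1)) / (1 - p1)
    a1 <- a1 * m1
    cache$m1 <- m1
  }
  z2 <- dense_apply(a1, d2)
  b2 <- bn_apply(z2, bn2, training)
  a2 <- pmax(b2$out, 0)
  if (training && p2 > 0) {
    m2 <- matrix(stats::runif(length(a2)) >= p2, nrow(a2)) / (1 - p2)
    a2 <- a2 * m2
    cache$m2 <- m2
  }
  cache$b1 <- b1; cache$b2 <- b2; cache$a1 <- a1
  cache$relu1 <- b1$out > 0; cache$relu2 <- b2$out > 0
  list(out = a2, cache = cache, bn1 = b1$bn, bn2 = b2$bn)
}

# Full forward pass on an n x p matrix. Returns probabilities plus the
# caches needed for backprop and the (possibly updated) batch-norm stats.
splitnet_forward_matrix <- function(params, X, training = FALSE) {
  cfg <- params$config
  ifp <- seq_len(params$n_fp)
  Hfp <- head_forward(X[, ifp, drop = FALSE],
                      params$fp1, params$fp1_bn, params$fp2, params$fp2_bn,
                      cfg$dropout_in, cfg$dropout_hidden, training)
  Hfg <- head_forward(X[, -ifp, drop = FALSE],
                      params$fg1, params$fg1_bn, params$fg2, params$fg2_bn,
                      cfg$dropout_in, cfg$dropout_hidden, training)
  C <- cbind(Hfp$out, Hfg$out)
  z3 <- dense_apply(C, params$joint)
  a3 <- pmax(z3, 0)
  z4 <- dense_apply(a3, params$out)
  if (training) {
    params$fp1_bn <- Hfp$bn1; params$fp2_bn <- Hfp$bn2
    params$fg1_bn <- Hfg$bn1; params$fg2_bn <- Hfg$bn2
  }
  list(prob = sigmoid(z4), z4 = z4, a3 = a3, relu3 = z3 > 0, C = C,
       h_fp = Hfp$out, h_fg = Hfg$out,
       cache_fp = Hfp$cache, cache_fg = Hfg$cache, params = params)
}

#' Forward pass of the split network
#'
#' Computes the 17 per-group presence probabilities for one spectrum (or a
#' matrix of spectra, one per row). In inference mode (the default)
#' dropout is inactive and batch normalization uses its running statistics,
#' so the output is deterministic given fixed parameters.
#'
#' @param params A `splitnet_params` object.
#' @param spectrum An `ir_spectrum`, a numeric vector on the model grid, or
#'   an n x p matrix of such vectors.
#' @param training Logical; when TRUE, dropout is applied and batch-norm
#'   batch statistics are used (training semantics).
#' @return Numeric vector of 17 probabilities in (0, 1) (or an n x 17
#'   matrix), named by functional group.
#' @export
splitnet_forward <- function(params, spectrum, training = FALSE) {
  stopifnot(inherits(params, "splitnet_params"))
  x <- if (inherits(spectrum, "ir_spectrum")) spectrum$intensities
       else spectrum
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else x
  if (ncol(X) != params$n_fp + params$n_fg) {
    stop("spectrum length ", ncol(X), " does not match model grid (",
         params$n_fp + params$n_fg, " points)", call. = FALSE)
  }
  P <- splitnet_forward_matrix(params, X, training = training)$prob
  colnames(P) <- fg_names()[seq_len(params$config$n_outputs)]
  if (single) P[1, ] else P
}

#' Head features h1, h2 for a spectrum
#'
#' Exposes the learned per-region feature vectors before the joint
#' classifier; used to verify that the two heads are isolated (perturbing
#' the functional-group region never changes h1, and vice versa).
#'
#' @inheritParams splitnet_forward
#' @return List with `h_fp` and `h_fg` numeric vectors (length 256 each by
#'   default).
#' @export
splitnet_head_features <- function(params, spectrum) {
  x <- if (inherits(spectrum, "ir_spectrum")) spectrum$intensities
       else spectrum
  fwd <- splitnet_forward_matrix(params, matrix(x, nrow = 1),
                                 training = FALSE)
  list(h_fp = fwd$h_fp[1, ], h_fg = fwd$h_fg[1, ])
}

#' Threshold probabilities into a label vector
#'
#' @param probabilities Numeric vector (or matrix) of probabilities in
#'   `[0, 1]`.
#' @param threshold Decision threshold; a probability equal to the
#'   threshold counts as present.
#' @return Integer 0/1 vector (or matrix) of the same shape.
#' @export
predict_labels <- function(probabilities, threshold = 0.5) {
  stopifnot(all(probabilities >= 0), all(probabilities <= 1))
  out <- ifelse(probabilities >= threshold, 1L, 0L)
  if (!is.null(dim(probabilities))) dim(out) <- dim(probabilities)
  out
}

#' Save a model checkpoint
#'
#' Single-file container holding the full parameter set (config, weights,
#' batch-norm statistics, grid) plus the functional-group catalog hash.
#'
#' @param params A `splitnet_params`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "splitnet_params"))
  saveRDS(params, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Refuses to load a checkpoint whose catalog hash differs from the current
#' functional-group catalog, since the output units would then be aligned
#' to different label definitions.
#'
#' @param path Checkpoint file path.
#' @return A `splitnet_params`.
#' @export
load_checkpoint <- function(path) {
  params <- readRDS(path)
  if (!inherits(params, "splitnet_params")) {
    stop("not a splitnet checkpoint: ", path, call. = FALSE)
  }
  if (!identical(params$catalog_hash, fg_catalog_hash())) {
    stop("checkpoint was trained against a different functional-group ",
         "catalog (hash mismatch); refusing to load", call. = FALSE)
  }
  params
}
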