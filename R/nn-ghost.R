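#' Ghost convolution specification
#'
#' Describes a ghost feature-map composition: \code{m} intrinsic maps are
#' produced by a dense convolution of the input with the primary kernels,
#' then each intrinsic map is expanded into \code{s} maps by cheap per-map
#' (depthwise) linear kernels, of which the first is fixed to the identity
#' so every intrinsic map is itself emitted. The output channel count is
#' \code{m * s}.
#'
#' @slot primary numeric 4-D array \code{(kh, kw, C, m)} of dense kernels.
#' @slot cheap numeric 4-D array \code{(kh2, kw2, m, s)} of per-map
#'   kernels; \code{cheap[, , i, 1]} is the identity (centre delta).
#' @slot m,s intrinsic map count and maps generated per intrinsic map.
#' @aliases GhostSpec-class
#' @exportClass GhostSpec
setClass("GhostSpec",
  representation(primary = "array", cheap = "array",
                 m = "integer", s = "integer"))

setValidity("GhostSpec", function(object) {
  dp <- dim(object@primary); dc <- dim(object@cheap)
  if (length(dp) != 4L) return("'primary' must be a 4-D (kh, kw, C, m) array")
  if (length(dc) != 4L) return("'cheap' must be a 4-D (kh2, kw2, m, s) array")
  if (any(c(dp[1:2], dc[1:2]) %% 2 == 0))
    return("kernel extents must be odd")
  if (dp[4] != object@m || dc[3] != object@m || dc[4] != object@s)
    return("kernel array extents disagree with m, s")
  ident <- array(0, dc[1:2]); ident[(dc[1] + 1) / 2, (dc[2] + 1) / 2] <- 1
  for (i in seq_len(object@m))
    if (max(abs(object@cheap[, , i, 1] - ident)) > 0)
      return("cheap[, , i, 1] must be the identity kernel")
  TRUE
})

#' Construct a ghost convolution spec
#'
#' @param primary dense kernels, 4-D array \code{(kh, kw, C, m)}.
#' @param cheap per-map linear kernels for the ghost maps, 4-D array
#'   \code{(kh2, kw2, m, s - 1)}, or \code{NULL} for \code{s = 1} (no
#'   ghost maps). The identity kernel for \code{j = 1} is prepended
#'   automatically.
#' @return A \linkS4class{GhostSpec}.
#' @examples
#' prim <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
#' cheap <- array(rnorm(3 * 3 * 2 * 1), c(3, 3, 2, 1))
#' ghostSpec(prim, cheap) # m = 2, s = 2 -> 4 output channels
#' @export
ghostSpec <- function(primary, cheap = NULL) {
  dp <- dim(primary)
  m <- dp[4]
  if (is.null(cheap)) {
    s <- 1L
    kh2 <- 3L; kw2 <- 3L
    full <- array(0, c(kh2, kw2, m, 1L))
  } else {
    dc <- dim(cheap)
    if (length(dc) != 4L || dc[3] != m)
      stop("'cheap' must be (kh2, kw2, m, s - 1)")
    s <- dc[4] + 1L
    kh2 <- dc[1]; kw2 <- dc[2]
    full <- array(0, c(kh2, kw2, m, s))
    full[, , , 2:s] <- cheap
  }
  for (i in seq_len(m)) full[(kh2 + 1) / 2, (kw2 + 1) / 2, i, 1] <- 1
  new("GhostSpec", primary = primary, cheap = full,
      m = as.integer(m), s = as.integer(s))
}

setMethod("show", "GhostSpec", function(object) {
  dp <- dim(object@primary)
  cat(sprintf("GhostSpec: %d intrinsic maps (%dx%d kernels, %d in-channels), s=%d -> %d out-channels\n",
              object@m, dp[1], dp[2], dp[3], object@s, object@m * object@s))
})

# zero-padded shift of a matrix by (di, dj)
shiftPad <- function(M, di, dj) {
  h <- nrow(M); w <- ncol(M)
  out <- matrix(0, h, w)
  r0 <- max(1, 1 + di); r1 <- min(h, h + di)
  c0 <- max(1, 1 + dj); c1 <- min(w, w + dj)
  if (r0 <= r1 && c0 <= c1) {
    rs <- r0:r1; cs <- c0:c1
    out[rs, cs] <- M[rs - di, cs - dj]
  }
  out
}

# dense same-size correlation of X (C, H, W) with kernels (kh, kw, C, m)
conv2dDense <- function(X, kernels) {
  dk <- dim(kernels)
  kh <- dk[1]; kw <- dk[2]; C <- dk[3]; m <- dk[4]
  H <- dim(X)[2]; W <- dim(X)[3]
  stopifnot(dim(X)[1] == C)
  out <- array(0, c(m, H, W))
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  for (o in seq_len(m)) {
    acc <- matrix(0, H, W)
    for (c in seq_len(C)) {
      Xc <- matrix(X[c, , ], H, W)
      for (di in -rh:rh) for (dj in -rw:rw) {
        wgt <- kernels[di + rh + 1, dj + rw + 1, c, o]
        if (wgt != 0) acc <- acc + wgt * shiftPad(Xc, -di, -dj)
      }
    }
    out[o, , ] <- acc
  }
  out
}

# per-map same-size correlation of one map with one kernel
convMap <- function(M, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  acc <- matrix(0, nrow(M), ncol(M))
  for (di in -rh:rh) for (dj in -rw:rw) {
    wgt <- kernel[di + rh + 1, dj + rw + 1]
    if (wgt != 0) acc <- acc + wgt * shiftPad(M, -di, -dj)
  }
  acc
}

#' Ghost feature-map composition (forward)
#'
#' Dense convolution of the input with the primary kernels yields the
#' intrinsic maps; each intrinsic map is then expanded by its cheap linear
#' kernels (identity first, so the intrinsic map itself is emitted) and
#' all maps are concatenated in lexicographic (intrinsic, ghost) order.
#' Channels-first layout, zero padding, stride 1, forward semantics only.
#'
#' @param X input tensor, numeric array \code{(C, H, W)}.
#' @param spec a \linkS4class{GhostSpec}.
#' @return output tensor \code{(m * s, H, W)}; channel \code{(i-1)*s + j}
#'   is ghost map \code{j} of intrinsic map \code{i}.
#' @export
ghostFeatures <- function(X, spec) {
  stopifnot(is(spec, "GhostSpec"), length(dim(X)) == 3L)
  if (dim(X)[1] != dim(spec@primary)[3])
    stop("input channel count does not match the primary kernels")
  H <- dim(X)[2]; W <- dim(X)[3]
  intrinsic <- conv2dDense(X, spec@primary)
  out <- array(0, c(spec@m * spec@s, H, W))
  kh2 <- dim(spec@cheap)[1]; kw2 <- dim(spec@cheap)[2]
  for (i in seq_len(spec@m)) {
    Mi <- matrix(intrinsic[i, , ], H, W)
    for (j in seq_len(spec@s))
      out[(i - 1L) * spec@s + j, , ] <-
        convMap(Mi, matrix(spec@cheap[, , i, j], kh2, kw2))
  }
  out
}

#' Learnable parameter counts: ghost versus dense
#'
#' Counts the learnable weights of a ghost composition (dense primary
#' kernels plus the non-identity cheap kernels) against a dense
#' convolution producing the same \code{m * s} output channels with the
#' primary kernel extent. Whenever \code{s > 1} the ghost count is
#' strictly smaller.
#'
#' @param spec a \linkS4class{GhostSpec}.
#' @return named numeric \code{c(ghost, dense)}.
#' @export
ghostParamCount <- function(spec) {
  dp <- dim(spec@primary); dc <- dim(spec@cheap)
  ghost <- prod(dp) + dc[1] * dc[2] * spec@m * (spec@s - 1L)
  dense <- dp[1] * dp[2] * dp[3] * (spec@m * spec@s)
  c(ghost = ghost, dense = dense)
}
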