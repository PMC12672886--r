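# shared fixtures and independent oracles

# float (unquantised) HSV -> RGB, standard sextant formula
hsv2rgbFloat <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = c(v, t, p), "1" = c(q, v, p), "2" = c(p, v, t),
         "3" = c(p, q, v), "4" = c(t, p, v), "5" = c(v, p, q))
}

# uniform HSV patch as an RGB array (full float precision)
patchHSV <- function(h, s = 0.9, v = 0.9, nr = 20, nc = 20) {
  col <- hsv2rgbFloat(h, s, v)
  arr <- array(0, c(nr, nc, 3))
  for (ch in 1:3) arr[, , ch] <- col[ch]
  arr
}

# brute-force eps-graph connected components via igraph (independent of
# the package's DBSCAN implementation)
epsGraphComponents <- function(coords, eps) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  adj <- (d <= eps) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# canonicalise a label vector so partitions can be compared directly:
# clusters renumbered by first appearance
canonicalPartition <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

# naive triple-loop dense correlation oracle: X (C,H,W), K (kh,kw,C,m)
naiveConv <- function(X, K) {
  dk <- dim(K); kh <- dk[1]; kw <- dk[2]; C <- dk[3]; m <- dk[4]
  H <- dim(X)[2]; W <- dim(X)[3]
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  out <- array(0, c(m, H, W))
  for (o in seq_len(m)) for (y in seq_len(H)) for (x in seq_len(W)) {
    acc <- 0
    for (c in seq_len(C)) for (di in -rh:rh) for (dj in -rw:rw) {
      yy <- y + di; xx <- x + dj
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W)
        acc <- acc + K[di + rh + 1, dj + rw + 1, c, o] * X[c, yy, xx]
    }
    out[o, y, x] <- acc
  }
  out
}

# naive ghost composition built on the naive convolution
naiveGhost <- function(X, spec) {
  intr <- naiveConv(X, spec@primary)
  H <- dim(X)[2]; W <- dim(X)[3]
  out <- array(0, c(spec@m * spec@s, H, W))
  for (i in seq_len(spec@m)) for (j in seq_len(spec@s)) {
    K1 <- array(spec@cheap[, , i, j],
                c(dim(spec@cheap)[1], dim(spec@cheap)[2], 1, 1))
    Xi <- array(intr[i, , ], c(1, H, W))
    out[(i - 1) * spec@s + j, , ] <- naiveConv(Xi, K1)[1, , ]
  }
  out
}

# exhaustive TP-maximising detection matching on tiny instances
bruteForceTP <- function(preds, truths, iouThreshold) {
  nP <- nrow(preds); nT <- nrow(truths)
  iou <- matrix(0, nP, nT)
  for (i in seq_len(nP)) for (j in seq_len(nT))
    iou[i, j] <- boxIoU(c(cx = preds$cx_px[i], cy = preds$cy_px[i],
                          w = preds$w_px[i], h = preds$h_px[i]),
                        c(cx = truths$cx_px[j], cy = truths$cy_px[j],
                          w = truths$w_px[j], h = truths$h_px[j]))
  feas <- iou >= iouThreshold
  best <- 0
  recurse <- function(i, used, tp) {
    if (tp + (nP - i + 1) <= best) return()
    if (i > nP) { best <<- max(best, tp); return() }
    for (j in seq_len(nT))
      if (feas[i, j] && !used[j]) {
        used[j] <- TRUE
        recurse(i + 1, used, tp + 1)
        used[j] <- FALSE
      }
    recurse(i + 1, used, tp)
  }
  recurse(1, rep(FALSE, nT), 0)
  best
}
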