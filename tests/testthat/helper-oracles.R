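# Independent oracle implementations used to cross-check the package.
# These deliberately re-derive quantities by brute force and share no code
# with the implementation paths they verify.

# edge-by-edge accumulation of the rate matrix from an explicit edge list
oracleSystemMatrix <- function(params, known = defaultKnownRates()) {
  edges <- data.frame(
    from = "Blood",
    to = c("KidneyElim", "LiverElim", "KidneyRet", "LiverRet", "Bone",
           "Spleen", "Lung", "Others"),
    rate = as.numeric(params[paramNames()]))
  for (nm in names(known)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1L]]
    edges <- rbind(edges, data.frame(from = ft[1], to = ft[2],
                                     rate = known[[nm]]))
  }
  st <- stateNames()
  A <- matrix(0, 11, 11, dimnames = list(st, st))
  for (i in st) for (j in st)
    A[j, i] <- sum(edges$rate[edges$from == i & edges$to == j])
  for (i in st) A[i, i] <- -sum(edges$rate[edges$from == i])
  A
}

# direct 3D Gaussian sum with mirrored indices (no separable shortcut)
oracleBlur3d <- function(x, sigmaVox) {
  d <- dim(x)
  R <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  offs <- (-R):R
  k1 <- exp(-offs^2 / (2 * sigmaVox^2))
  k1 <- k1 / sum(k1)
  mirror <- function(idx, n) {
    idx <- ((idx - 1) %% (2 * n)) + 1
    ifelse(idx > n, 2 * n + 1 - idx, idx)
  }
  out <- array(0, d)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    w <- k1[ox + R + 1] * k1[oy + R + 1] * k1[oz + R + 1]
    out <- out + w * x[mirror(seq_len(d[1]) + ox, d[1]),
                       mirror(seq_len(d[2]) + oy, d[2]),
                       mirror(seq_len(d[3]) + oz, d[3])]
  }
  out
}

# naive elementwise triple-loop matrix product
oracleMatProd <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      for (k in seq_len(ncol(A)))
        out[i, j] <- out[i, j] + A[i, k] * B[k, j]
  out
}

# loop-based sum of squared residuals
oracleSse <- function(pred, meas) {
  s <- 0
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred)))
      s <- s + unname((pred[i, j] - meas[i, j])^2)
  s
}

# closed-form simple OLS (slope, classical SE, R^2)
oracleOls <- function(y, x) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = b, se = sqrt(s2 / sum((x - mean(x))^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

randomParams <- function(lo = 0.001, hi = 0.02) {
  stats::setNames(stats::runif(8, lo, hi), paramNames())
}
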