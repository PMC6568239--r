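# Independent oracles, deliberately naive, for cross-checking the package's
# implementations.

# stack-based flood fill over a logical matrix; returns number of components
# and a label matrix
flood_fill_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  comp <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        comp <- comp + 1L
        stack <- list(c(i, j))
        lab[i, j] <- comp
        while (length(stack)) {
          cur <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (k in seq_len(nrow(offs))) {
            a <- cur[1] + offs[k, 1]
            b <- cur[2] + offs[k, 2]
            if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
                mask[a, b] && lab[a, b] == 0L) {
              lab[a, b] <- comp
              stack[[length(stack) + 1L]] <- c(a, b)
            }
          }
        }
      }
    }
  }
  list(n = comp, labels = lab)
}

# closed-form simple OLS of y on x via the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x)
  sy <- sum(y)
  sxx <- sum(x^2)
  sxy <- sum(x * y)
  syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  r2 <- (n * sxy - sx * sy)^2 / ((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, r2 = r2)
}

# Kruskal-Wallis H from the rank-sum formula (no tie correction; use on
# tie-free fixtures)
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 0
  for (g in unique(groups)) {
    idx <- groups == g
    h <- h + sum(r[idx])^2 / sum(idx)
  }
  12 / (N * (N + 1)) * h - 3 * (N + 1)
}
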