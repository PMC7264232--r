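# Independent brute-force oracles, deliberately written without reusing any
# package internals.

ORACLE_SITES <- c("GGTACC", "TCTAGA")

# Character-by-character scan: does placing `variable` between `left` and
# `right` create a homopolymer run > max_run or a KpnI/XbaI/SfiI site that
# overlaps the variable bases?
oracle_violates <- function(variable, left = "", right = "", max_run = 3) {
  s <- paste0(left, variable, right)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  v1 <- nchar(left) + 1
  v2 <- nchar(left) + nchar(variable)
  overlaps <- function(a, b) a <= v2 && b >= v1
  # homopolymer runs of length max_run + 1
  L <- max_run + 1
  for (i in seq_len(max(0, n - L + 1))) {
    seg <- ch[i:(i + L - 1)]
    if (length(unique(seg)) == 1 && overlaps(i, i + L - 1)) return(TRUE)
  }
  for (site in ORACLE_SITES) {
    w <- nchar(site)
    for (i in seq_len(max(0, n - w + 1))) {
      if (substr(s, i, i + w - 1) == site && overlaps(i, i + w - 1)) return(TRUE)
    }
  }
  # SfiI: GGCCNNNNNGGCC
  for (i in seq_len(max(0, n - 13 + 1))) {
    if (substr(s, i, i + 3) == "GGCC" && substr(s, i + 9, i + 12) == "GGCC" &&
        overlaps(i, i + 12)) {
      return(TRUE)
    }
  }
  FALSE
}

# Quadratic per-variant interval scan (BED 0-based half-open).
oracle_overlaps_track <- function(chrom, pos1, track) {
  pos0 <- pos1 - 1
  any(track$chrom == chrom & track$start <= pos0 & pos0 < track$end)
}

# OLS + sandwich covariance from the normal equations, no QR.
oracle_ols_hc <- function(X, y, type = "HC3") {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  e <- as.numeric(y - X %*% beta)
  H <- X %*% xtx_inv %*% t(X)
  h <- diag(H)
  n <- nrow(X); p <- ncol(X)
  w <- switch(type,
              HC0 = e^2,
              HC1 = e^2 * n / (n - p),
              HC2 = e^2 / (1 - h),
              HC3 = e^2 / (1 - h)^2)
  meat <- t(X) %*% diag(w) %*% X
  list(beta = as.numeric(beta),
       V = xtx_inv %*% meat %*% xtx_inv,
       ols_cov = sum(e^2) / (n - p) * xtx_inv,
       leverages = h)
}

# BH step-up straight from the definition: adj_i = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive grep-style counter: prefix match of barcode + context per read.
oracle_count <- function(reads, barcodes, context) {
  vapply(barcodes, function(b) {
    sum(startsWith(reads, paste0(b, context)))
  }, integer(1))
}

# Exact two-sided one-sample signed-rank p by full enumeration (small n,
# distinct non-zero magnitudes).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Quartile/fence recomputation for the label-swapped outlier call.
oracle_ms_classes <- function(x, y, k = 1.5) {
  x <- x - median(x); y <- y - median(y)
  fence <- function(v) {
    q <- quantile(v, c(.25, .75), names = FALSE)
    c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
  }
  fx <- fence(x); fy <- fence(y)
  cls <- rep("none", length(x))
  cls[x > fx[2] & y < fy[1]] <- "A_preferential"
  cls[x < fx[1] & y > fy[2]] <- "C_preferential"
  cls[(x > fx[2] & y > fy[2]) | (x < fx[1] & y < fy[1])] <- "inconsistent"
  cls
}
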