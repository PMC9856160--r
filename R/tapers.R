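# Discrete prolate spheroidal sequences (Slepian tapers).
#
# The tapers are the top eigenvectors of the symmetric tridiagonal matrix
# that commutes with the band-limiting operator (Slepian's trick):
# diagonal ((N-1-2i)/2)^2 cos(2*pi*W), off-diagonal i(N-i)/2.  The k
# largest eigenvalues are located by bisection on the Sturm-sequence
# count and the eigenvectors recovered by inverse iteration with a
# pivoted tridiagonal solve, all O(N) per taper.

.taper_cache <- new.env(parent = emptyenv())

tridiag_matvec <- function(d, e, v) {
  n <- length(d)
  y <- d * v
  y[1:(n - 1L)] <- y[1:(n - 1L)] + e * v[2:n]
  y[2:n] <- y[2:n] + e * v[1:(n - 1L)]
  y
}

# Number of eigenvalues of tridiag(d, e) strictly less than x.
sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    denom <- if (q == 0) 1e-300 else q
    q <- (d[i] - x) - e[i - 1L]^2 / denom
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# Solve (tridiag(d, e) - lam*I) x = r by Gaussian elimination with
# partial pivoting (one superdiagonal of fill-in).
tridiag_shift_solve <- function(d, e, lam, r) {
  n <- length(d)
  a <- c(e, 0)            # subdiagonal entries a[i] couples rows i, i+1
  b <- d - lam            # main diagonal
  cc <- c(e, 0)           # superdiagonal
  f <- numeric(n)         # second superdiagonal (fill-in)
  x <- r
  for (i in 1:(n - 1L)) {
    if (abs(a[i]) > abs(b[i])) {
      tmp <- b[i]; b[i] <- a[i]; a[i] <- tmp
      tmp <- cc[i]; cc[i] <- b[i + 1L]; b[i + 1L] <- tmp
      if (i < n - 1L) { tmp <- f[i]; f[i] <- cc[i + 1L]; cc[i + 1L] <- tmp }
      tmp <- x[i]; x[i] <- x[i + 1L]; x[i + 1L] <- tmp
    }
    if (b[i] == 0) b[i] <- 1e-300
    m <- a[i] / b[i]
    b[i + 1L] <- b[i + 1L] - m * cc[i]
    if (i < n - 1L) cc[i + 1L] <- cc[i + 1L] - m * f[i]
    x[i + 1L] <- x[i + 1L] - m * x[i]
  }
  if (b[n] == 0) b[n] <- 1e-300
  x[n] <- x[n] / b[n]
  x[n - 1L] <- (x[n - 1L] - cc[n - 1L] * x[n]) / b[n - 1L]
  if (n > 2L) {
    for (i in (n - 2L):1L) {
      x[i] <- (x[i] - cc[i] * x[i + 1L] - f[i] * x[i + 2L]) / b[i]
    }
  }
  x
}

#' Slepian (DPSS) tapers
#'
#' Returns the first `k` discrete prolate spheroidal sequences of length
#' `n` with time-bandwidth product `nw`, each normalised to unit energy.
#' Sign convention: symmetric tapers have positive mean, antisymmetric
#' tapers start positive.  Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers, at most `2*nw - 1` (default `2*nw - 1`).
#' @return `n` x `k` matrix of tapers (columns ordered by decreasing
#'   spectral concentration).
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  if (k > 2 * nw - 1) stop("k must be at most 2*nw - 1 for usable concentration")
  if (n < 2 * k) stop("taper length too short for k tapers")
  key <- paste(n, nw, k, sep = "|")
  hit <- get0(key, envir = .taper_cache)
  if (!is.null(hit)) return(hit)

  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- (i[-1] * (n - i[-1])) / 2

  # Gershgorin bounds for bisection
  eext <- c(0, e, 0)
  lo <- min(d - abs(eext[1:n]) - abs(eext[2:(n + 1)]))
  hi <- max(d + abs(eext[1:n]) + abs(eext[2:(n + 1)]))
  span <- hi - lo
  tol <- span * 1e-14

  lams <- numeric(k)
  for (j in seq_len(k)) {
    # j-th largest eigenvalue: count of eigenvalues < x must reach n - j
    target <- n - j
    a <- lo; b <- hi
    while (b - a > tol) {
      mid <- (a + b) / 2
      if (sturm_count(d, e, mid) > target) b <- mid else a <- mid
    }
    lams[j] <- (a + b) / 2
  }

  tap <- matrix(0, n, k)
  v0 <- sin(sqrt(2) * seq_len(n)) + 0.5 * cos(sqrt(3) * seq_len(n))
  for (j in seq_len(k)) {
    v <- v0 / sqrt(sum(v0^2))
    for (it in 1:4) {
      v <- tridiag_shift_solve(d, e, lams[j], v)
      if (j > 1) {
        prev <- tap[, 1:(j - 1L), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
      res <- tridiag_matvec(d, e, v) - sum(v * tridiag_matvec(d, e, v)) * v
      if (sqrt(sum(res^2)) < span * 1e-12) break
    }
    tap[, j] <- v
  }
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else {
      lead <- which(abs(tap[, j]) > 0.1 * max(abs(tap[, j])))[1]
      if (tap[lead, j] < 0) tap[, j] <- -tap[, j]
    }
  }
  assign(key, tap, envir = .taper_cache)
  tap
}
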