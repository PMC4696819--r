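# Numeric differentiation helpers used for gradients of mean functions,
# observed-information Hessians, and delta-method gradients of derived doses.

# step h_j = sqrt(machine eps) * max(|x_j|, 1), central differences
fd_step <- function(x) sqrt(.Machine$double.eps) * pmax(abs(x), 1)

#' Central-difference gradient
#'
#' @param f scalar-valued function of a numeric vector
#' @param x point of evaluation
#' @param h optional step sizes (one per coordinate)
#' @return numeric gradient vector
#' @keywords internal
#' @noRd
num_gradient <- function(f, x, h = fd_step(x)) {
  p <- length(x)
  g <- numeric(p)
  for (j in seq_len(p)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- x[j] - h[j]
    g[j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  g
}

# Central-difference Hessian, h_j = eps^(1/4) * max(|x_j|, 1) (optimal order
# for second differences).  Symmetrised.
num_hessian <- function(f, x, h = .Machine$double.eps^0.25 * pmax(abs(x), 1)) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (j in seq_len(p)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- x[j] - h[j]
    H[j, j] <- (f(xp) - 2 * f0 + f(xm)) / h[j]^2
    if (j < p) {
      for (k in seq((j + 1), p)) {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(j, k)] <- x[c(j, k)] + h[c(j, k)]
        xmm[c(j, k)] <- x[c(j, k)] - h[c(j, k)]
        xpm[j] <- x[j] + h[j]; xpm[k] <- x[k] - h[k]
        xmp[j] <- x[j] - h[j]; xmp[k] <- x[k] + h[k]
        H[j, k] <- H[k, j] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[j] * h[k])
      }
    }
  }
  (H + t(H)) / 2
}

# Invert a symmetric matrix via Cholesky; NULL when not positive definite.
chol_inverse <- function(H) {
  out <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(out)) {
    out <- tryCatch(solve(H), error = function(e) NULL)
  }
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
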