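# Output-only subspace identification of innovation-form state-space models.

#' Innovation-form state-space model
#'
#' The scalar-output innovation form
#' \deqn{u_{k+1} = A u_k + K e_k, \qquad y_k = B u_k + e_k}
#' with dynamics matrix `A` (n x n), output row `B` (1 x n), steady-state
#' Kalman gain `K` (n x 1) and white innovations `e_k`.
#'
#' @param A n x n dynamics matrix.
#' @param B 1 x n output row.
#' @param K n x 1 Kalman gain column.
#' @param residual_variance variance of the innovations.
#' @return An object of class `ss_model` with the fields above plus
#'   `order` and `spectral_radius`.
#' @export
ss_model <- function(A, B, K, residual_variance = 1) {
  A <- as.matrix(A)
  n <- nrow(A)
  B <- matrix(as.numeric(B), 1, n)
  K <- matrix(as.numeric(K), n, 1)
  if (ncol(A) != n) stop("A must be square")
  if (!all(is.finite(A), is.finite(B), is.finite(K)))
    stop("model matrices must be finite")
  structure(list(A = A, B = B, K = K, order = n,
                 residual_variance = residual_variance,
                 spectral_radius = max(Mod(eigen(A, only.values = TRUE)$values))),
            class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf("<ss_model> order %d, spectral radius %.4f, innov. var %.4g\n",
              x$order, x$spectral_radius, x$residual_variance))
  invisible(x)
}

# least-squares projection of the rows of B onto the row space of A
.row_project <- function(A, B) t(qr.fitted(qr(t(A)), t(B)))

#' Estimate an innovation-form state-space model from a scalar series
#'
#' Output-only subspace identification (N4SID family): the series is mean
#' centred, past and future block-Hankel matrices of depth `horizon` are
#' formed, the future is projected orthogonally onto the row space of the
#' past, the projection's SVD is truncated at the requested order to give
#' the extended observability matrix and Kalman state sequence, `A` and `B`
#' follow from the state/output least-squares regression, and the Kalman
#' gain from the joint residual regression `K = cov(state residual,
#' innovation) / var(innovation)`.
#'
#' The estimate is a pure function of `(y, order, horizon)`: the SVD basis
#' is canonicalized (states ordered by descending singular value, each left
#' singular vector's largest-magnitude entry made positive) so repeated
#' calls return identical matrices.  Note that `(A, B, K)` is identified
#' only up to this canonical basis; across different data realizations only
#' similarity invariants (e.g. eigenvalues) are comparable.
#'
#' @param y numeric vector, at least `10 * horizon` samples, non-constant.
#' @param order model order n.
#' @param horizon block-Hankel depth (default `2*order + 1`).
#' @return An [ss_model].
#' @export
estimate_ssm <- function(y, order, horizon = 2 * order + 1) {
  y <- as.numeric(y)
  n <- as.integer(order)
  i <- as.integer(horizon)
  if (n < 1) stop("order must be >= 1")
  if (i < n + 1) stop("horizon must exceed the order")
  tn <- length(y)
  if (tn < 10 * i)
    stop("series too short: need at least 10*horizon = ", 10 * i,
         " samples, got ", tn)
  if (stats::sd(y) <= 1e-8 * max(abs(y), 1))
    stop("zero-variance series: cannot identify dynamics")
  yc <- y - mean(y)
  ncol_ <- tn - 2 * i + 1
  idx <- outer(seq_len(2 * i), seq_len(ncol_) - 1L, "+")
  hk <- matrix(yc[idx], nrow = 2 * i)
  yp <- hk[1:i, , drop = FALSE]
  yf <- hk[(i + 1):(2 * i), , drop = FALSE]
  of <- .row_project(yp, yf)
  sv <- svd(of)
  tol <- max(sv$d[1] * 1e-10, .Machine$double.eps)
  eff_rank <- sum(sv$d > tol)
  if (eff_rank < n)
    stop("requested order ", n, " exceeds the effective rank ", eff_rank,
         " of the projected data")
  u <- sv$u[, 1:n, drop = FALSE]
  d <- sv$d[1:n]
  # deterministic sign convention
  for (c in seq_len(n)) {
    jmx <- which.max(abs(u[, c]))
    if (u[jmx, c] < 0) u[, c] <- -u[, c]
  }
  gamma <- u %*% diag(sqrt(d), n)
  xf <- qr.solve(gamma, of)
  ypp <- hk[1:(i + 1), , drop = FALSE]
  yfm <- hk[(i + 2):(2 * i), , drop = FALSE]
  ofm <- .row_project(ypp, yfm)
  xfp <- qr.solve(gamma[1:(i - 1), , drop = FALSE], ofm)
  rhs <- rbind(xfp, hk[i + 1, ])
  theta <- t(qr.solve(t(xf) , t(rhs)))
  a <- theta[1:n, , drop = FALSE]
  b <- theta[n + 1, , drop = FALSE]
  resid <- rhs - theta %*% xf
  rv <- resid[n + 1, ]
  r0 <- mean(rv^2)
  if (r0 < 1e-12) r0 <- 1e-12  # numerically exact fit; clamp variance floor
  k <- (resid[1:n, , drop = FALSE] %*% rv) / (ncol_ * r0)
  m <- ss_model(a, b, k, residual_variance = r0)
  m$horizon <- i
  m
}

#' Simulate an innovation-form state-space model
#'
#' Runs the forward recursion `u_{k+1} = A u_k + K e_k`, `y_k = B u_k +
#' e_k` from a zero initial state with i.i.d. Gaussian innovations.  Used
#' as the simulation oracle for the estimator.
#'
#' @param model an [ss_model].
#' @param n_samples series length T.
#' @param noise_sd innovation standard deviation (default: square root of
#'   the model's residual variance).
#' @param seed optional integer; when given the run is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of length `n_samples`.
#' @export
simulate_ssm <- function(model, n_samples,
                         noise_sd = sqrt(model$residual_variance),
                         seed = NULL) {
  stopifnot(inherits(model, "ss_model"), n_samples >= 1)
  if (model$spectral_radius >= 1)
    warning("model is not stable (spectral radius ",
            round(model$spectral_radius, 4), "); simulation may diverge")
  e <- .with_seed(seed, stats::rnorm(n_samples, sd = noise_sd))
  n <- model$order
  y <- numeric(n_samples)
  u <- numeric(n)
  A <- model$A; B <- as.numeric(model$B); K <- as.numeric(model$K)
  for (k in seq_len(n_samples)) {
    y[k] <- sum(B * u) + e[k]
    u <- A %*% u + K * e[k]
  }
  y
}

#' One-step-ahead prediction residuals of a fitted model
#'
#' Runs the model as a predictor (Kalman innovation filter) over a series
#' and returns the innovation sequence; its variance measures out-of-sample
#' fit quality.
#'
#' @param model an [ss_model].
#' @param y numeric series.
#' @return Numeric vector of one-step prediction residuals.
#' @export
ssm_innovations <- function(model, y) {
  stopifnot(inherits(model, "ss_model"))
  yc <- as.numeric(y) - mean(y)
  n <- model$order
  u <- numeric(n)
  e <- numeric(length(yc))
  A <- model$A; B <- as.numeric(model$B); K <- as.numeric(model$K)
  for (k in seq_along(yc)) {
    e[k] <- yc[k] - sum(B * u)
    u <- A %*% u + K * e[k]
  }
  e
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
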