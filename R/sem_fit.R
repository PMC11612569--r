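# Parameter table construction and RAM matrices.
#
# The model is held in RAM form: one asymmetric matrix A of directed paths
# (loadings latent->indicator and structural regressions), one symmetric
# matrix S of (residual) variances and covariances, and the filter F onto
# the observed variables. The covariance over all variables is
#   Sigma_all = (I - A)^-1 S (I - A)^-T,   Sigma_obs = F Sigma_all F'.

param_table <- function(model) {
  rows <- list()
  for (lat in model$latents) {
    inds <- model$loadings$indicator[model$loadings$latent == lat]
    for (k in seq_along(inds)) {
      rows[[length(rows) + 1]] <- data.frame(
        type = "loading", from = lat, to = inds[k],
        free = k > 1, value = 1, stringsAsFactors = FALSE)
    }
  }
  if (nrow(model$regressions)) {
    for (k in seq_len(nrow(model$regressions)))
      rows[[length(rows) + 1]] <- data.frame(
        type = "reg", from = model$regressions$from[k],
        to = model$regressions$to[k], free = TRUE, value = 0,
        stringsAsFactors = FALSE)
  }
  for (v in model$vars)
    rows[[length(rows) + 1]] <- data.frame(
      type = "var", from = v, to = v, free = TRUE, value = 0.5,
      stringsAsFactors = FALSE)
  if (nrow(model$covariances)) {
    for (k in seq_len(nrow(model$covariances)))
      rows[[length(rows) + 1]] <- data.frame(
        type = "cov", from = model$covariances$a[k],
        to = model$covariances$b[k], free = TRUE, value = 0,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

ram_matrices <- function(model, pt) {
  v <- model$vars
  nv <- length(v)
  A <- matrix(0, nv, nv, dimnames = list(v, v))
  S <- matrix(0, nv, nv, dimnames = list(v, v))
  for (k in seq_len(nrow(pt))) {
    type <- pt$type[k]; from <- pt$from[k]; to <- pt$to[k]; val <- pt$value[k]
    if (type %in% c("loading", "reg")) {
      A[to, from] <- val
    } else if (type == "var") {
      S[to, to] <- val
    } else {  # cov
      S[from, to] <- val
      S[to, from] <- val
    }
  }
  list(A = A, S = S)
}

#' Model-implied covariance of the observed variables
#'
#' Composes the measurement and structural parts of the model into the
#' covariance matrix the parameters imply over the observed variables.
#'
#' @param model a [path_model()].
#' @param pt parameter table (as in the `params` element of a [fit_ml()]
#'   result, or built internally) with current `value`s.
#' @return symmetric p x p matrix, p = number of observed variables.
#' @export
implied_covariance <- function(model, pt) {
  m <- ram_matrices(model, pt)
  nv <- length(model$vars)
  IA <- diag(nv) - m$A
  det_ia <- det(IA)
  if (!is.finite(det_ia) || abs(det_ia) < 1e-12)
    stop("(I - B) is singular: structural paths do not define a model")
  Binv <- solve(IA)
  Sig_all <- Binv %*% m$S %*% t(Binv)
  Sig_all <- (Sig_all + t(Sig_all)) / 2
  Sig_all[model$observed, model$observed, drop = FALSE]
}

# covariance over ALL variables (observed + latent), used to standardize
implied_cov_all <- function(model, pt) {
  m <- ram_matrices(model, pt)
  IA <- diag(length(model$vars)) - m$A
  Binv <- solve(IA)
  Sig <- Binv %*% m$S %*% t(Binv)
  dimnames(Sig) <- list(model$vars, model$vars)
  (Sig + t(Sig)) / 2
}

ml_discrepancy <- function(Sigma, S) {
  p <- nrow(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdet_sig <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% S
  logdet_s <- determinant(S, logarithm = TRUE)$modulus[1]
  as.numeric(logdet_sig + sum(diag(Sinv_S)) - logdet_s - p)
}

# theta packing: variances on log scale to keep them positive
pack <- function(pt) {
  free <- which(pt$free)
  th <- pt$value[free]
  isv <- pt$type[free] == "var"
  th[isv] <- log(th[isv])
  th
}
unpack <- function(pt, theta) {
  free <- which(pt$free)
  isv <- pt$type[free] == "var"
  val <- theta
  val[isv] <- exp(pmin(val[isv], 50))
  pt$value[free] <- val
  pt
}

#' Fit a path model to a sample covariance matrix by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \deqn{F = \log|\Sigma(\theta)| + tr(S\,\Sigma(\theta)^{-1})
#'        - \log|S| - p}
#' over the free parameters (first loading per latent fixed to 1;
#' variances kept positive via a log parameterization) with BFGS and up to
#' `restarts` jittered restarts. Returns unstandardized and standardized
#' estimates plus chi-square-based fit indices (CFI, GFI, RMSEA, SRMR)
#' against the conventional acceptance gates CFI > 0.90, GFI > 0.90,
#' RMSEA < 0.06, SRMR < 0.05.
#'
#' @param sample_cov sample covariance matrix of the observed variables
#'   (dimnames must name them).
#' @param n sample size behind `sample_cov`.
#' @param model a [path_model()].
#' @param restarts max jittered restarts after the deterministic start.
#' @param seed seed for the jitter.
#' @param reltol optimizer relative tolerance.
#' @return list with `params` (parameter table with `value` and `std`),
#'   `fit` (list chisq, df, pvalue, CFI, GFI, RMSEA, SRMR), `Sigma`
#'   (implied covariance), `discrepancy`, `converged`, `model`.
#' @export
fit_ml <- function(sample_cov, n, model, restarts = 5, seed = 1,
                   reltol = 1e-10) {
  S <- as.matrix(sample_cov)
  if (is.null(dimnames(S)[[1]])) stop("sample_cov must have dimnames")
  miss <- setdiff(model$observed, rownames(S))
  if (length(miss))
    stop(sprintf("sample_cov lacks variable(s): %s", paste(miss, collapse = ", ")))
  S <- S[model$observed, model$observed]
  p <- nrow(S)
  if (n <= p) stop("sample size must exceed the number of observed variables")
  if (inherits(tryCatch(chol(S), error = function(e) e), "error"))
    stop("sample covariance is not positive-definite")
  pt <- param_table(model)
  # data-informed starting variances
  for (k in which(pt$type == "var")) {
    v <- pt$to[k]
    pt$value[k] <- if (v %in% model$observed) 0.5 * S[v, v] else {
      inds <- model$loadings$indicator[model$loadings$latent == v]
      if (length(inds)) 0.5 * S[inds[1], inds[1]] else 0.5
    }
  }
  objective <- function(theta) {
    pt2 <- unpack(pt, theta)
    Sig <- tryCatch(implied_covariance(model, pt2), error = function(e) NULL)
    if (is.null(Sig)) return(1e10)
    f <- ml_discrepancy(Sig, S)
    if (!is.finite(f)) 1e10 else f
  }
  th0 <- pack(pt)
  best <- NULL
  set.seed(seed)
  starts <- c(list(th0),
              lapply(seq_len(restarts), function(i)
                th0 + stats::rnorm(length(th0), 0, 0.2)))
  for (st in starts) {
    f_start <- objective(st)
    opt <- tryCatch(
      stats::optim(st, objective, method = "BFGS",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$value > f_start + 1e-8) next  # optimizer made things worse
    if (is.null(best) || opt$value < best$value) best <- opt
    if (!is.null(best) && best$value < 1e9 && best$convergence == 0) break
  }
  if (is.null(best) || best$value >= 1e9)
    stop("ML fit did not converge; best discrepancy so far: ",
         if (is.null(best)) "none" else format(best$value))
  pt <- unpack(pt, best$par)
  Sigma <- implied_covariance(model, pt)
  Fmin <- ml_discrepancy(Sigma, S)
  # standardized solution from the implied variances of all variables
  Sig_all <- implied_cov_all(model, pt)
  sdv <- sqrt(pmax(diag(Sig_all), 0))
  pt$std <- NA_real_
  for (k in seq_len(nrow(pt))) {
    f <- pt$from[k]; t <- pt$to[k]
    pt$std[k] <- switch(pt$type[k],
      loading = , reg = pt$value[k] * sdv[f] / sdv[t],
      var = pt$value[k] / (sdv[t]^2),
      cov = pt$value[k] / (sdv[f] * sdv[t]))
  }
  fit <- fit_indices(Fmin, S, Sigma, n, n_free = sum(pt$free))
  list(params = pt, fit = fit, Sigma = Sigma, discrepancy = Fmin,
       converged = best$convergence == 0, model = model)
}

# chi-square based fit indices against the independence baseline
fit_indices <- function(Fmin, S, Sigma, n, n_free) {
  p <- nrow(S)
  Tstat <- (n - 1) * Fmin
  df <- p * (p + 1) / 2 - n_free
  # baseline: diagonal covariance (independence)
  F_b <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
  T_b <- (n - 1) * F_b
  df_b <- p * (p - 1) / 2
  d <- max(Tstat - df, 0)
  d_b <- max(T_b - df_b, d, 0)
  CFI <- if (d_b > 0) 1 - d / d_b else 1
  Sinv_resid <- solve(Sigma) %*% (S - Sigma)
  num <- sum(diag(Sinv_resid %*% Sinv_resid))
  SiS <- solve(Sigma) %*% S
  GFI <- 1 - num / sum(diag(SiS %*% SiS))
  RMSEA <- if (df > 0) sqrt(max((Tstat - df) / (df * (n - 1)), 0)) else 0
  dS <- sqrt(diag(S))
  res <- (S - Sigma) / outer(dS, dS)
  SRMR <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  list(chisq = as.numeric(Tstat), df = df,
       pvalue = if (df > 0) stats::pchisq(as.numeric(Tstat), df,
                                          lower.tail = FALSE) else NA_real_,
       CFI = as.numeric(CFI), GFI = as.numeric(GFI),
       RMSEA = as.numeric(RMSEA), SRMR = as.numeric(SRMR))
}

#' Rank-based inverse-normal transform
#'
#' Deterministic normalizing stand-in used before SEM fitting: ranks are
#' mapped through the normal quantile function (Blom offsets) and the
#' result z-standardized to mean 0, sd 1. Monotone in the input; ties get
#' average ranks.
#'
#' @param x numeric vector with at least 3 finite values.
#' @return transformed vector (NA positions preserved), mean 0, sd 1.
#' @export
rank_normalize <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 3) stop("need at least 3 finite values")
  v <- x[ok]
  if (length(unique(v)) == 1) stop("all values tied: cannot normalize")
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  z <- (z - mean(z)) / stats::sd(z)
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  out
}
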