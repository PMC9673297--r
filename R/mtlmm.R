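#' Assemble a multi-trait model frame
#'
#' Builds the complete-case design for the Kronecker-structured multi-trait
#' mixed model: `t` stacked traits, fixed effects (intercept, sex, house
#' dummies with the first level as reference), and the genomic relationship
#' matrix aligned to the retained individuals. Individuals with any missing
#' trait or covariate are dropped and counted; the GRM is subset and
#' reordered to match by sample id.
#'
#' @param ph data.frame with a `sample_id` column, the trait columns, and
#'   the covariate columns.
#' @param K a `"grm"` object (see [vanraden_grm()]).
#' @param trait_columns character vector of trait column names.
#' @param covariate_columns character vector of covariate column names;
#'   columns named in `factor_covariates` are dummy-coded.
#' @param factor_covariates covariates to treat as factors.
#' @return object of class `"model_frame"`: list with `Y` (n x t), `X`
#'   (n x p), `K` (n x n), `sample_ids`, `trait_names`, `n_dropped`.
#' @export
build_model_frame <- function(ph, K, trait_columns,
                              covariate_columns = c("sex", "house"),
                              factor_covariates = "house") {
  stopifnot(is.data.frame(ph), "sample_id" %in% names(ph),
            all(trait_columns %in% names(ph)),
            all(covariate_columns %in% names(ph)))
  if (anyDuplicated(ph$sample_id)) stop("sample ids must be unique")
  used <- c(trait_columns, covariate_columns)
  complete <- stats::complete.cases(ph[, used, drop = FALSE])
  n_dropped <- sum(!complete)
  ph <- ph[complete, , drop = FALSE]
  idx <- match(ph$sample_id, K$sample_ids)
  if (anyNA(idx)) stop("phenotyped individuals missing from the GRM: ",
                       paste(utils::head(ph$sample_id[is.na(idx)], 5),
                             collapse = ", "))
  Km <- K$K[idx, idx, drop = FALSE]

  X <- matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariate_columns) {
    if (cv %in% factor_covariates) {
      f <- factor(ph[[cv]])
      if (nlevels(f) < 2L) {
        warning("covariate '", cv, "' has a single level and was dropped")
        next
      }
      d <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(d) <- paste0(cv, levels(f)[-1])
      X <- cbind(X, d)
    } else {
      X <- cbind(X, stats::setNames(ph[, cv, drop = FALSE], cv))
    }
  }
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("fixed-effect design is rank deficient; offending columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  Y <- as.matrix(ph[, trait_columns, drop = FALSE])
  n <- nrow(Y); t <- ncol(Y); p <- ncol(X)
  if (n < t + p + 1) stop("too few complete cases for the model")
  structure(list(Y = Y, X = X, K = Km, sample_ids = ph$sample_id,
                 trait_names = trait_columns, n_dropped = n_dropped),
            class = "model_frame")
}

#' @export
print.model_frame <- function(x, ...) {
  cat("model_frame:", nrow(x$Y), "individuals,", ncol(x$Y), "traits,",
      ncol(x$X), "fixed-effect columns (", x$n_dropped,
      "incomplete cases dropped )\n")
  invisible(x)
}

# --- internal linear algebra -------------------------------------------------

# symmetric eigen-clip to the PSD cone: floor eigenvalues at
# 1e-6 * trace / t (or at `floor_abs` if the trace is not positive)
.psd_clip <- function(S, rel = 1e-6, floor_abs = 1e-8) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lo <- max(rel * sum(pmax(diag(S), 0)) / nrow(S), floor_abs)
  if (min(e$values) >= lo) return(S)
  v <- pmax(e$values, lo)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

# simultaneous diagonalization of (Sigma_u, Sigma_e):
# returns T (t x t) and d with T' Su T = diag(d), T' Se T = I
.vc_transform <- function(Sigma_u, Sigma_e) {
  L <- t(chol(Sigma_e))
  Li <- forwardsolve(L, diag(nrow(L)))
  B <- Li %*% Sigma_u %*% t(Li)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(T = t(Li) %*% e$vectors, d = e$values,
       logdet_e = 2 * sum(log(diag(L))))
}

# per-trait weighted regressions after the double rotation; the workhorse
# shared by the REML objective, its derivatives and the association scans.
# Ytil = U'Y, Xtil = U'X, lambda = eigenvalues of K.
.rotated_fit <- function(Ytil, Xtil, lambda, Sigma_u, Sigma_e) {
  tr <- .vc_transform(Sigma_u, Sigma_e)
  t_ <- length(tr$d); n <- nrow(Ytil); p <- ncol(Xtil)
  W <- 1 / (outer(lambda, tr$d) + 1)          # n x t weights
  Yhat <- Ytil %*% tr$T
  beta <- matrix(0, p, t_); quad <- logdetC <- numeric(t_)
  Rhat <- matrix(0, n, t_)
  H <- matrix(0, n, t_)                        # leverage x_i' C_k^{-1} x_i
  Cinv <- vector("list", t_)
  for (k in seq_len(t_)) {
    wk <- W[, k]
    Xw <- Xtil * wk
    Ck <- crossprod(Xw, Xtil)
    R <- chol(Ck)
    Cinv[[k]] <- chol2inv(R)
    logdetC[k] <- 2 * sum(log(diag(R)))
    xy <- crossprod(Xw, Yhat[, k])
    beta[, k] <- Cinv[[k]] %*% xy
    quad[k] <- sum(wk * Yhat[, k]^2) - sum(xy * beta[, k])
    Rhat[, k] <- wk * (Yhat[, k] - Xtil %*% beta[, k])
    H[, k] <- rowSums((Xtil %*% Cinv[[k]]) * Xtil)
  }
  ll <- -0.5 * ((n * t_ - p * t_) * log(2 * pi) +
                (n - p) * tr$logdet_e + sum(log(outer(lambda, tr$d) + 1)) +
                sum(logdetC) + sum(quad))
  list(T = tr$T, d = tr$d, W = W, Yhat = Yhat, beta = beta, Rhat = Rhat,
       H = H, Cinv = Cinv, loglik = ll)
}

# score vector and average-information matrix at the current fit
.reml_score_ai <- function(fit, lambda, Xtil) {
  T_ <- fit$T; t_ <- length(fit$d); n <- nrow(fit$W)
  G <- fit$W - fit$W^2 * fit$H                 # diagonal of transformed P
  su <- colSums(G * lambda); se <- colSums(G)
  Auu <- crossprod(fit$Rhat * lambda, fit$Rhat)
  Aee <- crossprod(fit$Rhat)
  pars <- .vc_par_index(t_)
  q <- nrow(pars)
  score <- numeric(q)
  Vr <- vector("list", q)                      # dV %*% Py, transformed
  for (s in seq_len(q)) {
    a <- pars$a[s]; b <- pars$b[s]
    M <- outer(T_[a, ], T_[b, ])
    if (a != b) M <- M + t(M)
    if (pars$mat[s] == "u") {
      score[s] <- -0.5 * (sum(diag(M) * su) - sum(M * Auu))
      Vr[[s]] <- (fit$Rhat %*% M) * lambda
    } else {
      score[s] <- -0.5 * (sum(diag(M) * se) - sum(M * Aee))
      Vr[[s]] <- fit$Rhat %*% M
    }
  }
  # s_b = P (dV_b Py); AI_ab = 0.5 (dV_a Py)' s_b
  Pv <- lapply(Vr, function(v) {
    out <- v
    for (k in seq_len(t_)) {
      wv <- fit$W[, k] * v[, k]
      out[, k] <- wv - fit$W[, k] * (Xtil %*% (fit$Cinv[[k]] %*%
                                                 crossprod(Xtil, wv)))
    }
    out
  })
  AI <- matrix(0, q, q)
  for (s1 in seq_len(q)) for (s2 in seq_len(s1)) {
    AI[s1, s2] <- AI[s2, s1] <- 0.5 * sum(Vr[[s1]] * Pv[[s2]])
  }
  list(score = score, AI = AI, G = G, su = su, se = se,
       Auu = Auu, Aee = Aee)
}

.vc_par_index <- function(t_) {
  ut <- which(upper.tri(diag(t_), diag = TRUE), arr.ind = TRUE)
  data.frame(mat = rep(c("u", "e"), each = nrow(ut)),
             a = rep(ut[, 1], 2), b = rep(ut[, 2], 2))
}

.vc_from_par <- function(theta, t_) {
  q <- t_ * (t_ + 1) / 2
  fill <- function(v) {
    S <- matrix(0, t_, t_)
    S[upper.tri(S, diag = TRUE)] <- v
    S <- S + t(S) - diag(diag(S), t_)
    S
  }
  list(Sigma_u = fill(theta[seq_len(q)]), Sigma_e = fill(theta[q + seq_len(q)]))
}

.vc_to_par <- function(Sigma_u, Sigma_e) {
  c(Sigma_u[upper.tri(Sigma_u, diag = TRUE)],
    Sigma_e[upper.tri(Sigma_e, diag = TRUE)])
}

# one EM-REML update (guaranteed to stay in the PSD cone)
.em_update <- function(fit, sa, lambda, Sigma_u, Sigma_e) {
  n <- nrow(fit$W)
  Tinv <- solve(fit$T)
  Bu <- sa$Auu - diag(sa$su, length(fit$d))
  Be <- sa$Aee - diag(sa$se, length(fit$d))
  DBuD <- outer(fit$d, fit$d) * Bu
  list(Sigma_u = .psd_clip(Sigma_u + crossprod(Tinv, DBuD) %*% Tinv / n),
       Sigma_e = .psd_clip(Sigma_e + crossprod(Tinv, Be) %*% Tinv / n))
}

#' Fit the multi-trait genomic mixed model by REML
#'
#' Maximizes the restricted likelihood of the stacked multi-trait model
#' `y = (I_t (x) X) b + u + e` with `u ~ N(0, Sigma_u (x) K)` and
#' `e ~ N(0, Sigma_e (x) I)` over positive semidefinite trait covariance
#' matrices `Sigma_u`, `Sigma_e`.
#'
#' The GRM is eigendecomposed once (`K = U L U'`) and phenotypes and design
#' are rotated by `U'`, which block-diagonalizes the covariance per
#' individual; each likelihood evaluation then reduces to `t` weighted
#' regressions after a second, trait-space rotation that simultaneously
#' diagonalizes the two covariance matrices. Optimization uses
#' average-information (AI) REML with step-halving; an AI step whose
#' eigen-clipped update would decrease the restricted likelihood falls back
#' to an EM-REML step, which cannot decrease it. Convergence requires both
#' an absolute log-likelihood change below `tol` and a maximum relative
#' parameter change below `1e-6`.
#'
#' @param frame a `"model_frame"` from [build_model_frame()].
#' @param max_iter maximum number of iterations.
#' @param tol absolute restricted log-likelihood convergence tolerance.
#' @param start optional list with starting `Sigma_u`, `Sigma_e`; defaults
#'   to half the phenotypic covariance each.
#' @param extra_covariates optional n x c matrix appended to the fixed
#'   design (one coefficient per trait per column), e.g. a lead-SNP
#'   genotype for QTL-heritability refits.
#' @return object of class `"mtlmm"` with elements `Sigma_u`, `Sigma_e`,
#'   `loglik`, `converged`, `n_iter`, `beta` (p x t fixed effects on the
#'   original trait scale), `h2` (per-trait heritability), `frame`, and the
#'   cached rotation (`U`, `lambda`, `Ytil`, `Xtil`).
#' @export
fit_mtlmm <- function(frame, max_iter = 200, tol = 1e-8, start = NULL,
                      extra_covariates = NULL) {
  stopifnot(inherits(frame, "model_frame"))
  Y <- frame$Y; X <- frame$X
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.matrix(extra_covariates)
    colnames(extra_covariates) <- colnames(extra_covariates) %||%
      paste0("cov", seq_len(ncol(extra_covariates)))
    X <- cbind(X, extra_covariates)
    if (qr(X)$rank < ncol(X)) stop("extra covariates are collinear with the design")
  }
  n <- nrow(Y); t_ <- ncol(Y)
  eK <- eigen((frame$K + t(frame$K)) / 2, symmetric = TRUE)
  lambda <- pmax(eK$values, 0)
  identifiable <- stats::sd(lambda) > 1e-8 * max(mean(lambda), 1)
  if (!identifiable)
    warning("GRM eigenvalues are all equal (K proportional to I): only the ",
            "sum Sigma_u + Sigma_e is identified")
  U <- eK$vectors
  Ytil <- crossprod(U, Y)
  Xtil <- crossprod(U, X)

  S0 <- .psd_clip(stats::cov(Y))
  # residual covariance keeps a small positive floor on the phenotypic
  # scale so the per-trait weights stay numerically sane near the boundary
  se_floor <- 1e-6 * mean(diag(S0))
  Sigma_u <- .psd_clip(if (is.null(start)) S0 / 2 else start$Sigma_u)
  Sigma_e <- .psd_clip(if (is.null(start)) S0 / 2 else start$Sigma_e,
                       floor_abs = se_floor)

  fit <- .rotated_fit(Ytil, Xtil, lambda, Sigma_u, Sigma_e)
  ll <- fit$loglik
  converged <- FALSE; iter <- 0L
  for (iter in seq_len(max_iter)) {
    sa <- .reml_score_ai(fit, lambda, Xtil)
    theta <- .vc_to_par(Sigma_u, Sigma_e)
    delta <- tryCatch(solve(sa$AI + diag(1e-10, length(theta)), sa$score),
                      error = function(e) NULL)
    accepted <- FALSE
    if (iter > 2L && !is.null(delta)) {       # warm up with EM first
      step <- 1
      for (h in seq_len(10L)) {
        cand <- .vc_from_par(theta + step * delta, t_)
        Su_c <- .psd_clip(cand$Sigma_u)
        Se_c <- .psd_clip(cand$Sigma_e, floor_abs = se_floor)
        fit_c <- tryCatch(.rotated_fit(Ytil, Xtil, lambda, Su_c, Se_c),
                          error = function(e) NULL)
        if (!is.null(fit_c) && is.finite(fit_c$loglik) &&
            fit_c$loglik >= ll - 1e-12) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!accepted) {                           # EM fallback
      em <- .em_update(fit, sa, lambda, Sigma_u, Sigma_e)
      Su_c <- em$Sigma_u
      Se_c <- .psd_clip(em$Sigma_e, floor_abs = se_floor)
      fit_c <- .rotated_fit(Ytil, Xtil, lambda, Su_c, Se_c)
      if (!is.finite(fit_c$loglik))
        stop("restricted likelihood diverged; last logL = ", ll)
    }
    rel <- max(abs(.vc_to_par(Su_c, Se_c) - theta)) /
      max(abs(theta), 1e-8)
    dll <- fit_c$loglik - ll
    Sigma_u <- Su_c; Sigma_e <- Se_c; fit <- fit_c; ll <- fit_c$loglik
    if (abs(dll) < tol && rel < 1e-6) {
      converged <- TRUE
      break
    }
  }
  dimnames(Sigma_u) <- dimnames(Sigma_e) <-
    list(frame$trait_names, frame$trait_names)
  Tinv <- solve(fit$T)
  beta <- fit$beta %*% Tinv                    # back to original trait scale
  dimnames(beta) <- list(colnames(X), frame$trait_names)
  h2 <- diag(Sigma_u) / (diag(Sigma_u) + diag(Sigma_e))
  structure(list(Sigma_u = Sigma_u, Sigma_e = Sigma_e, loglik = ll,
                 converged = converged, n_iter = iter, beta = beta, h2 = h2,
                 identifiable = identifiable, frame = frame,
                 U = U, lambda = lambda, Ytil = Ytil, Xtil = Xtil,
                 X = X, rotated = fit),
            class = "mtlmm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restricted log-likelihood of the multi-trait model at fixed components
#'
#' Evaluates the REML objective maximized by [fit_mtlmm()] at
#' user-supplied `Sigma_u`, `Sigma_e`, using the rotated block computation.
#' Constant terms are included, so the value is comparable with a direct
#' dense-matrix evaluation of the restricted likelihood.
#'
#' @param frame a `"model_frame"`.
#' @param Sigma_u,Sigma_e trait covariance matrices (t x t, PSD; `Sigma_e`
#'   positive definite).
#' @return the restricted log-likelihood (scalar).
#' @export
mtlmm_loglik <- function(frame, Sigma_u, Sigma_e) {
  eK <- eigen((frame$K + t(frame$K)) / 2, symmetric = TRUE)
  lambda <- pmax(eK$values, 0)
  U <- eK$vectors
  .rotated_fit(crossprod(U, frame$Y), crossprod(U, frame$X), lambda,
               as.matrix(Sigma_u), as.matrix(Sigma_e))$loglik
}

#' Per-trait narrow-sense heritability from fitted variance components
#'
#' `h2_i = Sigma_u[i,i] / (Sigma_u[i,i] + Sigma_e[i,i])`.
#'
#' @param vc an `"mtlmm"` fit, or a list with `Sigma_u` and `Sigma_e`.
#' @param i trait index (vectorized); default all traits.
#' @return heritabilities in `[0, 1]`.
#' @export
heritability_from_vc <- function(vc, i = NULL) {
  su <- diag(as.matrix(vc$Sigma_u)); se <- diag(as.matrix(vc$Sigma_e))
  if (is.null(i)) i <- seq_along(su)
  tot <- su[i] + se[i]
  if (any(tot <= 0)) stop("zero total variance: heritability undefined")
  su[i] / tot
}

#' Genetic correlation matrix from an mtlmm fit
#' @param vc an `"mtlmm"` fit (or list with `Sigma_u`).
#' @return t x t correlation matrix of the additive genetic effects.
#' @export
genetic_correlation <- function(vc) {
  stats::cov2cor(as.matrix(vc$Sigma_u))
}

#' @export
print.mtlmm <- function(x, ...) {
  cat("Multi-trait genomic REML fit (", ncol(x$frame$Y), "traits,",
      nrow(x$frame$Y), "individuals )\n")
  cat(sprintf("  restricted logL = %.4f after %d iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("  per-trait h2:", paste(sprintf("%.3f", x$h2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mtlmm <- function(object, ...) {
  out <- list(Sigma_u = object$Sigma_u, Sigma_e = object$Sigma_e,
              h2 = object$h2, rg = genetic_correlation(object),
              beta = object$beta, loglik = object$loglik,
              converged = object$converged, n_iter = object$n_iter)
  class(out) <- "summary.mtlmm"
  out
}

#' @export
print.summary.mtlmm <- function(x, ...) {
  cat("Genetic covariance (Sigma_u):\n"); print(round(x$Sigma_u, 4))
  cat("Residual covariance (Sigma_e):\n"); print(round(x$Sigma_e, 4))
  cat("Heritability:\n"); print(round(x$h2, 4))
  cat("Genetic correlations:\n"); print(round(x$rg, 4))
  cat("Fixed effects:\n"); print(round(x$beta, 4))
  cat(sprintf("Restricted logL: %.4f (%s, %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
coef.mtlmm <- function(object, ...) object$beta

#' @export
logLik.mtlmm <- function(object, ...) {
  p <- ncol(object$X) * ncol(object$frame$Y)
  t_ <- ncol(object$frame$Y)
  val <- object$loglik
  attr(val, "df") <- t_ * (t_ + 1) + p
  attr(val, "nobs") <- length(object$frame$Y)
  class(val) <- "logLik"
  val
}

#' @export
fitted.mtlmm <- function(object, ...) {
  f <- object$X %*% object$beta
  colnames(f) <- object$frame$trait_names
  f
}

#' @export
residuals.mtlmm <- function(object, ...) {
  object$frame$Y - fitted(object)
}
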