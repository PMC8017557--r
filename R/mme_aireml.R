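## ---- model design ---------------------------------------------------------

#' Build the fixed-effect design for one trait
#'
#' Fixed effects are year-of-birth classes plus the age-at-slaughter
#' covariate; age is omitted for TEND and FLAV, where it carries no signal
#' in this population's models.  Under `conditional = TRUE` (the pleiotropy
#' scan's causal correction) all trait phenotypes other than the target
#' enter as covariates and only complete cases are kept.
#'
#' @param traits `trait_table`: `animal`, `birth_year`, optional `age`, one
#'   column per trait
#' @param target trait name to model
#' @param conditional fit all other traits as covariates?
#' @param use_age force the age covariate in (`TRUE`) or out (`FALSE`);
#'   default `NULL` applies the TEND/FLAV rule when an `age` column exists
#' @return `model_design` list: response `y`, design `X` (year classes,
#'   no intercept, plus covariates), record `animal` ids
#' @export
build_design <- function(traits, target, conditional = FALSE, use_age = NULL) {
  if (!target %in% names(traits)) stop("unknown trait: ", target)
  trait_cols <- setdiff(names(traits), c("animal", "birth_year", "age", "sex",
                                         "generation", "genotyped"))
  if (is.null(use_age))
    use_age <- "age" %in% names(traits) && !target %in% c("TEND", "FLAV")
  covs <- if (conditional) setdiff(trait_cols, target) else character()

  need <- c(target, if (use_age) "age", covs)
  keep <- stats::complete.cases(traits[, c("birth_year", need), drop = FALSE])
  d <- traits[keep, , drop = FALSE]
  if (!nrow(d)) stop("no usable records for trait ", target)

  yr <- factor(d$birth_year)
  X <- outer(as.character(d$birth_year), levels(yr), `==`) * 1
  colnames(X) <- paste0("year_", levels(yr))
  if (use_age) X <- cbind(X, age = d$age)
  for (cv in covs) X <- cbind(X, stats::setNames(d[, cv, drop = FALSE], cv))
  X <- as.matrix(X)

  structure(list(y = d[[target]], X = X, animal = as.character(d$animal),
                 target = target, conditional = conditional, use_age = use_age,
                 covariates = covs, n = nrow(d)),
            class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("<model_design %s: %d records, %d fixed-effect columns%s>\n",
              x$target, x$n, ncol(x$X),
              if (x$conditional) ", conditional" else ""))
  invisible(x)
}

## relmat -> covariance (invert the *inv kinds); returns matrix + labels
.relmat_cov <- function(K) {
  stopifnot(inherits(K, "relmat"))
  if (grepl("inv$", K$kind)) chol2inv(chol(K$values)) else K$values
}

.relmat_inv <- function(K) {
  stopifnot(inherits(K, "relmat"))
  if (grepl("inv$", K$kind)) K$values else chol2inv(chol(K$values))
}

## drop aliased fixed-effect columns (pivoted QR), warn once
.drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- q$pivot[(q$rank + 1L):ncol(X)]
    warning("dropping ", length(drop), " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

## ---- mixed-model equations ------------------------------------------------

#' Solve the single-trait mixed-model equations
#'
#' Solves `[X'X, X'W; W'X, W'W + (sigma_e2/sigma_u2) K^-1] [b; u] = [X'y; W'y]`
#' where `W` links records to animals and `K^-1` is the supplied
#' relationship inverse (H^-1, A^-1, ...).  Animals without records receive
#' breeding values through the relationship structure.  A singular
#' fixed-effect block is reported and resolved by a generalized inverse.
#'
#' @param design `model_design`
#' @param vc list or `varcomp` with `sigma_u2` and `sigma_e2` (> 0)
#' @param K `relmat` over all animals; inverse kinds are used directly,
#'   covariance kinds are inverted
#' @return list of class `mme_fit`: fixed-effect solutions `b`, breeding
#'   values `u` (named, all animals), `lambda`, residuals, and the solved
#'   system's residual norm
#' @export
solve_mme <- function(design, vc, K) {
  stopifnot(vc$sigma_u2 > 0, vc$sigma_e2 > 0)
  Kinv <- .relmat_inv(K)
  labs <- K$labels
  j <- match(design$animal, labs)
  if (anyNA(j)) stop("records refer to animals absent from the relationship matrix")
  X <- .drop_aliased(design$X)
  y <- design$y
  p <- ncol(X); q <- length(labs)
  lambda <- vc$sigma_e2 / vc$sigma_u2

  XtX <- crossprod(X)
  WtX <- matrix(0, q, p)
  rs <- rowsum(X, j)
  WtX[as.integer(rownames(rs)), ] <- rs
  Wty <- numeric(q)
  ys <- rowsum(y, j)
  Wty[as.integer(rownames(ys))] <- ys
  cnt <- tabulate(j, q)

  C <- matrix(0, p + q, p + q)
  C[1:p, 1:p] <- XtX
  C[1:p, p + 1:q] <- t(WtX)
  C[p + 1:q, 1:p] <- WtX
  C[p + 1:q, p + 1:q] <- lambda * Kinv
  diag(C)[p + 1:q] <- diag(C)[p + 1:q] + cnt
  rhs <- c(crossprod(X, y), Wty)

  sol <- tryCatch(solve(C, rhs), error = function(e) {
    warning("singular mixed-model equations; using a generalized inverse")
    MASS::ginv(C) %*% rhs
  })
  sol <- drop(sol)
  b <- stats::setNames(sol[1:p], colnames(X))
  u <- stats::setNames(sol[p + 1:q], labs)
  fitted <- drop(X %*% b) + u[design$animal]
  structure(list(b = b, u = u, lambda = lambda, fitted = fitted,
                 residuals = y - fitted,
                 sys_residual = max(abs(C %*% sol - rhs)) / max(1, max(abs(rhs))),
                 design = design),
            class = "mme_fit")
}

## ---- single-trait AI-REML -------------------------------------------------

## All REML computations run in the eigenbasis of K over the recorded
## animals, where V = sigma_u2*K + sigma_e2*I is diagonal; requires each
## record to map to a distinct animal (always true for these animal models).
.st_eval <- function(theta, lam, tX, ty) {
  v <- theta[1] * lam + theta[2]
  iv <- 1 / v
  C <- crossprod(tX, iv * tX)
  Cch <- chol(C)
  Cinv <- chol2inv(Cch)
  b <- Cinv %*% crossprod(tX, iv * ty)
  r <- drop(ty - tX %*% b)
  pv <- iv * r
  h <- rowSums((tX %*% Cinv) * tX)
  Pii <- iv - iv^2 * h
  yPy <- sum(r * pv)
  score <- -0.5 * c(u = sum(lam * Pii) - sum(lam * pv^2),
                    e = sum(Pii) - sum(pv^2))
  Pf <- function(f) iv * f - iv * drop(tX %*% (Cinv %*% crossprod(tX, iv * f)))
  fK <- lam * pv
  PfK <- Pf(fK); Pfe <- Pf(pv)
  AI <- 0.5 * matrix(c(sum(fK * PfK), sum(fK * Pfe),
                       sum(fK * Pfe), sum(pv * Pfe)), 2, 2)
  loglik <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(Cch))) + yPy)
  list(score = score, AI = AI, loglik = loglik,
       quad = c(sum(lam * pv^2), sum(pv^2)),
       trc = c(sum(lam * Pii), sum(Pii)))
}

#' Single-trait AI-REML variance components
#'
#' Estimates `(sigma_u2, sigma_e2)` of the animal model by average-
#' information REML: Newton steps on the restricted likelihood using the AI
#' matrix, with an EM-REML step whenever an AI update would leave the
#' parameter space or reduce the likelihood.  Standard errors come from the
#' inverse AI matrix; `se(h2)` by the delta method (approximate).
#'
#' @param design `model_design` (each record a distinct animal)
#' @param K `relmat` over all animals (e.g. H^-1 or A^-1; covariance kinds
#'   also accepted)
#' @param start optional `c(sigma_u2, sigma_e2)` starting values; default
#'   half the phenotypic variance each
#' @param max_rounds,tol iteration cap and relative-change tolerance
#' @return object of class `varcomp`
#' @export
aireml_single <- function(design, K, start = NULL, max_rounds = 200, tol = 1e-9) {
  if (anyDuplicated(design$animal))
    stop("repeated records per animal are not supported")
  if (length(unique(design$animal)) < 2) stop("need records on >= 2 animals")
  Kmat <- .relmat_cov(K)
  idx <- match(design$animal, K$labels)
  if (anyNA(idx)) stop("records refer to animals absent from the relationship matrix")
  Kobs <- Kmat[idx, idx]
  eg <- eigen(Kobs, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-12)
  X <- .drop_aliased(design$X)
  tX <- crossprod(eg$vectors, X)
  ty <- drop(crossprod(eg$vectors, design$y))
  n <- length(ty); p <- ncol(X)

  vp <- sum(qr.resid(qr(X), design$y)^2) / max(1, n - p)
  floor_v <- 1e-8 * vp
  theta <- if (is.null(start)) c(vp / 2, vp / 2) else as.numeric(start)
  theta <- pmax(theta, floor_v)

  cur <- .st_eval(theta, lam, tX, ty)
  converged <- FALSE; round <- 0L
  while (round < max_rounds) {
    round <- round + 1L
    em <- pmax(theta + theta^2 * (cur$quad - cur$trc) / n, floor_v)
    step <- tryCatch(solve(cur$AI, cur$score), error = function(e) NULL)
    cand <- NULL
    if (!is.null(step)) {
      fac <- 1
      for (k in 1:12) {
        prop <- theta + fac * step
        if (all(prop > floor_v * 0.999)) {
          ev <- tryCatch(.st_eval(prop, lam, tX, ty), error = function(e) NULL)
          if (!is.null(ev) && ev$loglik >= cur$loglik - 1e-8) {
            cand <- prop; cand_ev <- ev; break
          }
        }
        fac <- fac / 2
      }
    }
    if (is.null(cand)) {
      cand <- em
      cand_ev <- .st_eval(cand, lam, tX, ty)
    }
    delta <- max(abs(cand - theta) / (abs(theta) + floor_v))
    delta_abs <- max(abs(cand - theta)) / vp
    theta <- cand; cur <- cand_ev
    if (delta < tol || delta_abs < tol) { converged <- TRUE; break }
  }

  AIinv <- tryCatch(solve(cur$AI), error = function(e) matrix(NA_real_, 2, 2))
  s <- sum(theta)
  h2 <- theta[1] / s
  g <- c(theta[2], -theta[1]) / s^2
  se_h2 <- sqrt(max(0, drop(t(g) %*% AIinv %*% g)))
  if (!converged)
    warning("AI-REML did not converge in ", max_rounds, " rounds; last values returned")
  structure(list(sigma_u2 = theta[1], sigma_e2 = theta[2], h2 = h2,
                 se = c(sigma_u2 = sqrt(max(0, AIinv[1, 1])),
                        sigma_e2 = sqrt(max(0, AIinv[2, 2])), h2 = se_h2),
                 loglik = cur$loglik, converged = converged, rounds = round,
                 n_records = n, trait = design$target),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  if (!is.null(x$T)) {
    cat(sprintf("<varcomp bivariate %s/%s: r_g=%.3f r_p=%.3f h2=(%.3f, %.3f) %s>\n",
                x$traits[1], x$traits[2], x$r_g, x$r_p, x$h2[1], x$h2[2],
                if (x$converged) "converged" else "NOT converged"))
  } else {
    cat(sprintf("<varcomp %s: sigma_u2=%.4g sigma_e2=%.4g h2=%.3f (se %.3f) %s>\n",
                x$trait %||% "", x$sigma_u2, x$sigma_e2, x$h2, x$se["h2"],
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- bivariate AI-REML ----------------------------------------------------

## parameter vector order: T11 T12 T22 R11 R12 R22
.pd2 <- function(m11, m12, m22) m11 > 0 && m22 > 0 && m11 * m22 - m12^2 > 0

.bv_eval <- function(th, lam, tX1, tX2, ty1, ty2) {
  n <- length(ty1)
  v11 <- th[1] * lam + th[4]
  v12 <- th[2] * lam + th[5]
  v22 <- th[3] * lam + th[6]
  dt <- v11 * v22 - v12^2
  if (any(dt <= 0)) return(NULL)
  iv11 <- v22 / dt; iv22 <- v11 / dt; iv12 <- -v12 / dt
  p1c <- ncol(tX1); p2c <- ncol(tX2); p <- p1c + p2c

  C <- matrix(0, p, p)
  C[1:p1c, 1:p1c] <- crossprod(tX1, iv11 * tX1)
  C[1:p1c, p1c + 1:p2c] <- crossprod(tX1, iv12 * tX2)
  C[p1c + 1:p2c, 1:p1c] <- t(C[1:p1c, p1c + 1:p2c])
  C[p1c + 1:p2c, p1c + 1:p2c] <- crossprod(tX2, iv22 * tX2)
  rhs <- c(crossprod(tX1, iv11 * ty1 + iv12 * ty2),
           crossprod(tX2, iv12 * ty1 + iv22 * ty2))
  Cch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Cch)) return(NULL)
  Cinv <- chol2inv(Cch)
  b <- drop(Cinv %*% rhs)
  r1 <- ty1 - drop(tX1 %*% b[1:p1c])
  r2 <- ty2 - drop(tX2 %*% b[p1c + 1:p2c])
  pv1 <- iv11 * r1 + iv12 * r2
  pv2 <- iv12 * r1 + iv22 * r2
  yPy <- sum(r1 * pv1 + r2 * pv2)
  loglik <- -0.5 * (sum(log(dt)) + 2 * sum(log(diag(Cch))) + yPy)

  ## A-rows of V^-1 X: A1 = e1' V^-1 X, A2 = e2' V^-1 X (n x p)
  A1 <- cbind(iv11 * tX1, iv12 * tX2)
  A2 <- cbind(iv12 * tX1, iv22 * tX2)
  h11 <- rowSums((A1 %*% Cinv) * A1)
  h12 <- rowSums((A1 %*% Cinv) * A2)
  h22 <- rowSums((A2 %*% Cinv) * A2)
  P11 <- iv11 - h11; P12 <- iv12 - h12; P22 <- iv22 - h22

  ## tr(P B_m) and p' B_m p per parameter
  trPB <- c(sum(lam * P11), 2 * sum(lam * P12), sum(lam * P22),
            sum(P11), 2 * sum(P12), sum(P22))
  pBp <- c(sum(lam * pv1^2), 2 * sum(lam * pv1 * pv2), sum(lam * pv2^2),
           sum(pv1^2), 2 * sum(pv1 * pv2), sum(pv2^2))
  score <- -0.5 * (trPB - pBp)

  ## AI matrix: f_m = B_m P y (n x 2 each)
  f1 <- list(lam * pv1, 0 * pv1)        # T11
  f2 <- list(lam * pv2, lam * pv1)      # T12
  f3 <- list(0 * pv1, lam * pv2)        # T22
  f4 <- list(pv1, 0 * pv1)              # R11
  f5 <- list(pv2, pv1)                  # R12
  f6 <- list(0 * pv1, pv2)              # R22
  fs <- list(f1, f2, f3, f4, f5, f6)
  g1 <- lapply(fs, function(f) iv11 * f[[1]] + iv12 * f[[2]])
  g2 <- lapply(fs, function(f) iv12 * f[[1]] + iv22 * f[[2]])
  us <- lapply(seq_along(fs), function(m)
    c(crossprod(tX1, g1[[m]]), crossprod(tX2, g2[[m]])))
  AI <- matrix(0, 6, 6)
  for (m in 1:6) for (l in m:6) {
    val <- 0.5 * (sum(fs[[m]][[1]] * g1[[l]] + fs[[m]][[2]] * g2[[l]]) -
                    drop(t(us[[m]]) %*% Cinv %*% us[[l]]))
    AI[m, l] <- val; AI[l, m] <- val
  }

  ## EM ingredients: Psi_T = sum lam (pp' - P_ii), Psi_R same with weight 1
  PsiT <- matrix(c(sum(lam * (pv1^2 - P11)), sum(lam * (pv1 * pv2 - P12)),
                   sum(lam * (pv1 * pv2 - P12)), sum(lam * (pv2^2 - P22))), 2, 2)
  PsiR <- matrix(c(sum(pv1^2 - P11), sum(pv1 * pv2 - P12),
                   sum(pv1 * pv2 - P12), sum(pv2^2 - P22)), 2, 2)
  list(score = score, AI = AI, loglik = loglik, PsiT = PsiT, PsiR = PsiR, n = n)
}

.bv_em <- function(th, ev) {
  Tm <- matrix(th[c(1, 2, 2, 3)], 2, 2)
  Rm <- matrix(th[c(4, 5, 5, 6)], 2, 2)
  Tn <- Tm + Tm %*% ev$PsiT %*% Tm / ev$n
  Rn <- Rm + Rm %*% ev$PsiR %*% Rm / ev$n
  c(Tn[1, 1], Tn[1, 2], Tn[2, 2], Rn[1, 1], Rn[1, 2], Rn[2, 2])
}

#' Two-trait AI-REML variance components
#'
#' Estimates the full 2x2 additive (`T`) and residual (`R`) covariance
#' matrices of the two-trait animal model, and the derived genetic
#' (`r_g = T12/sqrt(T11 T22)`) and phenotypic
#' (`r_p = (T12+R12)/sqrt((T11+R11)(T22+R22))`) correlations.  When both
#' traits are recorded on the same animals the likelihood is evaluated in
#' the eigenbasis of their relationship block (fast path, any scale);
#' differing missingness patterns are handled by a dense general path
#' (records enter trait-wise, residual covariance only for animals observed
#' for both), intended for moderate record counts.
#'
#' @param designA,designB `model_design` for the two traits (shared pedigree)
#' @param K `relmat` over all animals
#' @param start optional list with `T` and `R` 2x2 start matrices
#' @param max_rounds,tol iteration cap and relative-change tolerance
#' @return object of class `varcomp` with `T`, `R`, `r_g`, `r_p`, `h2`
#' @export
aireml_bivariate <- function(designA, designB, K, start = NULL,
                             max_rounds = 200, tol = 1e-9) {
  if (anyDuplicated(designA$animal) || anyDuplicated(designB$animal))
    stop("repeated records per animal are not supported")
  same <- identical(sort(designA$animal), sort(designB$animal))
  if (same) {
    .aireml_bv_fast(designA, designB, K, start, max_rounds, tol)
  } else {
    .aireml_bv_direct(designA, designB, K, start, max_rounds, tol)
  }
}

.bv_start <- function(designA, designB, start) {
  vfun <- function(d) {
    X <- .drop_aliased(d$X)
    sum(qr.resid(qr(X), d$y)^2) / max(1, length(d$y) - ncol(X))
  }
  v1 <- vfun(designA); v2 <- vfun(designB)
  if (!is.null(start)) {
    th <- c(start$T[1, 1], start$T[1, 2], start$T[2, 2],
            start$R[1, 1], start$R[1, 2], start$R[2, 2])
  } else {
    th <- c(v1 / 2, 0, v2 / 2, v1 / 2, 0, v2 / 2)
  }
  list(theta = th, floor_v = 1e-8 * c(v1, v2))
}

.bv_wrap <- function(th, AI, loglik, converged, rounds, designA, designB, n) {
  Tm <- matrix(th[c(1, 2, 2, 3)], 2, 2)
  Rm <- matrix(th[c(4, 5, 5, 6)], 2, 2)
  tn <- c(designA$target, designB$target)
  dimnames(Tm) <- dimnames(Rm) <- list(tn, tn)
  r_g <- Tm[1, 2] / sqrt(Tm[1, 1] * Tm[2, 2])
  r_p <- (Tm[1, 2] + Rm[1, 2]) /
    sqrt((Tm[1, 1] + Rm[1, 1]) * (Tm[2, 2] + Rm[2, 2]))
  for (nm in c("r_g", "r_p")) {
    v <- get(nm)
    if (is.finite(v) && abs(v) > 1) {
      warning(nm, " = ", round(v, 4), " clamped to [-1, 1]")
      assign(nm, sign(v))
    }
  }
  AIinv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 6, 6))
  gr <- c(-r_g / (2 * Tm[1, 1]), 1 / sqrt(Tm[1, 1] * Tm[2, 2]),
          -r_g / (2 * Tm[2, 2]), 0, 0, 0)
  se_rg <- sqrt(max(0, drop(t(gr) %*% AIinv %*% gr)))
  h2 <- diag(Tm) / (diag(Tm) + diag(Rm))
  if (!converged)
    warning("bivariate AI-REML did not converge in ", rounds, " rounds")
  structure(list(T = Tm, R = Rm, r_g = r_g, r_p = r_p, h2 = h2,
                 se = c(r_g = se_rg),
                 se_theta = sqrt(pmax(0, diag(AIinv))),
                 sigma_u2 = diag(Tm), sigma_e2 = diag(Rm),
                 loglik = loglik, converged = converged, rounds = rounds,
                 n_records = n, traits = tn),
            class = "varcomp")
}

.bv_iterate <- function(theta, floor_v, evalf, max_rounds, tol,
                        fallback = .bv_em) {
  valid <- function(th) {
    th[1] >= floor_v[1] * 0.999 && th[3] >= floor_v[2] * 0.999 &&
      th[4] >= floor_v[1] * 0.999 && th[6] >= floor_v[2] * 0.999 &&
      th[1] * th[3] - th[2]^2 >= -1e-12 * th[1] * th[3] &&
      th[4] * th[6] - th[5]^2 >= -1e-12 * th[4] * th[6]
  }
  shrink_cov <- function(th) {
    ## pull covariances inside the PD cone if rounding pushed them out
    for (k in c(2, 5)) {
      i <- k - 1; j <- k + 1
      lim <- 0.999 * sqrt(th[i] * th[j])
      th[k] <- max(min(th[k], lim), -lim)
    }
    th
  }
  cur <- evalf(theta)
  if (is.null(cur)) stop("starting values give a non-PD covariance structure")
  converged <- FALSE; round <- 0L
  while (round < max_rounds) {
    round <- round + 1L
    step <- tryCatch(solve(cur$AI, cur$score), error = function(e) NULL)
    cand <- NULL
    if (!is.null(step)) {
      fac <- 1
      for (k in 1:12) {
        prop <- shrink_cov(pmax_floor(theta + fac * step, floor_v))
        if (valid(prop)) {
          ev <- evalf(prop)
          if (!is.null(ev) && ev$loglik >= cur$loglik - 1e-8) {
            cand <- prop; cand_ev <- ev; break
          }
        }
        fac <- fac / 2
      }
    }
    if (is.null(cand)) {
      prop <- shrink_cov(pmax_floor(fallback(theta, cur), floor_v))
      cand_ev <- if (valid(prop)) evalf(prop) else NULL
      if (is.null(cand_ev)) break   # stuck on the boundary; report last values
      cand <- prop
    }
    delta <- max(abs(cand - theta) /
                   (abs(theta) + rep(c(floor_v[1], sqrt(prod(floor_v)), floor_v[2]), 2)))
    theta <- cand; cur <- cand_ev
    if (delta < tol) { converged <- TRUE; break }
  }
  list(theta = theta, cur = cur, converged = converged, rounds = round)
}

pmax_floor <- function(th, floor_v) {
  th[1] <- max(th[1], floor_v[1]); th[3] <- max(th[3], floor_v[2])
  th[4] <- max(th[4], floor_v[1]); th[6] <- max(th[6], floor_v[2])
  th
}

.aireml_bv_fast <- function(designA, designB, K, start, max_rounds, tol) {
  Kmat <- .relmat_cov(K)
  ids <- designA$animal
  ordB <- match(ids, designB$animal)
  idx <- match(ids, K$labels)
  if (anyNA(idx)) stop("records refer to animals absent from the relationship matrix")
  Kobs <- Kmat[idx, idx]
  eg <- eigen(Kobs, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-12)
  X1 <- .drop_aliased(designA$X)
  X2 <- .drop_aliased(designB$X)[ordB, , drop = FALSE]
  tX1 <- crossprod(eg$vectors, X1)
  tX2 <- crossprod(eg$vectors, X2)
  ty1 <- drop(crossprod(eg$vectors, designA$y))
  ty2 <- drop(crossprod(eg$vectors, designB$y[ordB]))

  st <- .bv_start(designA, designB, start)
  res <- .bv_iterate(st$theta, st$floor_v,
                     function(th) .bv_eval(th, lam, tX1, tX2, ty1, ty2),
                     max_rounds, tol)
  .bv_wrap(res$theta, res$cur$AI, res$cur$loglik, res$converged, res$rounds,
           designA, designB, length(ty1))
}

## general path: dense V over stacked records; B_m basis matrices built once
.aireml_bv_direct <- function(designA, designB, K, start, max_rounds, tol) {
  Kmat <- .relmat_cov(K)
  i1 <- match(designA$animal, K$labels)
  i2 <- match(designB$animal, K$labels)
  if (anyNA(i1) || anyNA(i2))
    stop("records refer to animals absent from the relationship matrix")
  n1 <- length(i1); n2 <- length(i2); N <- n1 + n2
  X1 <- .drop_aliased(designA$X); X2 <- .drop_aliased(designB$X)
  X <- matrix(0, N, ncol(X1) + ncol(X2))
  X[1:n1, 1:ncol(X1)] <- X1
  X[n1 + 1:n2, ncol(X1) + 1:ncol(X2)] <- X2
  y <- c(designA$y, designB$y)

  K11 <- Kmat[i1, i1]; K12 <- Kmat[i1, i2]; K22 <- Kmat[i2, i2]
  J12 <- outer(designA$animal, designB$animal, `==`) * 1
  zero <- function(a, b) matrix(0, a, b)
  Bs <- list(
    T11 = rbind(cbind(K11, zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
    T12 = rbind(cbind(zero(n1, n1), K12), cbind(t(K12), zero(n2, n2))),
    T22 = rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), K22)),
    R11 = rbind(cbind(diag(n1), zero(n1, n2)), cbind(zero(n2, n1), zero(n2, n2))),
    R12 = rbind(cbind(zero(n1, n1), J12), cbind(t(J12), zero(n2, n2))),
    R22 = rbind(cbind(zero(n1, n1), zero(n1, n2)), cbind(zero(n2, n1), diag(n2))))

  evalf <- function(th) {
    V <- th[1] * Bs$T11 + th[2] * Bs$T12 + th[3] * Bs$T22 +
      th[4] * Bs$R11 + th[5] * Bs$R12 + th[6] * Bs$R22
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    C <- crossprod(X, Vi %*% X)
    Cch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(Cch)) return(NULL)
    Cinv <- chol2inv(Cch)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% Cinv %*% t(ViX)
    pv <- drop(P %*% y)
    trPB <- vapply(Bs, function(B) sum(P * B), 0)
    pBp <- vapply(Bs, function(B) drop(t(pv) %*% B %*% pv), 0)
    score <- -0.5 * (trPB - pBp)
    Fm <- vapply(Bs, function(B) drop(B %*% pv), numeric(N))
    PF <- P %*% Fm
    AI <- 0.5 * crossprod(Fm, PF)
    loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(Cch))) + sum(y * pv))
    list(score = score, AI = AI, loglik = loglik, n = N)
  }

  st <- .bv_start(designA, designB, start)
  ## fallback when the AI step fails: short damped step along the score
  grad_step <- function(theta, cur) {
    s <- cur$score
    d <- 0.1 * max(abs(theta)) / max(abs(s), 1e-12)
    theta + d * s
  }
  res <- .bv_iterate(st$theta, st$floor_v, evalf, max_rounds, tol,
                     fallback = grad_step)
  .bv_wrap(res$theta, res$cur$AI, res$cur$loglik, res$converged, res$rounds,
           designA, designB, N)
}

## ---- serialization --------------------------------------------------------

#' Write variance-component estimates as TSV
#'
#' Single-trait results become one row per trait (`trait, sigma_u2,
#' sigma_e2, h2, se_h2, loglik, converged`); bivariate results one row per
#' pair (`trait1, trait2, r_g, se_rg, r_p, loglik, converged`).
#'
#' @param vcs a `varcomp` or list of them (all single- or all two-trait)
#' @param file path
#' @export
write_varcomp <- function(vcs, file) {
  if (inherits(vcs, "varcomp")) vcs <- list(vcs)
  rows <- lapply(vcs, function(v) {
    if (!is.null(v$T))
      data.frame(trait1 = v$traits[1], trait2 = v$traits[2], r_g = v$r_g,
                 se_rg = unname(v$se["r_g"]), r_p = v$r_p, loglik = v$loglik,
                 converged = v$converged)
    else
      data.frame(trait = v$trait %||% NA, sigma_u2 = v$sigma_u2,
                 sigma_e2 = v$sigma_e2, h2 = v$h2,
                 se_h2 = unname(v$se["h2"]), loglik = v$loglik,
                 converged = v$converged)
  })
  data.table::fwrite(do.call(rbind, rows), file, sep = "\t")
  invisible(file)
}
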