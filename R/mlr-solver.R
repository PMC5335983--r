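#' @include utils.R
NULL

# Internal solver for the working-set subproblem of metric learning to
# rank. The primal over the current constraint set is
#
#   min_{w PSD}  lambda * tr(w) + (mu/2) ||w||_F^2
#                + sum_q cap * max(0, max_{r in W_q} (Delta_r - <w, dPsi_r>))
#
# with cap = C / nQueries; (lambda, mu) = (1, traceDamp) selects the
# damped trace regularizer and (0, 1) the Frobenius one. The dual has
# one multiplier alpha_r >= 0 per constraint, capped per query group
# (sum_{r in W_q} alpha_r <= cap), and the closed-form primal map
#
#   w(alpha) = (M(alpha) - lambda I)_+ / mu,  M = sum_r alpha_r dPsi_r,
#
# so the PSD cone is enforced exactly through eigenvalue shrinkage
# (the trace term acts as a spectral shift that zeroes all
# eigendirections of M below 1, which is what gives trace-regularized
# metrics their low-rank character). The dual objective
# g(alpha) = alpha'Delta - ||(M - lambda I)_+||^2 / (2 mu) is smooth
# and concave with gradient Lipschitz constant sigma_max(Psi)^2 / mu;
# it is maximised by monotone FISTA with per-group projection. Warm
# starts across cutting-plane iterations keep the recorded dual
# objective non-decreasing.

# Projection of v onto {x >= 0, sum(x) <= cap}.
projectCappedSimplex <- function(v, cap) {
  x <- pmax(v, 0)
  if (sum(x) <= cap) {
    return(x)
  }
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - cap
  rho <- max(which(u - css / seq_along(u) > 0))
  pmax(v - css[rho] / rho, 0)
}

projectGroups <- function(v, groups, cap) {
  for (g in groups) {
    v[g] <- projectCappedSimplex(v[g], cap)
  }
  v
}

# Shrinkage w = (M - lambda I)_+ / mu and the squared norm of the
# shrunk part (for the dual value).
shrinkPSD <- function(M, lambda, mu) {
  d <- nrow(M)
  e <- eigen((M + t(M)) / 2 - lambda * diag(d), symmetric = TRUE)
  pos <- e$values > 0
  if (!any(pos)) {
    return(list(w = matrix(0, d, d), sq = 0))
  }
  v <- e$vectors[, pos, drop = FALSE]
  shr <- v %*% (e$values[pos] * t(v))
  list(w = (shr + t(shr)) / 2 / mu, sq = sum(e$values[pos]^2))
}

dualValue <- function(alpha, Delta, sq, mu) {
  sum(alpha * Delta) - sq / (2 * mu)
}

primalOf <- function(alpha, Psi, lambda, mu, d) {
  M <- matrix(drop(crossprod(Psi, alpha)), d, d)
  shrinkPSD(M, lambda, mu)
}

# Monotone FISTA on the dual; returns alpha, w, and the dual objective.
solveWorkingSet <- function(Psi, Delta, qidx, cap, lambda, mu, d,
                            alpha0 = NULL, maxInner = 1500,
                            innerTol = 1e-11) {
  m <- nrow(Psi)
  groups <- split(seq_len(m), qidx)
  if (is.null(alpha0)) {
    alpha0 <- numeric(m)
  }
  # Lipschitz bound via power iteration on Psi'Psi
  v <- rep(1 / sqrt(m), m)
  sig2 <- 1
  for (i in 1:30) {
    pv <- drop(Psi %*% drop(crossprod(Psi, v)))
    nv <- sqrt(sum(pv^2))
    if (nv < 1e-300) break
    sig2 <- nv
    v <- pv / nv
  }
  L <- max(sig2, 1e-12) * 1.05 / mu
  alpha <- projectGroups(alpha0, groups, cap)
  pr <- primalOf(alpha, Psi, lambda, mu, d)
  gBest <- dualValue(alpha, Delta, pr$sq, mu)
  wBest <- pr$w
  y <- alpha
  tk <- 1
  stall <- 0
  for (it in seq_len(maxInner)) {
    prY <- primalOf(y, Psi, lambda, mu, d)
    grad <- Delta - drop(Psi %*% as.vector(prY$w))
    cand <- projectGroups(y + grad / L, groups, cap)
    prC <- primalOf(cand, Psi, lambda, mu, d)
    gC <- dualValue(cand, Delta, prC$sq, mu)
    if (gC < gBest) {
      # monotone safeguard: plain projected gradient from the best point
      prB <- primalOf(alpha, Psi, lambda, mu, d)
      gradB <- Delta - drop(Psi %*% as.vector(prB$w))
      cand2 <- projectGroups(alpha + gradB / L, groups, cap)
      prC2 <- primalOf(cand2, Psi, lambda, mu, d)
      gC2 <- dualValue(cand2, Delta, prC2$sq, mu)
      if (gC2 > gC) {
        cand <- cand2
        gC <- gC2
        prC <- prC2
      }
      tk <- 1
      y <- cand
    }
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + ((tk - 1) / tNew) * (cand - alpha)
    tk <- tNew
    improve <- gC - gBest
    if (gC >= gBest) {
      gBest <- gC
      wBest <- prC$w
      alpha <- cand
    }
    if (improve >= 0 && improve < innerTol * (1 + abs(gBest))) {
      stall <- stall + 1
      if (stall >= 10) break
    } else {
      stall <- 0
    }
  }
  list(alpha = alpha, w = wBest, dual = gBest)
}
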