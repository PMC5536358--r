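# Convex quadratic programming for the flux-selection stage.
#
# Minimises  sum_i w_i * x_i^2   subject to  A x = b,  lb <= x <= ub,
# and optionally one extra inequality  g'x >= h  (the objective floor).
#
# Primary path: equality constraints (including variables pinned by
# lb == ub) are eliminated through a QR null-space reduction and the
# reduced box-only problem goes to quadprog::solve.QP. The single
# inequality is handled exactly by case analysis: the minimiser either
# satisfies it strictly (solve without it) or holds it with equality
# (re-solve with the row folded into the equality system).
#
# The dual active-set method can fail spuriously on degenerate faces (many
# simultaneously tight bounds, as happens when the objective floor equals
# the true optimum). Failures are therefore arbitrated: a simplex phase-1
# run decides feasibility exactly, and feasible-but-failed problems fall
# back to an operator-splitting (ADMM) iteration whose answer is polished
# on its active set and certified against the KKT conditions.

qp_weighted_norm <- function(w, A, b, lb, ub, G = NULL, h = NULL,
                             tol = 1e-8) {
  n <- length(w)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = NULL))

  pinned <- which(ub - lb <= 1e-12)
  Ae0 <- A; be0 <- b
  if (length(pinned)) {
    U <- matrix(0, length(pinned), n)
    U[cbind(seq_along(pinned), pinned)] <- 1
    Ae0 <- rbind(Ae0, U); be0 <- c(be0, lb[pinned])
  }
  free_idx <- setdiff(seq_len(n), pinned)

  solve_eq <- function(Ae, be) {
    # min sum w x^2 s.t. Ae x = be plus box constraints on free variables;
    # null-space reduction from one QR: t(Ae)[, piv] = Q R.
    qtA <- qr(t(Ae))
    r <- qtA$rank
    Q <- qr.Q(qtA, complete = TRUE)
    R <- qr.R(qtA)
    piv <- qtA$pivot
    x0 <- if (r > 0) {
      u1 <- forwardsolve(t(R[seq_len(r), seq_len(r), drop = FALSE]),
                         be[piv][seq_len(r)])
      as.vector(Q[, seq_len(r), drop = FALSE] %*% u1)
    } else rep(0, n)
    if (max(abs(Ae %*% x0 - be)) > tol * max(1, max(abs(be))))
      return(list(status = "infeasible", x = NULL))
    if (r >= n) {
      viol <- max(c(lb - x0, x0 - ub))
      return(if (viol <= 1e-6) list(status = "optimal", x = as.vector(x0))
             else list(status = "infeasible", x = NULL))
    }
    Z <- Q[, (r + 1L):n, drop = FALSE]
    W <- diag(w, n)
    Dr <- crossprod(Z, W %*% Z)
    Dr <- (Dr + t(Dr)) / 2
    Dr <- Dr + diag(1e-10 * max(1, max(diag(Dr))), ncol(Z))
    dvec <- -as.vector(crossprod(Z, W %*% x0))
    fl <- free_idx[is.finite(lb[free_idx])]
    fu <- free_idx[is.finite(ub[free_idx])]
    Cons <- rbind(Z[fl, , drop = FALSE], -Z[fu, , drop = FALSE])
    rhs <- c(lb[fl] - x0[fl], x0[fu] - ub[fu])
    live <- rowSums(abs(Cons)) > 1e-12
    if (any(!live & rhs > 1e-7))
      return(list(status = "infeasible", x = NULL))
    Cons <- Cons[live, , drop = FALSE]; rhs <- rhs[live]
    sol <- tryCatch(
      quadprog::solve.QP(2 * Dr, 2 * dvec, t(Cons), rhs, meq = 0),
      error = function(e) conditionMessage(e))
    if (is.character(sol))
      return(arbitrate(Ae, be, sol))
    list(status = "optimal", x = as.vector(x0 + Z %*% sol$solution))
  }

  # quadprog failed: decide feasibility exactly, then fall back to ADMM
  arbitrate <- function(Ae, be, msg) {
    fe <- simplex_lp(rep(0, n), Ae, be, lb, ub, maximize = TRUE)
    if (identical(fe$status, "infeasible"))
      return(list(status = "infeasible", x = NULL))
    adm <- admm_box_qp(w, Ae, be, lb, ub)
    if (is.null(adm))
      return(list(status = "numerical_failure", x = NULL, message = msg))
    list(status = "optimal", x = adm)
  }

  res <- solve_eq(Ae0, be0)
  if (!is.null(G)) {
    g <- as.numeric(G)
    stopifnot(length(g) == n, length(h) == 1L)
    if (!(identical(res$status, "optimal") &&
          sum(g * res$x) >= h - tol * max(1, abs(h)))) {
      # floor active (or the relaxed problem failed): fold it in as equality
      res <- solve_eq(rbind(Ae0, g), c(be0, h))
    }
  }
  if (identical(res$status, "optimal"))
    res$objective <- sum(w * res$x^2)
  res
}

# Operator-splitting solve of  min sum w x^2  s.t. Ae x = be, lb <= x <= ub,
# followed by an exact KKT polish on the identified active set. Returns the
# certified solution, or NULL when certification fails.
admm_box_qp <- function(w, Ae, be, lb, ub, rho = 1, sigma = 1e-6,
                        max_iter = 50000L, check_every = 500L) {
  n <- length(w)
  At <- rbind(Ae, diag(n))
  lo <- c(be, lb); hi <- c(be, ub)
  K <- diag(2 * w + sigma, n) + rho * crossprod(At)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  x <- rep(0, n); z <- as.vector(At %*% x); y <- rep(0, nrow(At))
  scale <- max(1, max(abs(be)), max(abs(ub[is.finite(ub)]), 0))
  for (it in seq_len(max_iter)) {
    rhsv <- sigma * x + crossprod(At, rho * z - y)
    x <- backsolve(ch, forwardsolve(t(ch), rhsv))
    Ax <- as.vector(At %*% x)
    z_new <- pmin(pmax(Ax + y / rho, lo), hi)
    y <- y + rho * (Ax - z_new)
    if (it %% check_every == 0L &&
        max(abs(Ax - z_new)) < 1e-10 * scale &&
        max(abs(z_new - z)) < 1e-10 * scale) { z <- z_new; break }
    z <- z_new
  }
  x <- as.numeric(x)
  # polish: equality-solve on the active rows, then certify the KKT system
  Ax <- as.vector(At %*% x)
  atol <- 1e-6 * scale
  act <- which(Ax <= lo + atol | Ax >= hi - atol | lo == hi)
  vals <- ifelse(lo[act] == hi[act], lo[act],
                 ifelse(Ax[act] <= lo[act] + atol, lo[act], hi[act]))
  Aact <- At[act, , drop = FALSE]
  KKT <- rbind(cbind(diag(2 * w + 1e-12, n), t(Aact)),
               cbind(Aact, matrix(0, length(act), length(act))))
  sol <- tryCatch(qr.coef(qr(KKT, LAPACK = TRUE), c(rep(0, n), vals)),
                  error = function(e) NULL)
  if (!is.null(sol)) {
    xp <- sol[seq_len(n)]; xp[is.na(xp)] <- 0
    lam <- sol[-seq_len(n)]; lam[is.na(lam)] <- 0
    Axp <- as.vector(At %*% xp)
    feas <- max(c(lo - Axp, Axp - hi)) < 1e-7 * scale
    # stationarity: 2 W xp = At_act' lambda
    stat <- max(abs(2 * w * xp - as.vector(crossprod(Aact, lam)))) <
      1e-6 * max(1, max(abs(xp)))
    # multiplier signs: >= 0 on lower-active rows, <= 0 on upper-active
    ineq <- lo[act] != hi[act]
    at_lo <- ineq & vals <= lo[act] + atol
    at_hi <- ineq & !at_lo
    signs_ok <- all(lam[at_lo] > -1e-6) && all(lam[at_hi] < 1e-6)
    if (feas && stat && signs_ok &&
        sum(w * xp^2) <= sum(w * x^2) + 1e-8 * max(1, sum(w * x^2)))
      return(as.numeric(xp))
  }
  # fall back to the converged iterate if it is feasible to tolerance
  if (max(c(lo - Ax, Ax - hi)) < 1e-8 * scale) return(x)
  NULL
}
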