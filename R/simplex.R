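# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u
# with finite or infinite bounds.  Nonbasic variables sit at one of their
# bounds; Bland's rule (smallest-index entering and leaving candidates)
# guards against cycling.  Intended for the dense, desk-scale systems this
# package works with (tens to a few hundred columns), where an exact,
# dependency-free vertex solver is preferable to an approximate one.
#
# Returns list(status, x, z); status is one of "optimal", "infeasible",
# "unbounded" (with `unbounded_var`, a column index of A), or
# "numerical_failure".

simplex_lp <- function(cc, A, b, lb, ub, maximize = TRUE,
                       tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = NULL, z = NA_real_))
  lb <- pmin(lb, ub)  # collapse inverted-by-roundoff pairs
  if (m == 0L) {
    want <- if (maximize) cc else -cc
    x <- ifelse(want > 0, ub, lb)
    if (any(!is.finite(x) & abs(want) > tol)) {
      j <- which(!is.finite(x) & abs(want) > tol)[1L]
      return(list(status = "unbounded", x = NULL, z = NA_real_, unbounded_var = j))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, z = sum(cc * x)))
  }
  obj <- if (maximize) cc else -cc

  # start structural variables at a finite bound (prefer lower), absorb the
  # residual with one artificial per row
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  resid <- b - as.vector(A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, m))
  lbf <- c(lb, rep(0, m)); ubf <- c(ub, rep(Inf, m))
  nf <- n + m
  state <- list(basis = (n + 1L):nf,
                xf = c(x0, abs(resid)),
                at_upper = c(!is.finite(lb) & is.finite(ub), rep(FALSE, m)))

  run_phase <- function(cvec, state, lock_artificials) {
    basis <- state$basis; xf <- state$xf; at_upper <- state$at_upper
    for (iter in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Binv <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Binv)) return(list(status = "singular"))
      y <- as.vector(crossprod(Binv, cvec[basis]))
      nonbasic <- setdiff(seq_len(nf), basis)
      if (lock_artificials) nonbasic <- nonbasic[nonbasic <= n]
      rc <- cvec[nonbasic] - as.vector(crossprod(Afull[, nonbasic, drop = FALSE], y))
      fixed <- lbf[nonbasic] >= ubf[nonbasic] - 1e-15   # pinned variables never enter
      improving <- ((rc > tol & !at_upper[nonbasic]) |
                    (rc < -tol & at_upper[nonbasic])) & !fixed
      if (!any(improving))
        return(list(status = "optimal", basis = basis, xf = xf, at_upper = at_upper))
      j <- min(nonbasic[improving])                     # Bland
      dir_up <- !at_upper[j]
      d <- as.vector(Binv %*% Afull[, j])
      if (!dir_up) d <- -d                              # so basic update is x_B - t*d
      # ratio test: largest step t >= 0 keeping everything in bounds
      tmax <- if (dir_up) ubf[j] - xf[j] else xf[j] - lbf[j]
      leave <- 0L; leave_to_upper <- FALSE
      lims <- rep(Inf, length(basis)); to_up <- logical(length(basis))
      dec <- d > tol; inc <- d < -tol
      lims[dec] <- (xf[basis][dec] - lbf[basis][dec]) / d[dec]
      has_ub <- inc & is.finite(ubf[basis])
      lims[has_ub] <- (ubf[basis][has_ub] - xf[basis][has_ub]) / (-d[has_ub])
      to_up[has_ub] <- TRUE
      if (any(inc & !is.finite(ubf[basis]))) lims[inc & !is.finite(ubf[basis])] <- Inf
      tbasic <- suppressWarnings(min(lims))
      if (tbasic < tmax) {
        cands <- which(lims <= tbasic + tol * max(1, abs(tbasic)))
        leave <- cands[which.min(basis[cands])]          # Bland on leaving
        leave_to_upper <- to_up[leave]
        tmax <- lims[leave]
      }
      if (!is.finite(tmax))
        return(list(status = "unbounded", unbounded_var = j))
      tmax <- max(tmax, 0)
      xf[basis] <- xf[basis] - tmax * d
      xf[j] <- xf[j] + if (dir_up) tmax else -tmax
      if (leave == 0L) {
        at_upper[j] <- dir_up                            # bound-to-bound move
      } else {
        bi <- basis[leave]
        at_upper[bi] <- leave_to_upper
        xf[bi] <- if (leave_to_upper) ubf[bi] else lbf[bi]   # snap exactly
        basis[leave] <- j
        at_upper[j] <- FALSE
      }
    }
    list(status = "iteration_limit")
  }

  # phase 1: drive artificials to zero
  p1 <- run_phase(c(rep(0, n), rep(-1, m)), state, lock_artificials = FALSE)
  if (identical(p1$status, "unbounded") || !identical(p1$status, "optimal"))
    return(list(status = "numerical_failure", x = NULL, z = NA_real_))
  art <- (n + 1L):nf
  if (sum(p1$xf[art]) > 1e-7 * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL, z = NA_real_))
  ubf[art] <- 0
  p1$xf[art] <- 0

  # phase 2: optimise the real objective; artificials stay pinned at 0
  p2 <- run_phase(c(obj, rep(0, m)),
                  list(basis = p1$basis, xf = p1$xf, at_upper = p1$at_upper),
                  lock_artificials = TRUE)
  if (identical(p2$status, "unbounded"))
    return(list(status = "unbounded", x = NULL, z = NA_real_,
                unbounded_var = if (p2$unbounded_var <= n) p2$unbounded_var else NA_integer_))
  if (!identical(p2$status, "optimal"))
    return(list(status = "numerical_failure", x = NULL, z = NA_real_))
  xs <- p2$xf[seq_len(n)]
  list(status = "optimal", x = xs, z = sum(cc * xs))
}
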