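# Independent oracles used by the test suite. Each re-derives a quantity by
# a route disjoint from the package implementation: the LP oracle is scipy's
# HiGHS solver driven through a batched python call; the QP oracle is an
# ADMM iteration with an exact KKT polish; production rates and similarity
# ratios have literal brute-force loops.

# ---- batched LP oracle (scipy linprog / HiGHS) ----
# cases: list of list(c, A, b, lb, ub, maximize); returns list of
# list(status = "optimal"|"infeasible"|"unbounded", z)
oracle_lp_batch <- function(cases) {
  stopifnot(nzchar(Sys.which("python")))
  inp <- tempfile(fileext = ".json"); outp <- tempfile(fileext = ".json")
  enc <- lapply(cases, function(p) list(
    c = as.numeric(p$c), A = lapply(seq_len(nrow(p$A)), function(i) as.numeric(p$A[i, ])),
    b = as.numeric(p$b), lb = as.numeric(p$lb), ub = as.numeric(p$ub),
    maximize = isTRUE(p$maximize)))
  jsonlite::write_json(enc, inp, digits = NA, auto_unbox = FALSE)
  script <- sprintf("
import json, numpy as np
from scipy.optimize import linprog
cases = json.load(open(%s))
out = []
for d in cases:
    c = np.array(d['c'], float)
    if d['maximize'][0]: c = -c
    A = np.array(d['A'], float)
    lb = np.array(d['lb'], float); ub = np.array(d['ub'], float)
    bounds = [(l if np.isfinite(l) else None, u if np.isfinite(u) else None)
              for l, u in zip(lb, ub)]
    r = linprog(c, A_eq=A, b_eq=np.array(d['b'], float), bounds=bounds,
                method='highs')
    status = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(r.status, 'other')
    z = float(-r.fun) if (r.status == 0 and d['maximize'][0]) else (
        float(r.fun) if r.status == 0 else None)
    out.append({'status': status, 'z': z})
json.dump(out, open(%s, 'w'))
", deparse(inp), deparse(outp))
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outp))
    stop("LP oracle failed: ", paste(res, collapse = "\n"))
  jsonlite::fromJSON(outp, simplifyDataFrame = FALSE)
}

# ---- ADMM + KKT-polish QP oracle ----
# same problem as qp_weighted_norm: min sum w_i x_i^2 s.t. A x = b,
# lb <= x <= ub, G x >= h
oracle_qp_admm <- function(w, A, b, lb, ub, G = NULL, h = NULL,
                           iters = 20000L, rho = 1, sigma = 1e-6) {
  n <- length(w)
  At <- rbind(A, diag(n), if (!is.null(G)) G)
  lo <- c(b, lb, if (!is.null(G)) h)
  hi <- c(b, ub, if (!is.null(G)) rep(Inf, nrow(G)))
  P <- diag(2 * w, n)
  K <- P + sigma * diag(n) + rho * crossprod(At)
  ch <- chol(K)
  x <- rep(0, n); z <- as.vector(At %*% x); y <- rep(0, nrow(At))
  for (it in seq_len(iters)) {
    rhsv <- sigma * x + t(At) %*% (rho * z - y)
    x <- backsolve(ch, forwardsolve(t(ch), rhsv))
    Ax <- as.vector(At %*% x)
    z <- pmin(pmax(Ax + y / rho, lo), hi)
    y <- y + rho * (Ax - z)
  }
  # polish: solve the equality-constrained problem on the active set exactly
  Ax <- as.vector(At %*% x)
  act <- which(Ax <= lo + 1e-6 | Ax >= hi - 1e-6 | lo == hi)
  vals <- ifelse(Ax[act] <= lo[act] + 1e-6, lo[act], hi[act])
  vals[lo[act] == hi[act]] <- lo[act][lo[act] == hi[act]]
  Aact <- At[act, , drop = FALSE]
  W2 <- diag(2 * w + 1e-10, n)
  KKT <- rbind(cbind(W2, t(Aact)),
               cbind(Aact, matrix(0, length(act), length(act))))
  sol <- tryCatch(qr.coef(qr(KKT, LAPACK = TRUE), c(rep(0, n), vals)),
                  error = function(e) NULL)
  if (!is.null(sol)) {
    xp <- sol[seq_len(n)]; xp[is.na(xp)] <- 0
    Axp <- as.vector(At %*% xp)
    if (max(c(lo - Axp, Axp - hi)) < 1e-7 &&
        sum(w * xp^2) <= sum(w * x^2) + 1e-9) x <- xp
  }
  as.numeric(x)
}

# minimize_norm re-derived through the oracle, from a split system
oracle_minimize_norm <- function(system, z_star, exterior_weight = 1e-8) {
  w <- ifelse(system$cols$internal, 1, exterior_weight)
  A <- as.matrix(system$S)
  oracle_qp_admm(w, A, rep(0, nrow(A)), system$cols$lb, system$cols$ub,
                 G = matrix(system$obj, nrow = 1),
                 h = z_star - 1e-9 * max(1, abs(z_star)))
}

# ---- literal production-rate loop over the original reaction matrix ----
brute_production_rate <- function(system, state, base_id) {
  model <- system$model
  mets <- model$metabolites
  rows <- which(mets$base_id == base_id &
                mets$compartment != model$boundary_compartment)
  stopifnot(length(rows) > 0L)
  total <- 0
  for (i in rows) {
    for (rid in model$reactions$id) {
      Nij <- model$stoich[i, rid]
      if (Nij == 0) next
      vf <- unname(state$v[paste0(rid, "_f")])
      vb <- if (paste0(rid, "_b") %in% names(state$v))
        unname(state$v[paste0(rid, "_b")]) else 0
      if (Nij > 0) total <- total + Nij * vf
      if (Nij < 0) total <- total - Nij * vb
    }
  }
  total
}

# ---- brute-force similarity agreement count ----
brute_similarity <- function(pred, ref_signs, policy = "all") {
  mets <- names(ref_signs)
  agree <- 0L; denom <- 0L
  for (m in mets) {
    p <- if (m %in% names(pred)) pred[[m]] else 0L
    r <- ref_signs[[m]]
    if (policy == "defined_only" && (p == 0L || r == 0L)) next
    denom <- denom + 1L
    if (p == r) agree <- agree + 1L
  }
  list(agree = agree, denom = denom, sr = agree / denom)
}

# ---- grid-scan regulation-strength oracle ----
grid_scan_delta <- function(model, system, gene, mode, normal, ranges,
                            step = 0.001) {
  grid <- seq(0, 1, by = step)
  feas <- vapply(grid, function(d) {
    sp <- build_regulation(model, system, gene, mode, d, normal, ranges)
    st <- maximize_objective(system, apply_regulation(system, sp))
    identical(st$status, "optimal")
  }, logical(1))
  max(grid[feas])
}
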