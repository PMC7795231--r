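# Independent oracle for the binary RBF-SVM dual on tiny problems.
#
# Maximise  sum(lambda) - 0.5 * lambda' Q lambda,  Q_ij = y_i y_j K(x_i, x_j)
# s.t.      sum(lambda * y) = 0,  0 <= lambda_i <= C.
#
# With n <= 4 points every active set (each lambda at 0, at C, or free) can
# be enumerated and the free block solved from the KKT system exactly; the
# feasible candidate with the highest objective is the global optimum of
# this concave QP. This never touches the package's solver path.

oracle_rbf <- function(X, Z, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

solve_dual_exact <- function(X, y, C, gamma, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- oracle_rbf(X, X, gamma)
  Q <- (y %o% y) * K
  states <- expand.grid(rep(list(c("lo", "up", "free")), n),
                        stringsAsFactors = FALSE)
  best <- NULL
  for (r in seq_len(nrow(states))) {
    st <- unlist(states[r, ])
    lam <- ifelse(st == "up", C, 0)
    Fr <- which(st == "free")
    nu <- NA_real_
    if (length(Fr) > 0) {
      Fx <- which(st != "free")
      A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], y[Fr]), c(y[Fr], 0))
      fixed_part <- if (length(Fx)) as.numeric(Q[Fr, Fx, drop = FALSE] %*% lam[Fx]) else rep(0, length(Fr))
      rhs <- c(1 - fixed_part, -sum(y[Fx] * lam[Fx]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      lam[Fr] <- sol[seq_along(Fr)]
      nu <- sol[length(sol)]
      if (any(lam[Fr] < -tol) || any(lam[Fr] > C + tol)) next
      lam[Fr] <- pmin(pmax(lam[Fr], 0), C)
    } else {
      if (abs(sum(lam * y)) > tol) next
      # nu must satisfy the bound KKT inequalities; take any feasible value
      grad <- 1 - as.numeric(Q %*% lam)
      lower <- -Inf; upper <- Inf
      for (i in seq_len(n)) {
        # lambda_i = 0: grad_i - nu*y_i <= 0 ; lambda_i = C: >= 0
        if (st[i] == "lo") {
          if (y[i] > 0) lower <- max(lower, grad[i]) else upper <- min(upper, -grad[i])
        } else {
          if (y[i] > 0) upper <- min(upper, grad[i]) else lower <- max(lower, -grad[i])
        }
      }
      if (lower > upper + tol) next
      nu <- if (is.finite(lower) && is.finite(upper)) (lower + upper) / 2
            else if (is.finite(lower)) lower else if (is.finite(upper)) upper else 0
    }
    # verify full KKT for the bound variables under this nu
    grad <- 1 - as.numeric(Q %*% lam)
    ok <- TRUE
    for (i in seq_len(n)) {
      s <- grad[i] - nu * y[i]
      if (st[i] == "lo" && s > tol) ok <- FALSE
      if (st[i] == "up" && s < -tol) ok <- FALSE
      if (st[i] == "free" && abs(s) > 1e-6) ok <- FALSE
    }
    if (!ok || abs(sum(lam * y)) > 1e-6) next
    obj <- sum(lam) - 0.5 * as.numeric(t(lam) %*% Q %*% lam)
    if (is.null(best) || obj > best$objective + 1e-12) {
      best <- list(lambda = lam, nu = nu, objective = obj)
    }
  }
  if (is.null(best)) stop("Exact dual oracle found no feasible KKT point.")
  best
}

# Oracle decision values at probe points: f(z) = sum lambda_i y_i K(x_i,z) + b,
# with b = nu (stationarity of the free variables).
oracle_decision <- function(X, y, C, gamma, probes) {
  sol <- solve_dual_exact(as.matrix(X), y, C, gamma)
  K <- oracle_rbf(as.matrix(X), as.matrix(probes), gamma)
  as.numeric(crossprod(K, sol$lambda * y)) + sol$nu
}
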