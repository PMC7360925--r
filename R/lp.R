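## Bounded-variable two-phase simplex.
##
## Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
## with Bland's anti-cycling rule, which guarantees finite termination on
## the highly degenerate LPs that flux splitting produces. Written in
## plain dense linear algebra: community models here have tens of
## reactions, so a revised simplex with a full re-solve per iteration is
## simple, fast enough, and deterministic.
##
## Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
.simplexBV <- function(cc, A, b, lb, ub, maximize = FALSE,
                       tol = 1e-9, max_iter = 20000L) {
  cmin <- if (maximize) -cc else cc
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cmin) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, value = NA_real_))

  ## start structurals at a finite bound; artificials absorb the residual
  start_at_lb <- is.finite(lb) | !is.finite(ub)
  x0 <- ifelse(start_at_lb, ifelse(is.finite(lb), lb, 0), ub)
  r <- b - as.vector(A %*% x0)
  Aall <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  state <- list(x = c(x0, abs(r)),
                basis = n + seq_len(m),
                status = c(ifelse(start_at_lb, "L", "U"), rep("B", m)))

  run <- function(cost, state, lball, uball) {
    x <- state$x; basis <- state$basis; status <- state$status
    for (it in seq_len(max_iter)) {
      Binv <- tryCatch(solve(Aall[, basis, drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(Binv))
        stop("singular LP basis (numerically degenerate model)")
      nonbasic <- setdiff(seq_along(cost), basis)
      x[basis] <- as.vector(
        Binv %*% (b - Aall[, nonbasic, drop = FALSE] %*% x[nonbasic]))
      y <- as.vector(t(cost[basis]) %*% Binv)
      d <- cost[nonbasic] - as.vector(y %*% Aall[, nonbasic, drop = FALSE])
      improving <- (status[nonbasic] == "L" & d < -tol) |
                   (status[nonbasic] == "U" & d > tol)
      if (!any(improving))
        return(list(x = x, basis = basis, status = status,
                    value = sum(cost * x), ok = TRUE))
      j <- min(nonbasic[improving])                    # Bland: entering
      sgn <- if (status[j] == "L") 1 else -1
      w <- as.vector(Binv %*% Aall[, j])
      tflip <- if (is.finite(uball[j] - lball[j])) uball[j] - lball[j] else Inf
      tk <- rep(Inf, m)
      for (k in seq_len(m)) {
        move <- -sgn * w[k]
        bk <- basis[k]
        if (move < -tol && is.finite(lball[bk]))
          tk[k] <- max(0, (x[bk] - lball[bk]) / (-move))
        else if (move > tol && is.finite(uball[bk]))
          tk[k] <- max(0, (uball[bk] - x[bk]) / move)
      }
      tmax <- min(tk, tflip)
      if (!is.finite(tmax))
        return(list(ok = FALSE))                       # unbounded
      ## Bland: among the blocking constraints pick the basic variable
      ## with the smallest index; a pure bound flip only when no basic
      ## variable blocks at tmax
      blocking <- which(tk <= tmax + tol)
      leave <- if (length(blocking)) blocking[which.min(basis[blocking])]
               else 0L
      x[j] <- x[j] + sgn * tmax
      x[basis] <- x[basis] - sgn * tmax * w
      if (leave == 0L) {
        status[j] <- if (status[j] == "L") "U" else "L"
        x[j] <- if (status[j] == "L") lball[j] else uball[j]
      } else {
        out <- basis[leave]
        at_lb <- -sgn * w[leave] < 0
        status[out] <- if (at_lb) "L" else "U"
        x[out] <- if (at_lb) lball[out] else uball[out]
        status[j] <- "B"
        basis[leave] <- j
      }
    }
    stop("LP iteration limit reached (", max_iter, " iterations)")
  }

  p1 <- run(c(rep(0, n), rep(1, m)), state, lball, uball)
  if (!isTRUE(p1$ok))
    stop("phase-1 LP reported unbounded; this cannot happen")
  if (p1$value > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  uball[n + seq_len(m)] <- 0                           # pin artificials
  p2 <- run(c(cmin, rep(0, m)), p1, lball, uball)
  if (!isTRUE(p2$ok))
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  x <- p2$x[seq_len(n)]
  obj <- sum(cmin * x)
  list(status = "optimal", x = x, value = if (maximize) -obj else obj)
}
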