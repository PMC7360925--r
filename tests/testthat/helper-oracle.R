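# Independent pFBA oracle: exhaustive active-set enumeration.
#
# min sum|v| over {S v = 0, lb <= v <= ub} is attained at a point where
# the active constraints (rows of S, bounds, and the hyperplanes v_j = 0
# bounding the orthants on which |v| is linear) determine v. Enumerate
# every assignment of each reaction to {at lb, at ub, at 0, free}, solve
# the free part from S, keep feasible candidates, and take the minimum
# total flux. Independent of the simplex implementation.
oraclePFBATotalFlux <- function(model, tol = 1e-8) {
  S <- as.matrix(stoichiometricMatrix(model))
  b <- reactionBounds(model)[colnames(S), , drop = FALSE]
  lb <- b[, "lb"]; ub <- b[, "ub"]
  n <- ncol(S)
  states_of <- lapply(seq_len(n), function(j) {
    st <- c("L", "F")
    if (ub[j] != lb[j]) st <- c(st, "U")
    if (lb[j] < 0 && ub[j] > 0) st <- c(st, "Z")
    st
  })
  grid <- expand.grid(states_of, stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- unlist(grid[g, ], use.names = FALSE)
    v <- numeric(n)
    v[st == "L"] <- lb[st == "L"]
    v[st == "U"] <- ub[st == "U"]
    free <- which(st == "F")
    if (length(free)) {
      Sf <- S[, free, drop = FALSE]
      qrS <- qr(Sf)
      if (qrS$rank < length(free)) next        # not a determined point
      rhs <- -S[, -free, drop = FALSE] %*% v[-free]
      sol <- qr.coef(qrS, rhs)
      if (anyNA(sol)) next
      v[free] <- sol
    }
    if (max(abs(S %*% v)) > tol) next          # inconsistent
    if (any(v < lb - tol) || any(v > ub + tol)) next
    best <- min(best, sum(abs(v)))
  }
  best
}
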