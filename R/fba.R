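## Internal LP contract: minimize/maximize obj'x subject to
##   Aeq x = beq,  Ale x <= ble,  lower <= x <= upper.
## Inequality rows become equalities with nonnegative slack variables,
## then everything goes to the bounded-variable simplex in lp.R. All
## structural bounds must be finite (the package uses the +-1000
## mmol/gDW/h convention for unconstrained reactions), which keeps every
## flux LP bounded.
.solveLP <- function(obj, Aeq, beq, lower, upper, maximize = FALSE,
                     Ale = NULL, ble = NULL) {
  n <- length(obj)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("non-finite flux bounds are not supported; use the +-1000 convention")
  A <- as.matrix(Aeq); b <- beq
  cc <- obj; lb <- lower; ub <- upper
  if (!is.null(Ale)) {
    k <- nrow(Ale)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(Ale, diag(1, k)))
    b <- c(b, ble)
    cc <- c(cc, rep(0, k)); lb <- c(lb, rep(0, k)); ub <- c(ub, rep(Inf, k))
  }
  res <- .simplexBV(cc, A, b, lb, ub, maximize = maximize)
  if (res$status == "optimal") res$x <- res$x[seq_len(n)]
  res
}

## model -> LP ingredients with deterministic (sorted) ordering and fixed
## demands pinned lb = ub
.modelLP <- function(model) {
  S <- as.matrix(stoichiometricMatrix(model))
  rxn <- model@reactions
  ord <- match(colnames(S), rxn$id)
  lb <- rxn$lb[ord]; ub <- rxn$ub[ord]
  if (is(model, "CommunityModel") && length(model@fixedDemands)) {
    i <- match(names(model@fixedDemands), colnames(S))
    lb[i] <- ub[i] <- unname(model@fixedDemands)
  }
  list(S = S, lb = lb, ub = ub, rxn_ids = colnames(S),
       met_ids = rownames(S))
}

.asSolution <- function(status, value, v, ids) {
  new("FluxSolution", status = status,
      objectiveValue = if (identical(status, "optimal")) value else NA_real_,
      fluxes = if (identical(status, "optimal")) setNames(v, ids)
               else setNames(numeric(0), character(0)))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear objective c'v subject to steady-state
#' mass balance S v = 0 and flux bounds, with any fixed demands pinned at
#' `lb = ub`. Infeasibility is reported in the solution status, never as a
#' silent zero-flux vector.
#'
#' @param model an [OrganismModel-class] or [CommunityModel-class] with
#'   exchange reactions (i.e. a solvable boundary).
#' @param objective named numeric of reaction weights; defaults to the
#'   model's own objective.
#' @param sense `"max"` or `"min"`.
#' @return a [FluxSolution-class].
#' @seealso [solvePFBA()], [fluxVariability()], [checkBalance()]
#' @export
solveFBA <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  validObject(model)
  lp <- .modelLP(model)
  if (is.null(objective)) objective <- model@objective
  if (!length(objective))
    stop("no objective: supply a named weight vector or use solvePFBA()")
  bad <- setdiff(names(objective), lp$rxn_ids)
  if (length(bad))
    stop("objective references unknown reaction(s): ",
         paste(bad, collapse = ", "))
  cc <- setNames(rep(0, length(lp$rxn_ids)), lp$rxn_ids)
  cc[names(objective)] <- objective
  res <- .solveLP(unname(cc), lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub,
                  maximize = identical(sense, "max"))
  .asSolution(res$status, res$value, res$x, lp$rxn_ids)
}

## split formulation shared by pFBA and FVA: variables (p, q), v = p - q,
## with box bounds capturing lb <= v <= ub exactly
.splitLP <- function(lp, extra_eq = NULL, extra_beq = NULL) {
  n <- length(lp$rxn_ids)
  lower <- c(pmax(lp$lb, 0), pmax(-lp$ub, 0))
  upper <- c(pmax(lp$ub, 0), pmax(-lp$lb, 0))
  Aeq <- cbind(lp$S, -lp$S)
  beq <- rep(0, nrow(lp$S))
  if (!is.null(extra_eq)) {
    Aeq <- rbind(Aeq, cbind(extra_eq, -extra_eq))
    beq <- c(beq, extra_beq)
  }
  list(n = n, lower = lower, upper = upper, Aeq = Aeq, beq = beq)
}

#' Parsimonious FBA
#'
#' Minimizes total absolute flux (via flux splitting, v = p - q with
#' p, q >= 0) subject to mass balance, bounds and fixed demands. When the
#' model declares an objective, that objective is first optimized and then
#' held at its optimum while total flux is minimized, which is the usual
#' pFBA recipe; a community whose host is encoded as fixed demands needs no
#' objective at all. The result is the unique economical flux distribution
#' used for all sweep readouts, and `objectiveValue` is the minimal total
#' flux.
#'
#' @inheritParams solveFBA
#' @return a [FluxSolution-class]; `objectiveValue` is the total absolute
#'   flux at the optimum.
#' @export
solvePFBA <- function(model, objective = NULL) {
  validObject(model)
  lp <- .modelLP(model)
  if (is.null(objective)) objective <- model@objective
  extra_eq <- NULL; extra_beq <- NULL
  if (length(objective)) {
    fba <- solveFBA(model, objective, "max")
    if (fba@status != "optimal")
      return(.asSolution(fba@status, NA_real_, NULL, lp$rxn_ids))
    cc <- setNames(rep(0, length(lp$rxn_ids)), lp$rxn_ids)
    cc[names(objective)] <- objective
    extra_eq <- matrix(unname(cc), nrow = 1)
    extra_beq <- fba@objectiveValue
  }
  sp <- .splitLP(lp, extra_eq, extra_beq)
  res <- .solveLP(rep(1, 2 * sp$n), sp$Aeq, sp$beq, sp$lower, sp$upper,
                  maximize = FALSE)
  if (res$status != "optimal")
    return(.asSolution(res$status, NA_real_, NULL, lp$rxn_ids))
  v <- res$x[seq_len(sp$n)] - res$x[sp$n + seq_len(sp$n)]
  .asSolution("optimal", sum(abs(v)), v, lp$rxn_ids)
}

#' Flux variability analysis under a pFBA envelope
#'
#' For each listed reaction, the minimum and maximum flux compatible with
#' mass balance, bounds, fixed demands and a total-flux budget of
#' `(1 + gamma)` times the pFBA optimum.
#'
#' @inheritParams solveFBA
#' @param reactions reaction ids to scan.
#' @param gamma optimality tolerance fraction (>= 0); `gamma = 0` keeps
#'   total flux at the pFBA minimum.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
fluxVariability <- function(model, reactions, gamma = 0) {
  stopifnot(gamma >= 0)
  validObject(model)
  lp <- .modelLP(model)
  bad <- setdiff(reactions, lp$rxn_ids)
  if (length(bad))
    stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  base <- solvePFBA(model)
  if (base@status != "optimal")
    stop("base problem is ", base@status, "; FVA undefined")
  budget <- (1 + gamma) * base@objectiveValue
  sp <- .splitLP(lp)
  Ale <- matrix(1, nrow = 1, ncol = 2 * sp$n)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_)
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], lp$rxn_ids)
    cc <- rep(0, 2 * sp$n); cc[j] <- 1; cc[sp$n + j] <- -1
    for (sense in c("min", "max")) {
      res <- .solveLP(cc, sp$Aeq, sp$beq, sp$lower, sp$upper,
                      maximize = identical(sense, "max"),
                      Ale = Ale, ble = budget)
      if (res$status != "optimal")
        stop("FVA subproblem ", sense, "(", reactions[k], ") is ", res$status)
      out[[sense]][k] <- res$x[j] - res$x[sp$n + j]
    }
  }
  out
}

#' Mass-balance check of a flux solution
#'
#' Computes S v and reports every metabolite whose net production exceeds
#' `eps` in absolute value. Valid optimal solutions give an empty report.
#'
#' @inheritParams solveFBA
#' @param solution an optimal [FluxSolution-class] for `model`.
#' @param eps componentwise tolerance (mmol/gDW/h), default `1e-6`.
#' @return data.frame with columns `metabolite`, `imbalance` (possibly
#'   zero rows).
#' @export
checkBalance <- function(model, solution, eps = 1e-6) {
  stopifnot(is(solution, "FluxSolution"))
  if (solution@status != "optimal")
    stop("checkBalance() needs an optimal solution (status: ",
         solution@status, ")")
  S <- stoichiometricMatrix(model)
  v <- solution@fluxes[colnames(S)]
  if (anyNA(v))
    stop("solution is missing fluxes for some reactions of the model")
  resid <- as.vector(S %*% v)
  bad <- which(abs(resid) > eps)
  data.frame(metabolite = rownames(S)[bad], imbalance = resid[bad],
             row.names = NULL)
}
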