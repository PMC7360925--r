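#' @import methods
#' @importFrom stats setNames
NULL

REACTION_KINDS <- c("internal", "transport", "exchange", "demand", "biomass")

#' OrganismModel: a compartmentalized stoichiometric metabolic model
#'
#' The unit of model I/O. Holds the metabolites, reactions, flux bounds,
#' stoichiometry and (optional) objective of a single organism. Fluxes are
#' in mmol per gram dry weight per hour throughout.
#'
#' @slot id single organism identifier (e.g. `"Buchnera"`).
#' @slot compartments declared compartment ids.
#' @slot metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula`, `charge`, `transportable`. The `transportable` flag marks
#'   metabolites that may be exchanged with the shared hemolymph pool when
#'   the organism enters a community ([assembleCommunity()]).
#' @slot reactions `data.frame` with columns `id`, `lb`, `ub`, `kind`
#'   (one of internal, transport, exchange, demand, biomass) and
#'   `gene_rule`. A demand reaction with `lb == ub > 0` is a fixed
#'   per-gram demand, pinned at community assembly.
#' @slot stoichiometry named list, one entry per reaction id: a named
#'   numeric vector of signed coefficients (negative = consumed).
#' @slot biomassId optional reaction id of the biomass reaction.
#' @slot objective named numeric of reaction weights (may be empty).
#'
#' @seealso [organismModel()], [readOrganismModel()], [stoichiometricMatrix()]
#' @export
setClass("OrganismModel",
  representation(
    id            = "character",
    compartments  = "character",
    metabolites   = "data.frame",
    reactions     = "data.frame",
    stoichiometry = "list",
    biomassId     = "character",
    objective     = "numeric"
  ),
  prototype(
    biomassId = character(0),
    objective = setNames(numeric(0), character(0))
  )
)

.validOrganismModel <- function(object) {
  msg <- character(0)
  met <- object@metabolites
  rxn <- object@reactions
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "model 'id' must be a single nonempty string")
  need_met <- c("id", "name", "compartment", "formula", "charge", "transportable")
  if (!all(need_met %in% names(met)))
    return(paste("metabolites table must have columns:",
                 paste(need_met, collapse = ", ")))
  need_rxn <- c("id", "lb", "ub", "kind", "gene_rule")
  if (!all(need_rxn %in% names(rxn)))
    return(paste("reactions table must have columns:",
                 paste(need_rxn, collapse = ", ")))
  if (nrow(met) == 0L)
    msg <- c(msg, "model has no metabolites")
  if (nrow(rxn) == 0L)
    msg <- c(msg, "model has no reactions")
  if (anyDuplicated(met$id) || any(!nzchar(met$id)))
    msg <- c(msg, "metabolite ids must be nonempty and unique")
  if (anyDuplicated(rxn$id) || any(!nzchar(rxn$id)))
    msg <- c(msg, "reaction ids must be nonempty and unique")
  bad_cmp <- setdiff(unique(met$compartment), object@compartments)
  if (length(bad_cmp))
    msg <- c(msg, paste0("metabolite compartment(s) not declared: ",
                         paste(bad_cmp, collapse = ", ")))
  if (any(rxn$lb > rxn$ub))
    msg <- c(msg, paste0("lb > ub for reaction(s): ",
                         paste(rxn$id[rxn$lb > rxn$ub], collapse = ", ")))
  if (!all(rxn$kind %in% REACTION_KINDS))
    msg <- c(msg, paste0("unknown reaction kind(s): ",
                         paste(setdiff(rxn$kind, REACTION_KINDS), collapse = ", ")))
  if (!setequal(names(object@stoichiometry), rxn$id))
    msg <- c(msg, "stoichiometry entries must match reaction ids exactly")
  for (rid in intersect(names(object@stoichiometry), rxn$id)) {
    st <- object@stoichiometry[[rid]]
    if (length(st) == 0L) {
      msg <- c(msg, paste0("reaction '", rid, "' has empty stoichiometry"))
      next
    }
    dangling <- setdiff(names(st), met$id)
    if (length(dangling))
      msg <- c(msg, paste0("reaction '", rid,
                           "' references undeclared metabolite(s): ",
                           paste(dangling, collapse = ", ")))
    kind <- rxn$kind[match(rid, rxn$id)]
    if (identical(kind, "exchange") && length(st) != 1L)
      msg <- c(msg, paste0("exchange reaction '", rid,
                           "' must touch exactly one metabolite"))
  }
  if (length(object@biomassId) > 1L)
    msg <- c(msg, "'biomassId' must have length 0 or 1")
  if (length(object@biomassId) == 1L && !object@biomassId %in% rxn$id)
    msg <- c(msg, paste0("biomassId '", object@biomassId,
                         "' is not a reaction id"))
  bad_obj <- setdiff(names(object@objective), rxn$id)
  if (length(bad_obj))
    msg <- c(msg, paste0("objective references unknown reaction(s): ",
                         paste(bad_obj, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("OrganismModel", .validOrganismModel)

#' CommunityModel: host and symbionts coupled through a shared pool
#'
#' An [OrganismModel-class] whose metabolite and reaction ids are tagged
#' with their organism of origin (`met__Organism`), plus bookkeeping for
#' biomass-ratio scaling. All community fluxes are expressed per gram dry
#' weight of the reference organism.
#'
#' @slot organismOf named character: reaction id -> organism id (the shared
#'   pool's exchange reactions belong to `"pool"`).
#' @slot scaling named numeric: organism id -> biomass in grams per gram of
#'   the reference organism; `scaling[reference] == 1`.
#' @slot reference id of the organism normalizing all fluxes.
#' @slot pool compartment id of the shared (hemolymph) pool.
#' @slot fixedDemands named numeric: demand reaction id -> pinned flux on
#'   the community scale (already multiplied by the organism's scaling).
#' @slot medium named numeric: metabolite id -> maximum uptake rate, as
#'   last applied by [applyMedium()].
#'
#' @seealso [assembleCommunity()], [setBiomassRatio()], [solvePFBA()]
#' @export
setClass("CommunityModel",
  contains = "OrganismModel",
  representation(
    organismOf   = "character",
    scaling      = "numeric",
    reference    = "character",
    pool         = "character",
    fixedDemands = "numeric",
    medium       = "numeric"
  )
)

.validCommunityModel <- function(object) {
  msg <- character(0)
  rxn_ids <- object@reactions$id
  if (!setequal(names(object@organismOf), rxn_ids))
    msg <- c(msg, "every reaction must be assigned to exactly one organism or the pool")
  if (length(object@reference) != 1L || !object@reference %in% names(object@scaling))
    msg <- c(msg, "reference organism missing from scaling map")
  else if (!isTRUE(all.equal(unname(object@scaling[object@reference]), 1)))
    msg <- c(msg, "scaling of the reference organism must equal 1")
  if (any(object@scaling <= 0))
    msg <- c(msg, "all biomass scalings must be > 0")
  fd <- names(object@fixedDemands)
  if (length(fd)) {
    kinds <- object@reactions$kind[match(fd, rxn_ids)]
    if (anyNA(kinds) || !all(kinds == "demand"))
      msg <- c(msg, "fixedDemands keys must be demand-kind reactions")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CommunityModel", .validCommunityModel)

#' FluxSolution: a solved flux distribution
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @slot objectiveValue objective at the optimum (`NA` unless optimal).
#' @slot fluxes named numeric, reaction id -> flux
#'   (mmol per gDW of the reference organism per hour).
#'
#' @seealso [solveFBA()], [solvePFBA()], [checkBalance()]
#' @export
setClass("FluxSolution",
  representation(
    status         = "character",
    objectiveValue = "numeric",
    fluxes         = "numeric"
  )
)

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' SweepResult: biomass-ratio sweep of HisD flux and AICAR overflow
#'
#' @slot table `data.frame` with columns `ratio`, `r`, `status`,
#'   `hisd_flux`, `aicar_overflow`, `pct_hisd_increase`, `overflow_fold`,
#'   sorted by `r` ascending; the `r = 0` row is the symbiont-free
#'   baseline.
#' @slot organism id of the swept symbiont.
#' @slot floor numeric floor substituted for a zero baseline overflow when
#'   computing fold changes.
#'
#' @seealso [runRatioSweep()]
#' @export
setClass("SweepResult",
  representation(
    table    = "data.frame",
    organism = "character",
    floor    = "numeric"
  )
)

setValidity("SweepResult", function(object) {
  tab <- object@table
  need <- c("ratio", "r", "status", "hisd_flux", "aicar_overflow",
            "pct_hisd_increase", "overflow_fold")
  if (!all(need %in% names(tab)))
    return(paste("sweep table must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(tab$r))
    return("sweep points must be sorted by r ascending")
  ok <- tab$status == "optimal"
  if (any(tab$aicar_overflow[ok] < 0, na.rm = TRUE))
    return("reported AICAR overflow must be nonnegative")
  TRUE
})

#' IsotopologueTable: peak areas per mass isotopologue
#'
#' Peak areas A0..Ak for the isotopologues M+0..M+k of one compound in one
#' sample, as produced by LC-MS after a 13C labeling experiment.
#'
#' @slot compound compound name (e.g. `"histidine"`).
#' @slot sample sample identifier.
#' @slot group biological group (e.g. an aphid line).
#' @slot fractionKind `"soluble"` or `"protein"`.
#' @slot areas numeric vector of nonnegative peak areas, element `i` being
#'   M+(i-1); at least M+0 and M+1 must be present and at least one area
#'   must be positive.
#'
#' @seealso [isotopologueFractions()], [labelRatio()], [genIsotopologueTables()]
#' @export
setClass("IsotopologueTable",
  representation(
    compound     = "character",
    sample       = "character",
    group        = "character",
    fractionKind = "character",
    areas        = "numeric"
  )
)

setValidity("IsotopologueTable", function(object) {
  msg <- character(0)
  if (length(object@areas) < 2L)
    msg <- c(msg, "need areas for at least M+0 and M+1 (k >= 1)")
  if (any(object@areas < 0) || anyNA(object@areas))
    msg <- c(msg, "areas must be nonnegative and non-missing")
  if (!any(object@areas > 0))
    msg <- c(msg, "at least one area must be positive")
  if (!object@fractionKind %in% c("soluble", "protein"))
    msg <- c(msg, "fractionKind must be 'soluble' or 'protein'")
  if (length(msg)) msg else TRUE
})

#' CommunitySpec: recipe for assembling a community model
#'
#' @slot host the host [OrganismModel-class] (represented by fixed demand
#'   fluxes on the shared pool; scaling 1).
#' @slot symbionts named list of symbiont [OrganismModel-class] objects.
#' @slot ratios named numeric: symbiont id -> biomass in grams per gram of
#'   the reference organism (the reference itself has ratio 1).
#' @slot reference symbiont id normalizing all fluxes (default Buchnera).
#' @slot pool compartment id for the shared hemolymph pool.
#' @slot linkedMets named list: organism id -> metabolite ids exchangeable
#'   with the pool. Empty entries fall back to the organism's
#'   `transportable` flags.
#' @slot medium named numeric: metabolite id -> max uptake rate (>= 0).
#'
#' @seealso [communitySpec()], [assembleCommunity()]
#' @export
setClass("CommunitySpec",
  representation(
    host       = "OrganismModel",
    symbionts  = "list",
    ratios     = "numeric",
    reference  = "character",
    pool       = "character",
    linkedMets = "list",
    medium     = "numeric"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character(0)
  if (!length(object@symbionts))
    msg <- c(msg, "at least one symbiont is required")
  ids <- vapply(object@symbionts, function(m) m@id, character(1))
  if (!identical(unname(names(object@symbionts)), unname(ids)))
    msg <- c(msg, "symbiont list names must equal the organism ids")
  if (!setequal(names(object@ratios), ids))
    msg <- c(msg, "ratios must be named by symbiont id")
  if (any(object@ratios <= 0))
    msg <- c(msg, "all biomass ratios r must be > 0")
  if (!object@reference %in% ids)
    msg <- c(msg, "reference organism not among the symbionts")
  if (any(object@medium < 0))
    msg <- c(msg, "medium uptake rates must be >= 0")
  if (length(msg)) msg else TRUE
})
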