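#' Construct an OrganismModel
#'
#' @param id organism id.
#' @param compartments character vector of compartment ids; defaults to the
#'   compartments used by `metabolites`.
#' @param metabolites data.frame with at least `id` and `compartment`;
#'   missing `name`, `formula`, `charge`, `transportable` columns are
#'   filled with defaults (`name = id`, `NA`, `NA`, `FALSE`).
#' @param reactions data.frame with at least `id`; missing `lb`, `ub`,
#'   `kind`, `gene_rule` are filled with `-1000`, `1000`, `"internal"`,
#'   `NA`.
#' @param stoichiometry named list (reaction id -> named numeric of signed
#'   coefficients, negative = consumed).
#' @param biomassId optional biomass reaction id.
#' @param objective optional named numeric of reaction weights.
#'
#' @return a validated [OrganismModel-class].
#' @examples
#' m <- organismModel(
#'   id = "demo", metabolites = data.frame(id = c("A", "B"), compartment = "c"),
#'   reactions = data.frame(id = c("EX_A", "R1", "DM_B"),
#'                          lb = c(-10, 0, 1), ub = c(0, 1000, 1),
#'                          kind = c("exchange", "internal", "demand")),
#'   stoichiometry = list(EX_A = c(A = -1), R1 = c(A = -1, B = 1),
#'                        DM_B = c(B = -1)))
#' m
#' @export
organismModel <- function(id, metabolites, reactions, stoichiometry,
                          compartments = NULL, biomassId = character(0),
                          objective = numeric(0)) {
  metabolites <- .completeMetabolites(metabolites)
  reactions <- .completeReactions(reactions)
  if (is.null(compartments))
    compartments <- unique(metabolites$compartment)
  stoichiometry <- lapply(stoichiometry, function(st) {
    st <- unlist(st)
    storage.mode(st) <- "double"
    st
  })
  if (length(objective) && is.null(names(objective)))
    stop("'objective' must be a named numeric vector")
  if (!length(objective)) objective <- setNames(numeric(0), character(0))
  new("OrganismModel",
      id = as.character(id), compartments = as.character(compartments),
      metabolites = metabolites, reactions = reactions,
      stoichiometry = stoichiometry,
      biomassId = as.character(biomassId),
      objective = objective)
}

.completeMetabolites <- function(met) {
  met <- as.data.frame(met, stringsAsFactors = FALSE)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$formula)) met$formula <- NA_character_
  if (is.null(met$charge)) met$charge <- NA_integer_
  if (is.null(met$transportable)) met$transportable <- FALSE
  met$id <- as.character(met$id)
  met$name <- as.character(met$name)
  met$compartment <- as.character(met$compartment)
  met$formula <- as.character(met$formula)
  met$charge <- as.integer(met$charge)
  met$transportable <- as.logical(met$transportable)
  rownames(met) <- NULL
  met[c("id", "name", "compartment", "formula", "charge", "transportable")]
}

.completeReactions <- function(rxn) {
  rxn <- as.data.frame(rxn, stringsAsFactors = FALSE)
  if (nrow(rxn) == 0L) stop("model has no reactions")
  if (is.null(rxn$lb)) rxn$lb <- -1000
  if (is.null(rxn$ub)) rxn$ub <- 1000
  if (is.null(rxn$kind)) rxn$kind <- "internal"
  if (is.null(rxn$gene_rule)) rxn$gene_rule <- NA_character_
  rxn$id <- as.character(rxn$id)
  rxn$lb <- as.numeric(rxn$lb)
  rxn$ub <- as.numeric(rxn$ub)
  rxn$kind <- as.character(rxn$kind)
  rxn$gene_rule <- as.character(rxn$gene_rule)
  rownames(rxn) <- NULL
  rxn[c("id", "lb", "ub", "kind", "gene_rule")]
}

#' @describeIn organismModel organism id accessor.
#' @param x,object an [OrganismModel-class].
#' @export
modelId <- function(x) x@id

#' Accessors for OrganismModel components
#'
#' @param x an [OrganismModel-class].
#' @return `metabolites()` and `reactions()` return the respective
#'   data.frames; `stoichiometry()` the named list of coefficient vectors;
#'   `reactionIds()`/`metaboliteIds()` character vectors; `reactionBounds()`
#'   a two-column matrix (`lb`, `ub`) with reaction-id rownames.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))
#' @rdname model-accessors
#' @export
setMethod("metabolites", "OrganismModel", function(x) x@metabolites)

#' @rdname model-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname model-accessors
#' @export
setMethod("reactions", "OrganismModel", function(x) x@reactions)

#' @rdname model-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))
#' @rdname model-accessors
#' @export
setMethod("stoichiometry", "OrganismModel", function(x) x@stoichiometry)

#' @rdname model-accessors
#' @export
reactionIds <- function(x) x@reactions$id

#' @rdname model-accessors
#' @export
metaboliteIds <- function(x) x@metabolites$id

#' @rdname model-accessors
#' @export
reactionBounds <- function(x) {
  b <- cbind(lb = x@reactions$lb, ub = x@reactions$ub)
  rownames(b) <- x@reactions$id
  b
}

setMethod("show", "OrganismModel", function(object) {
  cat("OrganismModel '", object@id, "'\n", sep = "")
  cat("  ", nrow(object@metabolites), " metabolites in ",
      length(object@compartments), " compartment(s): ",
      paste(object@compartments, collapse = ", "), "\n", sep = "")
  kinds <- table(object@reactions$kind)
  cat("  ", nrow(object@reactions), " reactions (",
      paste(names(kinds), unname(kinds), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  if (length(object@objective))
    cat("  objective:", paste(names(object@objective), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CommunityModel", function(object) {
  callNextMethod()
  sc <- object@scaling
  cat("  organisms (g per g ", object@reference, "): ",
      paste(names(sc), signif(sc, 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  shared pool compartment: '", object@pool, "'; ",
      length(object@fixedDemands), " fixed demand(s)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution: status ", object@status, sep = "")
  if (object@status == "optimal")
    cat(", objective ", format(object@objectiveValue), ", ",
        length(object@fluxes), " fluxes", sep = "")
  cat("\n")
  invisible(NULL)
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult: symbiont '", object@organism, "', ",
      nrow(object@table), " point(s) incl. baseline\n", sep = "")
  print(object@table, row.names = FALSE, digits = 6)
  invisible(NULL)
})

setMethod("show", "IsotopologueTable", function(object) {
  cat("IsotopologueTable: ", object@compound, " [", object@fractionKind,
      "], sample ", object@sample, " (group ", object@group, ")\n", sep = "")
  a <- object@areas
  names(a) <- paste0("M+", seq_along(a) - 1L)
  print(a)
  invisible(NULL)
})

#' Solution accessors
#'
#' @param x a [FluxSolution-class].
#' @return `fluxes()` the named flux vector; `solutionStatus()` the solver
#'   status; `objectiveValue()` the objective at the optimum.
#' @name solution-accessors
NULL

#' @rdname solution-accessors
#' @export
fluxes <- function(x) x@fluxes

#' @rdname solution-accessors
#' @export
solutionStatus <- function(x) x@status

#' @rdname solution-accessors
#' @export
objectiveValue <- function(x) x@objectiveValue

#' @rdname runRatioSweep
#' @export
sweepTable <- function(x) x@table
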