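ORG_SEP <- "__"
POOL_ID <- "pool"

.tag <- function(id, org) paste0(id, ORG_SEP, org)

#' Construct a CommunitySpec
#'
#' Recipe for [assembleCommunity()]: the host, a named list of symbionts
#' with their biomass (grams per gram of the reference organism), the
#' shared-pool compartment, the metabolites each organism may exchange with
#' the pool, and the growth medium.
#'
#' @param host host [OrganismModel-class].
#' @param symbionts list of symbiont [OrganismModel-class] objects (named
#'   by organism id, or names are taken from the models).
#' @param ratios named numeric: biomass r (g per g reference) for each
#'   symbiont; the reference must have r = 1.
#' @param reference organism id normalizing all community fluxes
#'   (default `"Buchnera"` if present, otherwise the first symbiont).
#' @param pool shared-pool compartment id.
#' @param linkedMets optional named list (organism id -> metabolite ids)
#'   overriding the default allow-list, which is each organism's
#'   `transportable`-flagged metabolites.
#' @param medium named numeric of max uptake rates (mmol/gDW/h).
#' @return a validated [CommunitySpec-class].
#' @export
communitySpec <- function(host, symbionts, ratios, reference = NULL,
                          pool = POOL_ID, linkedMets = list(),
                          medium = numeric(0)) {
  if (is.null(names(symbionts)))
    names(symbionts) <- vapply(symbionts, function(m) m@id, character(1))
  if (is.null(reference))
    reference <- if ("Buchnera" %in% names(symbionts)) "Buchnera"
                 else names(symbionts)[1]
  ratios <- ratios[names(symbionts)]
  new("CommunitySpec", host = host, symbionts = symbionts,
      ratios = ratios, reference = reference, pool = pool,
      linkedMets = linkedMets, medium = medium)
}

.linkedMetsOf <- function(spec, org, model) {
  lm <- spec@linkedMets[[org]]
  if (is.null(lm)) lm <- model@metabolites$id[model@metabolites$transportable]
  lm
}

#' Assemble a multi-compartment community model
#'
#' Merges the host and symbiont models of a [CommunitySpec-class] into one
#' [CommunityModel-class]. Metabolite, reaction and compartment ids are
#' tagged with an organism suffix (`his__Buchnera`); each linked metabolite
#' gets a reversible pool-transport reaction per organism
#' (`T_<met>__<org>`, positive flux = export into the pool) and a pool
#' exchange reaction (`EX_<met>__pool`, positive flux = export out of the
#' community); the medium is applied to the pool exchanges.
#'
#' Biomass-ratio coupling: all community fluxes are expressed per gram of
#' the reference organism, so the bounds and fixed demands of an organism
#' with biomass r (g per g reference) are multiplied by r. Fixed demands
#' are demand reactions declared with `lb == ub` in the organism files;
#' they stay pinned (`lb = ub = r * per-gram demand`) in the community.
#'
#' @param spec a [CommunitySpec-class].
#' @param checkFeasible solve the assembled community once by [solvePFBA()]
#'   and error if infeasible (default TRUE). (Single organisms are not
#'   required to be feasible in isolation: a host whose demands are met
#'   only by symbiont products never is.)
#' @return a validated [CommunityModel-class].
#' @examples
#' toy <- makeToySymbiosis()
#' cm <- assembleCommunity(toy$spec)
#' cm
#' @export
assembleCommunity <- function(spec, checkFeasible = TRUE) {
  validObject(spec)
  organisms <- c(list(spec@host), spec@symbionts)
  names(organisms)[1] <- spec@host@id
  if (anyDuplicated(names(organisms)))
    stop("duplicate organism ids in community: ",
         paste(names(organisms)[duplicated(names(organisms))], collapse = ", "))
  scaling <- c(1, unname(spec@ratios))
  names(scaling) <- names(organisms)
  scaling[spec@reference] <- 1

  met_list <- list(); rxn_list <- list(); stoich <- list()
  organismOf <- character(0); fixedDemands <- numeric(0)
  pool_mets <- character(0)

  for (org in names(organisms)) {
    m <- organisms[[org]]
    validObject(m)
    r <- scaling[[org]]
    linked <- .linkedMetsOf(spec, org, m)
    missing_lm <- setdiff(linked, m@metabolites$id)
    if (length(missing_lm))
      stop("linked metabolite(s) absent from organism '", org, "': ",
           paste(missing_lm, collapse = ", "))
    met <- m@metabolites
    met$base_id <- met$id
    met$id <- .tag(met$id, org)
    met$compartment <- .tag(met$compartment, org)
    rxn <- m@reactions
    rxn$id <- .tag(rxn$id, org)
    rxn$lb <- rxn$lb * r
    rxn$ub <- rxn$ub * r
    st <- lapply(m@stoichiometry, function(s) setNames(s, .tag(names(s), org)))
    names(st) <- rxn$id
    ## pool transports: met__org <-> met__pool, positive = export to pool
    for (lm in linked) {
      tid <- .tag(paste0("T_", lm), org)
      rxn <- rbind(rxn, data.frame(id = tid, lb = -DEFAULT_BOUND * r,
                                   ub = DEFAULT_BOUND * r, kind = "transport",
                                   gene_rule = NA_character_))
      st[[tid]] <- setNames(c(-1, 1), c(.tag(lm, org), .tag(lm, spec@pool)))
      pool_mets <- union(pool_mets, lm)
    }
    is_fixed <- rxn$kind == "demand" & rxn$lb == rxn$ub & rxn$ub > 0
    fd <- setNames(rxn$ub[is_fixed], rxn$id[is_fixed])
    fixedDemands <- c(fixedDemands, fd)
    organismOf <- c(organismOf, setNames(rep(org, nrow(rxn)), rxn$id))
    met_list[[org]] <- met; rxn_list[[org]] <- rxn
    stoich <- c(stoich, st)
  }

  ## shared pool metabolites and exchange reactions
  if (length(pool_mets)) {
    met_list[[spec@pool]] <- data.frame(
      id = .tag(pool_mets, spec@pool), name = pool_mets,
      compartment = spec@pool, formula = NA_character_,
      charge = NA_integer_, transportable = TRUE, base_id = pool_mets)
    ex <- data.frame(id = .tag(paste0("EX_", pool_mets), spec@pool),
                     lb = 0, ub = DEFAULT_BOUND, kind = "exchange",
                     gene_rule = NA_character_)
    for (i in seq_along(pool_mets))
      stoich[[ex$id[i]]] <- setNames(-1, .tag(pool_mets[i], spec@pool))
    rxn_list[[spec@pool]] <- ex
    organismOf <- c(organismOf, setNames(rep(POOL_ID, nrow(ex)), ex$id))
  }

  met_all <- do.call(rbind, met_list)
  rxn_all <- do.call(rbind, rxn_list)
  if (anyDuplicated(met_all$id))
    stop("metabolite id collision after organism tagging: ",
         paste(unique(met_all$id[duplicated(met_all$id)]), collapse = ", "))
  if (anyDuplicated(rxn_all$id))
    stop("reaction id collision after organism tagging: ",
         paste(unique(rxn_all$id[duplicated(rxn_all$id)]), collapse = ", "))
  met_all$base_id <- NULL
  rownames(met_all) <- rownames(rxn_all) <- NULL

  community <- new("CommunityModel",
                   id = paste0("community:", paste(names(organisms), collapse = "+")),
                   compartments = unique(met_all$compartment),
                   metabolites = met_all, reactions = rxn_all,
                   stoichiometry = stoich,
                   biomassId = character(0),
                   objective = setNames(numeric(0), character(0)),
                   organismOf = organismOf,
                   scaling = setNames(c(unname(scaling), 1),
                                      c(names(scaling), POOL_ID)),
                   reference = spec@reference, pool = spec@pool,
                   fixedDemands = fixedDemands,
                   medium = numeric(0))
  community <- applyMedium(community, spec@medium)
  if (checkFeasible) {
    sol <- solvePFBA(community)
    if (sol@status != "optimal")
      stop("assembled community is ", sol@status, " on the given medium")
  }
  community
}

#' Re-scale one organism's biomass ratio in place
#'
#' Returns a community whose bounds and fixed demands for `organism` are
#' multiplied by `r / r_old`, keeping all fluxes per gram of the reference
#' organism. Setting the current r again is an exact no-op.
#'
#' @param community a [CommunityModel-class].
#' @param organism organism id (must not be the reference, whose scaling is
#'   1 by definition).
#' @param r new biomass in grams per gram of the reference organism (> 0).
#' @return the re-scaled [CommunityModel-class].
#' @seealso [assembleCommunity()], [runRatioSweep()]
#' @export
setBiomassRatio <- function(community, organism, r) {
  stopifnot(is(community, "CommunityModel"))
  if (!organism %in% names(community@scaling))
    stop("unknown organism: '", organism, "'")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop("biomass ratio r must be a single positive number")
  if (organism == community@reference && r != 1)
    stop("the reference organism's scaling is fixed at 1")
  old <- community@scaling[[organism]]
  f <- r / old
  if (f == 1) return(community)
  sel <- names(community@organismOf)[community@organismOf == organism]
  i <- community@reactions$id %in% sel
  community@reactions$lb[i] <- community@reactions$lb[i] * f
  community@reactions$ub[i] <- community@reactions$ub[i] * f
  fd <- intersect(names(community@fixedDemands), sel)
  community@fixedDemands[fd] <- community@fixedDemands[fd] * f
  community@scaling[[organism]] <- r
  validObject(community)
  community
}

#' Apply a growth medium to the pool exchanges
#'
#' Each listed metabolite's pool exchange gets `lb = -rate` (uptake is
#' negative flux); the exchanges of unlisted metabolites get `lb = 0`, i.e.
#' no uptake, with `ub` unchanged so secretion stays possible. A rate of 0
#' therefore blocks uptake but still allows export.
#'
#' @param community a [CommunityModel-class].
#' @param medium named numeric: metabolite id (as in the organism files,
#'   untagged) -> max uptake rate (mmol/gDW/h, >= 0).
#' @return the constrained [CommunityModel-class].
#' @export
applyMedium <- function(community, medium) {
  stopifnot(is(community, "CommunityModel"))
  if (any(medium < 0)) stop("medium uptake rates must be >= 0")
  ex_ids <- names(community@organismOf)[community@organismOf == POOL_ID]
  ex_base <- sub(paste0(ORG_SEP, community@pool, "$"), "",
                 sub("^EX_", "", ex_ids))
  missing_ex <- setdiff(names(medium), ex_base)
  if (length(missing_ex))
    stop("medium metabolite(s) without a pool exchange reaction: ",
         paste(missing_ex, collapse = ", "))
  lb <- setNames(rep(0, length(ex_ids)), ex_ids)
  lb[ex_ids[match(names(medium), ex_base)]] <- -unname(medium)
  i <- match(ex_ids, community@reactions$id)
  community@reactions$lb[i] <- unname(lb)
  community@medium <- medium
  community
}

#' Organisms of a community and their biomass scalings
#'
#' @param x a [CommunityModel-class].
#' @return `organismScaling()` the named scaling vector (g per g
#'   reference); `organismOf()` the reaction -> organism map.
#' @export
organismScaling <- function(x) x@scaling

#' @rdname organismScaling
#' @export
organismOf <- function(x) x@organismOf

#' Read/write a CommunitySpec as a YAML configuration
#'
#' The YAML lists organism model file paths (native JSON), their roles and
#' biomass ratios, the linked metabolites, and a medium TSV path:
#' \preformatted{
#' host: host.json
#' symbionts:
#'   Buchnera:     {path: buchnera.json, r: 1}
#'   Hamiltonella: {path: hamiltonella.json, r: 0.149}
#' reference: Buchnera
#' pool: pool
#' medium: medium.tsv
#' }
#'
#' @param path YAML file path; relative model/medium paths are resolved
#'   against its directory.
#' @return a [CommunitySpec-class].
#' @export
readCommunitySpec <- function(path) {
  if (!file.exists(path)) stop("community spec not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  host <- readOrganismModel(resolve(cfg$host), "native-json")
  symbionts <- lapply(cfg$symbionts, function(s)
    readOrganismModel(resolve(s$path), "native-json"))
  ratios <- vapply(cfg$symbionts, function(s) as.numeric(s$r), numeric(1))
  medium <- if (!is.null(cfg$medium)) readMedium(resolve(cfg$medium))
            else numeric(0)
  linked <- if (!is.null(cfg$linked_mets)) lapply(cfg$linked_mets, unlist)
            else list()
  communitySpec(host = host, symbionts = symbionts, ratios = ratios,
                reference = cfg$reference,
                pool = .jnull(cfg$pool, POOL_ID),
                linkedMets = linked, medium = medium)
}

#' @rdname readCommunitySpec
#' @param spec a [CommunitySpec-class].
#' @param dir directory to write `<organism>.json` files, `medium.tsv` and
#'   `community.yaml` into.
#' @return (write) the path of the written YAML, invisibly.
#' @export
writeCommunitySpec <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  organisms <- c(list(spec@host), spec@symbionts)
  names(organisms)[1] <- spec@host@id
  for (org in names(organisms))
    writeOrganismModel(organisms[[org]], file.path(dir, paste0(org, ".json")),
                       "native-json")
  writeMedium(spec@medium, file.path(dir, "medium.tsv"))
  cfg <- list(
    host = paste0(spec@host@id, ".json"),
    symbionts = setNames(lapply(names(spec@symbionts), function(org)
      list(path = paste0(org, ".json"), r = unname(spec@ratios[[org]]))),
      names(spec@symbionts)),
    reference = spec@reference, pool = spec@pool, medium = "medium.tsv")
  if (length(spec@linkedMets)) cfg$linked_mets <- spec@linkedMets
  out <- file.path(dir, "community.yaml")
  yaml::write_yaml(cfg, out)
  invisible(out)
}
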