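DEFAULT_BOUND <- 1000

#' Read an organism model from disk
#'
#' Supported formats: the package's native JSON, a TSV pair
#' (`<prefix>.metabolites.tsv` + `<prefix>.reactions.tsv`) and read-only
#' SBML Level 3 core import. SBML flux bounds are taken from fbc
#' attributes when present, from `LOWER_BOUND`/`UPPER_BOUND` kinetic-law
#' parameters as fallback, and default to -1000/1000 mmol/gDW/h otherwise
#' (lower bound 0 when the reaction is flagged irreversible). SBML
#' annotations and groups are ignored; ids are preserved verbatim.
#'
#' @param path file path (for `tsv-pair`, the common prefix of the two
#'   files).
#' @param format one of `"native-json"`, `"tsv-pair"`, `"sbml"`.
#' @return a validated [OrganismModel-class].
#' @seealso [writeOrganismModel()]
#' @export
readOrganismModel <- function(path,
                              format = c("native-json", "tsv-pair", "sbml")) {
  format <- match.arg(format)
  switch(format,
         "native-json" = .readModelJSON(path),
         "tsv-pair"    = .readModelTSV(path),
         "sbml"        = .readModelSBML(path))
}

#' Write an organism model to disk
#'
#' Round-trip guarantee: `readOrganismModel(writeOrganismModel(m, p), fmt)`
#' reproduces `m` field-for-field (numeric stoichiometry to full double
#' precision). SBML export is not provided.
#'
#' @param model a validated [OrganismModel-class].
#' @param path output path (for `tsv-pair`, the common prefix).
#' @param format `"native-json"` or `"tsv-pair"`.
#' @return `path`, invisibly.
#' @export
writeOrganismModel <- function(model, path,
                               format = c("native-json", "tsv-pair")) {
  format <- match.arg(format)
  validObject(model)
  switch(format,
         "native-json" = .writeModelJSON(model, path),
         "tsv-pair"    = .writeModelTSV(model, path))
  invisible(path)
}

## ---- native JSON ----

.readModelJSON <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("id", "compartments", "metabolites", "reactions"))
    if (is.null(doc[[field]]))
      stop("native-json model is missing element '", field, "'")
  met <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, name = .jnull(m$name, m$id),
               compartment = m$compartment,
               formula = .jnull(m$formula, NA_character_),
               charge = .jnull(m$charge, NA_integer_),
               transportable = isTRUE(m$transportable),
               stringsAsFactors = FALSE)
  }))
  rxn <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id, lb = .jnull(r$lb, -DEFAULT_BOUND),
               ub = .jnull(r$ub, DEFAULT_BOUND),
               kind = .jnull(r$kind, "internal"),
               gene_rule = .jnull(r$gene_rule, NA_character_),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) unlist(r$stoich))
  names(stoich) <- rxn$id
  obj <- unlist(doc$objective)
  if (is.null(obj)) obj <- setNames(numeric(0), character(0))
  organismModel(id = doc$id, compartments = unlist(doc$compartments),
                metabolites = met, reactions = rxn, stoichiometry = stoich,
                biomassId = as.character(unlist(doc$biomass_id)),
                objective = obj)
}

.jnull <- function(x, default) if (is.null(x) || length(x) == 0L) default else x

.writeModelJSON <- function(model, path) {
  rxns <- lapply(seq_len(nrow(model@reactions)), function(i) {
    r <- model@reactions[i, ]
    list(id = r$id, stoich = as.list(model@stoichiometry[[r$id]]),
         lb = r$lb, ub = r$ub, kind = r$kind,
         gene_rule = if (is.na(r$gene_rule)) NULL else r$gene_rule)
  })
  mets <- lapply(seq_len(nrow(model@metabolites)), function(i) {
    m <- model@metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment,
         formula = if (is.na(m$formula)) NULL else m$formula,
         charge = if (is.na(m$charge)) NULL else m$charge,
         transportable = m$transportable)
  })
  doc <- list(id = model@id,
              compartments = as.list(model@compartments),
              metabolites = mets, reactions = rxns,
              biomass_id = if (length(model@biomassId)) model@biomassId else NULL,
              objective = as.list(model@objective))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

## ---- TSV pair ----

.tsvPaths <- function(prefix)
  c(met = paste0(prefix, ".metabolites.tsv"),
    rxn = paste0(prefix, ".reactions.tsv"))

.writeModelTSV <- function(model, prefix) {
  p <- .tsvPaths(prefix)
  met <- model@metabolites
  header <- c(paste0("#! id=", model@id),
              paste0("#! compartments=", paste(model@compartments, collapse = ",")))
  con <- file(p[["met"]], "w")
  writeLines(header, con)
  utils::write.table(met, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  rxn <- model@reactions
  rxn$stoich <- vapply(model@stoichiometry[rxn$id], .stoichToString, character(1))
  rxn$objective_weight <- unname(model@objective[rxn$id])
  rxn$is_biomass <- rxn$id %in% model@biomassId
  rxn <- rxn[c("id", "stoich", "lb", "ub", "kind", "gene_rule",
               "objective_weight", "is_biomass")]
  utils::write.table(rxn, p[["rxn"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.stoichToString <- function(st)
  paste(sprintf("%s:%.17g", names(st), unname(st)), collapse = ";")

.stoichFromString <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop("malformed stoichiometry string: '", s, "'")
  setNames(as.numeric(vapply(parts, `[`, character(1), 2L)),
           vapply(parts, `[`, character(1), 1L))
}

.readModelTSV <- function(prefix) {
  p <- .tsvPaths(prefix)
  if (!all(file.exists(p)))
    stop("tsv-pair files not found at prefix: ", prefix)
  hdr <- readLines(p[["met"]], n = 2L)
  hdr <- hdr[startsWith(hdr, "#!")]
  meta <- setNames(sub("^#! [a-z]+=", "", hdr),
                   sub("=.*$", "", sub("^#! ", "", hdr)))
  met <- utils::read.delim(p[["met"]], comment.char = "#",
                           stringsAsFactors = FALSE)
  rxn <- utils::read.delim(p[["rxn"]], stringsAsFactors = FALSE)
  stoich <- lapply(rxn$stoich, .stoichFromString)
  names(stoich) <- rxn$id
  obj <- rxn$objective_weight
  names(obj) <- rxn$id
  obj <- obj[!is.na(obj)]
  if (!length(obj)) obj <- setNames(numeric(0), character(0))
  organismModel(id = meta[["id"]],
                compartments = strsplit(meta[["compartments"]], ",")[[1]],
                metabolites = met,
                reactions = rxn[c("id", "lb", "ub", "kind", "gene_rule")],
                stoichiometry = stoich,
                biomassId = rxn$id[isTRUE(rxn$is_biomass) | rxn$is_biomass %in% TRUE],
                objective = obj)
}

## ---- SBML L3 import (read-only) ----

.readModelSBML <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("SBML file has no <model> element")
  comp_nodes <- xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")
  spec_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(spec_nodes)) stop("SBML model declares no species")
  met <- data.frame(
    id = xml2::xml_attr(spec_nodes, "id"),
    name = xml2::xml_attr(spec_nodes, "name"),
    compartment = xml2::xml_attr(spec_nodes, "compartment"),
    formula = xml2::xml_attr(spec_nodes, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(spec_nodes, "charge"))),
    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]
  met$transportable <- FALSE
  ## boundaryCondition species are the implicit outside: dropped from
  ## stoichiometries, as constraint-based tools conventionally do
  boundary <- met$id[xml2::xml_attr(spec_nodes, "boundaryCondition") %in% "true"]
  met <- met[!met$id %in% boundary, , drop = FALSE]
  ## global fbc flux-bound parameters
  par_nodes <- xml2::xml_find_all(mdl, ".//listOfParameters/parameter")
  pars <- setNames(suppressWarnings(as.numeric(xml2::xml_attr(par_nodes, "value"))),
                   xml2::xml_attr(par_nodes, "id"))
  rxn_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  if (!length(rxn_nodes)) stop("SBML model declares no reactions")
  stoich <- vector("list", length(rxn_nodes))
  rxn <- data.frame(id = xml2::xml_attr(rxn_nodes, "id"),
                    lb = NA_real_, ub = NA_real_, kind = "internal",
                    gene_rule = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[i]]
    st <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      co <- .sbmlStoich(ref)
      st[xml2::xml_attr(ref, "species")] <- -co
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(ref, "species")
      prev <- if (sp %in% names(st)) st[[sp]] else 0
      st[sp] <- prev + .sbmlStoich(ref)
    }
    st <- st[!is.na(st) & st != 0]
    st <- st[!names(st) %in% boundary]
    if (!length(st))
      stop("SBML reaction '", rxn$id[i], "' has empty stoichiometry")
    stoich[[i]] <- st
    rev <- !identical(xml2::xml_attr(node, "reversible"), "false")
    lb <- .sbmlBound(node, "lowerFluxBound", "LOWER_BOUND", pars)
    ub <- .sbmlBound(node, "upperFluxBound", "UPPER_BOUND", pars)
    if (is.na(lb)) lb <- if (rev) -DEFAULT_BOUND else 0
    if (is.na(ub)) ub <- DEFAULT_BOUND
    rxn$lb[i] <- lb
    rxn$ub[i] <- ub
    if (length(st) == 1L) rxn$kind[i] <- "exchange"
  }
  names(stoich) <- rxn$id
  ## fbc objective, if declared
  obj_nodes <- xml2::xml_find_all(mdl, ".//listOfFluxObjectives/fluxObjective")
  obj <- setNames(suppressWarnings(as.numeric(xml2::xml_attr(obj_nodes, "coefficient"))),
                  xml2::xml_attr(obj_nodes, "reaction"))
  obj <- obj[!is.na(obj) & names(obj) %in% rxn$id]
  if (!length(obj)) obj <- setNames(numeric(0), character(0))
  organismModel(id = .jnull(xml2::xml_attr(mdl, "id"),
                            tools::file_path_sans_ext(basename(path))),
                compartments = compartments, metabolites = met,
                reactions = rxn, stoichiometry = stoich, objective = obj)
}

.sbmlStoich <- function(ref) {
  v <- suppressWarnings(as.numeric(xml2::xml_attr(ref, "stoichiometry")))
  if (is.na(v)) 1 else v
}

.sbmlBound <- function(node, fbc_attr, kl_name, pars) {
  ref <- xml2::xml_attr(node, fbc_attr)
  if (!is.na(ref) && ref %in% names(pars)) return(pars[[ref]])
  kl <- xml2::xml_find_first(
    node, paste0("./kineticLaw//parameter[@id='", kl_name, "']"))
  if (!inherits(kl, "xml_missing"))
    return(suppressWarnings(as.numeric(xml2::xml_attr(kl, "value"))))
  NA_real_
}

## ---- medium ----

#' Read a growth-medium table
#'
#' Two-column TSV `metabolite<TAB>max_uptake` (mmol/gDW/h, nonnegative),
#' with a header row, emulating the hemolymph growth medium used for
#' community simulations.
#'
#' @param path TSV path.
#' @return named numeric vector of maximum uptake rates.
#' @seealso [applyMedium()]
#' @export
readMedium <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("medium table must have two columns: metabolite, max_uptake")
  rates <- as.numeric(tab[[2]])
  if (any(is.na(rates) | rates < 0))
    stop("medium uptake rates must be nonnegative numbers")
  setNames(rates, as.character(tab[[1]]))
}

#' @rdname readMedium
#' @param medium named numeric of max uptake rates.
#' @export
writeMedium <- function(medium, path) {
  utils::write.table(
    data.frame(metabolite = names(medium), max_uptake = unname(medium)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
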