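#' Parse and format B:H ratio strings
#'
#' Ratio strings are `"a:b"` with decimals allowed, read as Buchnera
#' (reference) : symbiont. The internal scalar is `r = b / a`, the symbiont
#' biomass in grams per gram of reference.
#'
#' @param ratio ratio string(s) such as `"10:1"` or `"1:5"`.
#' @return `parseRatio()`: numeric `r` (symbiont g per g reference).
#' @export
parseRatio <- function(ratio) {
  parts <- strsplit(as.character(ratio), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L) stop("ratio must be of the form 'a:b': ", paste(p, collapse = ":"))
    ab <- as.numeric(p)
    if (anyNA(ab) || any(ab <= 0)) stop("ratio components must be positive numbers")
    ab[2] / ab[1]
  }, numeric(1))
}

#' @rdname parseRatio
#' @param r symbiont biomass in g per g reference.
#' @param digits significant digits for the label.
#' @return `formatRatio()`: normalized label `"x:1"` (r <= 1) or `"1:x"`.
#' @export
formatRatio <- function(r, digits = 2) {
  vapply(r, function(ri) {
    if (ri <= 0) stop("ratio must be positive")
    if (ri <= 1) paste0(format(signif(1 / ri, digits)), ":1")
    else paste0("1:", format(signif(ri, digits)))
  }, character(1))
}

.findReaction <- function(community, id, what) {
  rxn_ids <- community@reactions$id
  if (id %in% rxn_ids) return(id)
  hit <- rxn_ids[startsWith(rxn_ids, paste0(id, ORG_SEP))]
  if (length(hit) == 1L) return(hit)
  stop(what, " reaction '", id, "' not found in the community",
       if (length(hit)) paste0(" (ambiguous: ", paste(hit, collapse = ", "), ")")
       else paste0("; available: ",
                   paste(utils::head(sort(rxn_ids), 8), collapse = ", "), ", ..."))
}

#' HisD flux readout
#'
#' Flux through the terminal histidine-biosynthesis reaction (HisD),
#' the index of total histidine production by the reference symbiont.
#'
#' @param community a [CommunityModel-class].
#' @param solution an optimal [FluxSolution-class] for it.
#' @param reaction HisD reaction id; untagged ids are resolved against the
#'   reference organism's suffix (default `"HisD"`).
#' @return flux in mmol per gDW of the reference organism per hour.
#' @export
hisdFlux <- function(community, solution, reaction = "HisD") {
  stopifnot(is(solution, "FluxSolution"))
  if (solution@status != "optimal")
    stop("solution is not optimal (status: ", solution@status, ")")
  rid <- .findReaction(community, reaction, "HisD")
  unname(solution@fluxes[rid])
}

#' AICAR overflow readout
#'
#' Net flux of AICAR out of the reference (Buchnera) compartment into the
#' shared pool, i.e. the flux of the Buchnera->pool AICAR transport. The
#' reported value is clipped at zero from below; the raw signed flux is
#' attached as attribute `"raw"`.
#'
#' @inheritParams hisdFlux
#' @param metabolite AICAR metabolite id as used in the organism files.
#' @param organism exporting organism (default the community reference).
#' @return nonnegative overflow in mmol per gDW reference per hour, with
#'   attribute `raw`.
#' @export
aicarOverflow <- function(community, solution, metabolite = "aicar",
                          organism = NULL) {
  stopifnot(is(solution, "FluxSolution"))
  if (solution@status != "optimal")
    stop("solution is not optimal (status: ", solution@status, ")")
  if (is.null(organism)) organism <- community@reference
  tid <- .tag(paste0("T_", metabolite), organism)
  if (!tid %in% names(solution@fluxes))
    stop("AICAR transport reaction '", tid, "' absent: no pool transport ",
         "for metabolite '", metabolite, "' in organism '", organism, "'")
  raw <- unname(solution@fluxes[tid])
  structure(max(0, raw), raw = raw)
}

#' Sweep the symbiont biomass ratio
#'
#' The in-silico experiment behind the package: solve the symbiont-free
#' two-compartment baseline, then re-solve the three-compartment community
#' by pFBA at each requested reference:symbiont biomass ratio, recording
#' HisD flux, AICAR overflow, the percent HisD increase over baseline and
#' the overflow fold change. An infeasible ratio is flagged in the
#' `status` column and the sweep continues.
#'
#' @param spec a three-compartment [CommunitySpec-class] containing the
#'   swept symbiont.
#' @param ratios character vector of reference:symbiont ratio strings
#'   (e.g. `c("10:1", "1:5")`); see [parseRatio()]. Defaults to the grid
#'   `10:1, 5:1, 6.7:1, 2:1, 1:1, 1:2, 1:5` covering both printed range
#'   endpoints and the empirically observed 6.7:1 ratio.
#' @param organism id of the swept symbiont; defaults to the one
#'   non-reference symbiont.
#' @param hisdReaction,aicarMetabolite readout configuration, see
#'   [hisdFlux()] and [aicarOverflow()].
#' @param floor numeric floor substituted for a zero baseline overflow in
#'   the fold-change column (default `1e-9`); `Inf` folds are reported as
#'   is when the floor is hit.
#' @return a [SweepResult-class]; the `r = 0` row is the baseline.
#' @examples
#' toy <- makeToySymbiosis()
#' sw <- runRatioSweep(toy$spec, c("10:1", "1:1", "1:5"))
#' sweepTable(sw)
#' @export
runRatioSweep <- function(spec, ratios = c("10:1", "5:1", "6.7:1", "2:1",
                                           "1:1", "1:2", "1:5"),
                          organism = NULL, hisdReaction = "HisD",
                          aicarMetabolite = "aicar", floor = 1e-9) {
  validObject(spec)
  if (is.null(organism)) {
    cand <- setdiff(names(spec@symbionts), spec@reference)
    if (length(cand) != 1L)
      stop("cannot infer the swept symbiont; pass 'organism'")
    organism <- cand
  }
  rs <- parseRatio(ratios)
  ord <- order(rs)
  rs <- rs[ord]; ratios <- ratios[ord]

  ## baseline: the community without the swept symbiont
  base_spec <- communitySpec(
    host = spec@host,
    symbionts = spec@symbionts[setdiff(names(spec@symbionts), organism)],
    ratios = spec@ratios[setdiff(names(spec@ratios), organism)],
    reference = spec@reference, pool = spec@pool,
    linkedMets = spec@linkedMets[setdiff(names(spec@linkedMets), organism)],
    medium = spec@medium)
  base_cm <- assembleCommunity(base_spec, checkFeasible = FALSE)
  base_sol <- solvePFBA(base_cm)
  if (base_sol@status != "optimal")
    stop("baseline (symbiont-free) community is ", base_sol@status)
  base_his <- hisdFlux(base_cm, base_sol, hisdReaction)
  base_ov <- as.numeric(aicarOverflow(base_cm, base_sol, aicarMetabolite))

  cm <- assembleCommunity(spec, checkFeasible = FALSE)
  rows <- lapply(seq_along(rs), function(k) {
    cmk <- setBiomassRatio(cm, organism, rs[k])
    sol <- solvePFBA(cmk)
    if (sol@status != "optimal")
      return(data.frame(ratio = ratios[k], r = rs[k], status = sol@status,
                        hisd_flux = NA_real_, aicar_overflow = NA_real_,
                        pct_hisd_increase = NA_real_, overflow_fold = NA_real_))
    his <- hisdFlux(cmk, sol, hisdReaction)
    ov <- as.numeric(aicarOverflow(cmk, sol, aicarMetabolite))
    data.frame(ratio = ratios[k], r = rs[k], status = "optimal",
               hisd_flux = his, aicar_overflow = ov,
               pct_hisd_increase = 100 * (his - base_his) / base_his,
               overflow_fold = ov / max(base_ov, floor))
  })
  tab <- rbind(
    data.frame(ratio = "baseline", r = 0, status = "optimal",
               hisd_flux = base_his, aicar_overflow = base_ov,
               pct_hisd_increase = 0,
               overflow_fold = base_ov / max(base_ov, floor)),
    do.call(rbind, rows))
  rownames(tab) <- NULL
  new("SweepResult", table = tab, organism = organism, floor = floor)
}

#' @rdname runRatioSweep
#' @param x a [SweepResult-class].
#' @param path output TSV path.
#' @export
writeSweepTSV <- function(x, path) {
  stopifnot(is(x, "SweepResult"))
  tab <- x@table
  tab$overflow_fold <- ifelse(is.finite(tab$overflow_fold),
                              format(tab$overflow_fold, digits = 10),
                              "Inf")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-cell mass factor from a biomass/cell-number ratio pair
#'
#' Calibrates how many grams one reference-organism (Buchnera) cell weighs
#' relative to one symbiont (Hamiltonella) cell, from a matched pair of a
#' biomass ratio and the cell-number ratio it corresponds to:
#' `factor = (cells_H / cells_B) / (mass_H / mass_B)`.
#'
#' @param biomassRatio B:H biomass ratio string (e.g. `"1:5"`).
#' @param cellRatio matched B:H cell-number ratio string (e.g. `"1:130"`).
#' @return the per-cell mass factor (g per Buchnera cell / g per
#'   Hamiltonella cell); e.g. 26 for the pair above.
#' @seealso [cellsToBiomass()]
#' @export
calibratePerCellMass <- function(biomassRatio, cellRatio) {
  parseRatio(cellRatio) / parseRatio(biomassRatio)
}

#' Convert a cell-number ratio to a biomass ratio
#'
#' `biomass B:H = (cells_B * factor) : cells_H`, normalized to `"x:1"` or
#' `"1:x"` with 2 significant figures.
#'
#' @param cellRatio B:H cell-number ratio string.
#' @param factor per-cell mass factor from [calibratePerCellMass()]
#'   (> 0).
#' @return list with `label` (normalized string), `r` (H grams per B
#'   gram) and `factor`.
#' @examples
#' f <- calibratePerCellMass("1:5", "1:130")  # 26
#' cellsToBiomass("1:3.9", f)$label           # "6.7:1"
#' @export
cellsToBiomass <- function(cellRatio, factor) {
  if (!is.numeric(factor) || factor <= 0)
    stop("per-cell mass factor must be positive")
  r_cells <- parseRatio(cellRatio)      # cells_H per cell_B
  r_mass <- r_cells / factor            # g H per g B
  list(label = formatRatio(r_mass), r = r_mass, factor = factor)
}
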