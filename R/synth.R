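#' Parameters of the analytic toy symbiosis
#'
#' The toy collapses the histidine/AICAR coupling into four rates, all in
#' mmol per gDW of Buchnera per hour:
#' \describe{
#'   \item{h_A}{host histidine demand (default 1.0).}
#'   \item{a}{Buchnera AICAR consumption for purine synthesis (default
#'     1.0, so baseline AICAR overflow is exactly zero).}
#'   \item{h_H}{Hamiltonella histidine demand per gram of Hamiltonella
#'     (default 0.0536, calibrated so the empirically observed 6.7:1
#'     Buchnera:Hamiltonella biomass ratio raises HisD flux by 0.8\%).}
#'   \item{b}{Buchnera's own histidine use (default 0).}
#'   \item{uptake}{pool precursor (PRPP) uptake cap (default 10).}
#' }
#'
#' @param h_A,a,h_H,b,uptake see above; all must be nonnegative.
#' @return a named list of class `toyParams`.
#' @seealso [makeToySymbiosis()]
#' @export
toyParams <- function(h_A = 1.0, a = 1.0, h_H = 0.0536, b = 0, uptake = 10) {
  p <- list(h_A = h_A, a = a, h_H = h_H, b = b, uptake = uptake)
  if (any(unlist(p) < 0) || anyNA(unlist(p)))
    stop("all toy parameters must be nonnegative")
  structure(p, class = "toyParams")
}

#' Build the analytic toy symbiosis
#'
#' A minimal aphid/Buchnera/Hamiltonella system with the full
#' histidine-AICAR coupling logic:
#' \itemize{
#'   \item Buchnera: a lumped histidine pathway `HisD` (PRPP -> His +
#'     AICAR, 1:1 co-production), a pinned purine-synthesis demand
#'     consuming AICAR at rate `a`, optionally a pinned own histidine use
#'     `b`; PRPP, His and AICAR are pool-transportable.
#'   \item Hamiltonella: histidine-auxotrophic; only a pinned per-gram
#'     histidine demand `h_H` fed by pool uptake.
#'   \item Host: a pinned histidine drain `h_A` plus free accumulation
#'     sinks for AICAR (the overflow destination) and for histidine (used
#'     only when purine demand forces His production above total demand,
#'     which keeps the model feasible for any parameters).
#' }
#' The returned `expected` functions are the closed-form pFBA solution:
#' `vHis(r) = max(a, h_A + b + r h_H)` and
#' `overflow(r) = max(0, h_A + b + r h_H - a)`, with `r` the Hamiltonella
#' biomass in grams per gram Buchnera.
#'
#' @param params a [toyParams()] list.
#' @param r initial Hamiltonella biomass (g per g Buchnera) encoded in the
#'   returned three-compartment spec (default 1).
#' @return list with elements `host`, `buchnera`, `hamiltonella`
#'   ([OrganismModel-class]s), `spec` (three-compartment
#'   [CommunitySpec-class]), `specTwo` (Hamiltonella-free two-compartment
#'   spec), `expected` (list of functions `vHis(r)`, `overflow(r)`) and
#'   `params`.
#' @examples
#' toy <- makeToySymbiosis()
#' toy$expected$vHis(5)      # 1.268
#' toy$expected$overflow(5)  # 0.268
#' @export
makeToySymbiosis <- function(params = toyParams(), r = 1) {
  stopifnot(inherits(params, "toyParams"))
  B <- 1000
  buch_rxn <- data.frame(
    id = c("HisD", "DM_purine"),
    lb = c(0, params$a), ub = c(B, params$a),
    kind = c("internal", "demand"))
  buch_st <- list(HisD = c(prpp = -1, his = 1, aicar = 1),
                  DM_purine = c(aicar = -1))
  if (params$b > 0) {
    buch_rxn <- rbind(buch_rxn,
                      data.frame(id = "DM_his_self", lb = params$b,
                                 ub = params$b, kind = "demand"))
    buch_st$DM_his_self <- c(his = -1)
  }
  buchnera <- organismModel(
    id = "Buchnera",
    metabolites = data.frame(id = c("prpp", "his", "aicar"),
                             compartment = "c", transportable = TRUE),
    reactions = buch_rxn, stoichiometry = buch_st)

  hamiltonella <- organismModel(
    id = "Hamiltonella",
    metabolites = data.frame(id = "his", compartment = "c",
                             transportable = TRUE),
    reactions = data.frame(id = "DM_his", lb = params$h_H, ub = params$h_H,
                           kind = "demand"),
    stoichiometry = list(DM_his = c(his = -1)))

  host <- organismModel(
    id = "host",
    metabolites = data.frame(id = c("his", "aicar"), compartment = "c",
                             transportable = TRUE),
    reactions = data.frame(
      id = c("DM_his_host", "SINK_aicar", "SINK_his"),
      lb = c(params$h_A, 0, 0), ub = c(params$h_A, B, B),
      kind = "demand"),
    stoichiometry = list(DM_his_host = c(his = -1),
                         SINK_aicar = c(aicar = -1),
                         SINK_his = c(his = -1)))

  medium <- c(prpp = params$uptake)
  spec <- communitySpec(host = host,
                        symbionts = list(Buchnera = buchnera,
                                         Hamiltonella = hamiltonella),
                        ratios = c(Buchnera = 1, Hamiltonella = r),
                        reference = "Buchnera", medium = medium)
  specTwo <- communitySpec(host = host,
                           symbionts = list(Buchnera = buchnera),
                           ratios = c(Buchnera = 1),
                           reference = "Buchnera", medium = medium)
  vHis <- function(r) pmax(params$a, params$h_A + params$b + r * params$h_H)
  overflow <- function(r) pmax(0, params$h_A + params$b + r * params$h_H - params$a)
  list(host = host, buchnera = buchnera, hamiltonella = hamiltonella,
       spec = spec, specTwo = specTwo,
       expected = list(vHis = vHis, overflow = overflow),
       params = params)
}

#' Random feasible single-organism network
#'
#' Builds a connected, mass-balanced chain from an exchanged source
#' metabolite to a pinned terminal demand, plus optional random internal
#' shortcut reactions; feasibility is guaranteed by construction (the
#' chain can always carry the demand). Deterministic per seed.
#'
#' @param seed integer seed.
#' @param nMets number of metabolites (>= 1).
#' @param nRxns number of reactions (>= 1); the first `nMets + 1` build
#'   the exchange + chain + demand backbone, the rest are random
#'   shortcuts.
#' @param demand pinned flux of the terminal demand (default 1); only
#'   present when `nRxns >= 3`.
#' @return an [OrganismModel-class] directly solvable by [solvePFBA()].
#' @export
randomNetwork <- function(seed, nMets, nRxns, demand = 1) {
  stopifnot(nMets >= 1, nRxns >= 1)
  withr::with_seed(seed, {
    mets <- paste0("m", seq_len(nMets))
    rxn <- data.frame(id = "EX_m1", lb = -DEFAULT_BOUND, ub = DEFAULT_BOUND,
                      kind = "exchange")
    st <- list(EX_m1 = c(m1 = -1))
    n_chain <- min(nMets - 1L, max(0L, nRxns - 2L))
    for (i in seq_len(n_chain)) {
      id <- paste0("R", i)
      rxn <- rbind(rxn, data.frame(id = id, lb = 0, ub = DEFAULT_BOUND,
                                   kind = "internal"))
      st[[id]] <- setNames(c(-1, 1), c(mets[i], mets[i + 1]))
    }
    if (nRxns >= 3 || (nRxns == 2 && nMets == 1)) {
      last <- mets[n_chain + 1L]
      rxn <- rbind(rxn, data.frame(id = "DM_sink", lb = demand, ub = demand,
                                   kind = "demand"))
      st$DM_sink <- setNames(-1, last)
    }
    while (nrow(rxn) < nRxns) {
      id <- paste0("X", nrow(rxn))
      pick <- sample(nMets, 2, replace = nMets == 1L)
      rxn <- rbind(rxn, data.frame(id = id, lb = 0, ub = DEFAULT_BOUND,
                                   kind = "internal"))
      st[[id]] <- if (pick[1] == pick[2])
        setNames(-1, mets[pick[1]])  # degenerate self-sink
      else setNames(c(-1, 1), mets[pick])
    }
    rxn <- rxn[seq_len(nRxns), , drop = FALSE]
    st <- st[rxn$id]
    used <- unique(unlist(lapply(st, names)))
    organismModel(id = paste0("rand", seed),
                  metabolites = data.frame(id = mets, compartment = "c",
                                           transportable = FALSE)[
                                             mets %in% used, , drop = FALSE],
                  reactions = rxn, stoichiometry = st)
  })
}

#' Generate synthetic isotopologue peak-area tables
#'
#' Draws peak areas `totalArea * fraction_k * LN(1, cv)` where `LN(1, cv)`
#' is a lognormal with mean 1 and coefficient of variation `cv`
#' (multiplicative noise: areas are positive and right-skewed). With
#' `cv = 0` every table reproduces the true fractions exactly.
#' Deterministic per seed.
#'
#' @param trueFractions numeric vector of isotopologue fractions
#'   M+0..M+k, summing to 1.
#' @param cv noise coefficient of variation (>= 0).
#' @param nSamples number of tables to draw.
#' @param seed integer seed.
#' @param compound,group,fractionKind metadata for the tables.
#' @param totalArea expected total peak area per table.
#' @return list of [IsotopologueTable-class] objects.
#' @export
genIsotopologueTables <- function(trueFractions, cv, nSamples, seed,
                                  compound = "histidine", group = "synthetic",
                                  fractionKind = "soluble",
                                  totalArea = 1e6) {
  if (abs(sum(trueFractions) - 1) > 1e-8 || any(trueFractions < 0))
    stop("trueFractions must be nonnegative and sum to 1")
  stopifnot(cv >= 0, nSamples >= 1)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # lognormal mean 1
  withr::with_seed(seed, {
    lapply(seq_len(nSamples), function(i) {
      noise <- if (cv == 0) rep(1, length(trueFractions))
               else stats::rlnorm(length(trueFractions), meanlog, sdlog)
      new("IsotopologueTable", compound = compound,
          sample = sprintf("%s_s%02d", group, i), group = group,
          fractionKind = fractionKind,
          areas = totalArea * trueFractions * noise)
    })
  })
}

#' Generate a synthetic metabolomics matrix with genotype structure
#'
#' Log-scale abundances: per-feature baseline + genotype random intercept
#' (sd `genotypeSd`, drawn per feature and genotype) + a fixed symbiont
#' status effect + i.i.d. noise. Half of the genotypes are flagged
#' symbiont-positive, mimicking naturally infected vs uninfected lines;
#' status is therefore confounded with genotype identity exactly as in
#' such field collections. Deterministic per seed.
#'
#' @param nFeatures number of metabolite features.
#' @param nGenotypes number of genotypes (>= 2; even values split evenly
#'   into the two status groups).
#' @param nReps replicates per genotype (>= 2).
#' @param genotypeSd sd of the genotype random intercepts.
#' @param statusEffects numeric of length `nFeatures` (recycled) giving
#'   each feature's additive status effect on the log scale.
#' @param noiseSd residual sd.
#' @param seed integer seed.
#' @return list with `matrix` (features x samples) and `design`
#'   (data.frame: `sample`, `genotype`, `status` with levels
#'   `"positive"`/`"negative"`).
#' @seealso [metaboliteScreen()]
#' @export
genMetabolomicsMatrix <- function(nFeatures, nGenotypes, nReps,
                                  genotypeSd, statusEffects, noiseSd, seed) {
  stopifnot(nGenotypes >= 2, nReps >= 2, nFeatures >= 1)
  statusEffects <- rep_len(statusEffects, nFeatures)
  genotypes <- sprintf("G%02d", seq_len(nGenotypes))
  status_of <- ifelse(seq_len(nGenotypes) <= nGenotypes / 2,
                      "positive", "negative")
  design <- data.frame(
    sample = paste0(rep(genotypes, each = nReps), "_r", seq_len(nReps)),
    genotype = rep(genotypes, each = nReps),
    status = rep(status_of, each = nReps),
    stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    baseline <- stats::rnorm(nFeatures, mean = 12, sd = 2)
    geno_int <- matrix(stats::rnorm(nFeatures * nGenotypes, 0, genotypeSd),
                       nFeatures, nGenotypes, dimnames = list(NULL, genotypes))
    noise <- matrix(stats::rnorm(nFeatures * nrow(design), 0, noiseSd),
                    nFeatures, nrow(design))
    mat <- baseline +
      geno_int[, design$genotype, drop = FALSE] +
      outer(statusEffects, as.numeric(design$status == "positive")) +
      noise
    dimnames(mat) <- list(sprintf("feat%04d", seq_len(nFeatures)),
                          design$sample)
    list(matrix = mat, design = design)
  })
}

#' Generate raw per-aphid performance samples
#'
#' Normal draws standing in for the raw replicate values behind printed
#' mean +- SE summaries. Deterministic per seed.
#'
#' @param mean,sd,n normal parameters and sample size (`n >= 2`,
#'   `sd >= 0`).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
genPerformanceSamples <- function(mean, sd, n, seed) {
  stopifnot(n >= 2, sd >= 0)
  withr::with_seed(seed, stats::rnorm(n, mean, sd))
}
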