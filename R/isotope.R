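#' Construct an IsotopologueTable
#'
#' @param compound,sample,group,fractionKind metadata; `fractionKind` is
#'   `"soluble"` or `"protein"`.
#' @param areas numeric vector of nonnegative peak areas for M+0..M+k
#'   (k >= 1, at least one positive).
#' @return an [IsotopologueTable-class].
#' @export
isotopologueTable <- function(areas, compound = "histidine",
                              sample = "s1", group = "g1",
                              fractionKind = "soluble") {
  new("IsotopologueTable", compound = compound, sample = sample,
      group = group, fractionKind = fractionKind,
      areas = as.numeric(areas))
}

#' Isotopologue fractions
#'
#' Relative proportion of each mass isotopologue:
#' `fraction_k = A_k / sum(A)`.
#'
#' @param table an [IsotopologueTable-class].
#' @return numeric vector of fractions, named `M+0..M+k`, summing to 1.
#' @export
isotopologueFractions <- function(table) {
  stopifnot(is(table, "IsotopologueTable"))
  total <- sum(table@areas)
  if (total <= 0) stop("all peak areas are zero; fractions undefined")
  setNames(table@areas / total, paste0("M+", seq_along(table@areas) - 1L))
}

#' 13C/12C label ratio
#'
#' Ratio of labeled to unlabeled compound from isotopologue peak areas.
#' `"all-labeled"` (default) counts every isotopologue with at least one
#' heavy atom: `sum(A_1..A_k) / A_0`; `"m6-only"` counts only the fully
#' labeled M+6 species: `A_6 / A_0` (for a six-carbon compound such as
#' histidine fed as uniformly 13C-labeled tracer). All-labeled is the
#' default because partially labeled isotopologues are routinely abundant;
#' both modes are first-class.
#'
#' @param table an [IsotopologueTable-class] with `A_0 > 0`.
#' @param mode `"all-labeled"` or `"m6-only"`.
#' @return dimensionless ratio (>= 0).
#' @export
labelRatio <- function(table, mode = c("all-labeled", "m6-only")) {
  stopifnot(is(table, "IsotopologueTable"))
  mode <- match.arg(mode)
  a <- table@areas
  if (a[1] <= 0)
    stop("M+0 area is zero: the 13C/12C ratio is infinite; ",
         "use isotopologueFractions() instead")
  if (mode == "all-labeled") sum(a[-1]) / a[1]
  else {
    if (length(a) < 7L)
      stop("m6-only mode needs areas up to M+6 (got M+0..M+",
           length(a) - 1L, ")")
    a[7] / a[1]
  }
}

#' Group summary and two-group test of 13C enrichment
#'
#' Computes the per-sample label ratio for each table, summarizes it per
#' group within each fraction kind (mean, SE, n) and tests the two groups
#' with a pooled t test ([pooledTSummary()]). The design is strictly
#' pairwise: exactly two groups per fraction kind. When both fraction
#' kinds (soluble and protein) are tested, the Bonferroni-adjusted
#' critical probability `alpha / nTests` is reported alongside each p
#' value.
#'
#' @param tables list of [IsotopologueTable-class] objects (>= 2 groups,
#'   >= 2 replicates each).
#' @param mode passed to [labelRatio()].
#' @param alpha nominal significance level before correction
#'   (default 0.05).
#' @param nTests number of tests for the Bonferroni-adjusted critical
#'   probability; defaults to the number of fraction kinds present.
#' @return data.frame with one row per fraction kind: group names, means,
#'   SEs, ns, `t`, `df`, `p`, `alpha_critical`, `significant`.
#' @export
summarizeEnrichment <- function(tables, mode = c("all-labeled", "m6-only"),
                                alpha = 0.05, nTests = NULL) {
  mode <- match.arg(mode)
  meta <- data.frame(
    group = vapply(tables, function(t) t@group, character(1)),
    kind = vapply(tables, function(t) t@fractionKind, character(1)),
    ratio = vapply(tables, labelRatio, numeric(1), mode = mode),
    stringsAsFactors = FALSE)
  kinds <- unique(meta$kind)
  if (is.null(nTests)) nTests <- length(kinds)
  out <- lapply(kinds, function(k) {
    sub <- meta[meta$kind == k, ]
    groups <- sort(unique(sub$group))
    if (length(groups) != 2L)
      stop("pairwise design only: fraction kind '", k, "' has ",
           length(groups), " group(s), need exactly 2")
    gs <- lapply(groups, function(g) {
      x <- sub$ratio[sub$group == g]
      if (length(x) < 2L)
        stop("group '", g, "' has a single replicate; SE undefined")
      groupSummary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
    })
    tt <- pooledTSummary(gs[[1]], gs[[2]])
    data.frame(fraction_kind = k,
               group1 = groups[1], mean1 = gs[[1]]$mean, se1 = gs[[1]]$se,
               n1 = gs[[1]]$n,
               group2 = groups[2], mean2 = gs[[2]]$mean, se2 = gs[[2]]$se,
               n2 = gs[[2]]$n,
               t = tt$statistic, df = tt$df, p = tt$p,
               alpha_critical = alpha / nTests,
               significant = tt$p < alpha / nTests,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read/write isotopologue tables as TSV
#'
#' Columns: `compound, sample, group, fraction_kind, M0..Mk`.
#'
#' @param path TSV path.
#' @return a list of [IsotopologueTable-class] objects.
#' @export
readIsotopologueTables <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  mcols <- grep("^M[0-9]+$", names(tab), value = TRUE)
  if (!length(mcols))
    stop("no isotopologue columns (M0, M1, ...) found in ", path)
  mcols <- mcols[order(as.integer(sub("^M", "", mcols)))]
  lapply(seq_len(nrow(tab)), function(i)
    isotopologueTable(as.numeric(tab[i, mcols]),
                      compound = tab$compound[i], sample = tab$sample[i],
                      group = tab$group[i],
                      fractionKind = tab$fraction_kind[i]))
}

#' @rdname readIsotopologueTables
#' @param tables list of [IsotopologueTable-class] objects (equal k).
#' @export
writeIsotopologueTables <- function(tables, path) {
  k <- unique(vapply(tables, function(t) length(t@areas), integer(1)))
  if (length(k) != 1L)
    stop("all tables must cover the same isotopologue range")
  areas <- do.call(rbind, lapply(tables, function(t) t@areas))
  colnames(areas) <- paste0("M", seq_len(k) - 1L)
  out <- cbind(
    data.frame(compound = vapply(tables, function(t) t@compound, character(1)),
               sample = vapply(tables, function(t) t@sample, character(1)),
               group = vapply(tables, function(t) t@group, character(1)),
               fraction_kind = vapply(tables, function(t) t@fractionKind,
                                      character(1))),
    as.data.frame(areas))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
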