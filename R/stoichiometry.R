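#' Stoichiometric matrix S of a model
#'
#' One row per metabolite, one column per reaction, entries equal to the
#' signed stoichiometric coefficients. Rows and columns are ordered by
#' sorted id so the representation is deterministic.
#'
#' @param model an [OrganismModel-class] (or [CommunityModel-class]).
#' @param sparse return a `Matrix::sparseMatrix` (default) or a dense base
#'   matrix.
#' @return the m x n matrix S with dimnames `(metabolite ids, reaction ids)`.
#' @examples
#' m <- makeToySymbiosis()$buchnera
#' stoichiometricMatrix(m)
#' @export
stoichiometricMatrix <- function(model, sparse = TRUE) {
  validObject(model)
  met_ids <- sort(model@metabolites$id)
  rxn_ids <- sort(model@reactions$id)
  st <- model@stoichiometry
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxn_ids)) {
    s <- st[[rxn_ids[k]]]
    i <- c(i, match(names(s), met_ids))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}
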