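#' Packaged X-H bond-length reference tables
#'
#' Published X-H bond lengths from kinematical refinements against
#' simulated data ("kin", neutron 15 K reference) and dynamical
#' refinements against experimental data ("dyn", neutron 60 K
#' reference), shipped as worked-example inputs for the ME/RMSD
#' machinery.
#'
#' @return Data frame with columns `table`, `bond`, `reference` and one
#'   column per refinement model.
#' @export
xh_reference_tables <- function() {
  path <- system.file("extdata", "xh_reference_tables.csv", package = "aspherED")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' ME / RMSD summary of the packaged X-H tables
#'
#' Recomputes mean error and root-mean-square deviation of each
#' refinement column of [xh_reference_tables()] against its reference
#' column.
#'
#' @return Data frame: table, model, ME, RMSD (Angstrom).
#' @export
xh_table_stats <- function() {
  tab <- xh_reference_tables()
  out <- NULL
  for (tb in unique(tab$table)) {
    sub <- tab[tab$table == tb, ]
    for (model in c("IAM", "TAAM", "molecule_TAAM", "crystal_TAAM")) {
      if (!model %in% names(sub) || anyNA(sub[[model]])) next
      st <- me_rmsd(sub[[model]], sub$reference)
      out <- rbind(out, data.frame(table = tb, model = model,
                                   ME = st$ME, RMSD = st$RMSD))
    }
  }
  out
}
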