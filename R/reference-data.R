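#' Bundled reference measurements for the quercetin/cyclodextrin systems
#'
#' Small plain-text tables of published desk-scale measurements for the
#' QUE/2HP-b-CD and QUE/2,6Me-b-CD inclusion complexes, shipped under
#' `inst/extdata/` and used by the worked examples, the regression tests
#' and the acceptance report:
#'
#' * `ref_t1_table()` -- longitudinal relaxation times (s) of the host
#'   protons before and after complexation, with the printed
#'   percentage-change column.  Multiplet rows given as ranges carry a
#'   `*_hi` bound and are excluded from scalar checks.  The duplicated H2
#'   environment of 2,6Me-b-CD (methylated vs unmethylated glucose units)
#'   is disambiguated as `H2` / `H2b`.
#' * `ref_shift_table_26me()` -- 1H chemical shifts (ppm) of 2,6Me-b-CD
#'   free and complexed, as a [shift_table()], plus the printed
#'   perturbation column in attribute `printed_delta_delta`.
#' * `ref_replica_table()` -- per-replica absolute binding free energies
#'   (kcal/mol) from four independent non-equilibrium alchemical replicas
#'   per system.
#' * `ref_binding_constants()` -- fluorescence-derived association
#'   constants (1/M) and DOSY diffusion coefficients (m^2/s).
#'
#' @return a data.frame (or [shift_table()]); see above
#' @name reference-data
NULL

ref_path <- function(file) {
  system.file("extdata", file, package = "cdbind", mustWork = TRUE)
}

#' @rdname reference-data
#' @export
ref_t1_table <- function() {
  utils::read.csv(ref_path("t1_reference.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference-data
#' @export
ref_shift_table_26me <- function() {
  df <- utils::read.csv(ref_path("shifts_26me.csv"), stringsAsFactors = FALSE)
  st <- shift_table(df$label, df$delta_free, df$delta_complex,
                    delta_free_hi = df$delta_free_hi,
                    delta_complex_hi = df$delta_complex_hi)
  attr(st, "printed_delta_delta") <-
    stats::setNames(df$delta_delta_printed, df$label)
  st
}

#' @rdname reference-data
#' @export
ref_replica_table <- function() {
  utils::read.csv(ref_path("replica_dg.csv"), stringsAsFactors = FALSE)
}

#' @rdname reference-data
#' @export
ref_binding_constants <- function() {
  utils::read.csv(ref_path("binding_reference.csv"), stringsAsFactors = FALSE)
}
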