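#' Thermal and perfusion properties of the modeled tissues
#'
#' Literature-derived constants for the nine lumbar-back tissues used by the
#' bio-heat solver: thermal conductivity `k` (W m^-1 K^-1), density `rho`
#' (kg m^-3), specific heat `c` (J kg^-1 K^-1), blood density `rho_b` and
#' specific heat `c_b`, perfusion rate `w_b` (1/s), blood temperature `T_b`
#' (degrees C, converted once from Kelvin here so the whole package works in
#' Celsius), and metabolic heat rate `Q_m` (W m^-3).
#'
#' Subcutaneous and epidural fat share one property set.  The intervertebral
#' disc and CSF are avascular in this model (`w_b = 0`, `Q_m = 0`), so their
#' perfusion term vanishes.  The heated actuators are represented as boundary
#' conditions, not as meshed solids, and therefore carry no row here.
#'
#' @return A data frame with one row per tissue and columns
#'   `tissue`, `k`, `rho`, `c`, `rho_b`, `c_b`, `w_b`, `T_b`, `Q_m`.
#' @examples
#' property_table()
#' @export
property_table <- function() {
  data.frame(
    tissue = c("skin", "subcutaneous fat", "soft tissue", "muscle",
               "vertebrae", "i.v. disc", "epidural fat", "CSF",
               "spinal cord"),
    k   = c(0.37, 0.21, 0.47, 0.47, 0.32, 0.49, 0.21, 0.57, 0.51),
    rho = c(1100, 1142, 1142, 1142, 1908, 1100, 1142, 1007, 1075),
    c   = c(3391, 2348, 3432, 3432, 1313, 3568, 2348, 4096, 3630),
    rho_b = c(1057, 1057, 1057, 1057, 1057, 0, 1057, 0, 1057),
    c_b   = c(3600, 3600, 3600, 3600, 3600, 0, 3600, 0, 3600),
    w_b   = c(4e-4, 8e-5, 4e-4, 4e-4, 3e-4, 0, 8e-5, 0, 8e-3),
    # 309.7 K and 310 K expressed in Celsius
    T_b = c(36.55, 36.55, 36.55, 36.55, 36.55, 36.55, 36.55, 36.85, 36.55),
    Q_m = c(457, 302, 457, 457, 342, 0, 302, 0, 9121),
    stringsAsFactors = FALSE
  )
}

#' Look up the properties of a single tissue
#'
#' @param tissue Tissue label, e.g. `"muscle"`.
#' @param table Property table, by default [property_table()].
#' @return A one-row list of the tissue's constants.
#' @examples
#' tissue_properties("muscle")$k
#' @export
tissue_properties <- function(tissue, table = property_table()) {
  i <- match(tissue, table$tissue)
  if (is.na(i)) {
    stop("unregistered tissue: '", tissue, "'", call. = FALSE)
  }
  as.list(table[i, , drop = FALSE])
}

# Per-voxel property arrays for an anatomy, as a list of numeric vectors
# aligned with vol$tissues.  Internal.
property_vectors <- function(vol, table = property_table()) {
  i <- match(vol$tissues, table$tissue)
  if (anyNA(i)) {
    stop("unregistered tissue label(s): ",
         paste(vol$tissues[is.na(i)], collapse = ", "), call. = FALSE)
  }
  lapply(table[, c("k", "rho", "c", "rho_b", "c_b", "w_b", "T_b", "Q_m")],
         function(col) col[i])
}
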