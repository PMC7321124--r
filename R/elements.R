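# Bundled per-element tables: van der Waals radii (Bondi-style, Angstrom),
# atomic masses, Pauling electronegativities and polarizabilities used by the
# voxelizer and the descriptor calculator.

.ELEMENT_TABLE <- local({
  tab <- rbind(
    #        vdw   mass     en    polar  valence
    H  = c(1.20,   1.008, 2.20,  0.667, 1),
    B  = c(1.92,  10.811, 2.04,  3.030, 3),
    C  = c(1.70,  12.011, 2.55,  1.760, 4),
    N  = c(1.55,  14.007, 3.04,  1.100, 3),
    O  = c(1.52,  15.999, 3.44,  0.802, 2),
    F  = c(1.47,  18.998, 3.98,  0.557, 1),
    NA_ = c(2.27, 22.990, 0.93, 24.110, 1),
    MG = c(1.73,  24.305, 1.31, 10.600, 2),
    SI = c(2.10,  28.086, 1.90,  5.380, 4),
    P  = c(1.80,  30.974, 2.19,  3.630, 3),
    S  = c(1.80,  32.066, 2.58,  2.900, 2),
    CL = c(1.75,  35.453, 3.16,  2.180, 1),
    K  = c(2.75,  39.098, 0.82, 43.400, 1),
    CA = c(2.31,  40.078, 1.00, 22.800, 2),
    MN = c(2.05,  54.938, 1.55,  9.400, 2),
    FE = c(2.05,  55.845, 1.83,  8.400, 2),
    CO = c(2.00,  58.933, 1.88,  7.500, 2),
    NI = c(1.63,  58.693, 1.91,  6.800, 2),
    CU = c(1.40,  63.546, 1.90,  6.200, 2),
    ZN = c(1.39,  65.380, 1.65,  5.750, 2),
    SE = c(1.90,  78.971, 2.55,  3.770, 2),
    BR = c(1.85,  79.904, 2.96,  3.050, 1),
    I  = c(1.98, 126.904, 2.66,  5.350, 1)
  )
  colnames(tab) <- c("vdw", "mass", "en", "polar", "valence")
  rownames(tab)[rownames(tab) == "NA_"] <- "NA"
  tab
})

.METAL_ELEMENTS <- c("NA", "MG", "K", "CA", "MN", "FE", "CO", "NI", "CU", "ZN")

.DEFAULT_VDW <- 1.8

.normElement <- function(element) {
  e <- toupper(trimws(element))
  e[e == ""] <- "C"
  e
}

#' Van der Waals radius lookup
#'
#' Returns the bundled Bondi-style van der Waals radius for each element
#' symbol; elements absent from the table fall back to 1.8 Angstrom.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdwRadius(c("C", "O", "Zn"))
#' @export
vdwRadius <- function(element) {
  e <- .normElement(element)
  r <- .ELEMENT_TABLE[match(e, rownames(.ELEMENT_TABLE)), "vdw"]
  r[is.na(r)] <- .DEFAULT_VDW
  unname(r)
}

.elementProperty <- function(element, property) {
  e <- .normElement(element)
  v <- .ELEMENT_TABLE[match(e, rownames(.ELEMENT_TABLE)), property]
  # fall back to carbon for unknown organics
  v[is.na(v)] <- .ELEMENT_TABLE["C", property]
  unname(v)
}

.isMetal <- function(element) .normElement(element) %in% .METAL_ELEMENTS
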