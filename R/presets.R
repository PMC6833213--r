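## Published strain parameter sets, usable as verification fixtures and as
## ready-made inputs to the online estimator.

#' E. coli-type maintenance polynomial
#'
#' Quadratic maintenance coefficient for recombinant E. coli BL21(DE3)
#' strains: `beta(X) = 7.2e-5 X^2 - 2.9625e-3 X + 4.27047e-2`.  The parabola
#' has no real root, so the biomass threshold falls back to its stationary
#' point, X_specific = 20.6 g/l (3 s.f.).
#'
#' @return a [MaintenanceModel-class].
#' @export
ecoliMaintenanceModel <- function() {
  maintenanceModel(kBeta2 = 7.2e-5, kBeta1 = -2.9625e-3, kBeta0 = 4.27047e-2,
                   degree = 2L)
}

#' S. cerevisiae-type maintenance line
#'
#' Linear maintenance coefficient for S. cerevisiae:
#' `beta(X) = 2.3851e-3 X - 1.5014e-2`, with root X_specific = 6.29 g/l
#' (3 s.f.).
#'
#' @return a [MaintenanceModel-class].
#' @export
yeastMaintenanceModel <- function() {
  maintenanceModel(kBeta2 = 0, kBeta1 = 2.3851e-3, kBeta0 = -1.5014e-2,
                   degree = 1L)
}

#' Published strain parameter presets
#'
#' Complete stoichiometric parameter sets for the two reference cultures:
#' `"ecoli"` (alpha = 1.01 g O2/g DCW, quadratic maintenance) and `"yeast"`
#' (S. cerevisiae, alpha = 1.35, linear maintenance), both with the default
#' weight coefficient kExp = 0.4.
#'
#' @param strain `"ecoli"` or `"yeast"`.
#' @return a [StrainParameters-class].
#' @examples
#' xSpecific(strainPreset("yeast"))   # 6.29 g/l
#' @export
strainPreset <- function(strain = c("ecoli", "yeast")) {
  strain <- match.arg(strain)
  switch(strain,
    ecoli = strainParameters(alpha = 1.01, maintenance = ecoliMaintenanceModel(),
                             kExp = 0.4, strainLabel = "E. coli BL21(DE3)"),
    yeast = strainParameters(alpha = 1.35, maintenance = yeastMaintenanceModel(),
                             kExp = 0.4, strainLabel = "S. cerevisiae"))
}
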