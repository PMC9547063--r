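#' Rheology parameters
#'
#' @param plasmaViscosity dynamic plasma viscosity, Pa s.  1.2e-3 is the
#'   package default, a conventional value for blood plasma at 37 C.
#' @param singleFileMax um.  At divergent bifurcations whose parent is
#'   wider than this, RBC partitioning follows the empirical
#'   phase-separation equations; in narrower parents RBCs travel in single
#'   file and follow the path of the largest pressure force.
#' @param lawVersion identifier of the empirical coefficient set recorded
#'   in provenance output.
#' @return a \linkS4class{RheologyParams}.
#' @export
rheologyParams <- function(plasmaViscosity = 1.2e-3, singleFileMax = 10,
                           lawVersion = "pries_invitro") {
    new("RheologyParams", plasmaViscosity = plasmaViscosity,
        singleFileMax = singleFileMax, lawVersion = lawVersion)
}

#' Relative effective viscosity of blood in a narrow tube
#'
#' Empirical in vitro law: the apparent viscosity of blood relative to
#' plasma as a function of tube diameter and discharge hematocrit.  It is
#' 1 at zero hematocrit, increases with hematocrit, and as a function of
#' diameter passes through the Fahraeus-Lindqvist minimum near 7-10 um.
#'
#' @param diameter vessel diameter, um (> 0).
#' @param dischargeHematocrit fraction in [0, 1].
#' @param params a \linkS4class{RheologyParams} (coefficients are those of
#'   the recorded \code{lawVersion}).
#' @return dimensionless multiplier >= 1 on the plasma viscosity.
#' @export
relativeViscosity <- function(diameter, dischargeHematocrit,
                              params = rheologyParams()) {
    if (any(diameter <= 0)) stop("diameter must be positive")
    if (any(dischargeHematocrit < 0 | dischargeHematocrit > 1))
        stop("dischargeHematocrit must lie in [0, 1]")
    cpp_murel(as.numeric(diameter), as.numeric(dischargeHematocrit))
}

#' Discharge hematocrit from tube hematocrit (Fahraeus effect)
#'
#' RBCs travel faster than bulk blood, so the instantaneous (tube)
#' hematocrit in a vessel is lower than the hematocrit of the blood
#' discharged from it.  This inverts the empirical Fahraeus relation;
#' the result is clamped to be at least the tube hematocrit.
#'
#' @param tubeHematocrit fraction in [0, 1].
#' @param diameter vessel diameter, um.
#' @return discharge hematocrit in [0, 1], >= \code{tubeHematocrit}.
#' @export
dischargeHematocrit <- function(tubeHematocrit, diameter) {
    if (any(tubeHematocrit < 0 | tubeHematocrit > 1))
        stop("tubeHematocrit must lie in [0, 1]")
    if (any(diameter <= 0)) stop("diameter must be positive")
    cpp_hd_from_ht(as.numeric(tubeHematocrit), as.numeric(diameter))
}

#' Tube hematocrit from discharge hematocrit (forward Fahraeus relation)
#'
#' @param dischargeHematocrit fraction in [0, 1].
#' @param diameter vessel diameter, um.
#' @return tube hematocrit in [0, 1].
#' @export
tubeHematocrit <- function(dischargeHematocrit, diameter) {
    if (any(dischargeHematocrit < 0 | dischargeHematocrit > 1))
        stop("dischargeHematocrit must lie in [0, 1]")
    cpp_ht_from_hd(as.numeric(dischargeHematocrit), as.numeric(diameter))
}

#' RBC flux partitioning at a divergent bifurcation (Zweifach-Fung)
#'
#' Empirical phase-separation law: the daughter vessel receiving the
#' larger fraction of bulk flow receives an even larger fraction of the
#' RBC flux.  Below a flow-fraction cutoff a daughter receives no RBCs at
#' all (so flow steal can fully de-perfuse a branch).  Applies to parents
#' wider than the single-file threshold.
#'
#' @param flowFraction fraction of the parent bulk flow entering the first
#'   daughter (the two daughters' flow fractions sum to 1).
#' @param parentDiameter um.
#' @param daughterDiameters length-2 numeric, um.
#' @param dischargeHematocrit parent discharge hematocrit.
#' @return matrix with columns \code{daughter1}, \code{daughter2}: RBC
#'   flux fractions (each row sums to 1).
#' @export
phaseSeparation <- function(flowFraction, parentDiameter,
                            daughterDiameters = c(parentDiameter,
                                                  parentDiameter) / 2^(1/3),
                            dischargeHematocrit = 0.3) {
    if (any(flowFraction < 0 | flowFraction > 1))
        stop("flowFraction must lie in [0, 1]")
    f1 <- cpp_phase_sep(as.numeric(flowFraction),
                        as.numeric(parentDiameter),
                        as.numeric(daughterDiameters[1]),
                        as.numeric(daughterDiameters[2]),
                        as.numeric(dischargeHematocrit))
    cbind(daughter1 = f1, daughter2 = 1 - f1)
}
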