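#' MicrovascularNetwork: a geometric vascular graph
#'
#' Vessels are edges with a diameter and a length; bifurcations are nodes
#' with 3-D positions in micrometres.  The z coordinate is cortical depth,
#' zero at the pial surface and increasing downward.  Edge tables are
#' undirected; the sign of a solved flow carries direction (positive =
#' \code{node_a} to \code{node_b}).
#'
#' @slot nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z} (um) and \code{is_boundary} (nodes on the simulation-domain
#'   boundary carry pressure boundary conditions).
#' @slot vessels data.frame with columns \code{id}, \code{node_a},
#'   \code{node_b}, \code{diameter} (um), \code{length} (um),
#'   \code{vessel_type} (one of pial_artery, descending_arteriole,
#'   capillary, ascending_venule, pial_vein) and, once
#'   \code{\link{assignBranchOrders}} has run, integer columns
#'   \code{arteriole_order} and \code{venule_order}.
#'
#' @exportClass MicrovascularNetwork
setClass("MicrovascularNetwork",
         representation(nodes = "data.frame", vessels = "data.frame"))

.validNetwork <- function(object) {
    nd <- object@nodes
    vs <- object@vessels
    msg <- character()
    need_n <- c("id", "x", "y", "z", "is_boundary")
    need_v <- c("id", "node_a", "node_b", "diameter", "length", "vessel_type")
    if (!all(need_n %in% names(nd)))
        return(paste("node table misses column(s):",
                     paste(setdiff(need_n, names(nd)), collapse = ", ")))
    if (!all(need_v %in% names(vs)))
        return(paste("vessel table misses column(s):",
                     paste(setdiff(need_v, names(vs)), collapse = ", ")))
    if (anyDuplicated(nd$id))
        msg <- c(msg, "duplicated node ids")
    if (anyDuplicated(vs$id))
        msg <- c(msg, "duplicated vessel ids")
    if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
        msg <- c(msg, "non-finite node positions")
    dangling <- !(vs$node_a %in% nd$id) | !(vs$node_b %in% nd$id)
    if (any(dangling)) {
        i <- which(dangling)[1L]
        bad <- setdiff(c(vs$node_a[i], vs$node_b[i]), nd$id)[1L]
        msg <- c(msg, sprintf("vessel %s references missing node %s",
                              vs$id[i], bad))
    }
    bad_d <- which(!is.finite(vs$diameter) | vs$diameter <= 0)
    if (length(bad_d))
        msg <- c(msg, sprintf("vessel %s has non-positive diameter",
                              vs$id[bad_d[1L]]))
    bad_l <- which(!is.finite(vs$length) | vs$length <= 0)
    if (length(bad_l))
        msg <- c(msg, sprintf("vessel %s has non-positive length",
                              vs$id[bad_l[1L]]))
    loops <- which(vs$node_a == vs$node_b)
    if (length(loops))
        msg <- c(msg, sprintf("vessel %s is a self-loop", vs$id[loops[1L]]))
    if (!all(vs$vessel_type %in% .VESSEL_TYPES))
        msg <- c(msg, paste("unknown vessel_type:",
                            paste(unique(setdiff(vs$vessel_type,
                                                 .VESSEL_TYPES)),
                                  collapse = ", ")))
    if (length(msg)) return(msg)
    # tortuosity >= 1 (small numerical slack)
    ia <- match(vs$node_a, nd$id)
    ib <- match(vs$node_b, nd$id)
    eu <- sqrt((nd$x[ia] - nd$x[ib])^2 + (nd$y[ia] - nd$y[ib])^2 +
               (nd$z[ia] - nd$z[ib])^2)
    short <- which(vs$length < eu * (1 - 1e-8))
    if (length(short))
        msg <- c(msg, sprintf(
            "vessel %s is shorter than the distance between its endpoints",
            vs$id[short[1L]]))
    # connectivity
    if (nrow(vs) > 0) {
        g <- igraph::graph_from_data_frame(
            data.frame(from = as.character(vs$node_a),
                       to = as.character(vs$node_b)),
            directed = FALSE,
            vertices = data.frame(name = as.character(nd$id)))
        if (igraph::components(g)$no > 1L)
            msg <- c(msg, "network is not connected")
    }
    if (length(msg)) msg else TRUE
}

setValidity("MicrovascularNetwork", .validNetwork)

#' FlowState: instantaneous hemodynamic state of a network
#'
#' @slot pressures numeric, mmHg, one per node (network node-table order).
#' @slot flows numeric, um^3/ms, one per vessel; positive means flow from
#'   \code{node_a} to \code{node_b}.
#' @slot tubeHematocrit,dischargeHematocrit numeric per vessel, in [0, 1].
#' @slot rbcFlux numeric per vessel, RBCs per second.
#'
#' @exportClass FlowState
setClass("FlowState",
         representation(pressures = "numeric", flows = "numeric",
                        tubeHematocrit = "numeric",
                        dischargeHematocrit = "numeric",
                        rbcFlux = "numeric"))

setValidity("FlowState", function(object) {
    h <- c(object@tubeHematocrit, object@dischargeHematocrit)
    if (length(h) && (min(h) < -1e-12 || max(h) > 1 + 1e-12))
        return("hematocrits must lie in [0, 1]")
    TRUE
})

#' TimeAveragedFlow: per-vessel flow field averaged over a window
#'
#' The unit of comparison between baseline and dilation scenarios; averaging
#' over the window smooths RBC-induced fluctuations.
#'
#' @slot meanFlow numeric per vessel, um^3/ms (signed, time average).
#' @slot meanRbcFlux numeric per vessel, RBCs/s, counted from tracked cells
#'   leaving the vessel during the window.
#' @slot meanDischargeHematocrit numeric per vessel (time average).
#' @slot window numeric, seconds.
#' @slot diagnostics list: per-vessel flow min/max over the window,
#'   conservation and RBC bookkeeping counters, final \code{FlowState}.
#'
#' @exportClass TimeAveragedFlow
setClass("TimeAveragedFlow",
         representation(meanFlow = "numeric", meanRbcFlux = "numeric",
                        meanDischargeHematocrit = "numeric",
                        window = "numeric", diagnostics = "list"))

setValidity("TimeAveragedFlow", function(object) {
    if (length(object@window) != 1L || object@window <= 0)
        return("window must be a positive scalar (seconds)")
    dg <- object@diagnostics
    if (!is.null(dg$flowMin) && !is.null(dg$flowMax)) {
        tol <- 1e-9 * (1 + max(abs(object@meanFlow)))
        if (any(object@meanFlow < dg$flowMin - tol) ||
            any(object@meanFlow > dg$flowMax + tol))
            return("meanFlow outside the [min, max] instantaneous envelope")
    }
    TRUE
})

#' GeneratorConfig: parameters of the synthetic cortical network generator
#'
#' Defaults emulate the capillary statistics of real cortical networks:
#' capillary diameters 3.04 +/- 0.59 um truncated to [2.17, 4.81] um and a
#' capillary fraction of at least 94 percent of vessels.
#'
#' @slot domainSize numeric length-3, um.
#' @slot targetVesselCount integer.
#' @slot capillaryFractionTarget fraction of vessels that are capillaries.
#' @slot capillaryDiameterMean,capillaryDiameterSd um.
#' @slot capillaryDiameterRange length-2 numeric, um (truncation bounds).
#' @slot meanSegmentLength um, mean capillary segment length.
#' @slot nPenetratingArterioles,nAscendingVenules integer tree counts.
#' @slot seed integer random seed (single named random stream).
#'
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
         representation(domainSize = "numeric",
                        targetVesselCount = "integer",
                        capillaryFractionTarget = "numeric",
                        capillaryDiameterMean = "numeric",
                        capillaryDiameterSd = "numeric",
                        capillaryDiameterRange = "numeric",
                        meanSegmentLength = "numeric",
                        nPenetratingArterioles = "integer",
                        nAscendingVenules = "integer",
                        seed = "integer"))

setValidity("GeneratorConfig", function(object) {
    if (length(object@domainSize) != 3L || any(object@domainSize <= 0))
        return("domainSize must be 3 positive lengths (um)")
    if (object@targetVesselCount < 50L)
        return("targetVesselCount too small to host arteriole/venule trees")
    rng <- object@capillaryDiameterRange
    if (length(rng) != 2L || rng[1] <= 0 || rng[2] <= rng[1])
        return("capillaryDiameterRange must be increasing and positive")
    m <- object@capillaryDiameterMean
    if (m < rng[1] || m > rng[2])
        return("capillaryDiameterMean must lie within the range")
    if (object@capillaryDiameterSd <= 0)
        return("capillaryDiameterSd must be positive")
    if (object@nPenetratingArterioles < 1L || object@nAscendingVenules < 1L)
        return("at least one arteriole and one venule tree required")
    TRUE
})

#' RheologyParams: parameters of the empirical blood rheology laws
#'
#' @slot plasmaViscosity Pa s (package default 1.2e-3).
#' @slot singleFileMax um; at parent diameters above this the empirical
#'   phase-separation equations apply at divergent bifurcations, below it
#'   RBCs travel in single file and follow the largest pressure force.
#' @slot lawVersion identifier of the empirical coefficient set.
#'
#' @exportClass RheologyParams
setClass("RheologyParams",
         representation(plasmaViscosity = "numeric",
                        singleFileMax = "numeric",
                        lawVersion = "character"))

setValidity("RheologyParams", function(object) {
    if (object@plasmaViscosity <= 0) return("plasmaViscosity must be > 0")
    if (object@singleFileMax <= 0) return("singleFileMax must be > 0")
    TRUE
})

#' BoundaryConditions: pressure boundary conditions and inflow hematocrit
#'
#' @slot pressures named numeric, mmHg; names are boundary node ids.  Every
#'   boundary node must have exactly one condition.
#' @slot inflowHematocrit discharge hematocrit of blood entering at inflow
#'   boundaries (default 0.3, kept constant across all simulations).
#'
#' @exportClass BoundaryConditions
setClass("BoundaryConditions",
         representation(pressures = "numeric",
                        inflowHematocrit = "numeric"))

setValidity("BoundaryConditions", function(object) {
    if (is.null(names(object@pressures)) || !length(object@pressures))
        return("pressures must be a non-empty named vector (node ids)")
    if (object@inflowHematocrit < 0 || object@inflowHematocrit > 1)
        return("inflowHematocrit must lie in [0, 1]")
    if (length(unique(object@pressures)) < 2L)
        warning("all boundary pressures identical: no net flow will result")
    TRUE
})

#' SimulationConfig: discrete RBC tracking parameters
#'
#' @slot duration seconds averaged over (default 15.4).
#' @slot timeStep ms (default 0.1).
#' @slot warmup seconds simulated before the averaging window opens
#'   (default: one full duration).
#' @slot couplingInterval steps between pressure re-solves.
#' @slot rbcVolume um^3 per red blood cell (default 55, mouse).
#' @slot hematocritCap maximum tube hematocrit used in the viscosity law.
#' @slot seed integer seed for the single random stream.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(duration = "numeric", timeStep = "numeric",
                        warmup = "numeric", couplingInterval = "integer",
                        rbcVolume = "numeric", hematocritCap = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@duration <= 0) return("duration must be > 0 (seconds)")
    if (object@timeStep <= 0) return("timeStep must be > 0 (ms)")
    if (object@warmup < 0) return("warmup must be >= 0 (seconds)")
    if (object@couplingInterval < 1L)
        return("couplingInterval must be >= 1 step")
    if (object@rbcVolume <= 0) return("rbcVolume must be > 0 (um^3)")
    if (object@hematocritCap <= 0 || object@hematocritCap > 1)
        return("hematocritCap must lie in (0, 1]")
    TRUE
})

#' SelectionCriteria: base-capillary selection rules
#'
#' A base capillary (around which the dilated set is grown) must be a
#' capillary at cortical depth within \code{depthRange}, more than
#' \code{arterioleOrderBeyond} branch orders from the 0th-order descending
#' arteriole main branch, more than \code{venuleOrderBeyond} branches from
#' the ascending venule main branch, at least \code{minBoundaryBranches}
#' branches from the simulation-domain boundary, and closer to the network
#' centre (x-y plane) than \code{maxCenterDistanceFactor} times the mean
#' vessel distance to the centre.
#'
#' @exportClass SelectionCriteria
setClass("SelectionCriteria",
         representation(depthRange = "numeric",
                        arterioleOrderBeyond = "integer",
                        venuleOrderBeyond = "integer",
                        minBoundaryBranches = "integer",
                        maxCenterDistanceFactor = "numeric"))

setValidity("SelectionCriteria", function(object) {
    if (length(object@depthRange) != 2L ||
        object@depthRange[1] >= object@depthRange[2])
        return("depthRange must be an increasing pair (um)")
    if (object@maxCenterDistanceFactor <= 0)
        return("maxCenterDistanceFactor must be positive")
    TRUE
})

#' AblationScenario: one focal dilation experiment
#'
#' @slot baseCapillary vessel id of the base capillary.
#' @slot affectedSet ordered vessel ids of the dilated capillaries
#'   (contains the base; all members are capillaries; at least 13).
#' @slot dilationIncrement um added to every affected diameter (0.6, 1.1
#'   and 1.6 um mimic the mean adult, mean aged and extreme aged responses
#'   to pericyte ablation).
#'
#' @exportClass AblationScenario
setClass("AblationScenario",
         representation(baseCapillary = "integer", affectedSet = "integer",
                        dilationIncrement = "numeric"))

setValidity("AblationScenario", function(object) {
    if (!(object@baseCapillary %in% object@affectedSet))
        return("affectedSet must contain the base capillary")
    if (object@dilationIncrement < 0)
        return("dilationIncrement must be >= 0 (um)")
    TRUE
})

#' FlowChangeReport: per-vessel baseline-vs-scenario comparison
#'
#' @slot table data.frame with one row per vessel: ids, vessel type,
#'   baseline and perturbed time-averaged flow magnitudes, relative flow and
#'   flux changes, neighbor class (dilated/gen1/gen2/other), distance to the
#'   centre of the dilated region and the increase/decrease/unchanged flag
#'   under the 10 percent rule.
#' @slot absThreshold um^3/ms; flow changes below it are set to zero.
#' @slot center numeric length-3, um: centre of the dilated region.
#'
#' @exportClass FlowChangeReport
setClass("FlowChangeReport",
         representation(table = "data.frame", absThreshold = "numeric",
                        center = "numeric"))

#' HeterogeneityReference: expected baseline flow heterogeneity
#'
#' Standard deviations of baseline flow over many affected-set-like groups
#' of capillaries; the median is the reference the dilated-set heterogeneity
#' is compared against.
#'
#' @slot setSds numeric, one SD per sampled capillary set (um^3/ms).
#' @slot reference median of \code{setSds}.
#' @slot quantiles named numeric, the 0.50 and 0.75 quantiles.
#'
#' @exportClass HeterogeneityReference
setClass("HeterogeneityReference",
         representation(setSds = "numeric", reference = "numeric",
                        quantiles = "numeric"))

setValidity("HeterogeneityReference", function(object) {
    if (length(object@setSds) &&
        !isTRUE(all.equal(object@reference,
                          stats::median(object@setSds))))
        return("reference must equal the median of setSds")
    TRUE
})
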