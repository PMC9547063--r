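#' Run the full focal-dilation experiment on a network
#'
#' End-to-end protocol: baseline simulation, base-capillary selection,
#' affected-set construction, one dilation scenario per increment with a
#' repeated simulation (same seed as baseline, so scenario differences
#' are paired), and the downstream analytics: per-vessel flow-change
#' reports, steal records at divergent bifurcations, affected-set
#' heterogeneity against the baseline reference, and the stall census.
#'
#' @param net a \linkS4class{MicrovascularNetwork} (branch orders are
#'   assigned if missing).
#' @param baseCapillary vessel id; when \code{NULL} one candidate is
#'   drawn with \code{\link{sampleBaseCapillaries}} under \code{seed}.
#' @param increments dilation increments, um.
#' @param bc boundary conditions; defaults to
#'   \code{\link{assignDefaultBoundaryPressures}}.
#' @param rheology a \linkS4class{RheologyParams}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param criteria a \linkS4class{SelectionCriteria}.
#' @param nHeterogeneitySets sets for the baseline heterogeneity
#'   reference.
#' @param seed integer seed (simulation stream and candidate draw).
#' @param baseline optional precomputed baseline
#'   \linkS4class{TimeAveragedFlow} for this network/seed, to share one
#'   baseline across several base capillaries.
#' @return list with elements \code{net}, \code{bc}, \code{baseline},
#'   \code{baseCapillary}, \code{scenarios} (one
#'   \linkS4class{AblationScenario} per increment), \code{flows} (named
#'   list: baseline + one per increment), \code{reports} (named list of
#'   \linkS4class{FlowChangeReport}), \code{steal} (named list of
#'   data.frames), \code{heterogeneity} (named numeric),
#'   \code{heterogeneityReference}, and \code{stalls}.
#' @export
runDilationExperiment <- function(net, baseCapillary = NULL,
                                  increments = c(0.6, 1.1, 1.6),
                                  bc = NULL,
                                  rheology = rheologyParams(),
                                  config = simulationConfig(),
                                  criteria = selectionCriteria(),
                                  nHeterogeneitySets = 50L,
                                  seed = 1L,
                                  baseline = NULL) {
    if (!all(c("arteriole_order", "venule_order") %in%
             names(net@vessels)))
        net <- assignBranchOrders(net)
    if (is.null(bc)) bc <- assignDefaultBoundaryPressures(net)
    if (is.null(baseline))
        baseline <- simulateFlow(net, bc, rheology, config, seed = seed)
    if (is.null(baseCapillary)) {
        cand <- selectBaseCapillaries(net, criteria)
        if (!length(cand)) stop("no qualifying base capillaries")
        baseCapillary <- sampleBaseCapillaries(cand, 1L, seed)
    }
    ids <- buildAffectedSet(net, baseCapillary, baseline)
    scenarios <- lapply(increments, function(dd)
        ablationScenario(baseCapillary, ids, dd))
    names(scenarios) <- sprintf("+%.1f", increments)
    flowList <- c(list(baseline = baseline),
                  lapply(scenarios, function(sc)
                      simulateFlow(applyDilation(net, sc), bc, rheology,
                                   config, seed = seed)))
    reports <- lapply(names(scenarios), function(nm)
        flowChangeReport(net, baseline, flowList[[nm]], scenarios[[nm]]))
    names(reports) <- names(scenarios)
    steal <- lapply(names(scenarios), function(nm)
        stealAtDivergentBifurcations(net, baseline, flowList[[nm]], ids))
    names(steal) <- names(scenarios)
    het <- dilationHeterogeneity(flowList, net, ids)
    hetRef <- baselineHeterogeneity(net, baseline, criteria,
                                    nHeterogeneitySets, seed)
    stalls <- stallCensus(net, flowList, ids)
    list(net = net, bc = bc, baseline = baseline,
         baseCapillary = baseCapillary, affectedSet = ids,
         scenarios = scenarios, flows = flowList, reports = reports,
         steal = steal, heterogeneity = het,
         heterogeneityReference = hetRef, stalls = stalls)
}
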