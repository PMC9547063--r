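#' Per-vessel relative flow change between two time-averaged fields
#'
#' Changes are computed on magnitudes of the signed time-averaged flow, so
#' a direction reversal registers as a large change.  To avoid spurious
#' large relative changes in capillaries with low baseline flow, changes
#' whose absolute magnitude difference is below \code{absThreshold} are
#' set to 0.
#'
#' @param baseline,perturbed \linkS4class{TimeAveragedFlow} objects over
#'   the same vessel set.
#' @param absThreshold um^3/ms (default 0.1).
#' @return numeric per vessel: (|q_post| - |q_pre|) / |q_pre|, zeroed
#'   below the absolute threshold.
#' @export
relativeFlowChange <- function(baseline, perturbed, absThreshold = 0.1) {
    qpre <- abs(meanFlow(baseline))
    qpost <- abs(meanFlow(perturbed))
    if (length(qpre) != length(qpost))
        stop("baseline and perturbed flow fields cover different vessels")
    delta <- qpost - qpre
    chg <- ifelse(qpre > 0, delta / qpre, ifelse(qpost > 0, Inf, 0))
    chg[abs(delta) < absThreshold] <- 0
    chg
}

#' Classify vessels by neighbor generation around the dilated set
#'
#' Mutually exclusive classes with precedence dilated > gen1 > gen2:
#' gen1 capillaries share a node with a dilated capillary, gen2
#' capillaries share a node with a gen1 capillary.  Non-capillaries and
#' everything farther away are "other".
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param affectedSet vessel ids of the dilated capillaries.
#' @return factor per vessel with levels dilated, gen1, gen2, other.
#' @export
classifyNeighbors <- function(net, affectedSet) {
    vs <- net@vessels
    idx <- match(affectedSet, vs$id)
    if (anyNA(idx)) stop("affected set references unknown vessel id")
    d <- vesselBranchDistance(net, affectedSet)
    cls <- rep("other", nrow(vs))
    cap <- vs$vessel_type == "capillary"
    cls[!is.na(d) & d == 2L & cap] <- "gen2"
    cls[!is.na(d) & d == 1L & cap] <- "gen1"
    cls[!is.na(d) & d == 0L] <- "dilated"
    factor(cls, levels = c("dilated", "gen1", "gen2", "other"))
}

#' Assemble a per-vessel flow-change report for one scenario
#'
#' @param net baseline \linkS4class{MicrovascularNetwork} (with branch
#'   orders).
#' @param baseline,perturbed \linkS4class{TimeAveragedFlow} fields.
#' @param scenario the \linkS4class{AblationScenario} that produced
#'   \code{perturbed}.
#' @param absThreshold um^3/ms, see \code{\link{relativeFlowChange}}.
#' @return a \linkS4class{FlowChangeReport}.  Vessels are flagged
#'   increased/decreased only when the relative change exceeds 10 percent
#'   (and survives the absolute threshold); everything else is unchanged.
#' @export
flowChangeReport <- function(net, baseline, perturbed, scenario,
                             absThreshold = 0.1) {
    vs <- net@vessels
    chg <- relativeFlowChange(baseline, perturbed, absThreshold)
    fpre <- meanRbcFlux(baseline)
    fpost <- meanRbcFlux(perturbed)
    fchg <- ifelse(fpre > 0, (fpost - fpre) / fpre,
                   ifelse(fpost > 0, Inf, 0))
    dtc <- vesselDistanceToCenter(net, scenario@affectedSet)
    flag <- ifelse(chg > 0.1, "increased",
                   ifelse(chg < -0.1, "decreased", "unchanged"))
    tb <- data.frame(
        vessel = vs$id, vessel_type = vs$vessel_type,
        baseline_flow = abs(meanFlow(baseline)),
        perturbed_flow = abs(meanFlow(perturbed)),
        rel_flow_change = chg, rel_flux_change = fchg,
        neighbor_class = classifyNeighbors(net, scenario@affectedSet),
        distance_to_center = dtc$distance,
        flag = factor(flag, levels = c("increased", "decreased",
                                       "unchanged")))
    new("FlowChangeReport", table = tb, absThreshold = absThreshold,
        center = dtc$center)
}

#' Radial profile of flow changes around the dilated region
#'
#' Vessels with a relative change above 10 percent are grouped into
#' distance-to-centre bins (analysis spheres), separately for increases
#' and decreases; medians and quartiles are reported per bin.
#'
#' @param report a \linkS4class{FlowChangeReport}.
#' @param binWidth um.
#' @return data.frame: bin bounds, direction, vessel count, median and
#'   quartiles of the relative change.
#' @export
distanceProfile <- function(report, binWidth = 50) {
    tb <- report@table
    tb <- tb[tb$flag != "unchanged" & is.finite(tb$rel_flow_change), ]
    if (!nrow(tb))
        return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                          direction = character(), n = integer(),
                          median = numeric(), q25 = numeric(),
                          q75 = numeric()))
    bin <- floor(tb$distance_to_center / binWidth)
    out <- do.call(rbind, lapply(split(tb, list(bin, tb$flag), drop = TRUE),
        function(d) data.frame(
            bin_lo = min(floor(d$distance_to_center / binWidth)) * binWidth,
            bin_hi = (min(floor(d$distance_to_center / binWidth)) + 1) *
                binWidth,
            direction = as.character(d$flag[1]), n = nrow(d),
            median = median(d$rel_flow_change),
            q25 = unname(quantile(d$rel_flow_change, 0.25)),
            q75 = unname(quantile(d$rel_flow_change, 0.75)))))
    rownames(out) <- NULL
    out[order(out$bin_lo, out$direction), ]
}

#' Flow steal at divergent bifurcations with one dilated outflow
#'
#' Finds every bifurcation whose baseline flow field diverges (one
#' inflow, two outflows) with exactly one dilated and one undilated
#' outflow capillary, and reports the relative flow and RBC-flux changes
#' of the undilated branch.  Phase separation amplifies the effect: the
#' undilated branch loses RBC flux at least as strongly as bulk flow.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param baseline,perturbed \linkS4class{TimeAveragedFlow} fields.
#' @param affectedSet vessel ids of the dilated capillaries.
#' @return data.frame, one row per such bifurcation: node id, dilated and
#'   undilated vessel ids, relative flow and flux change of the undilated
#'   branch (no absolute threshold applied).
#' @export
stealAtDivergentBifurcations <- function(net, baseline, perturbed,
                                         affectedSet) {
    vs <- net@vessels
    nd <- net@nodes
    q <- meanFlow(baseline)
    inc <- .incidence(net)
    ia <- match(vs$node_a, nd$id)
    dilated <- vs$id %in% affectedSet
    qpre <- abs(q)
    qpost <- abs(meanFlow(perturbed))
    fpre <- meanRbcFlux(baseline)
    fpost <- meanRbcFlux(perturbed)
    rows <- list()
    for (ni in seq_len(nrow(nd))) {
        ee <- inc[[ni]]
        if (length(ee) < 3L) next
        away <- ifelse(ia[ee] == ni, q[ee] > 0, q[ee] < 0)
        outs <- ee[away & abs(q[ee]) > 1e-14]
        ins <- ee[!away & abs(q[ee]) > 1e-14]
        if (length(outs) != 2L || length(ins) != 1L) next
        isd <- dilated[outs]
        if (sum(isd) != 1L) next
        und <- outs[!isd]
        dil <- outs[isd]
        rows[[length(rows) + 1L]] <- data.frame(
            node = nd$id[ni], dilated_vessel = vs$id[dil],
            undilated_vessel = vs$id[und],
            flow_change = if (qpre[und] > 0)
                (qpost[und] - qpre[und]) / qpre[und] else NA_real_,
            flux_change = if (fpre[und] > 0)
                (fpost[und] - fpre[und]) / fpre[und] else NA_real_)
    }
    if (!length(rows))
        return(data.frame(node = integer(), dilated_vessel = integer(),
                          undilated_vessel = integer(),
                          flow_change = numeric(),
                          flux_change = numeric()))
    do.call(rbind, rows)
}

#' Expected baseline flow heterogeneity from undilated capillary sets
#'
#' For many qualifying base capillaries, an affected-style set is built
#' (without dilating anything) and the standard deviation of baseline
#' time-averaged flow over the set recorded.  The median SD is the
#' reference the heterogeneity of a dilated set is compared against;
#' the 0.50 and 0.75 quantiles are reported alongside.
#'
#' @param net a \linkS4class{MicrovascularNetwork} with branch orders.
#' @param flow baseline \linkS4class{TimeAveragedFlow}.
#' @param criteria a \linkS4class{SelectionCriteria}.
#' @param nSets how many sets to sample from the qualifying candidates
#'   (all of them when fewer qualify).
#' @param seed integer seed for the candidate sample.
#' @return a \linkS4class{HeterogeneityReference}.
#' @export
baselineHeterogeneity <- function(net, flow,
                                  criteria = selectionCriteria(),
                                  nSets = 100L, seed = 1L) {
    cand <- selectBaseCapillaries(net, criteria)
    if (!length(cand)) stop("no qualifying base capillaries")
    if (length(cand) > nSets)
        cand <- sampleBaseCapillaries(cand, nSets, seed)
    q <- abs(meanFlow(flow))
    sds <- vapply(cand, function(b) {
        ids <- tryCatch(buildAffectedSet(net, b, flow),
                        error = function(e) NULL)
        if (is.null(ids)) return(NA_real_)
        sd(q[match(ids, net@vessels$id)])
    }, numeric(1))
    sds <- sds[!is.na(sds)]
    if (!length(sds)) stop("no buildable capillary sets")
    new("HeterogeneityReference", setSds = sds,
        reference = median(sds),
        quantiles = c("0.5" = unname(quantile(sds, 0.5)),
                      "0.75" = unname(quantile(sds, 0.75))))
}

#' Flow heterogeneity of the affected set across dilation scenarios
#'
#' @param flowList named list of \linkS4class{TimeAveragedFlow} fields
#'   (baseline and the dilation scenarios, in order).
#' @param net the baseline network.
#' @param affectedSet vessel ids of the affected capillaries.
#' @return named numeric: SD of time-averaged flow magnitude over the
#'   affected set, one entry per scenario.
#' @export
dilationHeterogeneity <- function(flowList, net, affectedSet) {
    idx <- match(affectedSet, net@vessels$id)
    if (anyNA(idx)) stop("affected set references unknown vessel id")
    vapply(flowList, function(fl) sd(abs(meanFlow(fl))[idx]), numeric(1))
}

#' Census of stalled / low-flow capillaries
#'
#' The stall threshold is the lowest-5-percent quantile (linear
#' interpolation between order statistics) of baseline time-averaged flow
#' magnitudes among vessels in the upper \code{depthLimit} um of cortex
#' (vessel midpoint z).  For every scenario the capillaries below the
#' threshold are counted per neighbor class and within \code{radius} um
#' of the centre of the dilated region.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param flowList named list of \linkS4class{TimeAveragedFlow} fields,
#'   first entry the baseline.
#' @param affectedSet vessel ids of the dilated capillaries.
#' @param depthLimit um (default 200: ablations are only feasible in the
#'   upper cortex, so the reference population is restricted to it).
#' @param radius um (default 200).
#' @param percentile stall quantile of the baseline distribution.
#' @return list: \code{threshold} (um^3/ms) and \code{counts}, a
#'   data.frame of stalled-capillary counts per scenario and class plus
#'   the within-radius count.
#' @export
stallCensus <- function(net, flowList, affectedSet, depthLimit = 200,
                        radius = 200, percentile = 0.05) {
    mid <- .vesselMidpoints(net)
    shallow <- mid[, "z"] <= depthLimit
    if (!any(shallow)) stop("no vessels within the depth range")
    qbase <- abs(meanFlow(flowList[[1]]))
    thr <- unname(quantile(qbase[shallow], percentile))
    cls <- classifyNeighbors(net, affectedSet)
    dtc <- vesselDistanceToCenter(net, affectedSet)$distance
    cap <- net@vessels$vessel_type == "capillary"
    counts <- do.call(rbind, lapply(names(flowList), function(nm) {
        q <- abs(meanFlow(flowList[[nm]]))
        stalled <- q < thr & cap
        data.frame(scenario = nm,
                   dilated = sum(stalled & cls == "dilated"),
                   gen1 = sum(stalled & cls == "gen1"),
                   gen2 = sum(stalled & cls == "gen2"),
                   within_radius = sum(stalled & dtc <= radius),
                   total_shallow = sum(stalled & shallow))
    }))
    list(threshold = thr, counts = counts)
}
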