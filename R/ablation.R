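#' Base-capillary selection criteria
#'
#' @param depthRange cortical depth window for the base capillary
#'   (vessel midpoint z), um.
#' @param arterioleOrderBeyond the base capillary must be beyond this many
#'   branch orders from the 0th-order descending-arteriole main branch
#'   (default: beyond 4, i.e. order >= 5).
#' @param venuleOrderBeyond beyond this many branches from the ascending
#'   venule main branch (default: beyond 1).
#' @param minBoundaryBranches minimum branches between the base capillary
#'   and the simulation-domain boundary.
#' @param maxCenterDistanceFactor the base capillary must be closer to the
#'   network centre in the x-y plane than this factor times the mean
#'   vessel distance to the centre.  Together with the boundary rule this
#'   keeps the dilated region away from the pressure boundary conditions.
#' @return a \linkS4class{SelectionCriteria}.
#' @export
selectionCriteria <- function(depthRange = c(20, 120),
                              arterioleOrderBeyond = 4L,
                              venuleOrderBeyond = 1L,
                              minBoundaryBranches = 2L,
                              maxCenterDistanceFactor = 0.9) {
    new("SelectionCriteria", depthRange = as.numeric(depthRange),
        arterioleOrderBeyond = as.integer(arterioleOrderBeyond),
        venuleOrderBeyond = as.integer(venuleOrderBeyond),
        minBoundaryBranches = as.integer(minBoundaryBranches),
        maxCenterDistanceFactor = maxCenterDistanceFactor)
}

#' Select candidate base capillaries
#'
#' Returns every capillary satisfying all criteria; deterministic and
#' idempotent (no randomness).  An empty result is allowed and reported
#' via an attribute with per-criterion counts.
#'
#' @param net a \linkS4class{MicrovascularNetwork} with branch orders
#'   assigned and boundary nodes flagged.
#' @param criteria a \linkS4class{SelectionCriteria}.
#' @return integer vector of vessel ids (ascending).
#' @export
selectBaseCapillaries <- function(net, criteria = selectionCriteria()) {
    vs <- net@vessels
    if (!all(c("arteriole_order", "venule_order") %in% names(vs)))
        stop("branch orders not assigned; run assignBranchOrders() first")
    mid <- .vesselMidpoints(net)
    bdist <- .boundaryBranchDistance(net)
    xyd <- .xyDistanceToNetworkCenter(net)
    ok_type <- vs$vessel_type == "capillary"
    ok_depth <- mid[, "z"] >= criteria@depthRange[1] &
                mid[, "z"] <= criteria@depthRange[2]
    ok_art <- !is.na(vs$arteriole_order) &
              vs$arteriole_order > criteria@arterioleOrderBeyond
    ok_ven <- !is.na(vs$venule_order) &
              vs$venule_order > criteria@venuleOrderBeyond
    ok_bnd <- !is.na(bdist) & bdist >= criteria@minBoundaryBranches
    ok_ctr <- xyd < criteria@maxCenterDistanceFactor * mean(xyd)
    ok <- ok_type & ok_depth & ok_art & ok_ven & ok_bnd & ok_ctr
    out <- sort(vs$id[ok])
    attr(out, "criterionCounts") <- c(
        capillary = sum(ok_type), depth = sum(ok_type & ok_depth),
        arteriole_order = sum(ok_type & ok_depth & ok_art),
        venule_order = sum(ok_type & ok_depth & ok_art & ok_ven),
        boundary = sum(ok_type & ok_depth & ok_art & ok_ven & ok_bnd),
        center = sum(ok))
    out
}

#' Randomly sample base capillaries from the candidate pool
#'
#' @param candidates vessel ids from \code{\link{selectBaseCapillaries}}.
#' @param n number to draw.
#' @param seed integer seed.
#' @return integer vector of vessel ids.
#' @export
sampleBaseCapillaries <- function(candidates, n = 7L, seed = 1L) {
    if (!length(candidates)) stop("no candidate base capillaries")
    set.seed(seed)
    sort(sample(candidates, min(n, length(candidates))))
}

# vessels eligible for addition to the affected set
.affectedEligible <- function(net, bdist) {
    vs <- net@vessels
    vs$vessel_type == "capillary" &
        !is.na(vs$arteriole_order) & vs$arteriole_order >= 2L &
        !is.na(vs$venule_order) & vs$venule_order >= 1L &
        !is.na(bdist) & bdist >= 2L
}

#' Build the set of affected capillaries around a base capillary
#'
#' Mimics the spatial extent of dilations seen after ablation of three
#' contiguous pericytes: starting from the upstream bifurcation of the
#' base capillary (its higher-pressure endpoint under the baseline flow
#' field), capillaries directly adjacent are added (generation 1), then
#' the capillaries connected to those (generation 2), and so on until at
#' least \code{minUpstream} have been added; the same expansion is then
#' initiated at the downstream node until at least \code{minTotal}
#' capillaries (including the base) are in the set.  Vessels that are
#' 0th-order main branches, less than two branches from a descending
#' arteriole main branch, or less than two branches from the domain
#' boundary are never added.  Ties and overshoot are resolved
#' deterministically: vessels of a generation are added in ascending id
#' order and the final generation is truncated so the set never exceeds
#' \code{maxTotal}.
#'
#' @param net a \linkS4class{MicrovascularNetwork} with branch orders.
#' @param baseCapillary vessel id.
#' @param flow baseline \linkS4class{TimeAveragedFlow} (or
#'   \linkS4class{FlowState}) used to orient the base capillary.
#' @param minUpstream,minTotal,maxTotal set-size rules.
#' @return integer vector of vessel ids, base first, in addition order.
#' @export
buildAffectedSet <- function(net, baseCapillary, flow, minUpstream = 6L,
                             minTotal = 13L, maxTotal = 15L) {
    vs <- net@vessels
    bi <- match(baseCapillary, vs$id)
    if (is.na(bi)) stop("unknown base capillary id")
    q <- if (is(flow, "TimeAveragedFlow")) flow@meanFlow else flow@flows
    bdist <- .boundaryBranchDistance(net)
    eligible <- .affectedEligible(net, bdist)
    inc <- .incidence(net)
    ia <- match(vs$node_a, net@nodes$id)
    ib <- match(vs$node_b, net@nodes$id)

    # upstream node: higher-pressure endpoint at baseline flow
    if (abs(q[bi]) > 1e-12) {
        up <- if (q[bi] > 0) ia[bi] else ib[bi]
    } else {
        # tie: the endpoint closer to the arterial tree
        ordAt <- function(ni) min(vs$arteriole_order[inc[[ni]]], na.rm = TRUE)
        up <- if (ordAt(ia[bi]) <= ordAt(ib[bi])) ia[bi] else ib[bi]
    }
    down <- if (up == ia[bi]) ib[bi] else ia[bi]

    inSet <- logical(nrow(vs))
    inSet[bi] <- TRUE
    order_added <- bi

    expand <- function(startNode, stopWhen) {
        added <- 0L
        frontier <- inc[[startNode]]
        frontier <- frontier[!inSet[frontier] & eligible[frontier]]
        while (length(frontier) && !stopWhen(added) &&
               sum(inSet) < maxTotal) {
            frontier <- sort(frontier)
            room <- maxTotal - sum(inSet)
            take <- frontier[seq_len(min(room, length(frontier)))]
            inSet[take] <<- TRUE
            order_added <<- c(order_added, take)
            added <- added + length(take)
            if (stopWhen(added)) break
            nxt <- unique(unlist(c(inc[ia[take]], inc[ib[take]]),
                                 use.names = FALSE))
            frontier <- nxt[!inSet[nxt] & eligible[nxt]]
        }
        added
    }
    expand(up, function(a) a >= minUpstream)
    if (sum(inSet) < minTotal)
        expand(down, function(a) sum(inSet) >= minTotal)
    if (sum(inSet) < minTotal)
        stop(sprintf(
            "only %d eligible capillaries reachable around vessel %d; try a different base capillary",
            sum(inSet), baseCapillary))
    vs$id[order_added]
}

#' Create an ablation scenario
#'
#' @param baseCapillary vessel id of the base capillary.
#' @param affectedSet vessel ids of the capillaries to dilate (contains
#'   the base capillary).
#' @param dilationIncrement um: 0.6 (mean adult response to pericyte
#'   ablation), 1.1 (mean aged response) or 1.6 (extreme aged response) in
#'   the canonical scenarios; any non-negative value is accepted.
#' @return an \linkS4class{AblationScenario}.
#' @export
ablationScenario <- function(baseCapillary, affectedSet,
                             dilationIncrement) {
    new("AblationScenario", baseCapillary = as.integer(baseCapillary),
        affectedSet = as.integer(affectedSet),
        dilationIncrement = dilationIncrement)
}

#' Apply a focal dilation to a network
#'
#' Every affected vessel's diameter grows by exactly the scenario's
#' increment; nothing else changes, and the input network is left
#' untouched.  By the D^4 law each dilated vessel's resistance strictly
#' decreases.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param scenario an \linkS4class{AblationScenario}.
#' @return a new \linkS4class{MicrovascularNetwork}.
#' @export
applyDilation <- function(net, scenario) {
    idx <- match(scenario@affectedSet, net@vessels$id)
    if (anyNA(idx)) stop("affected set references unknown vessel id")
    if (!all(net@vessels$vessel_type[idx] == "capillary"))
        stop("affected set must contain only capillaries")
    net@vessels$diameter[idx] <- net@vessels$diameter[idx] +
        scenario@dilationIncrement
    net
}
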