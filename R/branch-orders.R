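#' Multi-source breadth-first distance between vessels
#'
#' Distances are counted in bifurcations crossed along the vessel path:
#' a vessel adjacent to a source vessel (sharing a node) is 1 branch apart,
#' the sources themselves are 0.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param fromVessels vessel ids forming the source set.
#' @return integer vector of branch distances in vessel-table order
#'   (\code{NA} for unreachable vessels).
#' @export
vesselBranchDistance <- function(net, fromVessels) {
    vs <- net@vessels
    nv <- nrow(vs)
    src <- match(fromVessels, vs$id)
    if (anyNA(src)) stop("unknown vessel id in fromVessels")
    inc <- .incidence(net)
    ia <- match(vs$node_a, net@nodes$id)
    ib <- match(vs$node_b, net@nodes$id)
    dist <- rep(NA_integer_, nv)
    dist[src] <- 0L
    frontier <- src
    d <- 0L
    while (length(frontier)) {
        d <- d + 1L
        nbr <- unique(unlist(c(inc[ia[frontier]], inc[ib[frontier]]),
                             use.names = FALSE))
        nbr <- nbr[is.na(dist[nbr])]
        if (!length(nbr)) break
        dist[nbr] <- d
        frontier <- nbr
    }
    dist
}

#' Assign arteriole- and venule-side branch orders
#'
#' The penetrating (descending) arteriole main branch is 0th order on the
#' arterial tree and the ascending venule main branch 0th order on the
#' venous tree (pial vessels are also mains).  Every vessel is labelled
#' with the number of bifurcations on the shortest vessel path to the
#' nearest 0th-order vessel of each tree: a capillary branching directly
#' off a penetrating arteriole has arteriole order 1.
#'
#' @param net a \linkS4class{MicrovascularNetwork} with vessel types.
#' @return the network with integer columns \code{arteriole_order} and
#'   \code{venule_order} added to the vessel table.
#' @export
assignBranchOrders <- function(net) {
    vs <- net@vessels
    art0 <- vs$id[vs$vessel_type %in% c("descending_arteriole",
                                        "pial_artery")]
    ven0 <- vs$id[vs$vessel_type %in% c("ascending_venule", "pial_vein")]
    if (!length(art0))
        stop("no 0th-order arteriole main branch (descending_arteriole)")
    if (!length(ven0))
        stop("no 0th-order venule main branch (ascending_venule)")
    vs$arteriole_order <- vesselBranchDistance(net, art0)
    vs$venule_order <- vesselBranchDistance(net, ven0)
    net@vessels <- vs
    net
}

#' Distance of every vessel to the centre of a vessel set
#'
#' The centre is the averaged coordinate of all bifurcations (endpoint
#' nodes) of the given set, e.g. of the dilated capillaries; each vessel's
#' distance is measured from its midpoint to that centre.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param vesselSet non-empty vector of vessel ids.
#' @return list with \code{center} (length-3, um) and \code{distance}
#'   (numeric per vessel, vessel-table order, um).
#' @export
vesselDistanceToCenter <- function(net, vesselSet) {
    if (!length(vesselSet)) stop("vesselSet must be non-empty")
    idx <- match(vesselSet, net@vessels$id)
    if (anyNA(idx)) stop("unknown vessel id in vesselSet")
    nids <- unique(c(net@vessels$node_a[idx], net@vessels$node_b[idx]))
    ni <- match(nids, net@nodes$id)
    center <- c(x = mean(net@nodes$x[ni]), y = mean(net@nodes$y[ni]),
                z = mean(net@nodes$z[ni]))
    mid <- .vesselMidpoints(net)
    d <- sqrt((mid[, "x"] - center["x"])^2 + (mid[, "y"] - center["y"])^2 +
              (mid[, "z"] - center["z"])^2)
    list(center = center, distance = unname(d))
}

# x-y-plane distance of every vessel midpoint to the network centre
# (mean of all vessel midpoints)
.xyDistanceToNetworkCenter <- function(net) {
    mid <- .vesselMidpoints(net)
    cx <- mean(mid[, "x"])
    cy <- mean(mid[, "y"])
    sqrt((mid[, "x"] - cx)^2 + (mid[, "y"] - cy)^2)
}

# branch distance of every vessel from the simulation-domain boundary
# (vessels touching a boundary node are 0 branches apart)
.boundaryBranchDistance <- function(net) {
    bn <- net@nodes$id[net@nodes$is_boundary]
    touching <- net@vessels$id[net@vessels$node_a %in% bn |
                               net@vessels$node_b %in% bn]
    if (!length(touching)) return(rep(NA_integer_, nrow(net@vessels)))
    vesselBranchDistance(net, touching)
}
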