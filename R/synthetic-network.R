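#' Generator configuration for synthetic cortical networks
#'
#' Defaults target a desk-scale network of ~3,000 vessels in a
#' (600 um)^3 cortical block whose capillary statistics emulate real mouse
#' cortical networks: >= 94 percent capillaries with diameters drawn from a
#' truncated normal, 3.04 +/- 0.59 um on [2.17, 4.81] um.
#'
#' @param domainSize length-3 numeric, um.
#' @param targetVesselCount approximate total vessel count.
#' @param capillaryFractionTarget target fraction of capillary vessels.
#' @param capillaryDiameterMean,capillaryDiameterSd um.
#' @param capillaryDiameterRange truncation bounds, um.
#' @param meanSegmentLength mean capillary segment length, um.
#' @param nPenetratingArterioles,nAscendingVenules number of arteriole /
#'   venule trees.  Ascending venules outnumber penetrating arterioles in
#'   cortex, roughly two to one.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(domainSize = c(600, 600, 600),
                            targetVesselCount = 3000L,
                            capillaryFractionTarget = 0.96,
                            capillaryDiameterMean = 3.04,
                            capillaryDiameterSd = 0.59,
                            capillaryDiameterRange = c(2.17, 4.81),
                            meanSegmentLength = 60,
                            nPenetratingArterioles = 3L,
                            nAscendingVenules = 6L,
                            seed = 1L) {
    new("GeneratorConfig", domainSize = as.numeric(domainSize),
        targetVesselCount = as.integer(targetVesselCount),
        capillaryFractionTarget = capillaryFractionTarget,
        capillaryDiameterMean = capillaryDiameterMean,
        capillaryDiameterSd = capillaryDiameterSd,
        capillaryDiameterRange = as.numeric(capillaryDiameterRange),
        meanSegmentLength = meanSegmentLength,
        nPenetratingArterioles = as.integer(nPenetratingArterioles),
        nAscendingVenules = as.integer(nAscendingVenules),
        seed = as.integer(seed))
}

# truncated-normal sampling by rejection
.rtruncnorm <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
        out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
}

#' Generate a synthetic cortical microvascular network
#'
#' The capillary bed is a randomized 3-D lattice: node positions are
#' jittered, a random connected subset of lattice edges is kept (mean
#' bifurcation degree ~3) and segment lengths are tortuous (length >
#' Euclidean distance).  Penetrating-arteriole trees descend from the pial
#' surface and couple to the capillary mesh through short transition
#' offshoots (1st-order capillaries); ascending venules drain it
#' symmetrically; pial vessels connect the trunks to boundary nodes at the
#' surface.  Capillary-zone diameters are drawn from the configured
#' truncated normal; the first-order transition vessels coupling a trunk
#' to the mesh (arteriole-capillary transition zone and postcapillary
#' venules) are wider, ~5 um, as in vivo; trunk diameters taper
#' geometrically with depth (arteriole trunk 15 um, venule trunk 20 um at
#' the surface).  Nodes on the domain faces are flagged as boundary
#' nodes.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return a validated \linkS4class{MicrovascularNetwork} with branch
#'   orders assigned.
#' @export
generateCorticalNetwork <- function(config = generatorConfig()) {
    validObject(config)
    set.seed(config@seed)
    ds <- config@domainSize
    ncap <- round(config@targetVesselCount * config@capillaryFractionTarget)
    k <- max(5L, round((ncap / 1.55)^(1 / 3)))
    if (k < 5L) stop("targetVesselCount too small for a capillary lattice")
    h <- ds / k

    # --- capillary lattice nodes ------------------------------------------
    grid <- expand.grid(i = seq_len(k), j = seq_len(k), l = seq_len(k))
    nn <- nrow(grid)
    jit <- matrix(runif(3 * nn, -0.25, 0.25), ncol = 3)
    nodes <- data.frame(
        id = seq_len(nn),
        x = (grid$i - 0.5 + jit[, 1]) * h[1],
        y = (grid$j - 0.5 + jit[, 2]) * h[2],
        z = (grid$l - 0.5 + jit[, 3]) * h[3],
        is_boundary = grid$i %in% c(1L, k) | grid$j %in% c(1L, k) |
                      grid$l %in% c(1L, k))
    nid <- function(i, j, l) i + (j - 1L) * k + (l - 1L) * k * k

    # full lattice edge list
    e1 <- with(grid, cbind(nid(i, j, l), ifelse(i < k, nid(i + 1L, j, l), NA)))
    e2 <- with(grid, cbind(nid(i, j, l), ifelse(j < k, nid(i, j + 1L, l), NA)))
    e3 <- with(grid, cbind(nid(i, j, l), ifelse(l < k, nid(i, j, l + 1L), NA)))
    ee <- rbind(e1, e2, e3)
    ee <- ee[!is.na(ee[, 2]), , drop = FALSE]

    # keep a random connected subset: random spanning tree + extra edges
    g <- igraph::graph_from_edgelist(ee, directed = FALSE)
    igraph::E(g)$w <- runif(nrow(ee))
    igraph::E(g)$idx <- seq_len(nrow(ee))
    mst <- igraph::mst(g, weights = igraph::E(g)$w)
    intree <- logical(nrow(ee))
    intree[igraph::E(mst)$idx] <- TRUE
    nextra <- ncap - sum(intree)
    if (nextra < 0) stop("lattice too small for requested vessel count")
    # no interior dead ends: give every interior spanning-tree leaf a
    # second incident lattice edge
    keepFlag <- intree
    deg <- tabulate(ee[keepFlag, ], nbins = nn)
    leaves <- which(deg == 1L & !nodes$is_boundary)
    for (lf in leaves) {
        cand <- which(!keepFlag & (ee[, 1] == lf | ee[, 2] == lf))
        if (length(cand)) keepFlag[cand[sample.int(length(cand), 1L)]] <- TRUE
    }
    pool <- which(!keepFlag)
    nextra <- ncap - sum(keepFlag)
    if (nextra > 0)
        keepFlag[sample(pool, min(nextra, length(pool)))] <- TRUE
    ee <- ee[keepFlag, , drop = FALSE]

    vessels <- data.frame(id = seq_len(nrow(ee)), node_a = ee[, 1],
                          node_b = ee[, 2],
                          vessel_type = "capillary")

    # --- arteriole / venule trees -----------------------------------------
    interior <- which(!nodes$is_boundary)
    ij <- unique(grid[interior, c("i", "j")])
    ntree <- config@nPenetratingArterioles + config@nAscendingVenules
    if (nrow(ij) < ntree) stop("domain too small for the requested trees")
    # spread trunk columns: greedy max-min separation on a shuffled pool
    pool_ij <- ij[sample(nrow(ij)), ]
    chosen <- pool_ij[1, , drop = FALSE]
    while (nrow(chosen) < ntree) {
        dmin <- apply(pool_ij, 1, function(p)
            min((p[1] - chosen$i)^2 + (p[2] - chosen$j)^2))
        chosen <- rbind(chosen, pool_ij[which.max(dmin), ])
    }
    nextNode <- nn
    nextVes <- nrow(vessels)
    newNodes <- list()
    newVes <- list()
    depthLayers <- max(3L, floor(0.7 * k))
    addTree <- function(colIJ, type, trunkD0, pialType) {
        # trunk nodes alongside the lattice column (slight x offset)
        ii <- colIJ[[1]]; jj <- colIJ[[2]]
        tx <- (ii - 0.5) * h[1] + 0.3 * h[1]
        ty <- (jj - 0.5) * h[2]
        ids <- nextNode + seq_len(depthLayers + 1L)
        nextNode <<- nextNode + depthLayers + 1L
        zz <- c(0, ((seq_len(depthLayers)) - 0.5) * h[3])
        newNodes[[length(newNodes) + 1L]] <<- data.frame(
            id = ids, x = tx, y = ty, z = zz, is_boundary = FALSE)
        taper <- trunkD0 * 0.92^(seq_len(depthLayers) - 1L)
        trunk <- data.frame(id = nextVes + seq_len(depthLayers),
                            node_a = ids[-length(ids)], node_b = ids[-1],
                            vessel_type = type, diameter = taper,
                            length = NA_real_)
        nextVes <<- nextVes + depthLayers
        # pial vessel: connect trunk top to a boundary node at the surface
        pid <- nextNode + 1L
        nextNode <<- nextNode + 1L
        px <- if (ii < k / 2) 0 else ds[1]
        newNodes[[length(newNodes) + 1L]] <<- data.frame(
            id = pid, x = px, y = ty, z = 0, is_boundary = TRUE)
        pial <- data.frame(id = nextVes + 1L, node_a = pid, node_b = ids[1],
                           vessel_type = pialType, diameter = trunkD0 * 1.2,
                           length = NA_real_)
        nextVes <<- nextVes + 1L
        # offshoots: couple every trunk node to the two nearest interior
        # mesh nodes in the same depth layer (dense arteriole-capillary
        # transition, as along real penetrating vessels)
        off <- list()
        for (ly in seq_len(depthLayers)) {
            cand <- which(grid$l == ly & !nodes$is_boundary)
            if (!length(cand)) next
            d2 <- (nodes$x[cand] - tx)^2 + (nodes$y[cand] - ty)^2
            tgt <- cand[order(d2)[seq_len(min(2L, length(cand)))]]
            for (tg in tgt) {
                off[[length(off) + 1L]] <- data.frame(
                    id = nextVes + 1L, node_a = ids[ly + 1L],
                    node_b = nodes$id[tg], vessel_type = "capillary",
                    diameter = NA_real_, length = NA_real_)
                nextVes <<- nextVes + 1L
            }
        }
        newVes[[length(newVes) + 1L]] <<- rbind(trunk, pial,
                                                do.call(rbind, off))
    }
    for (t in seq_len(config@nPenetratingArterioles))
        addTree(chosen[t, ], "descending_arteriole", 15, "pial_artery")
    for (t in seq_len(config@nAscendingVenules))
        addTree(chosen[config@nPenetratingArterioles + t, ],
                "ascending_venule", 20, "pial_vein")

    nodes <- rbind(nodes, do.call(rbind, newNodes))
    extra <- do.call(rbind, newVes)
    vessels$diameter <- NA_real_
    vessels$length <- NA_real_
    vessels <- rbind(vessels, extra[, names(vessels)])

    # --- diameters and tortuous lengths -----------------------------------
    iscap <- vessels$vessel_type == "capillary"
    rng <- config@capillaryDiameterRange
    vessels$diameter[iscap] <- .rtruncnorm(sum(iscap),
                                           config@capillaryDiameterMean,
                                           config@capillaryDiameterSd,
                                           rng[1], rng[2])
    # arteriole-capillary transition offshoots are wider than capillary-
    # zone vessels (ensheathing-pericyte territory, ~5 um)
    net0 <- microvascularNetwork(nodes, transform(vessels,
        diameter = ifelse(is.na(diameter), 3, diameter),
        length = 1e6), validate = FALSE)
    aord <- vesselBranchDistance(net0, vessels$id[
        vessels$vessel_type %in% c("descending_arteriole", "pial_artery")])
    trans <- iscap & aord == 1L
    vessels$diameter[trans] <- .rtruncnorm(sum(trans), 5, 0.5, 4, 6)
    # ... and so are first-order postcapillary venules
    vord <- vesselBranchDistance(net0, vessels$id[
        vessels$vessel_type %in% c("ascending_venule", "pial_vein")])
    post <- iscap & vord == 1L & !trans
    vessels$diameter[post] <- .rtruncnorm(sum(post), 5, 0.5, 4, 6)
    ia <- match(vessels$node_a, nodes$id)
    ib <- match(vessels$node_b, nodes$id)
    eu <- sqrt((nodes$x[ia] - nodes$x[ib])^2 +
               (nodes$y[ia] - nodes$y[ib])^2 +
               (nodes$z[ia] - nodes$z[ib])^2)
    # tortuosity ~ 1 + Gamma; capillary mean segment length ~ configured
    tscale <- max(0.02, 0.5 * (config@meanSegmentLength /
                               mean(eu[iscap]) - 1))
    tort <- 1 + stats::rgamma(nrow(vessels), shape = 2, scale = tscale)
    tort[tort < 1] <- 1
    vessels$length <- pmax(eu * ifelse(iscap, tort, 1.05), 1e-3)

    net <- microvascularNetwork(nodes, vessels)
    assignBranchOrders(net)
}
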