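#' Per-vessel Poiseuille resistance
#'
#' R_e = 128 L mu mu_rel / (pi D^4), expressed in mmHg ms / um^3 so that
#' flow = pressure difference / resistance is in um^3/ms for pressures in
#' mmHg.  Doubling the diameter divides the resistance by 16.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param relViscosity relative effective viscosity per vessel (recycled;
#'   default 1 = pure plasma).
#' @param params a \linkS4class{RheologyParams} (plasma viscosity).
#' @return numeric vector of resistances, vessel-table order.
#' @export
computeResistances <- function(net, relViscosity = 1,
                               params = rheologyParams()) {
    if (any(relViscosity <= 0)) stop("relative viscosity must be positive")
    vs <- net@vessels
    mu <- params@plasmaViscosity
    g <- .MMHG_UM3_MS * pi * vs$diameter^4 /
        (128 * vs$length * mu * relViscosity)
    1 / g
}

#' Solve the network pressure field (steady Poiseuille flow)
#'
#' Linear Kirchhoff problem on node pressures: at every interior node the
#' signed vessel flows sum to zero; boundary nodes carry fixed pressures.
#' Solved with a sparse Cholesky factorization.  Conservation is asserted
#' after every solve (max interior imbalance below 1e-10 of the mean
#' absolute flow).
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param resistances per-vessel resistance (from
#'   \code{\link{computeResistances}}).
#' @param bc a \linkS4class{BoundaryConditions}; every boundary node must
#'   have a pressure and every connected component at least one.
#' @return a \linkS4class{FlowState} (pressures, flows; hematocrits zero).
#' @export
solvePressures <- function(net, resistances, bc) {
    nd <- net@nodes
    vs <- net@vessels
    nn <- nrow(nd)
    g <- 1 / resistances
    if (any(!is.finite(g) | g <= 0)) stop("non-positive vessel resistance")
    pfix <- rep(NA_real_, nn)
    bidx <- match(as.integer(names(bc@pressures)), nd$id)
    if (anyNA(bidx)) stop("boundary condition on unknown node id")
    pfix[bidx] <- unname(bc@pressures)
    bn <- nd$id[nd$is_boundary]
    nobc <- setdiff(bn, as.integer(names(bc@pressures)))
    if (length(nobc))
        stop("boundary node(s) without pressure condition: ",
             paste(head(nobc, 5L), collapse = ", "))
    # every connected component needs at least one fixed pressure
    comp <- igraph::components(.asIgraph(net))$membership
    compFix <- unique(comp[match(as.character(nd$id[!is.na(pfix)]),
                                 names(comp))])
    bad <- setdiff(unique(comp), compFix)
    if (length(bad))
        stop("no pressure boundary node in connected component ", bad[1L],
             " (e.g. node ", names(comp)[match(bad[1L], comp)], ")")

    ia <- match(vs$node_a, nd$id)
    ib <- match(vs$node_b, nd$id)
    interior <- which(is.na(pfix))
    # solve relative to the mean boundary pressure: only differences
    # matter and the offset frame preserves precision in the flows
    shift <- mean(pfix, na.rm = TRUE)
    pfix <- pfix - shift
    p <- pfix
    if (length(interior)) {
        ridx <- rep(NA_integer_, nn)
        ridx[interior] <- seq_along(interior)
        m <- length(interior)
        # Laplacian restricted to interior nodes
        iii <- c(ridx[ia], ridx[ib])
        jjj <- c(ridx[ib], ridx[ia])
        vvv <- c(-g, -g)
        keep <- !is.na(iii) & !is.na(jjj)
        A <- Matrix::sparseMatrix(
            i = c(iii[keep], ridx[ia][!is.na(ridx[ia])],
                  ridx[ib][!is.na(ridx[ib])]),
            j = c(jjj[keep], ridx[ia][!is.na(ridx[ia])],
                  ridx[ib][!is.na(ridx[ib])]),
            x = c(vvv[keep], g[!is.na(ridx[ia])], g[!is.na(ridx[ib])]),
            dims = c(m, m))
        b <- numeric(m)
        ba <- which(!is.na(ridx[ia]) & !is.na(pfix[ib]))
        bb <- which(!is.na(ridx[ib]) & !is.na(pfix[ia]))
        if (length(ba))
            b <- b + unname(tapply(g[ba] * pfix[ib][ba],
                                   factor(ridx[ia][ba], levels = 1:m),
                                   sum, default = 0))
        if (length(bb))
            b <- b + unname(tapply(g[bb] * pfix[ia][bb],
                                   factor(ridx[ib][bb], levels = 1:m),
                                   sum, default = 0))
        p[interior] <- as.numeric(Matrix::solve(A, b))
    }
    q <- g * (p[ia] - p[ib])
    # Kirchhoff balance at interior nodes
    if (length(interior)) {
        imb <- tapply(c(q, -q), factor(c(ib, ia), levels = seq_len(nn)),
                      sum, default = 0)[interior]
        scale <- mean(abs(q))
        tol <- if (scale > 0) 1e-10 * scale else 1e-12
        if (max(abs(imb)) > tol)
            stop(sprintf("flow conservation violated: max imbalance %.3e",
                         max(abs(imb))))
    }
    new("FlowState", pressures = unname(p) + shift, flows = unname(q),
        tubeHematocrit = numeric(length(q)),
        dischargeHematocrit = numeric(length(q)),
        rbcFlux = numeric(length(q)))
}

#' Default pressure boundary conditions for a cortical network
#'
#' Boundary nodes attached to pial-artery or descending-arteriole vessels
#' receive the arterial pressure, those attached to pial-vein or
#' ascending-venule vessels the venous pressure, and capillary boundary
#' nodes (cut capillaries on the domain faces) a pressure interpolated
#' between the two levels by relative network (hop) distance to the
#' nearest arterial- and venous-side boundary nodes.  The defaults are
#' package conventions exposed through the arguments, not measured values.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param arterialPressure,venousPressure mmHg.
#' @param inflowHematocrit discharge hematocrit at inflow boundaries.
#' @return a \linkS4class{BoundaryConditions}.
#' @export
assignDefaultBoundaryPressures <- function(net, arterialPressure = 60,
                                           venousPressure = 10,
                                           inflowHematocrit = 0.3) {
    nd <- net@nodes
    vs <- net@vessels
    bn <- nd$id[nd$is_boundary]
    if (!length(bn)) stop("network has no boundary nodes")
    sideType <- function(types)
        unique(c(vs$node_a[vs$vessel_type %in% types],
                 vs$node_b[vs$vessel_type %in% types]))
    artNodes <- intersect(bn, sideType(c("pial_artery",
                                         "descending_arteriole")))
    venNodes <- intersect(bn, sideType(c("pial_vein", "ascending_venule")))
    if (!length(artNodes)) stop("no arterial-side boundary nodes")
    if (!length(venNodes)) stop("no venous-side boundary nodes")
    p <- setNames(rep(NA_real_, length(bn)), bn)
    p[as.character(artNodes)] <- arterialPressure
    p[as.character(venNodes)] <- venousPressure
    rest <- bn[is.na(p[as.character(bn)])]
    if (length(rest)) {
        g <- .asIgraph(net)
        da <- igraph::distances(g, v = as.character(rest),
                                to = as.character(artNodes))
        dv <- igraph::distances(g, v = as.character(rest),
                                to = as.character(venNodes))
        dA <- apply(da, 1, min)
        dV <- apply(dv, 1, min)
        w <- dV / (dA + dV)
        p[as.character(rest)] <- venousPressure +
            (arterialPressure - venousPressure) * w
    }
    new("BoundaryConditions", pressures = p,
        inflowHematocrit = inflowHematocrit)
}

#' Boundary conditions from explicit pressures
#'
#' @param pressures named numeric (names = boundary node ids), mmHg.
#' @param inflowHematocrit discharge hematocrit at inflow boundaries.
#' @return a \linkS4class{BoundaryConditions}.
#' @export
boundaryConditions <- function(pressures, inflowHematocrit = 0.3) {
    new("BoundaryConditions", pressures = pressures,
        inflowHematocrit = inflowHematocrit)
}

#' Reynolds number per vessel
#'
#' Re = rho v D / (mu mu_rel), with blood density 1060 kg/m^3.  In the
#' microvasculature Re stays below 1 (Stokes regime), which is what makes
#' the Poiseuille description valid; a warning is emitted otherwise.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param state a \linkS4class{FlowState} or \linkS4class{TimeAveragedFlow}.
#' @param relViscosity per-vessel relative viscosity (default 1).
#' @param params a \linkS4class{RheologyParams}.
#' @return numeric vector of Reynolds numbers.
#' @export
reynoldsNumber <- function(net, state, relViscosity = 1,
                           params = rheologyParams()) {
    q <- if (is(state, "TimeAveragedFlow")) state@meanFlow else state@flows
    vs <- net@vessels
    area <- pi * vs$diameter^2 / 4
    v_m_s <- abs(q) / area * 1e-3          # um/ms -> m/s
    D_m <- vs$diameter * 1e-6
    re <- 1060 * v_m_s * D_m / (params@plasmaViscosity * relViscosity)
    if (any(re > 1))
        warning(sprintf("%d vessel(s) above Re = 1 (max %.2f)",
                        sum(re > 1), max(re)))
    re
}
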