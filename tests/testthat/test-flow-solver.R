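test_that("resistances follow the Poiseuille D^4 and L scalings", {
    base <- toyNetwork("single_tube", D = 4, L = 100)
    wide <- toyNetwork("single_tube", D = 8, L = 100)
    long <- toyNetwork("single_tube", D = 4, L = 200)
    r0 <- computeResistances(base)
    expect_equal(computeResistances(wide), r0 / 16)
    expect_equal(computeResistances(long), 2 * r0)
    # closed form at D = 4 um, L = 100 um, plasma
    expect_equal(1 / r0, oracle_conductance(4, 100), tolerance = 1e-12)
    # viscosity field scales the resistance linearly
    expect_equal(computeResistances(base, relViscosity = 2.5), 2.5 * r0)
    expect_error(computeResistances(base, relViscosity = -1), "positive")
})

test_that("single tube solves exactly: zero and finite pressure drops", {
    tube <- toyNetwork("single_tube", D = 4, L = 100)
    r <- computeResistances(tube)
    flat <- solvePressures(tube, r,
                           suppressWarnings(boundaryConditions(
                               c("1" = 20, "2" = 20))))
    expect_equal(flows(flat), 0)
    fs <- solvePressures(tube, r, boundaryConditions(c("1" = 30,
                                                       "2" = 10)))
    expect_equal(flows(fs), 20 / r, tolerance = 1e-12)
})

test_that("two identical tubes in series halve the drop at the midpoint", {
    nodes <- data.frame(id = 1:3, x = c(0, 100, 200), y = 0, z = 50,
                        is_boundary = c(TRUE, FALSE, TRUE))
    vessels <- data.frame(id = 1:2, node_a = c(1L, 2L), node_b = c(2L, 3L),
                          diameter = 4, length = 100,
                          vessel_type = "capillary")
    net <- microvascularNetwork(nodes, vessels)
    r <- computeResistances(net)
    fs <- solvePressures(net, r, boundaryConditions(c("1" = 40, "3" = 10)))
    expect_equal(pressures(fs)[2], 25, tolerance = 1e-12)
    expect_equal(flows(fs), rep(30 / (2 * r[1]), 2), tolerance = 1e-12)
})

test_that("the two-path loop matches hand-solved parallel circuit algebra", {
    loop <- toyNetwork("two_path_loop", D = 6, Da = 5, Db = 3)
    r <- computeResistances(loop)
    fs <- solvePressures(loop, r, boundaryConditions(c("1" = 50,
                                                       "4" = 10)))
    # series feed (r1), parallel limbs (r2+r3 and r4+r5), series drain (r6)
    rUp <- r[2] + r[3]
    rLo <- r[4] + r[5]
    rPar <- 1 / (1 / rUp + 1 / rLo)
    rTot <- r[1] + rPar + r[6]
    qTot <- 40 / rTot
    expect_equal(flows(fs)[1], qTot, tolerance = 1e-12)
    expect_equal(flows(fs)[6], qTot, tolerance = 1e-12)
    expect_equal(flows(fs)[2], qTot * rLo / (rUp + rLo), tolerance = 1e-12)
    expect_equal(flows(fs)[4], qTot * rUp / (rUp + rLo), tolerance = 1e-12)
})

test_that("interior flow conservation holds on toys and seeded networks", {
    nets <- list(toyNetwork("two_path_loop"),
                 toyNetwork("honeycomb_sheet", rows = 8L, cols = 10L),
                 fxSmallNet())
    for (net in nets) {
        bc <- if (any(vesselTable(net)$vessel_type != "capillary"))
            assignDefaultBoundaryPressures(net)
        else boundaryConditions(setNames(
            c(50, 10), as.character(nodeTable(net)$id[
                nodeTable(net)$is_boundary])[1:2]))
        fs <- solvePressures(net, computeResistances(net), bc)
        q <- flows(fs)
        vs <- vesselTable(net)
        nd <- nodeTable(net)
        imb <- tapply(c(q, -q),
                      factor(c(vs$node_b, vs$node_a), levels = nd$id),
                      sum, default = 0)
        interior <- !nd$is_boundary
        expect_lt(max(abs(imb[interior])), 1e-10 * mean(abs(q)))
    }
})

test_that("flows scale linearly with the boundary pressure differences", {
    net <- fxSmallNet()
    bc1 <- assignDefaultBoundaryPressures(net, 60, 10)
    fs1 <- solvePressures(net, computeResistances(net), bc1)
    # doubling all differences about the venous level doubles the flows
    p2 <- 10 + 2 * (bc1@pressures - 10)
    fs2 <- solvePressures(net, computeResistances(net),
                          boundaryConditions(p2))
    expect_equal(flows(fs2), 2 * flows(fs1), tolerance = 1e-9)
})

test_that("default boundary pressures respect sides and bounds", {
    y <- toyNetwork("divergent_Y", parentType = "pial_artery")
    vs <- vesselTable(y)
    vs$vessel_type[2:3] <- "pial_vein"
    y2 <- microvascularNetwork(nodeTable(y), vs)
    bc <- assignDefaultBoundaryPressures(y2, 60, 10)
    expect_equal(unname(bc@pressures[c("1", "3", "4")]), c(60, 10, 10))
    # capillary boundary cuts: strictly between the two levels
    net <- fxSmallNet()
    bc2 <- assignDefaultBoundaryPressures(net, 60, 10)
    vsn <- vesselTable(net)
    artAdj <- unique(c(vsn$node_a[vsn$vessel_type %in%
                                  c("pial_artery", "descending_arteriole")],
                       vsn$node_b[vsn$vessel_type %in%
                                  c("pial_artery", "descending_arteriole")]))
    venAdj <- unique(c(vsn$node_a[vsn$vessel_type %in%
                                  c("pial_vein", "ascending_venule")],
                       vsn$node_b[vsn$vessel_type %in%
                                  c("pial_vein", "ascending_venule")]))
    capBnd <- setdiff(as.integer(names(bc2@pressures)),
                      c(artAdj, venAdj))
    expect_true(all(bc2@pressures[as.character(capBnd)] > 10))
    expect_true(all(bc2@pressures[as.character(capBnd)] < 60))
})

test_that("capillary flow runs arteriole-to-venule through the mesh", {
    net <- fxMidNet(1L)
    bc <- assignDefaultBoundaryPressures(net)
    fs <- solvePressures(net, computeResistances(net), bc)
    vs <- vesselTable(net)
    # transition vessels: capillaries adjacent to the descending arteriole
    trans <- which(vs$vessel_type == "capillary" & vs$arteriole_order == 1L)
    trunkNodes <- unique(c(vs$node_a[vs$vessel_type ==
                                     "descending_arteriole"],
                           vs$node_b[vs$vessel_type ==
                                     "descending_arteriole"]))
    q <- flows(fs)
    awayFromTrunk <- ifelse(vs$node_a[trans] %in% trunkNodes,
                            q[trans] > 0, q[trans] < 0)
    expect_gte(mean(awayFromTrunk), 0.9)
})

test_that("a component without boundary pressure is reported", {
    nodes <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 50,
                        is_boundary = c(TRUE, TRUE))
    vessels <- data.frame(id = 1L, node_a = 1L, node_b = 2L, diameter = 4,
                          length = 100, vessel_type = "capillary")
    net <- microvascularNetwork(nodes, vessels)
    expect_error(solvePressures(net, computeResistances(net),
                                suppressWarnings(
                                    boundaryConditions(c("7" = 10)))),
                 "unknown node")
    # boundary node without a condition
    expect_error(solvePressures(net, computeResistances(net),
                                suppressWarnings(
                                    boundaryConditions(c("1" = 10)))),
                 "without pressure condition")
})

test_that("Reynolds numbers stay below 1 on a perfused cortical network", {
    net <- fxMidNet(1L)
    bc <- assignDefaultBoundaryPressures(net)
    fs <- solvePressures(net, computeResistances(net), bc)
    re <- reynoldsNumber(net, fs)
    expect_true(all(re < 1))
})
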