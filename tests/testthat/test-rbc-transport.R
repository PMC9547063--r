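test_that("plasma-only simulation reproduces the Poiseuille flow exactly", {
    tube <- toyNetwork("single_tube", D = 4, L = 100)
    bc <- boundaryConditions(c("1" = 30, "2" = 10), inflowHematocrit = 0)
    taf <- simulateFlow(tube, bc, config = fxShortConfig())
    r <- computeResistances(tube)
    expect_equal(meanFlow(taf), 20 / r, tolerance = 1e-12)
    expect_equal(meanRbcFlux(taf), 0)
    expect_equal(taf@diagnostics$rbcInjected, 0)
})

test_that("single tube with RBCs matches the self-consistent closed form", {
    tube <- toyNetwork("single_tube", D = 6, L = 1000)
    bc <- boundaryConditions(c("1" = 30, "2" = 10), inflowHematocrit = 0.3)
    taf <- simulateFlow(tube, bc,
                        config = simulationConfig(duration = 15.4),
                        seed = 2)
    # steady state: discharge hematocrit in the tube equals the inflow
    # hematocrit, so flow = dp * g0 / murel(D, 0.3)
    expected <- 20 * oracle_conductance(6, 1000,
                                        murel = relativeViscosity(6, 0.3))
    expect_equal(abs(meanFlow(taf)), expected, tolerance = 0.01)
    expect_equal(taf@meanDischargeHematocrit, 0.3, tolerance = 0.05)
})

test_that("RBC bookkeeping is exact and runs are seed-deterministic", {
    net <- fxSmallNet()
    bc <- assignDefaultBoundaryPressures(net)
    t1 <- simulateFlow(net, bc, config = fxShortConfig(), seed = 3)
    dg <- t1@diagnostics
    expect_identical(dg$rbcInitial + dg$rbcInjected - dg$rbcExited,
                     dg$rbcFinal)
    expect_identical(sum(dg$rbcCount), as.integer(dg$rbcFinal))
    t2 <- simulateFlow(net, bc, config = fxShortConfig(), seed = 3)
    expect_identical(meanFlow(t1), meanFlow(t2))
    expect_identical(meanRbcFlux(t1), meanRbcFlux(t2))
    t3 <- simulateFlow(net, bc, config = fxShortConfig(), seed = 4)
    expect_false(identical(meanFlow(t1), meanFlow(t3)))
})

test_that("zero inflow hematocrit gives zero flux and the plasma field", {
    net <- toyNetwork("two_path_loop", D = 6, Da = 5, Db = 4)
    pr <- c("1" = 40, "4" = 10)
    taf <- simulateFlow(net, boundaryConditions(pr, inflowHematocrit = 0),
                        config = fxShortConfig())
    fs <- solvePressures(net, computeResistances(net),
                         boundaryConditions(pr))
    expect_equal(meanFlow(taf), flows(fs), tolerance = 1e-10)
    expect_true(all(meanRbcFlux(taf) == 0))
})

test_that("advanceRbcs moves a cell by its Fahraeus velocity", {
    tube <- toyNetwork("single_tube", D = 6, L = 1000)
    # choose the bulk flow so that v_rbc = u * Hd/Ht = 1 um/ms
    ratio <- 0.40106469099157066 / 0.3      # frozen oracle at D=6, Ht=0.3
    area <- pi * 36 / 4
    state <- new("FlowState", pressures = c(30, 10),
                 flows = area / ratio, tubeHematocrit = 0.3,
                 dischargeHematocrit = 0.40106469099157066,
                 rbcFlux = 0)
    out <- advanceRbcs(tube, state,
                       data.frame(vessel = 1L, position = 500), dt = 1)
    expect_equal(out$rbcs$position, 501, tolerance = 1e-12)
    # kinematics: v_rbc = 1 mm/s for 1 ms advances 1 um
})

test_that("single-file routing follows the largest pressure force", {
    # asymmetric Y, parent D = 5 um (single file), equal daughter lengths
    # and outlet pressures: the wider daughter carries the stronger
    # stream and exerts the larger drag force on the cell at the mouth
    y <- toyNetwork("divergent_Y", D = 5, Da = 4, Db = 2, L = 100)
    bc <- boundaryConditions(c("1" = 40, "3" = 10, "4" = 10))
    fs <- solvePressures(y, computeResistances(y), bc)
    expect_gt(abs(flows(fs)[2]) / abs(flows(fs)[3]), 2) # forces > 2:1
    len <- vesselTable(y)$length[1]
    rb <- data.frame(vessel = 1L, position = len, atNode = TRUE)
    out <- advanceRbcs(y, fs, rb, dt = 0.1)
    expect_equal(out$rbcs$vessel, 2L)   # routed into the wider daughter
    expect_equal(out$departures[1], 1)
})

test_that("cells reaching a boundary node exit the domain", {
    tube <- toyNetwork("single_tube", D = 6, L = 100)
    state <- new("FlowState", pressures = c(30, 10), flows = 10,
                 tubeHematocrit = 0.1, dischargeHematocrit = 0.15,
                 rbcFlux = 0)
    out <- advanceRbcs(tube, state,
                       data.frame(vessel = 1L, position = 100,
                                  atNode = TRUE), dt = 0.1)
    expect_equal(nrow(out$rbcs), 0L)
    expect_equal(out$exited, 1)
})

test_that("tube hematocrit arithmetic and viscosity update are exact", {
    # vessel volume 1000 um^3 holding 5 cells of 55 um^3 -> Ht = 0.275
    L <- 1000 / (pi * 4^2 / 4)
    tube <- toyNetwork("single_tube", D = 4, L = L)
    rb <- data.frame(vessel = rep(1L, 5), position = seq(10, 50, 10))
    upd <- updateHematocrit(tube, rb, rbcVolume = 55)
    expect_equal(upd$tubeHematocrit, 0.275)
    expect_equal(upd$dischargeHematocrit,
                 dischargeHematocrit(0.275, 4))
    expect_equal(upd$relativeViscosity,
                 relativeViscosity(4, dischargeHematocrit(0.275, 4)))
    # empty vessel: plasma values
    upd0 <- updateHematocrit(tube, rb[0, , drop = FALSE])
    expect_equal(upd0$tubeHematocrit, 0)
    expect_equal(upd0$relativeViscosity, 1)
})

test_that("re-solving after a hematocrit update restores conservation", {
    net <- fxSmallNet()
    bc <- assignDefaultBoundaryPressures(net)
    taf <- simulateFlow(net, bc, config = fxShortConfig(), seed = 5)
    # the coupled run re-solves every coupling interval; the recorded
    # worst-case interior imbalance stays at solver tolerance
    expect_lt(taf@diagnostics$maxRelImbalance, 1e-10)
    # and the final state is a balanced flow field
    fs <- taf@diagnostics$finalState
    vs <- vesselTable(net)
    nd <- nodeTable(net)
    imb <- tapply(c(flows(fs), -flows(fs)),
                  factor(c(vs$node_b, vs$node_a), levels = nd$id),
                  sum, default = 0)
    expect_lt(max(abs(imb[!nd$is_boundary])),
              1e-10 * mean(abs(flows(fs))))
})

test_that("tracked RBC flux equals flow times discharge hematocrit", {
    loop <- toyNetwork("two_path_loop", D = 8, Da = 6, Db = 5, L = 200)
    bc <- boundaryConditions(c("1" = 45, "4" = 10), inflowHematocrit = 0.3)
    taf <- simulateFlow(loop, bc,
                        config = simulationConfig(duration = 15.4),
                        seed = 6)
    counted <- meanRbcFlux(taf)
    product <- abs(meanFlow(taf)) * taf@meanDischargeHematocrit / 55 * 1000
    expect_equal(counted, product, tolerance = 0.05)
})

test_that("an over-coarse time step is rejected with a suggested bound", {
    tube <- toyNetwork("single_tube", D = 6, L = 50)
    bc <- boundaryConditions(c("1" = 60, "2" = 10), inflowHematocrit = 0.3)
    expect_error(simulateFlow(tube, bc,
                              config = simulationConfig(duration = 0.1,
                                                        timeStep = 50)),
                 "time.?step")
})

test_that("a symmetric divergent Y splits flow and flux evenly", {
    fluxFrac <- vapply(1:6, function(s) {
        y <- toyNetwork("divergent_Y", D = 6, Da = 4, Db = 4, L = 150)
        bc <- boundaryConditions(c("1" = 45, "3" = 10, "4" = 10),
                                 inflowHematocrit = 0.3)
        taf <- simulateFlow(y, bc,
                            config = simulationConfig(duration = 6,
                                                      warmup = 3),
                            seed = s)
        fx <- meanRbcFlux(taf)
        fx[2] / (fx[2] + fx[3])
    }, numeric(1))
    sem <- stats::sd(fluxFrac) / sqrt(length(fluxFrac))
    expect_lt(abs(mean(fluxFrac) - 0.5), max(3 * sem, 0.02))
})

test_that("Zweifach-Fung partitioning emerges on an asymmetric Y", {
    y <- toyNetwork("divergent_Y", D = 6, Da = 4, Db = 4, L = 150)
    bc <- boundaryConditions(c("1" = 45, "3" = 10, "4" = 20),
                             inflowHematocrit = 0.3)
    taf <- simulateFlow(y, bc,
                        config = simulationConfig(duration = 6,
                                                  warmup = 3), seed = 7)
    q <- abs(meanFlow(taf))
    fx <- meanRbcFlux(taf)
    flowFrac <- q[2] / (q[2] + q[3])
    fluxFrac <- fx[2] / (fx[2] + fx[3])
    expect_gt(flowFrac, 0.5)
    expect_gt(fluxFrac, flowFrac)
})
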