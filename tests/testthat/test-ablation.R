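# exhaustive re-check of the selection rules, written independently of
# the package implementation
oracleSelect <- function(net, crit = selectionCriteria()) {
    vs <- vesselTable(net)
    nd <- nodeTable(net)
    midz <- (nd$z[match(vs$node_a, nd$id)] +
             nd$z[match(vs$node_b, nd$id)]) / 2
    midx <- (nd$x[match(vs$node_a, nd$id)] +
             nd$x[match(vs$node_b, nd$id)]) / 2
    midy <- (nd$y[match(vs$node_a, nd$id)] +
             nd$y[match(vs$node_b, nd$id)]) / 2
    xyd <- sqrt((midx - mean(midx))^2 + (midy - mean(midy))^2)
    bd <- vesselBranchDistance(net, vs$id[
        vs$node_a %in% nd$id[nd$is_boundary] |
        vs$node_b %in% nd$id[nd$is_boundary]])
    keep <- vs$vessel_type == "capillary" &
        midz >= crit@depthRange[1] & midz <= crit@depthRange[2] &
        vs$arteriole_order > crit@arterioleOrderBeyond &
        vs$venule_order > crit@venuleOrderBeyond &
        bd >= crit@minBoundaryBranches &
        xyd < crit@maxCenterDistanceFactor * mean(xyd)
    sort(vs$id[keep])
}

test_that("base-capillary selection enforces every criterion", {
    net <- fxSmallNet()
    got <- selectBaseCapillaries(net)
    expect_identical(as.integer(got), oracleSelect(net))
    expect_gt(length(got), 0)
    # idempotent and order-invariant: a permuted table selects the same ids
    perm <- sample(nVessels(net))
    net2 <- microvascularNetwork(nodeTable(net),
                                 vesselTable(net)[perm, ])
    expect_identical(sort(as.integer(selectBaseCapillaries(net2))),
                     sort(as.integer(got)))
    # depth and branch-order exclusions hold for every selected vessel
    vs <- vesselTable(net)
    nd <- nodeTable(net)
    midz <- (nd$z[match(vs$node_a, nd$id)] +
             nd$z[match(vs$node_b, nd$id)]) / 2
    sel <- match(got, vs$id)
    expect_true(all(midz[sel] >= 20 & midz[sel] <= 120))
    expect_true(all(vs$arteriole_order[sel] > 4))
    expect_true(all(vs$venule_order[sel] > 1))
})

test_that("deep and transition-zone capillaries are excluded", {
    net <- fxSmallNet()
    vs <- vesselTable(net)
    nd <- nodeTable(net)
    midz <- (nd$z[match(vs$node_a, nd$id)] +
             nd$z[match(vs$node_b, nd$id)]) / 2
    got <- selectBaseCapillaries(net)
    deep <- vs$id[midz > 120]                    # e.g. at 150 um depth
    expect_length(intersect(got, deep), 0)
    nearArt <- vs$id[vs$arteriole_order <= 4]    # e.g. 3rd branch order
    expect_length(intersect(got, nearArt), 0)
})

test_that("the affected set grows by the sequential two-sided rule", {
    net <- toyNetwork("honeycomb_sheet", rows = 12L, cols = 16L)
    net <- assignBranchOrders(net)
    bc <- assignDefaultBoundaryPressures(net)
    fs <- solvePressures(net, computeResistances(net), bc)
    # pick an interior capillary far from trunks and boundary
    bd <- vesselBranchDistance(net, vesselTable(net)$id[
        vesselTable(net)$node_a %in%
            nodeTable(net)$id[nodeTable(net)$is_boundary] |
        vesselTable(net)$node_b %in%
            nodeTable(net)$id[nodeTable(net)$is_boundary]])
    vs <- vesselTable(net)
    base <- vs$id[which(bd >= 3 & vs$arteriole_order >= 5 &
                        vs$venule_order >= 5)][1]
    ids <- buildAffectedSet(net, base, fs)
    expect_gte(length(ids), 13L)
    expect_lte(length(ids), 15L)
    expect_identical(ids[1], base)
    expect_true(all(vs$vessel_type[match(ids, vs$id)] == "capillary"))
    # every added vessel is adjacent to an earlier member of the set:
    # the expansion is generation by generation from the base
    for (k in seq(2, length(ids))) {
        vk <- match(ids[k], vs$id)
        before <- match(ids[seq_len(k - 1)], vs$id)
        shared <- any(c(vs$node_a[vk], vs$node_b[vk]) %in%
                      c(vs$node_a[before], vs$node_b[before]))
        expect_true(shared, label = paste("vessel", ids[k], "adjacency"))
    }
    # nothing within 2 branches of the boundary or an arteriole main
    expect_true(all(bd[match(ids, vs$id)] >= 2))
    expect_true(all(vs$arteriole_order[match(ids, vs$id)] >= 2))
})

test_that("a hand-traced fixture yields the exact affected set", {
    # line of capillaries: base in the middle, expansion alternates sides
    nodes <- data.frame(id = 1:24, x = (0:23) * 50, y = 0, z = 60,
                        is_boundary = c(TRUE, rep(FALSE, 22), TRUE))
    vessels <- data.frame(id = 1:23, node_a = 1:23, node_b = 2:24,
                          diameter = 3, length = 52,
                          vessel_type = "capillary")
    vessels$vessel_type[1] <- "descending_arteriole"
    vessels$vessel_type[23] <- "ascending_venule"
    net <- assignBranchOrders(microvascularNetwork(nodes, vessels))
    r <- computeResistances(net)
    fs <- solvePressures(net, r, boundaryConditions(c("1" = 50,
                                                      "24" = 10)))
    ids <- buildAffectedSet(net, 12L, fs)
    # flow runs 1 -> 24, so upstream node of vessel 12 is node 12;
    # upstream phase walks left one vessel per generation (11, 10, ...),
    # downstream phase right (13, 14, ...): 6 upstream, 6 downstream
    expect_identical(ids, c(12L, 11L, 10L, 9L, 8L, 7L, 6L,
                            13L, 14L, 15L, 16L, 17L, 18L))
})

test_that("dilation is exact, local and leaves the input untouched", {
    net <- fxSmallNet()
    cand <- selectBaseCapillaries(net)
    bc <- assignDefaultBoundaryPressures(net)
    fs <- solvePressures(net, computeResistances(net), bc)
    ids <- buildAffectedSet(net, cand[1], fs)
    sc <- ablationScenario(cand[1], ids, 1.1)
    before <- vesselTable(net)$diameter
    dil <- applyDilation(net, sc)
    after <- vesselTable(dil)$diameter
    idx <- match(ids, vesselTable(net)$id)
    expect_equal(after[idx], before[idx] + 1.1)
    expect_identical(after[-idx], before[-idx])
    expect_identical(vesselTable(net)$diameter, before)  # input unchanged
    expect_equal(sum(after != before), length(ids))
    # D^4 law: every dilated vessel's resistance strictly decreases
    expect_true(all(computeResistances(dil)[idx] <
                    computeResistances(net)[idx]))
    # zero increment is the identity
    id0 <- applyDilation(net, ablationScenario(cand[1], ids, 0))
    expect_identical(vesselTable(id0), vesselTable(net))
    # examples: 3.04 + 0.6 = 3.64
    expect_equal(unique(round(after[idx] - before[idx], 10)), 1.1)
})

test_that("scenario objects validate their invariants", {
    expect_error(ablationScenario(5L, c(1L, 2L), 0.6), "contain the base")
    expect_error(ablationScenario(1L, c(1L, 2L), -0.5), ">= 0")
    sc <- ablationScenario(1L, c(1L, 2L, 3L), 0.6)
    expect_identical(affectedSet(sc), c(1L, 2L, 3L))
})
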