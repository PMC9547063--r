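# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
    if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
    .fx[[key]]
}

# a small seeded cortical network (~800 vessels) for structural tests
fxSmallNet <- function(seed = 7L) {
    memo(paste0("small", seed),
         generateCorticalNetwork(generatorConfig(
             domainSize = c(420, 420, 420), targetVesselCount = 800L,
             seed = seed)))
}

# desk-scale network for conservation checks
fxMidNet <- function(seed = 1L) {
    memo(paste0("mid", seed),
         generateCorticalNetwork(generatorConfig(seed = seed)))
}

# short simulation config for unit-scale runs (not the full window)
fxShortConfig <- function(duration = 0.5, warmup = 0.25, coupling = 20L)
    simulationConfig(duration = duration, warmup = warmup,
                     couplingInterval = coupling)

# a hand-built 12-vessel arteriole tree for branch-order tests:
# trunk (3 segments) with offshoots of known order
fxHandTree <- function() {
    nodes <- data.frame(
        id = 1:13,
        x = c(0, 0, 0, 0, 30, 60, 30, 60, 90, 30, 60, 30, 60),
        y = c(0, 0, 0, 0, 0, 0, 20, 20, 20, 40, 40, -20, -20),
        z = c(0, 30, 60, 90, 30, 30, 60, 60, 60, 60, 60, 90, 90),
        is_boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                        FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
    vessels <- data.frame(
        id = 1:12,
        node_a = c(1, 2, 3, 2, 5, 3, 7, 8, 7, 10, 4, 12),
        node_b = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13),
        diameter = c(12, 11, 10, rep(3.2, 9)),
        length = c(31, 31, 31, 31, 31, 38, 31, 31, 21, 31, 68, 31),
        vessel_type = c(rep("descending_arteriole", 3),
                        rep("capillary", 8), "ascending_venule"))
    suppressWarnings(microvascularNetwork(nodes, vessels))
}
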