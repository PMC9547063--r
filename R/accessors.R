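#' @rdname accessors
#' @export
setMethod("nodeTable", "MicrovascularNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("vesselTable", "MicrovascularNetwork", function(x) x@vessels)

#' @rdname accessors
#' @export
setMethod("nNodes", "MicrovascularNetwork", function(x) nrow(x@nodes))

#' @rdname accessors
#' @export
setMethod("nVessels", "MicrovascularNetwork", function(x) nrow(x@vessels))

#' @rdname accessors
#' @export
setMethod("capillaryFraction", "MicrovascularNetwork", function(x)
    mean(x@vessels$vessel_type == "capillary"))

#' @rdname accessors
#' @export
setMethod("pressures", "FlowState", function(x) x@pressures)

#' @rdname accessors
#' @export
setMethod("flows", "FlowState", function(x) x@flows)

#' @rdname accessors
#' @export
setMethod("meanFlow", "TimeAveragedFlow", function(x) x@meanFlow)

#' @rdname accessors
#' @export
setMethod("meanRbcFlux", "TimeAveragedFlow", function(x) x@meanRbcFlux)

#' @rdname accessors
#' @export
setMethod("reportTable", "FlowChangeReport", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("affectedSet", "AblationScenario", function(x) x@affectedSet)

#' @export
setMethod("show", "MicrovascularNetwork", function(object) {
    tt <- table(object@vessels$vessel_type)
    cat("MicrovascularNetwork with", nrow(object@nodes), "nodes and",
        nrow(object@vessels), "vessels\n")
    cat(sprintf("  capillary fraction: %.1f%%\n",
                100 * capillaryFraction(object)))
    cat("  vessel types:",
        paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
        "\n")
    cat("  boundary nodes:", sum(object@nodes$is_boundary), "\n")
    if ("arteriole_order" %in% names(object@vessels))
        cat("  branch orders assigned\n")
})

#' @export
setMethod("show", "TimeAveragedFlow", function(object) {
    cat("TimeAveragedFlow over", object@window, "s window for",
        length(object@meanFlow), "vessels\n")
    cat(sprintf("  |flow|: median %.3g, max %.3g um^3/ms\n",
                stats::median(abs(object@meanFlow)),
                max(abs(object@meanFlow))))
    dg <- object@diagnostics
    if (!is.null(dg$maxRelImbalance))
        cat(sprintf("  max relative node imbalance: %.2e\n",
                    dg$maxRelImbalance))
})

#' @export
setMethod("show", "FlowChangeReport", function(object) {
    tb <- object@table
    cat("FlowChangeReport:", nrow(tb), "vessels;",
        sum(tb$flag == "increased"), "increased,",
        sum(tb$flag == "decreased"), "decreased (>10% rule)\n")
})

#' @export
setMethod("show", "HeterogeneityReference", function(object) {
    cat(sprintf(
        "HeterogeneityReference from %d capillary sets: median SD %.3g,",
        length(object@setSds), object@reference))
    cat(sprintf(" Q75 %.3g um^3/ms\n", object@quantiles[["0.75"]]))
})

#' @export
setMethod("show", "AblationScenario", function(object) {
    cat(sprintf(
        "AblationScenario: base capillary %d, %d affected capillaries, +%.1f um\n",
        object@baseCapillary, length(object@affectedSet),
        object@dilationIncrement))
})
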