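#' Simulation configuration for discrete RBC tracking
#'
#' @param duration averaging window, seconds.  The time-averaged flow
#'   field is computed over this window (default 15.4 s).
#' @param timeStep ms.  RBCs reaching a bifurcation within a step stop at
#'   the node and are routed at the start of the next step.
#' @param warmup seconds simulated before the window opens, so averaging
#'   starts from a developed RBC distribution; default one full duration.
#' @param couplingInterval steps between updates of hematocrit, viscosity
#'   and the pressure field (the two-way RBC-flow coupling).
#' @param rbcVolume um^3; 55 is a documented mouse red blood cell volume.
#' @param hematocritCap maximum tube hematocrit entering the viscosity
#'   law; persistent excess is reported as jamming in the diagnostics.
#' @param seed integer seed of the single random stream (injection times,
#'   phase-separation draws, tie-breaks).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(duration = 15.4, timeStep = 0.1,
                             warmup = duration, couplingInterval = 10L,
                             rbcVolume = 55, hematocritCap = 0.9,
                             seed = 1L) {
    new("SimulationConfig", duration = duration, timeStep = timeStep,
        warmup = warmup, couplingInterval = as.integer(couplingInterval),
        rbcVolume = rbcVolume, hematocritCap = hematocritCap,
        seed = as.integer(seed))
}

#' Simulate blood flow with discrete RBC tracking
#'
#' Tracks individual RBCs through the network: cells advect at the
#' Fahraeus-corrected velocity, partition at divergent bifurcations
#' (empirical phase separation above the single-file diameter threshold,
#' largest pressure force below it), and feed back on the flow field
#' through the hematocrit-dependent effective viscosity.  Pressures are
#' re-solved every \code{couplingInterval} steps.  New cells enter at
#' inflow boundaries as Poisson arrivals at the configured inflow
#' hematocrit; cells reaching a boundary node leave the domain.  The
#' returned field is averaged over the configured window after warm-up.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param bc a \linkS4class{BoundaryConditions}.
#' @param rheology a \linkS4class{RheologyParams}.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed overrides \code{config@seed} when given.
#' @return a \linkS4class{TimeAveragedFlow}; its \code{diagnostics} list
#'   carries the instantaneous flow envelope, conservation and RBC
#'   bookkeeping counters and the final \linkS4class{FlowState}.
#' @export
simulateFlow <- function(net, bc, rheology = rheologyParams(),
                         config = simulationConfig(), seed = NULL) {
    validObject(config)
    validObject(rheology)
    if (is.null(seed)) seed <- config@seed
    nd <- net@nodes
    pfix <- rep(NA_real_, nrow(nd))
    bidx <- match(as.integer(names(bc@pressures)), nd$id)
    if (anyNA(bidx)) stop("boundary condition on unknown node id")
    pfix[bidx] <- unname(bc@pressures)
    if (any(nd$is_boundary & is.na(pfix)))
        stop("boundary node(s) without pressure condition")
    isb <- !is.na(pfix)                 # every conditioned node is Dirichlet
    ei <- .edgeIndex(net)
    dt <- config@timeStep
    ci <- config@couplingInterval
    roundSteps <- function(sec) {
        st <- max(ci, round(sec * 1000 / dt))
        as.integer(ceiling(st / ci) * ci)
    }
    warmupSteps <- if (config@warmup > 0) roundSteps(config@warmup) else 0L
    windowSteps <- roundSteps(config@duration)
    res <- cpp_simulate(ei$a, ei$b, net@vessels$diameter,
                        net@vessels$length, isb,
                        ifelse(is.na(pfix), 0, pfix),
                        rheology@plasmaViscosity, rheology@singleFileMax,
                        bc@inflowHematocrit, dt, warmupSteps, windowSteps,
                        as.integer(ci), config@rbcVolume,
                        config@hematocritCap,
                        bc@inflowHematocrit > 0, as.integer(seed))
    finalFlux <- res$flows * res$dischargeHematocrit / config@rbcVolume *
        1000
    final <- new("FlowState", pressures = res$pressures, flows = res$flows,
                 tubeHematocrit = res$tubeHematocrit,
                 dischargeHematocrit = res$dischargeHematocrit,
                 rbcFlux = finalFlux)
    new("TimeAveragedFlow", meanFlow = res$meanFlow,
        meanRbcFlux = res$rbcFlux,
        meanDischargeHematocrit = res$meanDischargeHematocrit,
        window = windowSteps * dt / 1000,
        diagnostics = list(
            flowMin = res$flowMin, flowMax = res$flowMax,
            maxRelImbalance = res$maxRelImbalance,
            rbcInitial = res$rbcInitial, rbcInjected = res$rbcInjected,
            rbcExited = res$rbcExited, rbcFinal = res$rbcFinal,
            rbcCount = res$rbcCount, jamEvents = res$jamEvents,
            cgIterations = res$cgIterations, seed = seed,
            finalState = final))
}

#' Advance tracked RBCs by one time step
#'
#' Low-level stepping primitive (the same routine the simulation loop
#' uses): RBCs clamped at a node from the previous step are routed first
#' (boundary nodes: the cell exits; convergent nodes: the single outflow;
#' divergent nodes: empirical phase separation for parents wider than the
#' single-file threshold, otherwise the daughter exerting the largest
#' pressure force on the cell, i.e. the strongest stream), then every
#' cell moves by
#' \code{v_rbc * dt}, where \code{v_rbc} is the bulk velocity times the
#' Fahraeus ratio (discharge over tube hematocrit).
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param state a \linkS4class{FlowState} providing pressures, flows and
#'   tube hematocrits.
#' @param rbcs data.frame with columns \code{vessel} (vessel id),
#'   \code{position} (um from \code{node_a}) and optionally \code{atNode}.
#' @param dt time step, ms.
#' @param rheology a \linkS4class{RheologyParams}.
#' @param seed integer seed for routing tie-breaks and phase-separation
#'   draws.
#' @return list: updated \code{rbcs} data.frame, \code{exited} count, and
#'   per-vessel \code{departures}.
#' @export
advanceRbcs <- function(net, state, rbcs, dt,
                        rheology = rheologyParams(), seed = 1L) {
    vs <- net@vessels
    vidx <- match(rbcs$vessel, vs$id)
    if (anyNA(vidx)) stop("rbcs reference unknown vessel id")
    if (any(rbcs$position < 0 | rbcs$position > vs$length[vidx]))
        stop("rbc position outside its vessel")
    atn <- if ("atNode" %in% names(rbcs)) rbcs$atNode
           else rbcs$position <= 0 | rbcs$position >= vs$length[vidx]
    ei <- .edgeIndex(net)
    res <- cpp_advance_rbcs(ei$a, ei$b, vs$diameter, vs$length,
                            net@nodes$is_boundary, state@pressures,
                            state@flows, state@tubeHematocrit,
                            as.integer(vidx), rbcs$position, atn, dt,
                            rheology@singleFileMax, as.integer(seed))
    list(rbcs = data.frame(vessel = vs$id[res$vessel],
                           position = res$position,
                           atNode = res$atNode),
         exited = res$exited, departures = res$departures)
}

#' Tube hematocrit and viscosity from tracked RBC content
#'
#' Tube hematocrit per vessel is RBC count times cell volume over vessel
#' volume, capped at \code{cap}; the discharge hematocrit follows from
#' the Fahraeus relation and the relative viscosity from the empirical
#' viscosity law.
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param rbcs data.frame with a \code{vessel} column (vessel ids).
#' @param rbcVolume um^3.
#' @param cap maximum tube hematocrit.
#' @param params a \linkS4class{RheologyParams}.
#' @return data.frame per vessel: \code{tubeHematocrit},
#'   \code{dischargeHematocrit}, \code{relativeViscosity}.
#' @export
updateHematocrit <- function(net, rbcs, rbcVolume = 55, cap = 0.9,
                             params = rheologyParams()) {
    vs <- net@vessels
    cnt <- tabulate(match(rbcs$vessel, vs$id), nbins = nrow(vs))
    vol <- pi * vs$diameter^2 / 4 * vs$length
    ht <- pmin(cnt * rbcVolume / vol, cap)
    hd <- dischargeHematocrit(ht, vs$diameter)
    data.frame(tubeHematocrit = ht, dischargeHematocrit = hd,
               relativeViscosity = relativeViscosity(vs$diameter, hd,
                                                     params))
}
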