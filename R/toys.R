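#' Toy networks with exact, documented geometry
#'
#' Small fixtures for solver and bifurcation experiments:
#' \describe{
#'   \item{single_tube}{2 nodes, 1 vessel of diameter \code{D} and length
#'     \code{L} along x.}
#'   \item{divergent_Y}{an inflow parent splitting at one bifurcation into
#'     two outflow daughters (diameters \code{Da}, \code{Db}); with equal
#'     daughters the geometry is mirror symmetric.}
#'   \item{convergent_Y}{two inflow parents merging into one outflow.}
#'   \item{two_path_loop}{inlet and outlet connected by exactly two
#'     independent paths (diameters \code{Da}, \code{Db}).}
#'   \item{honeycomb_sheet}{a planar brick-lattice capillary sheet of
#'     \code{rows} x \code{cols} cells fed by a descending arteriole at one
#'     corner and drained by an ascending venule at the opposite corner
#'     (large enough sheets host full affected-set constructions).}
#' }
#' All vessels are capillaries unless stated; every terminal node is a
#' boundary node.
#'
#' @param name one of \code{"single_tube"}, \code{"divergent_Y"},
#'   \code{"convergent_Y"}, \code{"two_path_loop"},
#'   \code{"honeycomb_sheet"}.
#' @param D,Da,Db diameters, um.
#' @param L segment length, um.
#' @param parentLength length of the Y parent segment, um (defaults to
#'   \code{L}; a long, resistive parent makes bifurcation steal visible).
#' @param rows,cols honeycomb sheet size (cells).
#' @param parentType vessel type of the parent segment of the Y toys.
#' @return a validated \linkS4class{MicrovascularNetwork}.
#' @export
toyNetwork <- function(name, D = 4, Da = 4, Db = 4, L = 100,
                       parentLength = L, rows = 6L, cols = 8L,
                       parentType = "capillary") {
    mk <- function(nodes, vessels) microvascularNetwork(nodes, vessels)
    if (name == "single_tube") {
        nodes <- data.frame(id = 1:2, x = c(0, L), y = 0, z = 50,
                            is_boundary = c(TRUE, TRUE))
        vessels <- data.frame(id = 1L, node_a = 1L, node_b = 2L,
                              diameter = D, length = L,
                              vessel_type = parentType)
        return(mk(nodes, vessels))
    }
    if (name == "divergent_Y") {
        nodes <- data.frame(id = 1:4,
                            x = c(0, parentLength, parentLength + L,
                                  parentLength + L),
                            y = c(0, 0, L / 2, -L / 2), z = 50,
                            is_boundary = c(TRUE, FALSE, TRUE, TRUE))
        len <- sqrt(L^2 + (L / 2)^2)
        vessels <- data.frame(id = 1:3, node_a = c(1L, 2L, 2L),
                              node_b = c(2L, 3L, 4L),
                              diameter = c(D, Da, Db),
                              length = c(parentLength, len, len),
                              vessel_type = c(parentType, "capillary",
                                              "capillary"))
        return(mk(nodes, vessels))
    }
    if (name == "convergent_Y") {
        nodes <- data.frame(id = 1:4,
                            x = c(0, 0, L, 2 * L),
                            y = c(L / 2, -L / 2, 0, 0), z = 50,
                            is_boundary = c(TRUE, TRUE, FALSE, TRUE))
        len <- sqrt(L^2 + (L / 2)^2)
        vessels <- data.frame(id = 1:3, node_a = c(1L, 2L, 3L),
                              node_b = c(3L, 3L, 4L),
                              diameter = c(Da, Db, D),
                              length = c(len, len, L),
                              vessel_type = "capillary")
        return(mk(nodes, vessels))
    }
    if (name == "two_path_loop") {
        nodes <- data.frame(id = 1:4,
                            x = c(0, L, 2 * L, 3 * L),
                            y = 0, z = 50,
                            is_boundary = c(TRUE, FALSE, FALSE, TRUE))
        # two parallel limbs between nodes 2 and 3 (upper and lower)
        nodes <- rbind(nodes,
                       data.frame(id = 5L, x = 1.5 * L, y = L / 2, z = 50,
                                  is_boundary = FALSE),
                       data.frame(id = 6L, x = 1.5 * L, y = -L / 2, z = 50,
                                  is_boundary = FALSE))
        half <- sqrt((L / 2)^2 + (L / 2)^2)
        vessels <- data.frame(
            id = 1:6,
            node_a = c(1L, 2L, 5L, 2L, 6L, 3L),
            node_b = c(2L, 5L, 3L, 6L, 3L, 4L),
            diameter = c(D, Da, Da, Db, Db, D),
            length = c(L, half, half, half, half, L),
            vessel_type = "capillary")
        return(mk(nodes, vessels))
    }
    if (name == "honeycomb_sheet") {
        # brick lattice: nodes on a rows x cols grid, spacing L
        gr <- expand.grid(i = seq_len(cols), j = seq_len(rows))
        nn <- nrow(gr)
        nodes <- data.frame(id = seq_len(nn), x = (gr$i - 1) * L,
                            y = (gr$j - 1) * L, z = 60,
                            is_boundary = gr$i %in% c(1L, cols) |
                                          gr$j %in% c(1L, rows))
        nid <- function(i, j) i + (j - 1L) * cols
        eh <- with(gr, cbind(nid(i, j), ifelse(i < cols, nid(i + 1L, j), NA)))
        # vertical edges only on alternating columns per row (brick pattern)
        ev <- with(gr, cbind(nid(i, j),
                             ifelse(j < rows & ((i + j) %% 2L == 0L),
                                    nid(i, j + 1L), NA)))
        ee <- rbind(eh, ev)
        ee <- ee[!is.na(ee[, 2]), , drop = FALSE]
        vessels <- data.frame(id = seq_len(nrow(ee)), node_a = ee[, 1],
                              node_b = ee[, 2], diameter = D,
                              length = L * 1.05,
                              vessel_type = "capillary")
        # feed/drain trunks at opposite corners, rising to the surface
        a1 <- nn + 1L; a2 <- nn + 2L; v1 <- nn + 3L; v2 <- nn + 4L
        nodes <- rbind(nodes, data.frame(
            id = c(a1, a2, v1, v2),
            x = c(0, 0, (cols - 1) * L, (cols - 1) * L),
            y = c(0, 0, (rows - 1) * L, (rows - 1) * L),
            z = c(30, 0, 30, 0),
            is_boundary = c(FALSE, TRUE, FALSE, TRUE)))
        nv <- nrow(vessels)
        vessels <- rbind(vessels, data.frame(
            id = nv + 1:4,
            node_a = c(a1, a2, v1, v2),
            node_b = c(nid(1L, 1L), a1, nid(cols, rows), v1),
            diameter = c(12, 14, 16, 18),
            length = c(35, 35, 35, 35),
            vessel_type = c("descending_arteriole", "descending_arteriole",
                            "ascending_venule", "ascending_venule")))
        return(mk(nodes, vessels))
    }
    stop("unknown toy network name: ", name)
}
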