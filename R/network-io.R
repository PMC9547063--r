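#' Construct a MicrovascularNetwork from node and vessel tables
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{z}, \code{is_boundary}.
#' @param vessels data.frame with columns \code{id}, \code{node_a},
#'   \code{node_b}, \code{diameter}, \code{length}, \code{vessel_type}.
#' @param validate run the full validity check (connectivity, geometry,
#'   referential integrity).  Dangling degree-1 non-boundary nodes are
#'   flagged with a warning.
#' @return a validated \linkS4class{MicrovascularNetwork}.
#' @export
microvascularNetwork <- function(nodes, vessels, validate = TRUE) {
    nodes <- as.data.frame(nodes)
    vessels <- as.data.frame(vessels)
    nodes$id <- as.integer(nodes$id)
    nodes$is_boundary <- as.logical(nodes$is_boundary)
    for (cc in c("x", "y", "z")) nodes[[cc]] <- as.numeric(nodes[[cc]])
    vessels$id <- as.integer(vessels$id)
    vessels$node_a <- as.integer(vessels$node_a)
    vessels$node_b <- as.integer(vessels$node_b)
    vessels$diameter <- as.numeric(vessels$diameter)
    vessels$length <- as.numeric(vessels$length)
    vessels$vessel_type <- as.character(vessels$vessel_type)
    rownames(nodes) <- NULL
    rownames(vessels) <- NULL
    net <- new("MicrovascularNetwork", nodes = nodes, vessels = vessels)
    if (validate) {
        validObject(net)
        deg <- .nodeDegrees(net)
        lonely <- nodes$id[deg == 1L & !nodes$is_boundary]
        if (length(lonely))
            warning(sprintf(
                "%d degree-1 node(s) not flagged as boundary (e.g. node %d)",
                length(lonely), lonely[1L]))
    }
    net
}

# node degree in node-table order
.nodeDegrees <- function(net) {
    tab <- tabulate(c(match(net@vessels$node_a, net@nodes$id),
                      match(net@vessels$node_b, net@nodes$id)),
                    nbins = nrow(net@nodes))
    tab
}

# 0-based endpoint indices for the C++ core
.edgeIndex <- function(net) {
    list(a = match(net@vessels$node_a, net@nodes$id) - 1L,
         b = match(net@vessels$node_b, net@nodes$id) - 1L)
}

# igraph view (vertices named by node id, edges carry vessel ids)
.asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        data.frame(from = as.character(net@vessels$node_a),
                   to = as.character(net@vessels$node_b),
                   vessel = net@vessels$id),
        directed = FALSE,
        vertices = data.frame(name = as.character(net@nodes$id)))
}

# vessel midpoints, n x 3 matrix
.vesselMidpoints <- function(net) {
    ia <- match(net@vessels$node_a, net@nodes$id)
    ib <- match(net@vessels$node_b, net@nodes$id)
    cbind(x = (net@nodes$x[ia] + net@nodes$x[ib]) / 2,
          y = (net@nodes$y[ia] + net@nodes$y[ib]) / 2,
          z = (net@nodes$z[ia] + net@nodes$z[ib]) / 2)
}

# node id -> incident vessel row indices
.incidence <- function(net) {
    idx <- c(seq_len(nrow(net@vessels)), seq_len(nrow(net@vessels)))
    nod <- c(match(net@vessels$node_a, net@nodes$id),
             match(net@vessels$node_b, net@nodes$id))
    split(idx, factor(nod, levels = seq_len(nrow(net@nodes))))
}

#' Load a network from CSV node and edge tables
#'
#' Canonical on-disk format: \code{nodes.csv} with header
#' \code{id,x,y,z,is_boundary} and \code{edges.csv} with header
#' \code{id,node_a,node_b,diameter_um,length_um,vessel_type}
#' (branch-order columns are read back if present).  Units are um.
#'
#' @param nodeFile,edgeFile CSV file paths.
#' @return a validated \linkS4class{MicrovascularNetwork}.
#' @export
loadNetwork <- function(nodeFile, edgeFile) {
    nd <- read.csv(nodeFile)
    ed <- read.csv(edgeFile)
    need_e <- c("id", "node_a", "node_b", "diameter_um", "length_um",
                "vessel_type")
    miss <- setdiff(need_e, names(ed))
    if (length(miss))
        stop("edge table misses column(s): ", paste(miss, collapse = ", "))
    miss <- setdiff(c("id", "x", "y", "z", "is_boundary"), names(nd))
    if (length(miss))
        stop("node table misses column(s): ", paste(miss, collapse = ", "))
    vs <- data.frame(id = ed$id, node_a = ed$node_a, node_b = ed$node_b,
                     diameter = ed$diameter_um, length = ed$length_um,
                     vessel_type = ed$vessel_type)
    for (oc in c("arteriole_order", "venule_order"))
        if (oc %in% names(ed)) vs[[oc]] <- as.integer(ed[[oc]])
    microvascularNetwork(nd, vs)
}

#' Save a network as CSV node and edge tables
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param nodeFile,edgeFile output CSV paths.
#' @return invisibly, the two file paths.
#' @export
saveNetwork <- function(net, nodeFile, edgeFile) {
    stopifnot(is(net, "MicrovascularNetwork"))
    nd <- net@nodes[, c("id", "x", "y", "z", "is_boundary")]
    vs <- net@vessels
    ed <- data.frame(id = vs$id, node_a = vs$node_a, node_b = vs$node_b,
                     diameter_um = vs$diameter, length_um = vs$length,
                     vessel_type = vs$vessel_type)
    for (oc in c("arteriole_order", "venule_order"))
        if (oc %in% names(vs)) ed[[oc]] <- vs[[oc]]
    write.csv(format(nd, digits = 17, trim = TRUE), nodeFile,
              row.names = FALSE, quote = FALSE)
    write.csv(format(ed, digits = 17, trim = TRUE), edgeFile,
              row.names = FALSE, quote = FALSE)
    invisible(c(nodeFile, edgeFile))
}

#' Export a network as GraphML for visualization tools
#'
#' @param net a \linkS4class{MicrovascularNetwork}.
#' @param file output path.
#' @export
exportGraphML <- function(net, file) {
    g <- .asIgraph(net)
    igraph::V(g)$x <- net@nodes$x
    igraph::V(g)$y <- net@nodes$y
    igraph::V(g)$z <- net@nodes$z
    igraph::V(g)$is_boundary <- net@nodes$is_boundary
    igraph::E(g)$diameter_um <- net@vessels$diameter
    igraph::E(g)$length_um <- net@vessels$length
    igraph::E(g)$vessel_type <- net@vessels$vessel_type
    igraph::write_graph(g, file, format = "graphml")
    invisible(file)
}
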