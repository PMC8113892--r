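#' Construct a zone graph
#'
#' The experimental arena is a set of compartments ("zones") connected by
#' gates. Downstream code (occupancy reconstruction, following detection,
#' simulation) depends only on this graph, so any physical arena layout can be
#' represented by supplying its gate list.
#'
#' @param zones Integer vector of zone indices.
#' @param gates Two-column matrix (or coercible) of unordered zone pairs that
#'   share a gate.
#' @param start_zone Zone in which all individuals start a trial.
#' @param target_zone Zone containing the novel food patch.
#' @return An object of class `zone_graph`.
#' @export
#' @examples
#' g <- zone_graph(1:4, rbind(c(1, 2), c(2, 3), c(3, 4)), 1, 4)
#' is_gate(g, 2, 3)
zone_graph <- function(zones, gates, start_zone = 1L, target_zone = max(zones)) {
  zones <- as.integer(zones)
  if (anyDuplicated(zones)) stop("duplicate zone indices")
  gates <- matrix(as.integer(as.matrix(gates)), ncol = 2)
  if (any(gates[, 1] == gates[, 2])) stop("a gate must join two distinct zones")
  if (!all(c(gates) %in% zones)) stop("gate refers to a zone outside the zone set")
  start_zone <- as.integer(start_zone)
  target_zone <- as.integer(target_zone)
  if (!start_zone %in% zones || !target_zone %in% zones)
    stop("start_zone and target_zone must be member zones")
  if (start_zone == target_zone) stop("start_zone must differ from target_zone")
  # canonical order so serialization round-trips exactly
  gates <- t(apply(gates, 1, sort))
  gates <- gates[order(gates[, 1], gates[, 2]), , drop = FALSE]
  if (anyDuplicated(gates)) {
    warning("duplicate gates dropped")
    gates <- gates[!duplicated(gates), , drop = FALSE]
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(gates[, 1]), to = as.character(gates[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(zones))
  )
  if (!igraph::is_connected(ig)) stop("zone graph must be connected")
  structure(
    list(zones = zones, gates = gates, start_zone = start_zone,
         target_zone = target_zone),
    class = "zone_graph"
  )
}

#' Default 3x3 lattice arena
#'
#' Nine zones arranged row-major on a 3x3 grid with rook (edge-sharing)
#' adjacency: 12 gates, start in corner zone 1, food patch in the opposite
#' corner zone 9. The true physical gate layout of a given arena may differ;
#' supply it through [zone_graph()] to override.
#'
#' @return A `zone_graph` with 9 zones and 12 gates.
#' @export
default_zone_graph <- function() {
  gates <- list()
  for (r in 0:2) {
    for (c in 0:2) {
      z <- r * 3 + c + 1
      if (c < 2) gates[[length(gates) + 1]] <- c(z, z + 1)
      if (r < 2) gates[[length(gates) + 1]] <- c(z, z + 3)
    }
  }
  zone_graph(1:9, do.call(rbind, gates), start_zone = 1L, target_zone = 9L)
}

#' Test whether two zones share a gate
#' @param graph A `zone_graph`.
#' @param a,b Zone indices (vectorized).
#' @return Logical vector.
#' @export
is_gate <- function(graph, a, b) {
  key <- paste(pmin(a, b), pmax(a, b))
  key %in% paste(graph$gates[, 1], graph$gates[, 2])
}

#' Zones adjacent to a zone
#' @param graph A `zone_graph`.
#' @param zone A single zone index.
#' @return Integer vector of neighbouring zones.
#' @export
zone_neighbors <- function(graph, zone) {
  g <- graph$gates
  sort(c(g[g[, 1] == zone, 2], g[g[, 2] == zone, 1]))
}

#' @export
print.zone_graph <- function(x, ...) {
  cat(sprintf("zone_graph: %d zones, %d gates, start %d, target %d\n",
              length(x$zones), nrow(x$gates), x$start_zone, x$target_zone))
  invisible(x)
}

#' Read / write a zone graph as YAML
#'
#' @param path File path.
#' @return `read_zone_graph` returns a `zone_graph`; `write_zone_graph`
#'   invisibly returns `path`.
#' @export
read_zone_graph <- function(path) {
  y <- yaml::read_yaml(path)
  zone_graph(unlist(y$zones),
             do.call(rbind, lapply(y$gates, unlist)),
             start_zone = y$start_zone, target_zone = y$target_zone)
}

#' @rdname read_zone_graph
#' @param graph A `zone_graph`.
#' @export
write_zone_graph <- function(graph, path) {
  yaml::write_yaml(
    list(zones = as.integer(graph$zones),
         gates = lapply(seq_len(nrow(graph$gates)),
                        function(i) as.integer(graph$gates[i, ])),
         start_zone = graph$start_zone,
         target_zone = graph$target_zone),
    path)
  invisible(path)
}
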