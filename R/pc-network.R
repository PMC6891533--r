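# Promiscuity-cliff network: construction, hub detection and alternating
# pathway extraction.

#' Build a promiscuity-cliff network
#'
#' Nodes are compounds annotated with PD and multiclass status, edges are
#' pairwise PC relationships. Duplicate cliff records collapse to a single
#' edge. The network is bipartite by construction (every edge joins a
#' highly promiscuous node to a non-promiscuous/inactive node); a violating
#' edge indicates an upstream bug and is a hard error, as are self-loops.
#'
#' @param cliffs a \linkS4class{CliffSet} or a cliff data.frame.
#' @param multiclassIds optional character vector of compound ids that are
#'   multiclass ligands; when NULL, every promiscuous node is treated as
#'   multiclass.
#' @return a \linkS4class{PCNetwork}.
#' @export
buildPCNetwork <- function(cliffs, multiclassIds = NULL) {
  if (is(cliffs, "CliffSet")) {
    df <- cliffTable(cliffs)
    pdHi <- cliffs@pdHi; pdLo <- cliffs@pdLo
  } else {
    df <- cliffs
    pdHi <- if (nrow(df) > 0) min(df$pd_promiscuous) else 10
    pdLo <- if (nrow(df) > 0) max(df$pd_partner) else 1
  }
  if (nrow(df) > 0) {
    if (any(df$promiscuous_id == df$partner_id))
      stop("self-loop in cliff list: a compound cannot cliff with itself")
    if (any(df$pd_promiscuous < pdHi) || any(df$pd_partner > pdLo))
      stop("edge violating bipartiteness: PD sides overlap (upstream bug)")
  }
  key <- paste(df$promiscuous_id, df$partner_id, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]

  if (nrow(df) > 0) {
    promPd <- tapply(df$pd_promiscuous, df$promiscuous_id, max)
    partPd <- tapply(df$pd_partner, df$partner_id, max)
    both <- intersect(names(promPd), names(partPd))
    if (length(both) > 0)
      stop("edge violating bipartiteness: node(s) on both PD sides: ",
           paste(utils::head(both, 5), collapse = ", "))
    nodes <- rbind(
      data.frame(compound_id = names(promPd), pd = as.integer(promPd),
                 role = "promiscuous", stringsAsFactors = FALSE),
      data.frame(compound_id = names(partPd), pd = as.integer(partPd),
                 role = "partner", stringsAsFactors = FALSE))
  } else {
    nodes <- data.frame(compound_id = character(0), pd = integer(0),
                        role = character(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$compound_id, method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes$multiclass <- if (is.null(multiclassIds)) nodes$role == "promiscuous"
                      else nodes$compound_id %in% multiclassIds

  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes$compound_id)
  g <- igraph::set_vertex_attr(g, "pd", value = nodes$pd)
  g <- igraph::set_vertex_attr(g, "role", value = nodes$role)
  g <- igraph::set_vertex_attr(g, "multiclass", value = nodes$multiclass)
  if (nrow(df) > 0) {
    idx <- match(c(rbind(df$promiscuous_id, df$partner_id)), nodes$compound_id)
    g <- igraph::add_edges(g, idx)
    g <- igraph::set_edge_attr(g, "transformation", value = df$transformation)
    g <- igraph::set_edge_attr(g, "shared_tested", value = df$shared_tested)
  }
  new("PCNetwork", graph = g, nodes = nodes, pdHi = pdHi, pdLo = pdLo)
}

#' Find promiscuity hubs
#'
#' Promiscuity hubs are multiclass-ligand nodes forming many PC
#' relationships. The primary rule is a fixed degree threshold (at least
#' \code{minDegree} cliffs, default 10); \code{mode = "above_average"}
#' instead flags multiclass nodes whose degree exceeds the mean degree of
#' the promiscuous side.
#'
#' @param network a \linkS4class{PCNetwork}.
#' @param minDegree fixed degree threshold (default 10).
#' @param mode "fixed" (default) or "above_average".
#' @return character vector of hub compound ids (sorted).
#' @export
findPromiscuityHubs <- function(network, minDegree = 10,
                                mode = c("fixed", "above_average")) {
  mode <- match.arg(mode)
  g <- network@graph
  if (igraph::vcount(g) == 0) return(character(0))
  deg <- igraph::degree(g)
  nodes <- network@nodes
  prom <- nodes$role == "promiscuous" & nodes$multiclass
  thr <- if (mode == "fixed") minDegree
         else mean(deg[nodes$role == "promiscuous"])
  hubs <- nodes$compound_id[prom &
    (if (mode == "fixed") deg >= thr else deg > thr)]
  sort(hubs)
}

#' Extract alternating PC pathways
#'
#' Enumerates maximal simple paths of the PC network by depth-first search
#' with lexicographic node ordering (deterministic) and a hard cap on the
#' number of enumerated paths. A path is maximal when neither endpoint has
#' a neighbor outside the path. Because the network is bipartite, every
#' path alternates between highly promiscuous and non-promiscuous
#' compounds; this is verified, not assumed.
#'
#' @param network a \linkS4class{PCNetwork}.
#' @param minLength minimum number of nodes per reported path (default 3).
#' @param maxPaths enumeration cap (default 1000).
#' @return data.frame with columns path_id, n_nodes, n_promiscuous,
#'   n_partner, nodes ("|"-separated compound ids in path order).
#' @export
extractPathways <- function(network, minLength = 3, maxPaths = 1000) {
  g <- network@graph
  nodes <- network@nodes
  n <- nrow(nodes)
  out <- list()
  if (n > 0 && igraph::ecount(g) > 0) {
    adj <- lapply(seq_len(n), function(v)
      sort(as.integer(igraph::neighbors(g, v))))
    inPath <- logical(n)
    path <- integer(0)
    emit <- function() {
      first <- path[1L]; last <- path[length(path)]
      if (any(!inPath[adj[[first]]])) return()  # extendable at the start
      if (length(path) < minLength) return()
      # canonical orientation: smaller endpoint id first
      ids <- nodes$compound_id[path]
      if (ids[length(ids)] < ids[1L]) ids <- rev(ids)
      key <- paste(ids, collapse = "|")
      if (is.null(out[[key]])) {
        out[[key]] <<- data.frame(
          n_nodes = length(path),
          n_promiscuous = sum(nodes$role[path] == "promiscuous"),
          n_partner = sum(nodes$role[path] == "partner"),
          nodes = key, stringsAsFactors = FALSE)
      }
    }
    dfs <- function(v) {
      if (length(out) >= maxPaths) return()
      path[length(path) + 1L] <<- v
      inPath[v] <<- TRUE
      nxt <- adj[[v]][!inPath[adj[[v]]]]
      if (length(nxt) == 0L) emit() else for (w in nxt) dfs(w)
      inPath[v] <<- FALSE
      path <<- path[-length(path)]
    }
    for (v in order(nodes$compound_id, method = "radix")) {
      if (length(out) >= maxPaths) break
      dfs(v)
    }
  }
  if (length(out) == 0)
    return(data.frame(path_id = integer(0), n_nodes = integer(0),
                      n_promiscuous = integer(0), n_partner = integer(0),
                      nodes = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(-df$n_nodes, df$nodes, method = "radix"), , drop = FALSE]
  # verify alternation along every reported path
  for (k in seq_len(nrow(df))) {
    ids <- strsplit(df$nodes[k], "|", fixed = TRUE)[[1]]
    roles <- nodes$role[match(ids, nodes$compound_id)]
    if (any(roles[-1] == roles[-length(roles)]))
      stop("pathway alternation violated (upstream bipartiteness bug)")
  }
  df <- data.frame(path_id = seq_len(nrow(df)), df, row.names = NULL,
                   stringsAsFactors = FALSE)
  df
}

#' Export a PC network
#'
#' Writes the edge list as TSV and the annotated graph in GraphML format.
#'
#' @param network a \linkS4class{PCNetwork}.
#' @param edgePath TSV path for the edge list (NULL to skip).
#' @param graphmlPath GraphML path (NULL to skip).
#' @return invisibly, the written paths.
#' @export
exportPCNetwork <- function(network, edgePath = NULL, graphmlPath = NULL) {
  if (!is.null(edgePath)) {
    el <- networkEdges(network)
    ea <- igraph::edge_attr(network@graph)
    el$transformation <- ea$transformation
    el$shared_tested <- ea$shared_tested
    utils::write.table(el, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphmlPath))
    igraph::write_graph(network@graph, graphmlPath, format = "graphml")
  invisible(c(edgePath, graphmlPath))
}
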