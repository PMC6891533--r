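# Accessors, subsetting and show methods for the S4 containers.

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@ids)

#' @rdname smiles
#' @export
setMethod("smiles", "CompoundSet", function(x) stats::setNames(x@smiles, x@ids))

#' @rdname nHeavyAtoms
#' @export
setMethod("nHeavyAtoms", "CompoundSet", function(x) stats::setNames(x@nHeavy, x@ids))

#' @rdname rejectedStructures
#' @export
setMethod("rejectedStructures", "CompoundSet", function(x) x@rejected)

#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' Subset a CompoundSet by index or compound id
#' @param x a CompoundSet.
#' @param i numeric, logical or character index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  if (anyNA(i)) stop("unknown compound id(s) in subset")
  initialize(x, ids = x@ids[i], smiles = x@smiles[i],
             nHeavy = x@nHeavy[i], graphs = x@graphs[i],
             rejected = x@rejected)
})

setMethod("show", "CompoundSet", function(object) {
  cat("CompoundSet with", length(object@ids), "compounds")
  if (nrow(object@rejected) > 0)
    cat(" (", nrow(object@rejected), " inputs rejected)", sep = "")
  cat("\n")
  if (length(object@ids) > 0) {
    k <- seq_len(min(3L, length(object@ids)))
    cat(paste0("  ", object@ids[k], ": ", object@smiles[k], collapse = "\n"), "\n")
    if (length(object@ids) > 3L) cat("  ...\n")
  }
})

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "ActivityProfileSet", function(x) names(x@profiles))

#' @export
setMethod("length", "ActivityProfileSet", function(x) length(x@profiles))

#' @rdname testedTargets
#' @export
setMethod("testedTargets", "ActivityProfileSet",
          function(x) lapply(x@profiles, `[[`, "tested"))

#' @rdname activeTargets
#' @export
setMethod("activeTargets", "ActivityProfileSet",
          function(x) lapply(x@profiles, `[[`, "active"))

#' @rdname discardedTargets
#' @export
setMethod("discardedTargets", "ActivityProfileSet",
          function(x) lapply(x@profiles, `[[`, "discarded"))

#' @rdname promiscuityDegree
#' @export
setMethod("promiscuityDegree", "ActivityProfileSet", function(x) {
  vapply(x@profiles, function(p) length(p$active), integer(1))
})

#' @rdname profileTable
#' @export
setMethod("profileTable", "ActivityProfileSet", function(x) {
  data.frame(
    compound_id = names(x@profiles),
    n_tested = vapply(x@profiles, function(p) length(p$tested), integer(1)),
    pd = vapply(x@profiles, function(p) length(p$active), integer(1)),
    n_discarded = vapply(x@profiles, function(p) length(p$discarded), integer(1)),
    row.names = NULL
  )
})

#' Subset an ActivityProfileSet by index or compound id
#' @param x an ActivityProfileSet.
#' @param i numeric, logical or character index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ActivityProfileSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    if (!all(i %in% names(x@profiles))) stop("unknown compound id(s) in subset")
  }
  initialize(x, profiles = x@profiles[i])
})

setMethod("show", "ActivityProfileSet", function(object) {
  pd <- promiscuityDegree(object)
  cat("ActivityProfileSet with", length(object@profiles), "compounds\n")
  if (length(pd) > 0)
    cat("  PD range:", min(pd), "-", max(pd),
        "| median tested targets:",
        stats::median(vapply(object@profiles, function(p) length(p$tested),
                             integer(1))), "\n")
})

#' @rdname mmpTable
#' @export
setMethod("mmpTable", "MMPSet", function(x) x@pairs)

#' @export
setMethod("length", "MMPSet", function(x) nrow(x@pairs))

setMethod("show", "MMPSet", function(object) {
  cat("MMPSet with", nrow(object@pairs), "matched molecular pairs over",
      length(unique(object@pairs$core)), "distinct cores\n")
})

#' @rdname cliffTable
#' @export
setMethod("cliffTable", "CliffSet", function(x) x@cliffs)

#' @export
setMethod("length", "CliffSet", function(x) nrow(x@cliffs))

setMethod("show", "CliffSet", function(object) {
  cat("CliffSet with", nrow(object@cliffs), "promiscuity cliffs (PD >=",
      object@pdHi, "vs PD <=", object@pdLo, ")\n")
})

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "PCNetwork", function(x) x@nodes)

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "PCNetwork", function(x) {
  el <- igraph::as_edgelist(x@graph)
  if (nrow(el) == 0)
    return(data.frame(promiscuous_id = character(0),
                      partner_id = character(0)))
  # igraph does not guarantee endpoint order; orient by node role
  roleOf <- stats::setNames(x@nodes$role, x@nodes$compound_id)
  swap <- roleOf[el[, 1]] != "promiscuous"
  data.frame(promiscuous_id = ifelse(swap, el[, 2], el[, 1]),
             partner_id = ifelse(swap, el[, 1], el[, 2]),
             row.names = NULL)
})

setMethod("show", "PCNetwork", function(object) {
  g <- object@graph
  cat("PCNetwork:", igraph::vcount(g), "compounds,", igraph::ecount(g),
      "PC edges,", igraph::count_components(g), "components\n")
})
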