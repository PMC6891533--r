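#' @import methods
NULL

#' CompoundSet: standardized small-molecule structures
#'
#' Container for a set of screening compounds after structure
#' standardization (largest organic fragment, simple-charge neutralization,
#' canonical SMILES). Inputs that could not be parsed are retained in a
#' rejection log rather than silently dropped.
#'
#' @slot ids character, unique compound identifiers.
#' @slot smiles character, canonical SMILES (parallel to \code{ids}).
#' @slot nHeavy integer, heavy-atom counts.
#' @slot graphs list of internal molecular graphs (parallel to \code{ids}).
#' @slot rejected data.frame with columns \code{compound_id}, \code{input},
#'   \code{reason} for structures that failed standardization.
#' @exportClass CompoundSet
setClass("CompoundSet",
         representation(ids = "character", smiles = "character",
                        nHeavy = "integer", graphs = "list",
                        rejected = "data.frame"))

setValidity("CompoundSet", function(object) {
  msg <- NULL
  n <- length(object@ids)
  if (length(object@smiles) != n || length(object@nHeavy) != n ||
      length(object@graphs) != n)
    msg <- c(msg, "ids, smiles, nHeavy and graphs must have equal length")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "compound ids must be unique")
  if (n > 0 && any(object@nHeavy < 1L))
    msg <- c(msg, "every retained molecule must have at least one heavy atom")
  if (is.null(msg)) TRUE else msg
})

#' ActivityProfileSet: aggregated per-compound activity profiles
#'
#' Each compound's qualitative screening calls are aggregated into a tested
#' set, an active set and a discarded set (targets with contradictory calls,
#' which count neither as tested nor as active). The promiscuity degree (PD)
#' of a compound is the size of its active set.
#'
#' @slot profiles named list; per compound a list with character vectors
#'   \code{tested}, \code{active}, \code{discarded}.
#' @exportClass ActivityProfileSet
setClass("ActivityProfileSet", representation(profiles = "list"))

setValidity("ActivityProfileSet", function(object) {
  msg <- NULL
  p <- object@profiles
  if (length(p) > 0 && is.null(names(p)))
    msg <- c(msg, "profiles must be named by compound id")
  for (pr in p) {
    if (!all(pr$active %in% pr$tested)) {
      msg <- c(msg, "active targets must be a subset of tested targets")
      break
    }
    if (length(intersect(pr$discarded, pr$tested)) > 0) {
      msg <- c(msg, "discarded targets must be disjoint from tested targets")
      break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' MMPSet: matched molecular pairs
#'
#' Pairs of compounds that differ by a substituent exchange at a single site
#' over an identical core, subject to transformation size restrictions.
#'
#' @slot pairs data.frame with columns \code{compound_a}, \code{compound_b},
#'   \code{core}, \code{substituent_a}, \code{substituent_b},
#'   \code{transformation}, \code{size_a}, \code{size_b}.
#' @exportClass MMPSet
setClass("MMPSet", representation(pairs = "data.frame"))

setValidity("MMPSet", function(object) {
  df <- object@pairs
  need <- c("compound_a", "compound_b", "core", "substituent_a",
            "substituent_b", "transformation", "size_a", "size_b")
  if (!all(need %in% colnames(df)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) > 0 && any(df$compound_a == df$compound_b))
    return("an MMP cannot pair a compound with itself")
  if (nrow(df) > 0 && any(df$substituent_a == df$substituent_b))
    return("MMP substituents must differ")
  TRUE
})

#' CliffSet: promiscuity cliffs
#'
#' MMPs whose members sit on opposite ends of the promiscuity scale: one
#' highly promiscuous compound (PD >= pd_hi) and one non-promiscuous
#' (PD = 1) or consistently inactive (PD = 0) analog.
#'
#' @slot cliffs data.frame with columns \code{promiscuous_id},
#'   \code{partner_id}, \code{pd_promiscuous}, \code{pd_partner},
#'   \code{core}, \code{transformation}, \code{shared_tested}.
#' @slot pdHi numeric, promiscuity threshold used.
#' @slot pdLo numeric, partner threshold used.
#' @exportClass CliffSet
setClass("CliffSet", representation(cliffs = "data.frame", pdHi = "numeric",
                                    pdLo = "numeric"))

setValidity("CliffSet", function(object) {
  df <- object@cliffs
  need <- c("promiscuous_id", "partner_id", "pd_promiscuous", "pd_partner",
            "core", "transformation", "shared_tested")
  if (!all(need %in% colnames(df)))
    return(paste("cliffs must have columns:", paste(need, collapse = ", ")))
  if (nrow(df) > 0) {
    if (any(df$pd_promiscuous < object@pdHi))
      return("pd_promiscuous below the promiscuity threshold")
    if (any(df$pd_partner > object@pdLo))
      return("pd_partner above the partner threshold")
  }
  TRUE
})

#' PCNetwork: bipartite promiscuity-cliff network
#'
#' Nodes are compounds (annotated with PD and multiclass status), edges are
#' pairwise promiscuity-cliff relationships. The graph is bipartite by
#' construction: every edge joins a highly promiscuous node to a
#' non-promiscuous or inactive node.
#'
#' @slot graph an \code{igraph} object.
#' @slot nodes data.frame with columns \code{compound_id}, \code{pd},
#'   \code{role} ("promiscuous"/"partner"), \code{multiclass}.
#' @slot pdHi numeric threshold.
#' @slot pdLo numeric threshold.
#' @exportClass PCNetwork
setClass("PCNetwork", representation(graph = "ANY", nodes = "data.frame",
                                     pdHi = "numeric", pdLo = "numeric"))
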