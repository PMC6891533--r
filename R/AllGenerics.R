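#' Compound identifiers
#' @param x a PromCliff container.
#' @return character vector of compound ids.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Canonical SMILES strings
#' @param x a \linkS4class{CompoundSet}.
#' @return named character vector of canonical SMILES.
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))

#' Heavy-atom counts
#' @param x a \linkS4class{CompoundSet}.
#' @return named integer vector.
#' @export
setGeneric("nHeavyAtoms", function(x) standardGeneric("nHeavyAtoms"))

#' Structures rejected during standardization
#' @param x a \linkS4class{CompoundSet}.
#' @return data.frame with columns compound_id, input, reason.
#' @export
setGeneric("rejectedStructures", function(x) standardGeneric("rejectedStructures"))

#' Promiscuity degree (PD)
#'
#' The number of distinct targets a compound is active against in its
#' aggregated activity profile.
#'
#' @param x an \linkS4class{ActivityProfileSet}.
#' @return named integer vector of PD values.
#' @export
setGeneric("promiscuityDegree", function(x) standardGeneric("promiscuityDegree"))

#' Tested targets per compound
#' @param x an \linkS4class{ActivityProfileSet}.
#' @return named list of character vectors.
#' @export
setGeneric("testedTargets", function(x) standardGeneric("testedTargets"))

#' Active targets per compound
#' @param x an \linkS4class{ActivityProfileSet}.
#' @return named list of character vectors.
#' @export
setGeneric("activeTargets", function(x) standardGeneric("activeTargets"))

#' Targets discarded for contradictory calls, per compound
#' @param x an \linkS4class{ActivityProfileSet}.
#' @return named list of character vectors.
#' @export
setGeneric("discardedTargets", function(x) standardGeneric("discardedTargets"))

#' Profile summary table
#' @param x an \linkS4class{ActivityProfileSet}.
#' @return data.frame with compound_id, n_tested, pd, n_discarded.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' Matched-molecular-pair table
#' @param x an \linkS4class{MMPSet}.
#' @return data.frame of pairs.
#' @export
setGeneric("mmpTable", function(x) standardGeneric("mmpTable"))

#' Promiscuity-cliff table
#' @param x a \linkS4class{CliffSet}.
#' @return data.frame of cliffs.
#' @export
setGeneric("cliffTable", function(x) standardGeneric("cliffTable"))

#' Node table of a promiscuity-cliff network
#' @param x a \linkS4class{PCNetwork}.
#' @return data.frame of nodes with PD annotations.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a promiscuity-cliff network
#' @param x a \linkS4class{PCNetwork}.
#' @return data.frame of edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
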