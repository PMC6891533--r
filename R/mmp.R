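# Matched-molecular-pair engine: single-cut fragmentation with canonical
# core indexing, transformation size restrictions, and promiscuity-cliff
# detection. This is the structural heart of the package.

# Canonical token for a hydrogen substituent (attachment-point hydrogen).
H_SUBSTITUENT <- "[*][H]"

#' Transformation size restrictions for MMP analysis
#'
#' Defaults follow the established MMP methodology with size restrictions:
#' a substituent may have at most 13 heavy atoms, the shared core must be at
#' least twice the size of each substituent, and the two exchanged
#' substituents may differ by at most 8 heavy atoms.
#'
#' @param maxSubstituent maximum substituent heavy-atom count (default 13).
#' @param minCoreRatio minimum core-to-substituent size ratio (default 2.0).
#' @param maxTransformationDiff maximum heavy-atom difference between
#'   exchanged substituents (default 8).
#' @return list of class \code{"size_restrictions"}.
#' @export
sizeRestrictions <- function(maxSubstituent = 13, minCoreRatio = 2.0,
                             maxTransformationDiff = 8) {
  stopifnot(maxSubstituent > 0, minCoreRatio > 0, maxTransformationDiff > 0)
  structure(list(maxSubstituent = maxSubstituent,
                 minCoreRatio = minCoreRatio,
                 maxTransformationDiff = maxTransformationDiff),
            class = "size_restrictions")
}

# Bond-cut fragmentations of one graph. Eligible bonds are acyclic
# (bridge) single bonds between heavy atoms; each eligible bond yields the
# (core, substituent) orientation(s) permitted by the size rule.
#' @importFrom igraph make_graph bridges delete_edges components
.bondCuts <- function(g, restrictions) {
  nb <- nrow(g$bonds)
  out <- list()
  if (nb == 0L || length(g$elements) < 2L) return(out)
  ig <- igraph::make_graph(as.vector(t(g$bonds[, c("a", "b"), drop = FALSE])),
                           n = length(g$elements), directed = FALSE)
  br <- as.integer(igraph::bridges(ig))
  for (e in br) {
    if (g$bonds[e, "order"] != 1L) next
    i <- g$bonds[e, "a"]; j <- g$bonds[e, "b"]
    if (g$elements[i] %in% c("H", "*") || g$elements[j] %in% c("H", "*")) next
    memb <- igraph::components(igraph::delete_edges(ig, e))$membership
    sideI <- which(memb == memb[i])
    sideJ <- which(memb == memb[j])
    hI <- sum(g$elements[sideI] != "H")
    hJ <- sum(g$elements[sideJ] != "H")
    addFrag <- function(coreAtoms, coreAttach, subAtoms, subAttach, hc, hs) {
      if (hs <= restrictions$maxSubstituent &&
          hc >= restrictions$minCoreRatio * hs) {
        out[[length(out) + 1L]] <<- list(
          core = .fragmentGraph(g, coreAtoms, coreAttach),
          sub = .fragmentGraph(g, subAtoms, subAttach),
          core_size = hc, sub_size = hs)
      }
    }
    addFrag(sideI, i, sideJ, j, hI, hJ)
    addFrag(sideJ, j, sideI, i, hJ, hI)
  }
  out
}

# Hydrogen-attachment fragmentations: for every heavy atom carrying at
# least one implicit hydrogen, the whole molecule with an attachment point
# at that atom is a core whose substituent is hydrogen. These make
# hydrogen-replacement MMPs (e.g. H >> Cl) discoverable during matching.
.hCuts <- function(g) {
  out <- list()
  allAtoms <- seq_along(g$elements)
  for (a in which(g$implH >= 1L & g$elements != "H" & g$elements != "*")) {
    out[[length(out) + 1L]] <- list(
      core = .fragmentGraph(g, allAtoms, a), sub = NULL,
      core_size = g$nHeavy, sub_size = 0L)
  }
  out
}

# Full fragmentation table for a CompoundSet: one row per fragmentation
# with canonical core and substituent strings (batch-canonicalized).
.fragmentTable <- function(compounds, restrictions, includeH = FALSE) {
  frags <- list()
  owner <- character(0)
  for (k in seq_along(compounds@ids)) {
    g <- compounds@graphs[[k]]
    fr <- .bondCuts(g, restrictions)
    if (includeH) fr <- c(fr, .hCuts(g))
    if (length(fr) > 0) {
      frags <- c(frags, fr)
      owner <- c(owner, rep(compounds@ids[k], length(fr)))
    }
  }
  if (length(frags) == 0)
    return(data.frame(compound_id = character(0), core = character(0),
                      substituent = character(0), core_size = integer(0),
                      substituent_size = integer(0), stringsAsFactors = FALSE))
  graphsToCanon <- c(lapply(frags, `[[`, "core"),
                     lapply(frags, function(f) f$sub))
  isNull <- vapply(graphsToCanon, is.null, logical(1))
  canon <- rep(H_SUBSTITUENT, length(graphsToCanon))
  canon[!isNull] <- .canonicalizeGraphs(graphsToCanon[!isNull])
  n <- length(frags)
  df <- data.frame(
    compound_id = owner,
    core = canon[seq_len(n)],
    substituent = canon[n + seq_len(n)],
    core_size = vapply(frags, function(f) as.integer(f$core_size), integer(1)),
    substituent_size = vapply(frags, function(f) as.integer(f$sub_size),
                              integer(1)),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$core) & !is.na(df$substituent), , drop = FALSE]
  df[!duplicated(df[c("compound_id", "core", "substituent")]), , drop = FALSE]
}

#' Enumerate single-cut fragmentations
#'
#' Cuts every eligible bond (acyclic single bond between heavy atoms) of
#' each molecule once, producing a core and a substituent fragment with
#' matching attachment points (encoded as the wildcard atom \code{*} in the
#' canonical fragment SMILES). The (core, substituent) orientation is
#' decided by the size rule in \code{restrictions}; cuts whose fragments
#' violate the per-molecule restrictions are not returned. Molecules with
#' no eligible bond (e.g. benzene, single atoms) yield no rows.
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param restrictions a \code{\link{sizeRestrictions}} object.
#' @return data.frame with columns compound_id, core, substituent,
#'   core_size, substituent_size.
#' @examples
#' cs <- standardizeMolecules(c("c1ccccc1", "CCc1ccccc1"),
#'                            ids = c("benzene", "ethylbenzene"))
#' enumerateSingleCuts(cs)   # benzene contributes no fragmentations
#' @export
enumerateSingleCuts <- function(compounds, restrictions = sizeRestrictions()) {
  stopifnot(is(compounds, "CompoundSet"),
            inherits(restrictions, "size_restrictions"))
  .fragmentTable(compounds, restrictions, includeH = FALSE)
}

#' Find matched molecular pairs
#'
#' Systematic MMP search by canonical core indexing: two compounds form an
#' MMP when they share an identical canonical core and differ in the
#' substituent at its attachment point (a single-site transformation).
#' Hydrogen counts as a substituent, so hydrogen-replacement pairs
#' (e.g. H >> Cl) are found. All transformation size restrictions are
#' enforced; the result contains no duplicate unordered pairs, and is
#' independent of input order.
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param restrictions a \code{\link{sizeRestrictions}} object.
#' @return an \linkS4class{MMPSet}.
#' @examples
#' cs <- standardizeMolecules(c("c1ccccc1", "Clc1ccccc1"),
#'                            ids = c("benzene", "chlorobenzene"))
#' mmpTable(findMMPs(cs))    # one pair, transformation [*][H] >> [*]Cl
#' @export
findMMPs <- function(compounds, restrictions = sizeRestrictions()) {
  stopifnot(is(compounds, "CompoundSet"),
            inherits(restrictions, "size_restrictions"))
  ft <- .fragmentTable(compounds, restrictions, includeH = TRUE)
  empty <- data.frame(compound_a = character(0), compound_b = character(0),
                      core = character(0), substituent_a = character(0),
                      substituent_b = character(0),
                      transformation = character(0),
                      size_a = integer(0), size_b = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(ft) == 0) return(new("MMPSet", pairs = empty))

  rows <- list()
  for (grp in split(seq_len(nrow(ft)), ft$core)) {
    if (length(grp) < 2L) next
    for (x in seq_along(grp)[-length(grp)]) {
      for (y in seq((x + 1L), length(grp))) {
        i <- grp[x]; j <- grp[y]
        if (ft$compound_id[i] == ft$compound_id[j]) next
        if (ft$substituent[i] == ft$substituent[j]) next
        if (abs(ft$substituent_size[i] - ft$substituent_size[j]) >
            restrictions$maxTransformationDiff) next
        if (ft$compound_id[i] > ft$compound_id[j]) { tmp <- i; i <- j; j <- tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          compound_a = ft$compound_id[i], compound_b = ft$compound_id[j],
          core = ft$core[i],
          substituent_a = ft$substituent[i], substituent_b = ft$substituent[j],
          transformation = paste(ft$substituent[i], ">>", ft$substituent[j]),
          size_a = ft$substituent_size[i], size_b = ft$substituent_size[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(new("MMPSet", pairs = empty))
  df <- do.call(rbind, rows)
  # One record per unordered pair: prefer the smallest transformation,
  # breaking ties lexicographically for determinism.
  key <- paste(df$compound_a, df$compound_b, sep = "\r")
  ord <- order(key, pmax(df$size_a, df$size_b), df$transformation,
               method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$compound_a, df$compound_b, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  new("MMPSet", pairs = df)
}

#' Reassemble a core and substituent into a whole molecule
#'
#' Joins the attachment points (wildcard \code{*} atoms) of a canonical core
#' and substituent fragment by a single bond and returns the canonical
#' SMILES of the product; a hydrogen substituent restores the implicit
#' hydrogen. Used to verify the reconstruction invariant of MMP
#' fragmentation.
#'
#' @param core canonical core fragment SMILES (one \code{*}).
#' @param substituent canonical substituent fragment SMILES (one \code{*}),
#'   or the hydrogen token \code{"[*][H]"}.
#' @return canonical SMILES of the reassembled molecule.
#' @export
weldFragments <- function(core, substituent) {
  gs <- .graphsFromSmiles(core)
  gc <- gs[[1]]
  if (is.null(gc)) stop("could not parse core fragment: ", core)
  starC <- which(gc$elements == "*")
  if (length(starC) != 1L) stop("core must contain exactly one * atom")
  nbrC <- .starNeighbor(gc, starC)
  if (substituent == H_SUBSTITUENT || substituent %in% c("*[H]", "[H][*]")) {
    keep <- setdiff(seq_along(gc$elements), starC)
    joined <- .dropAtoms(gc, starC)
  } else {
    gsub <- .graphsFromSmiles(substituent)[[1]]
    if (is.null(gsub)) stop("could not parse substituent fragment: ", substituent)
    starS <- which(gsub$elements == "*")
    if (length(starS) != 1L) stop("substituent must contain exactly one * atom")
    nbrS <- .starNeighbor(gsub, starS)
    a <- .dropAtoms(gc, starC)
    b <- .dropAtoms(gsub, starS)
    off <- length(a$elements)
    joined <- list(
      elements = c(a$elements, b$elements),
      bonds = rbind(a$bonds,
                    cbind(a = b$bonds[, "a"] + off, b = b$bonds[, "b"] + off,
                          order = b$bonds[, "order"]),
                    c(a = attr(a, "map")[nbrC], b = attr(b, "map")[nbrS] + off,
                      order = 1L)),
      charges = c(a$charges, b$charges),
      nHeavy = a$nHeavy + b$nHeavy)
  }
  out <- .canonicalizeGraphs(list(joined))
  if (is.na(out)) stop("reassembly produced an unparseable structure")
  out
}

.starNeighbor <- function(g, star) {
  hit <- g$bonds[, "a"] == star | g$bonds[, "b"] == star
  nb <- setdiff(as.vector(g$bonds[hit, c("a", "b")]), star)
  if (length(nb) != 1L) stop("attachment atom must have exactly one neighbor")
  nb
}

# Remove atoms (by index) from a graph, renumbering bonds; the index map is
# attached as an attribute.
.dropAtoms <- function(g, drop) {
  keep <- setdiff(seq_along(g$elements), drop)
  map <- integer(length(g$elements))
  map[keep] <- seq_along(keep)
  sel <- !(g$bonds[, "a"] %in% drop) & !(g$bonds[, "b"] %in% drop)
  bonds <- g$bonds[sel, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds[, "a"] <- map[bonds[, "a"]]
    bonds[, "b"] <- map[bonds[, "b"]]
  }
  out <- list(elements = g$elements[keep], bonds = bonds,
              charges = g$charges[keep],
              nHeavy = sum(!g$elements[keep] %in% c("H", "*")))
  attr(out, "map") <- map
  out
}

#' Detect promiscuity cliffs
#'
#' A promiscuity cliff (PC) is an MMP joining a highly promiscuous compound
#' (PD >= \code{pdHi}) to a non-promiscuous (PD = 1) or consistently
#' inactive (PD = 0) analog. For every cliff, the number of tested targets
#' shared by both members is recorded as a confidence measure. MMP members
#' without an activity profile are skipped (and counted in the
#' \code{"skipped"} attribute), never silently dropped.
#'
#' @param mmps an \linkS4class{MMPSet}.
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param pdHi promiscuous-side threshold (default 10).
#' @param pdLo partner-side threshold (default 1).
#' @return a \linkS4class{CliffSet}.
#' @export
detectPromiscuityCliffs <- function(mmps, profiles, pdHi = 10, pdLo = 1) {
  stopifnot(is(mmps, "MMPSet"), is(profiles, "ActivityProfileSet"),
            pdLo < pdHi)
  pd <- promiscuityDegree(profiles)
  tested <- testedTargets(profiles)
  df <- mmps@pairs
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(df))) {
    a <- df$compound_a[k]; b <- df$compound_b[k]
    if (!(a %in% names(pd)) || !(b %in% names(pd))) {
      skipped <- skipped + 1L
      next
    }
    pa <- pd[[a]]; pb <- pd[[b]]
    if (pa >= pdHi && pb <= pdLo) {
      prom <- a; part <- b; pp <- pa; ppart <- pb
      trans <- paste(df$substituent_a[k], ">>", df$substituent_b[k])
    } else if (pb >= pdHi && pa <= pdLo) {
      prom <- b; part <- a; pp <- pb; ppart <- pa
      trans <- paste(df$substituent_b[k], ">>", df$substituent_a[k])
    } else next
    rows[[length(rows) + 1L]] <- data.frame(
      promiscuous_id = prom, partner_id = part,
      pd_promiscuous = pp, pd_partner = ppart,
      core = df$core[k], transformation = trans,
      shared_tested = length(intersect(tested[[prom]], tested[[part]])),
      stringsAsFactors = FALSE)
  }
  cliffs <- if (length(rows) == 0) {
    data.frame(promiscuous_id = character(0), partner_id = character(0),
               pd_promiscuous = integer(0), pd_partner = integer(0),
               core = character(0), transformation = character(0),
               shared_tested = integer(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(cliffs) <- NULL
  out <- new("CliffSet", cliffs = cliffs, pdHi = pdHi, pdLo = pdLo)
  attr(out@cliffs, "skipped") <- skipped
  out
}
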