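# Lightweight molecular graph used by the MMP fragmentation engine.
# Graphs are derived from OpenBabel-written (kekulized) SDF blocks parsed by
# ChemmineR; only connectivity, bond orders, element symbols and formal
# charges are retained. Attachment points are the dummy element "*".

# Default valences for implicit-hydrogen computation on neutral atoms.
.VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
              Cl = 1, Br = 1, I = 1, "*" = 0)

# MDL legacy charge codes (molfile atom-block field) -> formal charge.
.MDL_CHARGE <- c("0" = 0, "1" = 3, "2" = 2, "3" = 1, "4" = 0, "5" = -1,
                 "6" = -2, "7" = -3)

.implicitH <- function(elements, bondOrderSum, charges) {
  val <- .VALENCE[elements]
  val[is.na(val)] <- 0
  adj <- ifelse(elements %in% c("N", "P", "O", "S", "C"), charges, 0)
  pmax(0L, as.integer(val + adj - bondOrderSum))
}

# Parse one ChemmineR SDF object into a graph list. Single-atom molecules
# (no bond block) are supported.
#' @importFrom ChemmineR atomblock bondblock
.graphFromSDF <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  chg <- rep(0L, n)
  if ("C6" %in% colnames(ab)) {
    code <- as.character(ab[, "C6"])
    chg <- as.integer(.MDL_CHARGE[code])
    chg[is.na(chg)] <- 0L
  }
  bb <- try(ChemmineR::bondblock(sdf), silent = TRUE)
  if (inherits(bb, "try-error") || is.null(dim(bb)) || nrow(bb) == 0L ||
      ncol(bb) < 3L) {
    bonds <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
  } else {
    bonds <- cbind(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  ordSum <- rep(0L, n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      ordSum[bonds[k, "a"]] <- ordSum[bonds[k, "a"]] + bonds[k, "order"]
      ordSum[bonds[k, "b"]] <- ordSum[bonds[k, "b"]] + bonds[k, "order"]
    }
  }
  list(elements = elements, bonds = bonds, charges = chg,
       implH = .implicitH(elements, ordSum, chg),
       nHeavy = sum(elements != "H" & elements != "*"))
}

# Batch: SMILES vector -> list of graphs (NULL where conversion failed).
#' @importFrom ChemmineR read.SDFset
.graphsFromSmiles <- function(smiles) {
  n <- length(smiles)
  res <- vector("list", n)
  if (n == 0L) return(res)
  titles <- .mkTitles(n)
  sdfstr <- .obConvert("SMI", "SDF", .smiInput(smiles, titles))
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) return(res)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(lines))
  got <- vapply(ChemmineR::SDFset2SDF(sdfs), function(s) s@header[["Molecule_Name"]],
                character(1))
  idx <- match(got, titles)
  for (k in seq_along(idx)) {
    if (!is.na(idx[k])) res[[idx[k]]] <- .graphFromSDF(sdfs[[k]])
  }
  res
}

# Write a graph (possibly holding "*" atoms) as a V2000 molfile block.
# Zero coordinates; OpenBabel re-perceives aromaticity from the kekulized
# bond orders.
.molfileFromGraph <- function(g, title) {
  n <- length(g$elements)
  nb <- nrow(g$bonds)
  atomLines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, g$elements)
  bondLines <- if (nb > 0L) {
    sprintf("%3d%3d%3d%3d", g$bonds[, "a"], g$bonds[, "b"], g$bonds[, "order"], 0L)
  } else character(0)
  chgIdx <- which(g$charges != 0L)
  chgLines <- if (length(chgIdx) > 0L) {
    vapply(chgIdx, function(i) sprintf("M  CHG  1 %3d %3d", i, g$charges[i]),
           character(1))
  } else character(0)
  paste(c(title, "  PromCliff", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
          atomLines, bondLines, chgLines, "M  END", "$$$$"),
        collapse = "\n")
}

# Batch-canonicalize fragment graphs: list of graphs -> canonical SMILES
# (NA where OpenBabel failed).
.canonicalizeGraphs <- function(graphs) {
  n <- length(graphs)
  if (n == 0L) return(character(0))
  titles <- .mkTitles(n)
  blocks <- vapply(seq_len(n), function(i) .molfileFromGraph(graphs[[i]], titles[i]),
                   character(1))
  out <- .obConvert("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"))
  got <- .parseSmiOutput(out)
  res <- rep(NA_character_, n)
  hit <- match(titles, names(got))
  ok <- !is.na(hit)
  res[ok] <- unname(got[hit[ok]])
  res
}

# Induced subgraph on `keep` atoms plus a "*" attachment atom bonded to
# `attachTo` (index within the parent graph, must be in `keep`).
.fragmentGraph <- function(g, keep, attachTo) {
  keep <- sort(keep)
  map <- integer(length(g$elements))
  map[keep] <- seq_along(keep)
  bsel <- g$bonds[, "a"] %in% keep & g$bonds[, "b"] %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds[, "a"] <- map[bonds[, "a"]]
    bonds[, "b"] <- map[bonds[, "b"]]
  }
  star <- length(keep) + 1L
  bonds <- rbind(bonds, c(a = map[attachTo], b = star, order = 1L))
  list(elements = c(g$elements[keep], "*"),
       bonds = bonds,
       charges = c(g$charges[keep], 0L),
       implH = NULL,
       nHeavy = sum(g$elements[keep] != "H" & g$elements[keep] != "*"))
}
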