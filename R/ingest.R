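# Ingest: table readers, structure standardization, profile aggregation and
# the extensively-tested compound filter.

.OUTCOMES <- c("active", "inactive")

#' Read a compound table
#'
#' Tab-separated with a header row; requires columns \code{compound_id} and
#' \code{smiles}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCompoundTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "smiles")
  if (!all(need %in% colnames(df)))
    stop("compound table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read an activity-call table
#'
#' Tab-separated with a header row; requires columns \code{compound_id},
#' \code{assay_id}, \code{target_id}, \code{outcome}. Outcomes must be
#' exactly "active" or "inactive" (the analysis is qualitative; no potency
#' values are used).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readActivityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "assay_id", "target_id", "outcome")
  if (!all(need %in% colnames(df)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$outcome), .OUTCOMES)
  if (length(bad) > 0)
    stop("unknown outcome token(s): ", paste(sQuote(bad), collapse = ", "))
  df
}

#' Read a target table
#'
#' Tab-separated with a header row; requires columns \code{target_id} and
#' \code{protein_name}; \code{family_name} and \code{class_label} are
#' optional and filled with empty strings when absent.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTargetTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("target_id", "protein_name")
  if (!all(need %in% colnames(df)))
    stop("target table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$target_id))
    stop("target ids must be unique within a target table")
  if (is.null(df$family_name)) df$family_name <- ""
  if (is.null(df$class_label)) df$class_label <- ""
  df$family_name[is.na(df$family_name)] <- ""
  df$class_label[is.na(df$class_label)] <- ""
  df
}

#' Standardize compound structures
#'
#' Standardization keeps the largest organic (contiguous) fragment,
#' neutralizes simple charges and writes canonical SMILES; tautomers are
#' canonicalized as given (no tautomer enumeration). The recipe is
#' idempotent: re-standardizing a standardized structure is a no-op.
#' Unparseable inputs are never silently dropped; they are collected in the
#' rejection log (see \code{\link{rejectedStructures}}).
#'
#' @param smiles character vector of raw SMILES, or a data.frame with
#'   columns \code{compound_id} and \code{smiles}.
#' @param ids compound identifiers (ignored when \code{smiles} is a
#'   data.frame). Defaults to \code{CPD<i>}.
#' @return a \linkS4class{CompoundSet}.
#' @examples
#' cs <- standardizeMolecules(c("OCC", "CCO", "C1=CC=CC=C1"),
#'                            ids = c("a", "b", "benzene"))
#' smiles(cs)       # "a" and "b" collapse to the same canonical form
#' nHeavyAtoms(cs)
#' @export
standardizeMolecules <- function(smiles, ids = NULL) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$compound_id)
    smiles <- as.character(smiles$smiles)
  }
  if (is.null(ids)) ids <- sprintf("CPD%d", seq_along(smiles))
  ids <- as.character(ids)
  if (length(ids) != length(smiles)) stop("ids and smiles lengths differ")
  if (anyDuplicated(ids)) stop("compound ids must be unique")

  smiles <- as.character(smiles)
  empty <- is.na(smiles) | !nzchar(trimws(smiles))
  canon <- rep(NA_character_, length(smiles))
  canon[!empty] <- .canonicalSmiles(smiles[!empty], standardize = TRUE)

  reason <- rep(NA_character_, length(smiles))
  reason[empty] <- "empty_input"
  reason[!empty & is.na(canon)] <- "parse_error"

  keep <- is.na(reason)
  graphs <- .graphsFromSmiles(canon[keep])
  gFail <- vapply(graphs, is.null, logical(1))
  if (any(gFail)) {
    reason[which(keep)[gFail]] <- "parse_error"
    keep <- is.na(reason)
    graphs <- graphs[!gFail]
  }
  nHeavy <- vapply(graphs, function(g) as.integer(g$nHeavy), integer(1))
  zero <- nHeavy < 1L
  if (any(zero)) {
    reason[which(keep)[zero]] <- "no_heavy_atoms"
    keep <- is.na(reason)
    graphs <- graphs[!zero]
    nHeavy <- nHeavy[!zero]
  }

  rejected <- data.frame(compound_id = ids[!keep], input = smiles[!keep],
                         reason = reason[!keep], row.names = NULL,
                         stringsAsFactors = FALSE)
  new("CompoundSet", ids = ids[keep], smiles = unname(canon[keep]),
      nHeavy = nHeavy, graphs = graphs, rejected = rejected)
}

#' Write the rejected-structure log
#'
#' @param compounds a \linkS4class{CompoundSet}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeRejectedLog <- function(compounds, path) {
  utils::write.table(rejectedStructures(compounds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate activity calls into consistent per-compound profiles
#'
#' Multiple assays of the same compound-target pair must consistently report
#' the same qualitative outcome; consistent duplicates collapse to a single
#' call, while a pair with at least one "active" and one "inactive" call is
#' discarded entirely (it counts neither as tested nor towards PD).
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{assay_id}, \code{target_id}, \code{outcome}.
#' @return an \linkS4class{ActivityProfileSet}.
#' @examples
#' rec <- data.frame(compound_id = "C1", assay_id = c("A1", "A2", "A1"),
#'                   target_id = c("T1", "T1", "T2"),
#'                   outcome = c("active", "inactive", "active"))
#' prof <- aggregateProfiles(rec)
#' promiscuityDegree(prof)      # T1 is contradictory -> PD counts only T2
#' discardedTargets(prof)
#' @export
aggregateProfiles <- function(records) {
  bad <- setdiff(unique(records$outcome), .OUTCOMES)
  if (length(bad) > 0)
    stop("unknown outcome token(s): ", paste(sQuote(bad), collapse = ", "))
  if (nrow(records) == 0) return(new("ActivityProfileSet", profiles = list()))

  cid <- as.character(records$compound_id)
  tid <- as.character(records$target_id)
  key <- paste(cid, tid, sep = "\r")
  m <- rowsum(cbind(act = as.integer(records$outcome == "active"),
                    inact = as.integer(records$outcome == "inactive")),
              group = key, reorder = FALSE)
  keys <- rownames(m)
  sp <- regmatches(keys, regexpr("\r", keys), invert = TRUE)
  kc <- vapply(sp, `[`, character(1), 1L)
  kt <- vapply(sp, `[`, character(1), 2L)
  status <- ifelse(m[, "act"] > 0 & m[, "inact"] > 0, "discarded",
                   ifelse(m[, "act"] > 0, "active", "inactive"))

  ord <- order(kc, kt, method = "radix")
  kc <- kc[ord]; kt <- kt[ord]; status <- status[ord]
  profiles <- lapply(split(seq_along(kc), factor(kc, levels = unique(kc))),
                     function(ii) {
    st <- status[ii]; tg <- kt[ii]
    list(tested = tg[st != "discarded"],
         active = tg[st == "active"],
         discarded = tg[st == "discarded"])
  })
  new("ActivityProfileSet", profiles = profiles)
}

#' Select extensively tested compounds
#'
#' Retains compounds tested against at least \code{minTargets} distinct
#' targets, counted after conflict discarding. The default of 100 reflects
#' the test-frequency requirement of large-scale promiscuity analysis.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param minTargets minimum number of distinct tested targets (default 100).
#' @return a filtered \linkS4class{ActivityProfileSet}.
#' @export
selectExtensivelyTested <- function(profiles, minTargets = 100) {
  stopifnot(minTargets >= 1)
  keep <- vapply(profiles@profiles, function(p) length(p$tested) >= minTargets,
                 logical(1))
  new("ActivityProfileSet", profiles = profiles@profiles[keep])
}
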