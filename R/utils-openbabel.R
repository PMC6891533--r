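# Thin wrappers around ChemmineOB/OpenBabel. Everything chemical that is not
# the package's own contribution (parsing, canonicalization, SMARTS, FP2
# fingerprints, atomic-contribution logP) is delegated here.

# Internal molecule titles: user-facing ids may contain whitespace, so batch
# conversions always run under synthetic titles "m<i>" and are mapped back by
# position in the title, never by output order.
.mkTitles <- function(n) sprintf("m%d", seq_len(n))

.smiInput <- function(smiles, titles) {
  paste0(paste(smiles, titles, sep = "\t"), "\n", collapse = "")
}

# Parse "SMILES\ttitle" lines emitted by OpenBabel into a titled character
# vector. Molecules OpenBabel failed to read are simply absent from the
# output, which is how parse failures are detected.
.parseSmiOutput <- function(out) {
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(character(0))
  parts <- regmatches(lines, regexpr("\t", lines), invert = TRUE)
  smi <- vapply(parts, `[`, character(1), 1L)
  ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", character(1)))
  names(smi) <- ttl
  smi
}

#' @importFrom ChemmineOB convertFormat
.obConvert <- function(from, to, src, options = NULL) {
  if (is.null(options)) options <- data.frame(names = character(0), args = character(0))
  ChemmineOB::convertFormat(from, to, src, options = options)
}

# Canonical SMILES for a vector of SMILES strings; NA where OpenBabel cannot
# parse the input. With standardize = TRUE the largest contiguous fragment is
# kept and simple charges are neutralized first (screening-data practice).
# OpenBabel aborts a batch conversion at the first unparseable record, so the
# batch is resumed past each failure until every record is accounted for.
.canonicalSmiles <- function(smiles, standardize = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  titles <- .mkTitles(n)
  opts <- if (standardize) {
    data.frame(names = c("r", "neutralize"), args = c("", ""))
  } else NULL
  res <- rep(NA_character_, n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    out <- tryCatch(
      .obConvert("SMI", "CAN", .smiInput(smiles[todo], titles[todo]),
                 options = opts),
      error = function(e) "")
    got <- .parseSmiOutput(out)
    hit <- match(titles[todo], names(got))
    emitted <- !is.na(hit)
    res[todo[emitted]] <- unname(got[hit[emitted]])
    if (all(emitted)) break
    # the first non-emitted record is the one OpenBabel choked on
    todo <- todo[!emitted][-1L]
  }
  res[!is.na(res) & !nzchar(res)] <- NA_character_
  res
}

# Wildman-Crippen logP (sum of atomic contributions) via the OpenBabel logP
# descriptor, appended to a SMILES round trip so that single-atom molecules
# are handled uniformly.
.obLogP <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(numeric(0))
  titles <- .mkTitles(n)
  out <- .obConvert("SMI", "SMI", .smiInput(smiles, titles),
                    options = data.frame(names = "append", args = "logP"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_real_, n)
  for (ln in lines) {
    p <- strsplit(ln, "[\t ]+")[[1]]
    if (length(p) >= 3L) {
      i <- match(p[2L], titles)
      if (!is.na(i)) res[i] <- suppressWarnings(as.numeric(p[3L]))
    }
  }
  res
}

#' @importFrom ChemmineOB forEachMol prop_OB smartsSearch_OB fingerprint_OB
.obMolRefs <- function(smiles) {
  titles <- .mkTitles(length(smiles))
  ChemmineOB::forEachMol("SMILES", .smiInput(smiles, titles), identity)
}

# Count of (non-unique) substructure matches of one SMARTS pattern against
# each molecule. A malformed pattern raises a condition that callers turn
# into a named hard error.
.smartsCounts <- function(molRefs, smarts) {
  ChemmineOB::smartsSearch_OB(molRefs, smarts, uniqueMatches = FALSE)
}

# FP2 path-based fingerprints as a 0/1 matrix (rows = molecules).
.fp2Matrix <- function(smiles) {
  if (length(smiles) == 0L) return(matrix(0, nrow = 0, ncol = 1024))
  x <- ChemmineOB::fingerprint_OB(.obMolRefs(smiles), "FP2")
  if (is.vector(x)) x <- t(as.matrix(x))
  x
}

# Tanimoto similarity between every row of a and every row of b.
.tanimotoMatrix <- function(a, b) {
  inter <- a %*% t(b)
  ca <- rowSums(a)
  cb <- rowSums(b)
  denom <- outer(ca, cb, `+`) - inter
  out <- inter / denom
  out[denom == 0] <- 0
  out
}
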