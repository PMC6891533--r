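# Promiscuity-degree census and distribution summaries.

#' Default promiscuity-degree bins
#'
#' The census rows used throughout: all compounds, the exact bins PD = 0 and
#' PD = 1, and the nested threshold bins PD >= 2, 5, 10, 15.
#'
#' @return data.frame with columns label, type ("all", "eq", "ge"), value.
#' @export
defaultPdBins <- function() {
  data.frame(label = c("all", "PD = 0", "PD = 1", "PD >= 2", "PD >= 5",
                       "PD >= 10", "PD >= 15"),
             type = c("all", "eq", "eq", "ge", "ge", "ge", "ge"),
             value = c(NA, 0, 1, 2, 5, 10, 15),
             stringsAsFactors = FALSE)
}

.binMembers <- function(pd, bin) {
  switch(bin$type,
         all = rep(TRUE, length(pd)),
         eq = pd == bin$value,
         ge = pd >= bin$value,
         stop("unknown bin type: ", bin$type))
}

#' Promiscuity-degree census
#'
#' Counts compounds per PD bin. When the default bins are used the census is
#' checked for conservation (\code{PD=0 + PD=1 + PD>=2 = all}) and for
#' non-increasing counts over the nested threshold bins; a violation is an
#' assertion failure, not a warning.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}, or a numeric vector
#'   of PD values.
#' @param bins bin definition (see \code{\link{defaultPdBins}}).
#' @return data.frame with columns label, count; attribute \code{"pd"}
#'   carries the underlying PD vector.
#' @examples
#' pdCensus(c(0, 0, 0, 1, 1, 2, 10))
#' @export
pdCensus <- function(profiles, bins = defaultPdBins()) {
  pd <- if (is(profiles, "ActivityProfileSet")) promiscuityDegree(profiles)
        else as.numeric(profiles)
  counts <- vapply(seq_len(nrow(bins)), function(i)
    sum(.binMembers(pd, bins[i, ])), integer(1))
  out <- data.frame(label = bins$label, count = counts,
                    stringsAsFactors = FALSE)
  eq <- bins$type == "eq"
  ge <- bins$type == "ge"
  if (any(bins$type == "all") && setequal(bins$value[eq], c(0, 1)) &&
      2 %in% bins$value[ge]) {
    total <- counts[bins$type == "all"][1]
    parts <- sum(counts[eq]) + counts[ge & bins$value == 2][1]
    if (parts != total)
      stop("census conservation violated: PD=0 + PD=1 + PD>=2 != all")
  }
  geOrd <- order(bins$value[ge])
  if (any(diff(counts[ge][geOrd]) > 0))
    stop("census nesting violated: counts over nested >= bins must be non-increasing")
  attr(out, "pd") <- pd
  out
}

# Five-number summary with 1.5*IQR whiskers. Quartiles use linear
# interpolation between order statistics (quantile type 7); min/max are the
# extremes of the non-outlying points, and outliers beyond the whisker
# fences are listed separately (standard boxplot semantics).
.fiveNumber <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0)
    return(list(n = 0L, min = NA_real_, q1 = NA_real_, median = NA_real_,
                q3 = NA_real_, max = NA_real_, outliers = numeric(0)))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v >= lo & v <= hi
  list(n = n, min = min(v[inside]), q1 = q[1], median = q[2], q3 = q[3],
       max = max(v[inside]), outliers = sort(v[!inside]))
}

.summarizeGroups <- function(values, members, labels) {
  rows <- lapply(seq_along(labels), function(i) {
    s <- .fiveNumber(values[members[[i]]])
    data.frame(group = labels[i], n = s$n, min = s$min, q1 = s$q1,
               median = s$median, q3 = s$q3, max = s$max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "outliers") <- stats::setNames(
    lapply(seq_along(labels),
           function(i) .fiveNumber(values[members[[i]]])$outliers), labels)
  out
}

#' Tested-target distributions per promiscuity bin
#'
#' Five-number summaries (plus boxplot outliers) of the number of tested
#' targets per compound, for each PD bin. This is the tested-target
#' distribution analysis that verifies promiscuity is not an artifact of
#' test frequency.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param bins PD bin definition (see \code{\link{defaultPdBins}}).
#' @return data.frame with columns group, n, min, q1, median, q3, max and an
#'   \code{"outliers"} attribute (named list of values beyond the 1.5*IQR
#'   whiskers).
#' @export
testedDistributionByPd <- function(profiles, bins = defaultPdBins()) {
  pd <- promiscuityDegree(profiles)
  nTested <- vapply(profiles@profiles, function(p) length(p$tested), integer(1))
  members <- lapply(seq_len(nrow(bins)), function(i)
    which(.binMembers(pd, bins[i, ])))
  .summarizeGroups(as.numeric(nTested), members, bins$label)
}

#' logP distributions per promiscuity stratum
#'
#' Five-number summaries of atomic-contribution logP per PD stratum, with
#' optional Gaussian kernel density estimates (bandwidth by Scott's rule)
#' for plotting. Profiled compounds without a resolvable structure are
#' skipped.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param compounds a \linkS4class{CompoundSet}.
#' @param strata PD bin definition (see \code{\link{defaultPdBins}}).
#' @param density logical; attach per-stratum \code{stats::density} objects
#'   as a \code{"density"} attribute.
#' @return data.frame as in \code{\link{testedDistributionByPd}} but over
#'   logP values.
#' @export
logpDistributionByPd <- function(profiles, compounds,
                                 strata = defaultPdBins(), density = FALSE) {
  pd <- promiscuityDegree(profiles)
  ids <- compoundIds(profiles)
  have <- ids %in% compounds@ids
  logp <- rep(NA_real_, length(ids))
  logp[have] <- unname(calcLogP(compounds[ids[have]]))
  members <- lapply(seq_len(nrow(strata)), function(i)
    which(.binMembers(pd, strata[i, ]) & have))
  out <- .summarizeGroups(logp, members, strata$label)
  if (density) {
    attr(out, "density") <- stats::setNames(lapply(members, function(m) {
      v <- logp[m]
      if (length(v) >= 2 && stats::sd(v) > 0)
        stats::density(v, bw = "nrd") else NULL
    }), strata$label)
  }
  out
}

#' Write a census table
#' @param census output of \code{\link{pdCensus}}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeCensus <- function(census, path) {
  utils::write.table(census, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a distribution-summary table
#' @param distr output of \code{\link{testedDistributionByPd}} or
#'   \code{\link{logpDistributionByPd}}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeDistributions <- function(distr, path) {
  utils::write.table(distr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
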