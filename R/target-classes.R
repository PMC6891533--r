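# Target classification into eight drug-target classes and derivation of
# per-compound class profiles (multiclass ligands, single-class promiscuous
# compounds).

#' The eight target-class labels
#' @return character vector of class labels in reporting order.
#' @export
targetClassLabels <- function() {
  c("Enzymes", "G protein-coupled receptors", "Transcription factors",
    "Ion channels", "Receptors", "Transporters", "Others", "Unclassified")
}

#' Default keyword classification scheme
#'
#' Ordered keyword rules (case-insensitive regular expressions matched
#' against the concatenated protein and family names); the first matching
#' rule wins, so specific rules precede generic ones (e.g. enzyme keywords
#' before the generic "receptor" fallback, so that receptor kinases classify
#' as enzymes). Targets matching no rule are Unclassified. The "Others"
#' class is assigned only via an explicit \code{class_label} in the target
#' table, never by keyword.
#'
#' @return data.frame with columns pattern, class (ordered).
#' @export
defaultClassScheme <- function() {
  path <- system.file("extdata", "class_scheme.yaml", package = "PromCliff")
  loadClassScheme(path)
}

#' Load a classification scheme from a YAML file
#'
#' The file holds an ordered list of \code{pattern}/\code{class} pairs.
#'
#' @param path YAML file path.
#' @return data.frame with columns pattern, class.
#' @export
loadClassScheme <- function(path) {
  y <- yaml::read_yaml(path)
  df <- data.frame(pattern = vapply(y$rules, `[[`, character(1), "pattern"),
                   class = vapply(y$rules, `[[`, character(1), "class"),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$class, targetClassLabels())
  if (length(bad) > 0)
    stop("unknown class label(s) in scheme: ", paste(bad, collapse = ", "))
  df
}

#' Assign targets to classes
#'
#' Every target receives exactly one of the eight class labels. An explicit,
#' valid \code{class_label} column value takes precedence; otherwise the
#' first keyword rule matching the protein or family name decides; targets
#' matching nothing are Unclassified.
#'
#' @param targets data.frame with columns target_id, protein_name and
#'   optionally family_name, class_label.
#' @param scheme ordered rule data.frame (see
#'   \code{\link{defaultClassScheme}}).
#' @return the target data.frame with an added \code{class} column.
#' @export
assignTargetClasses <- function(targets, scheme = defaultClassScheme()) {
  if (is.null(targets$family_name)) targets$family_name <- ""
  if (is.null(targets$class_label)) targets$class_label <- ""
  text <- paste(targets$protein_name, targets$family_name)
  cls <- rep("Unclassified", nrow(targets))
  assigned <- rep(FALSE, nrow(targets))
  explicit <- targets$class_label %in% targetClassLabels()
  cls[explicit] <- targets$class_label[explicit]
  assigned[explicit] <- TRUE
  for (i in seq_len(nrow(scheme))) {
    hit <- !assigned & grepl(scheme$pattern[i], text, ignore.case = TRUE)
    cls[hit] <- scheme$class[i]
    assigned[hit] <- TRUE
  }
  targets$class <- factor(cls, levels = targetClassLabels())
  targets
}

#' Class-size table
#'
#' Number of targets per class, in reporting order (the two-column
#' class-composition table of the data set).
#'
#' @param targets output of \code{\link{assignTargetClasses}}.
#' @return data.frame with columns class, n_targets.
#' @export
classSizeTable <- function(targets) {
  tab <- table(targets$class)
  data.frame(class = names(tab), n_targets = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Per-compound class profiles and multiclass-ligand flags
#'
#' Maps each compound's tested and active targets to classes. A compound is
#' a multiclass ligand when it is highly promiscuous (PD >= \code{pdHi})
#' and its active targets span at least two classes.
#'
#' @param profiles an \linkS4class{ActivityProfileSet}.
#' @param targets classified target table (must resolve every target id
#'   occurring in the profiles; unknown ids are a hard error).
#' @param pdHi promiscuity threshold for multiclass ligands (default 10).
#' @return data.frame with columns compound_id, pd, n_tested_classes,
#'   n_active_classes, active_classes (";"-collapsed), is_multiclass.
#' @export
classProfiles <- function(profiles, targets, pdHi = 10) {
  if (is.null(targets$class))
    stop("targets must be classified first (assignTargetClasses)")
  classOf <- stats::setNames(as.character(targets$class), targets$target_id)
  allIds <- unique(unlist(lapply(profiles@profiles,
                                 function(p) c(p$tested, p$active)),
                          use.names = FALSE))
  missing <- setdiff(allIds, names(classOf))
  if (length(missing) > 0)
    stop("unknown target id(s) in profiles: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "")
  rows <- lapply(names(profiles@profiles), function(id) {
    p <- profiles@profiles[[id]]
    ac <- sort(unique(unname(classOf[p$active])))
    tc <- sort(unique(unname(classOf[p$tested])))
    pd <- length(p$active)
    data.frame(compound_id = id, pd = pd,
               n_tested_classes = length(tc), n_active_classes = length(ac),
               active_classes = paste(ac, collapse = ";"),
               is_multiclass = pd >= pdHi && length(ac) >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of active-class counts among highly promiscuous compounds
#'
#' Distribution of highly promiscuous compounds (PD >= \code{pdHi}) over
#' increasing numbers of target classes hit; the histogram total equals the
#' number of PD >= \code{pdHi} compounds.
#'
#' @param classProf output of \code{\link{classProfiles}}.
#' @param pdHi promiscuity threshold (default 10).
#' @return named integer vector (number of active classes -> compound count).
#' @export
classCountHistogram <- function(classProf, pdHi = 10) {
  sel <- classProf[classProf$pd >= pdHi, , drop = FALSE]
  if (nrow(sel) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(sel$n_active_classes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Single-class promiscuous compounds
#'
#' Compounds active against multiple targets (PD >= 2) that all belong to
#' one class.
#'
#' @param classProf output of \code{\link{classProfiles}}.
#' @return character vector of compound ids.
#' @export
singleClassPromiscuous <- function(classProf) {
  classProf$compound_id[classProf$pd >= 2 & classProf$n_active_classes == 1]
}
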