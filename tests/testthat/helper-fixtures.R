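# Shared fixtures and independent oracles, built in code.

# Small synthetic spec for fast unit tests: 2x2 scaffolds, 6 substituents.
miniSpec <- function(seed = 1, ...) {
  syntheticSpec(seed = seed,
                ringA = c("thiophene2", "furan2"),
                ringB = c("benzene", "pyrimidine"),
                substituents = c(H = "", Cl = "Cl", Me = "C", OMe = "OC",
                                 CN = "C#N", NH2 = "N"),
                pdPlan = c(0, 1, 2, 5, 12, 16),
                nTargets = 120, nTestedRange = c(105, 120),
                liabilitySpikes = NULL, ...)
}

# Construct an ActivityProfileSet directly from per-compound target sets.
mkProfiles <- function(spec) {
  profiles <- lapply(spec, function(p) {
    list(tested = sort(unique(c(p$tested, p$active))),
         active = sort(unique(p$active)),
         discarded = sort(unique(if (is.null(p$discarded)) character(0)
                                 else p$discarded)))
  })
  new("ActivityProfileSet", profiles = profiles)
}

# Independent brute-force MMP oracle: pairwise scan over per-molecule
# fragmentation tables, no core index, no early dedup. Returns the set of
# unordered compound-id pairs.
bruteForceMMPPairs <- function(compounds, restrictions = sizeRestrictions()) {
  ft <- PromCliff:::.fragmentTable(compounds, restrictions, includeH = TRUE)
  ids <- compoundIds(compounds)
  byId <- split(ft, ft$compound_id)
  found <- character(0)
  for (x in seq_along(ids)[-length(ids)]) {
    for (y in seq((x + 1L), length(ids))) {
      fa <- byId[[ids[x]]]; fb <- byId[[ids[y]]]
      if (is.null(fa) || is.null(fb)) next
      hit <- FALSE
      for (i in seq_len(nrow(fa))) {
        for (j in seq_len(nrow(fb))) {
          if (fa$core[i] == fb$core[j] &&
              fa$substituent[i] != fb$substituent[j] &&
              abs(fa$substituent_size[i] - fb$substituent_size[j]) <=
                restrictions$maxTransformationDiff) {
            hit <- TRUE; break
          }
        }
        if (hit) break
      }
      if (hit) found <- c(found, paste(sort(c(ids[x], ids[y])), collapse = " "))
    }
  }
  sort(found)
}

# Independent maximal-simple-path oracle built on igraph's path enumerator.
pathwayOracle <- function(network, minLength = 3) {
  g <- network@graph
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(character(0))
  keys <- character(0)
  for (v in seq_len(n)) {
    paths <- igraph::all_simple_paths(g, from = v)
    for (p in paths) {
      p <- as.integer(p)
      if (length(p) < minLength) next
      endNbrs <- c(as.integer(igraph::neighbors(g, p[1])),
                   as.integer(igraph::neighbors(g, p[length(p)])))
      if (any(!(endNbrs %in% p))) next   # extendable => not maximal
      ids <- igraph::V(g)$name[p]
      if (ids[length(ids)] < ids[1]) ids <- rev(ids)
      keys <- c(keys, paste(ids, collapse = "|"))
    }
  }
  sort(unique(keys))
}

# Cliff data.frame row helper for constructed networks.
cliffRow <- function(prom, part, pdProm = 12, pdPart = 0, shared = 100) {
  data.frame(promiscuous_id = prom, partner_id = part,
             pd_promiscuous = pdProm, pd_partner = pdPart,
             core = "*c1ccccc1", transformation = "[*][H] >> *Cl",
             shared_tested = shared, stringsAsFactors = FALSE)
}
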