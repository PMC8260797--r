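# Fixtures built in code: tiny trees, peak tables, catalogs, response
# panels used across the test files.

tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n = 10, depth = 1) {
  # a basal polytomy reads as unrooted; the rooting warning is expected
  suppressWarnings(parse_newick(paste0(
    "(", paste(sprintf("t%d:%g", seq_len(n), depth), collapse = ","),
    ");")))
}

# peak table with explicit presence patterns: `design` is a list
# species -> list(male = c(feature = n_present_reps), female = ...,
# mated = ...); all strata get `n_reps` replicates; present replicates
# get area `area`.
make_peak_table <- function(design, n_reps = 6, area = 10) {
  rows <- list()
  for (sp in names(design)) {
    for (stratum in names(design[[sp]])) {
      sex <- if (stratum == "male") "male" else "female"
      mating <- if (stratum == "mated") "mated" else "virgin"
      feats <- design[[sp]][[stratum]]
      for (f in names(feats)) {
        k <- feats[[f]]
        if (k > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, sex = sex, mating = mating,
            replicate = paste0(stratum, "_", seq_len(k)),
            feature = f, area = area, stringsAsFactors = FALSE)
      }
      # anchor feature present in every replicate so each replicate id
      # exists even when the focal compound is absent from it
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, sex = sex, mating = mating,
        replicate = paste0(stratum, "_", seq_len(n_reps)),
        feature = "base", area = area, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# hand-built catalog for network tests: each species in `producers`
# produces the male-specific compound named after it
make_catalog <- function(species, producers = species) {
  feats <- paste0("cmp_", producers)
  structure(list(
    compounds = data.frame(
      feature = feats, specificity = "male_specific", transferred = NA,
      n_producing_species = 1L, stringsAsFactors = FALSE),
    producing = data.frame(species = producers, feature = feats,
                           sex = "male", stringsAsFactors = FALSE),
    species_status = data.frame(
      species = species,
      status = ifelse(species %in% producers, "dimorphic",
                      "monomorphic"),
      stringsAsFactors = FALSE)),
    class = "compound_catalog")
}

# response rows for a detector against a set of compounds
make_responses <- function(detector, compounds, responses,
                           sensillum = "at1") {
  k <- length(compounds)
  data.frame(detector = rep_len(detector, k),
             compound = compounds,
             sensillum = rep_len(sensillum, k),
             mean_response = responses,
             n = rep_len(5L, k), stringsAsFactors = FALSE)
}

# independent brute-force MRCA-path covariance: for every tip pair, sum
# the branch lengths of the shared root-to-MRCA edges
brute_covariance <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    out <- integer(0)
    while (v != root) {
      out <- c(out, v)
      v <- parent_of[v]
    }
    out
  }
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip))
    for (j in seq_len(ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(len_of[shared])
    }
  C
}

# exact two-sided Mann-Whitney p-value by enumeration of all
# choose(n1+n2, n1) group assignments (tie-free samples)
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ranks <- rank(pooled)
  w_all <- apply(combos, 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_all <= r_obs)
  p_up <- mean(w_all >= r_obs)
  min(1, 2 * min(p_low, p_up))
}
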