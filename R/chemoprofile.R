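#' Read a replicate-level chemical peak table
#'
#' @param path Delimited text file (TSV by default) with header columns
#'   `species, sex, mating, replicate, feature, area`.
#' @param sep Field separator. Default tab.
#' @return A validated peak-table data frame.
#' @export
read_peak_table <- function(path, sep = "\t") {
  pt <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_peak_table(pt)
}

#' Validate a peak table
#'
#' Checks the contract of the replicate-level peak table: required columns,
#' non-negative areas, legal sex/mating codes, and uniqueness of
#' (species, sex, mating, replicate, feature).
#'
#' @param pt Data frame with columns `species, sex, mating, replicate,
#'   feature, area`.
#' @param min_replicates Minimum replicates required per species-sex
#'   stratum (default 5). Strata below the minimum trigger a warning, not
#'   an error, so partial tables can still be explored.
#' @return `pt`, invisibly validated (returned unchanged on success).
#' @export
validate_peak_table <- function(pt, min_replicates = 5) {
  need <- c("species", "sex", "mating", "replicate", "feature", "area")
  miss <- setdiff(need, names(pt))
  if (length(miss))
    stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  if (any(pt$area < 0)) stop("peak areas must be >= 0")
  if (!all(pt$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(pt$mating %in% c("virgin", "mated")))
    stop("mating must be 'virgin' or 'mated'")
  key <- paste(pt$species, pt$sex, pt$mating, pt$replicate, pt$feature)
  if (anyDuplicated(key))
    stop("duplicate (species, sex, mating, replicate, feature) records")
  reps <- unique(pt[, c("species", "sex", "replicate")])
  cnt <- table(paste(reps$species, reps$sex))
  low <- cnt[cnt < min_replicates]
  if (length(low))
    warning(length(low), " species-sex stratum/strata below ",
            min_replicates, " replicates")
  pt
}

#' Standardize chemical profiles to a species x feature trait matrix
#'
#' Pipeline: (1) per replicate, divide each peak area by the replicate's
#' total so relative areas sum to 1; (2) log-transform with a pseudocount
#' of half the smallest nonzero relative area in the table (absent peaks
#' have relative area 0 and would otherwise map to -Inf); (3) z-transform
#' each feature across species (or replicates) so columns have mean 0 and
#' unit variance.
#'
#' @param pt Peak table (one sex; mixing sexes triggers a warning since
#'   the standardization is defined per sex).
#' @param level `"species_mean"` (default) averages relative areas across
#'   replicates before the log and z steps; `"replicate"` keeps one row
#'   per replicate.
#' @param mating Which mating status to use; default `"virgin"`.
#' @param transform How far to run the pipeline: `"z"` (default, all three
#'   steps), `"log"` (stop after the log step) or `"relative"` (relative
#'   areas only).
#' @return Numeric matrix (rows = species or species:replicate, columns =
#'   features), with a `transform` attribute recording the stage.
#' @export
standardize_profiles <- function(pt, level = c("species_mean", "replicate"),
                                 mating = "virgin",
                                 transform = c("z", "log", "relative")) {
  level <- match.arg(level)
  transform <- match.arg(transform)
  pt <- pt[pt$mating %in% mating, , drop = FALSE]
  if (!nrow(pt)) stop("no records for mating status ",
                      paste(mating, collapse = "/"))
  if (length(unique(pt$sex)) > 1L)
    warning("peak table mixes sexes; standardization is usually per sex")
  rep_id <- paste(pt$species, pt$sex, pt$mating, pt$replicate, sep = "\r")
  tot <- tapply(pt$area, rep_id, sum)
  if (any(tot <= 0))
    stop("replicate(s) with zero total area: ",
         paste(gsub("\r", "/", names(tot)[tot <= 0]), collapse = ", "))
  rel <- pt$area / tot[rep_id]

  feats <- sort(unique(pt$feature))
  if (level == "species_mean") {
    rows <- sort(unique(pt$species))
    row_of <- match(pt$species, rows)
  } else {
    rows <- sort(unique(rep_id))
    row_of <- match(rep_id, rows)
  }
  m <- matrix(0, length(rows), length(feats),
              dimnames = list(gsub("\r", "/", rows), feats))
  cnt <- matrix(0L, length(rows), length(feats))
  idx <- cbind(row_of, match(pt$feature, feats))
  # mean of relative areas per cell; features absent from a replicate
  # count as 0, so divide by the stratum's replicate count, not the
  # number of records
  nrep <- if (level == "species_mean") {
    tapply(rep_id, pt$species, function(z) length(unique(z)))[rows]
  } else rep(1L, length(rows))
  for (i in seq_len(nrow(pt)))
    m[idx[i, 1L], idx[i, 2L]] <- m[idx[i, 1L], idx[i, 2L]] + rel[i]
  m <- m / as.numeric(nrep)

  if (transform == "relative") {
    attr(m, "transform") <- "relative"
    return(m)
  }
  pseudo <- min(m[m > 0]) / 2
  m <- log(m + pseudo)
  attr(m, "pseudocount") <- pseudo
  if (transform == "log") {
    attr(m, "transform") <- "log"
    return(m)
  }
  m <- scale(m)
  # constant columns scale to NaN; keep them as 0 with a note
  bad <- !is.finite(colSums(m))
  if (any(bad)) m[, bad] <- 0
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  attr(m, "transform") <- "z"
  attr(m, "pseudocount") <- pseudo
  m
}

# presence call: share of a stratum's replicates in which the feature has
# area > floor
presence_fraction <- function(pt, floor = 0) {
  rep_id <- paste(pt$species, pt$sex, pt$mating, pt$replicate, sep = "\r")
  strata <- unique(pt[, c("species", "sex", "mating")])
  key <- function(sp, sx, mt) paste(sp, sx, mt, sep = "\r")
  nreps <- tapply(rep_id, key(pt$species, pt$sex, pt$mating),
                  function(z) length(unique(z)))
  present <- pt[pt$area > floor, , drop = FALSE]
  cnt <- tapply(present$replicate,
                paste(key(present$species, present$sex, present$mating),
                      present$feature, sep = "\r"),
                function(z) length(unique(z)))
  list(nreps = nreps, cnt = cnt, key = key)
}

#' Call sex-specific (dimorphic) compounds
#'
#' A compound is sex-specific for a species when it is present (area above
#' the detection floor in at least `presence_frac` of that sex's virgin
#' replicates) in exactly one sex and absent from every replicate of the
#' other sex. Species with no sex-specific compound in either direction
#' are labeled monomorphic, regardless of quantitative differences.
#' Compound-level specificity aggregates across species: a compound is
#' male-specific when it is present only in males wherever it occurs
#' (symmetrically for females), and shared otherwise.
#'
#' @param pt Peak table with both sexes (virgin replicates are used).
#' @param presence_frac Minimum fraction of replicates for a presence
#'   call. Default 0.5.
#' @param floor Detection floor on area. Default 0 (post peak-calling).
#' @return An object of class `"compound_catalog"`: list with
#'   `compounds` (feature, specificity, n_producing_species),
#'   `producing` (species, feature, sex of production),
#'   `species_status` (species, status in dimorphic/monomorphic/skipped).
#' @export
call_sex_specific <- function(pt, presence_frac = 0.5, floor = 0) {
  ptv <- pt[pt$mating == "virgin", , drop = FALSE]
  pf <- presence_fraction(ptv, floor)
  species <- sort(unique(ptv$species))
  feats <- sort(unique(pt$feature))
  prod <- list()
  status <- character(length(species))
  names(status) <- species
  for (sp in species) {
    have <- unique(ptv$sex[ptv$species == sp])
    if (length(have) < 2L) {
      warning("species ", sp, " lacks one sex; skipped")
      status[sp] <- "skipped"
      next
    }
    calls <- character(0)
    sexes <- character(0)
    for (f in feats) {
      frac <- det <- c(male = 0, female = 0)
      for (sx in c("male", "female")) {
        n <- pf$nreps[pf$key(sp, sx, "virgin")]
        k <- pf$cnt[paste(pf$key(sp, sx, "virgin"), f, sep = "\r")]
        if (is.na(k)) k <- 0
        frac[sx] <- k / n
        det[sx] <- k
      }
      if (frac["male"] >= presence_frac && det["female"] == 0) {
        calls <- c(calls, f); sexes <- c(sexes, "male")
      } else if (frac["female"] >= presence_frac && det["male"] == 0) {
        calls <- c(calls, f); sexes <- c(sexes, "female")
      }
    }
    status[sp] <- if (length(calls)) "dimorphic" else "monomorphic"
    if (length(calls))
      prod[[sp]] <- data.frame(species = sp, feature = calls, sex = sexes,
                               stringsAsFactors = FALSE)
  }
  producing <- if (length(prod)) do.call(rbind, prod) else
    data.frame(species = character(0), feature = character(0),
               sex = character(0))
  rownames(producing) <- NULL
  spec <- vapply(feats, function(f) {
    sx <- unique(producing$sex[producing$feature == f])
    if (length(sx) == 1L && sx == "male") "male_specific"
    else if (length(sx) == 1L && sx == "female") "female_specific"
    else "shared"
  }, character(1))
  nprod <- vapply(feats, function(f)
    sum(producing$feature == f), integer(1))
  structure(list(
    compounds = data.frame(feature = feats, specificity = unname(spec),
                           transferred = NA,
                           n_producing_species = unname(nprod),
                           stringsAsFactors = FALSE),
    producing = producing,
    species_status = data.frame(species = species,
                                status = unname(status[species]),
                                stringsAsFactors = FALSE)),
    class = "compound_catalog")
}

#' @export
print.compound_catalog <- function(x, ...) {
  tab <- table(x$compounds$specificity)
  st <- table(x$species_status$status)
  cat("Compound catalog: ", nrow(x$compounds), " compounds (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n", sep = "")
  cat("Species: ", paste(names(st), st, sep = " = ", collapse = ", "),
      "\n", sep = "")
  if (!all(is.na(x$compounds$transferred)))
    cat("Transferred male-specific compounds: ",
        sum(x$compounds$transferred, na.rm = TRUE), "\n", sep = "")
  invisible(x)
}

#' Flag male-specific compounds transferred to females during mating
#'
#' A male-specific compound is transferred when it is present on mated
#' females (in at least `presence_frac` of their replicates, for at least
#' one producing species) while absent from all virgin-female replicates.
#' Female-specific compounds are never flagged.
#'
#' @param pt Peak table including mated-female records.
#' @param catalog A `"compound_catalog"` from [call_sex_specific()].
#' @inheritParams call_sex_specific
#' @return The catalog with `compounds$transferred` filled for
#'   male-specific compounds (TRUE/FALSE; NA for other compounds) and a
#'   `transfer` data frame (species, feature, transferred).
#' @export
call_transferred <- function(pt, catalog, presence_frac = 0.5, floor = 0) {
  stopifnot(inherits(catalog, "compound_catalog"))
  mf <- pt[pt$sex == "female" & pt$mating == "mated", , drop = FALSE]
  if (!nrow(mf)) stop("no mated-female records in the peak table")
  vf <- pt[pt$sex == "female" & pt$mating == "virgin", , drop = FALSE]
  pf_m <- presence_fraction(mf, floor)
  ms <- catalog$compounds$feature[
    catalog$compounds$specificity == "male_specific"]
  rows <- catalog$producing[catalog$producing$feature %in% ms &
                              catalog$producing$sex == "male", ,
                            drop = FALSE]
  transfer <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    sp <- rows$species[i]; f <- rows$feature[i]
    n <- pf_m$nreps[pf_m$key(sp, "female", "mated")]
    k <- pf_m$cnt[paste(pf_m$key(sp, "female", "mated"), f, sep = "\r")]
    if (is.na(k)) k <- 0
    on_mated <- !is.na(n) && n > 0 && (k / n) >= presence_frac
    on_virgin <- any(vf$species == sp & vf$feature == f & vf$area > floor)
    transfer[[i]] <- data.frame(species = sp, feature = f,
                                transferred = on_mated && !on_virgin,
                                stringsAsFactors = FALSE)
  }
  transfer <- if (length(transfer)) do.call(rbind, transfer) else
    data.frame(species = character(0), feature = character(0),
               transferred = logical(0))
  tr_by_comp <- vapply(catalog$compounds$feature, function(f) {
    if (!(f %in% ms)) return(NA)
    any(transfer$transferred[transfer$feature == f])
  }, logical(1))
  catalog$compounds$transferred <- unname(tr_by_comp)
  catalog$transfer <- transfer
  catalog
}

#' Pairwise Pearson correlation between species chemical profiles
#'
#' @param tm Species x feature trait matrix.
#' @return Symmetric correlation matrix (diagonal exactly 1; entries in
#'   `[-1, 1]`); rows/columns of zero-variance species are set to `NA`
#'   with a warning.
#' @export
profile_correlation <- function(tm) {
  stopifnot(is.matrix(tm))
  if (ncol(tm) < 2L) stop("need >= 2 features per species")
  sds <- apply(tm, 1L, stats::sd)
  R <- suppressWarnings(stats::cor(t(tm), use = "pairwise.complete.obs"))
  bad <- which(sds == 0 | is.na(sds))
  if (length(bad)) {
    warning("zero-variance species set to NA: ",
            paste(rownames(tm)[bad], collapse = ", "))
    R[bad, ] <- NA
    R[, bad] <- NA
  }
  diag(R) <- 1
  R
}

#' Principal-component scores of chemical profiles
#'
#' @param tm Species (or replicate) x feature matrix.
#' @param k Number of components to return.
#' @return List with `scores` (rows x k), `explained` (variance fractions,
#'   non-increasing, summing to <= 1) and the full `prcomp` object.
#' @export
pca_scores <- function(tm, k = 2) {
  stopifnot(is.matrix(tm))
  pc <- stats::prcomp(tm, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) stop("k = ", k, " exceeds matrix rank ", rank)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       prcomp = pc)
}
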