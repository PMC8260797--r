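pt_two_species <- function() {
  make_peak_table(list(
    sp1 = list(male = c(msp = 6, shared = 6), female = c(shared = 6),
               mated = c(shared = 6)),
    sp2 = list(male = c(shared = 6), female = c(shared = 6),
               mated = c(shared = 6))), n_reps = 6)
}

test_that("relative areas sum to one per replicate", {
  pt <- data.frame(
    species = "s", sex = "male", mating = "virgin",
    replicate = rep(c("r1", "r2"), each = 2),
    feature = rep(c("f1", "f2"), 2),
    area = c(2, 2, 9, 1))
  rel <- standardize_profiles(pt, level = "replicate",
                              transform = "relative")
  expect_equal(unname(rowSums(rel)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(rel[1, ]), c(0.5, 0.5))
  expect_equal(unname(rel[2, ]), c(0.9, 0.1))

  single <- pt[pt$feature == "f1" & pt$replicate == "r1", ]
  rel1 <- standardize_profiles(single, level = "replicate",
                               transform = "relative")
  expect_equal(unname(rel1[1, 1]), 1)
})

test_that("z step yields column mean 0 and sd 1 across species", {
  set.seed(4)
  sim <- simulate_peak_table(sim_config(
    seed = 4, n_species = 8, n_shared = 12,
    n_sex_specific = c(male = 0, female = 0), n_replicates = 5))
  tm <- standardize_profiles(
    sim$peak_table[sim$peak_table$sex == "male", ])
  expect_lt(max(abs(colMeans(tm))), 1e-8)
  expect_equal(unname(apply(tm, 2, sd)), rep(1, ncol(tm)))
})

test_that("all-zero replicates are an error naming the replicate", {
  pt <- data.frame(species = "s", sex = "male", mating = "virgin",
                   replicate = "r1", feature = c("f1", "f2"),
                   area = c(0, 0))
  expect_error(standardize_profiles(pt), "zero total area")
  expect_error(standardize_profiles(pt), "r1")
})

test_that("sex-specific calls follow the one-sex presence rule", {
  pt <- pt_two_species()
  cat <- call_sex_specific(pt)
  cmp <- cat$compounds
  expect_equal(cmp$specificity[cmp$feature == "msp"], "male_specific")
  expect_equal(cmp$specificity[cmp$feature == "shared"], "shared")
  st <- cat$species_status
  expect_equal(st$status[st$species == "sp1"], "dimorphic")
  expect_equal(st$status[st$species == "sp2"], "monomorphic")
  expect_true(all(cat$producing$species == "sp1"))
})

test_that("presence below the replicate fraction is not called", {
  pt <- make_peak_table(list(
    s = list(male = c(rare = 2), female = c(dummy = 0))), n_reps = 6)
  cat <- call_sex_specific(pt, presence_frac = 0.5)
  expect_equal(
    cat$compounds$specificity[cat$compounds$feature == "rare"],
    "shared")
  expect_equal(cat$species_status$status, "monomorphic")
  # at 6/6 male replicates the same compound is called
  pt2 <- make_peak_table(list(
    s = list(male = c(rare = 6), female = c(dummy = 0))), n_reps = 6)
  cat2 <- call_sex_specific(pt2)
  expect_equal(
    cat2$compounds$specificity[cat2$compounds$feature == "rare"],
    "male_specific")
})

test_that("swapping sex labels swaps the specificity calls", {
  pt <- pt_two_species()
  swapped <- pt
  swapped$sex <- ifelse(pt$sex == "male", "female", "male")
  cat_a <- call_sex_specific(pt)
  cat_b <- call_sex_specific(swapped)
  a <- cat_a$compounds$specificity
  b <- cat_b$compounds$specificity
  expect_equal(b[a == "male_specific"],
               rep("female_specific", sum(a == "male_specific")))
  expect_equal(b[a == "shared"], rep("shared", sum(a == "shared")))
})

test_that("species lacking one sex are skipped with a warning", {
  pt <- make_peak_table(list(
    ok = list(male = c(f = 6), female = c(f = 6)),
    lone = list(male = c(f = 6))), n_reps = 6)
  expect_warning(cat <- call_sex_specific(pt), "lacks one sex")
  st <- cat$species_status
  expect_equal(st$status[st$species == "lone"], "skipped")
})

test_that("transfer is called from mated vs virgin female presence", {
  pt <- make_peak_table(list(
    sp1 = list(male = c(msp = 6), female = c(other = 6),
               mated = c(other = 6, msp = 5)),
    sp2 = list(male = c(msp2 = 6), female = c(other = 6),
               mated = c(other = 6))), n_reps = 6)
  cat <- call_transferred(pt, call_sex_specific(pt))
  cmp <- cat$compounds
  expect_true(cmp$transferred[cmp$feature == "msp"])
  expect_false(cmp$transferred[cmp$feature == "msp2"])
  # female-specific compounds never get a transfer flag
  expect_true(is.na(cmp$transferred[cmp$feature == "other"]))
})

test_that("transfer calling requires mated-female records", {
  pt <- pt_two_species()
  pt <- pt[pt$mating != "mated", ]
  expect_error(call_transferred(pt, call_sex_specific(pt)),
               "mated-female")
})

test_that("profile correlation matches a per-pair oracle", {
  set.seed(10)
  tm <- matrix(rnorm(50), 5, 10,
               dimnames = list(paste0("s", 1:5), paste0("f", 1:10)))
  R <- profile_correlation(tm)
  expect_equal(unname(diag(R)), rep(1, 5))
  expect_true(all(R >= -1 & R <= 1))
  for (i in 1:5)
    for (j in 1:5)
      if (i != j)
        expect_equal(R[i, j], cor(tm[i, ], tm[j, ]), tolerance = 1e-12)
  # identical profiles correlate at exactly 1
  tm2 <- rbind(a = tm[1, ], b = tm[1, ])
  expect_equal(profile_correlation(tm2)["a", "b"], 1)
})

test_that("zero-variance species are flagged NA in the correlation", {
  tm <- rbind(flat = rep(1, 6), s1 = rnorm(6), s2 = rnorm(6))
  colnames(tm) <- paste0("f", 1:6)
  expect_warning(R <- profile_correlation(tm), "flat")
  expect_true(all(is.na(R["flat", -1])))
  expect_equal(R["flat", "flat"], 1)
})

test_that("correlation is invariant to consistent feature reordering", {
  set.seed(11)
  tm <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  perm <- sample(10)
  expect_equal(profile_correlation(tm), profile_correlation(tm[, perm]))
})

test_that("pca_scores behaves like principal components should", {
  # two perfectly correlated features: one component carries everything
  tm <- cbind(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
  rownames(tm) <- paste0("s", 1:4)
  p <- pca_scores(tm, k = 1)
  expect_equal(p$explained[1], 1)
  expect_lt(max(abs(colMeans(p$scores))), 1e-12)
  expect_error(pca_scores(tm, k = 2), "rank")

  set.seed(12)
  tm2 <- matrix(rnorm(40), 8, 5)
  rownames(tm2) <- paste0("s", 1:8)
  p2 <- pca_scores(tm2, k = 5)
  recon <- p2$scores %*% t(p2$prcomp$rotation) +
    matrix(p2$prcomp$center, 8, 5, byrow = TRUE)
  expect_equal(recon, tm2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p2$explained) <= 1e-12))
  expect_lte(sum(p2$explained), 1 + 1e-12)
})

test_that("peak-table validation catches contract violations", {
  pt <- pt_two_species()
  expect_silent(validate_peak_table(pt))
  bad <- pt; bad$area[1] <- -1
  expect_error(validate_peak_table(bad), ">= 0")
  dup <- rbind(pt, pt[1, ])
  expect_error(validate_peak_table(dup), "duplicate")
  expect_warning(validate_peak_table(pt, min_replicates = 10),
                 "below 10 replicates")
})
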