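test_that("tree simulation is seeded and shaped as promised", {
  expect_identical(write_newick(simulate_tree(10, seed = 1)),
                   write_newick(simulate_tree(10, seed = 1)))
  cherry <- simulate_tree(2, seed = 2)
  expect_equal(length(cherry$tip.label), 2L)
  expect_equal(cherry$Nnode, 1L)
  expect_error(simulate_tree(1), ">= 2")
})

test_that("Yule depths match the analytic expectation", {
  n <- 10
  depths <- vapply(1:1000, function(i) {
    tr <- simulate_tree(n, birth_rate = 1, seed = 1000 + i)
    ape::node.depth.edgelength(tr)[1]
  }, numeric(1))
  expected <- sum(1 / (2:n))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("BM trait simulation honors its moments", {
  tr <- simulate_tree(5, seed = 3)
  # degenerate rate: every species sits at the root mean
  flat <- simulate_bm_traits(tr, 0.7, 0, mu = 1.5, n_traits = 3)
  expect_true(all(flat == 1.5))

  lam <- 0.5; s2 <- 1.3
  X <- simulate_bm_traits(tr, lam, s2, mu = 0, n_traits = 5000,
                          seed = 4)
  emp <- cov(t(X)) * (ncol(X) - 1) / ncol(X)
  target <- s2 * lambda_transform(phylo_covariance(tr), lam)
  expect_lt(max(abs(emp - target)), 0.05 * max(diag(target)))

  Z <- simulate_bm_traits(tr, 0, 1, mu = 0, n_traits = 5000, seed = 5)
  r <- cor(t(Z))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("Mk presence simulation respects rates and seeds", {
  tr <- simulate_tree(6, seed = 6)
  none <- simulate_mk_presence(tr, gain_rate = 0, loss_rate = 1,
                               root_state = 0L, n_compounds = 10,
                               seed = 7)
  expect_true(all(none == 0))
  expect_identical(
    simulate_mk_presence(tr, 0.5, 0.5, 0L, 5, seed = 8),
    simulate_mk_presence(tr, 0.5, 0.5, 0L, 5, seed = 8))

  # long branches: tip frequency approaches the stationary value 1/2
  long <- parse_newick("(A:50,B:50);")
  tips <- simulate_mk_presence(long, 1, 1, 0L, n_compounds = 2000,
                               seed = 9)
  freq <- mean(tips)
  se <- sqrt(0.25 / length(tips))
  expect_lt(abs(freq - 0.5), 3 * se)
})

test_that("peak-table generation matches its ground truth by design", {
  cfg <- sim_config(seed = 10, n_species = 8, n_shared = 10,
                    n_sex_specific = c(male = 4, female = 2),
                    transfer_prob = 1, n_replicates = 5)
  sim <- simulate_peak_table(cfg)
  pt <- sim$peak_table
  # every male-specific compound of a producing species reaches its
  # mated females when transfer_prob = 1
  prod_m <- sim$truth$producing[sim$truth$producing$sex == "male", ]
  for (i in seq_len(nrow(prod_m))) {
    on_mated <- pt$species == prod_m$species[i] &
      pt$mating == "mated" & pt$feature == prod_m$feature[i]
    expect_equal(sum(on_mated), cfg$n_replicates)
  }
  # calls on the simulated table recover the generating truth exactly
  cat <- call_transferred(pt, call_sex_specific(pt))
  m <- merge(sim$truth$compounds, cat$compounds, by = "feature")
  expect_equal(m$specificity.y, m$specificity.x)
  expect_equal(m$transferred.y, m$transferred.x)
  st <- merge(sim$truth$species_status, cat$species_status,
              by = "species")
  expect_equal(st$status.y, st$status.x)
})

test_that("without sex-specific compounds every species is monomorphic", {
  cfg <- sim_config(seed = 11, n_species = 6, n_shared = 8,
                    n_sex_specific = c(male = 0, female = 0))
  sim <- simulate_peak_table(cfg)
  cat <- call_sex_specific(sim$peak_table)
  expect_true(all(cat$compounds$specificity == "shared"))
  expect_true(all(cat$species_status$status == "monomorphic"))
})

test_that("zero replicate noise gives identical replicates", {
  cfg <- sim_config(seed = 12, n_species = 4, n_shared = 6,
                    n_sex_specific = c(male = 2, female = 0),
                    peak_noise_cv = 0)
  pt <- simulate_peak_table(cfg)$peak_table
  spread <- tapply(pt$area,
                   paste(pt$species, pt$sex, pt$mating, pt$feature),
                   function(a) diff(range(a)))
  expect_true(all(spread == 0))
})

test_that("response simulation recovers the planted network", {
  cfg <- sim_config(seed = 13, n_species = 6, n_shared = 6,
                    n_sex_specific = c(male = 3, female = 0))
  sim <- simulate_peak_table(cfg)
  rsim <- simulate_response_matrix(sim$truth, cfg)
  net <- build_network(sim$truth, rsim$response_matrix)
  got <- net$edges[, c("detector", "producer", "sensillum")]
  want <- rsim$truth_edges
  key <- function(d) sort(paste(d$detector, d$producer, d$sensillum))
  expect_equal(key(got), key(want))
  # same seed, same panel
  rsim2 <- simulate_response_matrix(sim$truth, cfg)
  expect_identical(rsim$response_matrix, rsim2$response_matrix)
})

test_that("detection probabilities shape the network as configured", {
  cfg <- sim_config(seed = 14, n_species = 6, n_shared = 6,
                    n_sex_specific = c(male = 6, female = 0),
                    detect_intra_prob = 1,
                    detect_inter_prob = c(at1 = 0, at4 = 0))
  # one compound per species: intra-only detection can only produce
  # self-loops
  catalog <- make_catalog(paste0("s", 1:6))
  rsim <- simulate_response_matrix(catalog, cfg)
  net <- build_network(catalog, rsim$response_matrix)
  expect_true(all(net$edges$detector == net$edges$producer))
  expect_equal(sort(unique(net$edges$detector)), paste0("s", 1:6))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(transfer_prob = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(n_replicates = 3), ">= 5")
  expect_error(sim_config(birth_rate = 0), "> 0")
  expect_error(sim_config(n_shared = 0), ">= 1")
})
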