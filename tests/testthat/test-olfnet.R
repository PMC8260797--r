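panel6 <- function() make_catalog(paste0("s", 1:6))

test_that("the 10 spikes/s exclusion is strict", {
  cat6 <- panel6()
  rm <- make_responses("s1", c("cmp_s2", "cmp_s3", "cmp_s4"),
                       c(10, 10.5, 9))
  net <- build_network(cat6, rm)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$producer, "s3")
  # negative (inhibitory) responses never create edges
  rm_neg <- make_responses("s1", "cmp_s2", -40)
  expect_equal(nrow(build_network(cat6, rm_neg)$edges), 0L)
})

test_that("an empty response panel yields nodes but no edges", {
  net <- build_network(panel6(),
                       make_responses(character(0), character(0),
                                      numeric(0)))
  expect_equal(length(net$nodes), 6L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("compounds missing from the catalog are ignored with warning", {
  rm <- rbind(make_responses("s1", "cmp_s2", 50),
              make_responses("s1", "mystery", 80))
  expect_warning(net <- build_network(panel6(), rm), "mystery")
  expect_equal(net$edges$producer, "s2")
})

test_that("self-loops arise from conspecific detection only", {
  rm <- rbind(make_responses("s1", "cmp_s1", 60, "at4"),
              make_responses("s2", "cmp_s1", 60, "at1"))
  net <- build_network(panel6(), rm)
  loops <- self_loop_summary(net)
  expect_false(loops$table$at1[loops$table$species == "s1"])
  expect_true(loops$table$at4[loops$table$species == "s1"])
  expect_equal(loops$totals, c(at1 = 0L, at4 = 1L))
})

test_that("clustering coefficient counts other-species detections", {
  cat6 <- panel6()
  # focal detects all 5 others plus itself through at1
  rm_all <- make_responses("s1", paste0("cmp_s", 1:6), rep(50, 6))
  net_all <- build_network(cat6, rm_all)
  expect_equal(clustering_coefficient(net_all, "s1", "at1"), 1)
  # the self-loop contributes to neither numerator nor denominator
  expect_equal(clustering_coefficient(net_all, "s1", "at4"), 0)

  rm_two <- make_responses("s1", c("cmp_s2", "cmp_s3"), c(50, 50))
  net_two <- build_network(cat6, rm_two)
  expect_equal(clustering_coefficient(net_two, "s1", "at1"), 0.4)

  net_none <- build_network(cat6, make_responses("s1", "cmp_s2", 5))
  expect_equal(clustering_coefficient(net_none, "s1", "at1"), 0)
  expect_error(clustering_coefficient(net_all, "sX", "at1"), "unknown")
})

test_that("multi-compound producers are detected species, counted once", {
  cat <- make_catalog(c("a", "b", "c"), producers = c("a", "b"))
  cat$compounds <- rbind(cat$compounds, data.frame(
    feature = "cmp_b2", specificity = "male_specific", transferred = NA,
    n_producing_species = 1L))
  cat$producing <- rbind(cat$producing, data.frame(
    species = "b", feature = "cmp_b2", sex = "male"))
  rm <- make_responses("a", c("cmp_b", "cmp_b2"), c(60, 70))
  net <- build_network(cat, rm)
  expect_equal(clustering_coefficient(net, "a", "at1"), 0.5)
})

test_that("coefficients match brute-force counts on random networks", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    species <- paste0("s", seq_len(n))
    cat <- make_catalog(species)
    rm <- do.call(rbind, lapply(species, function(d)
      make_responses(d, paste0("cmp_", species), runif(n, 0, 30),
                     sample(c("at1", "at4"), 1))))
    net <- build_network(cat, rm)
    for (sp in species)
      for (sens in c("at1", "at4")) {
        hits <- unique(net$edges$producer[
          net$edges$detector == sp & net$edges$sensillum == sens])
        brute <- length(setdiff(hits, sp)) / (n - 1)
        expect_equal(clustering_coefficient(net, sp, sens), brute)
        expect_gte(brute, 0); expect_lte(brute, 1)
      }
  }
})

test_that("raising the threshold never adds edges", {
  set.seed(72)
  species <- paste0("s", 1:6)
  cat <- make_catalog(species)
  rm <- do.call(rbind, lapply(species, function(d)
    make_responses(d, paste0("cmp_", species), runif(6, 0, 40))))
  edge_key <- function(net)
    paste(net$edges$detector, net$edges$producer, net$edges$sensillum)
  prev <- edge_key(build_network(cat, rm, threshold = 0))
  for (thr in c(5, 10, 20, 35)) {
    cur <- edge_key(build_network(cat, rm, threshold = thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # build_network is idempotent in its inputs
  expect_identical(build_network(cat, rm), build_network(cat, rm))
})

test_that("adding an edge never lowers the focal coefficient", {
  cat6 <- panel6()
  rm <- make_responses("s1", c("cmp_s2", "cmp_s3"), c(50, 50))
  base <- clustering_coefficient(build_network(cat6, rm), "s1", "at1")
  rm2 <- rbind(rm, make_responses("s1", "cmp_s4", 80))
  grown <- clustering_coefficient(build_network(cat6, rm2), "s1", "at1")
  expect_gte(grown, base)
})

test_that("at1 vs at4 comparison matches exact references", {
  cat6 <- panel6()
  # identical coefficient vectors: indistinguishable
  rm_same <- do.call(rbind, lapply(c("at1", "at4"), function(s)
    make_responses("s1", "cmp_s2", 50, s)))
  same <- compare_coefficients(build_network(cat6, rm_same))
  expect_equal(same$p_value, 1)

  # at1 saturated, at4 empty for 5 species: the extreme arrangement
  sp5 <- paste0("s", 1:5)
  cat5 <- make_catalog(sp5)
  rm_ext <- do.call(rbind, lapply(sp5, function(d)
    make_responses(d, paste0("cmp_", setdiff(sp5, d)), rep(50, 4))))
  net_ext <- build_network(cat5, rm_ext)
  cc <- clustering_coefficients(net_ext)
  expect_equal(cc$at1, rep(1, 5))
  expect_equal(cc$at4, rep(0, 5))
  res <- compare_coefficients(net_ext)
  expect_equal(res$p_value, enum_wilcox_p(cc$at1, cc$at4),
               tolerance = 1e-12)

  # species order has no effect
  perm <- build_network(cat5, rm_ext[sample(nrow(rm_ext)), ])
  expect_equal(compare_coefficients(perm)$statistic, res$statistic)
})

test_that("network edge lists round-trip through TSV export", {
  rm <- make_responses("s1", c("cmp_s2", "cmp_s3"), c(50, 50))
  net <- build_network(panel6(), rm)
  path <- tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, net$edges)
})
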