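#' Simulation configuration with study-scale defaults
#'
#' Bundles every knob of the synthetic-data generators. The defaults mirror
#' the structure of the empirical dataset the pipeline is designed for:
#' 99 species, 248/256 chemical features per sex of which 43/9 are
#' sex-specific, six replicates per species-sex, single-sensillum responses
#' between 25 and 125 spikes/s with sub-threshold noise at or below
#' 10 spikes/s, and a stronger phylogenetic signal in male than female
#' profiles (lambda 0.8 vs 0.2).
#'
#' @param seed Integer seed.
#' @param n_species Number of tips in the simulated phylogeny.
#' @param birth_rate Yule birth rate (per lineage, per unit time).
#' @param lambda_true Named vector `c(male=, female=)` of Pagel's lambda
#'   used for the species-mean log areas of shared features.
#' @param sigma2_true Brownian rate for species-mean log areas.
#' @param n_shared Number of features present in both sexes of every
#'   species; together with `n_sex_specific` this sets the ~250 features
#'   per sex.
#' @param n_sex_specific Named vector `c(male=, female=)`: number of
#'   compounds present in exactly one sex.
#' @param transfer_prob Probability a male-specific compound is transferred
#'   to females during mating.
#' @param n_replicates Replicates per species-sex stratum (>= 5).
#' @param peak_noise_cv Coefficient of variation of the log-normal
#'   replicate noise on peak areas.
#' @param detect_intra_prob Probability a species detects a conspecific
#'   male-specific compound (per sensillum).
#' @param detect_inter_prob Named vector `c(at1=, at4=)`: probability of
#'   detecting a heterospecific male-specific compound.
#' @param response_range Supra-threshold response interval, spikes/s.
#' @param noise_ceiling Upper bound of sub-threshold noise, spikes/s.
#' @param mk_gain,mk_loss Gain/loss rates of the two-state Markov process
#'   that scatters sex-specific compound production across the tree.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 99L,
                       birth_rate = 1,
                       lambda_true = c(male = 0.8, female = 0.2),
                       sigma2_true = 1,
                       n_shared = 210L,
                       n_sex_specific = c(male = 43L, female = 9L),
                       transfer_prob = 0.7,
                       n_replicates = 6L,
                       peak_noise_cv = 0.3,
                       detect_intra_prob = 0.73,
                       detect_inter_prob = c(at1 = 0.25, at4 = 0.10),
                       response_range = c(25, 125),
                       noise_ceiling = 10,
                       mk_gain = 0.2,
                       mk_loss = 0.8) {
  cfg <- list(seed = as.integer(seed), n_species = as.integer(n_species),
              birth_rate = birth_rate, lambda_true = lambda_true,
              sigma2_true = sigma2_true,
              n_shared = as.integer(n_shared),
              n_sex_specific = n_sex_specific,
              transfer_prob = transfer_prob,
              n_replicates = as.integer(n_replicates),
              peak_noise_cv = peak_noise_cv,
              detect_intra_prob = detect_intra_prob,
              detect_inter_prob = detect_inter_prob,
              response_range = response_range,
              noise_ceiling = noise_ceiling,
              mk_gain = mk_gain, mk_loss = mk_loss)
  probs <- c(cfg$transfer_prob, cfg$detect_intra_prob,
             cfg$detect_inter_prob, cfg$lambda_true)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and lambda values must lie in [0, 1]")
  if (cfg$n_replicates < 5L)
    stop("n_replicates must be >= 5")
  if (cfg$n_shared < 1L) stop("n_shared must be >= 1")
  if (any(cfg$n_sex_specific < 0L)) stop("n_sex_specific must be >= 0")
  if (cfg$birth_rate <= 0) stop("birth_rate must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Starts from a root with two lineages; while k lineages are extant the
#' next split waits an Exp(k * birth_rate) time and hits a uniformly
#' chosen lineage. The final epoch (k = n) also runs to its next (unused)
#' split time, so the expected root-to-tip depth is
#' `sum(1 / (k * birth_rate))` for k = 2..n. The tree is ultrametric with
#' tips `t1..tn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage birth rate (> 0).
#' @param seed Optional integer seed.
#' @return A `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  # node records: children[[i]] (ids) and pending edge length to parent
  children <- list()
  edge_len <- numeric(0)
  new_node <- function() {
    children[[length(children) + 1L]] <<- integer(0)
    edge_len[length(edge_len) + 1L] <<- 0
    length(children)
  }
  root <- new_node()
  active <- c(new_node(), new_node())
  children[[root]] <- active
  for (k in 2:n_tips) {
    t <- stats::rexp(1L, rate = k * birth_rate)
    edge_len[active] <- edge_len[active] + t
    if (k < n_tips) {
      i <- active[sample.int(k, 1L)]
      kids <- c(new_node(), new_node())
      children[[i]] <- kids
      active <- c(setdiff(active, i), kids)
    }
  }
  tip_no <- 0L
  build <- function(v) {
    if (!length(children[[v]])) {
      tip_no <<- tip_no + 1L
      return(sprintf("t%d:%.10g", tip_no, edge_len[v]))
    }
    inner <- paste(vapply(children[[v]], build, character(1)),
                   collapse = ",")
    if (v == root) sprintf("(%s);", inner)
    else sprintf("(%s):%.10g", inner, edge_len[v])
  }
  ape::read.tree(text = build(root))
}

#' Simulate traits under lambda-transformed Brownian motion
#'
#' Each trait column is one draw from MVN(mu * 1, sigma2 * C(lambda))
#' where C is the tree's Brownian covariance and C(lambda) its Pagel
#' transform.
#'
#' @param tree `"phylo"` object.
#' @param lam Pagel's lambda in `[0, 1]`.
#' @param sigma2 Brownian rate (>= 0; 0 gives constant traits equal to
#'   `mu`).
#' @param mu Root mean.
#' @param n_traits Number of independent trait columns.
#' @param seed Optional integer seed.
#' @return Species x trait matrix (rownames = tip labels).
#' @export
simulate_bm_traits <- function(tree, lam, sigma2, mu = 0, n_traits = 1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(tree)
  n <- nrow(C)
  out <- matrix(mu, n, n_traits,
                dimnames = list(rownames(C),
                                paste0("trait_", seq_len(n_traits))))
  if (sigma2 > 0) {
    ch <- chol_ridge(sigma2 * lambda_transform(C, lam))
    Z <- matrix(stats::rnorm(n * n_traits), n, n_traits)
    out <- out + crossprod(ch, Z)
  }
  out
}

#' Simulate binary compound presence under a two-state Markov model
#'
#' A gain/loss continuous-time Markov chain is run down every branch from
#' a fixed root state, independently per compound; this produces the
#' patchy across-clade presence patterns typical of male-specific
#' compounds.
#'
#' @param tree `"phylo"` object.
#' @param gain_rate,loss_rate Transition rates (>= 0).
#' @param root_state 0 (absent) or 1 (present) at the root.
#' @param n_compounds Number of independent compound columns.
#' @param seed Optional integer seed.
#' @return Species x compound 0/1 matrix.
#' @export
simulate_mk_presence <- function(tree, gain_rate, loss_rate,
                                 root_state = 0L, n_compounds = 1,
                                 seed = NULL) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (!root_state %in% c(0L, 1L)) stop("root_state must be 0 or 1")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  alpha <- gain_rate + loss_rate
  p <- if (alpha > 0) gain_rate / alpha else 0
  eo <- ape::reorder.phylo(tree, "cladewise")
  out <- matrix(0L, ntip, n_compounds,
                dimnames = list(tree$tip.label,
                                paste0("cmp_", seq_len(n_compounds))))
  for (j in seq_len(n_compounds)) {
    state <- integer(ntip + tree$Nnode)
    state[ntip + 1L] <- root_state
    for (i in seq_len(nrow(eo$edge))) {
      par <- eo$edge[i, 1L]; child <- eo$edge[i, 2L]
      decay <- if (alpha > 0) exp(-alpha * eo$edge.length[i]) else 1
      pr1 <- p + (state[par] - p) * decay
      state[child] <- stats::rbinom(1L, 1L, pr1)
    }
    out[, j] <- state[seq_len(ntip)]
  }
  out
}

#' Simulate a replicate-level peak table with known ground truth
#'
#' Shared features get species-mean log areas evolved under the per-sex
#' lambda model; sex-specific features are assigned producing species by
#' the gain/loss Markov process (at least one producer is guaranteed);
#' replicate areas are log-normal around the species mean with the
#' configured coefficient of variation. Transferred male-specific
#' compounds additionally appear on mated females of producing species.
#'
#' @param cfg A [sim_config()].
#' @param tree Optional `"phylo"`; simulated from `cfg` when missing.
#' @return List with `peak_table` (data frame), `truth` (a
#'   `"compound_catalog"` holding the generating specificity, transfer
#'   flags and producing species) and `tree`.
#' @export
simulate_peak_table <- function(cfg, tree = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(tree))
    tree <- simulate_tree(cfg$n_species, cfg$birth_rate)
  species <- tree$tip.label
  sdlog <- sqrt(log(1 + cfg$peak_noise_cv^2))

  shared <- paste0("sh_", seq_len(cfg$n_shared))
  specific <- list(); producing <- list(); transferred <- character(0)
  mean_log <- list()
  for (sex in c("male", "female")) {
    # shared features are present in both sexes; their per-sex
    # species-mean log areas carry the per-sex phylogenetic signal
    mean_log[[sex]] <- log(100) + simulate_bm_traits(
      tree, lam = cfg$lambda_true[[sex]], sigma2 = cfg$sigma2_true,
      mu = 0, n_traits = cfg$n_shared)
    colnames(mean_log[[sex]]) <- shared
    n_spec <- cfg$n_sex_specific[[sex]]
    sp_feats <- if (n_spec > 0)
      paste0(substr(sex, 1, 1), "sp_", seq_len(n_spec)) else character(0)
    specific[[sex]] <- sp_feats
    if (n_spec > 0) {
      pres <- simulate_mk_presence(tree, cfg$mk_gain, cfg$mk_loss,
                                   root_state = 0L, n_compounds = n_spec)
      colnames(pres) <- sp_feats
      for (f in sp_feats) {
        prods <- species[pres[, f] == 1L]
        if (!length(prods)) prods <- sample(species, 1L)
        producing[[f]] <- data.frame(species = prods, feature = f,
                                     sex = sex, stringsAsFactors = FALSE)
      }
      if (sex == "male")
        transferred <- sp_feats[stats::runif(n_spec) < cfg$transfer_prob]
    }
  }
  producing <- if (length(producing))
    do.call(rbind, c(producing, list(make.row.names = FALSE)))
  else
    data.frame(species = character(0), feature = character(0),
               sex = character(0))

  draw_area <- function(mlog, n) exp(mlog + sdlog * stats::rnorm(n))
  rows <- list()
  emit <- function(sp, sex, mating, feats, mlogs) {
    nr <- cfg$n_replicates
    for (r in seq_len(nr)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        species = sp, sex = sex, mating = mating,
        replicate = paste0(mating, "_", r), feature = feats,
        area = draw_area(mlogs, length(feats)),
        stringsAsFactors = FALSE)
    }
  }
  sp_mean_log <- log(50)  # sex-specific compounds: flat species mean
  for (sp in species) {
    m_spec <- producing$feature[producing$species == sp &
                                  producing$sex == "male"]
    f_spec <- producing$feature[producing$species == sp &
                                  producing$sex == "female"]
    emit(sp, "male", "virgin", c(shared, m_spec),
         c(mean_log$male[sp, ], rep(sp_mean_log, length(m_spec))))
    f_logs <- c(mean_log$female[sp, ], rep(sp_mean_log, length(f_spec)))
    emit(sp, "female", "virgin", c(shared, f_spec), f_logs)
    got <- intersect(m_spec, transferred)
    emit(sp, "female", "mated", c(shared, f_spec, got),
         c(f_logs, rep(sp_mean_log, length(got))))
  }
  pt <- do.call(rbind, rows)
  rownames(pt) <- NULL

  all_feats <- sort(c(shared, specific$male, specific$female))
  spec_of <- function(f) {
    if (f %in% specific$male) "male_specific"
    else if (f %in% specific$female) "female_specific"
    else "shared"
  }
  specificity <- vapply(all_feats, spec_of, character(1))
  truth <- structure(list(
    compounds = data.frame(
      feature = all_feats, specificity = unname(specificity),
      transferred = ifelse(specificity == "male_specific",
                           all_feats %in% transferred, NA),
      n_producing_species = vapply(all_feats, function(f)
        sum(producing$feature == f), integer(1)),
      stringsAsFactors = FALSE),
    producing = producing,
    species_status = data.frame(
      species = species,
      status = ifelse(species %in% producing$species, "dimorphic",
                      "monomorphic"),
      stringsAsFactors = FALSE)),
    class = "compound_catalog")
  list(peak_table = pt, truth = truth, tree = tree)
}

#' Simulate a single-sensillum response matrix with known ground truth
#'
#' For every detector species x male-specific compound x sensillum cell a
#' detection is drawn (conspecific compounds with `detect_intra_prob`,
#' heterospecific with the per-sensillum `detect_inter_prob`); detected
#' cells get responses uniform in `response_range`, the rest sub-threshold
#' noise uniform in `[0, noise_ceiling]`.
#'
#' @param catalog `"compound_catalog"` (truth or called) providing the
#'   producing species of each male-specific compound.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (defaults to `cfg$seed + 1`).
#' @return List with `response_matrix` (data frame) and `truth_edges`
#'   (detector, producer, sensillum of every generated detection).
#' @export
simulate_response_matrix <- function(catalog, cfg, seed = NULL) {
  stopifnot(inherits(catalog, "compound_catalog"),
            inherits(cfg, "sim_config"))
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  species <- catalog$species_status$species
  ms <- catalog$compounds$feature[
    catalog$compounds$specificity == "male_specific"]
  inter <- cfg$detect_inter_prob
  if (length(inter) == 1L) inter <- c(at1 = inter, at4 = unname(inter))
  rows <- list(); edges <- list()
  for (sens in c("at1", "at4")) {
    for (f in ms) {
      prods <- catalog$producing$species[catalog$producing$feature == f]
      for (sp in species) {
        p_det <- if (sp %in% prods) cfg$detect_intra_prob else
          inter[[sens]]
        hit <- stats::runif(1) < p_det
        resp <- if (hit)
          stats::runif(1, cfg$response_range[1], cfg$response_range[2])
        else stats::runif(1, 0, cfg$noise_ceiling)
        rows[[length(rows) + 1L]] <- data.frame(
          detector = sp, compound = f, sensillum = sens,
          mean_response = resp, n = sample(3:10, 1L),
          stringsAsFactors = FALSE)
        if (hit)
          for (pr in prods)
            edges[[length(edges) + 1L]] <- data.frame(
              detector = sp, producer = pr, sensillum = sens,
              stringsAsFactors = FALSE)
      }
    }
  }
  rm <- do.call(rbind, rows)
  truth <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(detector = character(0), producer = character(0),
               sensillum = character(0))
  rownames(rm) <- rownames(truth) <- NULL
  list(response_matrix = rm, truth_edges = truth)
}
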