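#' Read a species x compound x sensillum response matrix
#'
#' @param path TSV with header columns
#'   `detector, compound, sensillum, mean_response, n`.
#' @return Validated response data frame.
#' @export
read_response_matrix <- function(path) {
  rm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_response_matrix(rm)
}

#' Validate a response matrix
#'
#' @param rm Data frame with columns `detector, compound, sensillum,
#'   mean_response, n`. Responses are mean firing rates (spikes/s) and may
#'   be negative (inhibition); `n` is the number of recordings (>= 1).
#' @return `rm` unchanged on success.
#' @export
validate_response_matrix <- function(rm) {
  need <- c("detector", "compound", "sensillum", "mean_response", "n")
  miss <- setdiff(need, names(rm))
  if (length(miss))
    stop("response matrix missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(rm$sensillum %in% c("at1", "at4")))
    stop("sensillum must be 'at1' or 'at4'")
  if (any(rm$n < 1)) stop("n_recordings must be >= 1")
  rm
}

#' Build the olfactory detection network
#'
#' Directed graph: an edge detector -> producer (per sensillum class)
#' exists when at least one of the producer's male-specific compounds
#' elicits a mean response strictly above `threshold` spikes/s in the
#' detector; responses at or below the threshold are excluded. A species
#' detecting one of its own male-specific compounds carries a self-loop.
#' Negative (inhibitory) responses never create edges. Species without
#' male-specific compounds (monomorphic) are nodes that can detect but
#' never be detected.
#'
#' @param catalog `"compound_catalog"` providing producing species per
#'   male-specific compound.
#' @param rm Response data frame (see [validate_response_matrix()]).
#' @param threshold Exclusion threshold in spikes/s; default 10.
#' @return Object of class `"detection_network"`: `nodes` (all species),
#'   `edges` data frame (detector, producer, sensillum,
#'   compounds = comma-joined supporting compounds).
#' @export
build_network <- function(catalog, rm, threshold = 10) {
  stopifnot(inherits(catalog, "compound_catalog"))
  rm <- validate_response_matrix(rm)
  ms <- catalog$compounds$feature[
    catalog$compounds$specificity == "male_specific"]
  producers_of <- split(
    catalog$producing$species[catalog$producing$sex == "male"],
    catalog$producing$feature[catalog$producing$sex == "male"])
  nodes <- sort(unique(c(catalog$species_status$species, rm$detector)))
  unknown <- setdiff(unique(rm$compound), catalog$compounds$feature)
  if (length(unknown))
    warning("compound(s) absent from catalog ignored: ",
            paste(unknown, collapse = ", "))
  hit <- rm[rm$mean_response > threshold & rm$compound %in% ms, ,
            drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(hit))) {
    prods <- producers_of[[hit$compound[i]]]
    for (pr in prods)
      edges[[length(edges) + 1L]] <-
        data.frame(detector = hit$detector[i], producer = pr,
                   sensillum = hit$sensillum[i],
                   compound = hit$compound[i], stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(detector = character(0), producer = character(0),
               sensillum = character(0), compound = character(0))
  # collapse supporting compounds per (detector, producer, sensillum)
  if (nrow(edges)) {
    key <- paste(edges$detector, edges$producer, edges$sensillum,
                 sep = "\r")
    comp <- tapply(edges$compound, key,
                   function(z) paste(sort(unique(z)), collapse = ","))
    parts <- strsplit(names(comp), "\r", fixed = TRUE)
    edges <- data.frame(
      detector = vapply(parts, `[`, "", 1L),
      producer = vapply(parts, `[`, "", 2L),
      sensillum = vapply(parts, `[`, "", 3L),
      compounds = unname(comp), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(detector = character(0), producer = character(0),
                        sensillum = character(0),
                        compounds = character(0))
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "detection_network")
}

#' @export
print.detection_network <- function(x, ...) {
  loops <- sum(x$edges$detector == x$edges$producer)
  cat("Olfactory detection network: ", length(x$nodes), " species, ",
      nrow(x$edges), " edges (", loops, " self-loops), threshold > ",
      x$threshold, " spikes/s\n", sep = "")
  invisible(x)
}

#' Olfactory clustering coefficient of one species
#'
#' The number of *other* species whose male-specific compounds the focal
#' species detects through the given sensillum class, divided by the total
#' number of other species in the panel. Self-loops are excluded from both
#' numerator and denominator, so the coefficient runs from 0 (no species
#' detected) to 1 (all species detected).
#'
#' @param net `"detection_network"`.
#' @param focal Species label (must be a node).
#' @param sensillum `"at1"` or `"at4"`.
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net, focal, sensillum) {
  stopifnot(inherits(net, "detection_network"))
  if (!focal %in% net$nodes) stop("unknown focal species: ", focal)
  if (length(net$nodes) < 2L) stop("need >= 2 species")
  e <- net$edges
  detected <- unique(e$producer[e$detector == focal &
                                  e$sensillum == sensillum &
                                  e$producer != focal])
  length(detected) / (length(net$nodes) - 1L)
}

#' Clustering coefficients for all species and both sensilla
#'
#' @param net `"detection_network"`.
#' @return Data frame with columns `species`, `at1`, `at4`.
#' @export
clustering_coefficients <- function(net) {
  stopifnot(inherits(net, "detection_network"))
  data.frame(
    species = net$nodes,
    at1 = vapply(net$nodes, clustering_coefficient, numeric(1),
                 net = net, sensillum = "at1"),
    at4 = vapply(net$nodes, clustering_coefficient, numeric(1),
                 net = net, sensillum = "at4"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Self-loop (conspecific detection) summary
#'
#' A self-loop means the females of a species detect a male-specific
#' compound of their own males through the given sensillum class.
#'
#' @param net `"detection_network"`.
#' @return List with `table` (species x {at1, at4} logical data frame) and
#'   `totals` (named count of self-loops per sensillum).
#' @export
self_loop_summary <- function(net) {
  stopifnot(inherits(net, "detection_network"))
  e <- net$edges
  loops <- e[e$detector == e$producer, , drop = FALSE]
  tab <- data.frame(
    species = net$nodes,
    at1 = net$nodes %in% loops$detector[loops$sensillum == "at1"],
    at4 = net$nodes %in% loops$detector[loops$sensillum == "at4"],
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       totals = c(at1 = sum(tab$at1), at4 = sum(tab$at4)))
}

#' Compare at1 and at4 clustering coefficients across species
#'
#' Two-sided Mann-Whitney rank-sum test of the per-species clustering
#' coefficients through at1 versus at4 (unpaired, mirroring the original
#' analysis although the samples share species).
#'
#' @param net `"detection_network"` with >= 2 species.
#' @return A `"stat_result"`.
#' @export
compare_coefficients <- function(net) {
  cc <- clustering_coefficients(net)
  if (nrow(cc) < 2L) stop("need >= 2 species")
  rs <- rank_sum_test(cc$at1, cc$at4)
  stat_result(rs$statistic, rs$p_value,
              "Mann-Whitney (at1 vs at4 clustering coefficients)",
              nrow(cc), nrow(cc))
}

#' Export the network as an edge-list TSV
#'
#' @param net `"detection_network"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
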