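#' Parse a Newick string into a phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned object
#' is a standard `"phylo"` tree with tip labels in Newick appearance order
#' (cladewise), which is the label order used by [phylo_covariance()].
#'
#' @param text A single Newick string (one tree, terminated by `;`).
#' @param missing_length Branch length substituted for edges that carry no
#'   length in the input. Default 0.
#' @return An object of class `"phylo"`.
#' @details Tip labels must be unique: duplicate labels would make
#'   label-aligned trait vectors ambiguous, so they are an error. Negative
#'   branch lengths are rejected. A quick bracket scan reports the character
#'   position of the first unbalanced parenthesis before handing the string
#'   to the parser.
#' @export
parse_newick <- function(text, missing_length = 0) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unmatched ')' at position ", i)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e)))
  if (is.null(tree) || is.null(tree$tip.label))
    stop("malformed Newick: parser returned no tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(missing_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    tree$edge.length[is.na(tree$edge.length)] <- missing_length
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  if (!ape::is.rooted(tree)) {
    warning("tree is unrooted; rooting at the first child of the basal ",
            "multifurcation")
    tree <- ape::root(tree, outgroup = tree$tip.label[1L],
                      resolve.root = TRUE)
  }
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; if `""` (default) the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = "") {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = file)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' C[i, j] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. Under Brownian motion with rate
#' sigma^2 the tip trait covariance is sigma^2 * C.
#'
#' @param tree A `"phylo"` object with >= 2 tips and branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames, rows and
#'   columns in the tree's cladewise (Newick appearance) tip order.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L)
    stop("tree must have >= 2 tips for a comparative covariance")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  C <- ape::vcv.phylo(tree)
  C[C < 0 & C > -1e-12] <- 0  # clip tiny negative rounding
  C
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of `C` by `lam`, leaving the
#' diagonal untouched. `lam = 1` returns `C`; `lam = 0` removes all shared
#' history (a star phylogeny with the original tip depths).
#'
#' @param C Covariance matrix from [phylo_covariance()].
#' @param lam Lambda in `[0, 1]`. Values above 1 can break positive
#'   semi-definiteness on non-ultrametric trees and are rejected.
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  Ct <- C * lam
  diag(Ct) <- diag(C)
  Ct
}

# Cholesky of a covariance with a ridge fallback for (near-)singular C,
# e.g. exactly coincident tips from zero-length branches. Returns the
# upper-triangular factor; warns once when the ridge is engaged.
chol_ridge <- function(V, ridge_frac = 1e-10) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- ridge_frac * sum(diag(V))
    warning("covariance numerically singular; adding ridge ",
            format(ridge, digits = 3), " to the diagonal")
    ch <- chol(V + diag(ridge, nrow(V)))
  }
  ch
}
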