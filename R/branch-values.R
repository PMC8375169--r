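#' Stable branch identifiers
#'
#' A branch is identified by the sorted set of tip labels below it (its
#' subtended clade), joined with `"|"`. This identity survives re-reading the
#' tree from Newick and is how per-branch annotation maps (rate scalars,
#' branch-wise dN/dS) are keyed.
#'
#' @param tree A `phylo` object.
#' @return Character vector, one id per row of `tree$edge`.
#' @export
branch_ids <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  M <- branch_tip_matrix(tree)
  tips <- tree$tip.label
  apply(M, 1, function(row) paste(sort(tips[row]), collapse = "|"))
}

# E x ntip logical matrix: which tips lie below each edge
branch_tip_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  E <- nrow(edge)
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  # postorder accumulation
  ord <- postorder_edges(tree)
  for (e in ord) below[edge[e, 1], ] <- below[edge[e, 1], ] | below[edge[e, 2], ]
  M <- below[edge[, 2], , drop = FALSE]
  colnames(M) <- tree$tip.label
  M
}

# edge indices in postorder (children before parents); works for polytomies
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

#' Construct a branch-value map
#'
#' A tidy per-branch scalar field: one row per branch of `tree`, keyed by the
#' stable branch id. `kind` tags what the value is (`"r"`, `"rt"`, `"dN"`,
#' `"dS"`, or any label).
#'
#' @param tree A `phylo` object.
#' @param values Numeric vector in `tree$edge` row order, or a named vector
#'   keyed by branch id.
#' @param kind Value-kind tag.
#' @return Tibble with columns `branch`, `value`, `kind`.
#' @export
branch_values <- function(tree, values, kind = "value") {
  ids <- branch_ids(tree)
  if (!is.null(names(values))) {
    idx <- match(ids, names(values))
    if (anyNA(idx)) stop("missing value for branch(es): ",
                         paste(head(ids[is.na(idx)], 3), collapse = "; "),
                         call. = FALSE)
    values <- as.numeric(values[idx])
  }
  if (length(values) != length(ids))
    stop("need one value per branch (", length(ids), "), got ",
         length(values), call. = FALSE)
  if (any(values < 0 | !is.finite(values)))
    stop("branch values must be finite and >= 0", call. = FALSE)
  tibble::tibble(branch = ids, value = values, kind = kind)
}

# numeric vector aligned to tree$edge rows from a branch_values tibble
match_branch_values <- function(tree, bv) {
  stopifnot(is.data.frame(bv), all(c("branch", "value") %in% names(bv)))
  ids <- branch_ids(tree)
  idx <- match(ids, bv$branch)
  if (anyNA(idx))
    stop("branch-value map does not cover branch(es): ",
         paste(head(ids[is.na(idx)], 3), collapse = "; "), call. = FALSE)
  bv$value[idx]
}

#' Scale branch lengths by per-branch rate scalars
#'
#' Each branch length t becomes t * r: the rate-scaled branch length. Used to
#' build the phenotypic rate-scaled tree from posterior median rate scalars.
#'
#' @param tree A `phylo` object (lengths in time units).
#' @param scalars A [branch_values()] tibble of rate scalars, or a numeric
#'   vector in edge order.
#' @return A `phylo` with scaled branch lengths; topology unchanged.
#' @export
scale_branches <- function(tree, scalars) {
  r <- if (is.data.frame(scalars)) match_branch_values(tree, scalars)
       else {
         if (length(scalars) != nrow(tree$edge))
           stop("need one scalar per branch", call. = FALSE)
         as.numeric(scalars)
       }
  if (any(!is.finite(r) | r < 0)) stop("rate scalars must be finite and >= 0",
                                       call. = FALSE)
  tree$edge.length <- tree$edge.length * r
  tree
}

#' Root-to-tip path sums of a per-branch field
#'
#' For each species, sums the per-branch values along the unique path from the
#' root to that tip. With `values = NULL` the branch lengths themselves are
#' summed (root-to-tip distances).
#'
#' @param tree A rooted `phylo` object.
#' @param values Optional [branch_values()] tibble; defaults to branch
#'   lengths.
#' @param kind Tag for the output (`"R_phen"`, `"R_dN"`, `"R_dS"`, ...).
#' @return Tibble with columns `species`, `total`, `kind`.
#' @export
root_to_tip_sum <- function(tree, values = NULL, kind = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    stop("tree is unrooted: root it (e.g. on the outgroup) before computing ",
         "root-to-tip sums", call. = FALSE)
  v <- if (is.null(values)) tree$edge.length else match_branch_values(tree, values)
  if (is.null(kind)) kind <- if (is.null(values)) "length" else
    (if ("kind" %in% names(values)) values$kind[1] else "value")
  M <- branch_tip_matrix(tree)
  tot <- as.numeric(crossprod(M, v))
  tibble::tibble(species = tree$tip.label, total = tot, kind = kind)
}

#' Phylogenetic covariance matrix
#'
#' `V[i, j]` is the summed branch length shared by the root-to-tip paths of
#' species i and j: the Brownian-motion trait covariance implied by the tree.
#'
#' @param tree A rooted `phylo` object.
#' @return Symmetric matrix with species dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # the basal node serves as the root; a star tree yields a diagonal matrix
  M <- branch_tip_matrix(tree)
  w <- tree$edge.length
  V <- crossprod(M * sqrt(w))
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

# attach an outgroup tip below a new root; stem reaches back `stem` Myr
# beyond the ingroup root
add_outgroup <- function(tree, label = "Outgroup", stem = 50) {
  depth <- max(node_depths(tree))
  txt <- sub(";\\s*$", "", write_newick(tree))
  read_newick(sprintf("(%s:%g,%s:%g);", label, depth + stem, txt, stem))
}

# root-to-tip distance of every tip
node_depths <- function(tree) {
  rts <- root_to_tip_sum(tree)
  setNames(rts$total, rts$species)
}
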