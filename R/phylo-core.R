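#' Read a phylogeny from a newick file or string
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' ordinary `"phylo"` object; every branch must carry a nonnegative length and
#' tip labels must be unique, because all downstream covariance machinery
#' relies on both.
#'
#' @param file Path to a newick file (one tree).
#' @param text Newick string; exactly one of `file`/`text` must be given.
#' @return An object of class `"phylo"`.
#' @export
read_phylogeny <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of `file` or `text`")
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) stop("newick parse error: no tree could be read")
  if (inherits(tr, "multiPhylo"))
    stop("multiple trees found; use read_posterior_trees()")
  validate_phylogeny(tr)
  tr
}

#' Read a multi-tree newick file (e.g. a posterior tree set)
#'
#' @param file Path to a file with one newick tree per line.
#' @return A `"multiPhylo"` list of validated trees.
#' @export
read_posterior_trees <- function(file) {
  trs <- ape::read.tree(file)
  if (is.null(trs)) stop("no trees could be read from ", file)
  if (inherits(trs, "phylo")) trs <- c(trs)  # promote single tree
  for (i in seq_along(trs)) {
    ok <- tryCatch({ validate_phylogeny(trs[[i]]); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) stop("tree ", i, ": ", ok)
  }
  trs
}

#' Write one or more phylogenies to newick
#'
#' @param tree A `"phylo"` or `"multiPhylo"` object.
#' @param file Output path; multi-tree objects are written one tree per line.
#' @export
write_phylogeny <- function(tree, file) {
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks: branch lengths present and nonnegative, unique tip labels, all tips
#' reachable from the root. Zero-length branches are allowed (they arise from
#' polytomy resolution). A single-tip tree is accepted but is unusable for any
#' covariance computation.
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; they are required")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ntip <- length(tree$tip.label)
  if (ntip >= 2) {
    # all tips reachable from root: every tip appears as a child in the edge table
    kids <- tree$edge[, 2L]
    if (!all(seq_len(ntip) %in% kids))
      stop("tree is disconnected: some tips are unreachable from the root")
  }
  invisible(tree)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in `keep`, collapsing the resulting unary internal nodes
#' with their branch lengths summed, so path lengths between retained tips are
#' unchanged.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @export
prune_phylogeny <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Rows follow the tree's tip order and
#' carry tip labels; downstream joins are always by label.
#'
#' @param tree A `"phylo"` object with at least 2 tips.
#' @param check_psd Verify positive semidefiniteness (eigenvalues
#'   >= -1e-10 * trace).
#' @return A labeled symmetric matrix.
#' @export
phylo_vcv <- function(tree, check_psd = TRUE) {
  validate_phylogeny(tree)
  if (length(tree$tip.label) < 2)
    stop("covariance is undefined for a tree with fewer than 2 tips")
  C <- ape::vcv.phylo(tree)
  if (check_psd) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * sum(diag(C)))
      stop("phylogenetic covariance is not positive semidefinite")
  }
  C
}

#' Transform a phylogenetic covariance under an evolutionary model
#'
#' Applies the covariance transform implied by a continuous-trait model:
#' \describe{
#'   \item{BM}{`sigma2 * C`, unchanged shape.}
#'   \item{lambda}{Pagel's lambda: off-diagonals multiplied by `lambda`,
#'     diagonal untouched, then scaled by `sigma2`.}
#'   \item{OU}{Ornstein-Uhlenbeck with attraction `alpha`:
#'     `V[i,j] = sigma2/(2 alpha) * exp(-alpha d_ij) * (1 - exp(-2 alpha t_ij))`
#'     with `d_ij` the patristic distance and `t_ij` the shared root-to-MRCA
#'     depth. This is the non-ultrametric form (the behaviour of
#'     `nlme::corMartins` is the reference); on an ultrametric tree it reduces
#'     to the familiar stationary OU covariance.}
#'   \item{EB}{Early burst with decay `r_eb <= 0`: branch-increment rates decay
#'     as `exp(r_eb * t)` with `t` the distance from the root, giving
#'     `V = sigma2 * (exp(r_eb * C) - 1) / r_eb` elementwise (limit `C` as
#'     `r_eb -> 0`).}
#'   \item{white}{`sigma2 * I`: non-phylogenetic noise.}
#' }
#'
#' @param C Covariance from [phylo_vcv()] (BM scale).
#' @param kind One of `"BM"`, `"lambda"`, `"OU"`, `"EB"`, `"white"`, `"trend"`
#'   (trend shares the BM covariance; its trend enters through the mean).
#' @param lambda Pagel's lambda in \[0, 1\] (kind = "lambda").
#' @param alpha OU attraction, > 0 (kind = "OU").
#' @param r_eb Early-burst decay, <= 0 (kind = "EB").
#' @param sigma2 Brownian (or white-noise) rate, > 0.
#' @return The transformed covariance matrix with the same labels.
#' @export
vcv_transform <- function(C, kind = c("BM", "lambda", "OU", "EB", "white",
                                      "trend"),
                          lambda = 1, alpha = NULL, r_eb = 0, sigma2 = 1) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(C), nrow(C) == ncol(C), sigma2 > 0)
  switch(kind,
    BM = ,
    trend = sigma2 * C,
    lambda = {
      if (lambda < 0 || lambda > 1)
        stop("lambda must be in [0, 1], got ", lambda)
      V <- lambda * C
      diag(V) <- diag(C)
      sigma2 * V
    },
    OU = {
      if (is.null(alpha) || alpha <= 0)
        stop("OU requires alpha > 0")
      Ti <- diag(C)
      d <- outer(Ti, Ti, "+") - 2 * C       # patristic distances
      V <- sigma2 / (2 * alpha) * exp(-alpha * d) * (1 - exp(-2 * alpha * C))
      dimnames(V) <- dimnames(C)
      V
    },
    EB = {
      if (r_eb > 0) stop("EB requires r_eb <= 0")
      V <- if (abs(r_eb) < 1e-12) C else expm1(r_eb * C) / r_eb
      dimnames(V) <- dimnames(C)
      sigma2 * V
    },
    white = {
      V <- diag(sigma2, nrow(C))
      dimnames(V) <- dimnames(C)
      V
    }
  )
}

#' Export a covariance matrix as labeled CSV
#'
#' @param C Labeled square matrix.
#' @param file Output path.
#' @export
write_vcv_csv <- function(C, file) {
  df <- data.frame(taxon = rownames(C), C, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

# --- internal tree helpers shared by the rate models ------------------------

# depth of every node (root = 0), indexed by ape node number
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  depth <- numeric(nn)
  root <- n + 1L
  # edges in ape cladewise order are parent-before-child after reorder
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; c <- ord$edge[k, 2L]
    depth[c] <- depth[p] + ord$edge.length[k]
  }
  depth[root] <- 0
  depth
}

# n_tip x n_edge 0/1 incidence: A[i, e] = 1 if edge e lies on the root->tip i path
edge_incidence <- function(tree) {
  n <- length(tree$tip.label)
  m <- nrow(tree$edge)
  # descendant tips per edge via postorder accumulation
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  A <- matrix(0L, n, m)
  # map postorder edges back to original edge indices by matching child nodes
  child_orig <- tree$edge[, 2L]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    tips <- if (ch <= n) ch else desc[[ch]]
    desc[[p]] <- c(desc[[p]], tips)
    e <- match(ch, child_orig)
    A[tips, e] <- 1L
  }
  rownames(A) <- tree$tip.label
  A
}

# tips descending from each node (list indexed by ape node id)
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], if (ch <= n) ch else desc[[ch]])
  }
  desc
}
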