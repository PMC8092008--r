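#' Rooted species tree with a root branch descending from the WGT
#'
#' The loss chain runs from the triplication event down a rooted binary
#' tree.  The edge from the WGT to the first divergence is the *root
#' branch*; in Newick input it is given as the root edge (e.g.
#' `"((a:1,b:1):0.5,c:1):0.3;"` has root-branch length 0.3).  Branch
#' lengths are in expected-loss units `nu = alpha * t`.
#'
#' Internally every node carries the length of the branch above it; the
#' root node carries the root-branch length.  A single-genome tree (one
#' tip whose branch is the root branch) is allowed and useful for
#' closed-form checks.
#'
#' @param x a Newick string, a file path to one, or an [ape::phylo]
#'   object with a `root.edge`.
#' @param root_edge optional root-branch length overriding (or supplying)
#'   the Newick root edge.
#' @return an object of class `"wgt_tree"`: a list with elements `tips`
#'   (labels), `nnode` (total nodes), `child1`/`child2` (0-based child
#'   indices, -1 for tips), `tip_genome` (0-based genome index, -1 for
#'   internal nodes), `postorder` (0-based, root last), `root` (0-based),
#'   `lengths` (branch above each node; root branch for the root) and
#'   `labels`.
#' @examples
#' tr <- wgt_tree("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05):0.3;")
#' tr$tips
#' @export
wgt_tree <- function(x, root_edge = NULL) {
  if (inherits(x, "wgt_tree")) {
    if (!is.null(root_edge)) x$lengths[x$root + 1L] <- root_edge
    return(validate_wgt_tree(x))
  }
  if (is.character(x) && length(x) == 1L) {
    txt <- if (file.exists(x)) paste(readLines(x, warn = FALSE),
                                     collapse = "") else x
    phy <- ape::read.tree(text = txt)
    if (is.null(phy)) stop("could not parse Newick input")
  } else if (inherits(x, "phylo")) {
    phy <- x
  } else {
    stop("x must be a Newick string/file or an ape 'phylo' object")
  }

  if (!is.null(root_edge)) phy$root.edge <- root_edge
  if (is.null(phy$root.edge)) {
    stop("the species tree needs a root edge (the WGT -> first divergence ",
         "branch); supply it in the Newick string or via root_edge =")
  }
  if (is.null(phy$edge.length)) stop("the tree must have branch lengths")
  if (!ape::is.binary(phy)) stop("the species tree must be binary")

  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  lengths <- numeric(nnode)
  child1 <- child2 <- rep(-1L, nnode)
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    lengths[ch] <- phy$edge.length[e]
    if (child1[par] == -1L) child1[par] <- ch - 1L else child2[par] <- ch - 1L
  }
  lengths[root] <- phy$root.edge

  tip_genome <- rep(-1L, nnode)
  tip_genome[seq_len(ntip)] <- seq_len(ntip) - 1L

  # postorder: children before parents
  post <- integer(0)
  visit <- function(node) {       # node is 1-based here
    if (child1[node] != -1L) {
      visit(child1[node] + 1L)
      visit(child2[node] + 1L)
    }
    post <<- c(post, node - 1L)
  }
  visit(root)

  validate_wgt_tree(structure(
    list(tips = phy$tip.label, nnode = nnode,
         child1 = child1, child2 = child2,
         tip_genome = tip_genome, postorder = post, root = root - 1L,
         lengths = lengths, phylo = phy),
    class = "wgt_tree"
  ))
}

#' A single-genome tree whose only branch is the root branch
#' @param label tip label.
#' @param nu root-branch length.
#' @return a `"wgt_tree"` with one node.
#' @export
single_tip_tree <- function(label, nu) {
  structure(
    list(tips = label, nnode = 1L, child1 = -1L, child2 = -1L,
         tip_genome = 0L, postorder = 0L, root = 0L,
         lengths = as.numeric(nu), phylo = NULL),
    class = "wgt_tree"
  )
}

validate_wgt_tree <- function(tr) {
  if (anyDuplicated(tr$tips)) stop("tip labels must be unique")
  if (any(!is.finite(tr$lengths)) || any(tr$lengths < 0)) {
    stop("all branch lengths must be finite and nonnegative")
  }
  tr
}

#' @method print wgt_tree
#' @export
print.wgt_tree <- function(x, ...) {
  cat("WGT species tree with", length(x$tips), "genome(s):",
      paste(x$tips, collapse = ", "), "\n")
  cat(sprintf("  root-branch length %.4g; total branch length %.4g\n",
              x$lengths[x$root + 1L], sum(x$lengths)))
  invisible(x)
}

#' Number of genomes (tips) in a tree
#' @noRd
n_genomes <- function(tree) length(tree$tips)

#' Replace all branch lengths of a tree
#' @noRd
set_lengths <- function(tree, lengths) {
  stopifnot(length(lengths) == tree$nnode)
  tree$lengths <- as.numeric(lengths)
  validate_wgt_tree(tree)
}

#' Branch labels: tip name for tip branches, "node<k>" / "root" otherwise
#' @noRd
branch_labels <- function(tree) {
  lab <- character(tree$nnode)
  ntip <- length(tree$tips)
  lab[seq_len(ntip)] <- tree$tips
  if (tree$nnode > ntip) {
    lab[(ntip + 1L):tree$nnode] <- paste0("node", (ntip + 1L):tree$nnode)
  }
  lab[tree$root + 1L] <- "root"
  lab
}

#' Per-node transition matrices for a model on a tree
#'
#' @return list of 7 x 7 stochastic matrices, one per node (branch above
#'   that node); the root node gets the root-class generator.
#' @noRd
branch_transition_matrices <- function(tree, spec) {
  Qn <- build_generator(spec, "non_root")
  lapply(seq_len(tree$nnode), function(i) {
    if (i - 1L == tree$root) {
      if (spec$variant == "g3root") {
        # expanded chain: arrivals are one-off events (no re-arrival)
        g3root_root_matrix(spec, tree$lengths[i])
      } else {
        transition_probabilities(build_generator(spec, "root"),
                                 tree$lengths[i])
      }
    } else {
      transition_probabilities(Qn, tree$lengths[i])
    }
  })
}

#' Enumerate rooted binary topologies
#'
#' Generates all distinct rooted binary tree shapes over a set of tip
#' labels by sequential tip insertion (every rooted tree on `n` tips
#' arises exactly once, giving the double-factorial count `(2n-3)!!`).
#' Optionally restricts to topologies in which a given pair of tips is a
#' cherry (sister pair), which for four tips leaves the three possible
#' placements of the remaining two.
#'
#' @param tips character vector of at least 3 labels.
#' @param sister optional character vector of length 2: tips forced to be
#'   sisters.
#' @return character vector of Newick strings (no branch lengths).
#' @examples
#' length(enumerate_topologies(letters[1:4]))                    # 15
#' length(enumerate_topologies(letters[1:4], sister = c("a", "b")))  # 3
#' @export
enumerate_topologies <- function(tips, sister = NULL) {
  tips <- as.character(tips)
  if (length(tips) < 3L) stop("need at least 3 tips")
  if (anyDuplicated(tips)) stop("tip labels must be unique")

  # tree as nested list; insert next tip on every edge incl. above the root
  insert_all <- function(tree, tip) {
    res <- list(list(tree, tip))               # new root above old root
    if (is.list(tree)) {
      for (side in 1:2) {
        for (sub in insert_all(tree[[side]], tip)) {
          t2 <- tree
          t2[[side]] <- sub
          res <- c(res, list(t2))
        }
      }
    }
    res
  }
  to_newick <- function(tree) {
    if (!is.list(tree)) return(tree)
    paste0("(", to_newick(tree[[1]]), ",", to_newick(tree[[2]]), ")")
  }
  trees <- list(list(tips[1], tips[2]))
  for (tip in tips[-(1:2)]) {
    trees <- unlist(lapply(trees, insert_all, tip = tip), recursive = FALSE)
  }
  nwk <- paste0(vapply(trees, to_newick, character(1)), ";")

  if (!is.null(sister)) {
    stopifnot(length(sister) == 2L, all(sister %in% tips))
    pat1 <- paste0("(", sister[1], ",", sister[2], ")")
    pat2 <- paste0("(", sister[2], ",", sister[1], ")")
    keep <- grepl(pat1, nwk, fixed = TRUE) | grepl(pat2, nwk, fixed = TRUE)
    nwk <- nwk[keep]
  }
  nwk
}

#' Attach branch lengths to a topology string
#'
#' Gives every branch the same length and the root edge `root_edge`;
#' convenient for turning [enumerate_topologies()] output into
#' [wgt_tree()] input.
#'
#' @param newick topology string without branch lengths.
#' @param nu branch length for every edge.
#' @param root_edge root-branch length.
#' @return a `"wgt_tree"`.
#' @export
topology_with_lengths <- function(newick, nu = 0.1, root_edge = 0.3) {
  phy <- ape::read.tree(text = newick)
  phy$edge.length <- rep(nu, nrow(phy$edge))
  phy$root.edge <- root_edge
  wgt_tree(phy)
}

#' The default four-genome study tree
#'
#' The maximum-likelihood topology for the four hexaploid Brassiceae
#' genomes: the two *Brassica* species are sisters, *Crambe hispanica*
#' joins them, and *Sinapis alba* diverges first, at the end of the root
#' branch.  Branch lengths are round expected-loss values of the order
#' seen in mesopolyploid data: a long root branch (where roughly half of
#' all losses accrue) and shorter post-divergence branches.
#'
#' @param root_edge,internal,tip branch lengths (expected losses per copy
#'   at unit rate).
#' @return a `"wgt_tree"` over genomes `brapa`, `boleracea`, `chispanica`,
#'   `salba`.
#' @export
default_study_tree <- function(root_edge = 0.45, internal = 0.08,
                               tip = 0.12) {
  nwk <- sprintf(
    "(((brapa:%g,boleracea:%g):%g,chispanica:%g):%g,salba:%g):%g;",
    tip, tip, internal, tip + internal, internal, tip + 2 * internal,
    root_edge)
  wgt_tree(nwk)
}
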