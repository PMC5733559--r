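# Rooted phylogeny primitives. Trees are ape "phylo" objects throughout; the
# root's incoming edge (phylo$root.edge), when present, is a serialization
# artifact and contributes 0 to every total.

#' Parse a Newick string into a validated rooted tree
#'
#' Accepts a single Newick statement ending in `;`, with unquoted or
#' single-quoted labels, internal node labels (ignored by all metrics),
#' polytomies, and scientific-notation branch lengths. Every non-root edge
#' must carry a branch length; lengths must be non-negative; tip labels must
#' be unique and non-empty.
#'
#' @param text Newick string (length-1 character).
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' total_branch_length(tr)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("`text` must be a single Newick string")
  }
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "(") {
        depth <- depth + 1L
      } else if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) {
          stop(sprintf("malformed Newick: unbalanced ')' at character %d", i))
        }
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d '(' left unclosed at end of string", depth))
  }
  if (in_quote) stop("malformed Newick: unterminated quoted label")
  if (!grepl(";[[:space:]]*$", text)) {
    stop("malformed Newick: statement must end in ';'")
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: ape could not read the string")
  if (inherits(tree, "multiPhylo")) stop("`text` must contain exactly one tree")
  # single-quoted labels are kept verbatim, without the quotes
  tree$tip.label <- sub("^'(.*)'$", "\\1", tree$tip.label)
  check_tree(tree)
  tree
}

#' Read a single Newick tree from a file
#'
#' @param path Path to a file holding one Newick statement.
#' @return A `"phylo"` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Serialize a tree to Newick
#'
#' Emits plain labels (spaces replaced by `_`) at near-full double precision,
#' so that `parse_newick(write_newick(tree))` restores topology, labels and
#' branch lengths.
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; when given the string is also written to disk.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  check_tree(tree)
  tree$tip.label <- gsub(" ", "_", tree$tip.label, fixed = TRUE)
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# Validate the PhyloTree invariants shared by all metrics.
check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a \"phylo\" object")
  tl <- tree$tip.label
  if (any(!nzchar(tl))) stop("tree validation: empty tip label")
  if (anyDuplicated(tl)) {
    stop("tree validation: duplicated tip label(s): ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("tree validation: branch lengths are missing on all edges")
  }
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    stop("tree validation: missing branch length on edge(s) to node(s) ",
         paste(tree$edge[bad, 2], collapse = ", "))
  }
  if (any(tree$edge.length < 0)) {
    stop("tree validation: negative branch length")
  }
  invisible(tree)
}

# Tip indices for a character vector of labels, with a named lookup error.
tip_index <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "))
  }
  idx
}

# Logical incidence matrix: entry [e, i] is TRUE when edge e lies on the
# root-to-tip path of tip i. The workhorse behind PD, PhyloSor and patristic
# distances; polytomies need no special casing.
edge_tip_incidence <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(ne)
  root <- nt + 1L
  inc <- matrix(FALSE, ne, nt)
  for (tip in seq_len(nt)) {
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      inc[e, tip] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  colnames(inc) <- tree$tip.label
  inc
}

#' Total branch length of a tree
#'
#' Sum of all non-root branch lengths; the root's incoming edge is ignored.
#'
#' @param tree A `"phylo"` object.
#' @return Non-negative scalar in the tree's branch-length units.
#' @export
total_branch_length <- function(tree) {
  check_tree(tree)
  sum(tree$edge.length)
}

#' Patristic distance between two tips
#'
#' Sum of branch lengths on the path from `tipA` up to the most recent common
#' ancestor and down to `tipB`.
#'
#' @param tree A `"phylo"` object.
#' @param tipA,tipB Tip labels.
#' @return Non-negative scalar; 0 iff `tipA == tipB`.
#' @export
patristic_distance <- function(tree, tipA, tipB) {
  check_tree(tree)
  ia <- tip_index(tree, tipA)
  ib <- tip_index(tree, tipB)
  if (ia == ib) return(0)
  inc <- edge_tip_incidence(tree)
  sum(tree$edge.length[xor(inc[, ia], inc[, ib])])
}

#' All pairwise patristic distances
#'
#' @param tree A `"phylo"` object.
#' @return A symmetric matrix with zero diagonal, rows/columns in tip order.
#' @export
patristic_matrix <- function(tree) {
  check_tree(tree)
  inc <- edge_tip_incidence(tree)
  bl <- tree$edge.length
  depth <- colSums(inc * bl)
  shared <- crossprod(inc * bl, inc)   # shared root-path length per tip pair
  d <- outer(depth, depth, "+") - 2 * shared
  d[d < 0] <- 0                        # guard tiny negative rounding
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Branches spanned by a tip set (rooted convention)
#'
#' Returns the set of edges lying on any root-to-tip path of the given tips,
#' i.e. the Faith's-PD branch set *including* the path from the tips' MRCA up
#' to the root. This makes PD monotone under tip-set inclusion and makes the
#' full-set PD equal the total tree length exactly.
#'
#' @param tree A `"phylo"` object.
#' @param tips Non-empty character vector of tip labels.
#' @return An object of class `"branch_set"`: list with `edges` (row indices
#'   into `tree$edge`), `lengths`, and `total`.
#' @export
spanning_branch_set <- function(tree, tips) {
  check_tree(tree)
  if (length(tips) == 0) stop("`tips` must be non-empty")
  idx <- tip_index(tree, unique(tips))
  inc <- edge_tip_incidence(tree)
  sel <- rowSums(inc[, idx, drop = FALSE]) > 0
  structure(
    list(edges = which(sel),
         lengths = tree$edge.length[sel],
         total = sum(tree$edge.length[sel])),
    class = "branch_set"
  )
}

#' @export
print.branch_set <- function(x, ...) {
  cat("Branch set:", length(x$edges), "edges, total length",
      format(x$total), "\n")
  invisible(x)
}

#' Equal-branch-length comparison tree
#'
#' Same topology, with every non-root branch set to the common length
#' `total_branch_length(tree) / n_edges`, preserving the total. This is the
#' denominator tree of relative phylogenetic diversity (RPD).
#'
#' @param tree A `"phylo"` object with positive total branch length.
#' @return A `"phylo"` object.
#' @export
equalize_branch_lengths <- function(tree) {
  check_tree(tree)
  tot <- sum(tree$edge.length)
  if (tot <= 0) stop("cannot equalize a tree with zero total branch length")
  tree$edge.length[] <- tot / nrow(tree$edge)
  tree$root.edge <- NULL
  tree
}

#' Is the tree ultrametric?
#'
#' TRUE when all root-to-tip distances agree within a relative tolerance
#' (default 1e-6). Dated (time-calibrated) trees are ultrametric; none of the
#' metrics in this package require it.
#'
#' @param tree A `"phylo"` object.
#' @param tol Relative tolerance on the depth spread.
#' @return Logical flag.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  check_tree(tree)
  inc <- edge_tip_incidence(tree)
  depth <- colSums(inc * tree$edge.length)
  if (max(depth) == 0) return(TRUE)
  (max(depth) - min(depth)) / max(depth) <= tol
}
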