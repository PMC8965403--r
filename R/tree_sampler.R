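#' Read a taxonomy with monophyly constraints
#'
#' The taxonomy is a rooted classification tree over the analysis taxa.
#' Internal nodes may be polytomous; every internal node is treated as a
#' monophyly constraint. Input is Newick (possibly without branch lengths)
#' or a two-column parent-child table.
#'
#' @param path Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string (alternative to `path`).
#' @return An [ape::read.tree()] `phylo` object (singleton nodes collapsed),
#'   validated by [validate_taxonomy()].
#' @export
read_taxonomy <- function(path = NULL, text = NULL) {
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("taxonomy parse error: ", conditionMessage(e)),
    warning = function(w) stop("taxonomy parse error: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("taxonomy parse error: no tree found")
  if (length(phy$tip.label) < 2) stop("taxonomy needs at least 2 tips")
  phy <- ape::collapse.singles(phy)
  validate_taxonomy(phy)
  phy
}

#' Build a taxonomy from a parent-child classification table
#'
#' @param parent,child Character vectors: `child[i]` is a direct member of
#'   grouping `parent[i]`. Leaves are names that never appear as parents;
#'   the root is the unique name that never appears as a child.
#' @return A `phylo` taxonomy as from [read_taxonomy()].
#' @export
taxonomy_from_table <- function(parent, child) {
  stopifnot(length(parent) == length(child))
  if (anyDuplicated(child)) stop("conflicting constraints: a node has two parents")
  roots <- setdiff(parent, child)
  if (length(roots) != 1)
    stop("classification must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  kids <- split(child, factor(parent, levels = unique(parent)))
  build <- function(node) {
    if (!node %in% names(kids)) return(escape_newick(node))
    paste0("(", paste(vapply(kids[[node]], build, ""), collapse = ","), ")")
  }
  read_taxonomy(text = paste0(build(roots), ";"))
}

escape_newick <- function(x) gsub("[ ():,;]", "_", x)

#' Validate a taxonomy tree
#'
#' @param phy A `phylo` object.
#' @return `phy`, invisibly; errors on duplicate tips, fewer than two tips,
#'   or internal nodes with a single child.
#' @export
validate_taxonomy <- function(phy) {
  if (!inherits(phy, "phylo")) stop("taxonomy must be a 'phylo' object")
  if (length(phy$tip.label) < 2) stop("taxonomy needs at least 2 tips")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon in taxonomy: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  deg <- tabulate(phy$edge[, 1], nbins = length(phy$tip.label) + phy$Nnode)
  if (any(deg[deg > 0] < 2))
    stop("taxonomy has an internal node with a single child")
  invisible(phy)
}

#' Sample a data-free pseudo-posterior of resolved ultrametric trees
#'
#' Every internal node of the taxonomy is kept monophyletic in every sampled
#' tree (frequency 1 across the sample); each polytomy is resolved
#' independently per tree by uniform random sequential pair-joining, i.e.
#' uniformly over labeled histories, so unresolved groupings receive equal
#' support. Node heights come from `branch_model` and are rescaled so the
#' root height is exactly 1 (tips at height 0), making the trees ultrametric
#' and fixing the time unit in which transition rates are later expressed.
#'
#' @param taxonomy A `phylo` taxonomy (see [read_taxonomy()]).
#' @param n Number of trees to sample.
#' @param seed Integer master seed; tree `i` uses derived seed `seed + i - 1`.
#' @param branch_model `"yule"` (default): node heights follow a pure-birth
#'   process conditioned on the topology (inter-node intervals exponential
#'   with rate equal to the number of lineages); `"uniform-order"`: join
#'   heights equally spaced in join order.
#' @return Object of class `tree_posterior`: list with `trees` (a
#'   `multiPhylo`), `seed`, `n`, `branch_model`.
#' @export
sample_trees <- function(taxonomy, n, seed,
                         branch_model = c("yule", "uniform-order")) {
  branch_model <- match.arg(branch_model)
  validate_taxonomy(taxonomy)
  stopifnot(n >= 1)
  trees <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + i - 1L)
    trees[[i]] <- sample_one_tree(taxonomy, branch_model)
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, seed = seed, n = n,
                 branch_model = branch_model),
            class = "tree_posterior")
}

#' @export
print.tree_posterior <- function(x, ...) {
  cat(sprintf("tree_posterior: %d trees, %d tips, branch model '%s', seed %d\n",
              x$n, length(x$trees[[1]]$tip.label), x$branch_model, x$seed))
  invisible(x)
}

# One constrained resolved ultrametric tree, in two passes.
#
# Topology: each taxonomy node's polytomy is resolved independently by
# joining uniformly chosen pairs of its member lineages until one remains —
# uniform over labeled histories of the polytomy, so every resolution of an
# unresolved grouping is equally supported and resolutions of different
# groupings are independent.
#
# Heights: internal nodes are then dated bottom-up in a random order that
# respects the topology; under "yule" the inter-node intervals are the
# pure-birth waiting times (with k lineages in the interval above the j-th
# join from the tips, the interval is Exp(k)), under "uniform-order" join
# heights are equally spaced. Heights are rescaled so the root sits at
# exactly 1 and tips at 0.
sample_one_tree <- function(taxonomy, branch_model) {
  tips <- taxonomy$tip.label
  n <- length(tips)
  kids <- split(taxonomy$edge[, 2], taxonomy$edge[, 1])
  edge <- matrix(0L, 2L * (n - 1L), 2)
  njoin <- 0L
  next_tmp <- n + 1L + taxonomy$Nnode      # temp ids beyond taxonomy range
  resolve <- function(node) {
    if (node <= n) return(node)
    members <- vapply(as.integer(kids[[as.character(node)]]), resolve,
                      integer(1))
    while (length(members) > 1L) {
      pair <- if (length(members) == 2L) 1:2
              else sample.int(length(members), 2L)
      new_id <- next_tmp
      next_tmp <<- next_tmp + 1L
      njoin <<- njoin + 1L
      edge[2L * njoin - 1L, ] <<- c(new_id, members[pair[1]])
      edge[2L * njoin, ] <<- c(new_id, members[pair[2]])
      members <- c(members[-pair], new_id)
    }
    members
  }
  root_tmp <- resolve(n + 1L)
  # remap temp internal ids to ape numbering: root = n+1, rest arbitrary
  tmp_ids <- (n + 1L + taxonomy$Nnode):(next_tmp - 1L)
  map <- integer(next_tmp - 1L)
  map[seq_len(n)] <- seq_len(n)
  others <- tmp_ids[tmp_ids != root_tmp]
  map[others] <- n + 1L + seq_along(others)
  map[root_tmp] <- n + 1L
  edge <- matrix(map[edge], ncol = 2)
  # children of each internal node, and bottom-up random dating order
  ntot <- 2L * n - 1L
  child <- matrix(0L, ntot, 2)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    child[p, if (child[p, 1] == 0L) 1L else 2L] <- edge[e, 2]
  }
  assigned <- c(rep(TRUE, n), rep(FALSE, n - 1L))
  internals <- (n + 1L):ntot
  ready <- internals[assigned[child[internals, 1]] &
                       assigned[child[internals, 2]]]
  height <- numeric(ntot)
  t_now <- 0
  for (j in seq_len(n - 1L)) {
    pick <- if (length(ready) == 1L) ready else
      ready[sample.int(length(ready), 1L)]
    k <- n - j + 1L                        # lineages below this join
    t_now <- if (branch_model == "yule")
      t_now + stats::rexp(1, rate = k) else j / (n - 1)
    height[pick] <- t_now
    assigned[pick] <- TRUE
    ready <- setdiff(ready, pick)
    par <- edge[match(pick, edge[, 2]), 1]
    if (!is.na(par) && assigned[child[par, 1]] && assigned[child[par, 2]])
      ready <- c(ready, par)
  }
  height <- height / t_now                 # root height exactly 1
  phy <- structure(list(edge = edge,
                        edge.length = height[edge[, 1]] - height[edge[, 2]],
                        tip.label = tips, Nnode = n - 1L),
                   class = "phylo")
  stats::reorder(phy, "cladewise")
}

# Character keys ("a|b|c", tips sorted) of all non-trivial clades of a tree.
tree_clade_keys <- function(phy) {
  n <- length(phy$tip.label)
  po <- stats::reorder(phy, "postorder")
  desc <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) desc[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(desc[(n + 1):(n + phy$Nnode)],
         function(s) paste(sort(s), collapse = "|"), "")
}

#' Clade frequency of a tip set across a tree posterior
#'
#' @param posterior A `tree_posterior` (or `multiPhylo`).
#' @param tipset Character vector of at least two taxon names.
#' @return Fraction of trees in which `tipset` is exactly the tip set of
#'   some clade.
#' @export
clade_frequency <- function(posterior, tipset) {
  trees <- if (inherits(posterior, "tree_posterior")) posterior$trees
           else posterior
  all_tips <- trees[[1]]$tip.label
  unknown <- setdiff(tipset, all_tips)
  if (length(unknown) > 0)
    stop("unknown taxa in tipset: ", paste(unknown, collapse = ", "))
  if (length(tipset) < 2) stop("tipset must contain at least two taxa")
  key <- paste(sort(tipset), collapse = "|")
  mean(vapply(trees, function(tr) key %in% tree_clade_keys(tr), FALSE))
}

#' Frequencies of many tip sets in one pass over the posterior
#'
#' @inheritParams clade_frequency
#' @param tipsets List of character vectors of taxa.
#' @return Numeric vector of clade frequencies, one per tip set.
#' @export
clade_frequencies <- function(posterior, tipsets) {
  trees <- if (inherits(posterior, "tree_posterior")) posterior$trees
           else posterior
  keys <- vapply(tipsets, function(s) paste(sort(s), collapse = "|"), "")
  counts <- numeric(length(keys))
  for (tr in trees) {
    present <- keys %in% tree_clade_keys(tr)
    counts <- counts + present
  }
  counts / length(trees)
}

#' Write / read a tree posterior
#'
#' `"newick"` writes one Newick string per line; `"nexus"` writes a NEXUS
#' TREES block with a translate table. Branch lengths are written with 15
#' significant digits so the round trip is lossless to 1e-12 relative
#' precision.
#'
#' @param posterior A `tree_posterior` or `multiPhylo`.
#' @param path Output file.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_trees <- function(posterior, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  trees <- if (inherits(posterior, "tree_posterior")) posterior$trees
           else posterior
  if (format == "newick") {
    writeLines(vapply(trees, ape::write.tree, "", digits = 15), path)
  } else {
    labs <- trees[[1]]$tip.label
    lines <- c("#NEXUS", "BEGIN TAXA;",
               sprintf("\tDIMENSIONS NTAX=%d;", length(labs)),
               "\tTAXLABELS", paste0("\t\t", labs), "\t;", "END;",
               "BEGIN TREES;", "\tTRANSLATE",
               paste0("\t\t", seq_along(labs), " ", labs,
                      c(rep(",", length(labs) - 1), "")),
               "\t;")
    for (i in seq_along(trees)) {
      tr <- trees[[i]]
      tr$tip.label <- as.character(match(tr$tip.label, labs))
      lines <- c(lines, sprintf("\tTREE tree_%d = %s", i,
                                ape::write.tree(tr, digits = 15)))
    }
    writeLines(c(lines, "END;"), path)
  }
  invisible(path)
}

#' @rdname write_trees
#' @param seed Seed recorded on the returned posterior (reading cannot
#'   recover the generator seed; default `NA`).
#' @export
read_trees <- function(path, seed = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  trees <- tryCatch(
    if (grepl("^#NEXUS", first, ignore.case = TRUE)) ape::read.nexus(path)
    else ape::read.tree(path),
    error = function(e) stop("tree parse error in '", path, "': ",
                             conditionMessage(e)),
    warning = function(w) stop("tree parse error in '", path, "': ",
                               conditionMessage(w)))
  if (is.null(trees)) stop("tree parse error in '", path, "': no trees read")
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of length 1
  structure(list(trees = trees, seed = seed, n = length(trees),
                 branch_model = NA_character_),
            class = "tree_posterior")
}
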