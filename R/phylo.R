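#' Pairwise distance matrix from an alignment
#'
#' Proportion of differing sites over the columns where both sequences have
#' an unambiguous nucleotide (gaps `-` and `N` are excluded pairwise, i.e.
#' indels do not contribute), optionally followed by the Jukes-Cantor
#' correction. `gaps = "complete"` instead drops every column containing
#' any ambiguous character before comparing.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, a character matrix (taxa x sites), or a
#'   `Biostrings::DNAStringSet`.
#' @param model `"p"` (raw p-distance) or `"jc"` (Jukes-Cantor).
#' @param gaps `"pairwise"` or `"complete"` deletion.
#' @return symmetric numeric matrix with taxa as dimnames.
#' @examples
#' p_distance(c(a = "ACGT", b = "ACGA"))["a", "b"]  # 0.25
#' p_distance(c(a = "AC-T", b = "ACGT"))["a", "b"]  # 0 over 3 columns
#' @export
p_distance <- function(alignment, model = c("p", "jc"),
                       gaps = c("pairwise", "complete")) {
  model <- match.arg(model)
  gaps <- match.arg(gaps)
  x <- alignment_matrix(alignment)
  if (gaps == "complete") {
    keep <- colSums(is.na(x)) == 0
    if (!any(keep)) stop("no complete columns in alignment")
    x <- x[, keep, drop = FALSE]
  }
  n <- nrow(x)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !is.na(x[i, ]) & !is.na(x[j, ])
      nc <- sum(comp)
      if (nc == 0)
        stop("no comparable columns between ", rownames(x)[i], " and ",
             rownames(x)[j])
      d[i, j] <- d[j, i] <- sum(x[i, comp] != x[j, comp]) / nc
    }
  }
  if (model == "jc") {
    if (any(d >= 0.75)) stop("p-distance >= 0.75: Jukes-Cantor undefined")
    d[] <- -0.75 * log1p(-4 * d / 3)
    diag(d) <- 0
  }
  d
}

# Any supported alignment representation -> integer matrix (taxa x sites),
# NA for gap/N/ambiguity.
alignment_matrix <- function(alignment) {
  if (inherits(alignment, "DNAStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (is.matrix(alignment) && is.character(alignment))
    alignment <- setNames(apply(alignment, 1, paste, collapse = ""),
                          rownames(alignment))
  if (is.matrix(alignment) && is.numeric(alignment))
    return(alignment)
  if (is.character(alignment)) {
    stopifnot(length(unique(nchar(alignment))) == 1)
    nm <- names(alignment) %||% sprintf("seq%03d", seq_along(alignment))
    x <- t(vapply(alignment, function(s) {
      v <- dna_to_int(s)
      v[v == 0L] <- NA_integer_
      v
    }, integer(nchar(alignment[1]))))
    rownames(x) <- nm
    return(x)
  }
  stop("unsupported alignment representation")
}

# --- neighbor joining core ------------------------------------------------
#
# Saitou-Nei agglomeration with the Studier-Keppler criterion
#   Q(i, j) = (m - 2) d(i, j) - r_i - r_j
# over the m active nodes, deterministic lexicographic tie-break on the
# joined pair, standard split branch lengths with negative lengths clamped
# to zero and the deficit transferred to the sister branch. Returns the
# merge structure (children + branch lengths per internal node), from which
# both the Newick string and the bipartition set are derived.
nj_core <- function(d) {
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  children <- list()   # per internal node: integer children ids
  brlen <- list()      # matching branch lengths
  active <- seq_len(n) # node ids of active rows of d
  next_id <- n + 1L
  D <- d
  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    dij <- D[i, j]
    vi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    children[[next_id - n]] <- c(active[i], active[j])
    brlen[[next_id - n]] <- c(vi, vj)
    active <- c(active[keep], next_id)
    next_id <- next_id + 1L
  }
  # resolve the final star (3 active nodes; 2 if n == 2)
  if (length(active) == 3L) {
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    children[[next_id - n]] <- active
    brlen[[next_id - n]] <- pmax(0, c(la, lb, lc))
  } else {
    children[[next_id - n]] <- active
    brlen[[next_id - n]] <- c(D[1, 2] / 2, D[1, 2] / 2)
  }
  list(n = n, labels = labels, children = children, brlen = brlen,
       root = next_id)
}

core_newick <- function(core) {
  fmt <- function(id) {
    if (id <= core$n) return(core$labels[id])
    ch <- core$children[[id - core$n]]
    ln <- core$brlen[[id - core$n]]
    paste0("(", paste0(vapply(seq_along(ch), function(k)
      paste0(fmt(ch[k]), ":", format(ln[k], digits = 15)), character(1)),
      collapse = ","), ")")
  }
  paste0(fmt(core$root), ";")
}

# Canonical bipartition keys of all internal edges (root excluded). A split
# is keyed by the leaf-index set on the side not containing leaf 1, so the
# key is independent of orientation and of any outgroup rooting.
core_splits <- function(core) {
  n <- core$n
  n_int <- length(core$children)
  below <- vector("list", n + n_int)
  for (id in seq_len(n)) below[[id]] <- id
  for (u in seq_len(n_int))
    below[[n + u]] <- unlist(below[core$children[[u]]], use.names = FALSE)
  keys <- vapply(seq_len(n_int - 1L), function(u)
    split_key(below[[n + u]], n), character(1))
  keys[vapply(seq_len(n_int - 1L), function(u)
    length(below[[n + u]]) > 1L, logical(1))]
}

split_key <- function(side, n) {
  side <- sort(side)
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  paste(side, collapse = ",")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the Studier-Keppler Q-criterion,
#' deterministic tie-breaks (lexicographically smallest active pair), and
#' negative branch lengths clamped to zero with the deficit transferred to
#' the sister branch. On an additive (tree-like) distance matrix the
#' generating topology and branch lengths are recovered exactly. The result
#' is unrooted (trifurcating root node).
#'
#' @param d symmetric distance matrix with zero diagonal and taxa dimnames.
#' @return an [ape::phylo] tree.
#' @examples
#' d <- p_distance(c(a = "AAAA", b = "AAAT", c = "TTTA", d = "TTTT"))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances")
  core <- nj_core(d)
  ape::read.tree(text = core_newick(core))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and counts the occurrence of every internal bipartition
#' of the full-data tree. Supports (percent of replicates) are attached to
#' the tree's internal nodes as `node.label` (NA on the root, which carries
#' no bipartition). Bipartition matching uses orientation-free leaf-set
#' keys, so it is independent of any later rooting. Fully deterministic
#' given `seed`.
#'
#' @param alignment as for [p_distance()].
#' @param n_reps number of bootstrap replicates (1000 in the published
#'   analysis).
#' @param seed integer seed for column resampling.
#' @param model,gaps passed to [p_distance()].
#' @return an [ape::phylo] tree with numeric bootstrap supports in
#'   `node.label` and a data.frame of all observed bipartitions in
#'   `attr(, "splits")` (`key`, `support`).
#' @examples
#' sim <- simulate_admixed_alignment(
#'   sim_config(seed = 1, alignment = list(length_bp = 300, n_per_pop = 4,
#'                                         n_migrants = 1)))
#' tr <- bootstrap_support(sim$alignment, n_reps = 50, seed = 7)
#' tr$node.label
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L,
                              model = "p", gaps = "pairwise") {
  stopifnot(n_reps >= 1)
  x <- alignment_matrix(alignment)
  n <- nrow(x); S <- ncol(x)
  full_d <- p_distance(alignment, model = model, gaps = gaps)
  tree <- neighbor_joining(full_d)

  # pair x site mismatch / comparability indicators, consumed as matrix
  # products against the column-resampling weights
  pairs <- combn(n, 2)
  np <- ncol(pairs)
  MM <- matrix(0, np, S)
  any_na <- anyNA(x)
  CC <- if (any_na) matrix(0, np, S) else NULL
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    comp <- !is.na(x[i, ]) & !is.na(x[j, ])
    MM[k, ] <- as.numeric(comp & (x[i, ] != x[j, ]))
    if (any_na) CC[k, ] <- as.numeric(comp)
  }

  counts <- new.env(parent = emptyenv())
  withr::with_seed(seed, {
    chunk <- 100L
    done <- 0L
    while (done < n_reps) {
      nb <- min(chunk, n_reps - done)
      W <- matrix(0, S, nb)
      for (b in seq_len(nb))
        W[, b] <- tabulate(sample.int(S, S, replace = TRUE), nbins = S)
      num <- MM %*% W
      den <- if (any_na) CC %*% W else matrix(S, np, nb)
      for (b in seq_len(nb)) {
        if (any(den[, b] == 0))
          stop("bootstrap replicate with zero comparable columns for a pair")
        dv <- num[, b] / den[, b]
        if (model == "jc") dv <- -0.75 * log1p(-4 * dv / 3)
        D <- matrix(0, n, n)
        D[t(pairs)] <- dv
        D <- D + t(D)
        rownames(D) <- colnames(D) <- rownames(x)
        for (key in core_splits(nj_core(D)))
          assign(key, (counts[[key]] %||% 0L) + 1L, envir = counts)
      }
      done <- done + nb
    }
  })

  keys <- ls(counts)
  split_tab <- data.frame(
    key = keys,
    support = vapply(keys, function(k) 100 * counts[[k]] / n_reps,
                     numeric(1)))
  rownames(split_tab) <- NULL

  tree_keys <- phylo_node_keys(tree, rownames(x))
  support <- vapply(tree_keys, function(k) {
    if (is.na(k)) NA_real_
    else 100 * (counts[[k]] %||% 0L) / n_reps
  }, numeric(1))
  tree$node.label <- as.character(ifelse(is.na(support), "", support))
  attr(tree, "splits") <- split_tab
  attr(tree, "n_reps") <- n_reps
  tree
}

# Per-internal-node bipartition keys of a phylo tree, in node order
# (Ntip+1 ...). The root and any node whose "below" set is the full taxon
# set get NA. `ref_labels` fixes the leaf-index space of the keys.
phylo_node_keys <- function(tree, ref_labels = tree$tip.label) {
  n <- length(tree$tip.label)
  sides <- phylo_node_tipsets(tree)
  vapply(seq_along(sides), function(k) {
    side <- match(sides[[k]], ref_labels)
    if (length(side) >= length(ref_labels) || length(side) == 0) NA_character_
    else split_key(side, length(ref_labels))
  }, character(1))
}

# Tip-label sets below each internal node (node order Ntip+1 ...).
phylo_node_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  below <- vector("list", n + nn)
  for (i in seq_len(n)) below[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))  # parents before children
  for (e in rev(ord)) {             # children before parents
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below[(n + 1):(n + nn)]
}

#' Root a tree on its outgroup
#'
#' Roots the tree on the edge separating the outgroup taxa from the rest.
#' If the outgroup is not monophyletic on the unrooted tree, the tree is
#' rooted on the edge that best separates outgroup from ingroup (maximal
#' number of correctly separated taxa), with a warning.
#'
#' @param tree an [ape::phylo] tree (node labels, e.g. bootstrap supports,
#'   are preserved and stay attached to the correct edges).
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted [ape::phylo] tree.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,out:5);")
#' root_with_outgroup(tr, "out")
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(all(outgroup %in% tree$tip.label))
  n <- length(tree$tip.label)
  mono <- length(outgroup) == 1L
  if (!mono) {
    key_out <- split_key(match(outgroup, tree$tip.label), n)
    keys <- phylo_node_keys(tree)
    mono <- key_out %in% keys
  }
  if (mono)
    return(ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE))
  warning("outgroup is not monophyletic; rooting on the edge maximizing ",
          "outgroup separation")
  sides <- phylo_node_tipsets(tree)
  score <- vapply(sides, function(s) {
    inside <- sum(outgroup %in% s)
    outside <- length(setdiff(tree$tip.label, s)) -
      (length(outgroup) - inside)
    max(inside + outside,
        (length(outgroup) - inside) + (length(s) - inside))
  }, numeric(1))
  score[1] <- -Inf  # the root node itself is not an edge
  best <- which.max(score) + n
  ape::root(tree, node = best, resolve.root = TRUE, edgelabel = TRUE)
}

#' Bootstrap support of the smallest clade containing a taxon set
#'
#' Finds the bipartition side of minimal size containing every taxon in
#' `taxa` and returns its bootstrap support (taken from the tree's node
#' labels, as produced by [bootstrap_support()]).
#'
#' @param tree [ape::phylo] with numeric node labels.
#' @param taxa tip labels that must be contained.
#' @return list with `support`, `size`, and `taxa` (the clade's tip set).
#' @examples
#' sim <- simulate_admixed_alignment(
#'   sim_config(seed = 1, alignment = list(length_bp = 2000)))
#' tr <- bootstrap_support(sim$alignment, n_reps = 100, seed = 7)
#' grp <- sim$taxa$taxon[sim$taxa$migrant | sim$taxa$population == "B"]
#' clade_support(tr, grp)$support
#' @export
clade_support <- function(tree, taxa) {
  stopifnot(all(taxa %in% tree$tip.label))
  sides <- phylo_node_tipsets(tree)
  support <- suppressWarnings(as.numeric(tree$node.label))
  all_tips <- tree$tip.label
  best <- NULL
  for (k in seq_along(sides)) {
    for (side in list(sides[[k]], setdiff(all_tips, sides[[k]]))) {
      if (length(side) == 0 || length(side) == length(all_tips)) next
      if (!all(taxa %in% side)) next
      if (is.null(best) || length(side) < length(best$taxa))
        best <- list(support = support[k], size = length(side), taxa = side)
    }
  }
  if (is.null(best))
    best <- list(support = NA_real_, size = length(all_tips),
                 taxa = all_tips)
  best
}

#' Test whether focal taxa cluster inside a source population
#'
#' Admixture criterion on a tree: the focal taxa (e.g. deletion-bearing
#' African haplotypes) are called admixed from the source population if some
#' internal edge has, on one side, exactly the focal taxa plus a non-empty
#' subset (or all) of the source population and nothing else - in
#' particular no other member of the focal taxa's own population and no
#' outgroup. Among qualifying edges the best-supported one (smallest clade
#' on ties) is reported with its bootstrap support. On a fully unrooted
#' tree with no taxa outside `focal` and `source` the orientation of a
#' bipartition is ambiguous; keeping the outgroups in the tree (or rooting
#' first) anchors it, as in the published analysis.
#'
#' @param tree [ape::phylo], rooted or unrooted, ideally with bootstrap
#'   node labels.
#' @param focal tip labels of the putative migrants.
#' @param source tip labels of the candidate source population (disjoint
#'   from `focal`).
#' @return list with `admixed` (logical), `support`, and `clade` (tip set
#'   of the supporting edge, or NULL).
#' @examples
#' tr <- ape::read.tree(text = "((mig:1,(s1:1,s2:1):1):2,(a1:1,a2:1):2);")
#' is_admixed(tr, "mig", c("s1", "s2"))$admixed  # TRUE
#' @export
is_admixed <- function(tree, focal, source) {
  stopifnot(all(focal %in% tree$tip.label), all(source %in% tree$tip.label),
            length(intersect(focal, source)) == 0)
  sides <- phylo_node_tipsets(tree)
  support <- if (is.null(tree$node.label)) rep(NA_real_, length(sides))
             else suppressWarnings(as.numeric(tree$node.label))
  all_tips <- tree$tip.label
  best <- NULL
  better <- function(cand, cur) {
    if (is.null(cur)) return(TRUE)
    cs <- if (is.na(cand$support)) -Inf else cand$support
    bs <- if (is.na(cur$support)) -Inf else cur$support
    cs > bs || (cs == bs && length(cand$clade) < length(cur$clade))
  }
  for (k in seq_along(sides)) {
    for (side in list(sides[[k]], setdiff(all_tips, sides[[k]]))) {
      if (length(side) == 0 || length(side) == length(all_tips)) next
      if (!all(focal %in% side)) next
      rest <- setdiff(side, focal)
      if (length(rest) == 0 || !all(rest %in% source)) next
      cand <- list(admixed = TRUE, support = support[k], clade = side)
      if (better(cand, best)) best <- cand
    }
  }
  best %||% list(admixed = FALSE, support = NA_real_, clade = NULL)
}
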