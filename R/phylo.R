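#' Pairwise distances from an alignment
#'
#' For each sequence pair, `p` is the proportion of differing residues over
#' the columns where both sequences have a residue (gaps excluded pairwise).
#' The Dayhoff correction `d = -ln(1 - p - 0.2 p^2)` approximates the
#' expected number of substitutions per site under a Dayhoff-like process;
#' it diverges as `p` approaches ~0.8541, beyond which the input is outside
#' the model's domain.
#'
#' @param aln A gapped `seq_set` (equal-length rows).
#' @param model `"p"` (raw proportion) or `"dayhoff"` (corrected).
#' @return Symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames.
#' @export
distance_from_alignment <- function(aln, model = c("dayhoff", "p")) {
  model <- match.arg(model)
  w <- alignment_width(aln)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  nongap <- m != GAP
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  pmax_dayhoff <- (sqrt(1.8) - 1) / 0.4 # root of 0.2 p^2 + p - 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- nongap[i, ] & nongap[j, ]
      if (!any(shared)) {
        stop("sequences '", aln$id[i], "' and '", aln$id[j],
             "' share no non-gap columns")
      }
      p <- mean(m[i, shared] != m[j, shared])
      if (model == "dayhoff") {
        if (p >= pmax_dayhoff) {
          stop("p-distance ", round(p, 4), " between '", aln$id[i], "' and '",
               aln$id[j], "' is outside the Dayhoff correction's domain; ",
               "use model = \"p\"")
        }
        p <- -log(1 - p - 0.2 * p^2)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Exact on additive matrices: the
#' path-length matrix of the returned tree reproduces the input. Negative
#' branch lengths (possible on non-additive input) are clamped to zero and
#' the total clamped deficit is recorded in the `clamped` attribute.
#'
#' @param d Symmetric numeric matrix with zero diagonal and dimnames
#'   (taxon ids), at least 2 taxa.
#' @return An [ape::read.tree()]-compatible `phylo` object (unrooted;
#'   the root node is the final trifurcation for >= 3 taxa).
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(as.matrix(d)))) stop("distance matrix must be symmetric")
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  labels <- rownames(d)
  if (n < 2L) stop("need at least 2 taxa")
  clamp <- function(x) pmax(x, 0)
  clamped_total <- 0
  if (n == 2L) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                 edge.length = rep(clamp(d[1L, 2L] / 2), 2L),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "clamped") <- max(0, -d[1L, 2L])
    return(tree)
  }
  # active: node ids; tips 1..n, internal nodes numbered from n+1 upward
  active <- seq_len(n)
  next_node <- 2L * n - 2L # ape convention: root = n+1; fill downward later
  # build with provisional ids, renumber at the end
  node_id <- seq_len(n)
  prov <- n # provisional internal counter
  edges <- matrix(integer(), 0L, 2L)
  lens <- numeric()
  D <- d
  ids <- seq_len(n)
  while (length(ids) > 3L) {
    k <- length(ids)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- min(best); j <- max(best)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    clamped_total <- clamped_total + max(0, -li) + max(0, -lj)
    prov <- prov + 1L
    edges <- rbind(edges, c(prov, ids[i]), c(prov, ids[j]))
    lens <- c(lens, clamp(li), clamp(lj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], prov)
  }
  if (length(ids) == 3L) {
    la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    clamped_total <- clamped_total + sum(pmax(0, -c(la, lb, lc)))
    prov <- prov + 1L
    edges <- rbind(edges, c(prov, ids[1L]), c(prov, ids[2L]), c(prov, ids[3L]))
    lens <- c(lens, clamp(la), clamp(lb), clamp(lc))
  }
  # renumber internal nodes to ape convention: tips 1..n, root n+1, then
  # remaining internal nodes. Our last provisional node is the root.
  n_internal <- prov - n
  map <- integer(prov)
  map[seq_len(n)] <- seq_len(n)
  # provisional internal ids n+1..prov; root is prov
  map[prov] <- n + 1L
  rest <- setdiff((n + 1L):prov, prov)
  map[rest] <- n + 1L + seq_along(rest)
  edges <- matrix(map[edges], ncol = 2L)
  tree <- list(edge = edges[nrow(edges):1L, , drop = FALSE],
               edge.length = lens[length(lens):1L],
               tip.label = labels, Nnode = n_internal)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped_total
  tree
}

# Canonical keys of the non-trivial bipartitions induced by internal edges:
# for each internal edge, the sorted tip labels of the side not containing
# the alphabetically first taxon.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n + tree$Nnode)
  for (k in seq_len(n)) below[[k]] <- tree$tip.label[k]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]
    ch <- post$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  keys <- character()
  nodes <- integer()
  root <- n + 1L
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= n || ch == root) next
    side <- below[[ch]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  list(keys = keys, nodes = nodes)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and annotates every internal edge of the
#' full-data tree with the percentage of replicates containing the same
#' leaf bipartition. Supports are stored as internal node labels (the
#' standard Newick convention); the root label is empty. Replicates whose
#' distance computation fails (e.g. a resample pushing a pair outside the
#' Dayhoff domain) are redrawn, up to `10 * n_reps` attempts.
#'
#' @param aln A gapped `seq_set`.
#' @param model Distance model, see [distance_from_alignment()].
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the whole run uses one RNG stream, so equal
#'   seeds give bit-identical supports.
#' @return A `phylo` object with `node.label` supports in `[0, 100]`.
#' @export
bootstrap_tree <- function(aln, model = c("dayhoff", "p"), n_reps = 100L,
                           seed = 1L) {
  model <- match.arg(model)
  w <- alignment_width(aln)
  main <- neighbor_joining(distance_from_alignment(aln, model))
  bp <- tree_bipartitions(main)
  counts <- setNames(numeric(length(bp$keys)), bp$keys)
  m <- alignment_matrix(aln)
  withr::local_seed(seed)
  done <- 0L
  attempts <- 0L
  redrawn <- 0L
  while (done < n_reps) {
    attempts <- attempts + 1L
    if (attempts > 10L * n_reps) {
      stop("too many failed bootstrap replicates (", redrawn, " redraws)")
    }
    cols <- sample.int(w, w, replace = TRUE)
    rep_aln <- aln
    rep_aln$residues <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    dm <- tryCatch(distance_from_alignment(rep_aln, model),
                   error = function(e) NULL)
    if (is.null(dm)) { redrawn <- redrawn + 1L; next }
    rep_tree <- neighbor_joining(dm)
    rk <- tree_bipartitions(rep_tree)$keys
    hit <- bp$keys %in% rk
    counts[hit] <- counts[hit] + 1
    done <- done + 1L
  }
  support <- round(100 * counts / n_reps)
  labs <- rep("", main$Nnode)
  labs[bp$nodes - length(main$tip.label)] <- as.character(support)
  main$node.label <- labs
  attr(main, "n_reps") <- n_reps
  attr(main, "redrawn") <- redrawn
  main
}

#' Bootstrap support of the bipartition separating two groups
#'
#' Convenience accessor: returns the support attached to the internal edge
#' whose bipartition splits `group` from the rest, or `NA` if the tree does
#' not contain that bipartition.
#'
#' @param tree A supported tree from [bootstrap_tree()].
#' @param group Character vector of tip labels forming one side.
#' @return Support percentage or `NA`.
#' @export
bipartition_support <- function(tree, group) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  side <- if (ref %in% group) setdiff(tree$tip.label, group) else group
  key <- paste(sort(side), collapse = "|")
  bp <- tree_bipartitions(tree)
  hit <- match(key, bp$keys)
  if (is.na(hit)) return(NA_real_)
  as.numeric(tree$node.label[bp$nodes[hit] - n])
}

#' Serialize / parse Newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports travel as internal node labels. Round-trips topology, branch
#' lengths (to at least 6 decimals) and supports.
#'
#' @param tree A `phylo` object.
#' @return `write_newick`: a Newick string. `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' @rdname write_newick
#' @param text Newick string.
#' @export
read_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  tree
}
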