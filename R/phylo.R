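#' @include filters.R
NULL

#' Binary mutation matrix over tumor regions
#'
#' Presence/absence of each variant across the samples of one patient,
#' reduced to unique presence patterns with multiplicity weights, plus an
#' implicit all-zero outgroup (the normal tissue: somatic mutations are
#' absent there by definition).
#'
#' @slot mat integer 0/1 matrix, unique patterns x taxa (samples plus the
#'   outgroup as last column).
#' @slot weights integer multiplicity of each pattern.
#' @slot outgroup name of the outgroup taxon.
#' @exportClass BinaryMatrix
setClass("BinaryMatrix",
         representation(mat = "matrix", weights = "integer",
                        outgroup = "character"))

setValidity("BinaryMatrix", function(object) {
  msg <- character()
  if (!all(object@mat %in% c(0L, 1L))) msg <- c(msg, "entries must be 0/1")
  if (length(object@weights) != nrow(object@mat))
    msg <- c(msg, "one weight per pattern required")
  if (!object@outgroup %in% colnames(object@mat))
    msg <- c(msg, "outgroup must be a column of the matrix")
  if (nrow(object@mat) && any(rowSums(object@mat) == 0))
    msg <- c(msg, "all-zero patterns must be dropped")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinaryMatrix", function(object) {
  cat(sprintf("BinaryMatrix: %d unique patterns (%d variants) over %d taxa (outgroup '%s')\n",
              nrow(object@mat), sum(object@weights), ncol(object@mat),
              object@outgroup))
})

#' Build the binary SNV matrix of a patient
#'
#' Presence is the post-recovery filter state. Duplicate presence patterns
#' are collapsed with multiplicity weights; variants present in no sample
#' are dropped; the all-zero outgroup column is appended.
#'
#' @param table a filtered \linkS4class{VariantTable}, or a logical
#'   variants x samples presence matrix.
#' @param outgroup outgroup taxon name (default \code{"Normal"}).
#' @return a \linkS4class{BinaryMatrix}.
#' @export
buildMatrix <- function(table, outgroup = "Normal") {
  pres <- if (methods::is(table, "VariantTable")) presence(table)
          else as.matrix(table)
  if (ncol(pres) < 3) stop("need at least 3 samples for a topology")
  pres <- pres[rowSums(pres) > 0, , drop = FALSE] * 1L
  key <- apply(pres, 1, paste, collapse = "")
  w <- table(key)
  mat <- pres[match(names(w), key), , drop = FALSE]
  mat <- cbind(mat, 0L)
  colnames(mat)[ncol(mat)] <- outgroup
  rownames(mat) <- NULL
  methods::new("BinaryMatrix", mat = mat, weights = as.integer(w),
               outgroup = outgroup)
}

## ---- parsimony scoring -----------------------------------------------------
## State sets are bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}. Hartigan's rule at a
## node of any degree: each state scores the number of children whose set
## contains it; the node keeps the argmax set and adds (degree - max) changes.
## Exact on multifurcating trees, reduces to Fitch on binary ones.

## score an undirected tree given as an edge matrix; tips are 1..ntip with
## rows of tip_sets (ntip x P bitmask), internal nodes have larger ids
.treeScore <- function(edges, tip_sets, weights) {
  ntip <- nrow(tip_sets)
  P <- ncol(tip_sets)
  nodes <- unique(as.vector(edges))
  nmax <- max(nodes)
  adj <- vector("list", nmax)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- nodes[nodes > ntip][1]
  sets <- matrix(0L, nmax, P)
  changes <- 0
  visit <- function(v, parent) {
    if (v <= ntip) { sets[v, ] <<- tip_sets[v, ]; return(invisible(NULL)) }
    kids <- setdiff(adj[[v]], parent)
    c0 <- integer(P); c1 <- integer(P)
    for (k in kids) {
      visit(k, v)
      c0 <- c0 + bitwAnd(sets[k, ], 1L)
      c1 <- c1 + bitwShiftR(sets[k, ], 1L)
    }
    mx <- pmax(c0, c1)
    sets[v, ] <<- ifelse(c0 == mx, 1L, 0L) + ifelse(c1 == mx, 2L, 0L)
    changes <<- changes + sum((length(kids) - mx) * weights)
    invisible(NULL)
  }
  visit(root, 0L)
  changes
}

## canonical newick of an undirected tree: rooted at the internal node next
## to the outgroup, children sorted lexicographically, outgroup last
.canonicalNewick <- function(edges, taxa, outgroup) {
  ntip <- length(taxa)
  og <- match(outgroup, taxa)
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lab <- function(v, parent) {
    if (v <= ntip) return(taxa[v])
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(sort(vapply(kids, lab, "", parent = v)),
                      collapse = ","), ")")
  }
  root <- adj[[og]][1]
  kids <- setdiff(adj[[root]], og)
  paste0("(", paste(c(sort(vapply(kids, lab, "", parent = root)), outgroup),
                    collapse = ","), ");")
}

#' Fitch parsimony length of a topology
#'
#' Minimum number of binary state changes needed to explain every (weighted)
#' variant pattern on the given topology, with the outgroup fixed at state 0.
#' Multifurcating nodes are scored exactly (Hartigan's generalization).
#'
#' @param topology an \link[ape]{ape} \code{phylo} whose tip labels are
#'   exactly the taxa of \code{matrix}.
#' @param matrix a \linkS4class{BinaryMatrix}.
#' @return integer parsimony length.
#' @export
fitchScore <- function(topology, matrix) {
  taxa <- colnames(matrix@mat)
  if (!setequal(topology$tip.label, taxa))
    stop("topology tips do not match the matrix taxa")
  ## ape numbering: tips 1..ntip in tip.label order; order columns to match
  tip_sets <- t(ifelse(matrix@mat[, topology$tip.label, drop = FALSE] == 1L,
                       2L, 1L))
  as.integer(.treeScore(topology$edge, tip_sets, matrix@weights))
}

## minimum-change branch assignment on a rooted phylo: returns per-edge
## weighted change counts (order of phylo$edge) via Hartigan up + down pass
.branchCounts <- function(phy, matrix) {
  tip_sets <- t(ifelse(matrix@mat[, phy$tip.label, drop = FALSE] == 1L,
                       2L, 1L))
  weights <- matrix@weights
  ntip <- length(phy$tip.label)
  P <- ncol(tip_sets)
  nmax <- max(phy$edge)
  sets <- matrix(0L, nmax, P)
  sets[seq_len(ntip), ] <- tip_sets
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  up <- function(v) {
    k <- kids[[as.character(v)]]
    if (is.null(k)) return(invisible(NULL))
    c0 <- integer(P); c1 <- integer(P)
    for (x in k) {
      up(x)
      c0 <- c0 + bitwAnd(sets[x, ], 1L)
      c1 <- c1 + bitwShiftR(sets[x, ], 1L)
    }
    mx <- pmax(c0, c1)
    sets[v, ] <<- ifelse(c0 == mx, 1L, 0L) + ifelse(c1 == mx, 2L, 0L)
    invisible(NULL)
  }
  up(root)
  ## top-down state choice: keep the parent's state when admissible,
  ## prefer state 0 at the root (the outgroup/ancestral state)
  state <- matrix(0L, nmax, P)
  rs <- sets[root, ]
  state[root, ] <- ifelse(bitwAnd(rs, 1L) > 0L, 0L, 1L)
  down <- function(v) {
    k <- kids[[as.character(v)]]
    if (is.null(k)) return(invisible(NULL))
    for (x in k) {
      px <- state[v, ]
      sx <- sets[x, ]
      keep <- bitwAnd(sx, bitwShiftL(1L, px)) > 0L
      state[x, ] <<- ifelse(keep, px, ifelse(bitwAnd(sx, 1L) > 0L, 0L, 1L))
      down(x)
    }
    invisible(NULL)
  }
  down(root)
  counts <- integer(nrow(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    counts[i] <- sum(weights[state[a, ] != state[b, ]])
  }
  counts
}

#' Exact maximum parsimony by branch and bound
#'
#' Searches all unrooted binary topologies over the samples plus outgroup by
#' stepwise taxon addition. Partial trees are pruned when their Fitch score
#' (a lower bound, since adding taxa never decreases it) exceeds the
#' incumbent; a greedy addition pass seeds the incumbent. All co-optimal
#' topologies are returned, ordered by their canonical newick string.
#'
#' @param matrix a \linkS4class{BinaryMatrix} from [buildMatrix()].
#' @param max_samples refuse larger problems (exact search bound, default 12
#'   samples plus outgroup).
#' @return list of \linkS4class{SampleTree}, all with the same (minimal)
#'   parsimony score.
#' @export
maxParsimony <- function(matrix, max_samples = 12L) {
  taxa <- colnames(matrix@mat)
  ntip <- length(taxa)
  if (ntip - 1L > max_samples)
    stop(sprintf("%d samples exceed the exact-search bound of %d",
                 ntip - 1L, max_samples))
  if (ntip < 4) {
    ## unique unrooted topology: a star
    edges <- cbind(rep(ntip + 1L, ntip), seq_len(ntip))
    return(list(.sampleTree(edges, matrix)))
  }
  tip_sets <- t(ifelse(matrix@mat == 1L, 2L, 1L))
  w <- matrix@weights
  start <- cbind(rep(ntip + 1L, 3L), 1:3)
  insert <- function(edges, ei, tip, internal) {
    a <- edges[ei, 1]; b <- edges[ei, 2]
    rbind(edges[-ei, , drop = FALSE],
          c(a, internal), c(internal, b), c(internal, tip))
  }
  ## greedy pass for the incumbent
  edges <- start
  for (t in 4:ntip) {
    internal <- ntip + t - 2L
    cand <- lapply(seq_len(nrow(edges)), function(ei)
      insert(edges, ei, t, internal))
    sc <- vapply(cand, .treeScore, numeric(1), tip_sets = tip_sets,
                 weights = w)
    edges <- cand[[which.min(sc)]]
  }
  best <- .treeScore(edges, tip_sets, w)
  found <- list()
  rec <- function(edges, t) {
    if (t > ntip) {
      sc <- .treeScore(edges, tip_sets, w)
      if (sc < best) { best <<- sc; found <<- list(edges) }
      else if (sc == best) found <<- c(found, list(edges))
      return(invisible(NULL))
    }
    internal <- ntip + t - 2L
    for (ei in seq_len(nrow(edges))) {
      cand <- insert(edges, ei, t, internal)
      if (.treeScore(cand, tip_sets, w) <= best) rec(cand, t + 1L)
    }
    invisible(NULL)
  }
  rec(start, 4L)
  trees <- lapply(found, .sampleTree, matrix = matrix)
  trees <- trees[!duplicated(vapply(trees, function(x) x@newick, ""))]
  trees[order(vapply(trees, function(x) x@newick, ""))]
}

## build a SampleTree from an undirected edge matrix
.sampleTree <- function(edges, matrix) {
  taxa <- colnames(matrix@mat)
  nwk <- .canonicalNewick(edges, taxa, matrix@outgroup)
  phy <- ape::read.tree(text = nwk)
  counts <- .branchCounts(phy, matrix)
  methods::new("SampleTree", phylo = phy,
               score = as.integer(.treeScore(
                 edges, t(ifelse(matrix@mat == 1L, 2L, 1L)), matrix@weights)),
               branch_mutations = counts, newick = nwk)
}

#' @rdname accessors
setMethod("parsimonyScore", "SampleTree", function(x) x@score)

setMethod("show", "SampleTree", function(object) {
  cat(sprintf("SampleTree (parsimony score %d): %s\n", object@score,
              object@newick))
})

#' Write a sample tree as newick
#'
#' Outgroup-rooted orientation; branch lengths carry the number of variants
#' assigned to each branch.
#'
#' @param tree a \linkS4class{SampleTree}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path) {
  phy <- tree@phylo
  phy$edge.length <- as.numeric(tree@branch_mutations)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Lineage-ordering constraints from CCF values
#'
#' Simplified cell-fraction constraints between mutation clusters: cluster X
#' may be ancestral to Y iff its CCF is at least CCF(Y) - epsilon in every
#' sample (the pigeonhole/crossing rule), and X, Y may be siblings below Z
#' iff CCF(X) + CCF(Y) <= CCF(Z) + epsilon in every sample (their cell
#' populations are disjoint inside Z). All admissible relations and the
#' violated ones are reported.
#'
#' @param ccf numeric matrix, clusters x samples, of cancer cell fractions.
#' @param epsilon slack tolerance (default 0.1).
#' @return list with data.frames \code{ancestry} (ancestor, descendant,
#'   admissible, max_violation) and \code{siblings} (x, y, parent,
#'   admissible, max_violation).
#' @export
ccfOrderCheck <- function(ccf, epsilon = 0.1) {
  ccf <- as.matrix(ccf)
  if (nrow(ccf) < 2 || any(!is.finite(ccf)))
    stop("need >= 2 clusters with complete CCF values")
  cl <- rownames(ccf)
  if (is.null(cl)) cl <- rownames(ccf) <- paste0("K", seq_len(nrow(ccf)))
  anc <- expand.grid(ancestor = cl, descendant = cl,
                     stringsAsFactors = FALSE)
  anc <- anc[anc$ancestor != anc$descendant, ]
  anc$max_violation <- apply(anc, 1, function(r)
    max(ccf[r[["descendant"]], ] - ccf[r[["ancestor"]], ]))
  anc$admissible <- anc$max_violation <= epsilon
  sib <- NULL
  for (i in seq_len(nrow(ccf) - 1L)) for (j in (i + 1L):nrow(ccf))
    for (k in seq_len(nrow(ccf)))
      if (k != i && k != j)
        sib <- rbind(sib, data.frame(
          x = cl[i], y = cl[j], parent = cl[k],
          max_violation = max(ccf[i, ] + ccf[j, ] - ccf[k, ])))
  if (!is.null(sib)) sib$admissible <- sib$max_violation <= epsilon
  rownames(anc) <- NULL
  list(ancestry = anc[, c("ancestor", "descendant", "admissible",
                          "max_violation")],
       siblings = if (is.null(sib)) data.frame() else
         sib[, c("x", "y", "parent", "admissible", "max_violation")])
}
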