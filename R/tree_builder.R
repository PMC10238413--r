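# Haplotype tree construction by perfect phylogeny on polarized binary
# characters, with a small-parsimony fallback for the rare homoplasic
# variant. Y-chromosome data are near-homoplasy-free, so the tree is built
# from the laminar family of derived-sample sets rather than by heuristic
# parsimony search.

#' Four-gamete compatibility check
#'
#' On rooted (polarized) binary data, a variant pair is tree-compatible iff
#' the observed joint patterns do not include all three of (1,0), (0,1) and
#' (1,1). Pairs with no jointly non-missing sample cannot be assessed and
#' are skipped and counted.
#'
#' @param x a `polarized_matrix` (or a plain 0/1/NA matrix).
#' @return a list of class `conflict_report`: `violations` (data.frame of
#'   incompatible variant id pairs), `n_pairs_tested`, `n_pairs_skipped`.
#' @export
four_gamete_check <- function(x) {
  st <- if (inherits(x, "polarized_matrix")) x$states else as.matrix(x)
  ids <- colnames(st)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(st)))
  M1 <- (st == 1L) & !is.na(st); storage.mode(M1) <- "double"
  M0 <- (st == 0L) & !is.na(st); storage.mode(M0) <- "double"
  n11 <- crossprod(M1)
  n10 <- crossprod(M1, M0)
  n01 <- t(n10)
  nobs <- n11 + n10 + n01 + crossprod(M0)
  viol <- n11 > 0 & n10 > 0 & n01 > 0
  skip <- nobs == 0
  ut <- upper.tri(viol)
  vi <- which(viol & ut, arr.ind = TRUE)
  structure(list(
    violations = data.frame(v1 = ids[vi[, 1]], v2 = ids[vi[, 2]],
                            stringsAsFactors = FALSE),
    violation_matrix = viol,
    n_pairs_tested = sum(ut) - sum(skip & ut),
    n_pairs_skipped = sum(skip & ut)
  ), class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  cat(sprintf("conflict_report: %d incompatible pair(s), %d tested, %d skipped\n",
              nrow(x$violations), x$n_pairs_tested, x$n_pairs_skipped))
  invisible(x)
}

#' Build the haplotype tree by perfect phylogeny
#'
#' Constructs the rooted haplotype tree of all mutually compatible polarized
#' variants. Variants are processed by descending derived count (ties by
#' coordinate); variants sharing a derived-sample set share a branch, and
#' the laminar family of sets yields the topology directly. Samples with
#' identical placements collapse to one tip haplotype; multifurcations are
#' preserved. Variants failing the four-gamete test against an
#' already-accepted variant are excluded from topology and placed afterwards
#' by [place_homoplasic()], recorded in the homoplasy ledger.
#'
#' Missing data: a sample with a missing call at a splitting variant is
#' routed by its non-missing identifiers (the subtree holding the majority
#' of its observed derived calls); samples that cannot be resolved stop at
#' the deepest certain node and are flagged.
#'
#' @param x a `polarized_matrix`.
#' @param anchors optional named list for [name_haplogroups()]; when given,
#'   labels are assigned before returning.
#' @return an object of class `haplotype_tree`. Node 1 is the root; each
#'   other node represents the branch (edge) above it, carrying
#'   `branch_variants` (its identifier set). `node_samples` maps nodes to
#'   the samples whose haplotype terminates there.
#' @export
build_tree <- function(x, anchors = NULL) {
  stopifnot(inherits(x, "polarized_matrix"))
  v <- x$variants
  use <- which(v$ancestral != "unknown" & v$vclass != "STR")
  if (length(use) == 0L) stop("matrix has zero polarized variants")
  st <- x$states[, use, drop = FALSE]
  ids <- v$id[use]
  pos <- v$pos[use]
  n <- nrow(st)
  M1 <- (st == 1L) & !is.na(st)
  M0 <- (st == 0L) & !is.na(st)
  dcount <- colSums(M1)

  uninformative <- ids[dcount == 0L]
  active <- which(dcount > 0L)

  # greedy maximal compatible set, in construction order
  fg <- four_gamete_check(st[, active, drop = FALSE])
  V <- fg$violation_matrix
  ord <- order(-dcount[active], pos[active])
  accepted <- logical(length(active))
  for (j in ord) {
    accepted[j] <- !any(V[j, accepted])
  }
  excluded <- ids[active[!accepted]]
  acc <- active[accepted]

  # group accepted variants by derived-sample signature
  sig <- vapply(acc, function(j) paste(which(M1[, j]), collapse = ","),
                character(1))
  grp <- split(acc, sig)
  gsize <- vapply(grp, function(js) sum(M1[, js[1]]), numeric(1))
  gminpos <- vapply(grp, function(js) min(pos[js]), numeric(1))
  gord <- order(-gsize, gminpos)
  grp <- grp[gord]

  # tree arrays; node 1 = root
  parent <- NA_integer_
  children <- list(integer(0))
  branch_variants <- list(character(0))
  branch_cols <- list(integer(0))      # column indices into st
  node_set <- list(seq_len(n))         # observed derived-sample set per node
  flags <- data.frame(sample = character(0), note = character(0),
                      stringsAsFactors = FALSE)

  derived_set <- function(node) node_set[[node]]
  def_anc <- function(node, set) {
    # members of `set` definitely ancestral at node's branch
    js <- branch_cols[[node]]
    s <- set[rowSums(M0[set, js, drop = FALSE]) > 0 &
             rowSums(M1[set, js, drop = FALSE]) == 0]
    s
  }

  for (g in grp) {
    S <- which(M1[, g[1]])
    u <- 1L
    repeat {
      nxt <- 0L
      for (c in children[[u]]) {
        ov <- length(intersect(S, derived_set(c)))
        if (ov == 0L) next
        conf <- length(def_anc(c, S))
        if (ov == length(S) && conf == 0L) { nxt <- c; break }
      }
      if (nxt == 0L) {
        # messy overlap (possible only with missing data): majority routing
        best <- -1L
        for (c in children[[u]]) {
          ov <- length(intersect(S, derived_set(c)))
          if (ov == 0L) next
          conf <- length(def_anc(c, S))
          if (ov > conf && ov > best) { best <- ov; nxt <- c }
        }
        if (nxt == 0L) break
        u <- nxt
        next
      }
      u <- nxt
    }
    # A branch whose extra members are all missing at this group's variants
    # is observationally indistinguishable from the group's own set: the
    # single-origin (parsimony) resolution places the group on that branch
    # rather than fabricating a nested branch from missingness.
    if (u != 1L) {
      extra <- setdiff(derived_set(u), S)
      if (!length(extra) ||
          !any(M0[extra, g, drop = FALSE] | M1[extra, g, drop = FALSE])) {
        branch_variants[[u]] <- c(branch_variants[[u]], ids[g])
        branch_cols[[u]] <- c(branch_cols[[u]], g)
        next
      }
    }
    new <- length(parent) + 1L
    parent[new] <- u
    children[[u]] <- c(children[[u]], new)
    children[[new]] <- integer(0)
    branch_variants[[new]] <- ids[g]
    branch_cols[[new]] <- g
    node_set[[new]] <- S
  }

  n_nodes <- length(parent)
  # preorder
  preord <- integer(n_nodes); k <- 0L
  stack <- 1L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; preord[k] <- u
    stack <- c(stack, rev(children[[u]]))
  }

  col_node <- integer(ncol(st))
  for (nd in seq_len(n_nodes)) col_node[branch_cols[[nd]]] <- nd

  # per-sample placement
  node_samples <- rep(list(character(0)), n_nodes)
  placement <- integer(n)
  for (i in seq_len(n)) {
    d_node <- a_node <- numeric(n_nodes)
    j1 <- which(M1[i, ]); j0 <- which(M0[i, ])
    if (length(j1)) {
      t1 <- table(col_node[j1][col_node[j1] > 0])
      d_node[as.integer(names(t1))] <- as.integer(t1)
    }
    if (length(j0)) {
      t0 <- table(col_node[j0][col_node[j0] > 0])
      a_node[as.integer(names(t0))] <- as.integer(t0)
    }
    sub <- d_node
    for (u in rev(preord)) if (!is.na(parent[u]))
      sub[parent[u]] <- sub[parent[u]] + sub[u]
    u <- 1L
    repeat {
      cand <- 0L; best <- -1; nc <- 0L
      for (c in children[[u]]) {
        if (sub[c] < 1) next
        ok <- (d_node[c] >= 1 && d_node[c] > a_node[c]) ||
              (d_node[c] == 0 && a_node[c] == 0)
        if (d_node[c] >= 1 && a_node[c] >= d_node[c]) {
          flags <- rbind(flags, data.frame(
            sample = x$samples[i], note = "conflicting-branch",
            stringsAsFactors = FALSE))
          ok <- FALSE
        }
        if (ok) {
          nc <- nc + 1L
          if (sub[c] > best) { best <- sub[c]; cand <- c }
        }
      }
      if (nc > 1L)
        flags <- rbind(flags, data.frame(
          sample = x$samples[i], note = "ambiguous-routing",
          stringsAsFactors = FALSE))
      if (cand == 0L) break
      u <- cand
    }
    placement[i] <- u
    node_samples[[u]] <- c(node_samples[[u]], x$samples[i])
  }

  tree <- structure(list(
    n_nodes = n_nodes,
    parent = parent,
    children = children,
    branch_variants = branch_variants,
    node_samples = node_samples,
    labels = rep(NA_character_, n_nodes),
    samples = x$samples,
    placement = stats::setNames(placement, x$samples),
    variant_branch = stats::setNames(
      rep(seq_len(n_nodes), lengths(branch_variants)),
      unlist(branch_variants)),
    excluded_variants = excluded,
    uninformative_variants = uninformative,
    homoplasy = data.frame(variant = character(0), branches = character(0),
                           extra_steps = integer(0),
                           stringsAsFactors = FALSE),
    flags = unique(flags)
  ), class = "haplotype_tree")

  # place incompatible variants without altering topology
  for (vid in excluded) {
    sv <- stats::setNames(x$states[, vid], x$samples)
    pl <- place_homoplasic(tree, sv)
    tree$homoplasy <- rbind(tree$homoplasy, data.frame(
      variant = vid,
      branches = paste(pl$branches, collapse = ","),
      extra_steps = pl$extra_steps,
      stringsAsFactors = FALSE))
  }
  if (!is.null(anchors)) tree <- name_haplogroups(tree, anchors)
  tree
}

#' @export
print.haplotype_tree <- function(x, ...) {
  nt <- sum(lengths(x$children) == 0L)
  cat(sprintf(paste0(
    "haplotype_tree: %d nodes (%d tips), %d samples, ",
    "%d branch variants, %d homoplasic, %d flagged sample(s)\n"),
    x$n_nodes, nt, length(x$samples), length(x$variant_branch),
    length(x$excluded_variants), nrow(x$flags)))
  invisible(x)
}

#' Branch mutation counts
#'
#' Number of identifier variants on the branch above each node (root = 0).
#' @param tree a `haplotype_tree`.
#' @return integer vector over nodes.
#' @export
branch_mutation_count <- function(tree) lengths(tree$branch_variants)

#' Nodes on the root path of each sample
#'
#' @param tree a `haplotype_tree`.
#' @return named list: sample id -> integer vector of nodes from root to the
#'   sample's placement node (inclusive).
#' @export
sample_paths <- function(tree) {
  anc <- function(u) {
    p <- integer(0)
    while (!is.na(u)) { p <- c(u, p); u <- tree$parent[u] }
    p
  }
  lapply(tree$placement, anc)
}

#' Samples below each branch / variant-to-sample-set map
#'
#' For every variant placed on the topology, the set of samples in the
#' subtree below its branch. This is the canonical representation used to
#' compare reconstructed trees with simulator truth.
#' @param tree a `haplotype_tree`.
#' @return named list: variant id -> sorted character vector of samples.
#' @export
variant_sample_sets <- function(tree) {
  below <- rep(list(character(0)), tree$n_nodes)
  ord <- rev(tree_preorder(tree))
  for (u in ord) {
    below[[u]] <- c(tree$node_samples[[u]],
                    unlist(below[tree$children[[u]]], use.names = FALSE))
  }
  out <- lapply(seq_len(tree$n_nodes), function(u) sort(below[[u]]))
  stats::setNames(out[tree$variant_branch], names(tree$variant_branch))
}

tree_preorder <- function(tree) {
  ord <- integer(tree$n_nodes); k <- 0L; stack <- 1L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; ord[k] <- u
    stack <- c(stack, rev(tree$children[[u]]))
  }
  ord
}

#' Minimal-change placement of a homoplasic binary character
#'
#' Small parsimony for one polarized binary character on a fixed tree
#' (root constrained to the ancestral state), via one post-order dynamic
#' programming pass and one pre-order backtrace. Ties during backtrace
#' prefer the parent's state, so mutations are pushed tip-ward
#' deterministically. The tree topology is never altered.
#'
#' @param tree a `haplotype_tree`.
#' @param states named vector over (a subset of) the tree's samples with
#'   values 0, 1 or NA.
#' @return list: `branches` (nodes whose in-edge gains the derived state),
#'   `reversions` (in-edges losing it), `score` (parsimony score =
#'   total state changes), `extra_steps` (score minus one, floored at 0).
#' @export
place_homoplasic <- function(tree, states) {
  n <- tree$n_nodes
  INF <- 1e9
  # cost[u, s+1]: min changes in subtree of u given node u has state s,
  # counting sample observations at u as pseudo-tips.
  cost <- matrix(0, n, 2)
  obs_cost <- function(u, s) {
    smp <- tree$node_samples[[u]]
    if (!length(smp)) return(0)
    st <- states[smp]
    sum(!is.na(st) & st != s)
  }
  ord <- tree_preorder(tree)
  for (u in rev(ord)) {
    for (s in 0:1) {
      cc <- 0
      for (c in tree$children[[u]]) {
        cc <- cc + min(cost[c, s + 1], cost[c, 2 - s] + 1)
      }
      cost[u, s + 1] <- cc + obs_cost(u, s)
    }
  }
  score <- cost[1, 1]  # root ancestral
  assign <- integer(n)
  assign[1] <- 0L
  branches <- integer(0); reversions <- integer(0)
  for (u in ord) {
    if (u == 1L) next
    sp <- assign[tree$parent[u]]
    keep <- cost[u, sp + 1]
    flip <- cost[u, 2 - sp] + 1
    s <- if (flip < keep) 1L - sp else sp
    assign[u] <- s
    if (s != sp) {
      if (s == 1L) branches <- c(branches, u) else reversions <- c(reversions, u)
    }
  }
  list(branches = branches, reversions = reversions, score = score,
       extra_steps = max(0L, as.integer(score) - 1L),
       node_states = assign)
}

#' Assign deterministic haplogroup labels
#'
#' Backbone clade names are anchored via known samples or identifier
#' variants; unanchored children of a labelled node are ordered by
#' descending subtree sample count, then by smallest member sample id, and
#' receive suffix letters (`<parent>_A`, `<parent>_B`, ...). The label
#' grammar is a deterministic stand-in for published haplogroup
#' nomenclature. Samples sitting on internal nodes are reported with a
#' `'*'` suffix by [haplogroup_assignments()].
#'
#' @param tree a `haplotype_tree`.
#' @param anchors named list: label -> sample id or variant id that pins the
#'   label to a node (the node hosting that sample, or the branch carrying
#'   that variant).
#' @param root_label label for the root (default `"Y"`).
#' @return the tree with `labels` filled in.
#' @export
name_haplogroups <- function(tree, anchors = list(), root_label = "Y") {
  labels <- rep(NA_character_, tree$n_nodes)
  labels[1] <- root_label
  missing_anchors <- character(0)
  for (lab in names(anchors)) {
    key <- anchors[[lab]]
    node <- NA_integer_
    if (key %in% names(tree$variant_branch)) {
      node <- tree$variant_branch[[key]]
    } else if (key %in% tree$samples) {
      node <- unname(tree$placement[key])
    }
    if (is.na(node)) missing_anchors <- c(missing_anchors, key)
    else labels[node] <- lab
  }
  if (length(missing_anchors))
    stop("anchor sample/variant absent from tree: ",
         paste(missing_anchors, collapse = ", "))

  nsub <- subtree_sample_counts(tree)
  minid <- subtree_min_sample(tree)
  suffix <- function(k) {
    # A..Z, then AA, AB, ...
    if (k <= 26L) LETTERS[k]
    else paste0(LETTERS[(k - 1L) %/% 26L], LETTERS[(k - 1L) %% 26L + 1L])
  }
  for (u in tree_preorder(tree)) {
    kids <- tree$children[[u]]
    if (!length(kids)) next
    open <- kids[is.na(labels[kids])]
    if (!length(open)) next
    ord <- open[order(-nsub[open], minid[open])]
    base <- if (is.na(labels[u])) paste0("n", u) else labels[u]
    taken <- labels[kids][!is.na(labels[kids])]
    k <- 0L
    for (c in ord) {
      repeat {
        k <- k + 1L
        cand <- paste0(base, "_", suffix(k))
        if (!cand %in% taken) break
      }
      labels[c] <- cand
    }
  }
  tree$labels <- labels
  tree
}

subtree_sample_counts <- function(tree) {
  nsub <- lengths(tree$node_samples)
  for (u in rev(tree_preorder(tree)))
    if (!is.na(tree$parent[u])) nsub[tree$parent[u]] <- nsub[tree$parent[u]] + nsub[u]
  nsub
}

subtree_min_sample <- function(tree) {
  m <- vapply(tree$node_samples,
              function(s) if (length(s)) min(s) else "\uffff", character(1))
  for (u in rev(tree_preorder(tree))) {
    p <- tree$parent[u]
    if (!is.na(p)) m[p] <- min(m[p], m[u])
  }
  m
}

#' Per-sample haplogroup assignments from the tree
#'
#' Samples whose haplotype terminates at an internal node (one with
#' descendant branches) receive the node's label with a `'*'` suffix,
#' mirroring inner-node placements; samples at leaf nodes receive the plain
#' label.
#' @param tree a labelled `haplotype_tree` (see [name_haplogroups()]).
#' @return named character vector: sample -> haplogroup label.
#' @export
haplogroup_assignments <- function(tree) {
  if (all(is.na(tree$labels[-1]) & tree$n_nodes > 1L))
    stop("tree has no labels; run name_haplogroups() first")
  out <- character(length(tree$samples))
  names(out) <- tree$samples
  for (u in seq_len(tree$n_nodes)) {
    smp <- tree$node_samples[[u]]
    if (!length(smp)) next
    lab <- tree$labels[u]
    if (length(tree$children[[u]])) lab <- paste0(lab, "*")
    out[smp] <- lab
  }
  out
}

#' Export the haplotype tree as Newick
#'
#' Child order is canonical (descending subtree sample count, then smallest
#' sample id, then label), so the output is byte-stable. Samples at
#' internal nodes are emitted as zero-length pseudo-tips. Round-trips
#' through [ape::read.tree()].
#'
#' @param tree a `haplotype_tree`.
#' @param with_branch_mutations if `TRUE`, branch lengths are identifier
#'   counts.
#' @return a single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree, with_branch_mutations = FALSE) {
  nsub <- subtree_sample_counts(tree)
  minid <- subtree_min_sample(tree)
  lab <- function(u) {
    l <- tree$labels[u]
    if (is.na(l)) l <- paste0("n", u)
    gsub("[ ();,:\\[\\]]", "_", l)
  }
  tipname <- function(u) {
    smp <- sort(tree$node_samples[[u]])
    nm <- paste(smp, collapse = "|")
    gsub("[ ();,:\\[\\]]", "_", nm)
  }
  blen <- function(u) {
    if (!with_branch_mutations) return("")
    paste0(":", length(tree$branch_variants[[u]]))
  }
  rec <- function(u) {
    kids <- tree$children[[u]]
    has_samples <- length(tree$node_samples[[u]]) > 0L
    if (!length(kids)) {
      nm <- if (has_samples) tipname(u) else lab(u)
      return(paste0(nm, blen(u)))
    }
    kids <- kids[order(-nsub[kids], minid[kids],
                       vapply(kids, lab, character(1)))]
    parts <- vapply(kids, rec, character(1))
    if (has_samples) {
      pseudo <- paste0(tipname(u), if (with_branch_mutations) ":0" else "")
      parts <- c(pseudo, parts)
    }
    paste0("(", paste(parts, collapse = ","), ")", lab(u), blen(u))
  }
  body <- if (tree$n_nodes == 1L) {
    nm <- if (length(tree$node_samples[[1]])) tipname(1L) else "tip"
    paste0("(", nm, ")", lab(1L))
  } else rec(1L)
  paste0(body, ";")
}

#' Write the branch identifier table
#'
#' TSV with one row per topology variant: branch node, its label, its
#' parent's label and the variant id. The homoplasy ledger is written next
#' to it as `<path>.homoplasy.tsv`.
#' @param tree a `haplotype_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(tree, path) {
  vb <- tree$variant_branch
  lab <- function(u) ifelse(is.na(tree$labels[u]), paste0("n", u),
                            tree$labels[u])
  df <- data.frame(
    branch = unname(vb),
    label = lab(unname(vb)),
    parent_label = ifelse(is.na(tree$parent[unname(vb)]), "",
                          lab(tree$parent[unname(vb)])),
    variant = names(vb),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tree$homoplasy, paste0(path, ".homoplasy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
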