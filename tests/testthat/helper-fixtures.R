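# Shared fixtures: small matrices built in code, an enumerator of rooted
# multifurcating tree shapes, and a brute-force small-parsimony oracle that
# stays independent of place_homoplasic.

make_pm <- function(states, ...) {
  polarized_matrix(as.matrix(states), ...)
}

# ---- rooted tree shapes ------------------------------------------------
# All unordered rooted trees with n leaves and every internal node having
# >= 2 children, as nested lists (leaf = 0L). Parsimony scores depend only
# on (shape, tip character), so sweeping all 2^n characters on each shape
# covers every labelled tree as well.

enum_shapes <- function(n) {
  memo <- new.env()
  shapes <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 1) {
      res <- list(0L)
    } else {
      res <- list()
      # multisets of child subtree sizes (>= 2 parts), non-increasing
      parts <- function(n, maxpart) {
        if (n == 0) return(list(integer(0)))
        out <- list()
        for (p in seq_len(min(n, maxpart))) {
          for (rest in parts(n - p, p)) out <- c(out, list(c(p, rest)))
        }
        out
      }
      seen <- character(0)
      for (pp in parts(n, n - 1)) {
        if (length(pp) < 2) next
        # cartesian product of shape choices per part, as multiset
        choices <- lapply(pp, shapes)
        idx <- rep(1L, length(pp))
        repeat {
          kids <- mapply(function(ch, i) ch[[i]], choices, idx,
                         SIMPLIFY = FALSE)
          kk <- sort(vapply(kids, shape_key, character(1)))
          key2 <- paste(kk, collapse = "|")
          if (!key2 %in% seen) {
            seen <- c(seen, key2)
            res <- c(res, list(kids[order(vapply(kids, shape_key,
                                                 character(1)))]))
          }
          j <- length(idx)
          while (j >= 1) {
            idx[j] <- idx[j] + 1L
            if (idx[j] <= length(choices[[j]])) break
            idx[j] <- 1L
            j <- j - 1L
          }
          if (j < 1) break
        }
      }
    }
    memo[[key]] <- res
    res
  }
  shapes(n)
}

shape_key <- function(s) {
  if (identical(s, 0L)) return("x")
  paste0("(", paste(sort(vapply(s, shape_key, character(1))),
                    collapse = ","), ")")
}

shape_n_leaves <- function(s) {
  if (identical(s, 0L)) return(1L)
  sum(vapply(s, shape_n_leaves, integer(1)))
}

# Convert a shape to a minimal haplotype_tree-compatible object whose tips
# host samples t1..tn (left-to-right).
shape_to_tree <- function(shape) {
  parent <- NA_integer_
  children <- list(integer(0))
  node_samples <- list(character(0))
  tip_i <- 0L
  build <- function(s, par) {
    nd <- length(parent) + 1L
    parent[nd] <<- par
    children[[nd]] <<- integer(0)
    children[[par]] <<- c(children[[par]], nd)
    if (identical(s, 0L)) {
      tip_i <<- tip_i + 1L
      node_samples[[nd]] <<- paste0("t", tip_i)
    } else {
      node_samples[[nd]] <<- character(0)
      for (ch in s) build(ch, nd)
    }
  }
  if (identical(shape, 0L)) {
    tip_i <- 1L
    node_samples[[1]] <- "t1"
  } else {
    for (ch in shape) build(ch, 1L)
  }
  structure(list(
    n_nodes = length(parent), parent = parent, children = children,
    branch_variants = rep(list(character(0)), length(parent)),
    node_samples = node_samples,
    labels = rep(NA_character_, length(parent)),
    samples = paste0("t", seq_len(tip_i)),
    placement = NULL, variant_branch = integer(0),
    excluded_variants = character(0),
    uninformative_variants = character(0),
    homoplasy = NULL, flags = NULL
  ), class = "haplotype_tree")
}

# Brute-force small parsimony: enumerate every assignment of states to
# internal nodes (root fixed at 0, NA tips free) and count state changes
# along edges plus mismatches at observed pseudo-tips.
brute_parsimony <- function(tree, states) {
  n <- tree$n_nodes
  internal <- setdiff(seq_len(n), 1L)  # assignable nodes (root fixed 0)
  best <- Inf
  n_ass <- 2^length(internal)
  assign <- integer(n)
  for (mask in 0:(n_ass - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    assign[internal] <- bits
    assign[1] <- 0L
    cost <- 0
    for (u in seq_len(n)) {
      if (!is.na(tree$parent[u]) && assign[u] != assign[tree$parent[u]])
        cost <- cost + 1
      smp <- tree$node_samples[[u]]
      if (length(smp)) {
        st <- states[smp]
        cost <- cost + sum(!is.na(st) & st != assign[u])
      }
      if (cost >= best) break
    }
    if (cost < best) best <- cost
  }
  best
}

# ---- small diagnostic panel (10 mjHGs, 16 markers) ---------------------
fig_panel <- function() {
  branches <- c("p", "d", "db", "da1", "da2", "da3", "da4",
                "da1_N", "da1_U", "daC", "daC_A", "daC_T", "daC_O")
  parents <- c(p = NA, d = NA, db = "d", da1 = "d", da2 = "d", da3 = "d",
               da4 = "d", da1_N = "da1", da1_U = "da1", daC = "da1",
               daC_A = "daC", daC_T = "daC", daC_O = "daC")
  mk <- data.frame(
    marker = sprintf("mk%02d", 1:16),
    branch = c("p", "d", "d", "db", "da1", "da1", "da2", "da3", "da4",
               "da1_N", "da1_U", "daC", "daC", "daC_A", "daC_T", "daC_O"),
    ancestral = "A", derived = "G",
    stringsAsFactors = FALSE
  )
  marker_panel(mk, parents, name = "mjHG-16")
}

# calls for a sample derived along a branch path, ancestral elsewhere
path_calls <- function(panel, derived_branches, missing_markers = NULL) {
  mk <- panel$markers
  calls <- ifelse(mk$branch %in% derived_branches, mk$derived, mk$ancestral)
  names(calls) <- mk$marker
  if (!is.null(missing_markers)) calls[missing_markers] <- NA
  as.list(calls)
}

# backbone path helper (branch + its ancestors)
backbone_path <- function(panel, b) {
  path <- character(0)
  while (!is.na(b)) { path <- c(path, b); b <- unname(panel$parents[b]) }
  path
}

# ancient placement correctness: true clade, or internal node on the true
# root path (an error can make a lineage look mid-branch)
placement_correct <- function(row, truth_row, panel) {
  path <- backbone_path(panel, truth_row$branch)
  if (truth_row$class == "clade") {
    (row$class == "clade" && row$branch == truth_row$branch) ||
      (row$class == "internal" && row$branch %in% path)
  } else {
    row$class == "internal" && row$branch == truth_row$branch
  }
}
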