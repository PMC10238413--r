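# Tree-guided imputation of missing genotypes. A missing cell (sample s,
# variant v) is decided by whether v's branch lies on s's root path in the
# haplotype tree, but only when the decision is corroborated by at least one
# observed call, which protects against imputing from a mis-placed
# low-coverage sample.

#' Impute missing genotypes from the haplotype tree
#'
#' For a missing cell (s, v) with v on branch b:
#' * imputed 1 if b is on s's root path **and** s has at least one observed
#'   derived call on b itself (another identifier of b) or on a branch below
#'   b on its path;
#' * imputed 0 if s is observed ancestral at some identifier of b, or has an
#'   observed derived call on a branch disjoint from b (placing s outside
#'   b's subtree);
#' * otherwise left missing and counted as unresolved.
#'
#' Variants are processed root-ward to tip-ward so deeper certainty
#' propagates first. Observed (non-missing) cells are never altered, and a
#' second pass imputes nothing further.
#'
#' @param x a `polarized_matrix` (the matrix the tree was built from, or a
#'   compatible one over the same samples).
#' @param tree a `haplotype_tree` from [build_tree()] containing every
#'   sample of `x`.
#' @return list with `matrix` (imputed `polarized_matrix`), `report`
#'   (class `imputation_report`) and `mask` (logical matrix marking imputed
#'   cells).
#' @export
impute_missing <- function(x, tree) {
  stopifnot(inherits(x, "polarized_matrix"), inherits(tree, "haplotype_tree"))
  absent <- setdiff(x$samples, tree$samples)
  if (length(absent))
    stop("sample(s) absent from tree: ", paste(absent, collapse = ", "))

  st <- x$states
  n_missing0 <- sum(is.na(st))
  mask <- matrix(FALSE, nrow(st), ncol(st), dimnames = dimnames(st))

  paths <- sample_paths(tree)           # sample -> nodes root..placement
  preord <- tree_preorder(tree)
  depth <- integer(tree$n_nodes)
  for (u in preord) if (!is.na(tree$parent[u]))
    depth[u] <- depth[tree$parent[u]] + 1L

  # ancestor lookup: is a an ancestor-or-self of b?
  anc_of <- function(a, b) {
    while (!is.na(b)) { if (b == a) return(TRUE); b <- tree$parent[b] }
    FALSE
  }

  vb <- tree$variant_branch
  # order variants root-ward to tip-ward
  vord <- names(vb)[order(depth[vb])]
  vord <- intersect(vord, x$variants$id)

  # a variant with no observed derived call sits on no branch: every
  # missing cell at it is imputed ancestral, provided the sample's
  # placement rests on at least one observed derived identifier
  has_evidence <- rowSums(st == 1L, na.rm = TRUE) > 0
  for (vid in intersect(tree$uninformative_variants, x$variants$id)) {
    j <- match(vid, colnames(st))
    fill <- is.na(st[, j]) & has_evidence
    st[fill, j] <- 0L
    mask[fill, j] <- TRUE
  }

  # per sample: observed derived / ancestral counts per node (on current st)
  samp_idx <- match(x$samples, rownames(st))
  col_of <- match(names(vb), colnames(st))
  names(col_of) <- names(vb)

  for (vid in vord) {
    b <- vb[[vid]]
    j <- col_of[[vid]]
    if (is.na(j)) next
    miss <- which(is.na(st[, j]))
    if (!length(miss)) next
    bvars <- tree$branch_variants[[b]]
    bcols <- stats::setNames(match(bvars, colnames(st)), bvars)
    bcols <- bcols[!is.na(bcols)]
    for (i in miss) {
      s <- x$samples[i]
      path <- paths[[s]]
      on_path <- b %in% path
      row <- st[i, ]
      if (on_path) {
        # corroboration: observed derived at b (other identifier) or deeper
        deeper <- path[depth[path] >= depth[b]]
        support <- FALSE
        for (d in deeper) {
          dv <- tree$branch_variants[[d]]
          dc <- match(dv, colnames(st)); dc <- dc[!is.na(dc) & dc != j]
          if (length(dc) && any(row[dc] == 1L, na.rm = TRUE)) {
            support <- TRUE; break
          }
        }
        if (support) { st[i, j] <- 1L; mask[i, j] <- TRUE }
      } else {
        support <- FALSE
        oc <- bcols[bcols != j]
        if (length(oc) && any(row[oc] == 0L, na.rm = TRUE)) support <- TRUE
        if (!support) {
          # derived evidence on a branch disjoint from b
          for (d in path) {
            if (d == 1L || anc_of(d, b)) next
            dv <- tree$branch_variants[[d]]
            dc <- match(dv, colnames(st)); dc <- dc[!is.na(dc)]
            if (length(dc) && any(row[dc] == 1L, na.rm = TRUE)) {
              support <- TRUE; break
            }
          }
        }
        if (support) { st[i, j] <- 0L; mask[i, j] <- TRUE }
      }
    }
  }

  n_imputed <- sum(mask)
  report <- structure(list(
    imputed = n_imputed,
    unresolved = n_missing0 - n_imputed,
    input_missing = n_missing0,
    per_sample = rowSums(mask),
    per_variant = colSums(mask)
  ), class = "imputation_report")
  out <- polarized_matrix(st, variants = x$variants, samples = x$samples,
                          groups = x$groups, str_alleles = x$str_alleles)
  list(matrix = out, report = report, mask = mask)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("imputation_report: %d missing in, %d imputed, %d unresolved\n",
              x$input_missing, x$imputed, x$unresolved))
  invisible(x)
}

#' Write an imputation report and mask
#'
#' @param result the list returned by [impute_missing()].
#' @param path base path; writes `<path>` (per-sample/per-variant counts)
#'   and `<path>.mask.tsv` (imputed-cell mask).
#' @return `path`, invisibly.
#' @export
write_imputation_report <- function(result, path) {
  df <- data.frame(sample = names(result$report$per_sample),
                   imputed = result$report$per_sample)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- data.frame(sample = rownames(result$mask),
                  result$mask * 1L, check.names = FALSE)
  utils::write.table(m, paste0(path, ".mask.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
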