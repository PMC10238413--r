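# Haplogroup assignment of modern samples from a small panel of diagnostic
# markers (KASP-style genotyping). The panel maps each marker to one branch
# of the haplogroup tree; assignment walks the branch order root-to-tip
# following derived calls.

#' Define a diagnostic marker panel
#'
#' @param markers data.frame with columns `marker`, `branch`, `ancestral`,
#'   `derived` (allele characters). Several markers may tag one branch.
#' @param parents named character vector giving each branch's parent branch
#'   (`NA` for branches hanging off the root). Must describe a tree order.
#' @param name panel name.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(markers, parents, name = "panel") {
  req <- c("marker", "branch", "ancestral", "derived")
  if (!all(req %in% names(markers)))
    stop("markers needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(markers$marker))
    stop("duplicate marker ids (each marker maps to exactly one branch)")
  branches <- unique(markers$branch)
  missing_parent <- setdiff(branches, names(parents))
  if (length(missing_parent))
    stop("no parent entry for branch(es): ",
         paste(missing_parent, collapse = ", "))
  # verify tree order: walking parents from any branch must reach NA
  for (b in branches) {
    seen <- character(0); u <- b
    while (!is.na(u)) {
      if (u %in% seen) stop("parent map contains a cycle at: ", u)
      seen <- c(seen, u)
      u <- unname(parents[u])
      if (!is.na(u) && !(u %in% names(parents)))
        stop("parent branch not in panel: ", u)
    }
  }
  structure(list(markers = markers, parents = parents, name = name),
            class = "marker_panel")
}

panel_children <- function(panel, branch = NA_character_) {
  p <- panel$parents
  if (is.na(branch)) names(p)[is.na(p)] else names(p)[!is.na(p) & p == branch]
}

panel_path <- function(panel, branch) {
  path <- character(0); u <- branch
  while (!is.na(u)) { path <- c(u, path); u <- unname(panel$parents[u]) }
  path
}

# tri-state branch call for one sample: "derived", "ancestral", "conflict"
# or NA (no genotyped marker on the branch)
branch_call <- function(panel, branch, calls) {
  mk <- panel$markers[panel$markers$branch == branch, , drop = FALSE]
  states <- character(0)
  for (r in seq_len(nrow(mk))) {
    a <- calls[[mk$marker[r]]]
    if (is.null(a) || is.na(a)) next
    if (a == mk$derived[r]) states <- c(states, "derived")
    else if (a == mk$ancestral[r]) states <- c(states, "ancestral")
    else stop("call '", a, "' at marker ", mk$marker[r],
              " is neither its ancestral (", mk$ancestral[r],
              ") nor derived (", mk$derived[r], ") allele")
  }
  if (!length(states)) return(NA_character_)
  if (all(states == "derived")) return("derived")
  if (all(states == "ancestral")) return("ancestral")
  "conflict"
}

#' Assign one sample to a haplogroup from panel calls
#'
#' Walks the panel's branch tree from the root following derived calls and
#' stops at the deepest branch whose marker is derived. A sample derived at
#' a branch whose ancestor branch is observed ancestral is `"inconsistent"`
#' (the conflicting pair is named). A missing marker on the path does not
#' truncate the walk when a deeper marker on the same path is derived
#' (assay dropout is unobserved, not ancestral); such assignments are
#' flagged `"path-gap"`. Samples with no genotyped marker are
#' `"unassigned"`.
#'
#' The label is the terminal branch name when the walk ends on a panel leaf
#' (a major haplogroup), and the branch name with a `'*'` suffix when it
#' ends above genotyped, ancestral, deeper markers (an inner-node
#' placement).
#'
#' @param panel a [marker_panel()].
#' @param calls named vector/list: marker id -> called allele (or NA).
#' @return a list of class `assignment`: `sample` label `calls` `notes`.
#' @export
assign_sample <- function(panel, calls) {
  mk <- panel$markers
  unknown <- setdiff(names(calls), mk$marker)
  if (length(unknown))
    stop("calls at markers absent from panel: ",
         paste(unknown, collapse = ", "))
  bc <- vapply(unique(mk$branch), function(b) branch_call(panel, b, calls),
               character(1))
  notes <- character(0)
  if (all(is.na(bc)))
    return(structure(list(label = "unassigned", branch = NA_character_,
                          branch_calls = bc, notes = "all markers missing"),
                     class = "assignment"))
  if (any(bc == "conflict", na.rm = TRUE)) {
    b <- names(bc)[which(bc == "conflict")[1]]
    return(structure(list(label = "inconsistent", branch = b,
                          branch_calls = bc,
                          notes = paste0("conflicting marker calls on branch ",
                                         b)),
                     class = "assignment"))
  }
  # deepest derived branch whose root path has no observed-ancestral branch
  derived_b <- names(bc)[!is.na(bc) & bc == "derived"]
  # inconsistency: derived branch under an observed-ancestral ancestor
  for (b in derived_b) {
    path <- panel_path(panel, b)
    above <- setdiff(path, b)
    bad <- above[!is.na(bc[above]) & bc[above] == "ancestral"]
    if (length(bad))
      return(structure(list(
        label = "inconsistent", branch = b, branch_calls = bc,
        notes = paste0("derived at ", b, " but ancestral at ancestor ",
                       bad[1])),
        class = "assignment"))
  }
  if (!length(derived_b)) {
    return(structure(list(label = "unassigned", branch = NA_character_,
                          branch_calls = bc,
                          notes = "no derived marker observed"),
                     class = "assignment"))
  }
  depth <- vapply(derived_b, function(b) length(panel_path(panel, b)),
                  integer(1))
  b <- derived_b[order(-depth, derived_b)][1]
  path <- panel_path(panel, b)
  if (any(is.na(bc[setdiff(path, b)]))) notes <- c(notes, "path-gap")
  kids <- panel_children(panel, b)
  if (!length(kids)) {
    label <- b                       # major haplogroup (panel leaf)
  } else {
    kc <- bc[kids]
    if (any(!is.na(kc) & kc == "derived"))
      stop("internal error: deeper derived branch not selected")
    label <- paste0(b, "*")          # inner-node placement
    if (all(is.na(kc))) notes <- c(notes, "no genotyped marker below")
  }
  structure(list(label = label, branch = b, branch_calls = bc,
                 notes = if (length(notes)) paste(notes, collapse = "; ")
                         else ""),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment: %s%s\n", x$label,
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' Assign many samples from a calls matrix
#'
#' @param panel a [marker_panel()].
#' @param calls matrix or data.frame, rows = samples, columns = markers,
#'   cells = called alleles or NA.
#' @return data.frame: sample, label, branch, notes.
#' @export
assign_samples <- function(panel, calls) {
  calls <- as.matrix(calls)
  out <- lapply(rownames(calls), function(s) {
    a <- assign_sample(panel, stats::setNames(as.list(calls[s, ]),
                                              colnames(calls)))
    data.frame(sample = s, label = a$label, branch = a$branch,
               notes = a$notes, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Haplogroup frequency table by group
#'
#' @param assignments data.frame from [assign_samples()] (or any with
#'   columns `sample`, `label`).
#' @param groups named character vector: sample -> group (region/breed).
#' @return data.frame: group, label, n, proportion (proportions sum to 1
#'   within each group).
#' @export
summarize_frequencies <- function(assignments, groups) {
  miss <- setdiff(assignments$sample, names(groups))
  if (length(miss))
    stop("samples without a group: ", paste(miss, collapse = ", "))
  g <- groups[assignments$sample]
  tab <- as.data.frame(table(group = g, label = assignments$label),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$group, sum)
  tab$proportion <- tab$n / as.numeric(tot[tab$group])
  tab <- tab[order(tab$group, -tab$n, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Refine assignments with a nested extension panel
#'
#' Re-assigns the samples carrying one prior label using a finer panel whose
#' branches nest within that label's subtree (e.g. splitting a major
#' haplogroup into sub-haplogroups); all other samples are untouched. A
#' sample ancestral at every genotyped extension marker keeps the prior
#' label with a `'*'` suffix (basal within the prior label).
#'
#' @param extension a [marker_panel()] whose root branches all descend from
#'   `target_label`'s branch conceptually; panel-internal parents must form
#'   a tree.
#' @param assignments data.frame from [assign_samples()].
#' @param calls calls matrix for the extension panel (rows = samples).
#' @param target_label the prior label to refine.
#' @return the assignments data.frame with refined labels and a
#'   `refined` logical column.
#' @export
refine_panel <- function(extension, assignments, calls, target_label) {
  roots <- panel_children(extension, NA_character_)
  if (!length(roots)) stop("extension panel has no root branches")
  sel <- assignments$label == target_label
  assignments$refined <- FALSE
  for (i in which(sel)) {
    s <- assignments$sample[i]
    if (!s %in% rownames(calls)) next
    a <- assign_sample(extension,
                       stats::setNames(as.list(as.matrix(calls)[s, ]),
                                       colnames(calls)))
    if (a$label == "unassigned") {
      if (identical(a$notes, "no derived marker observed")) {
        assignments$label[i] <- paste0(target_label, "*")
        assignments$refined[i] <- TRUE
      }
      next
    }
    if (a$label == "inconsistent") {
      assignments$label[i] <- "inconsistent"
      assignments$notes[i] <- a$notes
      assignments$refined[i] <- TRUE
      next
    }
    assignments$label[i] <- a$label
    assignments$refined[i] <- TRUE
  }
  assignments
}

#' Read / write panel definition and calls TSVs
#'
#' The panel TSV has columns marker, branch, parent, ancestral, derived
#' (parent empty for root branches).
#' @param path TSV path.
#' @param name panel name.
#' @return a `marker_panel`.
#' @export
read_panel_tsv <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  parents <- tapply(df$parent, df$branch, function(p) p[1])
  marker_panel(df[, c("marker", "branch", "ancestral", "derived")],
               stats::setNames(as.character(parents), names(parents)),
               name = name)
}

#' @rdname read_panel_tsv
#' @param panel a `marker_panel` to write.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- panel$markers
  df$parent <- unname(panel$parents[df$branch])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
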