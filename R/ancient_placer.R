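# Placement of degraded, low-coverage ancient samples onto the modern
# backbone from pseudo-haploid calls at identifier positions. A branch is
# "passed" when at least half of its genotyped identifiers are derived and
# none is ancestral; branches showing both states mark lineages that
# diverged mid-branch and yield internal-node placements (the groups seen
# only in ancient samples, labelled with Greek letters and '*').

GREEK <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
           "theta", "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron",
           "pi", "rho", "sigma", "tau", "upsilon", "phi", "chi", "psi",
           "omega")

#' Define a backbone of branch identifier sets
#'
#' @param identifier_sets named list: branch id -> character vector of
#'   identifier variant ids. Sets must be disjoint across branches.
#' @param parents named character vector: branch -> parent branch (`NA` for
#'   branches off the root).
#' @return object of class `backbone_panel`. Internal-node labels for each
#'   branch are drawn from the Greek alphabet in root-to-tip order (a
#'   deterministic stand-in for published ancient-only node names).
#' @export
backbone_panel <- function(identifier_sets, parents) {
  branches <- names(identifier_sets)
  if (is.null(branches)) stop("identifier_sets must be named by branch")
  ids <- unlist(identifier_sets, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("identifier sets must be disjoint across branches")
  miss <- setdiff(branches, names(parents))
  if (length(miss)) stop("no parent entry for: ", paste(miss, collapse = ", "))
  for (b in branches) {
    seen <- character(0); u <- b
    while (!is.na(u)) {
      if (u %in% seen) stop("parent map contains a cycle at: ", u)
      seen <- c(seen, u); u <- unname(parents[u])
    }
  }
  # root-to-tip order: depth then name
  depth <- vapply(branches, function(b) {
    d <- 0L; u <- unname(parents[b])
    while (!is.na(u)) { d <- d + 1L; u <- unname(parents[u]) }
    d
  }, integer(1))
  ord <- branches[order(depth, branches)]
  structure(list(
    identifier_sets = identifier_sets,
    parents = parents,
    branch_order = ord,
    internal_labels = stats::setNames(
      paste0(GREEK[seq_along(ord)], "*"), ord),
    panel_variants = ids
  ), class = "backbone_panel")
}

#' Per-sample pseudo-haploid calls at identifier positions
#'
#' @param sample sample id.
#' @param states named integer vector: variant id -> 0 (ancestral) or 1
#'   (derived). Only covered (called) sites appear.
#' @param metadata optional list (site, age BP, reference, ...).
#' @return object of class `ancient_calls` with a `covered` count.
#' @export
ancient_calls <- function(sample, states, metadata = list()) {
  states <- states[!is.na(states)]
  if (!all(states %in% c(0L, 1L)))
    stop("states must be 0 (ancestral) or 1 (derived)")
  structure(list(sample = sample, states = states,
                 covered = length(states), metadata = metadata),
            class = "ancient_calls")
}

#' @export
print.ancient_calls <- function(x, ...) {
  cat(sprintf("ancient_calls: %s, %d covered site(s), %d derived\n",
              x$sample, x$covered, sum(x$states == 1L)))
  invisible(x)
}

#' Coverage eligibility of an ancient sample
#'
#' A sample qualifies for placement when it is genotyped at a minimum
#' fraction of the identifier panel (published practice: at least 48 of 96,
#' i.e. 50%).
#'
#' @param calls an [ancient_calls()] object.
#' @param panel_size total identifier panel size (e.g. 96).
#' @param min_fraction required genotyped fraction, in (0, 1].
#' @return logical.
#' @export
eligibility <- function(calls, panel_size, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  calls$covered >= ceiling(min_fraction * panel_size)
}

branch_counts <- function(calls, panel) {
  t(vapply(names(panel$identifier_sets), function(b) {
    ids <- intersect(panel$identifier_sets[[b]], names(calls$states))
    st <- calls$states[ids]
    c(G = length(ids), D = sum(st == 1L), A = sum(st == 0L))
  }, c(G = 0, D = 0, A = 0)))
}

#' Place an ancient sample on the modern backbone
#'
#' Traverses the backbone root to tip. At each reached node, child branches
#' are examined: a branch passes when at least `min_derived_fraction` of its
#' genotyped identifiers are derived and none is ancestral; the walk
#' descends into the (unique) passing child. A child showing both derived
#' and ancestral identifier states, with no passing sibling, marks a
#' lineage that split mid-branch: the sample is placed at that branch's own
#' internal node and traversal stops. The final placement is the group
#' under the deepest passed branch, or `"unassigned"` when the walk never
#' leaves the root.
#'
#' @param calls an [ancient_calls()] object (should be eligibility-checked
#'   first; see [eligibility()]).
#' @param backbone a [backbone_panel()].
#' @param min_derived_fraction fraction of genotyped identifiers on a
#'   branch that must be derived for the branch to pass (default 0.5).
#' @param error_tolerance number of ancestral calls tolerated on a passing
#'   branch (default 0; a single ancestral call blocks the branch). Exposed
#'   for sensitivity analysis only.
#' @return object of class `placement`: `class` (`"clade"`, `"internal"` or
#'   `"unassigned"`), `branch`, `label`, `counts` (per-branch G/D/A audit
#'   matrix), `notes`.
#' @export
place_backbone <- function(calls, backbone, min_derived_fraction = 0.5,
                           error_tolerance = 0L) {
  stopifnot(inherits(calls, "ancient_calls"),
            inherits(backbone, "backbone_panel"))
  cnt <- branch_counts(calls, backbone)
  passed <- function(b) {
    G <- cnt[b, "G"]; D <- cnt[b, "D"]; A <- cnt[b, "A"]
    G > 0 && D >= ceiling(min_derived_fraction * G) && A <= error_tolerance
  }
  mixed <- function(b) cnt[b, "D"] >= 1 && cnt[b, "A"] >= 1
  notes <- character(0)
  at <- NA_character_   # deepest passed branch; NA = root
  repeat {
    kids <- names(backbone$parents)[
      if (is.na(at)) is.na(backbone$parents)
      else !is.na(backbone$parents) & backbone$parents == at]
    if (!length(kids)) break
    if (all(cnt[kids, "G"] == 0)) {
      notes <- c(notes, "uninformative-path")
      break
    }
    pk <- kids[vapply(kids, passed, logical(1))]
    if (length(pk) == 1L) { at <- pk; next }
    if (length(pk) > 1L) {
      # conflicting evidence across sibling branches; take the better
      # supported one and record the conflict
      frac <- cnt[pk, "D"] / pmax(cnt[pk, "G"], 1)
      at <- pk[order(-frac, pk)][1]
      notes <- c(notes, paste0("conflict: multiple passing siblings (",
                               paste(pk, collapse = ","), ")"))
      next
    }
    mk <- kids[vapply(kids, mixed, logical(1))]
    if (length(mk)) {
      frac <- cnt[mk, "D"] / pmax(cnt[mk, "G"], 1)
      b <- mk[order(-frac, mk)][1]
      return(structure(list(
        class = "internal", branch = b,
        label = unname(backbone$internal_labels[b]),
        counts = cnt, notes = paste(notes, collapse = "; ")),
        class = "placement"))
    }
    break
  }
  if (is.na(at))
    return(structure(list(class = "unassigned", branch = NA_character_,
                          label = "unassigned", counts = cnt,
                          notes = paste(notes, collapse = "; ")),
                     class = "placement"))
  structure(list(class = "clade", branch = at, label = at, counts = cnt,
                 notes = paste(notes, collapse = "; ")),
            class = "placement")
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("placement: %s (%s)%s\n", x$label, x$class,
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' Refine a basal placement over child major-haplogroup branches
#'
#' Ancient samples clustering at a backbone clade (e.g. the basal
#' multifurcation) are checked against the identifier sets of that clade's
#' child major haplogroups with the same derived/ancestral counting rule.
#' When no child branch passes, the sample stays basal.
#'
#' @param calls an [ancient_calls()] object placed in the parent clade.
#' @param mjhg_sets named list: mjHG branch -> identifier variant ids (flat
#'   siblings under the parent clade, or a nested parent map via
#'   `parents`).
#' @param parents optional named parent map among the mjHG branches;
#'   default: all are siblings off the parent.
#' @param parent_label label reported when nothing passes (default
#'   `"basal"`).
#' @param ... passed to [place_backbone()].
#' @return a `placement`; `label` is the mjHG, an internal-node label, or
#'   `"<parent_label>"` when no child branch passes (flagged
#'   `uninformative` when no child identifier was covered at all).
#' @export
refine_da1 <- function(calls, mjhg_sets,
                       parents = NULL, parent_label = "basal", ...) {
  if (is.null(parents))
    parents <- stats::setNames(rep(NA_character_, length(mjhg_sets)),
                               names(mjhg_sets))
  sub <- backbone_panel(mjhg_sets, parents)
  pl <- place_backbone(calls, sub, ...)
  if (pl$class == "unassigned") {
    pl$label <- parent_label
    pl$class <- "basal"
    if (all(pl$counts[, "G"] == 0))
      pl$notes <- paste(c(pl$notes[nzchar(pl$notes)], "uninformative"),
                        collapse = "; ")
  }
  pl
}

#' Tri-state lookup of a single identifier in ancient calls
#'
#' @param calls an [ancient_calls()] object.
#' @param single_identifier variant id; must belong to `known_variants`
#'   when that is supplied.
#' @param known_variants optional character vector of valid variant ids.
#' @return `"present"` (derived), `"absent"` (ancestral) or `"uncalled"`.
#' @export
detect_identifier <- function(calls, single_identifier,
                              known_variants = NULL) {
  if (!is.null(known_variants) && !single_identifier %in% known_variants)
    stop("unknown variant id: ", single_identifier)
  s <- calls$states[single_identifier]
  if (is.na(s)) return("uncalled")
  if (s == 1L) "present" else "absent"
}

#' Place a cohort of ancient samples with audit columns
#'
#' Runs eligibility, backbone placement and (optionally) refinement over
#' the basal clade for every sample, and returns one audit row per sample
#' with per-branch genotyped/derived/ancestral counts.
#'
#' @param calls_list list of [ancient_calls()] objects.
#' @param backbone a [backbone_panel()].
#' @param min_fraction eligibility threshold (fraction of the panel).
#' @param refine_clade optional branch id whose placements are refined.
#' @param mjhg_sets identifier sets for [refine_da1()] when `refine_clade`
#'   is given.
#' @param ... passed to [place_backbone()].
#' @return data.frame: sample, eligible, covered, class, branch, label,
#'   notes, then G/D/A columns per backbone branch.
#' @export
place_cohort <- function(calls_list, backbone, min_fraction = 0.5,
                         refine_clade = NULL, mjhg_sets = NULL, ...) {
  psize <- length(backbone$panel_variants)
  rows <- lapply(calls_list, function(cl) {
    # eligibility is assessed on the backbone panel sites only
    cl_panel <- cl
    cl_panel$covered <- sum(names(cl$states) %in% backbone$panel_variants)
    el <- eligibility(cl_panel, psize, min_fraction)
    if (!el) {
      cnt <- branch_counts(cl, backbone)
      row <- data.frame(sample = cl$sample, eligible = FALSE,
                        covered = cl_panel$covered, class = "ineligible",
                        branch = NA_character_, label = "ineligible",
                        notes = "", stringsAsFactors = FALSE)
    } else {
      pl <- place_backbone(cl, backbone, ...)
      cnt <- pl$counts
      label <- pl$label
      if (!is.null(refine_clade) && pl$class == "clade" &&
          identical(pl$branch, refine_clade)) {
        rf <- refine_da1(cl, mjhg_sets,
                         parent_label = paste0("basal ", refine_clade), ...)
        label <- rf$label
      }
      row <- data.frame(sample = cl$sample, eligible = TRUE,
                        covered = cl_panel$covered, class = pl$class,
                        branch = pl$branch, label = label,
                        notes = pl$notes, stringsAsFactors = FALSE)
    }
    aud <- as.vector(t(cnt))
    names(aud) <- paste0(rep(rownames(cnt), each = 3), "_", c("G", "D", "A"))
    cbind(row, as.data.frame(as.list(aud)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
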