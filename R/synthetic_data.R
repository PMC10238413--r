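# Synthetic data with known truth. The generator emulates the statistical
# structure of horse MSY data: a rooted backbone (Przewalski-type p versus
# the domestic d lineage, d splitting into db and the strongly
# multifurcating da1, with the young Crown clade daC nested inside da1),
# Poisson mutations under infinite sites at the MSY molecular clock over
# the ~5.06 Mb single-copy Y, modern missingness, and ancient samples with
# per-site callability and a small per-call error rate.

#' Simulation configuration
#'
#' Defaults state the world the pipeline is designed for: mutation rate
#' 1.69e-9 per site per year on L = 5,063,000 bp; a backbone whose dated
#' nodes match the domestication-era picture (basal domestic multifurcation
#' da1 about 4,000 years BP, Crown about 1,500 years BP, with the deepest
#' split old enough to give the long p and d stem branches their many
#' identifiers); 170 modern samples; ancient per-sample callability drawn
#' from Beta(2,2) rescaled to [0.2, 1] (uneven coverage, mean 60%) and a 1%
#' per-call error rate.
#'
#' @param seed mandatory RNG seed.
#' @param n_modern number of modern samples.
#' @param n_ancient number of ancient samples.
#' @param mu mutation rate per site per year.
#' @param L surveyed length in bp.
#' @param modern_missingness i.i.d. missing-call rate in the modern matrix.
#' @param ancient_error per-call symmetric flip probability for ancient
#'   calls.
#' @param ancient_error_mode `"symmetric"` or `"derived_only"` (suppresses
#'   ancestral-to-derived flips except deamination-like false derived
#'   calls are kept; used for sensitivity analysis).
#' @param callability `c(min, max, shape1, shape2)` for the rescaled Beta
#'   per-sample callability.
#' @param backbone_times named list of node ages in years BP: `root`
#'   (p/d split), `p_tmrca`, `d_split` (d into db/da1), `db_tmrca`, `da1`
#'   (basal multifurcation), `mjhg_tmrca`, `crown`.
#' @param clade_weights modern sample allocation over clades; names
#'   `p`, `db`, and the da1 major haplogroups (the remainder after `p` and
#'   `db` is spread over da1, mostly Crown).
#' @param n_mjhg number of da1 major-haplogroup clades beside the Crown.
#' @param str_mut_rate stepwise STR mutation rate per year (0 disables the
#'   STR).
#' @param yule_lambda,yule_T birth rate and duration for `mode = "yule"`.
#' @param coalescent_Ne haploid effective size (in years) for
#'   `mode = "coalescent"`.
#' @param mode `"backbone"`, `"yule"` or `"coalescent"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_modern = 170L,
                       n_ancient = 200L,
                       mu = 1.69e-9,
                       L = 5063000L,
                       modern_missingness = 0.02,
                       ancient_error = 0.01,
                       ancient_error_mode = c("symmetric", "derived_only"),
                       callability = c(min = 0.2, max = 1.0,
                                       shape1 = 2, shape2 = 2),
                       backbone_times = list(root = 9500, p_tmrca = 2500,
                                             d_split = 4500, db_tmrca = 2500,
                                             da1 = 4000, mjhg_tmrca = 3000,
                                             crown = 1500),
                       clade_weights = c(p = 0.03, db = 0.03,
                                         da1_A = 0.05, da1_B = 0.05,
                                         da1_C = 0.06, da1_D = 0.08,
                                         daC = 0.70),
                       n_mjhg = 4L,
                       str_mut_rate = 1e-4,
                       yule_lambda = 5e-4,
                       yule_T = 4000,
                       coalescent_Ne = 10000,
                       mode = c("backbone", "yule", "coalescent")) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  ancient_error_mode <- match.arg(ancient_error_mode)
  for (r in c(modern_missingness, ancient_error))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (any(unlist(backbone_times) <= 0)) stop("times must be positive")
  structure(as.list(environment()), class = "sim_config")
}

# ---- tree simulation ---------------------------------------------------

new_sim_tree <- function() {
  list(parent = integer(0), time = numeric(0), label = character(0))
}

add_node <- function(tr, parent, time, label) {
  tr$parent <- c(tr$parent, parent)
  tr$time <- c(tr$time, time)
  tr$label <- c(tr$label, label)
  tr
}

finish_sim_tree <- function(tr) {
  n <- length(tr$parent)
  kids <- rep(0L, n)
  pk <- tr$parent[!is.na(tr$parent)]
  if (length(pk)) { t <- table(pk); kids[as.integer(names(t))] <- as.integer(t) }
  tr$is_tip <- kids == 0L
  tr$n_nodes <- n
  class(tr) <- "sim_tree"
  tr
}

#' @export
print.sim_tree <- function(x, ...) {
  cat(sprintf("sim_tree: %d nodes, %d tips, root age %.0f years BP\n",
              x$n_nodes, sum(x$is_tip), max(x$time)))
  invisible(x)
}

# Kingman-style coalescent subtree under a clade root of age tmrca: draw
# exponential intercoalescent spans and rescale so the subtree's own root
# sits exactly at tmrca.
sim_clade <- function(tr, attach_to, tmrca, tip_names) {
  n <- length(tip_names)
  if (n == 1L) {
    return(add_node(tr, attach_to, 0, tip_names))
  }
  spans <- stats::rexp(n - 1, rate = choose(seq(n, 2), 2))
  times <- cumsum(spans) * (tmrca / sum(spans))
  # build bottom-up: active set of local node indices
  base <- length(tr$parent)
  for (nm in tip_names) tr <- add_node(tr, NA_integer_, 0, nm)
  active <- base + seq_len(n)
  for (k in seq_len(n - 1)) {
    pair <- sample(seq_along(active), 2L)
    anc_time <- times[k]
    tr <- add_node(tr, NA_integer_, anc_time, "")
    anc <- length(tr$parent)
    tr$parent[active[pair]] <- anc
    active <- c(active[-pair], anc)
  }
  tr$parent[active] <- attach_to
  tr
}

#' Simulate a tree
#'
#' Three modes: `"backbone"` returns the fixed MSY-like backbone (p versus
#' d; d into db and the multifurcating da1; da1 into major-haplogroup
#' clades including the young Crown daC) with coalescent subtrees inside
#' each clade; `"yule"` a pure birth tree of rate `yule_lambda` run for
#' `yule_T` years; `"coalescent"` a Kingman coalescent with haploid size
#' `coalescent_Ne` (in years). Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param set_seed whether to seed the RNG from `config$seed` (default
#'   TRUE; pass FALSE when composing inside a larger seeded simulation).
#' @return object of class `sim_tree`: `parent` (NA at root), `time`
#'   (years BP), `label` (tip/sample names and clade-root names),
#'   `is_tip`.
#' @export
simulate_tree <- function(config, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  switch(config$mode,
         backbone = sim_backbone_tree(config),
         yule = sim_yule_tree(config),
         coalescent = sim_coalescent_tree(config))
}

sim_backbone_tree <- function(config) {
  bt <- config$backbone_times
  w <- config$clade_weights
  w <- w / sum(w)
  n <- config$n_modern
  if (n == 1L) {
    tr <- new_sim_tree()
    tr <- add_node(tr, NA_integer_, bt$root, "root")
    tr <- add_node(tr, 1L, 0, "M001")
    return(finish_sim_tree(tr))
  }
  counts <- pmax(round(w * n), 1L)
  while (sum(counts) != n) {
    i <- which.max(counts)
    counts[i] <- counts[i] + (n - sum(counts))
  }
  tipnames <- split(sprintf("M%03d", seq_len(n)),
                    rep(names(counts), counts))
  tr <- new_sim_tree()
  tr <- add_node(tr, NA_integer_, bt$root, "root")      # 1
  tr <- add_node(tr, 1L, bt$p_tmrca, "p")               # 2
  tr <- add_node(tr, 1L, bt$d_split, "d")               # 3
  tr <- add_node(tr, 3L, bt$db_tmrca, "db")             # 4
  tr <- add_node(tr, 3L, bt$da1, "da1")                 # 5
  tr <- sim_clade(tr, 2L, bt$p_tmrca * 0.98, tipnames$p)
  tr <- sim_clade(tr, 4L, bt$db_tmrca * 0.98, tipnames$db)
  mj <- setdiff(names(counts), c("p", "db"))
  for (m in mj) {
    tm <- if (m == "daC") bt$crown else bt$mjhg_tmrca
    tr <- add_node(tr, 5L, tm, m)
    tr <- sim_clade(tr, length(tr$parent), tm * 0.98, tipnames[[m]])
  }
  finish_sim_tree(tr)
}

sim_yule_tree <- function(config) {
  lambda <- config$yule_lambda; Tend <- config$yule_T
  tr <- new_sim_tree()
  tr <- add_node(tr, NA_integer_, Tend, "root")
  # active lineages: node index of their origin, each currently unbroken
  active_origin <- 1L
  active_birth <- 0      # forward time the lineage started
  tau <- 0
  repeat {
    k <- length(active_origin)
    tau <- tau + stats::rexp(1, rate = k * lambda)
    if (tau >= Tend) break
    i <- sample.int(k, 1L)
    tr <- add_node(tr, active_origin[i], Tend - tau, "")
    nd <- length(tr$parent)
    active_origin <- c(active_origin[-i], nd, nd)
    active_birth <- c(active_birth[-i], tau, tau)
  }
  for (j in seq_along(active_origin)) {
    tr <- add_node(tr, active_origin[j], 0, sprintf("M%03d", j))
  }
  finish_sim_tree(tr)
}

sim_coalescent_tree <- function(config) {
  n <- config$n_modern; Ne <- config$coalescent_Ne
  tr <- new_sim_tree()
  for (i in seq_len(n)) tr <- add_node(tr, NA_integer_, 0, sprintf("M%03d", i))
  active <- seq_len(n)
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = choose(k, 2) / Ne)
    pair <- sample(seq_len(k), 2L)
    tr <- add_node(tr, NA_integer_, t, if (k == 2L) "root" else "")
    anc <- length(tr$parent)
    tr$parent[active[pair]] <- anc
    active <- c(active[-pair], anc)
  }
  finish_sim_tree(tr)
}

# ---- mutations ---------------------------------------------------------

#' Drop Poisson mutations on a simulated tree
#'
#' Each branch receives Poisson(mu * L * branch_years) mutations; sites are
#' drawn without replacement from 1..L (infinite sites), so every variant
#' has a single origin and the resulting matrix is four-gamete clean.
#'
#' @param tree a `sim_tree`.
#' @param mu mutation rate per site per year.
#' @param L sequence length in bp.
#' @return list: `variants` (a [variant_table()] with `ancestral = "ref"`),
#'   `branch` (named integer: variant id -> tree node whose in-edge carries
#'   it).
#' @export
drop_mutations <- function(tree, mu, L) {
  edges <- which(!is.na(tree$parent))
  len <- tree$time[tree$parent[edges]] - tree$time[edges]
  if (any(len < 0)) stop("branch with negative duration")
  k <- stats::rpois(length(edges), mu * L * len)
  total <- sum(k)
  if (total > L) stop("more mutations than sites (mu * L too large)")
  if (total == 0L) {
    return(list(variants = variant_table(character(0)), branch = integer(0)))
  }
  pos <- sort(sample.int(L, total))
  branch <- rep(edges, k)
  # order variants by coordinate for deterministic ids
  ord <- sample.int(total)      # shuffle branch attribution across positions
  branch <- branch[ord]
  ids <- sprintf("eS%05d", seq_len(total))
  ref <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  v <- variant_table(ids, contig = "Y", pos = pos, ref = ref, alt = alt,
                     vclass = "SNP", ancestral = "ref")
  list(variants = v, branch = stats::setNames(branch, ids))
}

tip_path_nodes <- function(tree, tip) {
  p <- integer(0); u <- tip
  while (!is.na(u)) { p <- c(p, u); u <- tree$parent[u] }
  p
}

#' Generate the modern sample matrix from simulated truth
#'
#' Each tip's haplotype is derived at exactly the variants on its
#' root-path; cells are then masked i.i.d. at the configured missingness.
#' The `truth` element records the pre-mask matrix and the
#' variant-to-sample-set map used to verify reconstruction.
#'
#' @param tree a `sim_tree`.
#' @param mutations result of [drop_mutations()].
#' @param config a [sim_config()] (uses `modern_missingness` and
#'   `str_mut_rate`).
#' @return list: `matrix` (a `polarized_matrix`), `truth` (list with
#'   `states_complete`, `variant_samples`, `tip_clade`, `str_alleles`).
#' @export
sample_modern <- function(tree, mutations, config) {
  tips <- which(tree$is_tip)
  tipnames <- tree$label[tips]
  v <- mutations$variants
  nv <- nrow(v)
  states <- matrix(0L, length(tips), nv,
                   dimnames = list(tipnames, v$id))
  paths <- lapply(tips, function(t) tip_path_nodes(tree, t))
  onpath <- lapply(paths, function(p) mutations$branch %in% p)
  for (i in seq_along(tips)) states[i, onpath[[i]]] <- 1L

  # clade of each tip = deepest labelled non-root ancestor
  tip_clade <- vapply(paths, function(p) {
    labs <- tree$label[p]
    labs <- labs[nzchar(labs) & labs != "root" & !grepl("^M", labs)]
    if (length(labs)) labs[1] else "root"
  }, character(1))
  names(tip_clade) <- tipnames

  str_alleles <- NULL
  if (config$str_mut_rate > 0) {
    # stepwise walk from repeat 12 at the root
    rep_at <- rep(NA_integer_, tree$n_nodes)
    ord <- order(-tree$time)
    for (u in ord) {
      if (is.na(tree$parent[u])) { rep_at[u] <- 12L; next }
      len <- tree$time[tree$parent[u]] - tree$time[u]
      steps <- stats::rpois(1, config$str_mut_rate * len)
      drift <- if (steps > 0)
        sum(sample(c(-1L, 1L), steps, replace = TRUE)) else 0L
      rep_at[u] <- rep_at[tree$parent[u]] + drift
    }
    str_alleles <- stats::setNames(rep_at[tips], tipnames)
  }

  complete <- states
  if (config$modern_missingness > 0) {
    mask <- matrix(stats::runif(length(states)) < config$modern_missingness,
                   nrow(states), ncol(states))
    states[mask] <- NA_integer_
  }
  vs <- lapply(v$id, function(id) {
    sort(tipnames[complete[, id] == 1L])
  })
  names(vs) <- v$id
  pm <- polarized_matrix(states, variants = v, samples = tipnames,
                         str_alleles = str_alleles)
  list(matrix = pm,
       truth = list(states_complete = complete, variant_samples = vs,
                    tip_clade = tip_clade, str_alleles = str_alleles,
                    branch = mutations$branch))
}

# ---- ancient samples ---------------------------------------------------

#' A synthetic MSY backbone identifier panel
#'
#' Builds the standard four-branch backbone (p and d off the root; db and
#' da1 under d) with the identifier counts genotypable in practice on both
#' horse Y references: 18 p-, 47 d-, 22 db- and 9 da1-identifiers, 96
#' sites in total. Identifier positions along each branch are evenly
#' spaced so that mid-branch (internal-node) lineages have a well-defined
#' derived prefix. All ids are synthetic.
#'
#' @param sizes named integer vector of identifiers per branch.
#' @return a [backbone_panel()] with an extra `branch_fraction` attribute
#'   (identifier position along its branch, 0 = rootward end).
#' @export
msy_backbone_panel <- function(sizes = c(p = 18L, d = 47L, db = 22L,
                                         da1 = 9L)) {
  sets <- lapply(names(sizes), function(b)
    sprintf("%s%03d", b, seq_len(sizes[[b]])))
  names(sets) <- names(sizes)
  parents <- c(p = NA_character_, d = NA_character_, db = "d", da1 = "d")
  parents <- parents[names(sizes)]
  panel <- backbone_panel(sets, parents)
  frac <- lapply(sizes, function(k) (seq_len(k) - 0.5) / k)
  names(frac) <- names(sizes)
  attr(panel, "branch_fraction") <- frac
  panel
}

#' Simulate ancient pseudo-haploid calls on an identifier panel
#'
#' Each sample gets a true placement: a backbone clade (under the deepest
#' branch of its path) or an internal position at fraction `u` along a
#' branch (emulating extinct lineages that diverged mid-branch and are
#' seen only in ancient samples). True states at panel sites follow the
#' placement; per-sample callability is drawn from the configured
#' distribution, each site is called independently with that probability,
#' and each call is flipped with the per-call error rate.
#'
#' @param panel a [msy_backbone_panel()] (or any `backbone_panel` with a
#'   `branch_fraction` attribute).
#' @param config a [sim_config()] (uses `n_ancient`, `callability`,
#'   `ancient_error`, `ancient_error_mode`).
#' @param clade_weights probability of a sample's true placement being the
#'   clade under each terminal backbone branch.
#' @param internal_weights probability of a true mid-branch placement on
#'   each branch; remaining mass goes to the clade weights.
#' @param mjhg_sets optional named list of identifier sets for major
#'   haplogroups under `mjhg_parent`; samples truly in that clade are
#'   further assigned a true mjHG by `mjhg_weights`.
#' @param mjhg_parent branch carrying the mjHG subdivision (default
#'   `"da1"`).
#' @param mjhg_weights named weights over `names(mjhg_sets)` plus
#'   `"basal"`.
#' @param set_seed seed the RNG from `config$seed` (default TRUE).
#' @return list: `calls` (list of [ancient_calls()]), `truth` (data.frame:
#'   sample, class, branch, u, mjhg, callability).
#' @export
sample_ancient <- function(panel, config,
                           clade_weights = c(p = 0.10, db = 0.22,
                                             da1 = 0.58),
                           internal_weights = c(p = 0.02, d = 0.03,
                                                db = 0.03, da1 = 0.02),
                           mjhg_sets = NULL, mjhg_parent = "da1",
                           mjhg_weights = NULL,
                           set_seed = TRUE) {
  stopifnot(inherits(panel, "backbone_panel"))
  if (set_seed) set.seed(config$seed)
  frac <- attr(panel, "branch_fraction")
  if (is.null(frac))
    frac <- lapply(panel$identifier_sets,
                   function(v) (seq_along(v) - 0.5) / length(v))
  cb <- config$callability
  n <- config$n_ancient
  classes <- c(names(clade_weights), paste0("internal:",
                                            names(internal_weights)))
  wts <- c(clade_weights, internal_weights)
  wts <- wts / sum(wts)
  draw <- sample(classes, n, replace = TRUE, prob = wts)
  allv <- panel$panel_variants
  mj_names <- names(mjhg_sets)
  if (!is.null(mjhg_sets) && is.null(mjhg_weights)) {
    mjhg_weights <- stats::setNames(rep(1, length(mj_names) + 1L),
                                    c(mj_names, "basal"))
    if ("daC" %in% mj_names) mjhg_weights["daC"] <- length(mj_names)
  }
  calls <- vector("list", n)
  truth <- data.frame(sample = sprintf("A%03d", seq_len(n)),
                      class = NA_character_, branch = NA_character_,
                      u = NA_real_, mjhg = NA_character_,
                      callability = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cls <- draw[i]
    internal <- startsWith(cls, "internal:")
    b <- sub("^internal:", "", cls)
    path <- character(0); uu <- b
    while (!is.na(uu)) { path <- c(uu, path); uu <- unname(panel$parents[uu]) }
    st <- stats::setNames(rep(0L, length(allv)), allv)
    for (pb in setdiff(path, b)) st[panel$identifier_sets[[pb]]] <- 1L
    u <- NA_real_
    if (internal) {
      u <- stats::runif(1, 0.15, 0.85)
      ids <- panel$identifier_sets[[b]]
      st[ids[frac[[b]] < u]] <- 1L
    } else {
      st[panel$identifier_sets[[b]]] <- 1L
    }
    mj <- NA_character_
    if (!internal && !is.null(mjhg_sets) && b == mjhg_parent) {
      mj <- sample(c(mj_names, "basal"), 1L,
                   prob = mjhg_weights[c(mj_names, "basal")])
      if (mj != "basal") {
        ext <- stats::setNames(rep(0L, length(unlist(mjhg_sets))),
                               unlist(mjhg_sets))
        ext[mjhg_sets[[mj]]] <- 1L
        st <- c(st, ext)
      } else {
        ext <- stats::setNames(rep(0L, length(unlist(mjhg_sets))),
                               unlist(mjhg_sets))
        st <- c(st, ext)
      }
    } else if (!is.null(mjhg_sets)) {
      # mjHG identifiers are ancestral for samples outside the parent clade
      ext <- stats::setNames(rep(0L, length(unlist(mjhg_sets))),
                             unlist(mjhg_sets))
      st <- c(st, ext)
    }
    callab <- cb["min"] + (cb["max"] - cb["min"]) *
      stats::rbeta(1, cb["shape1"], cb["shape2"])
    covered <- stats::runif(length(st)) < callab
    st <- st[covered]
    if (config$ancient_error > 0 && length(st)) {
      flip <- stats::runif(length(st)) < config$ancient_error
      if (config$ancient_error_mode == "derived_only") {
        flip <- flip & st == 0L   # only false derived calls (deamination)
      }
      st[flip] <- 1L - st[flip]
    }
    calls[[i]] <- ancient_calls(truth$sample[i], st,
                                metadata = list(callability = callab))
    truth$class[i] <- if (internal) "internal" else "clade"
    truth$branch[i] <- b
    truth$u[i] <- u
    truth$mjhg[i] <- mj
    truth$callability[i] <- unname(callab)
  }
  list(calls = calls, truth = truth)
}

#' One-call simulation of a full modern dataset
#'
#' Seeds the RNG, simulates the tree, drops mutations and emits the modern
#' matrix plus truth. Identifier sets of the backbone stem branches (edges
#' above the clade roots) are returned so ancient placement can be tested
#' against the same world.
#'
#' @param config a [sim_config()].
#' @return list: `tree`, `mutations`, `matrix`, `truth`,
#'   `backbone_sets` (named list of stem-branch identifier sets, backbone
#'   mode only).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  tree <- simulate_tree(config, set_seed = FALSE)
  mutations <- drop_mutations(tree, config$mu, config$L)
  ms <- sample_modern(tree, mutations, config)
  backbone_sets <- NULL
  if (config$mode == "backbone") {
    stem <- function(lab) {
      nd <- which(tree$label == lab)[1]
      names(mutations$branch)[mutations$branch == nd]
    }
    labs <- setdiff(unique(tree$label[nzchar(tree$label)]),
                    c("root", grep("^M", tree$label, value = TRUE)))
    backbone_sets <- lapply(labs, stem)
    names(backbone_sets) <- labs
  }
  list(tree = tree, mutations = mutations, matrix = ms$matrix,
       truth = ms$truth, backbone_sets = backbone_sets)
}
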