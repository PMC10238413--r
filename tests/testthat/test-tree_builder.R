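test_that("four-gamete check flags exactly the incompatible pairs", {
  # nested pair: compatible
  st <- cbind(A = c(1L, 1L, 0L, 0L), B = c(1L, 0L, 0L, 0L))
  rownames(st) <- paste0("s", 1:4)
  expect_equal(nrow(four_gamete_check(st)$violations), 0L)
  # patterns {10, 01, 11}: violation
  st2 <- cbind(A = c(1L, 0L, 1L), B = c(0L, 1L, 1L))
  fg2 <- four_gamete_check(st2)
  expect_equal(nrow(fg2$violations), 1L)
  expect_setequal(unlist(fg2$violations[1, ]), c("A", "B"))
  # pair with no joint observation is skipped and counted
  st3 <- cbind(A = c(1L, NA, NA), B = c(NA, 1L, 0L))
  fg3 <- four_gamete_check(st3)
  expect_equal(fg3$n_pairs_skipped, 1L)
})

test_that("simulated infinite-sites matrices are four-gamete clean", {
  for (sd in 1:3) {
    cfg <- sim_config(seed = sd, n_modern = 25, modern_missingness = 0,
                      mode = "coalescent", coalescent_Ne = 1500)
    ds <- simulate_dataset(cfg)
    expect_equal(nrow(four_gamete_check(ds$matrix)$violations), 0L)
  }
})

test_that("build_tree reconstructs the nested-pair caterpillar", {
  # A derived in s1,s2; B derived in s1 only -> ((s1)B, s2)A, (s3, s4)
  st <- cbind(A = c(1L, 1L, 0L, 0L), B = c(1L, 0L, 0L, 0L))
  rownames(st) <- paste0("s", 1:4)
  pm <- make_pm(st)
  tr <- build_tree(pm)
  vs <- variant_sample_sets(tr)
  expect_equal(vs[["A"]], c("s1", "s2"))
  expect_equal(vs[["B"]], "s1")
  # B's branch is a child of A's branch
  expect_equal(tr$parent[tr$variant_branch[["B"]]],
               unname(tr$variant_branch[["A"]]))
  # s3, s4 carry the root haplotype
  expect_setequal(tr$node_samples[[1]], c("s3", "s4"))
})

test_that("build_tree errors on zero polarized variants, tolerates one tip", {
  st <- cbind(v1 = c(0L, 0L))
  v <- variant_table("v1", ancestral = "unknown")
  expect_error(build_tree(make_pm(st, variants = v)), "zero polarized")
  # all-identical samples -> single-node tree, not an error
  st2 <- cbind(v1 = c(0L, 0L, 0L))
  tr <- build_tree(make_pm(st2))
  expect_equal(tr$n_nodes, 1L)
  expect_equal(length(tr$node_samples[[1]]), 3L)
})

test_that("reconstruction recovers simulator truth exactly (spot seeds)", {
  for (sd in c(2, 19, 101)) {
    cfg <- sim_config(seed = sd, n_modern = 30, modern_missingness = 0)
    ds <- simulate_dataset(cfg)
    tr <- build_tree(ds$matrix)
    vs <- variant_sample_sets(tr)
    truth <- ds$truth$variant_samples
    expect_equal(length(vs), length(truth))
    expect_true(all(vapply(names(vs), function(id)
      identical(vs[[id]], truth[[id]]), logical(1))))
    expect_equal(length(tr$excluded_variants), 0L)
  }
})

test_that("tree construction is invariant to sample and variant order", {
  cfg <- sim_config(seed = 77, n_modern = 20, modern_missingness = 0.03)
  ds <- simulate_dataset(cfg)
  pm <- ds$matrix
  set.seed(1); sp <- sample(nrow(pm$states)); vp <- sample(ncol(pm$states))
  pm2 <- polarized_matrix(pm$states[sp, vp],
                          variants = pm$variants[vp, ],
                          samples = pm$samples[sp])
  t1 <- name_haplogroups(build_tree(pm))
  t2 <- name_haplogroups(build_tree(pm2))
  vs1 <- variant_sample_sets(t1); vs2 <- variant_sample_sets(t2)
  expect_setequal(names(vs1), names(vs2))
  expect_true(all(vapply(names(vs1), function(id)
    identical(vs1[[id]], vs2[[id]]), logical(1))))
  expect_identical(to_newick(t1), to_newick(t2))
})

test_that("branch mutation counts reconcile with topology and ledger", {
  cfg <- sim_config(seed = 5, n_modern = 25, modern_missingness = 0)
  ds <- simulate_dataset(cfg)
  pm <- ds$matrix
  # inject one homoplasic variant: derived in two disjoint clades
  tr0 <- build_tree(pm)
  vs <- variant_sample_sets(tr0)
  sets <- vs[order(lengths(vs))]
  disj <- NULL
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && !length(intersect(sets[[i]], sets[[j]])) &&
          length(sets[[i]]) > 1 && length(sets[[j]]) > 1) {
        disj <- c(sets[i], sets[j]); break
      }
    }
    if (!is.null(disj)) break
  }
  hom <- stats::setNames(as.integer(pm$samples %in% unlist(disj)),
                         pm$samples)
  st <- cbind(pm$states, hom = hom)
  pm2 <- polarized_matrix(st, samples = pm$samples)
  tr <- build_tree(pm2)
  expect_true("hom" %in% tr$excluded_variants)
  expect_equal(nrow(tr$homoplasy), 1L)
  n_topo <- length(tr$variant_branch)
  extra <- sum(tr$homoplasy$extra_steps)
  n_led <- sum(lengths(strsplit(tr$homoplasy$branches, ",")))
  expect_equal(sum(branch_mutation_count(tr)), n_topo)
  # one origin per ledger row plus its extra steps
  expect_equal(n_led, nrow(tr$homoplasy) + extra)
})

test_that("place_homoplasic handles degenerate and two-origin characters", {
  cfg <- sim_config(seed = 9, n_modern = 16, modern_missingness = 0)
  ds <- simulate_dataset(cfg)
  tr <- build_tree(ds$matrix)
  vs <- variant_sample_sets(tr)
  # compatible character (one clade): 1 branch, 0 extra steps
  some <- names(vs)[[which.max(lengths(vs))]]
  states <- stats::setNames(as.integer(tr$samples %in% vs[[some]]),
                            tr$samples)
  pl <- place_homoplasic(tr, states)
  expect_equal(length(pl$branches), 1L)
  expect_equal(pl$extra_steps, 0L)
  expect_equal(pl$score, 1)
  # all-ancestral character: score 0
  pl0 <- place_homoplasic(tr, stats::setNames(rep(0L, length(tr$samples)),
                                              tr$samples))
  expect_equal(pl0$score, 0)
  expect_equal(length(pl0$branches), 0L)
  # two disjoint clades: 2 branches, 1 extra step
  sets <- vs[order(lengths(vs))]
  disj <- NULL
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && !length(intersect(sets[[i]], sets[[j]]))) {
        disj <- c(sets[i], sets[j]); break
      }
    }
    if (!is.null(disj)) break
  }
  states2 <- stats::setNames(
    as.integer(tr$samples %in% unlist(disj)), tr$samples)
  pl2 <- place_homoplasic(tr, states2)
  expect_equal(pl2$score, 2)
  expect_equal(pl2$extra_steps, 1L)
})

test_that("place_homoplasic matches the brute-force oracle on random trees", {
  set.seed(42)
  shapes <- enum_shapes(6)
  for (rep in 1:25) {
    sh <- shapes[[sample.int(length(shapes), 1)]]
    tr <- shape_to_tree(sh)
    n <- length(tr$samples)
    st <- stats::setNames(sample(c(0L, 1L, NA), n, TRUE, c(.4, .4, .2)),
                          tr$samples)
    expect_equal(place_homoplasic(tr, st)$score, brute_parsimony(tr, st),
                 info = paste("shape", shape_key(sh),
                              paste(st, collapse = "")))
  }
})

test_that("haplogroup naming is deterministic, anchored, and flags strays", {
  st <- cbind(p1 = c(1L, 0L, 0L, 0L), d1 = c(0L, 1L, 1L, 1L),
              c1 = c(0L, 1L, 1L, 0L), c2 = c(0L, 1L, 0L, 0L))
  rownames(st) <- c("prz", "dom1", "dom2", "dom3")
  pm <- make_pm(st)
  tr <- build_tree(pm, anchors = list(p = "p1", da = "d1", daC = "c1"))
  labs <- tr$labels
  expect_true(all(c("p", "da", "daC") %in% labs))
  # unanchored child of daC gets a suffix letter
  expect_equal(labs[tr$variant_branch[["c2"]]], "daC_A")
  # inner-node assignment carries the '*'
  hg <- haplogroup_assignments(tr)
  expect_equal(unname(hg["dom3"]), "da*")     # at da, above daC
  expect_equal(unname(hg["prz"]), "p")
  expect_error(build_tree(pm, anchors = list(p = "nonexistent")),
               "absent")
})

test_that("labels are stable when a new sample splits one tip", {
  st <- cbind(a = c(1L, 1L, 0L), b = c(0L, 0L, 1L), c = c(1L, 0L, 0L))
  rownames(st) <- c("s1", "s2", "s3")
  t1 <- name_haplogroups(build_tree(make_pm(st)), list(A = "a", B = "b"))
  # add s4 inside clade A with a new private variant splitting s2 off
  st2 <- rbind(st, s4 = c(1L, 0L, 0L))
  st2 <- cbind(st2, d = c(0L, 0L, 0L, 1L))
  t2 <- name_haplogroups(build_tree(make_pm(st2)), list(A = "a", B = "b"))
  lab_of <- function(tr, vid) tr$labels[tr$variant_branch[[vid]]]
  expect_equal(lab_of(t1, "a"), lab_of(t2, "a"))
  expect_equal(lab_of(t1, "b"), lab_of(t2, "b"))
  expect_equal(lab_of(t1, "c"), lab_of(t2, "c"))
})

test_that("to_newick is canonical, round-trips, and handles one tip", {
  # single-node tree
  st1 <- cbind(v1 = 0L); rownames(st1) <- "only"
  tr1 <- name_haplogroups(build_tree(make_pm(st1)))
  expect_equal(to_newick(tr1), "(only)Y;")
  # 4-tip fixture, byte-frozen under canonical child ordering
  st <- cbind(A = c(1L, 1L, 0L, 0L), B = c(1L, 0L, 0L, 0L))
  rownames(st) <- paste0("s", 1:4)
  tr <- name_haplogroups(build_tree(make_pm(st)))
  nwk <- to_newick(tr)
  expect_equal(nwk, "(s3|s4,(s2,s1)Y_A)Y;")
  expect_identical(to_newick(tr), nwk)  # byte-stable on re-export
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = to_newick(tr, with_branch_mutations = TRUE))
  expect_s3_class(ph, "phylo")
  rt <- ape::read.tree(text = ape::write.tree(ph))
  expect_equal(ape::Ntip(rt), ape::Ntip(ph))
  expect_identical(ape::write.tree(rt), ape::write.tree(ph))
})

test_that("branch identifier table exports and reconciles", {
  cfg <- sim_config(seed = 13, n_modern = 12, modern_missingness = 0)
  ds <- simulate_dataset(cfg)
  tr <- name_haplogroups(build_tree(ds$matrix))
  path <- tempfile(fileext = ".tsv")
  write_branch_table(tr, path)
  df <- read.delim(path)
  expect_equal(nrow(df), length(tr$variant_branch))
  expect_true(all(df$variant %in% ds$matrix$variants$id))
})
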