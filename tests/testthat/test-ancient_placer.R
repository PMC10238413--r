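test_that("eligibility uses the ceiling of the panel fraction", {
  mk48 <- ancient_calls("a", stats::setNames(rep(1L, 48), paste0("v", 1:48)))
  mk47 <- ancient_calls("a", stats::setNames(rep(1L, 47), paste0("v", 1:47)))
  mk96 <- ancient_calls("a", stats::setNames(rep(1L, 96), paste0("v", 1:96)))
  expect_true(eligibility(mk48, 96, 0.5))
  expect_false(eligibility(mk47, 96, 0.5))
  expect_true(eligibility(mk96, 96, 0.5))
  expect_error(eligibility(mk48, 96, 0), "\\(0, 1\\]")
})

test_that("clean derived/ancestral patterns place to the expected clade", {
  panel <- msy_backbone_panel()
  # all 18 p-identifiers derived, everything else ancestral -> clade p
  st <- stats::setNames(rep(0L, 96), panel$panel_variants)
  st[panel$identifier_sets$p] <- 1L
  pl <- place_backbone(ancient_calls("botai", st), panel)
  expect_equal(pl$class, "clade")
  expect_equal(pl$branch, "p")
  # audit counts reconcile with a brute-force recount
  expect_equal(unname(pl$counts["p", ]), c(18, 18, 0))
  expect_equal(unname(pl$counts["d", ]),
               c(47, sum(st[panel$identifier_sets$d] == 1),
                 sum(st[panel$identifier_sets$d] == 0)))
})

test_that("mixed branch states yield an internal-node placement", {
  panel <- msy_backbone_panel()
  # derived along d; db shows 2 derived and 5 ancestral -> internal(db)
  st <- stats::setNames(rep(0L, 96), panel$panel_variants)
  st[panel$identifier_sets$d] <- 1L
  st[panel$identifier_sets$db[1:2]] <- 1L
  st[panel$identifier_sets$db[3:7]] <- 0L
  st <- st[c(panel$identifier_sets$d, panel$identifier_sets$db[1:7],
             panel$identifier_sets$p)]
  pl <- place_backbone(ancient_calls("x", st), panel)
  expect_equal(pl$class, "internal")
  expect_equal(pl$branch, "db")
  expect_match(pl$label, "\\*$")
  expect_equal(unname(pl$counts["db", c("D", "A")]), c(2, 5))
})

test_that("uninformative path and unassigned cases are flagged", {
  panel <- msy_backbone_panel()
  # nothing covered on any root branch
  st <- stats::setNames(rep(1L, 5), panel$identifier_sets$db[1:5])
  pl <- place_backbone(ancient_calls("x", st), panel)
  expect_equal(pl$class, "unassigned")
  # covered but all-ancestral everywhere -> stays at root, unassigned
  st2 <- stats::setNames(rep(0L, 96), panel$panel_variants)
  pl2 <- place_backbone(ancient_calls("y", st2), panel)
  expect_equal(pl2$class, "unassigned")
})

test_that("refine_da1 assigns mjHGs or falls back to basal", {
  mj <- list(daC = paste0("c", 1:6), da1_N = paste0("n", 1:5))
  # at least half the genotyped daC identifiers derived, none ancestral
  st <- stats::setNames(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L),
                        c(paste0("c", 1:4), paste0("n", 1:4)))
  st["c4"] <- NA
  pl <- refine_da1(ancient_calls("yeni", st[!is.na(st)]), mj)
  expect_equal(pl$branch, "daC")
  expect_equal(pl$class, "clade")
  # no mjHG identifiers covered -> basal, flagged uninformative
  st2 <- stats::setNames(1L, "zzz")
  expect_error(ancient_calls("q", st2), NA)
  pl2 <- refine_da1(ancient_calls("q", st2), mj, parent_label = "basal da1")
  expect_equal(pl2$label, "basal da1")
  expect_match(pl2$notes, "uninformative")
})

test_that("detect_identifier is a tri-state lookup", {
  calls <- ancient_calls("marvele", c(rBA = 1L, xx = 0L))
  expect_equal(detect_identifier(calls, "rBA"), "present")
  expect_equal(detect_identifier(calls, "xx"), "absent")
  expect_equal(detect_identifier(calls, "notcovered"), "uncalled")
  expect_error(detect_identifier(calls, "bogus",
                                 known_variants = c("rBA", "xx")),
               "unknown variant")
})

test_that("simulated cohorts place accurately and audits reconcile", {
  panel <- msy_backbone_panel()
  cfg <- sim_config(seed = 12, n_ancient = 150)
  an <- sample_ancient(panel, cfg)
  pl <- place_cohort(an$calls, panel)
  ok <- vapply(seq_len(nrow(pl)), function(i) {
    if (!pl$eligible[i]) return(NA)
    placement_correct(pl[i, ], an$truth[i, ], panel)
  }, logical(1))
  expect_gt(mean(ok, na.rm = TRUE), 0.95)
  # D/A audit columns equal brute-force recounts from the raw calls
  for (i in sample(which(pl$eligible), 10)) {
    cl <- an$calls[[i]]
    for (b in names(panel$identifier_sets)) {
      ids <- intersect(panel$identifier_sets[[b]], names(cl$states))
      expect_equal(pl[[paste0(b, "_D")]][i], sum(cl$states[ids] == 1L))
      expect_equal(pl[[paste0(b, "_A")]][i], sum(cl$states[ids] == 0L))
    }
  }
})

test_that("lower callability only moves error-free samples shallower", {
  panel <- msy_backbone_panel()
  frac <- attr(panel, "branch_fraction")
  depth_of <- function(pl) {
    if (pl$class == "unassigned") return(0L)
    length(backbone_path(panel, pl$branch))
  }
  set.seed(99)
  full <- stats::setNames(rep(0L, 96), panel$panel_variants)
  full[c(panel$identifier_sets$d, panel$identifier_sets$da1)] <- 1L
  path_branches <- c("d", "da1")
  for (rep in 1:20) {
    for (cb in c(0.9, 0.6, 0.3)) {
      keep <- stats::runif(96) < cb
      st <- full[keep]
      if (!length(st)) next
      pl <- place_backbone(ancient_calls("s", st), panel)
      # never a wrong deeper clade: any clade/internal hit is on the path
      if (pl$class != "unassigned")
        expect_true(pl$branch %in% path_branches)
    }
  }
})

test_that("complete error-free calls reproduce tree placement on the backbone", {
  cfg <- sim_config(seed = 55, n_modern = 40, modern_missingness = 0)
  ds <- simulate_dataset(cfg)
  sets <- ds$backbone_sets[c("p", "d", "db", "da1")]
  skip_if(any(lengths(sets) == 0), "a stem branch drew zero mutations")
  panel <- backbone_panel(sets, c(p = NA, d = NA, db = "d", da1 = "d"))
  clade_of <- ds$truth$tip_clade
  for (s in sample(ds$matrix$samples, 12)) {
    st <- ds$matrix$states[s, unlist(sets)]
    pl <- place_backbone(ancient_calls(s, st), panel)
    want <- if (clade_of[[s]] == "p") "p"
            else if (clade_of[[s]] == "db") "db" else "da1"
    expect_equal(pl$branch, want)
    expect_equal(pl$class, "clade")
  }
})
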