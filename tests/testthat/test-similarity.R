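# Hand-built networks exercising every case of the local similarity indexes.

u4 <- c("00010", "00020", "00030", "00040")

test_that("pathway similarity covers all functional-level cases", {
  a <- make_net("aaa", u4, list(
    "00010" = list(reactions = rx(R00001 = 1, R00002 = 1, R00003 = 1)),
    "00020" = list(), # physical
    "00030" = list(reactions = rx(R00009 = 1)),
    "00040" = list() # physical in a, reaction in b: mixed
  ))
  b <- make_net("bbb", u4, list(
    "00010" = list(reactions = rx(R00002 = 1, R00003 = 1, R00004 = 1)),
    "00020" = list(), # physical
    "00040" = list(reactions = rx(R00007 = 1))
  ))

  # case 3: Jaccard of reaction sets, {R1,R2,R3} vs {R2,R3,R4} -> 2/4
  sp <- sim_pathway(a, b, "00010", "set")
  expect_equal(sp$value, 0.5)
  expect_equal(sp$case, "case3")
  expect_equal(sp$union_size, 4)

  # case 2: physical in both -> 1
  sp <- sim_pathway(a, b, "00020")
  expect_equal(sp$value, 1)
  expect_equal(sp$case, "case2")
  expect_equal(sp$union_size, 0)

  # case 1: present in exactly one organism -> 0
  sp <- sim_pathway(a, b, "00030")
  expect_equal(sp$value, 0)
  expect_equal(sp$case, "case1")
  expect_equal(sp$union_size, 1)

  # mixed physical/reaction sub-case -> 0 with its own label
  sp <- sim_pathway(a, b, "00040")
  expect_equal(sp$value, 0)
  expect_equal(sp$case, "case3_mixed")
  expect_equal(sp$union_size, 1)

  # absent in both is outside the comparison domain
  empty <- make_net("ccc", u4, list("00010" = list(reactions = rx(R00001 = 1))))
  expect_error(sim_pathway(empty, empty, "00020"), "absent from both")
})

test_that("multiset mode uses min/max multiplicity arithmetic", {
  a <- make_net("aaa", "00010", list(
    "00010" = list(reactions = rx(R00001 = 2, R00002 = 1))
  ))
  b <- make_net("bbb", "00010", list(
    "00010" = list(reactions = rx(R00001 = 1, R00002 = 2))
  ))
  # intersection min(2,1)+min(1,2)=2, union max(2,1)+max(1,2)=4
  expect_equal(sim_pathway(a, b, "00010", "multiset")$value, 0.5)
  # in set mode multiplicities collapse and the sets are identical
  expect_equal(sim_pathway(a, b, "00010", "set")$value, 1)
})

test_that("identical reaction multisets give similarity 1 in both modes", {
  a <- make_net("aaa", "00010", list(
    "00010" = list(reactions = rx(R00001 = 1, R00002 = 1))
  ))
  b <- make_net("bbb", "00010", list(
    "00010" = list(reactions = rx(R00001 = 1, R00002 = 1))
  ))
  expect_equal(sim_pathway(a, b, "00010", "set")$value, 1)
  expect_equal(sim_pathway(a, b, "00010", "multiset")$value, 1)
})

test_that("set and multiset modes agree when all multiplicities are 1", {
  for (seed in 1:8) {
    spec <- random_fixture_spec(seed, n_pathways = 5, p_duplicate = 0)
    nets <- fixture_networks(spec)
    cmp_set <- suppressWarnings(compare_pair(nets[[1]], nets[[2]], "set"))
    cmp_ms <- suppressWarnings(compare_pair(nets[[1]], nets[[2]], "multiset"))
    expect_equal(cmp_set$rows$sim_p, cmp_ms$rows$sim_p, tolerance = 1e-12)
    expect_equal(cmp_set$psim, cmp_ms$psim, tolerance = 1e-12)
  }
})

test_that("structure similarity covers all topological cases", {
  u <- c("00010", "00020", "00030", "00040", "00050")
  # a: 00010-00020, 00010-00030, 00010-00040 (hub), 00050 isolated
  a <- make_net("aaa", u, list(
    "00010" = list(compounds = c("C00100", "C00200", "C00300")),
    "00020" = list(compounds = "C00100"),
    "00030" = list(compounds = "C00200"),
    "00040" = list(compounds = "C00300"),
    "00050" = list(compounds = "C00999")
  ))
  # b: 00010-00020, 00010-00050; 00030 isolated; 00040 absent
  b <- make_net("bbb", u, list(
    "00010" = list(compounds = c("C00100", "C00500")),
    "00020" = list(compounds = "C00100"),
    "00030" = list(compounds = "C00777"),
    "00050" = list(compounds = "C00500")
  ))

  # case 4: neighbours {20,30,40} vs {20,50} -> 1/4
  ss <- sim_structure(a, b, "00010")
  expect_equal(ss$value, 0.25)
  expect_equal(ss$case, "case4")

  # case 4 with full agreement
  expect_equal(sim_structure(a, b, "00020")$value, 1)

  # case 3: isolated in one, degree 1 in the other -> 1/(1+1)
  ss <- sim_structure(a, b, "00030")
  expect_equal(ss$value, 0.5)
  expect_equal(ss$case, "case3")

  # case 1: node in exactly one graph
  ss <- sim_structure(a, b, "00040")
  expect_equal(ss$value, 0)
  expect_equal(ss$case, "case1")

  # case 3 seen from the other side: isolated in a, connected in b
  ss <- sim_structure(a, b, "00050")
  expect_equal(ss$value, 0.5)
  expect_equal(ss$case, "case3")
})

test_that("isolated in one organism and degree 3 in the other gives 1/4", {
  u <- c("00010", "00020", "00030", "00040")
  a <- make_net("aaa", u, list(
    "00010" = list(compounds = "C00999"),
    "00020" = list(compounds = "C00001"), # decoy only
    "00030" = list(),
    "00040" = list()
  ))
  b <- make_net("bbb", u, list(
    "00010" = list(compounds = c("C00100", "C00200", "C00300")),
    "00020" = list(compounds = "C00100"),
    "00030" = list(compounds = "C00200"),
    "00040" = list(compounds = "C00300")
  ))
  expect_equal(sim_structure(a, b, "00010")$value, 1 / (1 + 3))
})

test_that("isolated in both graphs scores 1", {
  a <- make_net("aaa", c("00010", "00020"), list(
    "00010" = list(compounds = "C00111"),
    "00020" = list(compounds = "C00222")
  ))
  b <- make_net("bbb", c("00010", "00020"), list(
    "00010" = list(compounds = "C00333"),
    "00020" = list(compounds = "C00444")
  ))
  ss <- sim_structure(a, b, "00010")
  expect_equal(ss$value, 1)
  expect_equal(ss$case, "case2")
})

test_that("compare_pair aggregates the global indexes from the rows", {
  # engineered: SimP = (1, 0.5, 0), SimS = (1, 1, 0)
  u <- c("00010", "00020", "00030")
  a <- make_net("aaa", u, list(
    "00010" = list(reactions = rx(R00001 = 1), compounds = "C00101"),
    "00020" = list(reactions = rx(R00002 = 1), compounds = "C00102"),
    "00030" = list(reactions = rx(R00009 = 1), compounds = "C00103")
  ))
  b <- make_net("bbb", u, list(
    "00010" = list(reactions = rx(R00001 = 1), compounds = "C00201"),
    "00020" = list(reactions = rx(R00002 = 1, R00004 = 1), compounds = "C00202")
  ))
  cmp <- compare_pair(a, b)
  expect_equal(cmp$rows$sim_p, c(1, 0.5, 0))
  expect_equal(cmp$rows$sim_s, c(1, 1, 0))
  expect_equal(cmp$psim, 0.5)
  expect_equal(cmp$ssim, 2 / 3)
  expect_equal(cmp$csim, (1 * 1 + 1 * 0.5 + 0 * 0) / 3)
  # weights |R u R'| = (1, 2, 1)
  expect_equal(cmp$psim_w, (1 * 1 + 0.5 * 2 + 0 * 1) / 4)
  expect_equal(cmp$n, 3)
})

test_that("the weighted index down-weights small reaction pathways", {
  # SimP = (1, 0.5) with union sizes (10, 2): PsimW = 11/12, Psim = 0.75
  u <- c("00010", "00020")
  big <- paste0("R1", sprintf("%04d", 1:10))
  a <- make_net("aaa", u, list(
    "00010" = list(reactions = stats::setNames(rep(1L, 10), big)),
    "00020" = list(reactions = rx(R00001 = 1, R00002 = 1))
  ))
  b <- make_net("bbb", u, list(
    "00010" = list(reactions = stats::setNames(rep(1L, 10), big)),
    "00020" = list(reactions = rx(R00001 = 1))
  ))
  cmp <- compare_pair(a, b)
  expect_equal(cmp$psim, 0.75)
  expect_equal(cmp$psim_w, (10 + 0.5 * 2) / 12)
})

test_that("PsimW is NA with a warning when no reaction pathway exists", {
  a <- make_net("aaa", c("00010", "00020"), list(
    "00010" = list(compounds = "C00100"),
    "00020" = list(compounds = "C00200")
  ))
  b <- make_net("bbb", c("00010", "00020"), list(
    "00010" = list(compounds = "C00300")
  ))
  expect_warning(cmp <- compare_pair(a, b), "undefined")
  expect_true(is.na(cmp$psim_w))
  expect_false(is.na(cmp$psim))
  expect_false(is.na(cmp$ssim))
  expect_false(is.na(cmp$csim))
})

test_that("compare_pair refuses an empty comparison domain", {
  a <- make_net("aaa", c("00010", "00020"), list())
  b <- make_net("bbb", c("00010", "00020"), list())
  expect_error(compare_pair(a, b), "present in either organism")
})

test_that("networks over different universes or exclusion lists are rejected", {
  a <- make_net("aaa", "00010", list("00010" = list()))
  b <- make_net("bbb", c("00010", "00020"), list("00010" = list()))
  expect_error(compare_pair(a, b), "different pathway universes")
  c2 <- make_net("ccc", "00010", list("00010" = list()), ubiquitous = "C00001")
  expect_error(compare_pair(a, c2), "ubiquitous")
})

test_that("comparison is symmetric and identity scores 1 everywhere", {
  for (seed in 1:5) {
    spec <- random_fixture_spec(seed, n_pathways = 6)
    nets <- fixture_networks(spec)
    ab <- suppressWarnings(compare_pair(nets[[1]], nets[[2]], "multiset"))
    ba <- suppressWarnings(compare_pair(nets[[2]], nets[[1]], "multiset"))
    expect_equal(ab$rows$sim_p, ba$rows$sim_p, tolerance = 1e-12)
    expect_equal(ab$rows$sim_s, ba$rows$sim_s, tolerance = 1e-12)
    expect_equal(
      c(ab$psim, ab$psim_w, ab$ssim, ab$csim),
      c(ba$psim, ba$psim_w, ba$ssim, ba$csim),
      tolerance = 1e-12
    )

    self <- suppressWarnings(compare_pair(nets[[1]], nets[[1]]))
    expect_true(all(self$rows$sim_p == 1))
    expect_true(all(self$rows$sim_s == 1))
    expect_equal(self$psim, 1)
    expect_equal(self$ssim, 1)
    expect_equal(self$csim, 1)
  }
})

test_that("removing an intersection reaction never increases pathway similarity", {
  # In set mode, deleting a shared accession from one organism removes one
  # unit of intersection and leaves the union unchanged. In multiset mode
  # the same is true of removing one occurrence counted in the intersection
  # (the organism's count does not exceed the partner's). Removing a
  # *surplus* occurrence instead shrinks the union only, which legitimately
  # raises the Jaccard value, so that case is excluded by construction.
  for (seed in 1:10) {
    spec <- random_fixture_spec(seed, n_pathways = 4)
    plan_a <- spec$plan[[1]]
    plan_b <- spec$plan[[2]]
    for (p in spec$universe) {
      ea <- plan_a[[p]]
      eb <- plan_b[[p]]
      if (is.null(ea) || is.null(eb)) next
      shared <- intersect(names(ea$reactions), names(eb$reactions))
      if (length(ea$reactions) < 2L) next

      # set mode: drop a whole shared accession
      for (drop in shared) {
        spec2 <- spec
        spec2$plan[[1]][[p]]$reactions <-
          ea$reactions[names(ea$reactions) != drop]
        before <- fixture_oracle(spec, "set")
        after <- fixture_oracle(spec2, "set")
        i <- match(p, before$rows$pathway)
        expect_lte(after$rows$sim_p[i], before$rows$sim_p[i] + 1e-12)
      }

      # multiset mode: decrement an occurrence inside the intersection
      inside <- shared[ea$reactions[shared] <= eb$reactions[shared]]
      for (drop in inside) {
        spec2 <- spec
        if (ea$reactions[[drop]] > 1L) {
          spec2$plan[[1]][[p]]$reactions[[drop]] <- ea$reactions[[drop]] - 1L
        } else {
          spec2$plan[[1]][[p]]$reactions <-
            ea$reactions[names(ea$reactions) != drop]
        }
        before <- fixture_oracle(spec, "multiset")
        after <- fixture_oracle(spec2, "multiset")
        i <- match(p, before$rows$pathway)
        expect_lte(after$rows$sim_p[i], before$rows$sim_p[i] + 1e-12)
      }
    }
  }
})
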