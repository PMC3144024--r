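test_that("the pairwise systems decide the Irev/Irev cases", {
  net <- fixture_network("CHAIN3")
  cls <- classify_reactions(net)
  # chain: R1 cannot run without R2
  expect_false(is_feasible(build_P1(net, cls, 1L, 2L)))
  # branch: either export can run without the other
  br <- fixture_network("BRANCH")
  cls_br <- classify_reactions(br)
  expect_true(is_feasible(build_P1(br, cls_br, 2L, 3L)))
  expect_true(is_feasible(build_P2(br, cls_br, 2L, 3L)))
  # chain ends: mutually coupled
  expect_false(is_feasible(build_P1(net, cls, 1L, 3L)))
  expect_false(is_feasible(build_P2(net, cls, 1L, 3L)))
})

test_that("(P4) decides Prev/Prev and Frev/Frev pairs with one system", {
  rp <- fixture_network("REVPAIR")
  cls <- classify_reactions(rp)
  expect_false(is_feasible(build_P4(rp, cls, 1L, 2L)))   # fully coupled

  # two reversible 2-cycles in disconnected blocks: independent, so feasible
  two <- metabolic_network(
    rbind(cbind(rp$stoich, matrix(0, 2, 2)),
          cbind(matrix(0, 2, 2), rp$stoich)),
    rep(TRUE, 4), c("A", "B", "C", "D"), c("R1", "R2", "R3", "R4"))
  cls2 <- classify_reactions(two)
  expect_true(is_feasible(build_P4(two, cls2, 1L, 3L)))

  # preconditions are contracts
  expect_error(build_P4(rp, cls, 1L, 1L), "distinct")
  expect_error(build_P3(rp, cls, 1L, 2L))
})

test_that("full vs partial resolution computes the flux ratio", {
  co <- fixture_network("COEF2")
  cls <- classify_reactions(co)
  r <- resolve_full_vs_partial(co, cls, 2L, 3L)
  expect_identical(r$relation, "full")
  expect_equal(r$ratio, 2)   # balance of B gives v_R3 = 2 v_R2

  vy <- variable_yield_net()
  cls_vy <- classify_reactions(vy)
  r2 <- resolve_full_vs_partial(vy, cls_vy, 1L, 4L)
  expect_identical(r2$relation, "partial")   # yield varies between routes
})

test_that("type dispatch prunes inadmissible combinations without LPs", {
  net <- mixed_type_net()   # has Irev, Prev and Frev reactions
  cls <- classify_reactions(net)
  expect_identical(ffca:::rt_of(cls, 2L), "prev")
  expect_identical(ffca:::rt_of(cls, 6L), "frev")
  lp_calls_reset()
  expect_identical(couple_pair(net, cls, 2L, 6L)$relation, "uncoupled")
  expect_identical(couple_pair(net, cls, 1L, 6L)$relation, "uncoupled")
  expect_identical(lp_calls(), integer())   # zero LP calls for pruned pairs
})

test_that("Irev/Prev pairs resolve to prev -> irev or uncoupled", {
  net <- fixture_network("PREVNET")
  cls <- classify_reactions(net)
  # R2 (prev) against every irreversible reaction: P2/P3 logic
  for (a in c(1L, 3L, 4L, 5L)) {
    rel <- couple_pair(net, cls, min(a, 2L), max(a, 2L))
    expect_true(rel$relation %in% c("uncoupled", "dir_1_to_2", "dir_2_to_1"))
  }
  # in PREVNET each side of R2 has an alternative route, so all uncoupled
  fc <- flux_coupling(net)
  expect_true(all(tidy(fc)$relation == "uncoupled"))
})

test_that("fixture truths hold end to end", {
  fc <- flux_coupling(fixture_network("CHAIN3"))
  td <- tidy(fc)
  expect_true(all(td$relation == "full"))
  expect_equal(td$ratio, c(1, 1, 1))

  fb <- tidy(flux_coupling(fixture_network("BRANCH")))
  expect_identical(fb$relation[fb$rxn_i == "R1" & fb$rxn_j == "R2"], "dir_2_to_1")
  expect_identical(fb$relation[fb$rxn_i == "R1" & fb$rxn_j == "R3"], "dir_2_to_1")
  expect_identical(fb$relation[fb$rxn_i == "R2" & fb$rxn_j == "R3"], "uncoupled")

  fr <- flux_coupling(fixture_network("REVPAIR"))
  expect_identical(fr$classification$frev, 1:2)
  expect_identical(tidy(fr)$relation, "full")
  expect_equal(tidy(fr)$ratio, 1)

  fco <- tidy(flux_coupling(fixture_network("COEF2")))
  expect_equal(fco$ratio[fco$rxn_i == "R2" & fco$rxn_j == "R3"], 2)
})

test_that("flipped reactions report ratios in original coordinates", {
  # R2 written backwards (B -> A): flux must be negative, ratio to R1 is -1
  flip <- metabolic_network(cbind(c(1, 0), c(1, -1), c(0, -1)),
                            c(FALSE, TRUE, FALSE), c("A", "B"),
                            c("R1", "R2", "R3"))
  fc <- flux_coupling(flip)
  oc <- oracle_coupling(flip)
  expect_same_coupling(fc, oc)
  td <- tidy(fc)
  expect_equal(td$ratio[td$rxn_i == "R1" & td$rxn_j == "R2"], -1)
})

test_that("coupling codes survive positive column scaling, ratios rescale", {
  set.seed(31)
  for (net in small_suite(8)) {
    fc <- flux_coupling(net)
    j <- sample.int(ncol(net$stoich), 1)
    cc <- 2.5
    scaled <- net
    scaled$stoich[, j] <- scaled$stoich[, j] * cc
    fs <- flux_coupling(scaled)
    expect_identical(tidy(fc)$relation, tidy(fs)$relation)
    a <- tidy(fc); b <- tidy(fs)
    full <- which(a$relation == "full")
    for (p in full) {
      expected <- a$ratio[[p]]
      # v_col = k v_i: scaling column j divides its flux by c
      if (a$j[[p]] == j) expected <- expected / cc
      if (a$i[[p]] == j) expected <- expected * cc
      expect_equal(b$ratio[[p]], expected, tolerance = 1e-6)
    }
  }
})

test_that("results are equivariant under reaction permutation", {
  set.seed(17)
  for (net in small_suite(6)) {
    n <- ncol(net$stoich)
    perm <- sample.int(n)
    pnet <- metabolic_network(net$stoich[, perm, drop = FALSE],
                              net$reversible[perm], net$metabolite_ids,
                              net$reaction_ids[perm])
    a <- flux_coupling(net); b <- flux_coupling(pnet)
    # compare relations by reaction-id pairs, orientation-normalized
    canon <- function(td) {
      key <- ifelse(td$rxn_i < td$rxn_j,
                    paste(td$rxn_i, td$rxn_j),
                    paste(td$rxn_j, td$rxn_i))
      rel <- ifelse(td$rxn_i < td$rxn_j, td$relation,
                    ifelse(td$relation == "dir_1_to_2", "dir_2_to_1",
                           ifelse(td$relation == "dir_2_to_1", "dir_1_to_2",
                                  td$relation)))
      ratio <- ifelse(td$rxn_i < td$rxn_j, td$ratio, 1 / td$ratio)
      o <- order(key)
      list(key = key[o], rel = rel[o], ratio = ratio[o])
    }
    ca <- canon(tidy(a)); cb <- canon(tidy(b))
    expect_identical(ca$key, cb$key)
    expect_identical(ca$rel, cb$rel)
    expect_equal(ca$ratio, cb$ratio, tolerance = 1e-6)
  }
})

test_that("structural invariants hold on fixtures and random networks", {
  for (name in c("CHAIN3", "BRANCH", "REVPAIR", "PREVNET", "DIAMOND", "COEF2"))
    check_coupling_invariants(flux_coupling(fixture_network(name)))
  check_coupling_invariants(flux_coupling(variable_yield_net()))
  check_coupling_invariants(flux_coupling(mixed_type_net()))
  for (net in small_suite(10))
    check_coupling_invariants(flux_coupling(net))
})
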