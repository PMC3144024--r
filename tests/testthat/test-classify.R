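test_that("blocked detection matches the cone's definition", {
  expect_identical(find_blocked(fixture_network("CHAIN3")), integer())

  # deleting the chain's export blocks the entire pathway: B cannot be
  # balanced
  cut <- metabolic_network(fixture_network("CHAIN3")$stoich[, 1:2],
                           c(FALSE, FALSE), c("A", "B"), c("R1", "R2"))
  expect_identical(find_blocked(cut), 1:2)

  # an all-zero column is unblocked (any value satisfies S v = 0)
  z <- metabolic_network(cbind(fixture_network("CHAIN3")$stoich, 0),
                         rep(FALSE, 4), c("A", "B"),
                         c("R1", "R2", "R3", "Rz"))
  expect_identical(find_blocked(z), integer())
})

test_that("reversibility typing separates Irev, Prev and Frev", {
  cls_rev <- classify_reactions(fixture_network("REVPAIR"))
  expect_identical(cls_rev$frev, 1:2)   # lineality space is span{(1,1)}

  cls_prev <- classify_reactions(fixture_network("PREVNET"))
  expect_identical(cls_prev$prev, 2L)   # both signs feasible, zero on lineality
  expect_identical(sort(cls_prev$irev), c(1L, 3L, 4L, 5L))

  # CHAIN3 with R2 declared reversible: still only forward-feasible
  net <- fixture_network("CHAIN3")
  net$reversible[2] <- TRUE
  cls <- classify_reactions(net)
  expect_true(2L %in% cls$irev)
  expect_false(2L %in% cls$flipped)

  # a reaction written against its only feasible direction gets flipped
  flip <- metabolic_network(cbind(c(1, 0), c(1, -1), c(0, -1)),
                            c(FALSE, TRUE, FALSE), c("A", "B"),
                            c("R1", "R2", "R3"))  # R2 written B -> A
  clsf <- classify_reactions(flip)
  expect_true(2L %in% clsf$irev)
  expect_identical(clsf$flipped, 2L)
})

test_that("an all-zero column is Frev when reversible, Irev otherwise", {
  base <- fixture_network("CHAIN3")$stoich
  z_rev <- metabolic_network(cbind(base, 0), c(FALSE, FALSE, FALSE, TRUE),
                             c("A", "B"), c("R1", "R2", "R3", "Rz"))
  expect_identical(classify_reactions(z_rev)$frev, 4L)
  z_irr <- metabolic_network(cbind(base, 0), rep(FALSE, 4),
                             c("A", "B"), c("R1", "R2", "R3", "Rz"))
  expect_true(4L %in% classify_reactions(z_irr)$irev)
})

test_that("classification is idempotent on the sign-normalized network", {
  for (net in small_suite(15)) {
    cls <- classify_reactions(net)
    nn <- ffca:::normalized_network(net, cls)
    cls2 <- classify_reactions(nn)
    expect_same_classification(cls, cls2)
    expect_identical(cls2$flipped, integer())
  }
})

test_that("the Frev lineality test is sign-symmetric", {
  for (net in small_suite(10)) {
    cls <- classify_reactions(net)
    irr <- which(!net$reversible)
    for (i in cls$frev) {
      pins <- stats::setNames(rep(0, length(irr)), irr)
      pins[as.character(i)] <- -1
      expect_true(is_feasible(feasibility_system(net$stoich, pinned = pins)))
    }
  }
})

test_that("deleting a blocked column leaves every other class unchanged", {
  found <- 0L
  for (net in small_suite(25)) {
    cls <- classify_reactions(net)
    if (length(cls$blocked) == 0L) next
    found <- found + 1L
    b <- cls$blocked[[1L]]
    keep <- setdiff(seq_len(ncol(net$stoich)), b)
    sub <- metabolic_network(net$stoich[, keep, drop = FALSE],
                             net$reversible[keep],
                             net$metabolite_ids, net$reaction_ids[keep])
    cls_sub <- classify_reactions(sub)
    remap <- function(v) match(setdiff(v, b), keep)
    expect_identical(sort(cls_sub$blocked), sort(remap(cls$blocked)))
    expect_identical(sort(cls_sub$irev), sort(remap(cls$irev)))
    expect_identical(sort(cls_sub$prev), sort(remap(cls$prev)))
    expect_identical(sort(cls_sub$frev), sort(remap(cls$frev)))
  }
  expect_gt(found, 0L)   # the property was actually exercised
})
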