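# Reconfiguration metrics: hand example, identities, brute-force oracle.

hand_example <- function() {
  # layer1 (A,B | C,D); layer2 all merged into C,D's community;
  # layer3 C departs alone
  lab <- cbind(c(1L, 1L, 2L, 2L),
               c(2L, 2L, 2L, 2L),
               c(2L, 2L, 3L, 2L))
  attr(lab, "aligned") <- TRUE
  partition_sequence(lab, node_labels = c("A", "B", "C", "D"))
}

test_that("hand example: transitions, node metrics, cohesion, community
           metrics", {
  P <- hand_example()
  ct <- classify_transitions(P)
  expect_identical(ct$used, 1:2)
  r1 <- ct$records[[1]]
  expect_identical(sort(r1$moved), 1:2)         # A and B move together
  expect_identical(r1$partners[[1]], 2L)        # A's partner is B
  expect_identical(r1$partners[[2]], 1L)
  r2 <- ct$records[[2]]
  expect_identical(r2$moved, 3L)                # C moves alone
  expect_length(r2$partners[[1]], 0L)

  nm <- node_metrics(P)
  expect_equal(nm$flexibility, c(0.5, 0.5, 0.5, 0))
  expect_equal(nm$disjointedness, c(0, 0, 0.5, 0))
  expect_equal(nm$cohesive_fraction, c(0.5, 0.5, 0, 0))

  ch <- cohesion(P)
  expect_identical(ch$counts[1, 2], 1L)
  expect_identical(sum(ch$counts), 2L)          # only the AB pair, twice
  expect_equal(unname(ch$strength), c(0.5, 0.5, 0, 0))

  cm <- community_metrics(P)
  expect_equal(unname(cm["community_cohesion"]), 0.25)
  expect_equal(unname(cm["community_disjointedness"]), 0.125)
  expect_equal(unname(cm["community_change"]), 0.375)
})

test_that("constant partitions yield all-zero metrics", {
  lab <- matrix(rep(c(1L, 1L, 2L), 4), 3, 4)
  attr(lab, "aligned") <- TRUE
  P <- partition_sequence(lab)
  ct <- classify_transitions(P)
  expect_true(all(vapply(ct$records, function(r) length(r$moved), 0L) == 0L))
  nm <- node_metrics(P)
  expect_true(all(nm$flexibility == 0))
  expect_true(all(cohesion(P)$counts == 0L))
})

test_that("metrics match the brute-force oracle exactly on 100 random
           sequences", {
  set.seed(60)
  for (r in 1:100) {
    N <- sample(4:10, 1)
    L <- sample(4:12, 1)
    P <- random_partition_sequence(N, L)
    nm <- node_metrics(P)
    ch <- cohesion(P)
    or <- oracle_reconfig(P$labels)
    expect_equal(nm$flexibility, or$flexibility, tolerance = 1e-12)
    expect_identical(nm$disjointedness, or$disjointedness)
    expect_identical(nm$cohesive_fraction, or$cohesive_fraction)
    expect_identical(unname(ch$counts), or$counts)
    expect_identical(unname(ch$strength), or$strength)
    # additive identity is exact by construction
    expect_identical(nm$flexibility,
                     nm$cohesive_fraction + nm$disjointedness)
    expect_true(all(nm$disjointedness <= nm$flexibility))
    expect_true(all(nm$flexibility <= 1))
    expect_true(all(ch$strength <= (N - 1) * nm$flexibility + 1e-12))
    cm <- community_metrics(P)
    expect_equal(unname(cm["community_change"]),
                 unname(cm["community_cohesion"] +
                          cm["community_disjointedness"]))
  }
})

test_that("metrics are invariant to a global relabeling of communities", {
  set.seed(61)
  P <- random_partition_sequence(8, 10)
  perm <- sample(10)
  lab2 <- matrix(perm[P$labels], nrow(P$labels), ncol(P$labels))
  attr(lab2, "aligned") <- TRUE
  P2 <- partition_sequence(lab2)
  expect_equal(node_metrics(P2)[-1], node_metrics(P)[-1])
  expect_identical(unname(cohesion(P2)$counts), unname(cohesion(P)$counts))
})

test_that("k nodes always moving together have strength k - 1", {
  # 4 nodes cycle through fresh communities at every transition
  L <- 6
  lab <- rbind(matrix(rep(1:L, each = 4), 4, L) + 1L,
               matrix(1L, 2, L))
  attr(lab, "aligned") <- TRUE
  P <- partition_sequence(lab)
  s <- cohesion(P)$strength
  expect_equal(unname(s), c(rep(3, 4), 0, 0))
})

test_that("an extra solo move raises d and f but not cohesion counts", {
  base <- cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L))
  mod <- base
  mod[1, 3] <- 3L # node 1 departs alone at transition 2
  attr(base, "aligned") <- TRUE
  attr(mod, "aligned") <- TRUE
  Pb <- partition_sequence(base); Pm <- partition_sequence(mod)
  nb <- node_metrics(Pb); nmod <- node_metrics(Pm)
  expect_gt(nmod$disjointedness[1], nb$disjointedness[1])
  expect_gt(nmod$flexibility[1], nb$flexibility[1])
  expect_identical(sum(cohesion(Pm)$counts), sum(cohesion(Pb)$counts))
})

test_that("invalid layers are skipped and rates renormalize by used
           transitions", {
  lab <- cbind(c(1L, 2L), c(2L, 2L), c(2L, 2L), c(1L, 2L))
  attr(lab, "aligned") <- TRUE
  # layer 2 invalid: only transition 3 (layers 3 -> 4) is usable
  P <- partition_sequence(lab, layer_valid = c(TRUE, FALSE, TRUE, TRUE))
  ct <- classify_transitions(P)
  expect_identical(ct$used, 3L)
  nm <- node_metrics(P)
  expect_equal(nm$flexibility, c(1, 0)) # one move in one used transition
  or <- oracle_reconfig(P$labels, P$layer_valid)
  expect_equal(nm$flexibility, or$flexibility, tolerance = 1e-12)

  # no usable transitions -> error
  P0 <- partition_sequence(lab, layer_valid = c(TRUE, FALSE, TRUE, FALSE))
  expect_error(node_metrics(P0), "usable transitions|undefined")
  # unaligned input -> error
  expect_error(classify_transitions(partition_sequence(unclass(lab[, ]))),
               "aligned")
})
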