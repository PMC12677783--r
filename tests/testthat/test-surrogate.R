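# Surrogate nulls and layer validation.

test_that("surrogates preserve binary degrees and the weight multiset", {
  set.seed(30)
  W <- random_weighted_graph(12, p = 0.4)
  surr <- surrogate_null(W, n_surrogates = 20, seed = 1)
  deg <- rowSums(W != 0)
  wts <- sort(W[upper.tri(W) & W != 0])
  for (S in surr) {
    expect_equal(unname(rowSums(S != 0)), unname(deg))
    expect_equal(sort(S[upper.tri(S) & S != 0]), wts)
    expect_equal(S, t(S))
    expect_true(all(diag(S) == 0))
  }
  # surrogates actually differ from the original
  expect_gt(max(vapply(surr, function(S) max(abs(S - W)), 0)), 0)
  expect_error(surrogate_null(diag(0, 4)), "too few edges")
})

test_that("observed modularity of a random graph sits inside the surrogate
           distribution", {
  set.seed(31)
  inside <- 0
  for (r in 1:20) {
    W <- matrix(0, 19, 19)
    iu <- upper.tri(W)
    w <- runif(sum(iu)) * (runif(sum(iu)) < 0.5)
    W[iu] <- w; W <- W + t(W)
    q_obs <- modularity(W, louvain_partition(W, seed = r))
    qs <- netreconfig:::surrogate_q(W, n_surrogates = 100, seed = r)
    lo <- quantile(qs, 0.025); hi <- quantile(qs, 0.975)
    if (q_obs >= lo && q_obs <= hi) inside <- inside + 1
  }
  expect_gte(inside, 18) # >= 90% of 20 seeded instances
})

test_that("validate_layers flags planted structure and rejects noise", {
  set.seed(32)
  mk_planted <- function() {
    W <- matrix(runif(19 * 19) * 0.2, 19, 19)
    W[1:9, 1:9] <- W[1:9, 1:9] + 0.6
    W[10:19, 10:19] <- W[10:19, 10:19] + 0.6
    W[lower.tri(W)] <- t(W)[lower.tri(W)]; diag(W) <- 0
    W
  }
  mk_null <- function() {
    W <- matrix(runif(19 * 19) * 0.8, 19, 19)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]; diag(W) <- 0
    W
  }
  layers <- c(lapply(1:5, function(i) mk_planted()),
              lapply(1:5, function(i) mk_null()))
  parts <- lapply(layers, louvain_partition, seed = 3)
  v <- validate_layers(layers, parts, n_surrogates = 100, seed = 4)
  expect_true(all(v[1:5]))          # planted layers retained
  expect_lte(sum(v[6:10]), 1)       # random layers rejected

  # empirical estimator follows the +1-corrected exceedance formula
  v_emp <- validate_layers(layers[1:2], parts[1:2], n_surrogates = 50,
                           seed = 5, method = "empirical")
  p <- attr(v_emp, "p")
  expect_true(all(p >= 1 / 51 & p <= 1))
  expect_identical(as.logical(v_emp), as.logical(p < 0.05 / 2))
})

test_that("validity flags are monotone in alpha", {
  set.seed(33)
  layers <- lapply(1:4, function(i) random_weighted_graph(10, p = 0.7))
  parts <- lapply(layers, louvain_partition, seed = 1)
  v_small <- validate_layers(layers, parts, alpha = 0.01,
                             n_surrogates = 50, seed = 2)
  v_big <- validate_layers(layers, parts, alpha = 0.5,
                           n_surrogates = 50, seed = 2)
  expect_true(all(v_big[v_small])) # anything valid at 0.01 is valid at 0.5
})
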