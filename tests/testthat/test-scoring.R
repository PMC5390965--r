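test_that("canonical form relabels by first occurrence and is idempotent", {
  expect_equal(canonical_form("221212", 3), "001010")
  expect_equal(canonical_form("001010", 3), "001010")
  expect_equal(canonical_form(c(5, 5, 2, 5), 6), c(0, 0, 1, 0))
  expect_error(canonical_form("0127", 3), "position 4")
  expect_error(canonical_form(c(0, 1, 9), 6), "position 3")
})

test_that("binary strings of length 3 collapse to 4 canonical classes", {
  all3 <- expand.grid(0:1, 0:1, 0:1)
  keys <- apply(all3, 1, function(r) canonical_form(paste0(r, collapse = ""), 2))
  expect_equal(length(unique(keys)), 4)
})

test_that("weighted class moments equal direct enumeration over the full space", {
  tab <- tt_table("tm3_2")
  spec <- rig_task("coin")
  spec$length <- 3L
  spec$block <- 3L
  mom <- string_space_moments(spec, tab)
  # direct oracle: all 8 strings of length 3
  all3 <- apply(expand.grid(0:1, 0:1, 0:1), 1, paste0, collapse = "")
  K <- ctm_lookup(tab, all3)$K
  expect_equal(mom$mu, mean(K), tolerance = 1e-12)
  expect_equal(mom$sigma, sqrt(mean((K - mean(K))^2)), tolerance = 1e-12)
  # and for a 3-symbol alphabet, length 4, blocks of 2
  spec$alphabet_size <- 3L
  spec$length <- 4L
  spec$block <- 2L
  mom3 <- string_space_moments(spec, tab)
  all4 <- apply(expand.grid(0:2, 0:2, 0:2, 0:2), 1, paste0, collapse = "")
  sc <- rigcomplexity:::score_keys(
    rigcomplexity:::cpp_canonicalize(all4), spec, tab)
  expect_equal(mom3$mu, mean(sc$K), tolerance = 1e-12)
  expect_equal(mom3$sigma, sqrt(mean((sc$K - mean(sc$K))^2)),
               tolerance = 1e-12)
})

test_that("canonical classes of 10 draws from 9 symbols count the set partitions", {
  rg <- rigcomplexity:::cpp_rgs(10L, 9L)
  # independent oracle: Stirling numbers of the second kind by recurrence
  S <- matrix(0, 11, 11)
  S[1, 1] <- 1
  for (n in 1:10) for (k in 1:n)
    S[n + 1, k + 1] <- S[n, k] + k * S[n, k + 1]
  expect_equal(length(rg$key), sum(S[11, 2:10]))
  # class weights add up to the full string space
  w <- exp(lfactorial(9) - lfactorial(9 - rg$n_distinct))
  expect_equal(sum(w), 9^10)
})

test_that("a constant-complexity table is rejected as degenerate", {
  tab <- tt_table("tm3_2")
  tab$K[] <- 5
  tab$fallback <- 5
  spec <- rig_task("coin")
  spec$block <- 12L  # single block: no multiplicity term to break the tie
  expect_error(string_space_moments(spec, tab), "sigma = 0")
})

test_that("scores are invariant under relabelling and carry the z identity", {
  tabs <- tt_tables_small()
  spec <- rig_task("die")
  tab <- tabs$tm2_6
  r1 <- c(0, 3, 2, 5, 1, 0, 4, 2, 3, 5)
  perm <- c(3, 5, 0, 2, 4, 1)
  r2 <- perm[r1 + 1]
  s1 <- score_response(r1, spec, tab)
  s2 <- score_response(r2, spec, tab)
  expect_identical(s1$z, s2$z)
  expect_identical(s1, score_response(r1, spec, tab))  # pure function
})

test_that("score_response validates shape and length", {
  tabs <- tt_tables_small()
  expect_error(score_response(c(0, 1), rig_task("coin"), tabs$tm4_2),
               "expected 12")
  expect_error(score_response(integer(0), rig_task("coin"), tabs$tm4_2),
               "empty")
  expect_error(score_response(matrix(0L, 2, 2), rig_task("grid"),
                              tabs$tm4_2), "shape")
  g <- score_response(matrix(0L, 3, 3), rig_task("grid"), tabs$tm4_2)
  expect_true(is.finite(g$z))
})

test_that("mean complexity averages available tasks and propagates missingness", {
  scores <- data.frame(
    participant_id = rep(c("a", "b", "c"), times = c(5, 4, 2)),
    z = c(rep(0.5, 5), 1, -1, 0, 0, NA, NA))
  m <- mean_complexity(scores)
  expect_equal(m$mean_z, c(0.5, 0, NA_real_))
  expect_equal(m$n_tasks, c(5L, 4L, 0L))
})

test_that("first-order entropy matches hand-computed values", {
  expect_equal(first_order_entropy("000000000000"), 0)
  expect_equal(first_order_entropy("010101010101"), 1)
  # counts (2,2,2,2,1,1)/10
  p <- c(.2, .2, .2, .2, .1, .1)
  expect_equal(first_order_entropy("0123450123", 6), -sum(p * log2(p)),
               tolerance = 1e-12)
  expect_error(first_order_entropy(""), "empty")
})

test_that("maximal entropy does not imply high algorithmic complexity", {
  tab <- tt_table("tm3_2")
  spec <- rig_task("coin")
  spec$table_id <- "tm3_2"
  alt <- "010101010101"
  expect_equal(first_order_entropy(alt), 1)  # maximal for binary
  wz <- tt_weighted_z(spec, tab)
  z_alt <- (rigcomplexity:::score_keys(alt, spec, tab)$K -
              string_space_moments(spec, tab)$mu) /
    string_space_moments(spec, tab)$sigma
  # weighted median over the full string space
  o <- order(wz$z)
  med <- wz$z[o][which(cumsum(wz$w[o]) >= sum(wz$w) / 2)[1]]
  expect_lt(z_alt, med)
})
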