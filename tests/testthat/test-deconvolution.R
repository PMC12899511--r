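# template abundances resembling a mid-sized oligonucleotide envelope
toy_d3 <- function() {
  d <- cbind(dnorm(1:7, 3.2, 1.6), dnorm(1:7, 3.0, 1.5), dnorm(1:7, 2.8, 1.4))
  sweep(d, 2, colSums(d) / 0.98, "/")
}

test_that("model matrix reproduces the shifted zero pattern", {
  ps <- toy_pattern_set(toy_d3(), deltas = c(2, 2))
  mm <- build_model_matrix(ps, 1:7)
  # p = 3, deltas (2, 2): column 2 zero in rows 1-2, column 3 in rows 1-4
  expect_equal(ps$omegas, c(2L, 4L))
  expect_equal(mm$t[1:2, 2], c(0, 0))
  expect_equal(mm$t[1:4, 3], rep(0, 4))
  expect_true(all(mm$t[3:7, 2] > 0))
  expect_true(all(mm$t[5:7, 3] > 0))
  # entries are the renormalised template columns shifted down
  d <- toy_d3()
  expect_equal(mm$t[, 1], d[, 1] / sum(d[, 1]))
  expect_equal(mm$t[3:7, 2], d[1:5, 2] / sum(d[1:5, 2]))
  expect_equal(mm$t[5:7, 3], d[1:3, 3] / sum(d[1:3, 3]))
  expect_equal(colSums(mm$t), c(A = 1, B = 1, C = 1), tolerance = 1e-14)
})

test_that("dropping a matched row renormalises the remaining columns", {
  ps <- toy_pattern_set(toy_d3(), deltas = c(2, 2))
  mm <- build_model_matrix(ps, c(1, 2, 4, 5, 6, 7))
  expect_equal(dim(mm$t), c(6L, 3L))
  expect_equal(unname(colSums(mm$t)), rep(1, 3), tolerance = 1e-14)
  d <- toy_d3()
  keep <- c(1, 2, 4, 5, 6, 7)
  col2 <- ifelse(keep > 2, d[pmax(keep - 2, 1), 2], 0)
  col2[keep <= 2] <- 0
  expect_equal(mm$t[, 2], col2 / sum(col2))
  # single component: one normalised column
  ps1 <- toy_pattern_set(toy_d3()[, 1, drop = FALSE], integer(0))
  mm1 <- build_model_matrix(ps1, c(2, 3, 5))
  expect_equal(mm1$t[, 1], toy_d3()[c(2, 3, 5), 1] /
                 sum(toy_d3()[c(2, 3, 5), 1]))
  expect_error(build_model_matrix(ps1, integer(0)), "non-empty")
  expect_error(build_model_matrix(ps1, c(3, 2)), "strictly increasing")
})

test_that("a component invisible on the matched rows is flagged", {
  ps <- toy_pattern_set(toy_d3(), deltas = c(2, 2))
  mm <- build_model_matrix(ps, 1:4)   # component C starts at row 5
  expect_equal(mm$unobservable, "C")
  env <- toy_envelope(rep(0.25, 4), iso_idx = 1:4)
  fit <- fit_scan(env, ps)
  expect_equal(fit$status, "skipped_underdetermined")
  expect_null(fit$coeffs)
})

test_that("noiseless mixtures are recovered exactly", {
  ps <- toy_pattern_set(toy_d3(), deltas = c(2, 2))
  mm <- build_model_matrix(ps, 1:7)
  o <- as.vector(mm$t %*% c(0.2, 0.3, 0.5))
  fit <- fit_scan(toy_envelope(o), ps)
  expect_equal(fit$status, "fitted")
  expect_equal(unname(fit$coeffs), c(0.2, 0.3, 0.5), tolerance = 1e-8)
  expect_lt(fit$rss, 1e-20)
  expect_equal(fit$theta, log(c(0.2, 0.3, 0.5)), tolerance = 1e-7)
  expect_length(fit$residuals, 7)
})

test_that("pure-component envelopes match the NNLS boundary solution", {
  ps <- toy_pattern_set(toy_d3()[, 1:2], deltas = 2)
  mm <- build_model_matrix(ps, 1:7)
  o <- mm$t[, 1]
  fit <- fit_scan(toy_envelope(o), ps)
  nn <- pracma::lsqnonneg(mm$t, o)
  expect_equal(nn$x[2], 0)
  expect_lt(unname(fit$coeffs[2]), 1e-4)
  expect_equal(unname(fit$coeffs[1]), 1, tolerance = 1e-6)
  rss_nnls <- sum((o - mm$t %*% nn$x)^2)
  expect_lt(abs(fit$rss - rss_nnls), 1e-8)
})

test_that("the exponential fit agrees with NNLS across random instances", {
  set.seed(2024)
  n_interior <- 0
  for (rep in 1:120) {
    p <- sample(2:3, 1)
    nt <- sample((p + 3):25, 1)
    deltas <- sample(1:3, p - 1, replace = TRUE)
    if (max(cumsum(c(0, deltas))) + 2 > nt) next
    d <- sapply(seq_len(p), function(i)
      dnorm(seq_len(nt), runif(1, 2, nt / 2 + 2), runif(1, 1.2, 3)))
    d <- sweep(d, 2, colSums(d), "/") * runif(1, 0.95, 1)
    ps <- toy_pattern_set(d, deltas = deltas)
    keep <- sort(sample(seq_len(nt), max(p + 2, nt - sample(0:3, 1))))
    mm <- build_model_matrix(ps, keep)
    if (length(mm$unobservable)) next
    truth <- runif(p)
    o <- as.vector(mm$t %*% truth) + abs(rnorm(length(keep), 0, 0.02))
    o <- o / sum(o)
    fit <- fit_scan(toy_envelope(o, iso_idx = keep), ps)
    nn <- pracma::lsqnonneg(mm$t, o)
    rss_nnls <- sum((o - mm$t %*% nn$x)^2)
    if (all(nn$x > 1e-8)) {
      n_interior <- n_interior + 1
      expect_equal(unname(fit$coeffs), nn$x, tolerance = 1e-6)
    } else {
      expect_lt(max(unname(fit$coeffs)[nn$x <= 1e-8]), 1e-4)
    }
    expect_lt(abs(fit$rss - rss_nnls), 1e-8)
  }
  expect_gt(n_interior, 50)
})

test_that("recovery is exact over many random noiseless mixtures", {
  set.seed(99)
  worst <- 0
  for (rep in 1:100) {
    d <- sapply(1:2, function(i)
      dnorm(1:15, runif(1, 3, 8), runif(1, 1.5, 3)))
    d <- sweep(d, 2, colSums(d), "/")
    ps <- toy_pattern_set(d, deltas = sample(1:4, 1))
    mm <- build_model_matrix(ps, 1:15)
    truth <- runif(2, 0.05, 1)
    truth <- truth / sum(truth)
    o <- as.vector(mm$t %*% truth)
    fit <- fit_scan(toy_envelope(o), ps)
    worst <- max(worst, max(abs(unname(fit$coeffs) - truth)))
  }
  expect_lt(worst, 1e-6)
})

test_that("coefficients are scale-equivariant and deterministic", {
  ps <- two_component_patterns()
  w <- build_windows(ps, 10)
  sim <- two_component_sim(0.35, seed = 5, noise = "gaussian")
  scan <- sim$run$scans[[60]]
  env1 <- match_scan(scan, w)
  scan_k <- dicquant:::new_scan(scan$rt, scan$mz, scan$intensity * 7.5)
  env2 <- match_scan(scan_k, w)
  f1 <- fit_scan(env1, ps)
  f2 <- fit_scan(env2, ps)
  expect_equal(f2$tic, 7.5 * f1$tic, tolerance = 1e-12)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)  # O_j is normalised
  # determinism: same inputs, bitwise identical estimates
  f3 <- fit_scan(env1, ps)
  expect_identical(f1$theta, f3$theta)
  # fitted total stays near one when the envelope is well explained
  expect_lt(abs(sum(f1$coeffs) - 1), sum(abs(f1$residuals)) + 1e-12)
})

test_that("fit_run yields one status-bearing fit per scan", {
  ps <- two_component_patterns()
  sim <- two_component_sim(0.25, seed = 2)
  fits <- fit_run(sim$run, ps, ppm = 10)
  expect_length(fits, sim$run$n_scans)
  expect_equal(vapply(fits, `[[`, numeric(1), "rt"), scan_rts(sim$run))
  s <- attr(fits, "summary")
  expect_equal(sum(s), sim$run$n_scans)
  expect_equal(unname(s[["fitted"]]), sim$run$n_scans)
  df <- as.data.frame(fits)
  expect_equal(nrow(df), sim$run$n_scans)
  expect_true(all(c("rt", "tic", "status", "rss", "coef_impurity",
                    "coef_FLP") %in% names(df)))
  # empty scans are skipped, not errors
  empty <- new_lcms_run_for_test(rt = c(1, 2),
                                 mz = list(numeric(0), numeric(0)),
                                 intensity = list(numeric(0), numeric(0)))
  fits0 <- fit_run(empty, ps, ppm = 10)
  expect_equal(vapply(fits0, `[[`, character(1), "status"),
               rep("skipped_empty", 2))
})

test_that("per-scan coefficient ratios track the generator ground truth", {
  ps <- two_component_patterns()
  sim <- two_component_sim(0.3, seed = 8)
  fits <- fit_run(sim$run, ps, ppm = 10)
  truth <- sim$truth$per_scan
  # compare on scans with meaningful signal from both components
  strong <- which(apply(truth, 1, min) > 1e-3 * max(truth))
  for (j in strong) {
    est_ratio <- fits[[j]]$coeffs[["impurity"]] / fits[[j]]$coeffs[["FLP"]]
    true_ratio <- unname(truth[j, "impurity"] / truth[j, "FLP"])
    expect_equal(est_ratio, true_ratio, tolerance = 0.02)
  }
})
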