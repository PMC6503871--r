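toy_matrix <- function(values, n_probes = 1) {
  m <- matrix(values, ncol = n_probes)
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))),
                      paste0("cg", seq_len(n_probes)))
  m
}

test_that("fences match the hand-computed type-7 quantiles", {
  m <- toy_matrix(seq(0.1, 0.9, by = 0.1))
  f <- compute_fences(m)
  expect_equal(f$q1, 0.3)
  expect_equal(f$q3, 0.7)
  expect_equal(f$iqr, 0.4)
  expect_equal(f$lower, -0.9)
  expect_equal(f$upper, 1.9)
  # fences are outside [0,1], so no beta value can be a SEM here
  expect_equal(sum(call_sems(m, f)$sem_mask), 0L)
})

test_that("degenerate constant probes collapse the fences without calls", {
  m <- toy_matrix(rep(0.5, 10))
  f <- compute_fences(m)
  expect_equal(f$lower, 0.5)
  expect_equal(f$upper, 0.5)
  expect_equal(call_sems(m, f)$burden, c(s1 = 0L, s2 = 0L, s3 = 0L, s4 = 0L,
                                         s5 = 0L, s6 = 0L, s7 = 0L, s8 = 0L,
                                         s9 = 0L, s10 = 0L),
               ignore_attr = FALSE)
})

test_that("fences are invariant to sample order", {
  set.seed(1)
  m <- toy_matrix(runif(200), n_probes = 10)
  f1 <- compute_fences(m)
  perm <- sample(nrow(m))
  f2 <- compute_fences(m[perm, ])
  expect_equal(f1, f2)
})

test_that("vectorized caller equals the naive two-loop oracle", {
  set.seed(7)
  m <- toy_matrix(runif(50 * 40), n_probes = 40)
  m[sample(length(m), 30)] <- NA
  res <- call_sems(m, min_samples = 8)
  expect_identical(res$sem_mask, naive_sem_mask(m))
  expect_identical(res$burden, setNames(as.integer(rowSums(naive_sem_mask(m))),
                                        rownames(m)))
})

test_that("burden transforms and zero handling behave", {
  m <- toy_matrix(c(rep(0.5, 11), 0.99), n_probes = 1)
  res <- call_sems(m)
  expect_equal(sum(res$burden), 1L)
  expect_equal(res$log_burden[res$burden == 0], rep(0, 11),
               ignore_attr = TRUE)
  expect_equal(unname(res$log_burden[res$burden == 1]), log(2))
  res_ln <- call_sems(m, log_transform = "log")
  expect_true(all(is.na(res_ln$log_burden[res_ln$burden == 0])))
  expect_equal(unname(res_ln$log_burden[res_ln$burden == 1]), 0)
})

test_that("pushing one value beyond a fence raises that burden by one", {
  set.seed(11)
  m <- toy_matrix(rbeta(600, 20, 20), n_probes = 20)
  fences <- compute_fences(m)
  base <- call_sems(m, fences)
  m2 <- m
  stopifnot(!base$sem_mask[3, 5])
  m2[3, 5] <- fences$upper[5] + 0.01
  bumped <- call_sems(m2, fences)  # fences held fixed
  expect_equal(bumped$burden[3], base$burden[3] + 1L, ignore_attr = TRUE)
  expect_equal(bumped$burden[-3], base$burden[-3])
})

test_that("SEM calls are equivariant under affine rescaling", {
  set.seed(5)
  m <- toy_matrix(runif(400), n_probes = 16)
  a <- 3.7
  b <- -1.2
  expect_identical(call_sems(m)$sem_mask, call_sems(a * m + b)$sem_mask)
})

test_that("the 3xIQR fence is extreme for Gaussian noise", {
  set.seed(2026)
  m <- toy_matrix(0.5 + rnorm(100 * 2000, sd = 0.03), n_probes = 2000)
  rate <- mean(call_sems(m)$sem_mask)
  expect_lt(rate, 1e-3)
})

test_that("probes under the sample floor are excluded, not an error", {
  m <- toy_matrix(runif(40), n_probes = 4)
  m[3:10, 2] <- NA
  expect_message(f <- compute_fences(m, min_samples = 8), "excluded")
  expect_false("cg2" %in% f$probe_id)
  expect_equal(attr(f, "excluded"), "cg2")
  # fences referring to probes absent from the matrix are an error
  expect_error(call_sems(m[, -1], f), "absent")
})

test_that("WBC residualization degenerates gracefully and removes cell signal", {
  set.seed(9)
  n <- 60
  m <- toy_matrix(runif(n * 8), n_probes = 8)
  # constant fractions: residuals are the probe-centered betas and the SEM
  # mask is unchanged (fences shift with the data)
  wbc_const <- matrix(c(0.6, 0.4), n, 2, byrow = TRUE,
                      dimnames = list(rownames(m), c("wbc_a", "wbc_b")))
  expect_error(wbc_adjust_betas(m, wbc_const), "aliased")
  wbc_const1 <- wbc_const[, 1, drop = FALSE]  # single column is dropped
  res <- wbc_adjust_betas(m, wbc_const1)
  expect_equal(res, sweep(m, 2, colMeans(m)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(call_sems(res)$sem_mask, call_sems(m)$sem_mask)

  # beta exactly linear in one fraction: residuals vanish
  f1 <- runif(n, 0.3, 0.7)
  wbc <- cbind(wbc_1 = f1, wbc_2 = 1 - f1)
  rownames(wbc) <- rownames(m)
  lin <- toy_matrix(rep(0.1, n) + 0.5 * f1, n_probes = 1)
  expect_lt(max(abs(wbc_adjust_betas(lin, wbc))), 1e-12)

  # planted cell-driven outliers: a few samples with extreme fractions give
  # raw SEM calls that the adjustment removes
  f_out <- c(rep(0.95, 3), rnorm(n - 3, 0.5, 0.01))
  wbc_out <- cbind(wbc_1 = f_out, wbc_2 = 1 - f_out)
  rownames(wbc_out) <- rownames(m)
  strong <- toy_matrix(0.1 + 0.8 * f_out + rnorm(n, sd = 0.004), n_probes = 1)
  raw_calls <- sum(call_sems(strong)$sem_mask[1:3, ])
  adj_calls <- sum(call_sems(wbc_adjust_betas(strong, wbc_out))$sem_mask[1:3, ])
  expect_equal(raw_calls, 3L)
  expect_equal(adj_calls, 0L)
})

test_that("missing values are never SEMs and burdens count available probes", {
  set.seed(3)
  m <- toy_matrix(runif(300), n_probes = 10)
  m[1, ] <- NA
  res <- call_sems(m)
  expect_false(any(res$sem_mask[1, ]))
  expect_equal(unname(res$burden[1]), 0L)
})

test_that("sem_loci pools recurrence across cohorts", {
  set.seed(14)
  m1 <- toy_matrix(c(rep(0.5, 11), 0.99), n_probes = 1)
  colnames(m1) <- "cgA"
  r1 <- call_sems(m1)
  loci1 <- sem_loci(r1)
  expect_equal(loci1, "cgA")
  expect_equal(sem_loci(list(r1, r1), min_recurrence = 3), character(0))
  expect_equal(sem_loci(list(r1, r1), min_recurrence = 2), "cgA")
})
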