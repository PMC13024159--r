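random_scan_instance <- function(seed, L = 12L, S = 4L, E = 3L) {
  withr::with_seed(seed, list(
    x = matrix(rnorm(L * E), L, E),
    delta = runif(L, 0.01, 0.3),
    A = -runif(1, 0.3, 3),
    B = matrix(rnorm(L * S), L, S),
    C = matrix(rnorm(L * S), L, S),
    D = runif(1)))
}

test_that("reference scan equals the dense causal operator", {
  for (s in 1:5) {
    L <- sample(4:16, 1L)
    inst <- random_scan_instance(500L + s, L = L)
    y <- ssd_scan_reference(inst$x, inst$delta, inst$A, inst$B, inst$C, inst$D)
    M <- oracle_ssd_dense(inst$delta, inst$A, inst$B, inst$C, inst$D)
    expect_lt(max(abs(y - M %*% inst$x)), 1e-6 * max(1, max(abs(y))))
  }
})

test_that("degenerate decay (A -> -Inf) is memoryless", {
  inst <- random_scan_instance(510L)
  y <- ssd_scan_reference(inst$x, inst$delta, -Inf, inst$B, inst$C, inst$D)
  expected <- t(vapply(seq_len(nrow(inst$x)), function(t)
    sum(inst$C[t, ] * inst$B[t, ]) * inst$delta[t] * inst$x[t, ] +
      inst$D * inst$x[t, ],
    numeric(ncol(inst$x))))
  expect_equal(y, expected, tolerance = 1e-12)
})

test_that("integrator limit reduces to a cumulative sum", {
  L <- 20L
  x <- matrix(withr::with_seed(9L, rnorm(L)), L, 1L)
  y <- ssd_scan_reference(x, delta = rep(1, L), A = -1e-12,
                          B_seq = matrix(1, L, 1L), C_seq = matrix(1, L, 1L),
                          D_skip = 0)
  expect_equal(as.numeric(y), cumsum(as.numeric(x)), tolerance = 1e-8)
})

test_that("batched multi-head scan agrees with the reference scan", {
  B <- 3L; L <- 10L; H <- 2L; hd <- 4L; S <- 5L
  withr::with_seed(520L, {
    x <- array(rnorm(B * L * H * hd), c(B, L, H, hd))
    dt <- array(runif(B * L * H, 0.01, 0.3), c(B, L, H))
    A <- -runif(H, 0.3, 2)
    Bs <- array(rnorm(B * L * S), c(B, L, S))
    Cs <- array(rnorm(B * L * S), c(B, L, S))
    Dk <- matrix(runif(H * hd), H, hd)
  })
  out <- eegmamba:::ssd_scan_batched_fw(x, dt, A, Bs, Cs, Dk)
  for (b in seq_len(B)) for (h in seq_len(H)) {
    yr <- ssd_scan_reference(matrix(x[b, , h, ], L, hd), dt[b, , h], A[h],
                             matrix(Bs[b, , ], L, S), matrix(Cs[b, , ], L, S),
                             Dk[h, ])
    expect_equal(out$y[b, , h, ], yr, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("batched scan backward matches finite differences", {
  B <- 2L; L <- 6L; H <- 2L; hd <- 3L; S <- 3L
  withr::with_seed(530L, {
    x <- array(rnorm(B * L * H * hd), c(B, L, H, hd))
    dt <- array(runif(B * L * H, 0.05, 0.3), c(B, L, H))
    A <- -runif(H, 0.3, 2)
    Bs <- array(rnorm(B * L * S), c(B, L, S))
    Cs <- array(rnorm(B * L * S), c(B, L, S))
    Dk <- matrix(runif(H * hd), H, hd)
  })
  loss_of <- function(x., dt., A., Bs., Cs., Dk.) {
    sum(eegmamba:::ssd_scan_batched_fw(x., dt., A., Bs., Cs., Dk.,
                                       keep_states = FALSE)$y^2)
  }
  fw <- eegmamba:::ssd_scan_batched_fw(x, dt, A, Bs, Cs, Dk)
  gr <- eegmamba:::ssd_scan_batched_bw(
    list(x = x, dt = dt, A = A, Bseq = Bs, Cseq = Cs, D_skip = Dk,
         states = fw$states), 2 * fw$y)
  checks <- list(
    list(g = gr$dx, get = function() x, set = function(v) loss_of(v, dt, A, Bs, Cs, Dk)),
    list(g = gr$ddt, get = function() dt, set = function(v) loss_of(x, v, A, Bs, Cs, Dk)),
    list(g = gr$dA, get = function() A, set = function(v) loss_of(x, dt, v, Bs, Cs, Dk)),
    list(g = gr$dB, get = function() Bs, set = function(v) loss_of(x, dt, A, v, Cs, Dk)),
    list(g = gr$dC, get = function() Cs, set = function(v) loss_of(x, dt, A, Bs, v, Dk)),
    list(g = gr$dD, get = function() Dk, set = function(v) loss_of(x, dt, A, Bs, Cs, v)))
  for (ck in checks) {
    v0 <- ck$get()
    idx <- withr::with_seed(540L, sample(length(v0), min(4L, length(v0))))
    for (i in idx) {
      fd <- fd_partial(function(val) {
        v <- v0; v[i] <- val; ck$set(v)
      }, c(v0[i]), 1L, eps = 1e-6)
      expect_equal(c(ck$g[i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("hidden state stays bounded over 10k steps with A < 0", {
  L <- 10000L
  x <- matrix(1, L, 1L)
  y <- ssd_scan_reference(x, delta = rep(0.05, L), A = -1,
                          B_seq = matrix(1, L, 1L), C_seq = matrix(1, L, 1L),
                          D_skip = 0)
  expect_true(all(is.finite(y)))
  # steady state of the scalar recurrence: delta / (1 - exp(delta * A))
  expect_lt(max(abs(y)), 2 * 0.05 / (1 - exp(-0.05)))
})

test_that("scan runtime grows roughly linearly in sequence length", {
  run_at <- function(L) {
    inst <- withr::with_seed(550L, list(
      x = matrix(rnorm(L * 4L), L, 4L), delta = runif(L, 0.01, 0.2),
      B = matrix(rnorm(L * 4L), L, 4L), C = matrix(rnorm(L * 4L), L, 4L)))
    min(vapply(1:3, function(i) system.time(
      for (r in 1:10) ssd_scan_reference(inst$x, inst$delta, -1, inst$B,
                                         inst$C, 0.5))[3L],
      numeric(1)))
  }
  t256 <- run_at(256L)
  t512 <- run_at(512L)
  expect_lt(t512 / max(t256, 1e-4), 2.6)
})
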