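test_that("local field: block shortcut agrees with the dense product", {
  bank <- build_template_bank(sig_ab())
  W <- hebb_weights_modified(bank)
  # state = template of A, p = 2 equal classes: h_i = (p/N)(N - 1) for i in A
  st <- template_state(bank, "A")
  h <- local_field(W, st)
  expect_equal(unname(h[1:3]), rep((2 / 6) * 5, 3))
  expect_equal(h, local_field(W, st, bank, method = "class_sum"),
               ignore_attr = TRUE, tolerance = 1e-12)
  # all-zero state
  expect_equal(local_field(W, rep(0L, 6)), rep(0, 6), ignore_attr = TRUE)
  # random ternary states on random layouts
  set.seed(19)
  for (rep in 1:8) {
    sig <- random_layout(p = sample(2:4, 1))
    bank <- build_template_bank(sig)
    W <- hebb_weights_modified(bank)
    x <- sample(c(-1L, 0L, 1L), bank$N, replace = TRUE)
    expect_equal(local_field(W, x), local_field(W, x, bank, "class_sum"),
                 tolerance = 1e-12)
  }
})

test_that("energy matches the brute-force double sum", {
  bank <- build_template_bank(sig_ab())
  W <- hebb_weights_modified(bank)
  expect_equal(state_energy(W, rep(0, 6)), 0)
  st <- template_state(bank, "A")
  expect_equal(state_energy(W, st), -5)           # -(p/2)(N-1) at p=2, N=6
  expect_equal(state_energy(W, st), energy_oracle(W, st))
  expect_equal(state_energy(W, st), state_energy(W, -st)) # quadratic form
  set.seed(5)
  x <- sample(c(-1, 0, 1), 6, replace = TRUE)
  expect_equal(state_energy(W, x), energy_oracle(W, x))
})

test_that("classic dynamics: stored patterns are fixed points and noise is healed", {
  set.seed(31)
  xi <- random_patterns(50, 1)
  W <- hebb_weights_classic(xi)
  res <- async_sweep_classic(xi[, 1], W)
  expect_equal(res$flips, 0)
  expect_equal(res$state, xi[, 1], ignore_attr = TRUE)
  # 10% corrupted bits are restored
  x <- xi[, 1]
  flip <- sample(50, 5)
  x[flip] <- -x[flip]
  ev <- hopclass:::cpp_evolve_classic(W, x, 100L)
  expect_true(ev$fixed_point)
  expect_equal(ev$state, xi[, 1], ignore_attr = TRUE)
})

test_that("classic dynamics: energy is non-increasing along every trajectory", {
  set.seed(99)
  for (rep in 1:6) {
    P <- random_patterns(40, sample(1:6, 1))
    W <- hebb_weights_classic(P)
    x <- random_patterns(40, 1)[, 1]
    for (sweep in 1:5) {
      e_before <- state_energy(W, x)
      res <- async_sweep_classic(x, W)
      x <- res$state
      expect_lte(state_energy(W, x), e_before + 1e-12)
      if (res$flips == 0) break
    }
    expect_equal(async_sweep_classic(x, W)$flips, 0) # terminated in a fixed point
  }
})

test_that("asymmetric dynamics: stable templates, zero permanence, elimination bookkeeping", {
  set.seed(7)
  # templates are fixed points when every class pair covers a majority of genes:
  # any two-class layout, and balanced three-class layouts, satisfy this
  layouts <- list(sig_ab(), sig_ab(4, 9), sig_abc(c(5, 5, 5)))
  for (sig in layouts) {
    bank <- build_template_bank(sig)
    W <- hebb_weights_modified(bank)
    for (cl in sig$classes) {
      st <- template_state(bank, cl)
      res <- async_sweep_asymmetric(st, W)
      expect_equal(res$changed, 0)
      expect_equal(res$state, st)
      expect_equal(match_fraction(res$state, bank$templates[, cl],
                                  rep(TRUE, bank$N)), 1.0)
    }
  }
  # zeroed nodes never revive, +1 count only decreases via eliminations
  bank <- build_template_bank(sig_abc(c(5, 5, 5)))
  W <- hebb_weights_modified(bank)
  for (rep in 1:10) {
    x <- sample(c(-1L, 0L, 1L), bank$N, replace = TRUE)
    res <- async_sweep_asymmetric(x, W)
    expect_true(all(res$state[x == 0L] == 0L))
    expect_equal(sum(x == 1L & res$state == 0L), res$eliminated)
    expect_true(all(res$state[x == 1L] %in% c(0L, 1L))) # +1 never becomes -1
    expect_true(all(res$state[x == -1L] %in% c(-1L, 1L)))
  }
})

test_that("match fraction counts eliminations as mismatches over the t=0 active set", {
  tmpl <- rep(c(1, -1), each = 10)
  expect_equal(match_fraction(tmpl, tmpl, rep(TRUE, 20)), 1.0)
  st <- tmpl
  st[1] <- 0 # one elimination among 20 active genes
  expect_equal(match_fraction(st, tmpl, rep(TRUE, 20)), 0.95)
  expect_lt(match_fraction(-tmpl, tmpl, rep(TRUE, 20)), 0.95)
  expect_error(match_fraction(tmpl, tmpl, rep(FALSE, 20)), "degenerate")
})

test_that("a template state converges to its own class in one sweep", {
  bank <- build_template_bank(sig_abc(c(5, 5, 5)))
  W <- hebb_weights_modified(bank)
  set.seed(2)
  out <- evolve_to_class(template_state(bank, "B"), bank, W, hop_config())
  expect_equal(out$converged_class, "B")
  expect_equal(out$match_fraction, 1.0)
  expect_lte(out$sweeps, 1)
  expect_equal(out$eliminated, 0)
})

test_that("two-class toy input converges to the dominant class", {
  # p = 2, 3 genes per class; input (+1,+1,-1 | -1,-1,+1): gene 3 is recruited
  # to +1 and gene 6 eliminated, so the best match against class A is 5/6;
  # the call therefore needs a threshold below 0.95 on this 6-gene toy
  bank <- build_template_bank(sig_ab())
  W <- hebb_weights_modified(bank)
  x0 <- c(1L, 1L, -1L, -1L, -1L, 1L)
  cfg <- hop_config(match_threshold = 0.8)
  set.seed(11)
  calls <- replicate(25, evolve_to_class(x0, bank, W, cfg)$converged_class)
  expect_true(all(calls == "A"))
  out <- evolve_to_class(x0, bank, W, cfg)
  expect_equal(out$match_fraction, 5 / 6)
  expect_equal(out$eliminated, 1)
  # at the default 0.95 threshold the same input is ambiguous: no call
  set.seed(11)
  expect_true(is.na(evolve_to_class(x0, bank, W, hop_config())$converged_class))
})

test_that("heavily conflicting input is returned unconverged", {
  bank <- build_template_bank(sig_ab(10, 10))
  W <- hebb_weights_modified(bank)
  # half of each signature up, half down: no template can reach 95%
  x0 <- c(rep(c(1L, -1L), 5), rep(c(1L, -1L), 5))
  set.seed(4)
  for (rep in 1:10) {
    out <- evolve_to_class(x0, bank, W, hop_config())
    expect_true(is.na(out$converged_class))
    expect_lt(out$match_fraction, 0.95)
  }
})
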