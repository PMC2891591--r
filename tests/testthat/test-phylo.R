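models <- load_default_models()

test_that("shipped models satisfy their invariants", {
  expect_equal(length(models$unpaired$pi), 4)
  expect_equal(sum(models$unpaired$pi), 1, tolerance = 1e-12)
  expect_equal(length(models$paired$pi), 16)
  expect_equal(sum(models$paired$pi), 1, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(models$paired$Q))), 1e-9)
  expect_lt(max(abs(rowSums(models$unpaired$Q))), 1e-9)
  for (m in models) {
    flux <- m$pi * m$Q
    expect_lt(max(abs(flux - t(flux))), 1e-9)
  }
  # state order is the documented one
  expect_equal(models$unpaired$states, c("A", "C", "G", "U"))
  expect_equal(models$paired$states[c(1, 4, 16)], c("AA", "AU", "UU"))
})

test_that("a non-reversible rate matrix is rejected by the loader", {
  Q <- matrix(c(-3, 1, 1, 1,
                2, -4, 1, 1,
                1, 1, -3, 1,
                1, 1, 1, -3), 4, 4, byrow = TRUE)
  expect_error(evo_model(c("A", "C", "G", "U"), rep(0.25, 4), Q),
               "reversible")
  f <- tempfile(fileext = ".txt")
  writeLines(c("states A C G U", "pi 0.25 0.25 0.25 0.25", "Q",
               apply(Q, 1, paste, collapse = " ")), f)
  expect_error(read_model_file(f), "reversible")
  expect_error(read_model_file(tempfile()), "not found")
})

test_that("transition matrices behave like exp(Qt)", {
  for (m in models) {
    expect_equal(transition_matrix(m, 0), diag(m$nstate),
                 ignore_attr = TRUE, tolerance = 1e-12)
    P_inf <- transition_matrix(m, 1e6)
    for (r in seq_len(m$nstate)) {
      expect_equal(unname(P_inf[r, ]), unname(m$pi), tolerance = 1e-6)
    }
    expect_lt(max(abs(rowSums(transition_matrix(m, 0.37)) - 1)), 1e-10)
    # Chapman-Kolmogorov
    expect_equal(transition_matrix(m, 0.2) %*% transition_matrix(m, 0.3),
                 transition_matrix(m, 0.5), tolerance = 1e-10)
    # detailed balance carries over to P(t)
    set.seed(5)
    for (t in runif(3, 0, 5)) {
      F <- m$pi * transition_matrix(m, t)
      expect_lt(max(abs(F - t(F))), 1e-10)
    }
  }
  expect_error(transition_matrix(models$unpaired, -1), "non-negative")
})

test_that("leaf vectors encode the gap semantics", {
  expect_equal(as.vector(leaf_vector_unpaired("A")), c(1, 0, 0, 0))
  expect_equal(as.vector(leaf_vector_unpaired("-")), rep(1, 4))
  expect_equal(as.vector(leaf_vector_unpaired("N")), rep(1, 4))
  expect_error(leaf_vector_unpaired("X"), "invalid")

  gc <- leaf_vector_paired("G", "C")
  expect_equal(sum(gc), 1)
  expect_equal(rownames(gc)[which(gc == 1)], "GC")

  expect_equal(as.vector(leaf_vector_paired("-", "-")), rep(1, 16))
  expect_equal(as.vector(leaf_vector_paired("N", "N")), rep(1, 16))

  # one-sided gap: non-consensus states sharing the observed base
  av <- leaf_vector_paired("A", "-")
  expect_setequal(rownames(av)[av[, 1] == 1], c("AA", "AC", "AG"))
  va <- leaf_vector_paired("-", "A")
  expect_setequal(rownames(va)[va[, 1] == 1], c("AA", "CA", "GA"))
  gv <- leaf_vector_paired("G", "N")
  expect_setequal(rownames(gv)[gv[, 1] == 1], c("GA", "GG"))
})

test_that("single-leaf and two-leaf likelihoods match closed forms", {
  # single sequence: likelihood of an observed state is its equilibrium freq
  aln1 <- rna_alignment(c("s1", "s2"), c("GA", "GA"))
  tr0 <- read_tree(text = "(s1:0,s2:0);")
  ll <- column_loglik_unpaired(aln1, tr0, models$unpaired, 1)
  expect_equal(exp(ll), unname(models$unpaired$pi[3]), tolerance = 1e-12)

  # two leaves, branches t1 and t2: sum over the 16 root states
  aln <- rna_alignment(c("s1", "s2"), c("GC", "GC"))
  tr <- read_tree(text = "(s1:0.3,s2:0.8);")
  P1 <- transition_matrix(models$paired, 0.3)
  P2 <- transition_matrix(models$paired, 0.8)
  expected <- sum(models$paired$pi * P1[, "GC"] * P2[, "GC"])
  got <- exp(column_loglik_paired(aln, tr, models$paired, cbind(1, 2)))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("pruning equals exhaustive internal-state summation on small trees", {
  set.seed(11)
  trees <- list(read_tree(text = "(s1:0.4,s2:0.9);"),
                read_tree(text = "((s1:0.2,s2:0.5):0.3,s3:0.7);"))
  for (tr in trees) {
    n <- ape::Ntip(tr)
    for (model in models) {
      for (rep in 1:5) {
        leafmats <- lapply(seq_len(n), function(i) {
          v <- matrix(0, model$nstate, 2)
          v[sample(model$nstate, 1), 1] <- 1
          v[, 2] <- runif(model$nstate) < 0.5  # partial observations too
          if (all(v[, 2] == 0)) v[1, 2] <- 1
          v
        })
        fast <- transat:::prune_loglik(leafmats, tr, model)
        slow <- brute_force_loglik(leafmats, tr, model)
        expect_equal(fast, slow, tolerance = 1e-12)
      }
    }
  }
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(21)
  for (rep in 1:20) {
    tr <- random_binary_tree(5)
    aln <- random_alignment(5, 8, gap_prob = 0.1)
    ll1u <- column_loglik_unpaired(aln, tr, models$unpaired)
    ll1p <- column_loglik_paired(aln, tr, models$paired,
                                 cbind(1:4, 8:5))
    # re-root at a random internal node of the unrooted tree
    tr2 <- reroot_random(tr)
    ll2u <- column_loglik_unpaired(aln, tr2, models$unpaired)
    ll2p <- column_loglik_paired(aln, tr2, models$paired,
                                 cbind(1:4, 8:5))
    expect_equal(ll1u, ll2u, tolerance = 1e-10)
    expect_equal(ll1p, ll2p, tolerance = 1e-10)
  }
})

test_that("likelihoods over all joint leaf observations sum to one", {
  tr <- read_tree(text = "(s1:0.4,s2:0.9);")
  nuc <- c("A", "C", "G", "U")
  tot_u <- 0
  for (x1 in nuc) for (x2 in nuc) {
    aln <- rna_alignment(c("s1", "s2"), c(paste0(x1, x1), paste0(x2, x2)))
    tot_u <- tot_u + exp(column_loglik_unpaired(aln, tr, models$unpaired, 1))
  }
  expect_equal(tot_u, 1, tolerance = 1e-10)

  dinucs <- as.vector(t(outer(nuc, nuc, paste0)))
  tot_p <- 0
  for (d1 in dinucs) for (d2 in dinucs) {
    aln <- rna_alignment(c("s1", "s2"), c(d1, d2))
    tot_p <- tot_p + exp(column_loglik_paired(aln, tr, models$paired,
                                              cbind(1, 2)))
  }
  expect_equal(tot_p, 1, tolerance = 1e-10)
})

test_that("helix scores are zero under an independence model", {
  # paired model = product of two independent unpaired chains: the paired
  # and unpaired hypotheses coincide, so every helix scores zero
  mu <- models$unpaired
  pi_ind <- as.vector(kronecker(mu$pi, mu$pi))  # first-base-major order
  Q_ind <- kronecker(mu$Q, diag(4)) + kronecker(diag(4), mu$Q)
  states <- as.vector(t(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                              paste0)))
  ind_paired <- evo_model(states, pi_ind, Q_ind)
  ind_models <- list(unpaired = mu, paired = ind_paired)

  set.seed(3)
  aln <- random_alignment(5, 30, gap_prob = 0)
  tr <- random_binary_tree(5)
  h <- collect_conserved_helices(aln, min_len = 2, min_loop = 3)
  if (nrow(h)) {
    scored <- score_helices(h, aln, tr, ind_models)
    expect_lt(max(abs(scored$score)), 1e-9)
  } else {
    succeed()
  }
})

test_that("duplicating every column pair leaves the score unchanged", {
  set.seed(8)
  aln <- random_alignment(4, 20, gap_prob = 0)
  tr <- random_binary_tree(4)
  pairs <- cbind(i = 1:4, j = 20:17)
  h1 <- tibble::tibble(helix = 1L, length = 4L, support = 1L,
                       pairs = list(pairs))
  h2 <- tibble::tibble(helix = 1L, length = 8L, support = 1L,
                       pairs = list(rbind(pairs, pairs)))
  s1 <- score_helices(h1, aln, tr, models)$score
  s2 <- score_helices(h2, aln, tr, models)$score
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("scores are invariant under joint row/leaf permutation", {
  set.seed(13)
  aln <- random_alignment(6, 25, gap_prob = 0.05)
  tr <- random_binary_tree(6)
  h <- collect_conserved_helices(aln, min_len = 2)
  if (!nrow(h)) h <- tibble::tibble(helix = 1L, length = 2L, support = 1L,
                                    pairs = list(cbind(i = 1:2, j = 25:24)))
  s1 <- score_helices(h, aln, tr, models)$score
  perm <- sample(6)
  aln2 <- rna_alignment(aln$ids[perm], unname(aln$seqs)[perm])
  s2 <- score_helices(h, aln2, tr, models)$score
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("column_likelihood wrapper returns probabilities", {
  aln <- rna_alignment(c("s1", "s2"), c("GC", "GC"))
  tr <- read_tree(text = "(s1:0.3,s2:0.8);")
  lu <- column_likelihood(aln, tr, models, col = 1)
  lp <- column_likelihood(aln, tr, models, pair = c(1, 2))
  expect_true(lu > 0 && lu <= 1)
  expect_true(lp > 0 && lp <= 1)
  expect_error(column_likelihood(aln, tr, models), "exactly one")
})
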