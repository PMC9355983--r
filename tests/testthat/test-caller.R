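# --- ssGSEA -----------------------------------------------------------------

test_that("ssGSEA running sum matches brute-force enumeration on a 5-gene toy", {
  # tau = 0: unweighted running sum computed from first principles for
  # every arrangement of 2 set genes among 5 ranks
  brute <- function(in_pos, N = 5) {
    s <- 0; nin <- 0; nout <- 0
    for (i in seq_len(N)) {
      if (i %in% in_pos) nin <- nin + 1 else nout <- nout + 1
      s <- s + nin / length(in_pos) - nout / (N - length(in_pos))
    }
    s
  }
  combos <- combn(5, 2)
  scores <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    x <- setNames(c(50, 40, 30, 20, 10), paste0("g", 1:5))
    set_genes <- names(x)[combos[, k]]
    scores[k] <- ssgsea_score(x, set_genes, tau = 0)
    expect_equal(scores[k], brute(combos[, k]))
  }
  # the top-1,2 arrangement is the unique maximum
  expect_equal(which.max(scores), 1L)
  expect_true(all(scores[-1] < scores[1]))
})

test_that("ssGSEA ignores permutations of out-of-set expression values", {
  set.seed(10)
  x <- setNames(sample(100, 20), sprintf("g%02d", 1:20))
  set_genes <- c("g03", "g07", "g15")
  s0 <- ssgsea_score(x, set_genes)
  out <- setdiff(names(x), set_genes)
  y <- x
  y[c(out[1], out[5])] <- y[c(out[5], out[1])]
  expect_equal(ssgsea_score(y, set_genes), s0)
})

test_that("ssGSEA is monotone in in-set expression", {
  set.seed(11)
  for (rep in 1:20) {
    x <- setNames(runif(15, 0, 100), sprintf("g%02d", 1:15))
    set_genes <- sample(names(x), 4)
    s0 <- ssgsea_score(x, set_genes)
    g <- sample(set_genes, 1)
    x2 <- x; x2[g] <- x2[g] + runif(1, 0, 50)
    expect_gte(ssgsea_score(x2, set_genes), s0 - 1e-12)
  }
})

test_that("ssGSEA degenerate and error cases behave as documented", {
  x <- setNames(c(3, 2, 1), c("a", "b", "c"))
  expect_warning(s <- ssgsea_score(x, c("a", "b", "c")), "defined as 0")
  expect_equal(s, 0)
  expect_error(ssgsea_score(x, c("zz", "yy")), "absent")
  expect_warning(s2 <- ssgsea_score(x, c("a", "zz")), "intersection")
  expect_equal(s2, ssgsea_score(x, "a"))
})

test_that("expression ties are broken lexicographically for determinism", {
  x <- setNames(c(5, 5, 5, 1), c("d", "b", "a", "c"))
  y <- x[c("a", "b", "c", "d")]
  expect_equal(ssgsea_score(x, c("a", "c")), ssgsea_score(y, c("a", "c")))
})

# --- kTSP -------------------------------------------------------------------

test_that("kTSP boundary and enumerated cases", {
  sig <- gene_signature(c("u1", "u2"), c("d1", "d2"))
  expect_equal(ktsp_score(c(u1 = 10, u2 = 9, d1 = 1, d2 = 2), sig), 1)
  expect_equal(ktsp_score(c(u1 = 1, u2 = 2, d1 = 10, d2 = 9), sig), 0)
  # exactly one violating pair of the 4: d2 > u2
  expect_equal(ktsp_score(c(u1 = 10, u2 = 4, d1 = 1, d2 = 5), sig), 0.75)
  # ties count as non-compliant
  expect_equal(ktsp_score(c(u1 = 5, u2 = 5, d1 = 5, d2 = 1), sig), 0.5)
})

test_that("kTSP equals brute-force pair enumeration on random 50-gene profiles", {
  sig <- gene_signature(sprintf("u%d", 1:8), sprintf("d%d", 1:5))
  genes <- c(sig$up_genes, sig$down_genes, sprintf("bg%d", 1:37))
  set.seed(12)
  for (rep in 1:5) {
    x <- setNames(rnorm(50), genes)
    n_ok <- 0
    for (d in sig$down_genes) for (u in sig$up_genes)
      if (x[d] < x[u]) n_ok <- n_ok + 1
    expect_equal(ktsp_score(x, sig), n_ok / 40)
  }
})

test_that("kTSP is invariant under strictly increasing transforms", {
  sig <- gene_signature(sprintf("u%d", 1:5), sprintf("d%d", 1:3))
  set.seed(13)
  x <- setNames(runif(30, 1, 100),
                c(sig$up_genes, sig$down_genes, sprintf("bg%d", 1:22)))
  s0 <- ktsp_score(x, sig)
  for (rep in 1:25) {
    a <- runif(1, 0.1, 3); b <- runif(1, -5, 5)
    transforms <- list(function(v) a * v + b,
                       function(v) v^3,
                       function(v) exp(a * v / 50),
                       function(v) log(v) * a)
    f <- transforms[[sample(4, 1)]]
    expect_equal(ktsp_score(f(x), sig), s0)
  }
})

test_that("kTSP errors when one side of the signature is absent", {
  sig <- gene_signature("u1", "d1")
  expect_error(ktsp_score(c(u1 = 1, bg = 2), sig), "down-regulated")
  expect_error(ktsp_score(c(d1 = 1, bg = 2), sig), "up-regulated")
})

# --- decision rule ----------------------------------------------------------

test_that("activation decision is the conjunction of the two thresholds", {
  scores <- data.frame(sample_id = c("a", "b", "c", "d"),
                       ssgsea_score = c(0.9, 0.8, 0.1, 0.2),
                       ktsp_score = c(1, 0, 1, 0.6))
  out <- call_activation(scores, caller_config())
  # median ssGSEA = 0.5: a passes both; b fails kTSP; c,d fail ssGSEA
  expect_identical(out$scores$call,
                   c("activated", "not_activated", "not_activated",
                     "not_activated"))
  out2 <- call_activation(scores, caller_config(ssgsea_threshold = 0.05))
  expect_identical(out2$scores$call[3], "activated")
  scores$ktsp_score[2] <- NA
  expect_error(call_activation(scores), "missing score.*b")
})

test_that("caller output is independent of gene row order", {
  sig <- tiny_signature(3, 2)
  co <- simulate_expression_cohort(cohort_spec(5, 5, 80, seed = 14), sig)
  f1 <- notch_call(co$counts, sig)
  perm <- sample(nrow(co$counts))
  shuffled <- expression_matrix(unclass(co$counts)[perm, ], "raw")
  f2 <- notch_call(shuffled, sig)
  expect_equal(f1$scores, f2$scores)
})

test_that("caller recovers truth labels on a strong synthetic cohort", {
  sig <- notch_signature()
  spec <- cohort_spec(10, 10, 500, up_effect = 4, down_effect = 0.25,
                      dispersion = 0.1, seed = 15)
  co <- simulate_expression_cohort(spec, sig)
  fit <- notch_call(co$counts, sig)
  called <- fit$scores$call == "activated"
  expect_gte(mean(called == unname(co$truth)), 0.9)
})

test_that("null cohorts are not called preferentially in either truth class", {
  sig <- notch_signature()
  spec <- cohort_spec(15, 15, 300, up_effect = 1, down_effect = 1, seed = 16)
  co <- simulate_expression_cohort(spec, sig)
  fit <- notch_call(co$counts, sig)
  called <- fit$scores$call == "activated"
  acc <- mean(called == unname(co$truth))
  expect_lt(abs(acc - 0.5), 0.3)
})

# --- clustering -------------------------------------------------------------

test_that("identical samples merge at height zero", {
  sig <- tiny_signature(3, 2)
  m <- make_matrix(c(sig$up_genes, sig$down_genes), c("s1", "s2", "s3"),
                   c(rep(c(5, 6, 7, 1, 2), 2), c(50, 60, 70, 10, 20)),
                   kind = "normalized")
  cl <- signature_cluster(m, sig)
  expect_equal(min(cl$hclust$height), 0)
  expect_identical(unname(cl$labels[1]), unname(cl$labels[2]))
})

test_that("well-separated blobs are recovered at the k = 2 cut", {
  sig <- tiny_signature(3, 2)
  genes <- c(sig$up_genes, sig$down_genes)
  set.seed(17)
  blob1 <- matrix(rnorm(5 * 6, 0, 1), nrow = 5)
  blob2 <- matrix(rnorm(5 * 6, 10, 1), nrow = 5)
  m <- cbind(blob1, blob2) + 20
  dimnames(m) <- list(genes, sprintf("s%02d", 1:12))
  cl <- signature_cluster(expression_matrix(m, "normalized"), sig)
  expect_equal(length(unique(cl$labels[1:6])), 1L)
  expect_equal(length(unique(cl$labels[7:12])), 1L)
  expect_false(cl$labels[1] == cl$labels[7])

  # permuting sample order relabels but does not regroup
  perm <- sample(12)
  cl2 <- signature_cluster(expression_matrix(m[, perm], "normalized"), sig)
  agree <- outer(cl$labels[perm], cl$labels[perm], `==`)
  agree2 <- outer(cl2$labels, cl2$labels, `==`)
  expect_true(all(agree == agree2))
  expect_error(signature_cluster(expression_matrix(m[, 1, drop = FALSE],
                                                   "normalized"), sig),
               ">= 2 samples")
})
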