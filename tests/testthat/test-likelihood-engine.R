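test_that("multi-copy drop-out factors follow alpha^(c-1) p^c", {
  expect_equal(dropout_prob(1, 0.2, 0.5), 0.2)
  expect_equal(dropout_prob(2, 0.2, 0.5), 0.5 * 0.04)  # alpha * P(D_O)^2
  expect_equal(dropout_prob(3, 0.1, 0.5), 0.25 * 0.001)
  expect_error(dropout_prob(0, 0.2, 0.5), "positive")
})

test_that("locus evidence probability multiplies the required event factors", {
  f <- c(a = 0.1, b = 0.05, x = 0.85)
  p <- lr_params(0.1, 0.01, 0, 0.5)
  # full match of a two-allele profile: detect both, no drop-in
  expect_equal(locus_evidence_prob(c("a", "b"), c("a", "b"), character(), p, f),
               0.9 * 0.9 * 0.99)
  # one contributor allele dropped
  expect_equal(locus_evidence_prob("a", c("a", "b"), character(), p, f),
               0.9 * 0.1 * 0.99)
  # homozygote detected plus a drop-in of b
  expect_equal(locus_evidence_prob(c("a", "b"), c(a = 2), character(), p, f),
               (1 - 0.5 * 0.01) * 0.01 * 0.05)
  # two unexplained alleles are impossible under at-most-one drop-in
  expect_equal(locus_evidence_prob(c("a", "b"), NULL, character(), p, f), 0)
  # drop-in disabled: any unexplained allele zeroes the locus
  p0 <- lr_params(0.1, 0, 0, 0.5)
  expect_equal(locus_evidence_prob(c("a", "b"), c(a = 2), character(), p0, f), 0)
})

test_that("masked alleles are certain detections regardless of copy number", {
  f <- c(a = 0.2, b = 0.3, c = 0.5)
  p <- lr_params(0.4, 0.01, 0, 0.5)
  # the masked allele contributes factor 1 even though the suspect carries it
  expect_equal(locus_evidence_prob(c("a", "b"), c(a = 2, b = 1), "a", p, f),
               (1 - 0.4) * 0.99)
  # masked allele not carried by any contributor: explained, no drop-in cost
  expect_equal(locus_evidence_prob(c("a", "b"), c(b = 1), "a", p, f),
               (1 - 0.4) * 0.99)
  expect_error(locus_evidence_prob("a", NULL, "b", p, f), "subset")
})

test_that("with drop-in disabled the evidence distribution is normalized", {
  set.seed(505)
  for (i in 1:20) {
    f <- random_locus_freqs(sample(2:6, 1))
    p <- lr_params(stats::runif(1, 0, 0.9), 0, 0,
                   alpha = stats::runif(1, 0.1, 1))
    cc <- sample(names(f), sample(1:6, 1), replace = TRUE)
    al <- unique(cc)
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(al)))
    tot <- sum(apply(subsets, 1, function(s)
      locus_evidence_prob(al[s], cc, character(), p, f)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("degenerate sums reduce to the fixed-contributor probability", {
  f <- c(a = 0.1, b = 0.1, x = 0.8)
  p <- lr_params(0.2, 0.01, 0.01, 0.5)
  expect_equal(sum_over_unknowns(c("a", "b"), c("a", "b"), character(), 0,
                                 NULL, c("a", "b"), p, f),
               locus_evidence_prob(c("a", "b"), c("a", "b"), character(), p, f))
  # one unknown, no drop-out/in: only the matching genotype survives
  p0 <- lr_params(0, 0, 0, 0.5)
  expect_equal(sum_over_unknowns(c("a", "b"), NULL, character(), 1, NULL,
                                 NULL, p0, f),
               2 * 0.1 * 0.1)
})

test_that("dynamic program agrees with exhaustive enumeration", {
  set.seed(606)
  for (i in 1:60) {
    cs <- random_engine_case()
    a <- sum_over_unknowns(cs$detected, cs$fixed, cs$mask, cs$n_unknown,
                           cs$relative, cs$base_cond, cs$params, cs$freqs)
    b <- brute_force_sum(cs$detected, cs$fixed, cs$mask, cs$n_unknown,
                         cs$relative, cs$base_cond, cs$params, cs$freqs)
    if (b == 0) expect_equal(a, 0) else
      expect_equal(a, b, tolerance = 1e-9)
  }
})

test_that("two unrelated unknowns on a two-allele locus match a hand expansion", {
  # theta = 0: genotype draws are independent, so the sum factorizes into the
  # nine ordered genotype pairs expanded by hand
  f <- c(a = 0.3, b = 0.7)
  p <- lr_params(0.25, 0.02, 0, 0.5)
  gts <- list(c("a", "a"), c("a", "b"), c("b", "b"))
  gp <- c(0.09, 2 * 0.21, 0.49)
  expected <- 0
  for (i in 1:3) for (j in 1:3) {
    cc <- c(gts[[i]], gts[[j]])
    expected <- expected + gp[i] * gp[j] *
      locus_evidence_prob("a", cc, character(), p, f)
  }
  got <- sum_over_unknowns("a", NULL, character(), 2, NULL, NULL, p, f)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("single-source LR reproduces the closed-form match probability", {
  p0 <- lr_params(0, 0, 0, 0.5)
  hp <- suspect_vs_unknown()
  f <- c(a = 0.1, b = 0.1, c = 0.8)
  het <- locus_lr(locus_evidence("L", c("a", "b")), genotype("a", "b"),
                  list(), hp, p0, f)
  expect_equal(het$lr, 1 / (2 * 0.1 * 0.1))
  hom <- locus_lr(locus_evidence("L", "a"), genotype("a", "a"),
                  list(), hp, p0, c(a = 0.1, c = 0.9))
  expect_equal(hom$lr, 1 / 0.01)
})

test_that("identical hypotheses give LR exactly one at every locus", {
  set.seed(707)
  f <- random_locus_freqs(5)
  hp <- hypothesis_pair(hypothesis(FALSE, 2L), hypothesis(FALSE, 2L))
  p <- lr_params(0.3, 0.01, 0.02, 0.5)
  r <- locus_lr(locus_evidence("L", sample(names(f), 2)), genotype(names(f)[1]),
                list(), hp, p, f)
  expect_identical(r$lr, 1)
})

test_that("zero denominators are reported, not fatal", {
  f <- c(a = 0.1, b = 0.1, c = 0.8)
  p0 <- lr_params(0, 0, 0, 0.5)
  # denominator side has no contributors; two unexplained alleles -> 0
  hp <- hypothesis_pair(hypothesis(TRUE, 0L), hypothesis(FALSE, 0L))
  r <- locus_lr(locus_evidence("L", c("a", "b")), genotype("a", "b"),
                list(), hp, p0, f)
  expect_identical(r$lr, Inf)
  expect_match(r$warning, "infinite")
  # both sides impossible: 0/0 reported as 1 with a warning
  hp2 <- hypothesis_pair(hypothesis(FALSE, 0L), hypothesis(FALSE, 0L))
  r2 <- locus_lr(locus_evidence("L", c("a", "b")), NULL, list(), hp2, p0, f)
  expect_identical(r2$lr, 1)
  expect_match(r2$warning, "0/0")
})

test_that("per-locus LR never exceeds the inverse conditional match probability", {
  set.seed(808)
  hp <- suspect_vs_unknown()
  for (i in 1:100) {
    f <- random_locus_freqs(sample(3:8, 1))
    p <- lr_params(stats::runif(1, 0, 0.8), stats::runif(1, 0, 0.05),
                   stats::runif(1, 0, 0.05), 0.5)
    sg <- genotype(sample(names(f), 1), sample(names(f), 1))
    detected <- unique(c(sg[stats::runif(2) < 0.8],
                         sample(names(f), sample(0:1, 1))))
    r <- locus_lr(locus_evidence("L", detected), sg, list(), hp, p, f)
    rmp <- genotype_prob(sg, sg, p$theta, f)
    expect_lte(r$lr, 1 / rmp + 1e-9)
  }
})

test_that("a relative with no IBD sharing is just an unrelated unknown", {
  set.seed(909)
  f <- random_locus_freqs(5)
  sg <- genotype(names(f)[1], names(f)[2])
  p <- lr_params(0.2, 0.01, 0.02, 0.5)
  hp_rel <- hypothesis_pair(hypothesis(TRUE, 0L),
                            hypothesis(FALSE, 1L, relative = ibd_triple(1, 0, 0)))
  hp_unk <- suspect_vs_unknown()
  e <- locus_evidence("L", sg)
  expect_equal(locus_lr(e, sg, list(), hp_rel, p, f)$lr,
               locus_lr(e, sg, list(), hp_unk, p, f)$lr)
})

test_that("an identical twin in the denominator forces LR one", {
  f <- c(a = 0.05, b = 0.15, c = 0.8)
  sg <- genotype("a", "b")
  p <- lr_params(0.3, 0.01, 0.02, 0.5)
  hp <- hypothesis_pair(hypothesis(TRUE, 0L),
                        hypothesis(FALSE, 1L, relative = ibd_triple(0, 0, 1)))
  for (det in list(c("a", "b"), "a", character())) {
    r <- locus_lr(locus_evidence("L", det), sg, list(), hp, p, f)
    expect_equal(r$lr, 1, tolerance = 1e-12)
  }
})

test_that("single-source full-match LR is non-increasing in theta", {
  # holds for the moderately rare alleles typical of STR loci (the
  # conditional match probability rises with theta when frequencies are
  # below ~0.3, so its inverse falls)
  set.seed(111)
  hp <- suspect_vs_unknown()
  p0 <- function(th) lr_params(0, 0, th, 0.5)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    f <- random_locus_freqs(n)
    f <- pmin(f, 0.3); f["filler"] <- 1 - sum(f)  # cap at 0.3, keep sum 1
    sg <- genotype(sample(names(f)[seq_len(n)], 1),
                   sample(names(f)[seq_len(n)], 1))
    e <- locus_evidence("L", sg)
    lrs <- vapply(c(0, 0.01, 0.03, 0.05), function(th)
      locus_lr(e, sg, list(), hp, p0(th), f)$lr, numeric(1))
    expect_true(all(diff(lrs) <= 1e-12))
  }
})

test_that("adding an unknown to both sides keeps the LR finite and positive", {
  set.seed(121)
  f <- random_locus_freqs(6)
  sg <- genotype(sample(names(f), 1), sample(names(f), 1))
  e <- locus_evidence("L", unique(c(sg, sample(names(f), 1))))
  p <- lr_params(0.3, 0.01, 0.01, 0.5)
  for (u in 0:2) {
    hp <- hypothesis_pair(hypothesis(TRUE, u), hypothesis(FALSE, u + 1L))
    r <- locus_lr(e, sg, list(), hp, p, f)
    expect_true(is.finite(r$lr) && r$lr > 0)
  }
})

test_that("compute_case floors frequencies, multiplies loci, echoes parameters", {
  set.seed(131)
  tab1 <- make_frequency_table(1, markers = 3, alleles_per_marker = 5,
                               n_individuals = 500, population = "popA")
  tab2 <- make_frequency_table(2, markers = 3, alleles_per_marker = 5,
                               n_individuals = 1036, population = "popB")
  sus <- sample_reference_profile(tab1, "S", seed = 7)
  ev <- simulate_evidence(list(sus), 0.2, 0.01, tab1, seed = 8)
  p <- lr_params(0.2)
  res <- compute_case(ev, sus, suspect_vs_unknown(), p, list(tab1, tab2))
  expect_length(res, 2)
  expect_identical(vapply(res, function(r) r$population, character(1)),
                   c("popA", "popB"))
  for (r in res) {
    expect_identical(names(r$per_locus), names(ev))
    expect_equal(r$overall, prod(r$per_locus), tolerance = 1e-9)
    expect_identical(r$params, p)
  }
  # a one-locus case equals locus_lr directly on floored frequencies
  fl <- apply_min_frequency(tab1, list(M01 = unique(c(ev$M01$detected,
                                                      sus$genotypes$M01))))
  direct <- locus_lr(ev$M01, sus$genotypes$M01, list(), suspect_vs_unknown(),
                     p, fl$freqs$M01)
  expect_equal(res[[1]]$per_locus[["M01"]], direct$lr)
})

test_that("suspect alleles below the floor actually get floored in a case", {
  # suspect carries a rare allele (0.0001 << 5/2n); the case computation must
  # use the floored value in both sides
  tab <- frequency_table("pop", 500,
                         list(L = c(a = 0.0001, b = 0.5, c = 0.4999)))
  sus <- reference_profile("S", list(L = genotype("a", "b")))
  ev <- list(L = locus_evidence("L", c("a", "b")))
  p0 <- lr_params(0, 0, 0, 0.5)
  res <- compute_case(ev, sus, suspect_vs_unknown(), p0, tab)
  expect_equal(res[[1]]$overall, 1 / (2 * 0.005 * 0.5))
})
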