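test_that("paired_subjects equals brute-force per-subject set intersection", {
  set.seed(101)
  subs <- sprintf("s%02d", 1:20)
  meta <- do.call(rbind, lapply(subs, function(s) {
    rs <- sample(c("BA9", "BA7", "BA17"), sample(1:3, 1))
    data.frame(sample_id = paste(s, gsub("/", ".", rs), sep = "_"),
               subject_id = s, region = rs,
               diagnosis = if (as.integer(substring(s, 2)) <= 10) "control" else "case",
               stringsAsFactors = FALSE)
  }))
  pk <- pair_key("BA9", "BA17", c("BA9", "BA7", "BA17"))
  for (grp in c("control", "case")) {
    got <- paired_subjects(meta, pk, grp)
    want <- sort(Filter(function(s) {
      rs <- meta$region[meta$subject_id == s & meta$diagnosis == grp]
      all(c("BA9", "BA17") %in% rs)
    }, unique(meta$subject_id[meta$diagnosis == grp])))
    expect_identical(got, want)
  }
  # a subject with only one region of the pair is excluded
  meta1 <- data.frame(sample_id = "x_BA9", subject_id = "x", region = "BA9",
                      diagnosis = "control", stringsAsFactors = FALSE)
  expect_identical(paired_subjects(rbind(meta, meta1), pk, "control"),
                   paired_subjects(meta, pk, "control"))
})

test_that("signed_rank_test handles degenerate and documented cases", {
  expect_equal(signed_rank_test(rep(0, 6)), 1)
  d <- c(1.2, 0.8, -0.3, 2.1, 1.7, 0.9)
  expect_equal(signed_rank_test(d), enum_signed_rank_p(d))
  # two-sided symmetry under negation
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(sample(3:30, 1))
    expect_equal(signed_rank_test(v), signed_rank_test(-v))
  }
  expect_error(signed_rank_test(c(1, NA)), "non-finite")
  expect_error(signed_rank_test(c(1, Inf)), "non-finite")
})

test_that("exact p matches full enumeration for 500 random small vectors", {
  set.seed(11)
  for (i in 1:500) {
    n <- sample(1:8, 1)
    d <- round(rnorm(n), 1)        # rounding induces frequent ties and zeros
    expect_equal(signed_rank_test(d), enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("exact p agrees with the classical distribution when tie-free", {
  set.seed(13)
  for (i in 1:50) {
    d <- rnorm(sample(4:25, 1))
    expect_equal(signed_rank_test(d), wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-n approximation matches the corrected normal reference", {
  set.seed(17)
  for (i in 1:20) {
    d <- round(rnorm(60), 1)
    got <- signed_rank_test(d)
    ref <- suppressWarnings(wilcox.test(d, exact = FALSE,
                                        correct = TRUE)$p.value)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("bh_adjust matches the brute-force step-up and is equivariant", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(19)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^2
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("count_de is zero on duplicated regions and matches the oracle", {
  set.seed(23)
  ng <- 12; k <- 7   # 7 paired subjects: the minimum two-sided p (2/2^7)
                     # survives BH across 12 genes at alpha 0.05
  ctl_a <- matrix(rnorm(ng * k, 5), ng, k)
  toy <- toy_two_region(ctl_a, ctl_a, ctl_a + 0.2, ctl_a + 0.2)
  pk <- pair_key("BA9", "BA17")
  r <- count_de(toy$expr, toy$meta, pk, "control")
  expect_equal(r$n_de, 0L)
  expect_true(all(r$table$q >= r$table$p))

  # planted differences scored against the enumeration + brute-BH oracle
  ctl_b <- ctl_a + matrix(rnorm(ng * k, 0, 0.5), ng, k) +
    rep(c(2, 0), length.out = ng)
  toy2 <- toy_two_region(ctl_a, ctl_b, ctl_a, ctl_a)
  r2 <- count_de(toy2$expr, toy2$meta, pk, "control")
  d <- toy2$expr[, (k + 1):(2 * k)] - toy2$expr[, 1:k]
  expect_equal(r2$n_de, oracle_de_count(d))
  expect_gt(r2$n_de, 0)
})

test_that("strong-gradient synthetic fixture recovers ~all planted genes", {
  cfg <- simulation_config(n_control = 15, n_case = 15, n_genes = 200,
                           gradient_fraction = 0.25, gradient_effect_sd = 0.8,
                           noise_sd = 0.3, missing_rate = 0, attenuation = 1,
                           seed = 83)
  ds <- generate_dataset(cfg)
  pk <- pair_key("BA9", "BA17")
  r <- count_de(ds$expr, ds$meta, pk, "control")
  grad <- ds$truth$gradient_gene_ids
  de <- r$table$gene_id[r$table$de_flag]
  expect_gte(length(intersect(de, grad)) / length(grad), 0.9)
  expect_lte(length(setdiff(de, grad)) / max(1, length(de)), 0.1)
})

test_that("n_de is invariant to swapping the pair orientation", {
  cfg <- simulation_config(n_control = 8, n_case = 8, n_genes = 50,
                           regions = c("BA9", "BA7", "BA17"),
                           gradient_fraction = 0.4, gradient_effect_sd = 0.6,
                           noise_sd = 0.3, missing_rate = 0, seed = 89)
  ds <- generate_dataset(cfg)
  pk <- pair_key("BA9", "BA17", cfg$regions)
  r1 <- count_de(ds$expr, ds$meta, pk, "control")
  # manual reversed orientation via a reversed region ordering
  pk_rev <- pair_key("BA9", "BA17", rev(cfg$regions))
  r2 <- count_de(ds$expr, ds$meta, pk_rev, "control")
  expect_equal(r1$n_de, r2$n_de)
  expect_equal(r1$table$p, r2$table$p)
  expect_equal(r1$table$direction, -r2$table$direction)
})

test_that("n_de is monotone non-increasing as alpha decreases", {
  cfg <- simulation_config(n_control = 10, n_case = 10, n_genes = 100,
                           regions = c("BA9", "BA17"), gradient_fraction = 0.5,
                           gradient_effect_sd = 0.4, noise_sd = 0.4,
                           missing_rate = 0, seed = 97)
  ds <- generate_dataset(cfg)
  pk <- pair_key("BA9", "BA17", cfg$regions)
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  counts <- vapply(alphas, function(a) {
    count_de(ds$expr, ds$meta, pk, "control", alpha = a)$n_de
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fewer than two paired subjects is an infeasible comparison", {
  toy <- toy_two_region(matrix(1, 3, 2), matrix(2, 3, 2),
                        matrix(1, 3, 2), matrix(2, 3, 2))
  meta <- toy$meta[toy$meta$subject_id != "ctl02" |
                     toy$meta$region != "BA17", ]
  expr <- toy$expr[, meta$sample_id]
  pk <- pair_key("BA9", "BA17")
  expect_error(count_de(expr, meta, pk, "control"), "infeasible")
})
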