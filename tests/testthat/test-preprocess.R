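make_counts <- function(values, lengths = 1000) {
  m <- matrix(values, nrow = length(values) / 4, byrow = TRUE)
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  count_matrix(m, lengths)
}

test_that("cpm matches hand-computed column sums", {
  cm <- make_counts(c(10, 0, 5, 1,
                      0, 0, 0, 0,
                      30, 10, 5, 3,
                      60, 90, 90, 96))
  x <- cpm(cm)
  lib <- c(100, 100, 100, 100)
  expect_equal(x["g1", ], c(s1 = 1e5, s2 = 0, s3 = 5e4, s4 = 1e4))
  expect_equal(unname(x["g2", ]), rep(0, 4))
  expect_equal(colSums(x), c(s1 = 1e6, s2 = 1e6, s3 = 1e6, s4 = 1e6))
  # single gene, count 10, library 10 -> CPM 1e6
  one <- count_matrix(matrix(10, 1, 1, dimnames = list("g", "s")))
  expect_equal(as.vector(cpm(one)), 1e6)
})

test_that("cpm rejects an empty sample", {
  cm <- make_counts(c(1, 0, 1, 1,  0, 0, 0, 0,  2, 0, 2, 2,  1, 0, 1, 1))
  expect_error(cpm(cm), "empty sample")
})

test_that("filter_features retains exactly the hand-enumerated gene set", {
  # 10 samples each with library size 1e6 so CPM == count; the 0.1 CPM cutoff
  # at >= 30% of samples requires a count > 0.1 in ceil(3) = 3 samples
  n <- 10
  filler <- 1e6 - c(0, 1, 1, 1, 2, 5)  # per-gene row sums below, per column
  rows <- rbind(
    g_allzero = rep(0, n),                       # fails CPM everywhere
    g_two     = c(1, 1, rep(0, 8)),              # passes in only 2 samples
    g_three   = c(1, 1, 1, rep(0, 7)),           # exactly 3 -> retained
    g_short   = c(1, 1, 1, rep(0, 7)),           # passes CPM, 10 bp -> removed
    g_all     = rep(2, n),                       # retained
    g_big     = rep(5, n))                       # retained
  pad <- matrix(1e6, 1, n, dimnames = list("g_pad", NULL)) -
    matrix(colSums(rows), 1, n)
  m <- rbind(rows, g_pad = pad)
  colnames(m) <- sprintf("s%02d", 1:n)
  cm <- count_matrix(m, c(1000, 1000, 1000, 10, 1000, 1000, 1000))
  kept <- filter_features(cm)
  expect_identical(rownames(kept$counts),
                   c("g_three", "g_all", "g_big", "g_pad"))
  # idempotence
  again <- filter_features(kept)
  expect_identical(again$counts, kept$counts)
})

test_that("filter boundary semantics: strict CPM inequality, ceiling fraction", {
  # expected counts chosen so library size is exactly 1e6, hence CPM == count:
  # a gene sitting exactly at CPM 0.1 must NOT qualify (strict >)
  n <- 10
  m <- matrix(0, 2, n, dimnames = list(c("g_at", "g_ref"), sprintf("s%d", 1:n)))
  m["g_at", ] <- 0.1
  m["g_ref", ] <- 1e6 - 0.1
  kept <- filter_features(count_matrix(m))
  expect_identical(rownames(kept$counts), "g_ref")
})

test_that("log_normalize maps the documented anchor values and is monotone", {
  n <- 4
  m <- matrix(c(0, 0, 0, 0, 1.5, 1.5, 1.5, 1.5), 2, n, byrow = TRUE,
              dimnames = list(c("gz", "gp"), sprintf("s%d", 1:n)))
  m <- rbind(m, pad = 1e6 - colSums(m))
  cm <- count_matrix(m)
  x <- log_normalize(cm, prior = 0.5)
  expect_equal(unname(x["gz", ]), rep(-1, n))   # log2(0 + 0.5)
  expect_equal(unname(x["gp", ]), rep(1, n))    # log2(1.5 + 0.5)
  # monotonicity over random draws
  set.seed(5)
  cnt <- matrix(rpois(200, 20), 20, 10,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  lx <- log_normalize(count_matrix(cnt))
  cp <- cpm(count_matrix(cnt))
  for (j in 1:10) {
    expect_identical(order(cp[, j]), order(lx[, j]))
  }
})

test_that("outlier detection flags a planted noisy sample by both criteria", {
  set.seed(17)
  ng <- 200; n <- 20
  # samples share strong per-gene structure (as real expression data does),
  # so ordinary samples are highly intercorrelated
  gene_means <- rnorm(ng, 5, 2)
  base <- gene_means + matrix(rnorm(ng * n, 0, 0.5), ng, n)
  base[, 20] <- gene_means + rnorm(ng, 0, 6)   # one wild sample
  dimnames(base) <- list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:n))
  meta <- data.frame(sample_id = colnames(base),
                     subject_id = sprintf("sub%02d", 1:n),
                     region = "BA17",
                     diagnosis = rep(c("control", "case"), 10),
                     stringsAsFactors = FALSE)
  rep_out <- detect_outliers(base, meta)
  expect_true(rep_out$outlier[20])
  expect_false(any(rep_out$outlier[1:19]))

  # independent recomputation of both criteria
  xc <- base - rowMeans(base)
  sc <- prcomp(t(xc), center = FALSE)$x[, 1:10]
  z <- scale(sc)
  expect_equal(rep_out$max_abs_pc_z, unname(apply(abs(z), 1, max)),
               tolerance = 1e-8)
  a <- ((1 + bicor(base)) / 2)^2
  k <- rowSums(a) - diag(a)
  expect_equal(rep_out$z_k, unname((k - mean(k)) / sd(k)), tolerance = 1e-8)
  expect_true(rep_out$max_abs_pc_z[20] > 3 && rep_out$z_k[20] < -2)
})

test_that("a sample extreme on only one criterion is not flagged (AND rule)", {
  set.seed(23)
  ng <- 150; n <- 12
  x <- matrix(rnorm(ng * n), ng, n)
  # shift one sample along the mean direction: big PC z, connectivity intact
  x[, 5] <- x[, 5] + 0.8
  dimnames(x) <- list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:n))
  meta <- data.frame(sample_id = colnames(x),
                     subject_id = sprintf("sub%02d", 1:n),
                     region = "BA9", diagnosis = "control",
                     stringsAsFactors = FALSE)
  rep_out <- detect_outliers(x, meta)
  if (any(rep_out$max_abs_pc_z > 3)) {
    expect_false(any(rep_out$outlier & rep_out$z_k >= -2))
  }
  expect_false(rep_out$outlier[5] && rep_out$z_k[5] >= -2)
})

test_that("identical samples yield no outliers and order does not matter", {
  ng <- 50; n <- 8
  x <- matrix(rep(rnorm(ng), n), ng, n,
              dimnames = list(sprintf("g%d", 1:ng), sprintf("s%d", 1:n)))
  meta <- data.frame(sample_id = colnames(x),
                     subject_id = sprintf("sub%d", 1:n),
                     region = "BA7", diagnosis = "control",
                     stringsAsFactors = FALSE)
  rep_out <- suppressWarnings(detect_outliers(x, meta))
  expect_false(any(rep_out$outlier))

  # ordering invariance on a random group
  set.seed(29)
  y <- matrix(rnorm(ng * 15), ng, 15,
              dimnames = list(sprintf("g%d", 1:ng), sprintf("t%02d", 1:15)))
  meta2 <- data.frame(sample_id = colnames(y),
                      subject_id = sprintf("u%02d", 1:15),
                      region = "BA7", diagnosis = "control",
                      stringsAsFactors = FALSE)
  r1 <- detect_outliers(y, meta2)
  perm <- sample(15)
  r2 <- detect_outliers(y[, perm], meta2[perm, ])
  expect_equal(r1$outlier[perm], r2$outlier)
  expect_equal(r1$z_k[perm], r2$z_k, tolerance = 1e-10)
})

test_that("regression with no nuisance effects is the identity", {
  cfg <- simulation_config(n_control = 4, n_case = 4, n_genes = 15,
                           regions = c("BA9", "BA7", "BA17"),
                           missing_rate = 0, seed = 61)
  ds <- generate_dataset(cfg)
  meta <- ds$meta[, c("sample_id", "subject_id", "region", "diagnosis")]
  out <- regress_covariates(ds$expr, meta)
  expect_equal(unclass(out)[, ], ds$expr, tolerance = 1e-12)
  expect_identical(attr(out, "removed_covariates"), character(0))
})

test_that("a planted batch effect is removed; diagnosis contrast preserved", {
  cfg <- simulation_config(n_control = 8, n_case = 8, n_genes = 12,
                           regions = c("BA9", "BA7", "BA17"),
                           missing_rate = 0, noise_sd = 0.3,
                           gradient_fraction = 0.5,
                           covariate_effects = list(batch = 1.0), seed = 67)
  ds <- generate_dataset(cfg)
  x <- as.numeric(ds$meta$batch != "b1")
  out <- regress_covariates(ds$expr, ds$meta, nuisance = "batch")
  # post-regression correlation with batch ~ 0 for every gene
  cor_post <- apply(out, 1, function(y) cor(y, x))
  cor_pre <- apply(ds$expr, 1, function(y) cor(y, x))
  expect_lt(max(abs(cor_post)), 0.25)
  expect_gt(max(abs(cor_pre)), 0.5)

  # the diagnosis group contrast is untouched within estimation tolerance
  fc_post <- compute_log2fc(out, ds$meta)
  fc_pre <- compute_log2fc(ds$expr, ds$meta)
  expect_equal(unname(fc_post), unname(fc_pre), tolerance = 0.35)
})

test_that("joint permutation of samples and covariates relabels the output", {
  cfg <- simulation_config(n_control = 5, n_case = 5, n_genes = 8,
                           regions = c("BA9", "BA17"), missing_rate = 0,
                           covariate_effects = list(batch = 0.8), seed = 71)
  ds <- generate_dataset(cfg)
  out1 <- regress_covariates(ds$expr, ds$meta, nuisance = "batch")
  perm <- sample(ncol(ds$expr))
  out2 <- regress_covariates(ds$expr[, perm], ds$meta[perm, ],
                             nuisance = "batch")
  expect_equal(unclass(out1)[, perm], unclass(out2)[, ], tolerance = 1e-8)
})

test_that("collinear covariates are named in the singular-design error", {
  cfg <- simulation_config(n_control = 3, n_case = 3, n_genes = 4,
                           regions = c("BA9", "BA17"), missing_rate = 0,
                           seed = 73)
  ds <- generate_dataset(cfg)
  ds$meta$dup <- ds$meta$age            # exact copy -> collinear
  expect_error(regress_covariates(ds$expr, ds$meta,
                                  nuisance = c("age", "dup")),
               "collinear")
})
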