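# Independent oracles used across the suite. These deliberately share no code
# with the package: brute-force enumeration and direct arithmetic only.

# two-sided signed-rank p by full enumeration of all 2^n sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# brute-force BH step-up with monotone enforcement
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# BH rejection count by definition
brute_bh_count <- function(p, alpha) sum(brute_bh(p) < alpha)

# DE count oracle on a paired-difference matrix: per-gene enumeration p,
# brute-force BH, count q < alpha (requires few nonzero diffs per gene)
oracle_de_count <- function(d, alpha = 0.05) {
  p <- apply(d, 1, enum_signed_rank_p)
  brute_bh_count(p, alpha)
}

# orthogonal-residual sum of squares for a line through angle theta
oracle_tls_slope <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  oss <- function(theta) {
    # unit normal to the line of angle theta
    nx <- -sin(theta); ny <- cos(theta)
    sum((xc * nx + yc * ny)^2)
  }
  opt <- stats::optimize(oss, c(-pi / 2 + 1e-9, pi / 2 - 1e-9), tol = 1e-12)
  tan(opt$minimum)
}

# a tiny two-region cohort built by hand: `k` subjects per group, expression
# for one pair of regions given as genes x subjects matrices
toy_two_region <- function(ctl_a, ctl_b, case_a, case_b,
                           regions = c("BA9", "BA17")) {
  ng <- nrow(ctl_a)
  gene_ids <- sprintf("g%03d", seq_len(ng))
  subj_c <- sprintf("ctl%02d", seq_len(ncol(ctl_a)))
  subj_a <- sprintf("case%02d", seq_len(ncol(case_a)))
  blocks <- list(list(subj_c, regions[1], "control", ctl_a),
                 list(subj_c, regions[2], "control", ctl_b),
                 list(subj_a, regions[1], "case", case_a),
                 list(subj_a, regions[2], "case", case_b))
  meta <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(sample_id = paste(b[[1]], gsub("/", ".", b[[2]]), sep = "_"),
               subject_id = b[[1]], region = b[[2]], diagnosis = b[[3]],
               age = 30, sex = "M", batch = "b1", stringsAsFactors = FALSE)
  }))
  expr <- do.call(cbind, lapply(blocks, function(b) b[[4]]))
  dimnames(expr) <- list(gene_ids, meta$sample_id)
  list(expr = expr, meta = meta)
}
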