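test_that("MAF filtering uses a strict bound on the minor allele", {
  G <- matrix(0, 100, 4, dimnames = list(paste0("h", 1:100), paste0("s", 1:4)))
  G[1:4, 1] <- 1     # freq 0.04 -> dropped
  G[1:50, 2] <- 1    # freq 0.50 -> retained
  G[1:5, 3] <- 1     # freq 0.05 exactly -> dropped (strict >)
  G[1:96, 4] <- 1    # freq 0.96 -> MAF 0.04 -> dropped
  kept <- maf_filter(G, 0.05)
  expect_equal(colnames(kept), "s2")
  expect_equal(attr(kept, "maf"), c(s2 = 0.5))
  G[, 1] <- NA
  expect_warning(maf_filter(G), "all-missing")
})

test_that("single-marker OLS matches closed form and lm on small data", {
  y <- c(1, 2, 3, 4)
  G <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(NULL, "s"))
  res <- associate(y, G)
  expect_equal(res$beta, 2.0)
  fit <- lm(y ~ G[, 1])
  expect_equal(unname(coef(fit)[1]), 1.5)
  expect_equal(res$p_value, summary(fit)$coefficients[2, 4], tolerance = 1e-12)

  # equivalence on 100 random datasets to 1e-10
  set.seed(202)
  for (r in 1:100) {
    n <- sample(6:25, 1)
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (var(x) == 0) next
    yy <- rnorm(n) + runif(1, -2, 2) * x
    rr <- associate(yy, matrix(x, n, 1, dimnames = list(NULL, "s")))
    sm <- summary(lm(yy ~ x))$coefficients
    expect_equal(rr$beta, sm[2, 1], tolerance = 1e-10)
    expect_equal(rr$se, sm[2, 2], tolerance = 1e-10)
    expect_equal(rr$p_value, sm[2, 4], tolerance = 1e-10)
  }
})

test_that("degenerate fits follow the stated conventions", {
  G <- matrix(c(0, 0, 1, 1, 0, 1), 6, 1, dimnames = list(NULL, "s"))
  # constant phenotype: no effect, p = 1
  res <- associate(rep(3, 6), G)
  expect_equal(res$beta, 0)
  expect_equal(res$p_value, 1)
  # perfect fit: p below any practical threshold
  x <- rep(c(0, 1), each = 5)
  res2 <- associate(x * 1.0, matrix(x, 10, 1, dimnames = list(NULL, "s")))
  expect_lt(res2$p_value, 1e-10)
  # zero-variance SNP is skipped and recorded
  Gz <- cbind(G, z = 0)
  res3 <- associate(c(1, 2, 3, 4, 5, 6), Gz)
  expect_true(is.na(res3$beta[2]))
  expect_equal(attr(res3, "skipped"), "z")
  expect_error(associate(1:2, G[1:2, , drop = FALSE]), "at least 3")
})

test_that("missing genotypes are mean-imputed and high-missingness SNPs dropped", {
  set.seed(33)
  n <- 50
  x <- rbinom(n, 1, 0.5)
  y <- x + rnorm(n, 0, 0.5)
  G <- cbind(a = x, b = x)
  G[1:2, "a"] <- NA              # 4% missing: imputed
  G[1:10, "b"] <- NA             # 20% missing: dropped
  res <- associate(y, G)
  expect_equal(res$snp, "a")
  xi <- G[, "a"]
  xi[is.na(xi)] <- mean(xi, na.rm = TRUE)
  sm <- summary(lm(y ~ xi))$coefficients
  expect_equal(res$beta, sm[2, 1], tolerance = 1e-10)
})

test_that("covariate adjustment equals the joint-model partial t-test", {
  set.seed(44)
  n <- 80
  q <- matrix(rnorm(2 * n), n, 2)
  x <- rbinom(n, 1, 0.4)
  y <- 0.5 * x + q %*% c(1, -1) + rnorm(n)
  res <- associate(as.numeric(y), matrix(x, n, 1, dimnames = list(NULL, "s")),
                   covariates = q)
  sm <- summary(lm(y ~ q + x))$coefficients
  expect_equal(res$beta, sm["x", 1], tolerance = 1e-10)
  expect_equal(res$se, sm["x", 2], tolerance = 1e-10)
  expect_equal(res$p_value, sm["x", 4], tolerance = 1e-10)
})

test_that("the significance line is inclusive at -log10(p) = 5", {
  res <- data.frame(snp = c("a", "b", "c"),
                    p_value = c(1e-5, 1.1e-5, 0.5))
  hits <- significant_hits(res, 5)
  expect_equal(hits$snp, "a")
  expect_equal(hits$neg_log10_p, 5)
  # null expectation: with uniform p at 2000 SNPs, hits are essentially absent
  set.seed(55)
  null_res <- data.frame(snp = paste0("s", 1:2000), p_value = runif(2000))
  expect_lte(nrow(significant_hits(null_res, 5)), 1)
})

test_that("genomic-control lambda is calibrated, directional and order-invariant", {
  set.seed(66)
  p <- runif(1e5)
  res <- data.frame(p_value = p)
  qi <- qq_inflation(res)
  expect_gt(qi$lambda, 0.97)
  expect_lt(qi$lambda, 1.03)
  expect_equal(nrow(qi$qq), 1e5)
  # halving all p-values inflates lambda above 1
  expect_gt(qq_inflation(data.frame(p_value = p / 2))$lambda, 1)
  expect_equal(qq_inflation(data.frame(p_value = rev(p)))$lambda, qi$lambda)
})

test_that("covariates deflate lambda on structured fixtures", {
  lambdas <- vapply(1:10, function(r) {
    cfg <- simulation_config(n_hosts = 150, n_bacteria = 2, n_fungi = 2,
                             n_snps = 400, n_subpops = 3, divergence = 0.25,
                             seed = 700 + r)
    G <- simulate_genotypes(cfg)
    sub <- attr(G, "subpop")
    y <- 0.8 * sub + rnorm(150)          # phenotype tracks structure
    res_raw <- associate(y, G)
    qcov <- stats::model.matrix(~ factor(sub))[, -1, drop = FALSE]
    res_adj <- associate(y, G, covariates = qcov)
    qq_inflation(res_raw)$lambda - qq_inflation(res_adj)$lambda
  }, numeric(1))
  expect_gt(mean(lambdas), 0)
})

test_that("heritability conventions: single-SNP R2, joint R2, ridge fallback", {
  # no hits -> total h2 = 0
  y <- rnorm(20)
  G <- matrix(rbinom(20 * 3, 1, 0.5), 20, 3, dimnames = list(NULL, paste0("s", 1:3)))
  h0 <- snp_heritability(y, data.frame(snp = character(0)), G)
  expect_equal(h0$total, 0)
  # noiseless y = x: per-SNP h2 = 1
  x <- rep(c(0, 1), 10)
  Gx <- matrix(x, 20, 1, dimnames = list(NULL, "s1"))
  h1 <- snp_heritability(x * 1.0, data.frame(snp = "s1"), Gx)
  expect_equal(h1$per_snp$h2, 1, tolerance = 1e-12)
  expect_equal(h1$total, 1, tolerance = 1e-12)
  # variance ratio 1:3 -> expected R2 = 0.25
  set.seed(77)
  n <- 1e4
  xx <- rbinom(n, 1, 0.5)
  beta <- 1
  noise_sd <- sqrt(3) * sqrt(var(xx) * beta^2)
  yy <- beta * xx + rnorm(n, 0, sqrt(3 * beta^2 * 0.25))
  h2 <- snp_heritability(yy, data.frame(snp = "s1"),
                         matrix(xx, n, 1, dimnames = list(NULL, "s1")))
  expect_gt(h2$per_snp$h2, 0.22)
  expect_lt(h2$per_snp$h2, 0.28)
  # more hits than hosts triggers the flagged ridge path with bounded R2
  set.seed(78)
  Gm <- matrix(rbinom(10 * 12, 1, 0.5), 10, 12,
               dimnames = list(NULL, paste0("s", 1:12)))
  hr <- snp_heritability(rnorm(10), data.frame(snp = paste0("s", 1:12)), Gm)
  expect_true(hr$ridge)
  expect_gte(hr$total, 0)
  expect_lte(hr$total, 1)
})

test_that("gwas_scan ties the stages together over an index table", {
  sim <- tiny_study(seed = 91, n_hosts = 40, n_otus_per_kingdom = 6,
                    n_snps = 60)
  it <- index_table(sim$abundance, sim$taxonomy)
  scan <- gwas_scan(it[, 1:4], sim$genotypes)
  expect_equal(length(scan), 3)
  expect_true(all(vapply(scan, function(s) is.finite(s$lambda), logical(1))))
  expect_true(all(vapply(scan, function(s) all(s$result$maf > 0.05), logical(1))))
})
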